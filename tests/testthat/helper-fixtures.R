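# shared test helpers: tiny atom tables, rigid motions, toy profiles

atom_row <- function(element, x, y, z, residue_index = 1L,
                     residue_name = "UNK", chain_id = "A",
                     atom_name = element) {
  data.frame(atom_name = atom_name, element = element, x = x, y = y, z = z,
             residue_index = residue_index, residue_name = residue_name,
             chain_id = chain_id, occupancy = 1, altloc = "",
             stringsAsFactors = FALSE)
}

single_atom <- function(element = "C") atom_row(element, 0, 0, 0)

# rotation matrix about an axis (unit vector) by angle degrees
rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

apply_rigid_motion <- function(model, axis = c(1, 2, 3), angle = 35,
                               translation = c(5, -3, 11)) {
  R <- rotation_matrix(axis, angle)
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(R)
  model$atoms$x <- xyz[, 1] + translation[1]
  model$atoms$y <- xyz[, 2] + translation[2]
  model$atoms$z <- xyz[, 3] + translation[3]
  model
}

toy_profile <- function(values, positions = seq_along(values),
                        units = "scaled", id = "toy") {
  accessibility_profile(positions, values, units = units, id = id)
}

# dihedral profile from explicit angle vectors (for formula spot-checks)
toy_dihedrals <- function(phi, psi) {
  out <- data.frame(residue_index = seq_along(phi),
                    residue_name = "ALA", phi = phi, psi = psi)
  class(out) <- c("dihedral_profile", "data.frame")
  out
}

# independent cross product (oracle for dihedral sign checks)
cross_oracle <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# dodecahedron vertices (20 points) on the unit sphere
dodecahedron_vertices <- function() {
  g <- (1 + sqrt(5)) / 2
  v <- rbind(
    expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1)),
    data.frame(x = 0, y = c(-1, -1, 1, 1) / g, z = c(-g, g, -g, g)),
    data.frame(x = c(-1, -1, 1, 1) / g, y = c(-g, g, -g, g), z = 0),
    data.frame(x = c(-g, g, -g, g), y = 0, z = c(-1, -1, 1, 1) / g)
  )
  as.matrix(v) / sqrt(3)
}
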