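#' Signed torsion (dihedral) angle of four points
#'
#' Computes the signed dihedral angle of the chain `p1-p2-p3-p4` in degrees,
#' using the standard `atan2` construction. The sign follows the usual
#' biochemical convention (IUPAC): looking down the `p2 -> p3` axis, a
#' clockwise rotation of `p4` relative to `p1` is positive.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors, coordinates in Angstrom.
#' @return Angle in degrees in `(-180, 180]`.
#' @examples
#' dihedral(c(1, 1, 0), c(0, 0, 0), c(0, 0, 1), c(1, -1, 1)) # ~ -90
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (sum(b2^2) == 0) stop("dihedral undefined: p2 and p3 coincide")
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20) {
    stop("dihedral undefined: three consecutive points are collinear")
  }
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2) / sqrt(sum(b2^2))
  wrap_angle(atan2(y, x) * 180 / pi)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# map any angle in degrees into (-180, 180]
wrap_angle <- function(x) {
  y <- x - 360 * round(x / 360)
  y[y <= -180] <- y[y <= -180] + 360
  y[y > 180] <- y[y > 180] - 360
  y
}

#' Backbone phi/psi dihedral profile of a chain
#'
#' Extracts per-residue backbone torsion angles from a parsed structure chain.
#' `phi_i` is the torsion of `C(i-1)-N(i)-CA(i)-C(i)`, `psi_i` the torsion of
#' `N(i)-CA(i)-C(i)-N(i+1)`. Angles are `NA` where a flanking residue or a
#' backbone atom is missing (first residue has no phi, last no psi).
#'
#' @param model A `snowflake_structure` from [parse_pdb()] or [make_backbone()].
#' @param chain_id Chain identifier; defaults to the first chain.
#' @return A data frame of class `dihedral_profile` with columns
#'   `residue_index`, `residue_name`, `phi`, `psi` (degrees).
#' @export
backbone_dihedrals <- function(model, chain_id = NULL) {
  atoms <- chain_atoms(model, chain_id)
  idx <- sort(unique(atoms$residue_index))
  n <- length(idx)
  get_atom <- function(res, name) {
    a <- atoms[atoms$residue_index == res & atoms$atom_name == name, , drop = FALSE]
    if (nrow(a) == 0) return(NULL)
    c(a$x[1], a$y[1], a$z[1])
  }
  phi <- rep(NA_real_, n)
  psi <- rep(NA_real_, n)
  rname <- character(n)
  for (k in seq_len(n)) {
    i <- idx[k]
    rname[k] <- atoms$residue_name[atoms$residue_index == i][1]
    N <- get_atom(i, "N"); CA <- get_atom(i, "CA"); CC <- get_atom(i, "C")
    if (is.null(N) || is.null(CA) || is.null(CC)) next
    if (k > 1 && (idx[k - 1] == i - 1)) {
      Cprev <- get_atom(i - 1, "C")
      if (!is.null(Cprev)) phi[k] <- dihedral(Cprev, N, CA, CC)
    }
    if (k < n && (idx[k + 1] == i + 1)) {
      Nnext <- get_atom(i + 1, "N")
      if (!is.null(Nnext)) psi[k] <- dihedral(N, CA, CC, Nnext)
    }
  }
  out <- data.frame(residue_index = idx, residue_name = rname,
                    phi = phi, psi = psi, stringsAsFactors = FALSE)
  class(out) <- c("dihedral_profile", "data.frame")
  out
}

#' Difference between two angles
#'
#' With `wrap = TRUE` (default) returns the minimal signed difference in
#' `(-180, 180]`, so 179 vs -179 differ by 2 degrees, not 358. With
#' `wrap = FALSE` returns the raw difference `a - b`.
#'
#' @param a,b Angles in degrees.
#' @param wrap Wrap the difference across the +/-180 seam?
#' @return Difference in degrees.
#' @export
angular_difference <- function(a, b, wrap = TRUE) {
  d <- a - b
  if (wrap) wrap_angle(d) else d
}

# align two dihedral profiles on shared, fully-defined positions.
# position_map: NULL (match residue_index) or a two-column matrix/data.frame
# of (index_a, index_b) pairs.
paired_dihedrals <- function(profile_a, profile_b, position_map = NULL) {
  if (is.null(position_map)) {
    shared <- intersect(profile_a$residue_index, profile_b$residue_index)
    position_map <- cbind(shared, shared)
  }
  position_map <- as.matrix(position_map)
  ia <- match(position_map[, 1], profile_a$residue_index)
  ib <- match(position_map[, 2], profile_b$residue_index)
  ok <- !is.na(ia) & !is.na(ib)
  ia <- ia[ok]; ib <- ib[ok]
  def <- !is.na(profile_a$phi[ia]) & !is.na(profile_a$psi[ia]) &
    !is.na(profile_b$phi[ib]) & !is.na(profile_b$psi[ib])
  list(
    position = profile_a$residue_index[ia][def],
    phi_a = profile_a$phi[ia][def], psi_a = profile_a$psi[ia][def],
    phi_b = profile_b$phi[ib][def], psi_b = profile_b$psi[ib][def],
    skipped = profile_a$residue_index[ia][!def]
  )
}

#' Position-specific squared dihedral-angle difference (SDA)
#'
#' For each paired position `i`, `SDA_i = (phi_ai - phi_bi)^2 +
#' (psi_ai - psi_bi)^2` in squared degrees. Positions lacking either angle in
#' either profile are skipped and reported in the `skipped` attribute.
#'
#' @param profile_a,profile_b Dihedral profiles from [backbone_dihedrals()].
#' @param position_map Optional two-column pairing of residue indices
#'   (a-index, b-index); by default positions are matched by residue index.
#' @param wrap Wrap angle differences across the +/-180 seam (default TRUE).
#' @return Data frame with columns `position`, `sda`; attribute `skipped`
#'   lists positions excluded for missing angles.
#' @export
sda <- function(profile_a, profile_b, position_map = NULL, wrap = TRUE) {
  p <- paired_dihedrals(profile_a, profile_b, position_map)
  if (length(p$position) == 0) stop("no overlapping positions with defined phi and psi")
  dphi <- angular_difference(p$phi_a, p$phi_b, wrap)
  dpsi <- angular_difference(p$psi_a, p$psi_b, wrap)
  out <- data.frame(position = p$position, sda = dphi^2 + dpsi^2)
  attr(out, "skipped") <- p$skipped
  out
}

#' Root mean squared dihedral-angle difference (RMSDA)
#'
#' `RMSDA = sqrt( (1/(2n)) * sum_i [ (phi_ai - phi_bi)^2 + (psi_ai - psi_bi)^2 ] )`
#' over the `n` shared positions with defined angles — an average over the
#' `2n` individual angle pairs, reported in degrees. Being built from torsion
#' angles only, it requires no superimposition of the two structures and local
#' differences do not propagate along the chain.
#'
#' @inheritParams sda
#' @return RMSDA in degrees (scalar).
#' @export
rmsda <- function(profile_a, profile_b, position_map = NULL, wrap = TRUE) {
  s <- sda(profile_a, profile_b, position_map, wrap)
  sqrt(sum(s$sda) / (2 * nrow(s)))
}
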