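#' Default van der Waals radii (Angstrom)
#'
#' Radii used by [shrake_rupley()] when none are supplied. Hydrogens are
#' excluded from the computation by default (crystal structures usually lack
#' them); the H radius is listed for callers that opt in.
#' @export
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20)

#' Quasi-uniform points on the unit sphere
#'
#' Golden-spiral (Fibonacci lattice) construction: deterministic for fixed
#' `n`, with near-uniform areal density. These are the test directions of the
#' Shrake-Rupley algorithm.
#'
#' @param n Number of points (>= 12).
#' @return `n x 3` matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  if (n < 12) stop("n must be >= 12")
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  phi <- golden * (seq_len(n) - 1)
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Solvent-accessible surface area by the Shrake-Rupley algorithm
#'
#' For each atom, `n_points` test points are placed on a sphere of radius
#' `r_vdw + probe` and each point is checked for occlusion by any neighbouring
#' atom's expanded sphere; the accessible fraction times the expanded sphere
#' area is the atom's SASA. Numerically this rolls a water-sized marble over
#' the structure and records where it touches. Neighbour search uses a spatial
#' grid with cell size `2 * max(r_vdw + probe)` (set `grid = FALSE` for the
#' brute-force all-pairs search; results are identical).
#'
#' @param atoms Either a `snowflake_structure` or its `atoms` data frame.
#' @param probe Probe radius in Angstrom (default 1.4, the size of a water
#'   molecule).
#' @param n_points Test points per atom (default 960).
#' @param radii Named vector of van der Waals radii per element
#'   (default [VDW_RADII]).
#' @param include_h Include hydrogens (default FALSE).
#' @param grid Use the grid-accelerated neighbour search (default TRUE).
#' @return Object of class `sasa_result`: the `atoms` data frame with an
#'   `area` column (Angstrom^2), plus the computation context.
#' @export
shrake_rupley <- function(atoms, probe = 1.4, n_points = 960,
                          radii = VDW_RADII, include_h = FALSE, grid = TRUE) {
  if (inherits(atoms, "snowflake_structure")) atoms <- atoms$atoms
  stopifnot(probe > 0)
  if (!include_h) atoms <- atoms[atoms$element != "H", , drop = FALSE]
  if (nrow(atoms) == 0) stop("no atoms to compute SASA for")
  unknown <- setdiff(unique(atoms$element), names(radii))
  if (length(unknown) > 0) {
    stop("no van der Waals radius for element(s): ", paste(unknown, collapse = ", "))
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rad <- unname(radii[atoms$element]) + probe
  pts <- sphere_points(n_points)
  n <- nrow(xyz)

  neighbors <- if (grid) grid_neighbors(xyz, rad) else {
    lapply(seq_len(n), function(i) setdiff(seq_len(n), i))
  }

  area <- numeric(n)
  for (i in seq_len(n)) {
    cand <- neighbors[[i]]
    if (length(cand) > 0) {
      d2 <- (xyz[cand, 1] - xyz[i, 1])^2 + (xyz[cand, 2] - xyz[i, 2])^2 +
        (xyz[cand, 3] - xyz[i, 3])^2
      cand <- cand[d2 < (rad[i] + rad[cand])^2 & d2 > 0]
    }
    p <- pts * rad[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in cand) {
      if (!any(free)) break
      dj2 <- (p[free, 1] - xyz[j, 1])^2 + (p[free, 2] - xyz[j, 2])^2 +
        (p[free, 3] - xyz[j, 3])^2
      free[free] <- dj2 >= rad[j]^2
    }
    area[i] <- 4 * pi * rad[i]^2 * sum(free) / n_points
  }
  out <- list(atoms = cbind(atoms, area = area),
              probe = probe, n_points = n_points,
              context = unique(atoms$chain_id))
  class(out) <- "sasa_result"
  out
}

# spatial-grid candidate neighbours; cell size = max expanded diameter so
# touching spheres are always within the 27-cell stencil
grid_neighbors <- function(xyz, rad) {
  n <- nrow(xyz)
  cell <- 2 * max(rad)
  key <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / cell)
  kstr <- paste(key[, 1], key[, 2], key[, 3], sep = ",")
  buckets <- split(seq_len(n), kstr)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  lapply(seq_len(n), function(i) {
    kk <- sweep(offs, 2, key[i, ], "+")
    cand <- unlist(buckets[paste(kk[, 1], kk[, 2], kk[, 3], sep = ",")],
                   use.names = FALSE)
    cand[cand != i]
  })
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("<sasa_result> %d atoms, probe %.2f A, %d points, total %.1f A^2\n",
              nrow(x$atoms), x$probe, x$n_points, sum(x$atoms$area)))
  invisible(x)
}

#' Per-residue solvent accessibility of one chain
#'
#' Sums per-atom areas over each residue of `target_chain`. The SASA run must
#' have included every chain that should shadow the target (for HLA: alpha
#' chain, beta-2-microglobulin and the bound peptide simultaneously), so that
#' residues buried under a partner chain come out with small areas.
#'
#' @param result A `sasa_result` from [shrake_rupley()].
#' @param target_chain Chain id whose residues to report.
#' @param position_map Optional [map_residues_to_positions()] result; when
#'   given, positions are translated into the allele frame and unmapped
#'   residues dropped.
#' @return An `accessibility_profile` data frame: `position`, `residue`,
#'   `value` (Angstrom^2), with `units = "raw_A2"`.
#' @export
residue_sasa <- function(result, target_chain, position_map = NULL) {
  at <- result$atoms[result$atoms$chain_id == target_chain, , drop = FALSE]
  if (nrow(at) == 0) stop("chain '", target_chain, "' absent from SASA result")
  agg <- stats::aggregate(area ~ residue_index + residue_name, data = at, FUN = sum)
  agg <- agg[order(agg$residue_index), ]
  pos <- agg$residue_index
  keep <- rep(TRUE, length(pos))
  if (!is.null(position_map)) {
    m <- position_map$mapping
    keep <- as.character(pos) %in% names(m)
    pos[keep] <- m[as.character(pos[keep])]
  }
  aa <- bio3d::aa321(agg$residue_name)
  aa[is.na(aa)] <- "X"
  accessibility_profile(position = pos[keep], value = agg$area[keep],
                        residue = aa[keep], units = "raw_A2",
                        id = target_chain)
}

#' Construct an accessibility profile
#'
#' Per-position solvent-accessibility values for one allele or one structure
#' chain, either raw areas in Angstrom^2 (`units = "raw_A2"`) or scores scaled
#' to `[0, 1]` (`units = "scaled"`, 0 inaccessible, 1 exposed).
#'
#' @param position Strictly increasing integer positions (1-based,
#'   mature-protein frame for alleles).
#' @param value Accessibility values.
#' @param residue Optional one-letter residues.
#' @param units `"raw_A2"` or `"scaled"`.
#' @param id Allele name or structure/chain identifier.
#' @return Data frame of class `accessibility_profile`.
#' @export
accessibility_profile <- function(position, value, residue = NA_character_,
                                  units = c("scaled", "raw_A2"), id = "") {
  units <- match.arg(units)
  ord <- order(position)
  position <- position[ord]; value <- value[ord]
  if (length(residue) > 1) residue <- residue[ord]
  if (any(diff(position) <= 0)) stop("positions must be strictly increasing")
  out <- data.frame(position = as.integer(position), residue = residue,
                    value = value, stringsAsFactors = FALSE)
  attr(out, "units") <- units
  attr(out, "id") <- id
  class(out) <- c("accessibility_profile", "data.frame")
  out
}

profile_units <- function(profile) attr(profile, "units")

# shared positions of two profiles (or an explicit pairing)
paired_values <- function(profile_a, profile_b, position_map = NULL) {
  if (is.null(position_map)) {
    shared <- intersect(profile_a$position, profile_b$position)
    position_map <- cbind(shared, shared)
  }
  position_map <- as.matrix(position_map)
  ia <- match(position_map[, 1], profile_a$position)
  ib <- match(position_map[, 2], profile_b$position)
  ok <- !is.na(ia) & !is.na(ib)
  if (!any(ok)) stop("no shared positions between profiles")
  list(position = profile_a$position[ia[ok]],
       a = profile_a$value[ia[ok]], b = profile_b$value[ib[ok]])
}

#' Position-specific squared surface-area difference (SSA)
#'
#' `SSA_i = (SA_ai - SA_bi)^2` over shared positions, in Angstrom^4 for raw
#' profiles.
#'
#' @param profile_a,profile_b Accessibility profiles on a common frame.
#' @param position_map Optional two-column pairing of positions.
#' @return Data frame with columns `position`, `ssa`.
#' @export
ssa <- function(profile_a, profile_b, position_map = NULL) {
  p <- paired_values(profile_a, profile_b, position_map)
  data.frame(position = p$position, ssa = (p$a - p$b)^2)
}

#' Root mean squared surface-area difference (RMSSA)
#'
#' `RMSSA = sqrt( (1/n) * sum_i (SA_ai - SA_bi)^2 )` over the `n` shared
#' positions — the functional surface-distance counterpart of [rmsda()].
#'
#' @inheritParams ssa
#' @return Scalar, in the units of the profiles (Angstrom^2 for raw areas).
#' @export
rmssa <- function(profile_a, profile_b, position_map = NULL) {
  s <- ssa(profile_a, profile_b, position_map)
  sqrt(mean(s$ssa))
}

#' Write accessibility profiles as TSV
#'
#' Columns `id`, `position`, `residue`, `score`; scores are written with six
#' decimals so reruns produce byte-identical files.
#'
#' @param profiles An `accessibility_profile` or a list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profiles, path) {
  if (inherits(profiles, "accessibility_profile")) profiles <- list(profiles)
  df <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(id = attr(p, "id"), position = p$position, residue = p$residue,
               score = sprintf("%.6f", p$value), stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read accessibility profiles from TSV
#'
#' Inverse of [write_profile_tsv()].
#'
#' @param path TSV with columns `id`, `position`, `residue`, `score`.
#' @param units Units flag to attach (default `"scaled"`).
#' @return Named list of `accessibility_profile`s, keyed by `id`.
#' @export
read_profiles_tsv <- function(path, units = "scaled") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "position", "residue", "score")
  if (!all(need %in% names(df))) {
    stop("profile TSV needs columns: ", paste(need, collapse = ", "))
  }
  lapply(split(df, df$id), function(d) {
    accessibility_profile(d$position, d$score, residue = d$residue,
                          units = units, id = d$id[1])
  })
}
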