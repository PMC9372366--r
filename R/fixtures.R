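# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# NeRF atom placement: position D such that |CD| = r, angle(B,C,D) = theta
# (degrees) and dihedral(A,B,C,D) = tau (degrees)
place_atom <- function(A, B, C, r, theta, tau) {
  theta <- theta * pi / 180
  tau <- tau * pi / 180
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- cross3(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d2 <- c(-r * cos(theta), r * sin(theta) * cos(tau), r * sin(theta) * sin(tau))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

# ideal peptide geometry (Angstrom / degrees)
BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N <- 1.329
BOND_C_O <- 1.231
ANGLE_N_CA_C <- 111.2
ANGLE_CA_C_N <- 116.6
ANGLE_C_N_CA <- 121.7
ANGLE_CA_C_O <- 120.1
OMEGA_TRANS <- 180

#' Build a backbone structure with specified phi/psi angles
#'
#' Constructs a backbone (N, CA, C, O atoms) by successive NeRF placement with
#' ideal bond lengths and angles, planar trans peptide bonds (omega = 180) and
#' the requested `(phi, psi)` at every residue where the angle is defined.
#' Serves as the geometric oracle for dihedral extraction: angles put in must
#' come back out.
#'
#' @param n_res Number of residues (>= 3); ignored when `sequence` is given.
#' @param phi,psi Backbone torsions in degrees, recycled along the chain.
#' @param sequence Optional one-letter amino-acid string naming the residues
#'   (backbone atoms only are generated); defaults to poly-alanine.
#' @param chain_id Chain identifier (default `"A"`).
#' @param offset Numeric 3-vector added to all coordinates.
#' @param path Optional file path; when given the model is also written as PDB.
#' @return A `snowflake_structure`.
#' @export
make_backbone <- function(n_res = NULL, phi = -57, psi = -47, sequence = NULL,
                          chain_id = "A", offset = c(0, 0, 0), path = NULL) {
  if (is.null(sequence)) {
    if (is.null(n_res) || n_res < 3) stop("n_res must be >= 3")
    aa3 <- rep("ALA", n_res)
  } else {
    aa1 <- strsplit(toupper(sequence), "")[[1]]
    n_res <- length(aa1)
    if (n_res < 3) stop("sequence must have >= 3 residues")
    aa3 <- vapply(aa1, function(a) {
      hit <- STANDARD_AA3[bio3d::aa321(STANDARD_AA3) == a]
      if (length(hit) == 0) "ALA" else hit[1]
    }, character(1))
  }
  phi <- rep_len(phi, n_res)
  psi <- rep_len(psi, n_res)

  coords <- matrix(NA_real_, nrow = 4 * n_res, ncol = 3)
  names_v <- character(4 * n_res)
  resi <- integer(4 * n_res)
  row <- 0L
  put <- function(name, res, xyz) {
    row <<- row + 1L
    coords[row, ] <<- xyz
    names_v[row] <<- name
    resi[row] <<- res
  }
  t1 <- ANGLE_N_CA_C * pi / 180
  N <- c(0, 0, 0)
  CA <- c(BOND_N_CA, 0, 0)
  CC <- CA + BOND_CA_C * c(-cos(t1), sin(t1), 0)
  put("N", 1L, N); put("CA", 1L, CA); put("C", 1L, CC)
  put("O", 1L, place_atom(N, CA, CC, BOND_C_O, ANGLE_CA_C_O, psi[1] + 180))
  for (i in 2:n_res) {
    Nn <- place_atom(N, CA, CC, BOND_C_N, ANGLE_CA_C_N, psi[i - 1])
    CAn <- place_atom(CA, CC, Nn, BOND_N_CA, ANGLE_C_N_CA, OMEGA_TRANS)
    Cn <- place_atom(CC, Nn, CAn, BOND_CA_C, ANGLE_N_CA_C, phi[i])
    put("N", i, Nn); put("CA", i, CAn); put("C", i, Cn)
    put("O", i, place_atom(Nn, CAn, Cn, BOND_C_O, ANGLE_CA_C_O, psi[i] + 180))
    N <- Nn; CA <- CAn; CC <- Cn
  }
  if (!all(is.finite(coords))) stop("geometrically impossible backbone parameters")
  atoms <- data.frame(
    atom_name = names_v,
    element = substr(names_v, 1, 1),
    x = coords[, 1] + offset[1], y = coords[, 2] + offset[2],
    z = coords[, 3] + offset[3],
    residue_index = resi, residue_name = aa3[resi],
    chain_id = chain_id, occupancy = 1, altloc = "",
    stringsAsFactors = FALSE
  )
  model <- structure_model(
    sprintf("backbone_%dres", n_res), atoms,
    metadata = list(phi = phi, psi = psi)
  )
  if (!is.null(path)) write_pdb(model, path)
  model
}

#' Combine chains of several structures into one model
#'
#' @param ... `snowflake_structure` objects with distinct chain ids.
#' @param structure_id Identifier of the combined model.
#' @return A `snowflake_structure`.
#' @export
combine_chains <- function(..., structure_id = "combined") {
  models <- list(...)
  atoms <- do.call(rbind, lapply(models, function(m) m$atoms))
  structure_model(structure_id, atoms)
}

#' Random atom cluster with a minimum-separation constraint
#'
#' Reproducible random placement of atoms inside a cubic box, with all
#' pairwise distances at least `min_sep`. Elements are drawn from C, N, O, S.
#' These clusters are the shared input of [shrake_rupley()] and the
#' independent [mc_sasa_oracle()].
#'
#' @param n_atoms Number of atoms (>= 1).
#' @param box Box edge length in Angstrom.
#' @param seed Integer seed; same seed, same cluster.
#' @param min_sep Minimum pairwise distance (default 1.5 A).
#' @return Atoms data frame usable by [shrake_rupley()].
#' @export
make_cluster <- function(n_atoms, box = 8, seed = 1, min_sep = 1.5) {
  stopifnot(n_atoms >= 1)
  with_seed(seed, {
    xyz <- matrix(NA_real_, n_atoms, 3)
    for (i in seq_len(n_atoms)) {
      placed <- FALSE
      for (try in 1:2000) {
        p <- stats::runif(3, 0, box)
        if (i == 1 || all(colSums((t(xyz[seq_len(i - 1), , drop = FALSE]) - p)^2) >= min_sep^2)) {
          xyz[i, ] <- p
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("box too small to place ", n_atoms,
                        " atoms with separation ", min_sep)
    }
    elements <- sample(c("C", "N", "O", "S"), n_atoms, replace = TRUE)
    data.frame(
      atom_name = elements, element = elements,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      residue_index = seq_len(n_atoms), residue_name = "UNK",
      chain_id = "A", occupancy = 1, altloc = "",
      stringsAsFactors = FALSE
    )
  })
}

#' Monte-Carlo solvent-accessible surface area oracle
#'
#' Brute-force SASA estimator deliberately independent of [shrake_rupley()]:
#' directions are uniform random (normalised Gaussian triples, no
#' deterministic lattice), occlusion is tested against every other atom with
#' no spatial grid. Returns a binomial standard error per atom.
#'
#' @param atoms Atoms data frame (or `snowflake_structure`).
#' @param probe Probe radius in Angstrom (default 1.4).
#' @param n_samples Random directions per atom (>= 1e4).
#' @param seed Integer seed.
#' @param radii Named van der Waals radii (default [VDW_RADII]).
#' @return Data frame with columns `area` and `se` (Angstrom^2).
#' @export
mc_sasa_oracle <- function(atoms, probe = 1.4, n_samples = 1e5, seed = 1,
                           radii = VDW_RADII) {
  if (inherits(atoms, "snowflake_structure")) atoms <- atoms$atoms
  stopifnot(n_samples >= 1e4)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rad <- unname(radii[atoms$element]) + probe
  n <- nrow(xyz)
  with_seed(seed, {
    area <- numeric(n)
    se <- numeric(n)
    for (i in seq_len(n)) {
      u <- matrix(stats::rnorm(3 * n_samples), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      p <- sweep(u * rad[i], 2, xyz[i, ], "+")
      free <- rep(TRUE, n_samples)
      for (j in seq_len(n)) {
        if (j == i) next
        d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 + (p[, 3] - xyz[j, 3])^2
        free <- free & (d2 >= rad[j]^2)
      }
      phat <- mean(free)
      full <- 4 * pi * rad[i]^2
      area[i] <- full * phat
      se[i] <- full * sqrt(phat * (1 - phat) / n_samples)
    }
    data.frame(area = area, se = se)
  })
}

#' Generate a synthetic allele family
#'
#' One base sequence with controlled polymorphisms: `n_polymorphic` positions
#' each carry 2-4 residue variants, and every allele draws one variant per
#' position (allele 1 is the unmodified base). Identifiers `HLA00001, ...` are
#' assigned in generation order and loci rotate over A, B, C — enough
#' structure to exercise chain assignment, allele calling, training and
#' matching without any real database.
#'
#' @param base_length Sequence length (default 60).
#' @param n_alleles Number of alleles.
#' @param n_polymorphic Number of polymorphic positions (< `base_length`).
#' @param seed Integer seed; fixed seed gives a byte-identical family.
#' @return List with `alleles` (named list of [allele_sequence()]),
#'   `polymorphic_positions`, `variants` (list of residue sets), `binders`
#'   (toy nonamer table, data frame allele/peptide) and `eplets` (long-format
#'   eplet table: eplet, position, residue, antibody_verified).
#' @export
make_allele_family <- function(base_length = 60, n_alleles = 12,
                               n_polymorphic = 8, seed = 1) {
  stopifnot(n_polymorphic < base_length)
  aa <- strsplit(AA_ALPHABET, "")[[1]]
  with_seed(seed, {
    base <- sample(aa, base_length, replace = TRUE)
    poly <- sort(sample(2:(base_length - 1), n_polymorphic))
    variants <- lapply(poly, function(p) {
      unique(c(base[p], sample(setdiff(aa, base[p]), sample(1:3, 1))))
    })
    names(variants) <- as.character(poly)

    loci <- rep(c("A", "B", "C"), length.out = n_alleles)
    counters <- c(A = 0L, B = 0L, C = 0L)
    alleles <- list()
    for (i in seq_len(n_alleles)) {
      s <- base
      if (i > 1) {
        for (k in seq_along(poly)) s[poly[k]] <- sample(variants[[k]], 1)
      }
      locus <- loci[i]
      counters[locus] <- counters[locus] + 1L
      name <- sprintf("%s*90:%02d", locus, counters[locus])
      alleles[[name]] <- allele_sequence(
        name, sprintf("HLA%05d", i), paste(s, collapse = ""), locus)
    }

    # toy binder table: nonamers for the first half of the family, plus
    # off-length peptides that select_binders must filter out
    with_binders <- names(alleles)[seq_len(ceiling(n_alleles / 2))]
    binders <- do.call(rbind, lapply(with_binders, function(nm) {
      peps <- vapply(1:3, function(j) paste(sample(aa, 9, replace = TRUE),
                                            collapse = ""), character(1))
      data.frame(allele = nm, peptide = peps, stringsAsFactors = FALSE)
    }))
    binders <- rbind(binders, data.frame(
      allele = with_binders[1],
      peptide = c(paste(sample(aa, 8, replace = TRUE), collapse = ""),
                  paste(sample(aa, 10, replace = TRUE), collapse = "")),
      stringsAsFactors = FALSE))

    # eplets derived from real polymorphisms so every eplet has >= 1 carrier
    n_eplets <- min(6, n_polymorphic)
    eplets <- do.call(rbind, lapply(seq_len(n_eplets), function(e) {
      k <- sample(1:min(3, n_polymorphic), 1)
      pos <- sort(sample(poly, k))
      carrier <- alleles[[sample(seq_along(alleles), 1)]]
      res <- substring(carrier$sequence, pos, pos)
      data.frame(eplet = paste0(pos[1], paste(res, collapse = "")),
                 position = pos, residue = res,
                 antibody_verified = e <= ceiling(n_eplets / 2),
                 stringsAsFactors = FALSE)
    }))
    eplets <- eplets[!duplicated(paste(eplets$eplet, eplets$position)), ]

    list(alleles = alleles, polymorphic_positions = poly, variants = variants,
         binders = binders, eplets = eplets)
  })
}

#' Write an allele family to disk (FASTA + CSV tables)
#'
#' @param family Result of [make_allele_family()].
#' @param dir Output directory (created if needed).
#' @return Named paths of the files written.
#' @export
write_allele_family <- function(family, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "alleles.fasta")
  lines <- unlist(lapply(family$alleles, function(a) {
    c(sprintf(">HLA:%s %s %d bp", a$allele_id, a$allele_name, nchar(a$sequence)),
      a$sequence)
  }))
  writeLines(lines, fasta)
  binders <- file.path(dir, "binders.csv")
  utils::write.csv(family$binders, binders, row.names = FALSE, quote = FALSE)
  eplets <- file.path(dir, "eplets.csv")
  utils::write.csv(family$eplets, eplets, row.names = FALSE, quote = FALSE)
  c(fasta = fasta, binders = binders, eplets = eplets)
}

#' Ground-truth accessibility profiles for a synthetic family
#'
#' Accessibility at position `i` is a deterministic function of the residue
#' and its two neighbours, drawn once per `rule_seed`: the same local context
#' always yields the same value in `[0, 1]`, so a bidirectional recurrent
#' model can represent the rule exactly, while polymorphic positions get
#' allele-specific values. This is the parameter-recovery target for the
#' accessibility predictor.
#'
#' @param family Result of [make_allele_family()].
#' @param rule_seed Seed of the context -> value lookup.
#' @return Named list of scaled `accessibility_profile`s, one per allele.
#' @export
make_ground_truth_profiles <- function(family, rule_seed = 99) {
  rule <- with_seed(rule_seed, array(stats::runif(21^3), dim = c(21, 21, 21)))
  aa <- strsplit(AA_ALPHABET, "")[[1]]
  idx <- function(ch) {
    i <- match(ch, aa)
    ifelse(is.na(i), 21L, i)
  }
  lapply(family$alleles, function(a) {
    s <- strsplit(a$sequence, "")[[1]]
    n <- length(s)
    prev <- c("X", s[-n])
    nxt <- c(s[-1], "X")
    vals <- rule[cbind(idx(prev), idx(s), idx(nxt))]
    accessibility_profile(seq_len(n), vals, residue = s,
                          units = "scaled", id = a$allele_name)
  })
}

#' Build an HLA-like synthetic structure for a family allele
#'
#' Composes an alpha chain built from the allele's sequence (chain A), a
#' beta-2-microglobulin chain (chain B), a second alpha-chain copy (chain C)
#' and a nonamer peptide chain (chain D), all as ideal-geometry backbones,
#' spatially separated unless `contact = TRUE`.
#'
#' @param allele An [allele_sequence()].
#' @param b2m_sequence B2M sequence for chain B (default [B2M_MATURE]).
#' @param peptide Optional nonamer sequence for the peptide chain.
#' @param contact Place the B2M chain adjacent to the alpha chain so that it
#'   shadows part of it (default FALSE: chains far apart).
#' @return A `snowflake_structure`.
#' @export
make_hla_fixture <- function(allele, b2m_sequence = B2M_MATURE,
                             peptide = "ALAKAAAAV", contact = FALSE) {
  alpha <- make_backbone(sequence = allele$sequence, phi = -57, psi = -47,
                         chain_id = "A")
  b2m_off <- if (contact) c(6, 0, 0) else c(60, 0, 0)
  b2m <- make_backbone(sequence = b2m_sequence, phi = -57, psi = -47,
                       chain_id = "B", offset = b2m_off)
  copy <- make_backbone(sequence = allele$sequence, phi = -57, psi = -47,
                        chain_id = "C", offset = c(0, 60, 0))
  chains <- list(alpha, b2m, copy)
  if (!is.null(peptide)) {
    chains <- c(chains, list(make_backbone(sequence = peptide, phi = -120,
                                           psi = 120, chain_id = "D",
                                           offset = c(0, 0, 60))))
  }
  do.call(combine_chains,
          c(chains, list(structure_id = paste0("synth_", allele$allele_id))))
}
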