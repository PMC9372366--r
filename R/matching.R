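#' Construct a genotype
#'
#' @param person_id Identifier of the individual.
#' @param alleles Character vector of allele names (typically two per locus
#'   over HLA-A, -B, -C).
#' @return List of class `genotype`.
#' @export
genotype <- function(person_id, alleles) {
  if (length(alleles) == 0) stop("genotype needs at least one allele")
  out <- list(person_id = person_id, alleles = alleles)
  class(out) <- "genotype"
  out
}

#' Positions of a profile exceeding an accessibility threshold
#'
#' @param profile A scaled `accessibility_profile`.
#' @param threshold Accessibility cutoff in `[0, 1]`; strictly exceeded
#'   positions qualify.
#' @return Integer vector of positions.
#' @export
accessible_positions <- function(profile, threshold) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  profile$position[profile$value > threshold]
}

#' Snowflake epitope mismatch score
#'
#' Counts donor amino-acid mismatches at donor-allele-specific,
#' surface-accessible positions. For each distinct donor allele, every
#' position whose predicted accessibility (on the donor allele) strictly
#' exceeds the threshold is checked: the position mismatches when the donor
#' residue is absent from the recipient reference set at that position. In
#' `intralocus` mode the reference set is the recipient alleles of the donor
#' allele's locus; in `interlocus` mode it is all recipient Class I alleles.
#' The score is the total number of mismatching (allele, position) pairs.
#'
#' @param donor,recipient [genotype()] objects.
#' @param profiles Named list of scaled `accessibility_profile`s covering
#'   every involved allele.
#' @param alleles Named list of [allele_sequence()] records (the shared
#'   positional frame) covering every involved allele.
#' @param mode `"intralocus"` (default) or `"interlocus"`.
#' @param threshold Accessibility cutoff in `[0, 1]`; `NULL` (default) uses
#'   each donor allele's own mean predicted accessibility, mirroring the
#'   mean-exceedance accessibility classification.
#' @return Object of class `match_result`: `score`, `mode`, `threshold`, and
#'   `detail` — one row per evaluated (donor allele, position) with the donor
#'   residue, its accessibility, the recipient residues seen and the mismatch
#'   flag. Positions with unknown residues (`X`) on either side are skipped.
#' @export
snowflake_score <- function(donor, recipient, profiles, alleles,
                            mode = c("intralocus", "interlocus"),
                            threshold = NULL) {
  mode <- match.arg(mode)
  involved <- unique(c(donor$alleles, recipient$alleles))
  for (a in involved) {
    if (is.null(alleles[[a]])) stop("no sequence for allele ", a)
  }
  for (a in unique(donor$alleles)) {
    if (is.null(profiles[[a]])) stop("no accessibility profile for allele ", a)
  }
  detail <- list()
  score <- 0L
  for (d in unique(donor$alleles)) {
    dseq <- alleles[[d]]
    prof <- profiles[[d]]
    thr <- if (is.null(threshold)) mean(prof$value) else threshold
    ref_names <- if (mode == "intralocus") {
      recipient$alleles[vapply(recipient$alleles,
                               function(r) alleles[[r]]$locus == dseq$locus,
                               logical(1))]
    } else recipient$alleles
    ref_names <- unique(ref_names)
    for (p in accessible_positions(prof, thr)) {
      dres <- substr(dseq$sequence, p, p)
      if (dres == "X" || dres == "") next
      rres <- vapply(ref_names, function(r) substr(alleles[[r]]$sequence, p, p),
                     character(1))
      rres <- rres[rres != "" & rres != "X"]
      mismatch <- length(rres) > 0 && !(dres %in% rres)
      if (length(rres) == 0) mismatch <- TRUE  # no reference residue at all
      if (mismatch) score <- score + 1L
      detail[[length(detail) + 1]] <- data.frame(
        donor_allele = d, position = p, donor_residue = dres,
        accessibility = prof$value[prof$position == p][1],
        recipient_residues = paste(sort(unique(rres)), collapse = ""),
        mismatch = mismatch, stringsAsFactors = FALSE)
    }
  }
  out <- list(score = score, mode = mode,
              threshold = if (is.null(threshold)) NA_real_ else threshold,
              detail = if (length(detail)) do.call(rbind, detail) else NULL)
  class(out) <- "match_result"
  out
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %s score = %d (%d positions evaluated)\n",
              x$mode, x$score, if (is.null(x$detail)) 0L else nrow(x$detail)))
  invisible(x)
}

#' Read eplet definitions from a long-format CSV
#'
#' Expected columns: `eplet`, `position`, `residue`, optional
#' `antibody_verified` — one row per (position, residue) component, one to
#' three components per eplet.
#'
#' @param path CSV path.
#' @return Data frame of eplet components.
#' @export
read_eplet_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("eplet", "position", "residue")
  if (!all(need %in% names(df))) {
    stop("eplet table needs columns: ", paste(need, collapse = ", "))
  }
  if (!"antibody_verified" %in% names(df)) df$antibody_verified <- NA
  sizes <- table(df$eplet)
  if (any(sizes > 3)) {
    stop("eplets must have 1-3 components: ",
         paste(names(sizes)[sizes > 3], collapse = ", "))
  }
  df
}

#' Accessibility distributions of eplet positions across carrier alleles
#'
#' For every eplet, the carrier set is the alleles whose sequence matches all
#' of the eplet's (position, residue) components; for each component position
#' the accessibility values of the carriers are collected. Eplets carried by
#' no allele are reported with empty distributions.
#'
#' @param eplets Eplet component table (see [read_eplet_table()]).
#' @param alleles Named list of [allele_sequence()] records.
#' @param profiles Named list of scaled `accessibility_profile`s aligned to
#'   the same positional frame.
#' @return Data frame with one row per (eplet, position, carrier allele) and
#'   columns `eplet`, `position`, `residue`, `allele`, `accessibility`;
#'   attribute `no_carriers` lists eplets with empty carrier sets.
#' @export
eplet_accessibility <- function(eplets, alleles, profiles) {
  max_pos <- min(vapply(alleles, function(a) nchar(a$sequence), numeric(1)))
  if (any(eplets$position > max_pos | eplets$position < 1)) {
    stop("eplet position outside the shared positional frame")
  }
  out <- list()
  empty <- character(0)
  for (e in unique(eplets$eplet)) {
    comp <- eplets[eplets$eplet == e, , drop = FALSE]
    carriers <- vapply(alleles, function(a) a$allele_name, character(1))[
      vapply(alleles, function(a) {
        all(substring(a$sequence, comp$position, comp$position) == comp$residue)
      }, logical(1))]
    if (length(carriers) == 0) {
      empty <- c(empty, e)
      next
    }
    for (k in seq_len(nrow(comp))) {
      for (ca in carriers) {
        prof <- profiles[[ca]]
        v <- prof$value[prof$position == comp$position[k]]
        out[[length(out) + 1]] <- data.frame(
          eplet = e, position = comp$position[k], residue = comp$residue[k],
          allele = ca, accessibility = if (length(v)) v[1] else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(eplet = character(0), position = integer(0),
               residue = character(0), allele = character(0),
               accessibility = numeric(0))
  attr(res, "no_carriers") <- empty
  res
}

#' Classify an eplet's accessibility pattern
#'
#' Maps the per-component carrier distributions onto the three observed
#' patterns: `consistently_accessible` — every component has high median
#' accessibility with a tight spread; `variable` — at least one component has
#' a wide spread (interquartile range at or above `spread_cut`);
#' `partially_accessible` — otherwise, with at least one high-median
#' component.
#'
#' @param distributions Rows of [eplet_accessibility()] for one eplet.
#' @param high_cut Median accessibility counted as "high" (default 0.5).
#' @param spread_cut Interquartile range counted as "wide" (default 0.25).
#' @return One of `"consistently_accessible"`, `"partially_accessible"`,
#'   `"variable"`, or `"inaccessible"` when no component has a high median.
#' @export
classify_eplet_pattern <- function(distributions, high_cut = 0.5,
                                   spread_cut = 0.25) {
  if (nrow(distributions) == 0) stop("empty distributions")
  med <- tapply(distributions$accessibility, distributions$position, stats::median)
  iqr <- tapply(distributions$accessibility, distributions$position, stats::IQR)
  if (any(iqr >= spread_cut)) return("variable")
  if (all(med > high_cut)) return("consistently_accessible")
  if (any(med > high_cut)) return("partially_accessible")
  "inaccessible"
}

#' Read genotypes from CSV
#'
#' Expected columns: `person_id`, `allele` (one row per allele).
#'
#' @param path CSV path.
#' @return Named list of [genotype()] objects.
#' @export
read_genotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("person_id", "allele") %in% names(df))) {
    stop("genotype CSV needs columns person_id, allele")
  }
  sp <- split(df$allele, df$person_id)
  Map(genotype, names(sp), sp)
}
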