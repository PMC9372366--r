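#' Mature beta-2-microglobulin reference sequence
#'
#' The invariant light chain of HLA Class I (UniProtKB P61769, signal peptide
#' removed, 99 residues). Used as the default reference when identifying the
#' B2M chain of a structure; override via the `b2m_reference` argument of
#' [identify_hla_chains()].
#' @export
B2M_MATURE <- paste0(
  "IQRTPKIQVYSRHPAENGKSNFLNCYVSGFHPSDIEVDLLKNGERIEKVEHSDLSFSKDW",
  "SFYLLYYTEFTPTEKDEYACRVNHVTLSQPKIVKWDRDM"
)

#' Construct an allele sequence record
#'
#' @param allele_name WHO nomenclature string, e.g. `"A*01:01"`.
#' @param allele_id Database identifier, e.g. `"HLA00001"`.
#' @param sequence Mature-protein amino-acid string (1-based positions, signal
#'   peptide removed — the frame used by eplet names like 127K).
#' @param locus Locus letter; derived from `allele_name` if omitted.
#' @return Object of class `allele_sequence`.
#' @export
allele_sequence <- function(allele_name, allele_id, sequence, locus = NULL) {
  if (is.null(locus)) locus <- sub("\\*.*$", "", allele_name)
  if (!startsWith(allele_name, locus)) {
    stop("locus '", locus, "' inconsistent with allele name '", allele_name, "'")
  }
  sequence <- toupper(sequence)
  bad <- setdiff(strsplit(sequence, "")[[1]], c(strsplit(AA_ALPHABET, "")[[1]], "X"))
  if (length(bad) > 0) stop("invalid residues in sequence: ", paste(bad, collapse = ""))
  out <- list(allele_name = allele_name, allele_id = allele_id,
              locus = locus, sequence = sequence)
  class(out) <- "allele_sequence"
  out
}

#' @export
print.allele_sequence <- function(x, ...) {
  cat(sprintf("<allele_sequence> %s (%s, locus %s, %d aa)\n",
              x$allele_name, x$allele_id, x$locus, nchar(x$sequence)))
  invisible(x)
}

#' Read an allele protein database from FASTA
#'
#' Headers are expected in the IMGT style `"HLA:HLA00001 A*01:01:01:01 ..."`:
#' the first token carries the database identifier, the second the allele
#' name. Allele names are truncated to two fields (protein level).
#'
#' @param path FASTA file path.
#' @return Named list of [allele_sequence()] records, keyed by allele name.
#' @export
read_allele_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0) stop("no sequences in ", path)
  out <- list()
  for (i in seq_along(seqs)) {
    header <- names(seqs)[i]
    tokens <- strsplit(trimws(header), "\\s+")[[1]]
    id <- sub("^HLA:", "", tokens[1])
    name <- protein_level_name(tokens[2])
    out[[name]] <- allele_sequence(name, id, as.character(seqs[[i]]))
  }
  out
}

# truncate e.g. A*01:01:01:01 to A*01:01
protein_level_name <- function(name) {
  fields <- strsplit(name, ":")[[1]]
  if (length(fields) <= 2) name else paste(fields[1:2], collapse = ":")
}

# raw local-alignment score, BLOSUM62, gap open 11 / extend 1 (protein-BLAST
# default penalties) — surrogate for the original BLAST raw-score cutoff
local_alignment_score <- function(query, subject) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(subject),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
}

# number of identically aligned residues under global alignment
global_identity_count <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1)
  Biostrings::nmatch(aln)
}

#' Identify HLA alpha chain, beta-2-microglobulin and peptide in a structure
#'
#' Reproduces the structure-intake filter: the model must contain chains
#' `A`, `B` and `C`; chain `B` must match the mature beta-2-microglobulin
#' reference (at least `b2m_min_identity` identity over the aligned length);
#' and chain `A` must achieve a local-alignment raw score above
#' `score_threshold` against at least one allele of the database. Any
#' additional chain of 8-11 residues is flagged as the bound peptide.
#' Rejection is a normal result (`accepted = FALSE`), not an error.
#'
#' @param model A `snowflake_structure`.
#' @param allele_db Named list of [allele_sequence()] records.
#' @param b2m_reference Mature B2M sequence (default [B2M_MATURE]).
#' @param score_threshold Alignment raw-score cutoff for the alpha chain
#'   (default 1300, the intake cutoff for full-length Class I chains).
#' @param b2m_min_identity Minimum fractional identity for the B2M chain
#'   (default 0.95, tolerating engineered tags and point mutants).
#' @return A list of class `chain_assignment`: `alpha_chain_id`,
#'   `b2m_chain_id`, `peptide_chain_id` (or `NA`), `alignment_score`,
#'   `accepted`.
#' @export
identify_hla_chains <- function(model, allele_db,
                                b2m_reference = B2M_MATURE,
                                score_threshold = 1300,
                                b2m_min_identity = 0.95) {
  if (length(allele_db) == 0) stop("allele_db is empty")
  chains <- structure_chains(model)
  out <- list(alpha_chain_id = "A", b2m_chain_id = "B",
              peptide_chain_id = NA_character_,
              alignment_score = NA_real_, accepted = FALSE)
  class(out) <- "chain_assignment"
  if (!all(c("A", "B", "C") %in% chains)) return(out)

  b2m_seq <- chain_sequence(model, "B")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(b2m_seq), Biostrings::AAString(b2m_reference),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1)
  b2m_identity <- Biostrings::nmatch(aln) /
    min(nchar(b2m_seq), nchar(b2m_reference))
  if (b2m_identity < b2m_min_identity) return(out)

  alpha_seq <- chain_sequence(model, "A")
  scores <- vapply(allele_db, function(a) local_alignment_score(alpha_seq, a$sequence),
                   numeric(1))
  out$alignment_score <- max(scores)

  lens <- vapply(chains, function(ch) {
    length(unique(model$atoms$residue_index[model$atoms$chain_id == ch]))
  }, integer(1))
  pept <- chains[chains != "A" & chains != "B" & lens[chains] >= 8 & lens[chains] <= 11]
  if (length(pept) > 0) out$peptide_chain_id <- pept[1]

  out$accepted <- out$alignment_score > score_threshold
  out
}

#' @export
print.chain_assignment <- function(x, ...) {
  cat(sprintf("<chain_assignment> alpha=%s b2m=%s peptide=%s score=%.0f accepted=%s\n",
              x$alpha_chain_id, x$b2m_chain_id,
              ifelse(is.na(x$peptide_chain_id), "-", x$peptide_chain_id),
              x$alignment_score, x$accepted))
  invisible(x)
}

#' Assign an allele to an alpha-chain sequence
#'
#' Picks the database allele with the maximum number of identically aligned
#' residues; ties are broken by the lexicographically lowest database
#' identifier.
#'
#' @param alpha_seq Amino-acid string of the structure's alpha chain.
#' @param allele_db Named list of [allele_sequence()] records.
#' @return List with `allele` (the winning [allele_sequence()]) and
#'   `identity_count`.
#' @export
assign_allele <- function(alpha_seq, allele_db) {
  if (length(allele_db) == 0) stop("allele_db is empty")
  if (!nzchar(alpha_seq)) stop("alpha_seq is empty")
  counts <- vapply(allele_db, function(a) global_identity_count(alpha_seq, a$sequence),
                   numeric(1))
  ids <- vapply(allele_db, function(a) a$allele_id, character(1))
  best <- which(counts == max(counts))
  winner <- best[order(ids[best])][1]
  list(allele = allele_db[[winner]], identity_count = as.integer(max(counts)))
}

#' Map structure residues to allele sequence positions
#'
#' Globally aligns the chain's residue sequence to the allele's mature-protein
#' sequence and returns, for each structure residue, its 1-based position in
#' the allele frame — the coordinate system shared by the accessibility
#' predictor, the eplet table and the mismatch scorer.
#'
#' @param model A `snowflake_structure`.
#' @param chain_id Chain to map.
#' @param allele An [allele_sequence()].
#' @param min_identity Minimum fractional identity over aligned residues below
#'   which mapping fails (default 0.8; failure signals a wrong allele).
#' @return List of class `position_map`: `mapping` (named integer vector,
#'   names = structure residue indices, values = allele positions) and
#'   `unmapped` (residue indices without a position, e.g. opposite gaps).
#' @export
map_residues_to_positions <- function(model, chain_id, allele, min_identity = 0.8) {
  atoms <- chain_atoms(model, chain_id)
  res_idx <- unique(atoms$residue_index)
  chain_seq <- chain_sequence(model, chain_id)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(chain_seq), Biostrings::AAString(allele$sequence),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1)
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ip <- 0L; is <- 0L
  mapping <- integer(0)
  n_ident <- 0L; n_aligned <- 0L
  for (k in seq_along(pat)) {
    if (pat[k] != "-") ip <- ip + 1L
    if (sub[k] != "-") is <- is + 1L
    if (pat[k] != "-" && sub[k] != "-") {
      mapping[as.character(res_idx[ip])] <- is
      n_aligned <- n_aligned + 1L
      if (pat[k] == sub[k]) n_ident <- n_ident + 1L
    }
  }
  if (n_aligned == 0 || n_ident / n_aligned < min_identity) {
    stop(sprintf("mapping failure: %.0f%% identity to %s (wrong allele?)",
                 100 * n_ident / max(n_aligned, 1), allele$allele_name))
  }
  out <- list(mapping = mapping,
              unmapped = setdiff(res_idx, as.integer(names(mapping))))
  class(out) <- "position_map"
  out
}

#' Select training peptides for an allele from a binder table
#'
#' Returns up to `k` nonameric binder peptides for `allele`. If the table
#' reports no nonamers for the allele itself, the peptides of the database
#' allele with the highest amino-acid identity in the extracellular domains
#' (positions 1-182 by default, the alpha-1/alpha-2 peptide-binding region)
#' are used instead; identity ties are broken by lowest database identifier.
#' Selection is deterministic: peptides are sorted lexicographically and the
#' first `k` taken.
#'
#' @param allele An [allele_sequence()].
#' @param binder_table Data frame with columns `allele` and `peptide`.
#' @param k Maximum number of peptides (default 10).
#' @param allele_db Named list of [allele_sequence()] records (fallback source).
#' @param extracellular Position range used for the fallback identity
#'   computation (default `c(1, 182)`; set `c(1, 275)` for alpha-1..3).
#' @return List with `source_allele` (name) and `peptides` (character vector).
#' @export
select_binders <- function(allele, binder_table, k = 10, allele_db = list(),
                           extracellular = c(1, 182)) {
  stopifnot(k >= 1)
  tab <- binder_table[nchar(binder_table$peptide) == 9, , drop = FALSE]
  if (nrow(tab) == 0) stop("binder table contains no nonamer peptides")
  own <- tab$peptide[tab$allele == allele$allele_name]
  if (length(own) > 0) {
    return(list(source_allele = allele$allele_name,
                peptides = utils::head(sort(own), k)))
  }
  candidates <- Filter(function(a) {
    a$allele_name != allele$allele_name && any(tab$allele == a$allele_name)
  }, allele_db)
  if (length(candidates) == 0) stop("no allele with reported nonamer binders")
  clip <- function(s) substr(s, extracellular[1], min(extracellular[2], nchar(s)))
  ident <- vapply(candidates, function(a) {
    global_identity_count(clip(allele$sequence), clip(a$sequence))
  }, numeric(1))
  ids <- vapply(candidates, function(a) a$allele_id, character(1))
  best <- which(ident == max(ident))
  winner <- candidates[[best[order(ids[best])][1]]]
  list(source_allele = winner$allele_name,
       peptides = utils::head(sort(tab$peptide[tab$allele == winner$allele_name]), k))
}

#' Ingest a directory of PDB structures into a manifest
#'
#' Runs [parse_pdb()], [identify_hla_chains()] and [assign_allele()] over every
#' `.pdb` file and writes one manifest row per structure.
#'
#' @param pdb_dir Directory containing `.pdb` files.
#' @param allele_db Named list of [allele_sequence()] records.
#' @param out Optional TSV path for the manifest.
#' @param score_threshold Alpha-chain alignment score cutoff (default 1300).
#' @return Data frame with columns `structure_id`, `alpha_chain`,
#'   `allele_name`, `allele_id`, `alignment_score`, `accepted`,
#'   `peptide_chain`.
#' @export
ingest_structures <- function(pdb_dir, allele_db, out = NULL,
                              score_threshold = 1300) {
  files <- sort(list.files(pdb_dir, pattern = "\\.pdb$", full.names = TRUE))
  rows <- lapply(files, function(f) {
    model <- parse_pdb(f)
    asn <- identify_hla_chains(model, allele_db, score_threshold = score_threshold)
    allele_name <- NA_character_; allele_id <- NA_character_
    if (asn$accepted) {
      hit <- assign_allele(chain_sequence(model, asn$alpha_chain_id), allele_db)
      allele_name <- hit$allele$allele_name
      allele_id <- hit$allele$allele_id
    }
    data.frame(structure_id = model$structure_id,
               alpha_chain = asn$alpha_chain_id,
               allele_name = allele_name, allele_id = allele_id,
               alignment_score = asn$alignment_score,
               accepted = asn$accepted,
               peptide_chain = asn$peptide_chain_id,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  if (!is.null(out)) {
    utils::write.table(manifest, out, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest
}
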