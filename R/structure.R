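#' Construct a structure model
#'
#' Lightweight container for a parsed 3D structure: one row per atom, grouped
#' by chain and residue. This is the common currency between the PDB reader,
#' the dihedral extractor, the surface-area calculator and the fixture
#' generators.
#'
#' @param structure_id Accession-like identifier string.
#' @param atoms Data frame with columns `atom_name`, `element`, `x`, `y`, `z`,
#'   `residue_index`, `residue_name`, `chain_id`, `occupancy`, `altloc`.
#' @param metadata Named list of free-form metadata.
#' @return Object of class `snowflake_structure`.
#' @export
structure_model <- function(structure_id, atoms, metadata = list()) {
  required <- c("atom_name", "element", "x", "y", "z",
                "residue_index", "residue_name", "chain_id",
                "occupancy", "altloc")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atoms is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) == 0) stop("empty structure: no protein atoms")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite atom coordinates")
  }
  if (any(atoms$occupancy < 0 | atoms$occupancy > 1, na.rm = TRUE)) {
    stop("occupancy outside [0, 1]")
  }
  if (any(!nzchar(atoms$element))) stop("empty element symbol")
  atoms <- atoms[order(match(atoms$chain_id, unique(atoms$chain_id)),
                       atoms$residue_index), , drop = FALSE]
  rownames(atoms) <- NULL
  out <- list(structure_id = structure_id, atoms = atoms, metadata = metadata)
  class(out) <- "snowflake_structure"
  out
}

#' @export
print.snowflake_structure <- function(x, ...) {
  ch <- table(x$atoms$chain_id)
  nres <- vapply(split(x$atoms$residue_index, x$atoms$chain_id),
                 function(r) length(unique(r)), integer(1))
  cat("<snowflake_structure>", x$structure_id, "\n")
  cat(sprintf("  chain %s: %d residues, %d atoms\n",
              names(ch), nres[names(ch)], as.integer(ch)), sep = "")
  invisible(x)
}

#' Chain identifiers of a structure
#' @param model A `snowflake_structure`.
#' @return Character vector of chain ids in file order.
#' @export
structure_chains <- function(model) unique(model$atoms$chain_id)

chain_atoms <- function(model, chain_id = NULL) {
  if (is.null(chain_id)) chain_id <- model$atoms$chain_id[1]
  atoms <- model$atoms[model$atoms$chain_id == chain_id, , drop = FALSE]
  if (nrow(atoms) == 0) stop("chain '", chain_id, "' not present in structure")
  atoms
}

#' One-letter amino-acid sequence of a chain
#'
#' @param model A `snowflake_structure`.
#' @param chain_id Chain identifier.
#' @return Single string; non-standard residues become `X`.
#' @export
chain_sequence <- function(model, chain_id = NULL) {
  atoms <- chain_atoms(model, chain_id)
  res <- atoms[!duplicated(atoms$residue_index), , drop = FALSE]
  aa <- bio3d::aa321(res$residue_name)
  aa[is.na(aa) | !aa %in% strsplit(AA_ALPHABET, "")[[1]]] <- "X"
  paste(aa, collapse = "")
}

AA_ALPHABET <- "ACDEFGHIKLMNPQRSTVWY"

STANDARD_AA3 <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

#' Parse a PDB file into a structure model
#'
#' Reads ATOM records of the first MODEL only. Waters and hetero small
#' molecules are excluded. Alternate locations are resolved per atom: by
#' default the highest-occupancy conformer is kept, ties broken in favour of
#' altloc `A`.
#'
#' @param path Path to a PDB-format file.
#' @param altloc_policy `"occupancy"` (default: highest occupancy, tie ->
#'   altloc `A`) or `"first"` (first conformer encountered).
#' @param structure_id Identifier; defaults to the file name without extension.
#' @return A `snowflake_structure`.
#' @export
parse_pdb <- function(path, altloc_policy = c("occupancy", "first"),
                      structure_id = NULL) {
  altloc_policy <- match.arg(altloc_policy)
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("PDB parse error in ", path, ": ", conditionMessage(e))
  )
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$resid %in% STANDARD_AA3, , drop = FALSE]
  if (nrow(at) == 0) stop("empty structure: no protein residues in ", path)
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(!nzchar(trimws(elem)))) {
    elem <- substr(trimws(at$elety), 1, 1)
  }
  elem <- toupper(trimws(elem))
  guess <- substr(trimws(at$elety), 1, 1)
  elem[!nzchar(elem) | is.na(elem)] <- guess[!nzchar(elem) | is.na(elem)]
  atoms <- data.frame(
    atom_name = trimws(at$elety), element = elem,
    x = at$x, y = at$y, z = at$z,
    residue_index = at$resno, residue_name = at$resid,
    chain_id = at$chain,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    altloc = ifelse(is.na(at$alt) | at$alt == "", "", at$alt),
    stringsAsFactors = FALSE
  )
  atoms <- resolve_altloc(atoms, altloc_policy)
  if (is.null(structure_id)) structure_id <- sub("\\.[^.]*$", "", basename(path))
  structure_model(structure_id, atoms, metadata = list(source = path))
}

# keep one conformer per (chain, residue, atom name)
resolve_altloc <- function(atoms, policy) {
  key <- paste(atoms$chain_id, atoms$residue_index, atoms$atom_name, sep = "\r")
  if (!anyDuplicated(key)) return(atoms)
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(ii) {
    if (length(ii) == 1) return(ii)
    if (policy == "first") return(ii[1])
    occ <- atoms$occupancy[ii]
    best <- ii[occ == max(occ)]
    if (length(best) > 1) {
      alt <- atoms$altloc[best]
      best <- if (any(alt == "A")) best[alt == "A"][1] else best[order(alt)][1]
    }
    best
  }), use.names = FALSE)
  atoms[sort(keep), , drop = FALSE]
}

#' Write a structure model as a PDB file
#'
#' Minimal fixed-column PDB writer (ATOM/TER/END records) used for
#' synthetic fixtures; coordinates are written at the format's 3-decimal
#' precision.
#'
#' @param model A `snowflake_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  at <- model$atoms
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  for (ch in unique(at$chain_id)) {
    ca <- at[at$chain_id == ch, , drop = FALSE]
    for (i in seq_len(nrow(ca))) {
      serial <- serial + 1L
      name <- ca$atom_name[i]
      # column 13-16: 1-letter elements are right-padded starting col 14
      name_f <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
      writeLines(sprintf(
        "ATOM  %5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, name_f, substr(ca$altloc[i], 1, 1), ca$residue_name[i],
        ca$chain_id[i], ca$residue_index[i], " ",
        ca$x[i], ca$y[i], ca$z[i], ca$occupancy[i], 0,
        ca$element[i]), con)
    }
    serial <- serial + 1L
    writeLines(sprintf("TER   %5d      %3s %1s%4d",
                       serial, ca$residue_name[nrow(ca)], ch,
                       ca$residue_index[nrow(ca)]), con)
  }
  writeLines("END", con)
  invisible(path)
}
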