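test_that("written fixtures re-parse with identical topology and coordinates", {
  m <- make_backbone(10, -57, -47)
  tmp <- tempfile(fileext = ".pdb")
  write_pdb(m, tmp)
  m2 <- parse_pdb(tmp)
  expect_equal(structure_chains(m2), "A")
  expect_equal(nrow(m2$atoms), nrow(m$atoms))
  expect_lt(max(abs(m$atoms$x - m2$atoms$x)), 1e-3 + 1e-9)
  expect_lt(max(abs(m$atoms$z - m2$atoms$z)), 1e-3 + 1e-9)
})

test_that("only the first MODEL is read; waters and hetero atoms are dropped", {
  tmp <- tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.421   0.000  1.00  0.00           C",
    "HETATM    4  O   HOH A 101      22.000  22.000  22.000  1.00  0.00           O",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  N   ALA A   1       9.000   9.000   9.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      10.458   9.000   9.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1      11.009  10.421   9.000  1.00  0.00           C",
    "ENDMDL",
    "END"), tmp)
  m <- parse_pdb(tmp)
  expect_equal(nrow(m$atoms), 3)
  expect_equal(m$atoms$x[1], 0)          # model-1 coordinates
  expect_false(any(m$atoms$residue_name == "HOH"))
})

test_that("altloc resolution keeps the highest-occupancy conformer, tie -> A", {
  tmp <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N  AALA A   1       0.000   0.000   0.000  0.40  0.00           N",
    "ATOM      2  N  BALA A   1       5.000   0.000   0.000  0.60  0.00           N",
    "ATOM      3  CA AALA A   1       1.458   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CA BALA A   1       6.458   0.000   0.000  0.50  0.00           C",
    "END"), tmp)
  m <- parse_pdb(tmp)
  expect_equal(nrow(m$atoms), 2)
  expect_equal(m$atoms$x[m$atoms$atom_name == "N"], 5)    # occ 0.6 wins
  expect_equal(m$atoms$x[m$atoms$atom_name == "CA"], 1.458)  # tie -> A
})

test_that("parsing fails cleanly on unreadable or protein-free files", {
  expect_error(parse_pdb(tempfile()), "cannot read")
  tmp <- tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
    "END"), tmp)
  expect_error(parse_pdb(tmp), "empty structure|no protein")
})

make_family_db <- function(...) make_allele_family(...)$alleles

test_that("chain identification accepts complete HLA-like models and is idempotent", {
  db <- make_family_db(base_length = 40, n_alleles = 4, n_polymorphic = 3, seed = 21)
  a1 <- db[[1]]
  model <- make_hla_fixture(a1)
  # synthetic chains are short, so the cutoff is set below the self-score
  self <- identify_hla_chains(model, db, score_threshold = 100)
  expect_true(self$accepted)
  expect_equal(self$peptide_chain_id, "D")
  # score equals the self local-alignment score of the exact allele sequence
  expect_gte(self$alignment_score, 100)
  again <- identify_hla_chains(model, db, score_threshold = 100)
  expect_identical(self, again)
})

test_that("models lacking chain C or with a foreign B chain are rejected", {
  db <- make_family_db(base_length = 40, n_alleles = 4, n_polymorphic = 3, seed = 21)
  a1 <- db[[1]]
  alpha <- make_backbone(sequence = a1$sequence, chain_id = "A")
  b2m <- make_backbone(sequence = substr(B2M_MATURE, 1, 40), chain_id = "B",
                       offset = c(50, 0, 0))
  no_c <- combine_chains(alpha, b2m)
  expect_false(identify_hla_chains(no_c, db, score_threshold = 100)$accepted)

  # chain B that is not beta-2-microglobulin
  wrong_b <- make_hla_fixture(a1, b2m_sequence = strrep("G", 60))
  expect_false(identify_hla_chains(wrong_b, db, score_threshold = 100)$accepted)
})

test_that("scrambled alpha chains score far below the full-length cutoff", {
  db <- make_family_db(base_length = 40, n_alleles = 4, n_polymorphic = 3, seed = 21)
  a1 <- db[[1]]
  set.seed(7)
  scrambled <- paste(sample(strsplit(a1$sequence, "")[[1]]), collapse = "")
  scr_allele <- allele_sequence("A*90:99", "HLA09999", scrambled)
  model <- make_hla_fixture(scr_allele)
  asn <- identify_hla_chains(model, db)  # default cutoff 1300
  expect_false(asn$accepted)
  expect_lt(asn$alignment_score, 1300)
})

test_that("allele assignment maximizes identity and breaks ties by lowest id", {
  db <- list(
    x = allele_sequence("A*90:01", "HLA00009", "ACDEFGHIKLMNPQRSTVWY"),
    y = allele_sequence("A*90:02", "HLA00001", "ACDEFGHIKLMNPQRSTVWY"),
    z = allele_sequence("B*90:01", "HLA00005", "ACDEFGHIKLYNPQRSTVWY")
  )
  # exact hit: tie between HLA00009 and HLA00001 -> HLA00001
  hit <- assign_allele("ACDEFGHIKLMNPQRSTVWY", db)
  expect_equal(hit$allele$allele_id, "HLA00001")
  expect_equal(hit$identity_count, 20L)
  # three mismatches reduce the identity count accordingly
  q <- "ACDEFGHIKLMNPQRSTVAA"  # 2 mismatches vs x/y
  expect_equal(assign_allele(q, db)$identity_count, 18L)
  expect_error(assign_allele("ACD", list()), "empty")
})

test_that("every family allele is re-assigned to itself", {
  db <- make_family_db(base_length = 50, n_alleles = 9, n_polymorphic = 5, seed = 3)
  for (a in db) {
    # ties (identical sequences under another id) must resolve to an id
    # whose sequence equals the query
    hit <- assign_allele(a$sequence, db)
    expect_equal(hit$allele$sequence, a$sequence)
    expect_equal(hit$identity_count, nchar(a$sequence))
  }
})

test_that("residue-to-position mapping handles identity, offsets and deletions", {
  allele <- allele_sequence("A*90:01", "HLA00001",
                            paste(rep("ACDEFGHIKL", 6), collapse = ""))
  m <- make_backbone(sequence = allele$sequence, chain_id = "A")
  pm <- map_residues_to_positions(m, "A", allele)
  expect_equal(unname(pm$mapping[as.character(1:60)]), 1:60)
  expect_length(pm$unmapped, 0)

  # chain missing the first two residues: residue 1 maps to position 3
  trimmed <- structure_model("t", m$atoms[m$atoms$residue_index > 2, ])
  trimmed$atoms$residue_index <- trimmed$atoms$residue_index - 2L
  pm2 <- map_residues_to_positions(trimmed, "A", allele)
  expect_equal(unname(pm2$mapping["1"]), 3)

  # internal deletion at position 30: later residues shift by one
  del <- structure_model("d", m$atoms[m$atoms$residue_index != 30, ])
  keep <- unique(del$atoms$residue_index)
  del$atoms$residue_index <- match(del$atoms$residue_index, keep)
  pm3 <- map_residues_to_positions(del, "A", allele)
  expect_equal(unname(pm3$mapping["29"]), 29)
  expect_equal(unname(pm3$mapping["30"]), 31)
  # mapping stays injective and invertible on mapped residues
  expect_false(any(duplicated(pm3$mapping)))
  inv <- stats::setNames(as.integer(names(pm3$mapping)), pm3$mapping)
  expect_equal(unname(inv[as.character(pm3$mapping)]),
               as.integer(names(pm3$mapping)))

  # an unrelated sequence fails the identity floor
  other <- allele_sequence("B*90:01", "HLA00002", strrep("W", 60))
  expect_error(map_residues_to_positions(m, "A", other), "mapping failure")
})

test_that("binder selection filters nonamers, sorts, and falls back by identity", {
  fam <- make_allele_family(base_length = 50, n_alleles = 8, n_polymorphic = 4,
                            seed = 13)
  db <- fam$alleles
  tab <- fam$binders
  with_own <- db[[tab$allele[1]]]
  sel <- select_binders(with_own, tab, k = 2, allele_db = db)
  expect_equal(sel$source_allele, with_own$allele_name)
  own_nonamers <- sort(tab$peptide[tab$allele == with_own$allele_name &
                                     nchar(tab$peptide) == 9])
  expect_equal(sel$peptides, head(own_nonamers, 2))
  expect_true(all(nchar(sel$peptides) == 9))

  # an allele without binders borrows from its closest relative
  no_binders <- db[[length(db)]]
  expect_false(no_binders$allele_name %in% tab$allele)
  sel2 <- select_binders(no_binders, tab, k = 10, allele_db = db)
  expect_true(sel2$source_allele %in% tab$allele)
  expect_lte(length(sel2$peptides), 10)

  # identity ties resolve to the lowest database identifier
  dbt <- list(
    a = allele_sequence("A*90:01", "HLA00007", strrep("A", 50)),
    b = allele_sequence("A*90:02", "HLA00002", strrep("A", 50)),
    q = allele_sequence("A*90:03", "HLA00009", strrep("A", 49))
  )
  tabt <- data.frame(allele = c("A*90:01", "A*90:02"),
                     peptide = c("AAAAAAAAA", "CCCCCCCCC"))
  sel3 <- select_binders(dbt$q, tabt, k = 1, allele_db = dbt)
  expect_equal(sel3$source_allele, "A*90:02")  # HLA00002 < HLA00007

  expect_error(select_binders(dbt$q, data.frame(allele = "A*90:01",
                                                peptide = "AAAA"),
                              allele_db = dbt),
               "no nonamer")
})

test_that("FASTA round-trip and ingest manifest work on a synthetic family", {
  fam <- make_allele_family(base_length = 40, n_alleles = 6, n_polymorphic = 3,
                            seed = 31)
  dir <- tempfile()
  paths <- write_allele_family(fam, dir)
  db <- read_allele_fasta(paths["fasta"])
  expect_equal(names(db), names(fam$alleles))
  expect_equal(db[[3]]$sequence, fam$alleles[[3]]$sequence)
  expect_equal(db[[2]]$locus, fam$alleles[[2]]$locus)

  pdb_dir <- file.path(dir, "structures")
  dir.create(pdb_dir)
  for (a in fam$alleles[1:2]) {
    write_pdb(make_hla_fixture(a), file.path(pdb_dir, paste0(a$allele_id, ".pdb")))
  }
  manifest <- ingest_structures(pdb_dir, db, score_threshold = 100,
                                out = file.path(dir, "manifest.tsv"))
  expect_equal(nrow(manifest), 2)
  expect_true(all(manifest$accepted))
  expect_equal(sort(manifest$allele_name),
               sort(unname(vapply(fam$alleles[1:2], function(a) a$allele_name, ""))))
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
})
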