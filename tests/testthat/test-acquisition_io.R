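test_that("read_fasta extracts records in order and normalizes case", {
  f <- write_tmp(c(">a", "MKV", ">b", "MK"), ".fasta")
  rec <- read_fasta(f)
  expect_equal(rec$id, c("a", "b"))
  expect_equal(rec$sequence, c("MKV", "MK"))

  f2 <- write_tmp(c(">lc", "mkv"), ".fasta")
  expect_equal(read_fasta(f2)$sequence, "MKV")
})

test_that("read_fasta rejects degenerate and non-FASTA input naming the line", {
  expect_error(read_fasta(write_tmp(c(">only_header"), ".fasta")),
               "empty sequence at line 1")
  expect_error(read_fasta(write_tmp(c("MKV", "MKL"), ".fasta")),
               "line 1")
  expect_error(read_fasta(write_tmp(character(0), ".fasta")), "empty")
  expect_error(read_fasta(write_tmp(c(">a", "MKV", ">gap", "", ">b", "ML"),
                                    ".fasta")),
               "empty sequence at line 3")
})

test_that("FASTA round-trip is identity on (id, sequence)", {
  rec <- data.frame(id = c("s1", "s2", "s3"),
                    sequence = c("MKVLA", "GG", "WYVRNDC"))
  f <- tempfile(fileext = ".fasta")
  write_fasta(rec, f)
  expect_equal(read_fasta(f), rec)
})

test_that("non-standard residue codes are flagged, not rejected", {
  f <- write_tmp(c(">x", "MKXB-Z"), ".fasta")
  expect_warning(rec <- read_fasta(f), "non-standard")
  expect_equal(rec$sequence, "MKXB-Z")
})

test_that("read_structure parses a toy PDB and its mmCIF rendering equally", {
  pdbf <- tempfile(fileext = ".pdb")
  make_toy_pdb("GAG", file = pdbf, ca_only = TRUE)
  m <- read_structure(pdbf)
  expect_equal(m$seq_index, 1:3)
  expect_equal(m$aa, c("G", "A", "G"))
  expect_equal(m$confidence, rep(90, 3))

  ciff <- tempfile(fileext = ".cif")
  make_toy_cif("GAVLK", file = ciff)
  pdbf2 <- tempfile(fileext = ".pdb")
  make_toy_pdb("GAVLK", file = pdbf2)
  a <- read_structure(pdbf2)
  b <- suppressWarnings(read_structure(ciff))
  expect_equal(a$aa, b$aa)
  expect_equal(a$seq_index, b$seq_index)
  expect_equal(a$confidence, b$confidence)
  expect_equal(a$atoms[, c("x", "y", "z")], b$atoms[, c("x", "y", "z")])
})

test_that("read_structure rejects structures without protein residues", {
  f <- write_tmp(c(
    "HETATM    1  O   HOH A   1      10.000  10.000  10.000  1.00  0.00           O",
    "END"), ".pdb")
  expect_error(suppressWarnings(read_structure(f)), "zero protein residues")
})

test_that("parse_dssp reads classic format, maps blank SS to C, skips breaks", {
  f <- dssp_classic_fixture(aa = c("M", "K", "V"), ss = c("H", "C", "E"),
                            acc = c(12, 100, 0), break_after = 2)
  rec <- parse_dssp(f)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$ss_code, c("H", "C", "E"))
  expect_equal(rec$acc, c(12, 100, 0))
  expect_true(all(rec$ss_code %in% c("G","H","I","E","B","T","S","P","C")))
})

test_that("parse_dssp reads the mmCIF dialect equivalently", {
  f <- tempfile(fileext = ".dssp")
  tagsite:::write_dssp_mmcif(c("M", "K", "V"), c("H", "C", "E"),
                             c(12, 100, 0), f)
  rec <- parse_dssp(f)
  expect_equal(rec$ss_code, c("H", "C", "E"))
  expect_equal(rec$acc, c(12, 100, 0))
})

test_that("parse_dssp errors on malformed rows with a line number", {
  f <- write_tmp(c(
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
    "    1    1 A M  H                 garbage-here"), ".dssp")
  expect_error(parse_dssp(f), "line 2")
})

test_that("parse_anchor2 reads long and two-column dialects", {
  f <- write_tmp(c("# IUPred2A", "# POS RES IUPRED2 ANCHOR2",
                   "5\tA\t0.41\t0.87"), ".txt")
  rec <- parse_anchor2(f)
  expect_equal(rec$seq_index, 5)
  expect_equal(rec$br, 0.87)

  f2 <- write_tmp(c("1 0.25", "2 0.50"), ".txt")
  expect_equal(parse_anchor2(f2)$br, c(0.25, 0.5))
})

test_that("parse_anchor2 enforces the [0,1] propensity invariant", {
  f <- write_tmp(c("5 A 0.41 1.2"), ".txt")
  expect_error(parse_anchor2(f), "outside \\[0,1\\]")
  expect_warning(empty <- parse_anchor2(write_tmp(c("# only", "# comments"))),
                 "no data rows")
  expect_equal(nrow(empty), 0)
})

test_that("parse_blast_tabular returns all rows with typed fields", {
  f <- write_tmp(c(
    paste(c("q", "Homo_sapiens|P1", 95, 100, 5, 0, 1, 100, 1, 100,
            "1e-50", 300), collapse = "\t"),
    paste(c("q", "Mus_musculus|Q1", 88, 100, 12, 0, 1, 100, 1, 100,
            "3e-10", 200), collapse = "\t")), ".tsv")
  hits <- parse_blast_tabular(f)
  expect_equal(nrow(hits), 2)
  expect_equal(hits$evalue, c(1e-50, 3e-10))
  expect_equal(hits$subject_species, c("Homo sapiens", "Mus musculus"))

  f0 <- write_tmp(paste(c("q", "s|x", 90, 10, 1, 0, 1, 10, 1, 10, "0.0", 50),
                        collapse = "\t"), ".tsv")
  expect_equal(parse_blast_tabular(f0)$evalue, 0)
})

test_that("parse_blast_tabular rejects truncated and non-numeric rows", {
  expect_error(parse_blast_tabular(write_tmp("q\ts\t90", ".tsv")),
               ">= 12 columns")
  bad <- write_tmp(paste(c("q", "s|x", 90, 10, 1, 0, 1, 10, 1, 10,
                           "not-a-number", 50), collapse = "\t"), ".tsv")
  expect_error(parse_blast_tabular(bad), "non-numeric E value")
})

test_that("fetch_query validates the accession before any request", {
  expect_error(fetch_query("??", offline = TRUE), "malformed")
  expect_error(fetch_query("Q9W7E7", offline = TRUE), "offline")
  expect_silent(validate_accession("A0A2R8QIW0"))
})
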