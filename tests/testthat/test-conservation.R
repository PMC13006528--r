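make_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(query_id = "q", subject_id = r[[1]], subject_species = r[[2]],
               evalue = as.numeric(r[[3]]), bitscore = as.numeric(r[[4]]),
               subject_sequence = NA_character_, stringsAsFactors = FALSE)
  }))
}

test_that("select_best_hits keeps the lowest-E-value hit per species", {
  hits <- make_hits(list("h1", "Homo sapiens", 1e-5, 100),
                    list("h2", "Homo sapiens", 1e-50, 90))
  hs <- suppressWarnings(select_best_hits(hits))
  expect_equal(hs$hits$subject_id, "h2")
})

test_that("ties on E value break by bitscore, then file order", {
  hits <- make_hits(list("a", "Mus musculus", 1e-20, 200),
                    list("b", "Mus musculus", 1e-20, 300),
                    list("c", "Mus musculus", 1e-20, 300))
  hs <- suppressWarnings(select_best_hits(hits))
  expect_equal(hs$hits$subject_id, "b")
})

test_that("species without hits are reported missing, not fatal", {
  hits <- make_hits(list("h1", "Homo sapiens", 1e-40, 300),
                    list("h2", "Mus musculus", 1e-30, 250),
                    list("h3", "Gallus gallus", 1e-20, 200),
                    list("h4", "Bos taurus", 1e-25, 220),
                    list("h5", "Canis lupus", 1e-22, 210))
  expect_warning(hs <- select_best_hits(hits), "Takifugu rubripes")
  expect_equal(nrow(hs$hits), 5)
  expect_setequal(hs$missing, c("Takifugu rubripes", "Xenopus tropicalis"))
  expect_error(select_best_hits(make_hits()[0, ]), "empty")
})

test_that("build_msa via the pre-aligned adapter reproduces the file", {
  seqs <- data.frame(id = c("q", "h1", "h2"),
                     sequence = c("MKV", "MAKV", "MAKC"))
  aln <- build_msa(seqs, prealigned_adapter(tiny_alignment_file()),
                   query_id = "q")
  expect_s3_class(aln, "Alignment")
  expect_equal(aln$seqs, c("M-KV", "MAKV", "MAKC"))
})

test_that("build_msa enforces the alignment invariants", {
  seqs <- data.frame(id = c("q", "h1"), sequence = c("MKV", "MAKV"))
  bad <- write_tmp(c(">q", "M-KV", ">h1", "MAKVA"), ".fasta")
  expect_error(build_msa(seqs, prealigned_adapter(bad), query_id = "q"),
               "unequal lengths")
  expect_error(build_msa(seqs[1, , drop = FALSE], prealigned_adapter(bad)),
               ">=2 sequences")
  # ungapped query row must equal the query sequence
  wrong <- write_tmp(c(">q", "MAAV", ">h1", "MAKV"), ".fasta")
  expect_error(build_msa(seqs, prealigned_adapter(wrong), query_id = "q"),
               "query row")
})

test_that("build_msa works through an external aligner (mafft)", {
  seqs <- data.frame(id = c("q", "h1", "h2"),
                     sequence = c("MKVLIKKW", "MKVLAIKKW", "MKVIKKW"))
  aln <- build_msa(seqs, external_aligner_adapter("mafft"), query_id = "q")
  expect_equal(gsub("-", "", aln$seqs[aln$ids == "q"]), "MKVLIKKW")
  expect_equal(length(unique(nchar(aln$seqs))), 1L)
})

test_that("map_columns_to_query maps non-gap query positions to columns", {
  aln <- read_alignment(tiny_alignment_file(), query_id = "q")
  expect_equal(map_columns_to_query(aln), c(0L, 2L, 3L))

  gapless <- read_alignment(write_tmp(c(">q", "MKVL", ">h", "MKVA"), ".fasta"),
                            query_id = "q")
  expect_equal(map_columns_to_query(gapless), 0:3)

  allgap <- read_alignment(write_tmp(c(">q", "---", ">h", "MKV"), ".fasta"),
                           query_id = "q")
  expect_error(map_columns_to_query(allgap), "all gaps")
})

test_that("shannon_entropy matches hand values and stays within bounds", {
  expect_equal(shannon_entropy(c("A", "A", "A", "A")), 0)
  expect_equal(shannon_entropy(c("A", "A", "C", "C")), 1)
  expect_equal(shannon_entropy(AA20), log2(20), tolerance = 1e-12)
  expect_equal(shannon_entropy(c("A", "-", "-")), 0)  # <2 counted residues
})

test_that("shannon_entropy equals the brute-force oracle on random columns", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(2:8, 1)
    col <- sample(c(AA20, "-", "X"), n, replace = TRUE)
    expect_equal(shannon_entropy(col), brute_entropy(col), tolerance = 1e-12)
  }
})

test_that("entropy is permutation- and duplication-invariant, gap-invariant", {
  set.seed(7)
  for (i in 1:50) {
    col <- sample(AA20, sample(3:8, 1), replace = TRUE)
    h <- shannon_entropy(col)
    expect_equal(shannon_entropy(sample(col)), h, tolerance = 1e-12)
    expect_equal(shannon_entropy(rep(col, 3)), h, tolerance = 1e-12)
    expect_equal(shannon_entropy(c(col, "-")), h, tolerance = 1e-12)
    expect_equal(shannon_entropy(c(col, "X")), h, tolerance = 1e-12)
  }
})

test_that("entropy_feature normalizes by 4.32 and clips to [0,1]", {
  # fully conserved columns -> all-zero track
  cons <- read_alignment(write_tmp(c(">q", "MMM", ">h1", "MMM", ">h2", "MMM"),
                                   ".fasta"), query_id = "q")
  expect_equal(entropy_feature(cons), c(0, 0, 0))

  # two residues at p = (0.5, 0.5) -> 1 bit / 4.32
  half <- read_alignment(write_tmp(c(">q", "A", ">h1", "C"), ".fasta"),
                         query_id = "q")
  expect_equal(entropy_feature(half), 1 / 4.32, tolerance = 1e-12)

  # maximally diverse column: 20 distinct residues -> clipped to 1
  rows <- as.vector(rbind(paste0(">s", 1:20), AA20))
  rows[1] <- ">q"
  div <- read_alignment(write_tmp(rows, ".fasta"), query_id = "q")
  expect_equal(entropy_feature(div), 1)
})

test_that("entropy track length equals query length with values in [0,1]", {
  set.seed(3)
  for (i in 1:10) {
    L <- sample(5:30, 1)
    n <- sample(3:8, 1)
    seqs <- c(paste(sample(AA20, L, TRUE), collapse = ""),
              replicate(n - 1, paste(sample(AA20, L, TRUE), collapse = "")))
    f <- write_tmp(as.vector(rbind(paste0(">r", 1:n), seqs)), ".fasta")
    tr <- entropy_feature(read_alignment(f, query_id = "r1"))
    expect_length(tr, L)
    expect_true(all(tr >= 0 & tr <= 1))
  }
})
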