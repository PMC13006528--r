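# Shared helpers: small literal fixtures written to tempfiles at test time.

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# a tiny 3-row pre-aligned FASTA (query row "q")
tiny_alignment_file <- function() {
  write_tmp(c(">q", "M-KV", ">h1", "MAKV", ">h2", "MAKC"), ".fasta")
}

# brute-force column entropy over the 20 standard codes
AA20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S",
          "T","W","Y","V")
brute_entropy <- function(column) {
  counted <- toupper(column)[toupper(column) %in% AA20]
  if (length(counted) < 2) return(0)
  h <- 0
  for (a in unique(counted)) {
    p <- sum(counted == a) / length(counted)
    h <- h - p * log2(p)
  }
  h
}

# brute-force clipped centered window mean
brute_window <- function(x, window) {
  h <- (window - 1) / 2
  out <- numeric(length(x))
  for (p in seq_along(x)) {
    acc <- 0; n <- 0
    for (q in seq_along(x)) {
      if (q >= p - h && q <= p + h) { acc <- acc + x[q]; n <- n + 1 }
    }
    out[p] <- acc / n
  }
  out
}

# classic-format DSSP fixture built from (aa, ss, acc) triples; ss "C" is
# written blank, and a "!" break row can be injected
dssp_classic_fixture <- function(aa, ss, acc, break_after = NULL) {
  ssf <- ifelse(ss == "C", " ", ss)
  rows <- sprintf("%5d%5d %1s %1s  %1s%17s%4d", seq_along(aa), seq_along(aa),
                  "A", aa, ssf, "", as.integer(acc))
  if (!is.null(break_after)) {
    brk <- sprintf("%5d      %1s %1s", break_after + 1L, " ", "!")
    rows <- append(rows, brk, after = break_after)
  }
  write_tmp(c(
    "==== Secondary Structure Definition by the program DSSP ====",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N    TCO",
    rows), ".dssp")
}
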