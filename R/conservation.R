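# Sequence-conservation feature: one homolog per species by best BLAST hit,
# MSA handling, alignment-column-to-query mapping, and the normalized
# Shannon-entropy track.

#' Default homolog species panel
#'
#' Seven vertebrate species spanning mammals, bird, amphibian and teleost,
#' used to measure conservation of a (typically zebrafish) query protein.
#' @export
DEFAULT_SPECIES <- c("Bos taurus", "Canis lupus", "Gallus gallus",
                     "Homo sapiens", "Mus musculus", "Takifugu rubripes",
                     "Xenopus tropicalis")

#' Select the best BLAST hit per species
#'
#' For each species in the panel, keeps the hit with the lowest E value
#' (ties broken by highest bitscore, then file order). Species with no hit
#' are reported with a warning, not an error.
#'
#' @param hits data.frame as returned by [parse_blast_tabular()].
#' @param species_list Species panel; default the seven-species vertebrate
#'   panel in [DEFAULT_SPECIES].
#' @return A list of class `HomologSet`: `hits` (one row per covered
#'   species), `missing` (species without hits).
#' @export
select_best_hits <- function(hits, species_list = DEFAULT_SPECIES) {
  if (!is.data.frame(hits) || nrow(hits) == 0) stop("empty BLAST hit list")
  picked <- lapply(species_list, function(sp) {
    h <- hits[hits$subject_species == sp, , drop = FALSE]
    if (nrow(h) == 0) return(NULL)
    h$.ord <- seq_len(nrow(h))
    h <- h[order(h$evalue, -h$bitscore, h$.ord), , drop = FALSE]
    h$.ord <- NULL
    h[1, , drop = FALSE]
  })
  covered <- !vapply(picked, is.null, logical(1))
  missing <- species_list[!covered]
  if (length(missing) > 0) {
    warning("no BLAST hit for species: ", paste(missing, collapse = ", "))
  }
  best <- do.call(rbind, picked[covered])
  rownames(best) <- NULL
  structure(list(hits = best, missing = missing), class = "HomologSet")
}

#' File-based aligner adapter (pre-aligned input)
#'
#' Satisfies the aligner-adapter contract (unaligned FASTA path in, aligned
#' FASTA path out) by returning a pre-computed alignment, enabling fully
#' offline runs and tests.
#' @param aligned_path Path to an aligned FASTA file.
#' @return A function usable as the `aligner` argument of [build_msa()].
#' @export
prealigned_adapter <- function(aligned_path) {
  force(aligned_path)
  function(unaligned_path) aligned_path
}

#' External aligner adapter
#'
#' Wraps a command-line multiple aligner that reads FASTA on argv and
#' writes aligned FASTA to stdout (MUSCLE- or MAFFT-style). The default
#' command is `mafft`.
#' @param command Aligner executable.
#' @param args Extra arguments placed before the input path.
#' @return A function usable as the `aligner` argument of [build_msa()].
#' @export
external_aligner_adapter <- function(command = "mafft",
                                     args = c("--auto", "--quiet")) {
  function(unaligned_path) {
    if (Sys.which(command) == "") {
      stop("aligner '", command, "' not found on PATH; supply a ",
           "pre-aligned FASTA via prealigned_adapter() instead")
    }
    out <- tempfile(fileext = ".afa")
    status <- system2(command, c(args, shQuote(unaligned_path)),
                      stdout = out, stderr = FALSE)
    if (status != 0 || !file.exists(out)) {
      stop("aligner '", command, "' failed with status ", status)
    }
    out
  }
}

#' Build or ingest a multiple sequence alignment
#'
#' @param sequences data.frame of unaligned records (`id`, `sequence`),
#'   query first or identified by `query_id`.
#' @param aligner Adapter function: unaligned FASTA path -> aligned FASTA
#'   path ([prealigned_adapter()], [external_aligner_adapter()]).
#' @param query_id Id of the query row; default the first record's id.
#' @return A list of class `Alignment`: `ids`, `seqs` (aligned, with `-`
#'   gaps), `query_id`.
#' @export
build_msa <- function(sequences, aligner, query_id = sequences$id[1]) {
  stopifnot(is.data.frame(sequences))
  if (nrow(sequences) < 2) stop(">=2 sequences required to build an MSA")
  if (!query_id %in% sequences$id) stop("query id '", query_id, "' not among sequences")
  tmp <- tempfile(fileext = ".fasta")
  write_fasta(sequences, tmp)
  aligned_path <- aligner(tmp)
  aln <- read_fasta(aligned_path, allow_gaps = TRUE)
  widths <- nchar(aln$sequence)
  if (length(unique(widths)) != 1) {
    stop("aligned sequences have unequal lengths: ",
         paste(unique(widths), collapse = ", "))
  }
  if (!query_id %in% aln$id) stop("query row '", query_id, "' absent from alignment")
  qrow <- aln$sequence[aln$id == query_id][1]
  qseq <- sequences$sequence[sequences$id == query_id][1]
  if (gsub("-", "", qrow) != toupper(qseq)) {
    stop("ungapped query row does not equal the query sequence")
  }
  structure(list(ids = aln$id, seqs = aln$sequence, query_id = query_id),
            class = "Alignment")
}

#' Load a pre-aligned FASTA as an Alignment
#' @param path Aligned FASTA.
#' @param query_id Id of the query row; default first record.
#' @return An `Alignment`.
#' @export
read_alignment <- function(path, query_id = NULL) {
  aln <- read_fasta(path, allow_gaps = TRUE)
  if (is.null(query_id)) query_id <- aln$id[1]
  widths <- nchar(aln$sequence)
  if (length(unique(widths)) != 1) {
    stop("aligned sequences have unequal lengths: ",
         paste(unique(widths), collapse = ", "))
  }
  if (!query_id %in% aln$id) stop("query row '", query_id, "' absent from alignment")
  structure(list(ids = aln$id, seqs = aln$sequence, query_id = query_id),
            class = "Alignment")
}

#' Map query positions to alignment columns
#'
#' Position `p` of the query maps to the alignment column holding its
#' `p`-th non-gap character (0-based column index).
#'
#' @param alignment An `Alignment`.
#' @return Integer vector: element `p` is the 0-based column for query
#'   position `p`; strictly increasing and total over the query.
#' @export
map_columns_to_query <- function(alignment) {
  stopifnot(inherits(alignment, "Alignment"))
  qrow <- alignment$seqs[alignment$ids == alignment$query_id][1]
  if (is.na(qrow)) stop("query row absent from alignment")
  chars <- strsplit(qrow, "")[[1]]
  cols <- which(chars != "-") - 1L
  if (length(cols) == 0) stop("query row is all gaps")
  cols
}

#' Shannon entropy of an alignment column
#'
#' `H = -sum_a p(a) log2 p(a)` over the 20 standard amino acids, with
#' frequencies computed after removing gaps and non-standard codes
#' (treated as missing data, not a 21st symbol). Columns with fewer than
#' two counted residues return 0.
#'
#' @param column Character vector of residue characters.
#' @return Entropy in bits, in \[0, log2(20)\].
#' @export
shannon_entropy <- function(column) {
  if (length(column) == 0) stop("empty alignment column")
  counted <- toupper(column)[toupper(column) %in% STANDARD_AA]
  if (length(counted) < 2) return(0)
  p <- table(counted) / length(counted)
  -sum(p * log2(p)) + 0  # + 0 normalizes IEEE -0 for fully conserved columns
}

#' Normalized Shannon-entropy feature track
#'
#' Per query position, the column entropy divided by the normalization
#' maximum (4.32 bits, the maximum entropy over 20 amino acids at the
#' precision used throughout; `log2(20)` at full precision is available via
#' `normalizer`), clipped to \[0,1\]. Higher values mean lower conservation
#' and greater suitability for tag insertion.
#'
#' @param alignment An `Alignment` containing the query row.
#' @param normalizer Normalization constant in bits; default 4.32.
#' @return Numeric vector of length equal to the ungapped query length,
#'   values in \[0,1\].
#' @export
entropy_feature <- function(alignment, normalizer = 4.32) {
  cols <- map_columns_to_query(alignment)
  mat <- do.call(rbind, strsplit(alignment$seqs, ""))
  vals <- vapply(cols + 1L, function(cc) shannon_entropy(mat[, cc]), numeric(1))
  pmin(pmax(vals / normalizer, 0), 1)
}
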