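# Optional network mode: fetch query sequence + predicted structure by
# UniProt accession. Everything else in the package works offline; every
# test passes with these fetchers disabled.

UNIPROT_ACCESSION_RE <-
  "^([OPQ][0-9][A-Z0-9]{3}[0-9]|[A-NR-Z][0-9]([A-Z][A-Z0-9]{2}[0-9]){1,2})$"

#' Validate a UniProt accession
#' @param accession Candidate accession string.
#' @return TRUE invisibly; errors on malformed input.
#' @export
validate_accession <- function(accession) {
  if (!is.character(accession) || length(accession) != 1 ||
      !grepl(UNIPROT_ACCESSION_RE, accession)) {
    stop("malformed UniProt accession: '", accession, "'")
  }
  invisible(TRUE)
}

#' Fetch a query protein by UniProt accession (network mode)
#'
#' Downloads the sequence from the UniProt REST endpoint and the predicted
#' structure from the AlphaFold model repository, caching both under
#' `cache_dir`. The structure's B-factor column is exposed as pLDDT
#' confidence. The sequence and structure lengths must agree.
#'
#' @param accession UniProt accession (validated before any request).
#' @param cache_dir Cache directory; fetched files are reused on re-runs.
#' @param offline Logical; when TRUE, error before any network activity.
#' @return A list of class `QueryProtein` with `accession`, `sequence`,
#'   and `structure` (a `StructureModel`).
#' @export
fetch_query <- function(accession,
                        cache_dir = file.path(tempdir(), "tagsite-cache"),
                        offline = FALSE) {
  validate_accession(accession)
  if (offline) stop("offline mode: cannot fetch accession ", accession)
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(cache_dir, paste0(accession, ".fasta"))
  pdbf <- file.path(cache_dir, paste0("AF-", accession, "-F1.pdb"))
  if (!file.exists(fasta)) {
    url <- paste0("https://rest.uniprot.org/uniprotkb/", accession, ".fasta")
    ok <- tryCatch(utils::download.file(url, fasta, quiet = TRUE) == 0,
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) { unlink(fasta); stop("failed to fetch UniProt sequence: ", url) }
  }
  if (!file.exists(pdbf)) {
    url <- paste0("https://alphafold.ebi.ac.uk/files/AF-", accession,
                  "-F1-model_v4.pdb")
    ok <- tryCatch(utils::download.file(url, pdbf, quiet = TRUE) == 0,
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) { unlink(pdbf); stop("failed to fetch AlphaFold model: ", url) }
  }
  seq <- read_fasta(fasta)
  model <- read_structure(pdbf, af_model = TRUE)
  if (nchar(seq$sequence[1]) != length(model$seq_index)) {
    stop("sequence/structure length mismatch for ", accession, ": ",
         nchar(seq$sequence[1]), " vs ", length(model$seq_index))
  }
  structure(list(accession = accession, sequence = seq$sequence[1],
                 structure = model), class = "QueryProtein")
}
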