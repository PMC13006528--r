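# Disordered-binding-region feature: the complement of the ANCHOR2
# binding propensity, so that high values mark residues unlikely to sit in
# a protein-binding interface and therefore suitable for tag insertion.

#' Disordered-binding-region feature track
#'
#' Per residue, `1 - BR` where BR is the ANCHOR2 binding propensity. No
#' smoothing is applied here; windowing happens only at the combined-score
#' stage.
#'
#' @param records data.frame from [parse_anchor2()] (`seq_index`, `br`),
#'   covering positions 1..`query_length` exactly once.
#' @param query_length Query sequence length.
#' @return Numeric vector of length `query_length`, values in \[0,1\].
#' @export
dbr_feature <- function(records, query_length) {
  stopifnot(is.data.frame(records), query_length >= 1)
  dup <- unique(records$seq_index[duplicated(records$seq_index)])
  if (length(dup) > 0) {
    stop("duplicate ANCHOR2 positions: ", paste(dup, collapse = ", "))
  }
  gaps <- setdiff(seq_len(query_length), records$seq_index)
  extra <- setdiff(records$seq_index, seq_len(query_length))
  if (length(gaps) > 0 || length(extra) > 0) {
    stop("ANCHOR2 coverage mismatch; missing position(s): ",
         paste(gaps, collapse = ", "),
         if (length(extra) > 0) paste0("; out-of-range position(s): ",
                                       paste(extra, collapse = ", ")))
  }
  out <- numeric(query_length)
  out[records$seq_index] <- 1 - records$br
  out
}
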