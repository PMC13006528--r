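# Combined per-residue scoring: assemble the four normalized feature
# tracks, compute the minimum-feature score E_i (a single unfavorable
# feature vetoes a site) and the weighted sum S_i, smooth E with a sliding
# window, and rank candidate insertion positions.

FEATURE_NAMES <- c("entropy", "secondary_structure", "rsa", "dbr")

#' Scoring configuration
#'
#' Default weights: entropy 1.5, all other features 1. Window 7 with
#' clipped centered averaging: the three positions nearest each terminus
#' average 4-6 residues instead of 7. `terminal_mode = "fixed4"` instead
#' averages exactly the four terminal residues at those positions.
#'
#' @param weights Named non-negative weights for
#'   entropy/secondary_structure/rsa/dbr.
#' @param window Odd window width >= 1 for smoothing the minimum score.
#' @param top_k Number of ranked candidate sites to report.
#' @param report_precision Decimal places for rounded report values.
#' @param terminal_mode `"clipped"` (default) or `"fixed4"`.
#' @return A list of class `ScoringConfig`.
#' @export
scoring_config <- function(weights = c(entropy = 1.5, secondary_structure = 1,
                                       rsa = 1, dbr = 1),
                           window = 7, top_k = 5, report_precision = 2,
                           terminal_mode = c("clipped", "fixed4")) {
  if (!all(FEATURE_NAMES %in% names(weights))) {
    stop("weights must name all of: ", paste(FEATURE_NAMES, collapse = ", "))
  }
  if (any(weights < 0)) stop("weights must be non-negative")
  if (all(weights == 0)) stop("at least one weight must be positive")
  if (window < 1 || window %% 2 == 0) stop("window must be odd and >= 1")
  if (top_k < 1) stop("top_k must be >= 1")
  structure(list(weights = weights[FEATURE_NAMES], window = as.integer(window),
                 top_k = as.integer(top_k),
                 report_precision = as.integer(report_precision),
                 terminal_mode = match.arg(terminal_mode)),
            class = "ScoringConfig")
}

#' Assemble the per-position feature matrix
#'
#' Normalization is upstream's job: any value outside \[0,1\] is an error
#' here, not silently clipped.
#'
#' @param entropy,ss,rsa,dbr Numeric tracks of equal length, values in \[0,1\].
#' @return Matrix (length x 4) with columns entropy, secondary_structure,
#'   rsa, dbr.
#' @export
assemble_features <- function(entropy, ss, rsa, dbr) {
  tracks <- list(entropy = entropy, secondary_structure = ss,
                 rsa = rsa, dbr = dbr)
  lens <- lengths(tracks)
  if (length(unique(lens)) != 1) {
    stop("feature tracks have unequal lengths: ",
         paste(names(tracks), lens, sep = "=", collapse = ", "))
  }
  for (nm in names(tracks)) {
    v <- tracks[[nm]]
    if (anyNA(v) || any(v < 0 | v > 1)) {
      stop("track '", nm, "' contains values outside [0,1]")
    }
  }
  mat <- do.call(cbind, tracks)
  colnames(mat) <- FEATURE_NAMES
  mat
}

#' Minimum-feature score E_i
#'
#' The minimum of a residue's feature values: one unfavorable feature is
#' enough to veto the position.
#' @param feature_vector Numeric vector of feature values in \[0,1\].
#' @return The minimum value.
#' @export
min_score <- function(feature_vector) {
  if (length(feature_vector) == 0) stop("empty feature vector")
  min(feature_vector)
}

#' Weighted-sum score S_i
#'
#' `S_i = sum_f w_f * value_f`. With default weights the range is
#' \[0, 4.5\].
#' @param feature_vector Named numeric vector of feature values.
#' @param weights Named weights covering every feature in `feature_vector`.
#' @return The weighted sum.
#' @export
weighted_score <- function(feature_vector,
                           weights = scoring_config()$weights) {
  miss <- setdiff(names(feature_vector), names(weights))
  if (length(miss) > 0) {
    stop("missing weight for feature(s): ", paste(miss, collapse = ", "))
  }
  sum(weights[names(feature_vector)] * feature_vector)
}

#' Sliding-window average with clipped terminal windows
#'
#' Value at position `p` is the mean of the track over
#' `max(1, p-h) .. min(L, p+h)` with `h = (window-1)/2`; for window 7 the
#' three positions at each terminus therefore average four to six residues.
#' With `terminal_mode = "fixed4"` the three positions at each terminus
#' instead average exactly the four terminal residues.
#'
#' @param track Numeric vector (length >= 1).
#' @param window Odd window width.
#' @param terminal_mode `"clipped"` or `"fixed4"`.
#' @return Smoothed track, same length.
#' @export
window_average <- function(track, window = 7,
                           terminal_mode = c("clipped", "fixed4")) {
  terminal_mode <- match.arg(terminal_mode)
  L <- length(track)
  if (L < 1) stop("track must have length >= 1")
  if (window < 1 || window %% 2 == 0) stop("window must be odd and >= 1")
  h <- (window - 1) / 2
  out <- vapply(seq_len(L), function(p) {
    mean(track[max(1, p - h):min(L, p + h)])
  }, numeric(1))
  if (terminal_mode == "fixed4" && L >= 4) {
    nterm <- seq_len(min(h, L))
    cterm <- seq2(L - min(h, L) + 1L, L)
    out[nterm] <- mean(track[1:4])
    out[cterm] <- mean(track[(L - 3):L])
  }
  out
}

#' Score every residue of a protein
#'
#' @param features Feature matrix from [assemble_features()].
#' @param config A `ScoringConfig`.
#' @param aa Optional character vector of residues (reported in the table).
#' @return data.frame with one row per position: position, aa, the four
#'   features, `e_min` (minimum-feature score), `s_weighted` (weighted
#'   sum), `e_windowed` (window-averaged minimum score).
#' @export
score_residues <- function(features, config = scoring_config(), aa = NULL) {
  stopifnot(is.matrix(features), ncol(features) == 4)
  e_min <- apply(features, 1, min_score)
  s_weighted <- apply(features, 1, weighted_score, weights = config$weights)
  e_windowed <- window_average(e_min, config$window, config$terminal_mode)
  data.frame(position = seq_len(nrow(features)),
             aa = if (is.null(aa)) NA_character_ else aa,
             entropy = features[, "entropy"],
             secondary_structure = features[, "secondary_structure"],
             rsa = features[, "rsa"], dbr = features[, "dbr"],
             e_min = e_min, s_weighted = s_weighted,
             e_windowed = e_windowed, stringsAsFactors = FALSE)
}

#' Rank candidate tag-insertion sites
#'
#' Candidates are sorted by windowed minimum score descending (ties by
#' ascending position); the top `top_k` are returned plus every position
#' tied with the k-th. The terminal positions (1 and L) are always
#' reported separately for N/C-terminal comparison.
#'
#' @param scores data.frame from [score_residues()].
#' @param top_k Number of candidates; default from `config`.
#' @param accession Optional query accession echoed in the report.
#' @param config A `ScoringConfig` (echoed in the report).
#' @return A list of class `TagSiteReport`: `accession`, `config`,
#'   `scores`, `candidates` (position, e_windowed, e_min), `terminals`.
#' @export
rank_sites <- function(scores, top_k = NULL, accession = NA_character_,
                       config = scoring_config()) {
  stopifnot(is.data.frame(scores),
            all(c("position", "e_min", "e_windowed") %in% names(scores)))
  if (is.null(top_k)) top_k <- config$top_k
  ord <- order(-scores$e_windowed, scores$position)
  ranked <- scores[ord, c("position", "e_windowed", "e_min")]
  rownames(ranked) <- NULL
  k <- min(top_k, nrow(ranked))
  kth <- ranked$e_windowed[k]
  # all positions tied with the k-th are included
  cand <- ranked[seq_len(max(which(ranked$e_windowed == kth))), , drop = FALSE]
  if (length(unique(scores$e_windowed)) == 1 && nrow(scores) > 1) {
    warning("all positions are tied at e_windowed = ", kth)
  }
  L <- max(scores$position)
  terminals <- scores[scores$position %in% c(1L, L),
                      c("position", "e_windowed", "e_min")]
  rownames(terminals) <- NULL
  structure(list(accession = accession, config = config, scores = scores,
                 candidates = cand, terminals = terminals),
            class = "TagSiteReport")
}

#' @export
print.TagSiteReport <- function(x, ...) {
  p <- x$config$report_precision
  cat("Tag-insertion site report",
      if (!is.na(x$accession)) paste0(" for ", x$accession), "\n", sep = "")
  cat(" query length:", nrow(x$scores), "residues\n")
  cat(" top candidate sites (windowed minimum-feature score):\n")
  top <- utils::head(x$candidates, 10)
  for (i in seq_len(nrow(top))) {
    cat(sprintf("   position %4d  windowed %.*f  raw %.*f\n",
                top$position[i], p, top$e_windowed[i], p, top$e_min[i]))
  }
  cat(" terminals:\n")
  for (i in seq_len(nrow(x$terminals))) {
    cat(sprintf("   position %4d  windowed %.*f  raw %.*f\n",
                x$terminals$position[i], p, x$terminals$e_windowed[i],
                p, x$terminals$e_min[i]))
  }
  invisible(x)
}
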