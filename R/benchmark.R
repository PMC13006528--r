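# Benchmark harness: the insertion-variant pathogenicity evaluation
# protocol — encode features of labeled in-frame insertion variants, fit a
# logistic model on a stratified 80:20 split, and report precision, recall
# and F1 — runnable end-to-end on a class-conditional simulator.

SS_CODE_LEVELS <- c("C", "T", "S", "G", "H", "I", "E", "B", "P")

# run expr with a local RNG state seeded by `seed`, restoring the global
# state afterwards
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulation parameters for labeled insertion variants
#'
#' Class-conditional feature distributions for a synthetic stand-in for a
#' curated pathogenic/benign in-frame insertion dataset. Defaults mirror
#' the 401 pathogenic / 433 benign class structure of the V5-length
#' insertion benchmark. Features are drawn from Beta distributions around
#' class means; DSSP codes from class-conditional categorical
#' distributions; benign variants sit in taggable-looking contexts (high
#' entropy/RSA, coil, low binding propensity), pathogenic the reverse.
#' `separation` in \[0, ~2\] scales the class contrast (0 = identical
#' classes).
#'
#' @param n_pathogenic,n_benign Class sizes.
#' @param separation Class-contrast multiplier (default 1).
#' @param concentration Beta concentration (larger = tighter spread).
#' @param seed RNG seed; the simulated dataset is a deterministic function
#'   of the parameters and this seed.
#' @return A list of class `SimulationParams`.
#' @export
simulation_params <- function(n_pathogenic = 401, n_benign = 433,
                              separation = 1, concentration = 8, seed = 1) {
  if (n_pathogenic <= 0 || n_benign <= 0) stop("class counts must be > 0")
  if (separation < 0) stop("separation must be >= 0")
  if (concentration <= 0) stop("concentration must be > 0")
  delta <- c(entropy = 0.15, rsa = 0.20, dbr = 0.25)
  clamp <- function(x) pmin(pmax(x, 0.02), 0.98)
  base_probs <- c(C = 0.25, T = 0.10, S = 0.10, G = 0.05, H = 0.25,
                  I = 0.02, E = 0.18, B = 0.03, P = 0.02)
  shift <- c(C = 0.30, T = 0.05, S = 0.05, G = -0.03, H = -0.20,
             I = -0.01, E = -0.13, B = -0.02, P = -0.01)
  mix <- function(sign) {
    p <- pmax(base_probs + sign * pmin(separation, 1) * shift, 0.001)
    p / sum(p)
  }
  structure(list(
    n_pathogenic = as.integer(n_pathogenic), n_benign = as.integer(n_benign),
    benign_means = clamp(0.5 + delta * separation),
    pathogenic_means = clamp(0.5 - delta * separation),
    concentration = concentration,
    ss_probs_benign = mix(+1), ss_probs_pathogenic = mix(-1),
    seed = as.integer(seed)
  ), class = "SimulationParams")
}

#' Simulate labeled insertion variants
#'
#' Draws entropy, RSA and DBR features from the class-conditional Beta
#' distributions and a DSSP code from the class-conditional categorical
#' distribution; the secondary-structure feature, the weighted sum
#' `s_weighted` and the minimum score `e_min` are then computed from the
#' sampled features through the scoring operations, never sampled
#' independently. Deterministic per seed.
#'
#' @param params A `SimulationParams`.
#' @return data.frame of variants: protein_id, position, label
#'   ("pathogenic"/"benign"), entropy, rsa, ss_code, ss_score, dbr,
#'   s_weighted, e_min.
#' @export
simulate_benchmark <- function(params = simulation_params()) {
  stopifnot(inherits(params, "SimulationParams"))
  k <- params$concentration
  draw_class <- function(n, means, ss_probs, label) {
    rb <- function(mu) stats::rbeta(n, mu * k, (1 - mu) * k)
    entropy <- rb(means[["entropy"]])
    rsa <- rb(means[["rsa"]])
    dbr <- rb(means[["dbr"]])
    ss_code <- sample(names(ss_probs), n, replace = TRUE, prob = ss_probs)
    data.frame(label = label, entropy = entropy, rsa = rsa,
               ss_code = ss_code, dbr = dbr, stringsAsFactors = FALSE)
  }
  out <- with_seed(params$seed, {
    rbind(
      draw_class(params$n_pathogenic, params$pathogenic_means,
                 params$ss_probs_pathogenic, "pathogenic"),
      draw_class(params$n_benign, params$benign_means,
                 params$ss_probs_benign, "benign")
    )
  })
  out$ss_score <- ss_feature(out$ss_code)
  w <- scoring_config()$weights
  feats <- cbind(entropy = out$entropy, secondary_structure = out$ss_score,
                 rsa = out$rsa, dbr = out$dbr)
  out$s_weighted <- apply(feats, 1, weighted_score, weights = w)
  out$e_min <- apply(feats, 1, min_score)
  out$protein_id <- sprintf("SYN%04d", seq_len(nrow(out)))
  out$position <- seq_len(nrow(out))
  out[, c("protein_id", "position", "label", "entropy", "rsa", "ss_code",
          "ss_score", "dbr", "s_weighted", "e_min")]
}

#' Encode the logistic-model design matrix
#'
#' Numeric columns in fixed order (entropy, rsa, ss_score, dbr,
#' s_weighted, e_min) followed by one-hot columns for each observed DSSP
#' code with the first (reference) code dropped. Labels are encoded
#' pathogenic = 1.
#'
#' @param variants data.frame of insertion variants (see
#'   [simulate_benchmark()] for the schema).
#' @param ss_levels Optional fixed DSSP-code levels (so train and test
#'   encode identically); default: codes observed in `variants`.
#' @return List with `x` (numeric matrix), `y` (0/1 integer vector),
#'   `ss_levels`.
#' @export
encode_design_matrix <- function(variants, ss_levels = NULL) {
  stopifnot(is.data.frame(variants))
  if (nrow(variants) < 2) stop(">=2 variants required")
  if (length(unique(variants$label)) < 2 && is.null(ss_levels)) {
    stop("both classes (pathogenic and benign) must be present")
  }
  num_cols <- c("entropy", "rsa", "ss_score", "dbr")
  for (nm in num_cols) {
    v <- variants[[nm]]
    if (any(v < 0 | v > 1)) stop("feature '", nm, "' outside [0,1]")
  }
  if (is.null(ss_levels)) {
    ss_levels <- intersect(SS_CODE_LEVELS, unique(variants$ss_code))
  }
  x <- as.matrix(variants[, c(num_cols[1:2], "ss_score",
                              num_cols[4], "s_weighted", "e_min")])
  colnames(x) <- c("entropy", "rsa", "ss_score", "dbr", "s_weighted", "e_min")
  if (length(ss_levels) >= 2) {
    hot <- ss_levels[-1]
    oh <- vapply(hot, function(code) as.numeric(variants$ss_code == code),
                 numeric(nrow(variants)))
    oh <- matrix(oh, nrow = nrow(variants),
                 dimnames = list(NULL, paste0("ss_", hot)))
    x <- cbind(x, oh)
  } else {
    warning("all variants share one secondary-structure code; ",
            "no one-hot columns encoded")
  }
  list(x = x, y = as.integer(variants$label == "pathogenic"),
       ss_levels = ss_levels)
}

#' Stratified train/test split
#'
#' 80:20 by default, stratified by label so both classes appear in small
#' test sets; `floor(fraction * n)` training rows per class; deterministic
#' for a fixed seed.
#'
#' @param variants Labeled variant data.frame.
#' @param fraction Training fraction in (0, 1).
#' @param seed RNG seed.
#' @return List with `train` and `test` data.frames.
#' @export
split_train_test <- function(variants, fraction = 0.8, seed = 1) {
  stopifnot(is.data.frame(variants))
  classes <- unique(variants$label)
  if (length(classes) < 2) stop("both classes required for a split")
  cnt <- table(variants$label)
  if (any(cnt < 2)) stop("each class needs >= 2 members")
  if (fraction <= 0 || fraction >= 1) {
    stop("fraction must be in (0,1): fraction ", fraction,
         " gives an empty train or test set")
  }
  idx_train <- with_seed(seed, {
    unlist(lapply(classes, function(cl) {
      rows <- which(variants$label == cl)
      sample(rows, floor(fraction * length(rows)))
    }))
  })
  list(train = variants[sort(idx_train), , drop = FALSE],
       test = variants[setdiff(seq_len(nrow(variants)), idx_train), ,
                       drop = FALSE])
}

#' Precision, recall and F1 from confusion counts
#'
#' `Pr = TP/(TP+FP)`, `Rc = TP/(TP+FN)`, `F1 = 2*Pr*Rc/(Pr+Rc)`; a
#' zero-denominator precision or recall is reported as 0, and F1 is 0 when
#' `Pr + Rc = 0`.
#'
#' @param TP,FP,FN,TN Non-negative confusion counts.
#' @return List: TP, FP, FN, TN, precision, recall, f1.
#' @export
precision_recall_f1 <- function(TP, FP, FN, TN) {
  stopifnot(TP >= 0, FP >= 0, FN >= 0, TN >= 0)
  pr <- if (TP + FP > 0) TP / (TP + FP) else 0
  rc <- if (TP + FN > 0) TP / (TP + FN) else 0
  f1 <- if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
  list(TP = TP, FP = FP, FN = FN, TN = TN,
       precision = pr, recall = rc, f1 = f1)
}

#' Fit a logistic model and evaluate on held-out variants
#'
#' Unregularized logistic regression (`stats::glm`, binomial) on the
#' encoded training matrix; test predictions thresholded at
#' `threshold`, pathogenic counted as the positive class. Rank-deficient
#' encodings (e.g. ss_score being a linear function of the one-hot
#' columns) are handled by glm's aliasing; perfect-separation warnings are
#' tolerated.
#'
#' @param train,test Labeled variant data.frames.
#' @param threshold Classification threshold on the predicted probability.
#' @return A list of class `MetricsRecord`: confusion counts, precision,
#'   recall, f1, n_train, n_test.
#' @export
fit_eval_logistic <- function(train, test, threshold = 0.5) {
  if (nrow(test) == 0) stop("empty test set")
  enc_tr <- encode_design_matrix(train)
  enc_te <- encode_design_matrix(test, ss_levels = enc_tr$ss_levels)
  df_tr <- data.frame(y = enc_tr$y, enc_tr$x)
  fit <- withCallingHandlers(
    stats::glm(y ~ ., family = stats::binomial(), data = df_tr,
               control = stats::glm.control(maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|algorithm did not converge",
                conditionMessage(w))) invokeRestart("muffleWarning")
    })
  # complete separation drives the deviance to ~0 without meeting the
  # relative-convergence criterion; that is a boundary solution, not failure
  if (!fit$converged && !fit$boundary && fit$deviance > 1e-6) {
    stop("logistic fit did not converge after ", fit$iter, " iterations; ",
         "deviance = ", format(fit$deviance))
  }
  df_te <- data.frame(enc_te$x)
  pred <- suppressWarnings(
    stats::predict(fit, newdata = df_te, type = "response")) >= threshold
  truth <- enc_te$y == 1
  m <- precision_recall_f1(TP = sum(pred & truth), FP = sum(pred & !truth),
                           FN = sum(!pred & truth), TN = sum(!pred & !truth))
  m$n_train <- nrow(train)
  m$n_test <- nrow(test)
  structure(m, class = "MetricsRecord")
}

#' @export
print.MetricsRecord <- function(x, ...) {
  cat(sprintf(
    "MetricsRecord: n_train=%d n_test=%d  TP=%d FP=%d FN=%d TN=%d\n",
    x$n_train, x$n_test, x$TP, x$FP, x$FN, x$TN))
  cat(sprintf("  precision=%.3f recall=%.3f F1=%.3f\n",
              x$precision, x$recall, x$f1))
  invisible(x)
}

#' Repeated split/fit evaluation
#'
#' Re-splits and refits `n_repeats` times with seeds derived from
#' `base_seed` (base_seed, base_seed+1, ...), reporting the mean and
#' sample standard deviation of F1 across repeats.
#'
#' @param variants Labeled variant data.frame.
#' @param n_repeats Number of repeats (>= 2).
#' @param base_seed First derived seed.
#' @param fraction Training fraction.
#' @param threshold Classification threshold.
#' @return List: `f1_mean`, `f1_sd`, `f1` (per-repeat vector), `records`.
#' @export
repeat_eval <- function(variants, n_repeats = 20, base_seed = 1,
                        fraction = 0.8, threshold = 0.5) {
  if (n_repeats < 2) stop("n_repeats must be >= 2")
  records <- lapply(seq_len(n_repeats) - 1L, function(i) {
    sp <- split_train_test(variants, fraction, seed = base_seed + i)
    fit_eval_logistic(sp$train, sp$test, threshold)
  })
  f1 <- vapply(records, `[[`, numeric(1), "f1")
  list(f1_mean = mean(f1), f1_sd = stats::sd(f1), f1 = f1, records = records)
}
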