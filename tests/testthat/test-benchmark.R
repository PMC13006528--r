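test_that("encode_design_matrix builds the documented column layout", {
  v <- data.frame(label = c("pathogenic", "benign"),
                  entropy = c(0.2, 0.8), rsa = c(0.3, 0.9),
                  ss_code = c("H", "C"), ss_score = c(0, 1),
                  dbr = c(0.1, 0.9), s_weighted = c(0.7, 4.0),
                  e_min = c(0.1, 0.8))
  enc <- encode_design_matrix(v)
  expect_equal(colnames(enc$x),
               c("entropy", "rsa", "ss_score", "dbr", "s_weighted", "e_min",
                 "ss_H"))
  expect_equal(enc$y, c(1L, 0L))

  bad <- v; bad$rsa[1] <- 1.2
  expect_error(encode_design_matrix(bad), "outside \\[0,1\\]")

  mono <- v; mono$ss_code <- "C"
  expect_warning(enc2 <- encode_design_matrix(mono), "one secondary-structure")
  expect_equal(ncol(enc2$x), 6)

  single <- v[v$label == "benign", ]
  expect_error(encode_design_matrix(rbind(single, single)), "both classes")
})

test_that("split_train_test is stratified, sized 80:20, and deterministic", {
  v <- simulate_benchmark(simulation_params(n_pathogenic = 100,
                                            n_benign = 100, seed = 2))
  sp <- split_train_test(v, 0.8, seed = 10)
  expect_equal(sum(sp$train$label == "pathogenic"), 80)
  expect_equal(sum(sp$train$label == "benign"), 80)
  expect_equal(nrow(sp$test), 40)
  expect_equal(sum(sp$test$label == "pathogenic"), 20)

  sp2 <- split_train_test(v, 0.8, seed = 10)
  expect_identical(sp$train$protein_id, sp2$train$protein_id)
  sp3 <- split_train_test(v, 0.8, seed = 11)
  expect_false(identical(sp$train$protein_id, sp3$train$protein_id))

  expect_error(split_train_test(v, 1.0), "empty")
  expect_error(split_train_test(v[v$label == "benign", ], 0.8),
               "both classes")
})

test_that("precision, recall and F1 follow their defining ratios", {
  m <- precision_recall_f1(TP = 3, FP = 1, FN = 1, TN = 5)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$f1, 0.75)
  z <- precision_recall_f1(TP = 0, FP = 0, FN = 0, TN = 10)
  expect_equal(z$f1, 0)
  # F1 under class swap: symmetric confusion matrix is invariant,
  # an asymmetric one is not
  sym <- precision_recall_f1(TP = 4, FP = 2, FN = 2, TN = 4)
  sym_swapped <- precision_recall_f1(TP = 4, FP = 2, FN = 2, TN = 4)
  expect_equal(sym$f1, sym_swapped$f1)
  asym <- precision_recall_f1(TP = 8, FP = 1, FN = 3, TN = 2)
  asym_swapped <- precision_recall_f1(TP = 2, FP = 3, FN = 1, TN = 8)
  expect_false(isTRUE(all.equal(asym$f1, asym_swapped$f1)))
})

test_that("a separable simulation yields F1 = 1 on the held-out set", {
  v <- simulate_benchmark(simulation_params(n_pathogenic = 150,
                                            n_benign = 150,
                                            separation = 2,
                                            concentration = 60, seed = 4))
  sp <- split_train_test(v, 0.8, seed = 1)
  m <- fit_eval_logistic(sp$train, sp$test)
  expect_equal(m$f1, 1)
  expect_equal(m$FP + m$FN, 0)
})

test_that("confusion counts always partition the test set", {
  for (s in 1:5) {
    v <- simulate_benchmark(simulation_params(n_pathogenic = 60,
                                              n_benign = 80, seed = s))
    sp <- split_train_test(v, 0.8, seed = s)
    m <- fit_eval_logistic(sp$train, sp$test)
    expect_equal(m$TP + m$FP + m$FN + m$TN, m$n_test)
    expect_equal(m$n_test, nrow(sp$test))
  }
})

test_that("zero class separation gives chance-level F1 over repeated splits", {
  v <- simulate_benchmark(simulation_params(n_pathogenic = 200,
                                            n_benign = 200,
                                            separation = 0, seed = 8))
  r <- repeat_eval(v, n_repeats = 20, base_seed = 100)
  # balanced classes, uninformative features: F1 fluctuates around the
  # ~0.5 chance regime; Monte-Carlo tolerance from the observed spread
  expect_gt(r$f1_mean, 0.30)
  expect_lt(r$f1_mean, 0.70)
  expect_gt(r$f1_sd, 0)
})

test_that("mean F1 is monotone in class separation up to noise", {
  lvl <- c(0, 0.5, 1, 2)
  f1 <- vapply(lvl, function(sep) {
    v <- simulate_benchmark(simulation_params(n_pathogenic = 150,
                                              n_benign = 150,
                                              separation = sep, seed = 13))
    repeat_eval(v, n_repeats = 5, base_seed = 50)$f1_mean
  }, numeric(1))
  expect_true(all(diff(f1) > -0.05))
  expect_gt(f1[4], f1[1] + 0.2)
})

test_that("logistic coefficients recover the generative feature directions", {
  v <- simulate_benchmark(simulation_params(n_pathogenic = 1200,
                                            n_benign = 1200,
                                            separation = 0.6, seed = 3))
  enc <- encode_design_matrix(v)
  fit <- suppressWarnings(
    stats::glm(y ~ entropy + rsa + dbr,
               family = stats::binomial(),
               data = data.frame(y = enc$y, enc$x)))
  # pathogenic (y=1) variants are generated with LOWER entropy/rsa/dbr
  expect_lt(coef(fit)[["entropy"]], 0)
  expect_lt(coef(fit)[["rsa"]], 0)
  expect_lt(coef(fit)[["dbr"]], 0)
})

test_that("simulation is deterministic per seed and scoring-consistent", {
  p <- simulation_params(n_pathogenic = 30, n_benign = 30, seed = 99)
  a <- simulate_benchmark(p)
  b <- simulate_benchmark(p)
  expect_identical(a, b)
  # s_weighted and e_min are computed from the sampled features
  w <- scoring_config()$weights
  i <- 7
  v <- c(entropy = a$entropy[i], secondary_structure = a$ss_score[i],
         rsa = a$rsa[i], dbr = a$dbr[i])
  expect_equal(a$s_weighted[i], weighted_score(v, w))
  expect_equal(a$e_min[i], min_score(v))
})

test_that("repeat_eval reports spread across derived seeds", {
  v <- simulate_benchmark(simulation_params(n_pathogenic = 120,
                                            n_benign = 120,
                                            separation = 2,
                                            concentration = 60, seed = 5))
  r <- repeat_eval(v, n_repeats = 3, base_seed = 7)
  expect_equal(r$f1_mean, 1)
  expect_equal(r$f1_sd, 0)
  expect_error(repeat_eval(v, n_repeats = 1), ">= 2")
})
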