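test_that("pwm scoring matches direct summation and skips N windows", {
  m <- motif_from_consensus("ACGTAC", strength = 0.9)
  cons_score <- sum(apply(m$log_odds, 2, max))
  expect_equal(unname(pwm_score("ACGTAC", m)), cons_score)
  # motif equal to background scores zero everywhere
  expect_warning(flat <- motif_matrix(matrix(1, 4, 5)), "zero-information")
  expect_equal(unname(pwm_score("ACGTACGTAC", flat)), 0)
  # N-containing windows are skipped, not propagated
  s <- "NNNNNNACGTACNNNN"
  expect_equal(unname(pwm_score(s, m)), cons_score)
  expect_identical(unname(pwm_score("NNNNNNNN", m)), -Inf)
  expect_error(pwm_score("ACG", m), "shorter")
})

test_that("pwm score is strand symmetric", {
  m <- motif_from_consensus("TGTGATCTAGATCACA", strength = 0.85)
  set.seed(14)
  for (i in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    expect_equal(pwm_score(s, m), pwm_score(reverse_complement(s), m),
                 tolerance = 1e-10)
  }
})

test_that("view features have the right shape and exclusions", {
  reg <- generate_regulon_dataset(n_targets = 5, n_nontargets = 5,
                                  seed = 2)
  v <- build_view_features(reg$genes, reg$motif, 93000, ECOLI_G)
  expect_equal(dim(v$sequence), c(10, 1))
  expect_equal(dim(v$position), c(10, 1))
  expect_identical(rownames(v$sequence), reg$genes$name)
  # positional column invariant under gene reordering
  v2 <- build_view_features(reg$genes[10:1, ], reg$motif, 93000, ECOLI_G)
  expect_equal(v2$position[rownames(v$position), 1], v$position[, 1])
  # a gene with no scorable sequence is excluded by name
  genes <- reg$genes
  genes$sequence[1] <- strrep("N", 200)
  expect_warning(v3 <- build_view_features(genes, reg$motif, 93000,
                                           ECOLI_G),
                 genes$name[1])
  expect_equal(nrow(v3$sequence), 9)
})

test_that("boosting reproduces the AdaBoost weight formula", {
  # engineered first stump: weighted error exactly 0.1
  X <- matrix(c(6, 7, 8, 9, 0.5, 1, 2, 3, 4, 5), ncol = 1,
              dimnames = list(NULL, "x"))
  y <- c(rep(1, 5), rep(-1, 5))
  m <- train_multiview_boost(list(v = X), y, n_iter = 1)
  expect_equal(m$stumps$error[1], 0.1)
  expect_equal(m$stumps$alpha[1], 0.5 * log(9), tolerance = 1e-12)
  # a perfectly separating column stops training after one iteration
  X2 <- matrix(c(y * 2 + rnorm(10, 0, 0.1)), ncol = 1,
               dimnames = list(NULL, "x"))
  m2 <- train_multiview_boost(list(v = X2), y, n_iter = 10)
  expect_equal(nrow(m2$stumps), 1)
  expect_equal(m2$stumps$error[1], 0)
  preds <- predict_scores(m2, list(v = X2))
  expect_equal(preds$label, y)
  expect_error(train_multiview_boost(list(v = X), rep(1, 10), 5),
               "both classes")
  expect_error(train_multiview_boost(list(v = X), y - 2 * (y == -1), 5),
               "\\+1 / -1")
})

test_that("per-iteration weights sum to one and loss never increases", {
  for (s in 1:5) {
    reg <- generate_regulon_dataset(n_targets = 20, n_nontargets = 30,
                                    seed = 40 + s)
    v <- build_view_features(reg$genes, motif_variants(reg$motif),
                             93000, ECOLI_G)
    y <- reg$genes$label
    m <- train_multiview_boost(v, y, n_iter = 8)
    expect_equal(rowSums(m$weight_history),
                 rep(1, nrow(m$weight_history)))
    # class-weighted exponential loss along the ensemble prefix
    w0 <- ifelse(y == 1, 0.5 / sum(y == 1), 0.5 / sum(y == -1))
    F <- rep(0, length(y))
    loss <- sum(w0 * exp(-y * F))
    for (i in seq_len(nrow(m$stumps))) {
      st <- m$stumps[i, ]
      h <- periscan:::stump_predict(v[[st$view]][, st$column],
                                    st$threshold, st$polarity)
      F <- F + st$alpha * h
      new_loss <- sum(w0 * exp(-y * F))
      expect_lte(new_loss, loss + 1e-9)
      loss <- new_loss
    }
  }
})

test_that("strong scores decompose exactly into per-view partial sums", {
  reg <- generate_regulon_dataset(seed = 5)
  v <- build_view_features(reg$genes, motif_variants(reg$motif),
                           93000, ECOLI_G)
  m <- train_multiview_boost(v, reg$genes$label, n_iter = 6)
  preds <- predict_scores(m, v)
  expect_equal(preds$score,
               preds$partial_sequence + preds$partial_position,
               tolerance = 1e-12)
  # missing column is named in the error
  v_bad <- v
  colnames(v_bad$sequence) <- paste0(colnames(v$sequence), "_x")
  expect_error(predict_scores(m, v_bad), "seq_full")
})

test_that("a hand-built one-stump model emits plus/minus alpha", {
  model <- structure(list(
    stumps = data.frame(iteration = 1L, view = "v", column = "x",
                        threshold = 0.5, polarity = 1, error = 0.25,
                        alpha = 1, stringsAsFactors = FALSE),
    trace = "v", weight_history = NULL, views = list(v = "x")),
    class = "boost_model")
  X <- matrix(c(-1, 0, 1, 2), ncol = 1, dimnames = list(NULL, "x"))
  preds <- predict_scores(model, list(v = X))
  expect_setequal(unique(preds$score), c(-1, 1))
})

test_that("iteration scores split by view with entries +/- alpha_t", {
  reg <- generate_regulon_dataset(seed = 6)
  v <- build_view_features(reg$genes, motif_variants(reg$motif),
                           93000, ECOLI_G)
  m <- train_multiview_boost(v, reg$genes$label, n_iter = 8)
  it <- extract_iteration_scores(m, v, orient = FALSE)
  expect_equal(ncol(it$sequence) + ncol(it$position), nrow(m$stumps))
  for (vn in names(it)) {
    ix <- which(m$stumps$view == vn)
    for (k in seq_along(ix)) {
      expect_setequal(unique(abs(it[[vn]][, k])),
                      m$stumps$alpha[ix[k]])
    }
  }
  # single-view model flags the missing block
  m1 <- train_multiview_boost(v["sequence"], reg$genes$label, n_iter = 4)
  expect_warning(it1 <- extract_iteration_scores(
    m1, list(sequence = v$sequence, position = v$position)),
    "position")
  expect_equal(ncol(it1$position), 0)
})

test_that("model files round-trip through JSON", {
  reg <- generate_regulon_dataset(seed = 7)
  v <- build_view_features(reg$genes, motif_variants(reg$motif),
                           93000, ECOLI_G)
  m <- train_multiview_boost(v, reg$genes$label, n_iter = 5)
  path <- tempfile(fileext = ".json")
  write_boost_model(m, path)
  m2 <- read_boost_model(path)
  expect_equal(m2$stumps$alpha, m$stumps$alpha)
  expect_equal(predict_scores(m2, v)$score, predict_scores(m, v)$score)
  expect_error(read_boost_model(write_lines_tmp("{}")), "not a boosting")
})

test_that("canonical correlations recover exact and null association", {
  set.seed(33)
  x <- rnorm(50)
  expect_error(canonical_correlations(cbind(x), cbind(rep(1, 50)),
                                      lambda = 0), "constant")
  cc <- canonical_correlations(cbind(x), cbind(-x), lambda = 0)
  expect_equal(cc$cor[1], 1, tolerance = 1e-9)
  expect_lt(cc$loadings$X[1, 1] * cc$loadings$Y[1, 1], 0)
  # independent noise: first canonical correlation stays small
  for (s in 1:5) {
    set.seed(s)
    X <- matrix(rnorm(200 * 3), 200)
    Y <- matrix(rnorm(200 * 3), 200)
    cc0 <- canonical_correlations(X, Y, lambda = 0)
    expect_lt(cc0$cor[1], 0.3)
    expect_false(is.unsorted(rev(cc0$cor)))
    expect_true(all(cc0$cor >= 0 & cc0$cor <= 1))
  }
})

test_that("unregularised correlations agree with stats::cancor and rcc", {
  set.seed(91)
  X <- matrix(rnorm(60 * 3), 60)
  Y <- X[, c(2, 3, 1)] * 0.5 + matrix(rnorm(60 * 3), 60)
  cc <- canonical_correlations(X, Y, lambda = 0)
  expect_equal(cc$cor, stats::cancor(scale(X), scale(Y))$cor,
               tolerance = 1e-6)
  skip_if_not_installed("mixOmics")
  rcc <- mixOmics::rcc(X, Y, lambda1 = 0.1, lambda2 = 0.1)
  cc_r <- canonical_correlations(X, Y, lambda = 0.1)
  expect_equal(cc_r$cor, unname(rcc$cor[seq_along(cc_r$cor)]),
               tolerance = 0.02)
})
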