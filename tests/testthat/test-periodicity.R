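test_that("phase transform is the positive modulo of the coordinate", {
  expect_equal(phase_transform(14930, 14830), 100)
  expect_equal(phase_transform(c(0, 14830, 29660), 14830), c(0, 0, 0))
  P <- 123.7
  ph <- phase_transform(runif(50, 0, 1e6), P)
  expect_true(all(ph >= 0 & ph < P))
  expect_error(phase_transform(10, 0), "positive")
  expect_error(phase_transform(10, -3), "positive")
})

test_that("concentration score matches its closed forms", {
  expect_equal(periodicity_score(rep(0, 20), 100), 20)
  expect_equal(periodicity_score(c(0, 50), 100), 0, tolerance = 1e-12)
  # angles {0, 0, pi/2, pi/2}: R = sqrt(2)/2, S = 2
  expect_equal(periodicity_score(c(0, 0, 25, 25), 100), 2,
               tolerance = 1e-12)
  expect_error(periodicity_score(5, 100), "at least 2")
})

test_that("score equals the brute-force complex sum and the C++ kernel", {
  set.seed(42)
  for (i in 1:1000) {
    n <- sample(2:60, 1)
    P <- runif(1, 10, 1e6)
    pos <- runif(n, 0, 5e6)
    ph <- phase_transform(pos, P)
    S <- periodicity_score(ph, P)
    expect_equal(S, score_oracle(ph, P), tolerance = 1e-12)
    expect_lte(S, n + 1e-9)
  }
  set.seed(7)
  pos <- runif(40, 1, ECOLI_G)
  grid <- seq(5e4, 2e5, by = 500)
  S_cpp <- periscan:::scan_scores_cpp(pos, grid)
  S_r <- vapply(grid, function(P)
    periodicity_score(phase_transform(pos, P), P), numeric(1))
  expect_equal(S_cpp, S_r, tolerance = 1e-9)
})

test_that("score is invariant under global translation of positions", {
  set.seed(11)
  pos <- runif(30, 1, ECOLI_G)
  for (P in c(93000, 12345.6, 500000)) {
    S0 <- periodicity_score(phase_transform(pos, P), P)
    for (shift in c(1, 17, 93000, 1.2e6)) {
      S1 <- periodicity_score(phase_transform(pos + shift, P), P)
      expect_equal(S1, S0, tolerance = 1e-8)
    }
  }
})

test_that("uniform-null p-values behave at the extremes and agree across methods", {
  # perfect alignment is essentially never matched by a uniform draw
  p_hi <- pvalue_uniform_null(20, 20, "monte_carlo", period = 93000,
                              genome_length = ECOLI_G, n_mc = 10000,
                              seed = 1)
  expect_lt(p_hi, 1e-3)
  # S = 0 cannot be beaten from below
  expect_equal(pvalue_uniform_null(0, 10, "monte_carlo", period = 1000,
                                   genome_length = 1e6, n_mc = 500,
                                   seed = 1), 1)
  expect_equal(pvalue_uniform_null(0, 10, "analytic"), 1)
  # Monte Carlo matches the analytic tail for moderate N
  for (S in c(2, 5, 8)) {
    for (n in c(30, 50, 80)) {
      p_mc <- pvalue_uniform_null(S, n, "monte_carlo", period = 1e5,
                                  genome_length = ECOLI_G, n_mc = 20000,
                                  seed = 100 + S + n)
      p_an <- pvalue_uniform_null(S, n, "analytic")
      expect_lt(abs(p_mc - p_an), 0.01)
    }
  }
  expect_error(pvalue_uniform_null(1, 1, "analytic"), ">= 2")
  expect_error(pvalue_uniform_null(1, 10, "monte_carlo", n_mc = 10),
               "n_mc")
})

test_that("Monte-Carlo p converges to the analytic value within 3 SE", {
  n <- 40
  S <- 4
  n_mc <- 50000
  p_mc <- pvalue_uniform_null(S, n, "monte_carlo", period = 2e5,
                              genome_length = ECOLI_G, n_mc = n_mc,
                              seed = 77)
  p_an <- pvalue_uniform_null(S, n, "analytic")
  se <- sqrt(p_an * (1 - p_an) / n_mc)
  expect_lt(abs(p_mc - p_an), 3 * se + 2 / n_mc)
})

test_that("single-period correction follows the Sidak form with m = floor(G/P)", {
  expect_equal(correct_pvalue(0.001, 93000, ECOLI_G), 0.0478,
               tolerance = 1e-3)
  # m = 1 when the period exceeds half the genome
  expect_equal(correct_pvalue(0.03, 0.6 * ECOLI_G, ECOLI_G), 0.03)
  expect_equal(correct_pvalue(0, 1000, ECOLI_G), 0)
  expect_equal(correct_pvalue(1, 1000, ECOLI_G), 1)
  # monotone in the number of repetitions
  p <- correct_pvalue(0.01, c(2e6, 1e6, 1e5, 1e4), ECOLI_G)
  expect_false(is.unsorted(p))
  expect_error(correct_pvalue(0.5, 2 * ECOLI_G, ECOLI_G), "<=")
  expect_error(correct_pvalue(1.5, 1e5, ECOLI_G), "0, 1")
})

test_that("CIRC mode enumerates integer divisions of the genome", {
  fs <- make_fs(c(10, 250, 333, 600, 910), G = 1000)
  scan <- scan_periods(fs, mode = "CIRC", p_min = 100, p_max = 500,
                       correction = "sidak")
  expect_equal(scan$candidates$period,
               sort(1000 / (2:10)), tolerance = 1e-9)
})

test_that("DOM scan recovers a planted lattice at the grid argmax", {
  sim <- generate_periodic_positions(seed = 5)
  scan <- scan_periods(sim$fs, p_min = 50000, p_max = 500000, step = 30,
                       n_null = 99, seed = 15)
  tp <- top_period(scan)
  expect_lt(abs(tp$period - 93000) / 93000, 0.01)
  expect_lt(tp$p_corrected, 0.05)
  # parameters are fully recorded and candidates sorted by period
  expect_false(is.unsorted(scan$candidates$period))
  expect_equal(scan$params$step, 30)
  expect_equal(scan$params$n_used, 70)
  # corrected p never smaller than raw p
  expect_true(all(scan$candidates$p_corrected >=
                    scan$candidates$p_raw - 1e-12))
})

test_that("an exact lattice is significant at the period and its half", {
  G <- ECOLI_G
  T0 <- 400000
  pos <- (123 + T0 * 0:10) %% G + 1
  fs <- make_fs(pos, G = G)
  scan <- scan_periods(fs, p_min = 150000, p_max = 450000, step = 500,
                       n_null = 99, seed = 2)
  cand <- scan$candidates
  at <- function(P) cand[which.min(abs(cand$period - P)), ]
  expect_equal(at(T0)$score, 11, tolerance = 1e-6)
  expect_equal(at(T0 / 2)$score, 11, tolerance = 1e-6)
  expect_lt(at(T0)$p_corrected, 0.05)
  expect_lt(at(T0 / 2)$p_corrected, 0.05)
  # and the harmonic grouping ties them together
  fams <- detect_harmonic_families(c(T0, T0 / 2), rel_tol = 0.01)
  expect_length(fams, 1)
})

test_that("scan errors are informative", {
  fs <- make_fs(c(100, 150, 210), G = 100000)
  expect_error(scan_periods(fs, p_min = 5e4, p_max = 4e4), "p_min < p_max")
  expect_error(scan_periods(fs, p_min = 1e3, p_max = 5e4,
                            proximity = 1000), "survived")
})

test_that("significant periods are selected and ordered by corrected p", {
  fake <- structure(list(
    candidates = data.frame(period = c(100, 200, 300, 400),
                            score = c(5, 9, 7, 2), n_features = 10,
                            p_raw = c(0.03, 0.001, 0.002, 0.5),
                            p_corrected = c(0.06, 0.04, 0.04, 0.9),
                            mode = "DOM"),
    params = list()), class = "period_scan")
  sig <- select_significant(fake, 0.05)
  expect_equal(sig$period, c(200, 300))   # tie on p, smaller period first
  expect_equal(nrow(select_significant(fake, 1)), 4)
  expect_equal(nrow(select_significant(fake, 1e-6)), 0)
  expect_error(select_significant(fake, 0), "alpha")
})

test_that("harmonic families group integer multiples within tolerance", {
  expect_length(detect_harmonic_families(c(93094, 186317), 0.01), 1)
  expect_length(detect_harmonic_families(c(100, 307), 0.01), 0)
  fams <- detect_harmonic_families(c(5000, 10000, 20000, 33333), 0.01)
  expect_length(fams, 1)
  expect_equal(fams[[1]], c(5000, 10000, 20000))
  expect_error(detect_harmonic_families(c(100, 200), 0.5), "rel_tol")
})

test_that("common periods across sets respect the 5 percent rule", {
  common <- find_common_periods(list(A = 93094, B = 90216))
  expect_equal(nrow(common), 2)  # reported from both sides
  expect_lt(max(common$rel_diff), 0.05)
  none <- find_common_periods(list(A = 93094, B = 750416))
  expect_equal(nrow(none), 0)
  all3 <- find_common_periods(list(A = 5e4, B = 5e4, C = 5e4))
  expect_equal(nrow(all3), 3)
  expect_error(find_common_periods(list(93094)), "2 entries")
})

test_that("periodobar table mirrors the scan and the significance flag", {
  sim <- generate_periodic_positions(n_lattice = 20, n_background = 10,
                                     seed = 9)
  scan <- scan_periods(sim$fs, p_min = 80000, p_max = 120000, step = 200,
                       n_null = 99, seed = 3)
  tbl <- periodobar_table(scan, alpha = 0.05)
  expect_equal(nrow(tbl), nrow(scan$candidates))
  expect_equal(tbl$neg_log10_p, -log10(tbl$p_corrected))
  expect_identical(tbl$significant, tbl$p_corrected < 0.05)
  expect_equal(periodobar_table(scan)$neg_log10_p[
    periodobar_table(scan)$p_corrected == 1],
    rep(0, sum(tbl$p_corrected == 1)))
  path <- tempfile(fileext = ".tsv")
  periodobar_table(scan, path = path)
  expect_true(file.exists(path))
  expect_s3_class(plot_periodobar(scan), "ggplot")
})

test_that("scan scores are invariant under translation", {
  sim <- generate_periodic_positions(n_lattice = 15, n_background = 15,
                                     seed = 21)
  fs1 <- sim$fs
  # plain shift (no wrap): invariance at every tested period
  pos_shift <- fs1$features$position + 1e5
  s1 <- scan_periods(fs1, p_min = 5e4, p_max = 1e5, step = 1000,
                     correction = "sidak")
  s2 <- scan_periods(make_fs(pos_shift, G = ECOLI_G + 2e5), p_min = 5e4,
                     p_max = 1e5, step = 1000, correction = "sidak")
  expect_lt(max(abs(s1$candidates$score - s2$candidates$score)), 1e-6)
  # shift modulo G: invariance on the CIRC grid, where P divides G
  pos_mod <- (fs1$features$position - 1 + 1234567) %% ECOLI_G + 1
  c1 <- scan_periods(fs1, mode = "CIRC", p_min = 5e4, p_max = 1e6,
                     correction = "sidak")
  c2 <- scan_periods(make_fs(pos_mod, G = ECOLI_G), mode = "CIRC",
                     p_min = 5e4, p_max = 1e6, correction = "sidak")
  expect_lt(max(abs(c1$candidates$score - c2$candidates$score)), 1e-6)
})

test_that("a precomputed calibration is validated and reused", {
  fs <- generate_null_positions(30, seed = 4)
  grid <- seq(5e4, 1e5, by = 1000)
  calib <- calibrate_scan(30, ECOLI_G, grid, n_null = 49, seed = 8)
  scan <- scan_periods(fs, p_min = 5e4, p_max = 1e5, step = 1000,
                       calibration = calib)
  expect_true(all(scan$candidates$p_corrected >= 1 / 50))
  wrong <- calibrate_scan(29, ECOLI_G, grid, n_null = 49, seed = 8)
  expect_error(scan_periods(fs, p_min = 5e4, p_max = 1e5, step = 1000,
                            calibration = wrong), "does not match")
})
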