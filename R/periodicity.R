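#' Phase coordinates of positions for a candidate period
#'
#' The phase of a feature is the remainder of its absolute coordinate modulo
#' the period length: features at exact multiples of the period share phase 0.
#'
#' @param positions numeric vector of coordinates in bp.
#' @param period period length P in bp, > 0.
#' @return numeric vector of phases in [0, P), in input order.
#' @examples
#' phase_transform(14930, 14830)  # 100
#' @export
phase_transform <- function(positions, period) {
  if (!is.numeric(period) || length(period) != 1 || is.na(period) ||
      period <= 0) {
    stop("`period` must be a single positive number", call. = FALSE)
  }
  positions %% period
}

#' Periodicity score of a set of phases
#'
#' Phases are mapped to angles \eqn{\theta_j = 2\pi\phi_j/P} on the circle;
#' with mean resultant length \eqn{R = |\sum_j e^{i\theta_j}|/N} the score is
#' the Rayleigh concentration statistic \eqn{S = N R^2}.  \eqn{S \le N}, with
#' equality when all phases coincide, and S is invariant under adding a
#' constant to all positions (a global rotation of the phase circle).
#'
#' @param phases numeric vector of phases in bp (any real values are
#'   accepted; only their value modulo \code{period} matters).
#' @param period period length P in bp.
#' @return the score S, a single non-negative number.
#' @examples
#' periodicity_score(rep(0, 20), 100)        # 20: perfect alignment
#' periodicity_score(c(0, 50), 100)          # 0: antipodal cancellation
#' @export
periodicity_score <- function(phases, period) {
  if (length(phases) < 2) {
    stop("the periodicity score needs at least 2 phases", call. = FALSE)
  }
  if (period <= 0) stop("`period` must be positive", call. = FALSE)
  theta <- 2 * pi * phases / period
  n <- length(theta)
  (sum(cos(theta))^2 + sum(sin(theta))^2) / n
}

# Large-N tail approximation of P(S* >= S) for the Rayleigh statistic
# (Greenwood-Durand / Zar correction terms).  Vectorised over S.
rayleigh_pvalue <- function(S, n) {
  p <- exp(-S) * (1 + (2 * S - S^2) / (4 * n) -
                    (24 * S - 132 * S^2 + 76 * S^3 - 9 * S^4) / (288 * n^2))
  pmin(1, pmax(0, p))
}

#' p-value of a periodicity score under the uniform null
#'
#' The null model draws \code{n} positions uniformly on [1, G] and scores
#' them at the same period.  \code{method = "monte_carlo"} (the reference)
#' uses the add-one estimator \eqn{p = (1 + \#\{S^* \ge S\})/(n_{mc} + 1)};
#' \code{method = "analytic"} uses the large-N tail approximation of the
#' Rayleigh test, which is much faster and agrees with Monte Carlo to well
#' under 0.01 for N of a few tens.
#'
#' @param S observed score.
#' @param n number of features the score was computed from (>= 2).
#' @param method \code{"monte_carlo"} or \code{"analytic"}.
#' @param period,genome_length the period and chromosome length used for the
#'   null draws (Monte Carlo only).
#' @param n_mc number of Monte-Carlo replicates (>= 100).
#' @param seed optional seed for the null draws; the caller's RNG stream is
#'   left untouched.
#' @return the raw (uncorrected) p-value.
#' @export
pvalue_uniform_null <- function(S, n, method = c("monte_carlo", "analytic"),
                                period = NULL, genome_length = NULL,
                                n_mc = 10000, seed = NULL) {
  method <- match.arg(method)
  if (n < 2) stop("`n` must be >= 2", call. = FALSE)
  if (method == "analytic") return(rayleigh_pvalue(S, n))
  if (n_mc < 100) stop("`n_mc` must be >= 100", call. = FALSE)
  if (is.null(period) || is.null(genome_length)) {
    stop("Monte-Carlo null needs `period` and `genome_length`",
         call. = FALSE)
  }
  null <- with_seed(seed,
                    null_scores_cpp(as.integer(n), period, genome_length,
                                    as.integer(n_mc)))
  (1 + sum(null >= S)) / (n_mc + 1)
}

#' Period-dependent correction of a single raw p-value
#'
#' Shorter periods admit more full repetitions along the chromosome and
#' therefore more chances of a spuriously aligned phase pattern.  The raw
#' p-value is corrected Šidák-style, \eqn{p_c = 1 - (1 - p)^{m(P)}} with
#' \eqn{m(P) = \max(1, \lfloor G/P \rfloor)}.
#'
#' This is the correction for testing one period in isolation.  A full scan
#' over a fine comb of periods tests many effectively independent candidates,
#' for which \code{\link{scan_periods}} applies an exact scan-wide
#' max-statistic calibration by default; see its documentation.
#'
#' @param p_raw raw p-value(s) in [0, 1].
#' @param period tested period P, 0 < P <= G.
#' @param genome_length chromosome length G.
#' @return corrected p-value(s), monotone non-decreasing in G/P.
#' @examples
#' correct_pvalue(0.001, 93000, 4641652)  # ~0.0478 (m = 49)
#' @export
correct_pvalue <- function(p_raw, period, genome_length) {
  if (any(p_raw < 0 | p_raw > 1, na.rm = TRUE)) {
    stop("`p_raw` must be in [0, 1]", call. = FALSE)
  }
  if (any(period <= 0) || any(period > genome_length)) {
    stop("`period` must satisfy 0 < P <= genome_length", call. = FALSE)
  }
  m <- pmax(1, floor(genome_length / period))
  1 - (1 - p_raw)^m
}

#' Scan-wide null calibration for a period grid
#'
#' Draws \code{n_null} uniform feature sets of size \code{n} on
#' [1, \code{genome_length}] and records, for each, the maximum periodicity
#' score over the whole period grid.  The empirical distribution of these
#' maxima converts an observed score into an exact scan-wide corrected
#' p-value: the probability that a fully random feature set would show a
#' score at least as large \emph{anywhere} in the scan.
#'
#' The calibration depends only on \code{n}, the grid and G, so it can be
#' computed once and reused across many scans of equally sized feature sets
#' (pass it to \code{\link{scan_periods}} via \code{calibration}).
#'
#' @param n number of features per null draw.
#' @param genome_length chromosome length G.
#' @param periods numeric vector: the period grid of the scan.
#' @param n_null number of null scans (the smallest attainable corrected
#'   p-value is \code{1/(n_null + 1)}).
#' @param seed optional seed.
#' @return object of class \code{scan_calibration}.
#' @export
calibrate_scan <- function(n, genome_length, periods, n_null = 200,
                           seed = NULL) {
  stopifnot(n >= 2, n_null >= 19, length(periods) >= 1)
  max_scores <- with_seed(seed,
    null_max_scores_cpp(as.integer(n), as.numeric(periods),
                        genome_length, as.integer(n_null)))
  structure(
    list(n = as.integer(n), genome_length = genome_length,
         n_periods = length(periods), period_range = range(periods),
         n_null = as.integer(n_null),
         max_scores = sort(max_scores)),
    class = "scan_calibration"
  )
}

# Corrected p-values from a calibration: P(null max-S >= S), add-one.
calibrated_pvalues <- function(S, calib) {
  v <- calib$max_scores
  n_lt <- findInterval(S, v, left.open = TRUE)  # #{v < S}
  (1 + (calib$n_null - n_lt)) / (calib$n_null + 1)
}

#' Scan all candidate periods of a feature set
#'
#' The scan engine of the layout analysis.  Two modes:
#' \describe{
#'   \item{DOM}{an exhaustive fine comb of the range
#'     [\code{p_min}, \code{p_max}] in increments of \code{step} bp
#'     (default 3).}
#'   \item{CIRC}{integer divisions of the genome length: all P = G/k falling
#'     in the range, kept as reals.}
#' }
#' Each candidate period receives the concentration score S of the (optionally
#' proximity-filtered) feature positions, a raw p-value under the uniform
#' null, and a corrected p-value.
#'
#' Two corrections are available.  \code{"max_stat"} (default) calibrates the
#' whole scan against \code{n_null} uniform feature sets scored on the same
#' grid, giving the exact probability that a random genome would produce an
#' equally extreme score anywhere in the scan — the scan-wise false-positive
#' rate is controlled at the nominal level by construction.
#' \code{"sidak"} applies the per-period correction of
#' \code{\link{correct_pvalue}} to each candidate independently; it is
#' appropriate when the candidates themselves are the object of interest but
#' is anti-conservative as a scan-wide criterion over a fine comb.
#'
#' @param fs a \code{\link{feature_set}}.
#' @param mode \code{"DOM"} or \code{"CIRC"}.
#' @param p_min,p_max period range in bp; defaults 10 kbp to G/2.
#' @param step DOM grid increment in bp.
#' @param proximity proximity-filter threshold applied once before scoring
#'   (\code{\link{remove_proximal}}); 0 disables.
#' @param method raw p-value method, \code{"analytic"} (default for scans) or
#'   \code{"monte_carlo"} (reference; per-candidate, only sensible for the
#'   coarse CIRC grid).
#' @param n_mc Monte-Carlo replicates per candidate when
#'   \code{method = "monte_carlo"}.
#' @param correction \code{"max_stat"} or \code{"sidak"}.
#' @param n_null null scans for the max-statistic calibration.
#' @param calibration optional precomputed \code{\link{calibrate_scan}}
#'   result (must match n, G and the grid).
#' @param seed optional seed governing all Monte-Carlo draws.
#' @return object of class \code{period_scan}: list with \code{candidates}
#'   (data frame: period, score, n_features, p_raw, p_corrected, sorted by
#'   period) and \code{params}.
#' @export
scan_periods <- function(fs, mode = c("DOM", "CIRC"), p_min = 10000,
                         p_max = NULL, step = 3, proximity = 0,
                         method = c("analytic", "monte_carlo"),
                         n_mc = 10000, correction = c("max_stat", "sidak"),
                         n_null = 200, calibration = NULL, seed = NULL) {
  stopifnot(inherits(fs, "feature_set"))
  mode <- match.arg(mode)
  method <- match.arg(method)
  correction <- match.arg(correction)
  G <- fs$genome_length
  p_max <- p_max %||% (G / 2)
  if (!(p_min < p_max && p_max <= G)) {
    stop("need p_min < p_max <= genome_length", call. = FALSE)
  }
  fs_used <- remove_proximal(fs, proximity)
  n <- n_features(fs_used)
  if (n < 2) {
    stop("only ", n, " feature(s) survived the proximity filter; ",
         "need at least 2", call. = FALSE)
  }
  periods <- switch(mode,
    DOM = seq(p_min, p_max, by = step),
    CIRC = {
      ks <- seq.int(ceiling(G / p_max), floor(G / p_min))
      ks <- ks[ks >= 1]
      P <- G / ks
      sort(P[P >= p_min & P <= p_max])
    }
  )
  if (length(periods) == 0) stop("empty period grid", call. = FALSE)

  pos <- fs_used$features$position
  S <- scan_scores_cpp(pos, periods)

  res <- with_seed(seed, {
    p_raw <- if (method == "analytic") {
      rayleigh_pvalue(S, n)
    } else {
      vapply(seq_along(periods), function(j) {
        null <- null_scores_cpp(as.integer(n), periods[j], G,
                                as.integer(n_mc))
        (1 + sum(null >= S[j])) / (n_mc + 1)
      }, numeric(1))
    }
    p_corrected <- if (correction == "sidak") {
      correct_pvalue(p_raw, periods, G)
    } else {
      calib <- calibration
      if (is.null(calib)) {
        calib <- calibrate_scan(n, G, periods, n_null = n_null, seed = NULL)
      } else {
        check_calibration(calib, n, G, periods)
      }
      calibrated_pvalues(S, calib)
    }
    list(p_raw = p_raw, p_corrected = pmin(1, pmax(p_corrected, p_raw)))
  })

  structure(
    list(
      candidates = data.frame(
        period = periods, score = S, n_features = n,
        p_raw = res$p_raw, p_corrected = res$p_corrected,
        mode = mode, stringsAsFactors = FALSE
      ),
      params = list(mode = mode, p_min = p_min, p_max = p_max, step = step,
                    proximity = proximity, method = method, n_mc = n_mc,
                    correction = correction, n_null = n_null, seed = seed,
                    genome_length = G, n_input = n_features(fs),
                    n_used = n)
    ),
    class = "period_scan"
  )
}

check_calibration <- function(calib, n, G, periods) {
  stopifnot(inherits(calib, "scan_calibration"))
  if (calib$n != n || calib$genome_length != G ||
      calib$n_periods != length(periods) ||
      any(abs(calib$period_range - range(periods)) > 1e-6)) {
    stop("supplied calibration does not match this scan ",
         "(n, genome length or period grid differ)", call. = FALSE)
  }
  calib
}

#' @export
print.period_scan <- function(x, ...) {
  cat(sprintf(
    "<period_scan> %s mode, %d candidate periods in [%s, %s] bp, N = %d\n",
    x$params$mode, nrow(x$candidates),
    format(x$params$p_min, big.mark = ","),
    format(x$params$p_max, big.mark = ","), x$params$n_used))
  best <- top_period(x)
  cat(sprintf("  top period %s bp (S = %.2f, corrected p = %.3g)\n",
              format(best$period, big.mark = ","), best$score,
              best$p_corrected))
  invisible(x)
}

#' Top-scoring period of a scan
#'
#' The candidate with the maximal score; ties are broken toward the smaller
#' period.  (Corrected p-values saturate at the Monte-Carlo floor
#' \code{1/(n_null+1)} for every strong candidate, so the score — not the
#' corrected p — ranks the winners.)
#'
#' @param result a \code{\link{scan_periods}} result.
#' @return the single best candidate row.
#' @export
top_period <- function(result) {
  stopifnot(inherits(result, "period_scan"))
  cand <- result$candidates
  cand <- cand[order(-cand$score, cand$period), , drop = FALSE]
  cand[1, , drop = FALSE]
}

#' Significant periods of a scan
#'
#' @param result a \code{\link{scan_periods}} result.
#' @param alpha significance threshold on the corrected p-value, in (0, 1].
#' @return the candidate rows with \code{p_corrected < alpha}, sorted by
#'   corrected p-value (ties: smaller period first).
#' @export
select_significant <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "period_scan"))
  if (!(alpha > 0 && alpha <= 1)) stop("`alpha` must be in (0, 1]",
                                       call. = FALSE)
  cand <- result$candidates
  sig <- cand[cand$p_corrected < alpha, , drop = FALSE]
  sig <- sig[order(sig$p_corrected, sig$period), , drop = FALSE]
  rownames(sig) <- NULL
  sig
}

#' Group periods into harmonic families
#'
#' Two periods belong to the same family when one is, within a relative
#' tolerance, an integer multiple (2x to 4x by default) of the other;
#' families are the connected components of this relation.  Singletons are
#' omitted.
#'
#' @param periods numeric vector of (significant) periods in bp.
#' @param rel_tol relative tolerance on the multiple, in (0, 0.1].
#' @param multiples integer multiples considered.
#' @return list of numeric vectors (each sorted ascending), ordered by their
#'   smallest member.
#' @examples
#' detect_harmonic_families(c(93094, 186317), rel_tol = 0.01)  # one family
#' @export
detect_harmonic_families <- function(periods, rel_tol = 0.01,
                                     multiples = 2:4) {
  if (!(rel_tol > 0 && rel_tol <= 0.1)) {
    stop("`rel_tol` must be in (0, 0.1]", call. = FALSE)
  }
  if (any(periods <= 0)) stop("periods must be positive", call. = FALSE)
  n <- length(periods)
  if (n < 2) return(list())
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- min(periods[i], periods[j])
      b <- max(periods[i], periods[j])
      if (any(abs(b - multiples * a) / (multiples * a) <= rel_tol)) {
        parent[find(j)] <- find(i)
      }
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  fams <- split(periods, roots)
  fams <- fams[vapply(fams, length, 1L) >= 2]
  fams <- lapply(fams, sort)
  fams <- unname(fams[order(vapply(fams, min, 1))])
  fams
}

#' Periods shared across feature sets
#'
#' Compares the (significant) periods of two or more named sets and reports
#' every period whose nearest neighbour in the \emph{other} sets differs by
#' at most \code{rel_tol}, relative to the larger of the two.
#'
#' @param period_sets named list (>= 2 entries) of numeric period vectors.
#' @param rel_tol relative difference threshold; default 0.05 (a period "no
#'   more than 5 percent different from its closest period in the group").
#' @return data frame with columns \code{set}, \code{period},
#'   \code{matched_set}, \code{matched_period}, \code{rel_diff}; zero rows if
#'   nothing is shared.
#' @export
find_common_periods <- function(period_sets, rel_tol = 0.05) {
  if (!is.list(period_sets) || length(period_sets) < 2 ||
      is.null(names(period_sets)) || any(!nzchar(names(period_sets)))) {
    stop("`period_sets` must be a named list with >= 2 entries",
         call. = FALSE)
  }
  out <- list()
  for (s in names(period_sets)) {
    own <- period_sets[[s]]
    others <- period_sets[names(period_sets) != s]
    other_p <- unlist(others, use.names = FALSE)
    other_set <- rep(names(others),
                     vapply(others, length, 1L))
    if (length(own) == 0 || length(other_p) == 0) next
    for (p in own) {
      rel <- abs(p - other_p) / pmax(p, other_p)
      j <- which.min(rel)
      if (rel[j] <= rel_tol) {
        out[[length(out) + 1]] <- data.frame(
          set = s, period = p, matched_set = other_set[j],
          matched_period = other_p[j], rel_diff = rel[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(set = character(), period = numeric(),
                      matched_set = character(), matched_period = numeric(),
                      rel_diff = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Plot-ready periodobar table
#'
#' One row per tested period with its score, raw and corrected p-values, the
#' \eqn{-\log_{10}} corrected p-value plotted by the periodobar, and a
#' significance flag consistent with \code{\link{select_significant}}.
#'
#' @param result a \code{\link{scan_periods}} result.
#' @param alpha significance threshold.
#' @param path optional TSV output path.
#' @return data frame, invisibly written to \code{path} if given.
#' @export
periodobar_table <- function(result, alpha = 0.05, path = NULL) {
  stopifnot(inherits(result, "period_scan"))
  cand <- result$candidates
  if (nrow(cand) == 0) stop("empty scan result", call. = FALSE)
  tbl <- data.frame(
    period = cand$period, score = cand$score, p_raw = cand$p_raw,
    p_corrected = cand$p_corrected,
    neg_log10_p = -log10(pmax(cand$p_corrected, .Machine$double.xmin)),
    significant = cand$p_corrected < alpha,
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) {
    write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tbl
}

#' Periodobar plot
#'
#' Bar plot of \eqn{-\log_{10}} corrected p-value against period length
#' (log-scaled horizontal axis), with the significance threshold as a dashed
#' line.
#'
#' @param result a \code{\link{scan_periods}} result.
#' @param alpha significance threshold drawn as a dashed line.
#' @return a ggplot object.
#' @export
plot_periodobar <- function(result, alpha = 0.05) {
  tbl <- periodobar_table(result, alpha)
  ggplot2::ggplot(tbl, ggplot2::aes(x = period,
                                    y = neg_log10_p)) +
    ggplot2::geom_col(width = 0.002 * tbl$period,
                      fill = "steelblue") +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "period (bp, log scale)",
                  y = expression(-log[10] ~ "corrected p"),
                  title = "Periodobar") +
    ggplot2::theme_minimal()
}
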