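#' Map genomic regions carrying a local periodic pattern
#'
#' A variable-size sliding-window scan.  Window sizes start at \code{w0}
#' (default 10 kbp) and grow geometrically by \code{growth} until they cover
#' 95 percent of the genome; each size slides along the chromosome in steps
#' of \code{step_frac} times the window.  Within every window holding at
#' least \code{min_features} features a period scan restricted to periods at
#' most the window length is run (grid: \code{oversample} points per natural
#' frequency, periods from \code{min_period_frac * w} to \code{w}).  The
#' window's best score is converted to a corrected p-value by a max-statistic
#' null calibration (uniform positions inside the window, same grid), cached
#' per feature count since the null is scale-free.  Windows with corrected
#' p-value below \code{p_cutoff} become candidate regions; overlapping
#' candidates whose periods differ by at most \code{merge_tol} are merged
#' into maximal regions keeping the best p-value.
#'
#' On a circular chromosome windows wrap around the origin; merged regions
#' crossing the origin are split into two rows for reporting.
#'
#' @param fs a \code{\link{feature_set}}.
#' @param p_cutoff corrected p-value cutoff for a window, in (0, 1).
#' @param w0 initial window size in bp (must be <= genome length).
#' @param growth window growth factor (> 1).
#' @param step_frac slide step as a fraction of the window size, in (0, 1].
#' @param min_features minimum features per window (>= 4).
#' @param min_period_frac smallest period tested, as a fraction of the
#'   window size; patterns much finer than the window are the business of
#'   smaller windows (or the global scan), and excluding them keeps the
#'   per-window multiple-testing burden low.
#' @param min_cycles minimum number of period repetitions a window must
#'   accommodate (largest period tested = window / min_cycles); fewer
#'   repetitions cannot be told apart from a single cluster of sites.
#' @param promote_fundamental harmonic tie-break: a lattice of period T
#'   also scores highly at its divisors T/2, T/3, ..., so when an integer
#'   multiple (2x-4x) of the window's best period is itself significant at
#'   \code{p_cutoff}, the largest such multiple (the fundamental spacing)
#'   is reported instead of the divisor.  A genuine fine-period pattern is
#'   unaffected: it is antipodal, hence insignificant, at its multiples.
#' @param oversample period-grid density: grid points per natural frequency.
#' @param n_null null scans per calibration; the smallest attainable
#'   corrected p-value is \code{1/(n_null + 1)}, so \code{n_null} must
#'   exceed \code{1/p_cutoff} for any window to pass.
#' @param merge_tol relative period difference below which overlapping
#'   candidate regions merge (default the 5 percent "common period"
#'   criterion).
#' @param proximity proximity-filter threshold applied to the feature set
#'   before windowing; 0 disables.
#' @param calibration_cache optional environment in which per-feature-count
#'   null calibrations are memoised; pass the same environment across calls
#'   (e.g. in simulation studies) to avoid recomputing them.
#' @param seed optional seed for the null calibrations.
#' @return object of class \code{periodic_regions}: a data frame with
#'   columns \code{start}, \code{end}, \code{period}, \code{p_corrected},
#'   \code{n_features}, \code{window_size}, plus attribute
#'   \code{genome_length}.
#' @export
map_periodic_regions <- function(fs, p_cutoff = 5e-4, w0 = 10000,
                                 growth = 1.5, step_frac = 0.5,
                                 min_features = 8, min_period_frac = 0.05,
                                 min_cycles = 4, oversample = 4,
                                 promote_fundamental = TRUE, n_null = 4000,
                                 merge_tol = 0.05, proximity = 0,
                                 calibration_cache = NULL,
                                 seed = NULL) {
  stopifnot(inherits(fs, "feature_set"))
  G <- fs$genome_length
  if (w0 > G) stop("`w0` must not exceed the genome length", call. = FALSE)
  if (!(p_cutoff > 0 && p_cutoff < 1)) stop("`p_cutoff` must be in (0, 1)",
                                            call. = FALSE)
  if (min_features < 4) stop("`min_features` must be >= 4", call. = FALSE)
  if (growth <= 1) stop("`growth` must be > 1", call. = FALSE)
  if (!(step_frac > 0 && step_frac <= 1)) {
    stop("`step_frac` must be in (0, 1]", call. = FALSE)
  }
  if (n_null + 1 < 1 / p_cutoff) {
    stop("`n_null` too small to resolve p_cutoff = ", p_cutoff,
         "; need n_null >= ", ceiling(1 / p_cutoff) - 1, call. = FALSE)
  }
  fs <- remove_proximal(fs, proximity)
  pos <- fs$features$position

  sizes <- w0 * growth^(0:floor(log(0.95 * G / w0, base = growth)))
  sizes <- sizes[sizes <= 0.95 * G]
  # relative period grid: oversample points per natural frequency
  stopifnot(min_cycles >= 1, min_period_frac < 1 / min_cycles)
  k_grid <- seq(oversample * min_cycles,
                ceiling(oversample / min_period_frac))
  rel_periods <- oversample / k_grid          # fractions of the window size

  calib_cache <- calibration_cache %||% new.env(parent = emptyenv())
  stopifnot(is.environment(calib_cache))
  cands <- list()
  with_seed(seed, {
    for (w in sizes) {
      step <- max(1, round(step_frac * w))
      max_start <- if (fs$circular) G else max(1, G - w + 1)
      starts <- seq(1, max_start, by = step)
      for (s in starts) {
        rel <- (pos - s) %% G
        inside <- rel < w
        m <- sum(inside)
        if (m < min_features) next
        rel_pos <- rel[inside] + 1
        periods <- rel_periods * w
        S <- scan_scores_cpp(rel_pos, periods)
        key <- as.character(m)
        calib <- calib_cache[[key]]
        if (is.null(calib)) {
          calib <- calibrate_scan(m, w, periods, n_null = n_null)
          calib$rel_window <- TRUE
          calib_cache[[key]] <- calib
        }
        # the null max-score distribution is invariant to rescaling the
        # window, so a calibration computed at one window size applies to all
        best <- which.max(S)
        if (promote_fundamental) {
          # prefer the fundamental over a divisor when it stands on its own
          for (mult in 4:2) {
            Q <- mult * periods[best]
            if (Q > max(periods)) next
            jq <- which.min(abs(periods - Q))
            if (abs(periods[jq] - Q) / Q < 0.02 &&
                calibrated_pvalues(S[jq], calib) < p_cutoff) {
              best <- jq
              break
            }
          }
        }
        p_corr <- calibrated_pvalues(S[best], calib)
        if (p_corr < p_cutoff) {
          cands[[length(cands) + 1]] <- data.frame(
            start = s, end = s + w - 1, period = periods[best],
            score = S[best], p_corrected = p_corr, n_features = m,
            window_size = w)
        }
      }
    }
  })

  if (length(cands) == 0) {
    return(empty_regions(G))
  }
  cand <- do.call(rbind, cands)
  merged <- merge_regions(cand, merge_tol)
  # split regions crossing the origin of a circular genome
  rows <- list()
  for (i in seq_len(nrow(merged))) {
    r <- merged[i, ]
    if (r$end > G) {
      r1 <- r; r1$end <- G
      r2 <- r; r2$start <- 1; r2$end <- r$end - G
      rows[[length(rows) + 1]] <- r1
      rows[[length(rows) + 1]] <- r2
    } else {
      rows[[length(rows) + 1]] <- r
    }
  }
  out <- do.call(rbind, rows)
  out$n_features <- vapply(seq_len(nrow(out)), function(i) {
    sum(pos >= out$start[i] & pos <= out$end[i])
  }, 1L)
  # an origin-split half that holds (almost) no features is not a region
  out <- out[out$start < out$end & out$n_features >= 2, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, genome_length = G, class = c("periodic_regions",
                                              "data.frame"))
}

empty_regions <- function(G) {
  structure(
    data.frame(start = numeric(), end = numeric(), period = numeric(),
               score = numeric(), p_corrected = numeric(),
               n_features = integer(), window_size = numeric()),
    genome_length = G, class = c("periodic_regions", "data.frame"))
}

# Merge candidate windows: connected components under "intervals overlap AND
# periods within tol (relative to the larger)".  A component collapses to the
# covering interval of its smallest-window members (larger windows detect the
# same pattern but smear its boundaries), keeping the best p-value of the
# whole component; iterated to a fixed point so the result is idempotent and
# order-independent.
merge_regions <- function(cand, tol = 0.05) {
  repeat {
    n <- nrow(cand)
    if (n <= 1) return(cand)
    parent <- seq_len(n)
    find <- function(i) {
      while (parent[i] != i) i <- parent[i]
      i
    }
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        overlap <- cand$start[i] <= cand$end[j] &&
          cand$start[j] <= cand$end[i]
        pd <- abs(cand$period[i] - cand$period[j]) /
          max(cand$period[i], cand$period[j])
        if (overlap && pd <= tol) parent[find(j)] <- find(i)
      }
    }
    roots <- vapply(seq_len(n), find, 1L)
    merged <- do.call(rbind, lapply(split(seq_len(n), roots), function(ix) {
      sub <- cand[ix, , drop = FALSE]
      core <- sub[sub$window_size == min(sub$window_size), , drop = FALSE]
      best <- core[order(core$p_corrected, -core$score)[1], , drop = FALSE]
      data.frame(start = min(core$start), end = max(core$end),
                 period = best$period, score = best$score,
                 p_corrected = min(sub$p_corrected),
                 n_features = max(core$n_features),
                 window_size = best$window_size)
    }))
    merged <- merged[order(merged$start, merged$end), , drop = FALSE]
    rownames(merged) <- NULL
    if (nrow(merged) == n) return(merged)
    cand <- merged
  }
}

#' Plot-ready chromogram table
#'
#' One row per periodic region, ordered by region length (longest first),
#' with the local period p, the number of contributing features g, the
#' corrected p-value and the window size that detected it.  Optional
#' macrodomain boundaries are validated against the genome length and
#' attached as an attribute for the rendering.
#'
#' @param regions a \code{\link{map_periodic_regions}} result.
#' @param macrodomain_boundaries optional numeric vector of boundary
#'   positions in bp to overlay (e.g. macrodomain borders).
#' @param path optional TSV output path.
#' @return data frame ordered by \code{end - start} descending.
#' @export
chromogram_table <- function(regions, macrodomain_boundaries = NULL,
                             path = NULL) {
  stopifnot(inherits(regions, "periodic_regions"))
  G <- attr(regions, "genome_length")
  if (!is.null(macrodomain_boundaries)) {
    if (any(macrodomain_boundaries < 1 | macrodomain_boundaries > G)) {
      stop("validation error: boundary outside [1, ", G, "]",
           call. = FALSE)
    }
  }
  tbl <- as.data.frame(regions)
  tbl <- tbl[order(-(tbl$end - tbl$start), tbl$start), , drop = FALSE]
  tbl <- tbl[, c("start", "end", "period", "n_features", "p_corrected",
                 "window_size")]
  rownames(tbl) <- NULL
  attr(tbl, "macrodomain_boundaries") <- macrodomain_boundaries
  attr(tbl, "genome_length") <- G
  if (!is.null(path)) {
    write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tbl
}

#' Chromogram plot
#'
#' Horizontal bars along the genome axis, one per periodic region, stacked
#' by length; bar thickness reflects the number of contributing features and
#' colour the corrected p-value.  Macrodomain boundaries, if supplied to
#' \code{\link{chromogram_table}}, are drawn as vertical dashed lines.
#'
#' @param tbl a \code{\link{chromogram_table}} result.
#' @return a ggplot object.
#' @export
plot_chromogram <- function(tbl) {
  G <- attr(tbl, "genome_length")
  bounds <- attr(tbl, "macrodomain_boundaries")
  p <- ggplot2::ggplot()
  if (nrow(tbl) > 0) {
    tbl$rank <- seq_len(nrow(tbl))
    tbl$thick <- 0.2 + 0.6 * tbl$n_features / max(tbl$n_features)
    p <- p + ggplot2::geom_rect(
      data = tbl,
      ggplot2::aes(xmin = start, xmax = end, ymin = rank - thick / 2,
                   ymax = rank + thick / 2, fill = -log10(p_corrected)))
  }
  if (!is.null(bounds)) {
    p <- p + ggplot2::geom_vline(xintercept = bounds, linetype = "dashed")
  }
  p +
    ggplot2::scale_fill_viridis_c(name = expression(-log[10] ~ p)) +
    ggplot2::xlim(0, G) +
    ggplot2::labs(x = "genome position (bp)", y = NULL,
                  title = "Chromogram: regions with a local periodic pattern") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
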