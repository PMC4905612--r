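#' Parameters for phase clustering
#'
#' The DBSCAN neighbourhood radius interpolates geometrically between the
#' period and the proximity threshold:
#' \eqn{\varepsilon = P^{1-e} d^{e}} where \eqn{e} is the clustering
#' exponent.  At \eqn{e = 1} the radius is the plain proximity threshold d;
#' as \eqn{e \to 0} it grows towards the full period, merging everything into
#' one cluster — the exponent therefore tunes the sensitivity of the
#' clustering.
#'
#' @param period significant period P in bp.
#' @param proximity proximity threshold d in bp (the same scale the
#'   proximity pre-filter uses).
#' @param clustering_exponent e in (0, 1].
#' @param min_cluster_size DBSCAN minPts, >= 2.
#' @return object of class \code{cluster_params} with the derived
#'   \code{eps}.
#' @examples
#' cluster_params(14830, 1000, 0.5)$eps  # sqrt(P * d) ~ 3851 bp
#' @export
cluster_params <- function(period, proximity = 1000,
                           clustering_exponent = 0.5,
                           min_cluster_size = 2) {
  if (!(clustering_exponent > 0 && clustering_exponent <= 1)) {
    stop("`clustering_exponent` must be in (0, 1]", call. = FALSE)
  }
  if (period <= 0 || proximity <= 0) {
    stop("`period` and `proximity` must be positive", call. = FALSE)
  }
  if (min_cluster_size < 2) stop("`min_cluster_size` must be >= 2",
                                 call. = FALSE)
  eps <- period^(1 - clustering_exponent) * proximity^clustering_exponent
  structure(
    list(period = period, proximity = proximity,
         clustering_exponent = clustering_exponent,
         min_cluster_size = as.integer(min_cluster_size), eps = eps),
    class = "cluster_params"
  )
}

# Deterministic DBSCAN on 1-D circular coordinates.
# dist(a, b) = min(|a - b|, period - |a - b|).  Points are visited in sorted
# phase order (ties broken by index); border points keep the label of the
# first core cluster that reaches them.  Label 0 marks noise.
dbscan_circular <- function(phi, period, eps, min_pts) {
  n <- length(phi)
  d <- abs(outer(phi, phi, "-"))
  d <- pmin(d, period - d)
  neigh <- d <= eps
  core <- rowSums(neigh) >= min_pts  # neighbourhood includes the point itself
  labels <- integer(n)
  ord <- order(phi, seq_len(n))
  cl <- 0L
  for (i in ord) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- i
    while (length(queue) > 0) {
      q <- queue[[1]]
      queue <- queue[-1]
      nb <- which(neigh[q, ])
      nb <- nb[order(phi[nb], nb)]
      for (m in nb) {
        if (labels[m] == 0L) {
          labels[m] <- cl
          if (core[m]) queue <- c(queue, m)
        }
      }
    }
  }
  labels
}

#' Cluster features that are in-phase for a period
#'
#' Transforms feature coordinates to phases for the given period and runs
#' DBSCAN on the phase circle with the circular distance
#' \eqn{\mathrm{dist}(\phi_1, \phi_2) = \min(|\phi_1-\phi_2|,
#' P - |\phi_1-\phi_2|)}, so clusters straddling phase 0 are never split.
#' The radius and minPts come from \code{\link{cluster_params}}.  Cluster
#' labels are contiguous integers from 1 assigned in phase order; 0 marks
#' noise.
#'
#' @param fs a \code{\link{feature_set}} (apply the proximity filter first if
#'   desired).
#' @param params a \code{\link{cluster_params}} object.
#' @return data frame (one row per feature, in position order) with columns
#'   \code{name}, \code{position}, \code{phase}, \code{cluster}.
#' @export
cluster_phases <- function(fs, params) {
  stopifnot(inherits(fs, "feature_set"), inherits(params, "cluster_params"))
  df <- fs$features
  if (nrow(df) < params$min_cluster_size) {
    stop("fewer features (", nrow(df), ") than min_cluster_size (",
         params$min_cluster_size, ")", call. = FALSE)
  }
  phi <- phase_transform(df$position, params$period)
  labels <- dbscan_circular(phi, params$period, params$eps,
                            params$min_cluster_size)
  data.frame(name = df$name, position = df$position, phase = phi,
             cluster = labels, stringsAsFactors = FALSE)
}

#' Positional score: per-feature contribution to a period's significance
#'
#' The contribution of feature i is the leave-one-out drop of the
#' periodicity score, \eqn{c_i = S(\mathrm{all}) - S(\mathrm{all} \setminus
#' i)}: features aligned with the dominant phase increase S (positive
#' \eqn{c_i}), features opposing it decrease S.  Contributions are min-max
#' normalised to [0, 1] across the set; if every contribution is equal all
#' scores are 1.
#'
#' @param fs a \code{\link{feature_set}} with at least 3 features.
#' @param period period P in bp.
#' @return named numeric vector of scores in [0, 1] (names = feature names,
#'   position order).
#' @export
positional_scores <- function(fs, period) {
  stopifnot(inherits(fs, "feature_set"))
  df <- fs$features
  n <- nrow(df)
  if (n < 3) stop("positional scores need at least 3 features",
                  call. = FALSE)
  theta <- 2 * pi * phase_transform(df$position, period) / period
  cs <- cos(theta)
  sn <- sin(theta)
  C <- sum(cs)
  Sm <- sum(sn)
  S_all <- (C^2 + Sm^2) / n
  S_loo <- ((C - cs)^2 + (Sm - sn)^2) / (n - 1)
  contrib <- S_all - S_loo
  rng <- range(contrib)
  scores <- if (diff(rng) < 1e-12) {
    rep(1, n)
  } else {
    (contrib - rng[1]) / diff(rng)
  }
  names(scores) <- df$name
  scores
}

#' Plot-ready clustergram table
#'
#' Joins cluster labels with positional scores, sorted by phase: the table
#' behind the clustergram, where in-phase features line up vertically and
#' carry their contribution to the period's significance on the right axis.
#'
#' @param fs a \code{\link{feature_set}}.
#' @param params a \code{\link{cluster_params}} object.
#' @param path optional TSV output path.
#' @return data frame with columns \code{name}, \code{position},
#'   \code{phase}, \code{cluster}, \code{positional_score}, sorted by phase.
#' @export
clustergram_table <- function(fs, params, path = NULL) {
  rows <- cluster_phases(fs, params)
  scores <- positional_scores(fs, params$period)
  rows$positional_score <- as.numeric(scores[rows$name])
  rows <- rows[order(rows$phase, rows$name), , drop = FALSE]
  rownames(rows) <- NULL
  if (!is.null(path)) {
    write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  rows
}

#' Clustergram plot
#'
#' Phase on the horizontal axis, one feature per horizontal line, coloured
#' by cluster (noise grey), point size proportional to the positional score.
#'
#' @param tbl a \code{\link{clustergram_table}} result.
#' @param params the \code{\link{cluster_params}} used.
#' @return a ggplot object.
#' @export
plot_clustergram <- function(tbl, params) {
  tbl$label <- factor(ifelse(tbl$cluster == 0, "noise", tbl$cluster))
  tbl$feature <- factor(tbl$name, levels = tbl$name)
  ggplot2::ggplot(tbl, ggplot2::aes(x = phase, y = feature,
                                    colour = label,
                                    size = positional_score)) +
    ggplot2::geom_point() +
    ggplot2::scale_size_continuous(range = c(1, 4)) +
    ggplot2::labs(x = sprintf("phase (bp) for period %s",
                              format(params$period, big.mark = ",")),
                  y = NULL, colour = "cluster",
                  size = "positional score",
                  title = "Clustergram") +
    ggplot2::theme_minimal()
}
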