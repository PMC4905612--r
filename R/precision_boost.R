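#' Best log-odds hit of a motif in a sequence
#'
#' Scans every window of the sequence on both strands with the motif's
#' log-odds matrix and returns the maximum window score.  Windows containing
#' an N (or any non-ACGT letter) are skipped; a sequence with no scorable
#' window returns \code{-Inf}.
#'
#' By construction the score is strand-symmetric:
#' \code{pwm_score(seq, m) == pwm_score(reverse_complement(seq), m)}.
#'
#' @param sequences character vector of nucleotide sequences (each at least
#'   as long as the motif).
#' @param motif a \code{\link{motif_matrix}}.
#' @return numeric vector of maximal log2-odds scores.
#' @export
pwm_score <- function(sequences, motif) {
  stopifnot(inherits(motif, "motif_matrix"))
  vapply(sequences, pwm_score_one, numeric(1), motif = motif,
         USE.NAMES = !is.null(names(sequences)))
}

pwm_score_one <- function(sequence, motif) {
  s <- toupper(sequence)
  n <- nchar(s)
  w <- motif$width
  if (n < w) {
    stop("sequence (length ", n, ") shorter than motif width ", w,
         call. = FALSE)
  }
  idx <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
  lo <- motif$log_odds
  n_win <- n - w + 1
  fwd <- numeric(n_win)
  # reverse complement: complement base index is 5 - idx, read right to left
  rc <- rev(5 - idx)
  rev_ <- numeric(n_win)
  for (j in seq_len(w)) {
    span <- j:(j + n_win - 1)
    fwd <- fwd + lo[cbind(idx[span], j)]
    rev_ <- rev_ + lo[cbind(rc[span], j)]
  }
  best <- suppressWarnings(max(c(fwd, rev_), na.rm = TRUE))
  if (!is.finite(best) && all(is.na(c(fwd, rev_)))) return(-Inf)
  if (is.na(best)) return(-Inf)
  best
}

#' Reverse complement of a nucleotide string
#' @param sequence character vector of sequences over A, C, G, T, N.
#' @return reverse-complemented sequences.
#' @export
reverse_complement <- function(sequence) {
  vapply(sequence, function(s) {
    paste(rev(strsplit(chartr("ACGTNacgtn", "TGCANtgcan", s), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Build the two classifier views: sequence scores and positional scores
#'
#' The sequence view scores every gene's regulatory sequence against each
#' motif variant (\code{\link{pwm_score}}); the position view computes, for
#' each significant period, the positional score of every gene with the
#' scores evaluated over all genes jointly (\code{\link{positional_scores}}).
#' Genes whose sequence yields no finite motif score (e.g. all-N) are
#' excluded from both views with a warning naming them.
#'
#' @param genes data frame with columns \code{name}, \code{position},
#'   \code{sequence} (as produced by \code{\link{generate_regulon_dataset}}).
#' @param motifs a single \code{\link{motif_matrix}} or a named list of them
#'   (see \code{\link{motif_variants}}).
#' @param periods numeric vector of significant periods.
#' @param genome_length chromosome length for the positional view.
#' @param circular is the chromosome circular?
#' @return list with matrices \code{sequence} (genes x motif variants) and
#'   \code{position} (genes x periods), rownames = gene names.
#' @export
build_view_features <- function(genes, motifs, periods, genome_length,
                                circular = TRUE) {
  stopifnot(is.data.frame(genes),
            all(c("name", "position", "sequence") %in% names(genes)))
  if (inherits(motifs, "motif_matrix")) motifs <- list(full = motifs)
  if (length(motifs) < 1 || length(periods) < 1) {
    stop("need at least one motif variant and one period", call. = FALSE)
  }
  seq_mat <- vapply(motifs, function(m) pwm_score(genes$sequence, m),
                    numeric(nrow(genes)))
  if (nrow(genes) == 1) seq_mat <- matrix(seq_mat, nrow = 1)
  colnames(seq_mat) <- paste0("seq_", names(motifs))
  rownames(seq_mat) <- genes$name

  bad <- !is.finite(seq_mat[, 1])
  if (any(bad)) {
    warning("excluding gene(s) without a scorable sequence: ",
            paste(genes$name[bad], collapse = ", "), call. = FALSE)
    genes <- genes[!bad, , drop = FALSE]
    seq_mat <- seq_mat[!bad, , drop = FALSE]
  }

  fs <- feature_set(genes$name, genes$position,
                    genome_length = genome_length, circular = circular)
  pos_mat <- vapply(periods, function(P) {
    sc <- positional_scores(fs, P)
    as.numeric(sc[genes$name])
  }, numeric(nrow(genes)))
  if (nrow(genes) == 1) pos_mat <- matrix(pos_mat, nrow = 1)
  colnames(pos_mat) <- paste0("pos_P", format(periods, scientific = FALSE,
                                              trim = TRUE))
  rownames(pos_mat) <- genes$name
  list(sequence = seq_mat, position = pos_mat)
}

# Best decision stump for one view under sample weights w.
# Thresholds are midpoints of sorted unique column values; h(x) =
# polarity * sign(x - threshold) with ties (x == threshold) classified -1
# for polarity +1.
best_stump <- function(X, y, w) {
  best <- list(error = Inf)
  for (col in seq_len(ncol(X))) {
    v <- X[, col]
    ord <- order(v, seq_along(v))
    vs <- v[ord]
    ws <- w[ord]
    ys <- y[ord]
    cum_pos <- cumsum(ws * (ys == 1))   # weight of positives at or below i
    cum_neg <- cumsum(ws * (ys == -1))
    tot_neg <- cum_neg[length(cum_neg)]
    cut <- which(diff(vs) > 0)          # boundaries between distinct values
    if (length(cut) == 0) next
    thr <- (vs[cut] + vs[cut + 1]) / 2
    # near-duplicate values can make the midpoint round onto one of them;
    # keep only thresholds that strictly separate their neighbours
    sep <- thr > vs[cut] & thr < vs[cut + 1]
    cut <- cut[sep]
    thr <- thr[sep]
    if (length(cut) == 0) next
    # polarity +1: predict +1 for x > thr
    err_plus <- cum_pos[cut] + (tot_neg - cum_neg[cut])
    err_minus <- 1 - err_plus
    for (k in seq_along(thr)) {
      if (err_plus[k] < best$error) {
        best <- list(column = colnames(X)[col], threshold = thr[k],
                     polarity = 1, error = err_plus[k])
      }
      if (err_minus[k] < best$error) {
        best <- list(column = colnames(X)[col], threshold = thr[k],
                     polarity = -1, error = err_minus[k])
      }
    }
  }
  best
}

stump_predict <- function(x, threshold, polarity) {
  ifelse(polarity * (x - threshold) > 0, 1, -1)
}

#' Train the multi-view boosting classifier
#'
#' A modified AdaBoost: at every iteration each view proposes its best
#' decision stump (column, threshold, polarity minimising the weighted
#' error), and the stump of the lower-error view is appended to the ensemble
#' with weight \eqn{\alpha = \frac{1}{2}\ln((1-\varepsilon)/\varepsilon)}.
#' Sample weights are updated multiplicatively,
#' \eqn{w_i \leftarrow w_i e^{-\alpha y_i h(x_i)}}, and renormalised.
#' Training stops early when no stump beats chance
#' (\eqn{\varepsilon \ge 0.5}) or when a stump is perfect
#' (\eqn{\varepsilon = 0}; it is appended with a capped weight).
#'
#' Class imbalance is absorbed by the initial weights: each class receives
#' total weight 1/2 split equally among its members.
#'
#' @param views named list of numeric matrices (same rows = genes, any
#'   number of columns), e.g. the output of
#'   \code{\link{build_view_features}}.
#' @param labels vector of +1 (target) / -1 (non-target), one per row.
#' @param n_iter maximum boosting iterations T.
#' @param seed unused by the deterministic stump learner; accepted for
#'   interface uniformity.
#' @return object of class \code{boost_model}: list with \code{stumps}
#'   (data frame: iteration, view, column, threshold, polarity, error,
#'   alpha), \code{trace} (view selected per iteration),
#'   \code{weight_history} (iterations x genes matrix of post-update
#'   weights) and \code{views} (column names per view).
#' @export
train_multiview_boost <- function(views, labels, n_iter = 10, seed = NULL) {
  stopifnot(is.list(views), length(views) >= 1, !is.null(names(views)))
  n <- length(labels)
  if (!all(labels %in% c(-1, 1))) {
    stop("labels must be +1 / -1", call. = FALSE)
  }
  if (length(unique(labels)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  if (n_iter < 1) stop("`n_iter` must be >= 1", call. = FALSE)
  for (v in names(views)) {
    if (nrow(views[[v]]) != n) {
      stop("view '", v, "' has ", nrow(views[[v]]), " rows; expected ", n,
           call. = FALSE)
    }
  }
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == -1)
  w <- ifelse(labels == 1, 0.5 / n_pos, 0.5 / n_neg)
  stumps <- list()
  weight_history <- list()
  for (t in seq_len(n_iter)) {
    proposals <- lapply(views, best_stump, y = labels, w = w)
    errs <- vapply(proposals, function(p) p$error, numeric(1))
    if (all(!is.finite(errs))) break
    view <- names(views)[which.min(errs)]   # ties: first view in list order
    st <- proposals[[view]]
    if (st$error >= 0.5) break
    eps <- max(st$error, 1e-12)
    alpha <- 0.5 * log((1 - eps) / eps)
    h <- stump_predict(views[[view]][, st$column], st$threshold,
                       st$polarity)
    stumps[[t]] <- data.frame(
      iteration = t, view = view, column = st$column,
      threshold = st$threshold, polarity = st$polarity,
      error = st$error, alpha = alpha, stringsAsFactors = FALSE)
    w <- w * exp(-alpha * labels * h)
    w <- w / sum(w)
    weight_history[[t]] <- w
    if (st$error == 0) break
  }
  if (length(stumps) == 0) {
    stop("no stump beat chance at the first iteration", call. = FALSE)
  }
  structure(
    list(stumps = do.call(rbind, stumps),
         trace = vapply(stumps, function(s) s$view, character(1)),
         weight_history = do.call(rbind, weight_history),
         views = lapply(views, colnames)),
    class = "boost_model"
  )
}

#' @export
print.boost_model <- function(x, ...) {
  tab <- table(x$trace)
  cat(sprintf("<boost_model> %d weak classifiers (%s)\n",
              nrow(x$stumps),
              paste(names(tab), tab, sep = ": ", collapse = ", ")))
  invisible(x)
}

check_model_columns <- function(model, views) {
  for (v in unique(model$stumps$view)) {
    if (is.null(views[[v]])) {
      stop("missing view '", v, "' in the supplied features", call. = FALSE)
    }
    need <- unique(model$stumps$column[model$stumps$view == v])
    missing <- setdiff(need, colnames(views[[v]]))
    if (length(missing) > 0) {
      stop("missing column(s) in view '", v, "': ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
}

#' Strong-classifier scores
#'
#' The strong classifier is the weighted vote
#' \eqn{F(x) = \sum_t \alpha_t h_t(x)}; \code{sign(F)} is the hard label.
#' Per-view partial sums are returned alongside and add up to F exactly.
#'
#' @param model a \code{\link{train_multiview_boost}} model.
#' @param views named list of feature matrices containing every column the
#'   model references.
#' @return data frame with \code{name}, \code{score}, \code{label} and one
#'   partial-sum column per view.
#' @export
predict_scores <- function(model, views) {
  stopifnot(inherits(model, "boost_model"))
  check_model_columns(model, views)
  first <- views[[1]]
  n <- nrow(first)
  nm <- rownames(first) %||% as.character(seq_len(n))
  partials <- matrix(0, n, length(views),
                     dimnames = list(nm, names(views)))
  for (i in seq_len(nrow(model$stumps))) {
    st <- model$stumps[i, ]
    h <- stump_predict(views[[st$view]][, st$column], st$threshold,
                       st$polarity)
    partials[, st$view] <- partials[, st$view] + st$alpha * h
  }
  score <- rowSums(partials)
  out <- data.frame(name = nm, score = score,
                    label = ifelse(score >= 0, 1, -1),
                    stringsAsFactors = FALSE)
  for (v in names(views)) out[[paste0("partial_", v)]] <- partials[, v]
  rownames(out) <- NULL
  out
}

#' Per-iteration weak-classifier scores, split by view
#'
#' For the interplay analysis: the weighted weak-classifier outputs
#' \eqn{\alpha_t h_t(x_i)} are collected into one gene x iteration matrix
#' per view — one matrix for the iterations where the position view was
#' selected, one for the sequence (or any other) view.  A view never
#' selected yields a zero-column matrix (flagged with a warning).
#'
#' A decision stump has a sign indeterminacy (h and -h with flipped
#' polarity describe the same boundary), so with \code{orient = TRUE}
#' (default) each column is oriented to correlate positively with its
#' view's aggregate score, making the signs of loadings comparable within
#' and across blocks on a correlation-circle display.
#'
#' @param model a \code{\link{train_multiview_boost}} model.
#' @param views named list of feature matrices.
#' @param orient resolve the per-column sign indeterminacy (see Details)?
#' @return named list of matrices, one per view of the model, columns named
#'   \code{<view><iteration>}.
#' @export
extract_iteration_scores <- function(model, views, orient = TRUE) {
  stopifnot(inherits(model, "boost_model"))
  check_model_columns(model, views)
  n <- nrow(views[[1]])
  nm <- rownames(views[[1]]) %||% as.character(seq_len(n))
  out <- lapply(names(views), function(v) {
    ix <- which(model$stumps$view == v)
    mat <- matrix(numeric(0), nrow = n, ncol = length(ix))
    rownames(mat) <- nm
    if (length(ix) == 0) return(mat)
    for (k in seq_along(ix)) {
      st <- model$stumps[ix[k], ]
      mat[, k] <- st$alpha * stump_predict(views[[v]][, st$column],
                                           st$threshold, st$polarity)
    }
    colnames(mat) <- paste0(v, model$stumps$iteration[ix])
    if (orient && ncol(mat) > 1) {
      tot <- rowSums(mat)
      for (k in seq_len(ncol(mat))) {
        r <- suppressWarnings(cor(mat[, k], tot))
        if (!is.na(r) && r < 0) mat[, k] <- -mat[, k]
      }
    }
    mat
  })
  names(out) <- names(views)
  empty <- names(out)[vapply(out, ncol, 1L) == 0]
  if (length(empty) > 0) {
    warning("view(s) never selected by the model: ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  out
}

#' Regularised canonical correlation of two variable blocks
#'
#' Finds paired linear combinations (variates) of the columns of X and Y
#' with maximal correlation.  Columns are standardised; a ridge term
#' \code{lambda} is added to the diagonal of each block's correlation matrix
#' before whitening, which keeps the problem well-posed when columns are
#' many or collinear.  With \code{lambda = 0} the canonical correlations
#' equal those of \code{stats::cancor}.
#'
#' Loadings are the correlations of each variable with the bisector of the
#' paired variates, \eqn{(U_d + V_d)/2}, for the first two variates — the
#' quantities drawn on a correlation-circle plot, where variables subtending
#' an obtuse angle (opposite-sign loadings on the first variate) are
#' negatively associated.
#'
#' @param X,Y numeric matrices with the same number of rows (>= 3) and at
#'   least one column each; constant columns are an error.
#' @param lambda ridge penalty for both blocks; default 0.1 when either
#'   block has at least rows/2 columns, else 0.
#' @return object of class \code{cca_result}: list with \code{cor}
#'   (canonical correlations, descending, in [0, 1]), \code{loadings}
#'   (list X, Y: variables x first two variates), \code{weights},
#'   \code{variates} and \code{lambda}.
#' @export
canonical_correlations <- function(X, Y, lambda = NULL) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(X)
  if (n < 3 || nrow(Y) != n) {
    stop("X and Y need the same number of rows, at least 3", call. = FALSE)
  }
  if (ncol(X) < 1 || ncol(Y) < 1) {
    stop("X and Y need at least one column each", call. = FALSE)
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("Y", seq_len(ncol(Y)))
  const <- c(colnames(X)[apply(X, 2, sd) == 0],
             colnames(Y)[apply(Y, 2, sd) == 0])
  if (length(const) > 0) {
    stop("constant column(s): ", paste(const, collapse = ", "),
         call. = FALSE)
  }
  lambda <- lambda %||%
    (if (ncol(X) >= n / 2 || ncol(Y) >= n / 2) 0.1 else 0)
  Xs <- scale(X)
  Ys <- scale(Y)
  Rxx <- crossprod(Xs) / (n - 1) + diag(lambda, ncol(X))
  Ryy <- crossprod(Ys) / (n - 1) + diag(lambda, ncol(Y))
  Rxy <- crossprod(Xs, Ys) / (n - 1)
  K <- inv_sqrt(Rxx) %*% Rxy %*% inv_sqrt(Ryy)
  sv <- svd(K)
  d <- min(ncol(X), ncol(Y))
  cors <- pmin(1, pmax(0, sv$d[seq_len(d)]))
  wx <- inv_sqrt(Rxx) %*% sv$u[, seq_len(d), drop = FALSE]
  wy <- inv_sqrt(Ryy) %*% sv$v[, seq_len(d), drop = FALSE]
  U <- Xs %*% wx
  V <- Ys %*% wy
  k <- min(2, d)
  Z <- (U[, seq_len(k), drop = FALSE] + V[, seq_len(k), drop = FALSE]) / 2
  load_x <- cor(Xs, Z)
  load_y <- cor(Ys, Z)
  colnames(load_x) <- colnames(load_y) <- paste0("variate", seq_len(k))
  structure(
    list(cor = cors, loadings = list(X = load_x, Y = load_y),
         weights = list(X = wx, Y = wy),
         variates = list(X = U, Y = V), lambda = lambda),
    class = "cca_result"
  )
}

inv_sqrt <- function(M) {
  e <- eigen(M, symmetric = TRUE)
  vals <- pmax(e$values, 1e-12)
  e$vectors %*% diag(1 / sqrt(vals), length(vals)) %*% t(e$vectors)
}

#' @export
print.cca_result <- function(x, ...) {
  cat("<cca_result> canonical correlations:",
      paste(sprintf("%.3f", x$cor), collapse = ", "),
      sprintf("(lambda = %g)\n", x$lambda))
  invisible(x)
}

#' Correlation-circle plot of a CCA result
#'
#' Variables of both blocks plotted by their loadings on the first two
#' variates inside the unit circle; points of the two blocks subtending an
#' obtuse angle at the origin are negatively associated.
#'
#' @param cca a \code{\link{canonical_correlations}} result.
#' @return a ggplot object.
#' @export
plot_correlation_circle <- function(cca) {
  stopifnot(inherits(cca, "cca_result"))
  lx <- cca$loadings$X
  ly <- cca$loadings$Y
  if (ncol(lx) < 2) {
    stop("correlation circle needs two variates", call. = FALSE)
  }
  df <- rbind(
    data.frame(name = rownames(lx), v1 = lx[, 1], v2 = lx[, 2],
               block = "X"),
    data.frame(name = rownames(ly), v1 = ly[, 1], v2 = ly[, 2],
               block = "Y"))
  th <- seq(0, 2 * pi, length.out = 200)
  circ <- data.frame(x = cos(th), y = sin(th))
  ggplot2::ggplot(df, ggplot2::aes(x = v1, y = v2, colour = block)) +
    ggplot2::geom_path(data = circ, ggplot2::aes(x = x, y = y),
                       inherit.aes = FALSE, colour = "grey70") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey85") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey85") +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = name), vjust = -0.8,
                       size = 3, show.legend = FALSE) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "variate 1", y = "variate 2",
                  title = "Correlation circle") +
    ggplot2::theme_minimal()
}

#' Write / read a boosting model as structured text
#'
#' The model is serialised as versioned JSON so that prediction can be run
#' later or elsewhere without the training data.
#'
#' @param model a \code{\link{train_multiview_boost}} model.
#' @param path file path.
#' @return \code{path} invisibly (write) or a \code{boost_model} (read).
#' @export
write_boost_model <- function(model, path) {
  stopifnot(inherits(model, "boost_model"))
  stumps <- model$stumps
  # serialise doubles as 17-significant-digit strings so the read-back
  # model is bit-identical (thresholds must not move by even one ulp)
  for (col in c("threshold", "error", "alpha")) {
    stumps[[col]] <- sprintf("%.17g", stumps[[col]])
  }
  payload <- list(
    format = "periscan_boost_model",
    version = 1L,
    package_version = as.character(packageVersion("periscan")),
    stumps = stumps,
    trace = model$trace,
    views = model$views
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_boost_model
#' @export
read_boost_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "periscan_boost_model")) {
    stop("not a boosting model file: ", path, call. = FALSE)
  }
  stumps <- payload$stumps
  for (col in c("threshold", "error", "alpha")) {
    stumps[[col]] <- as.numeric(stumps[[col]])
  }
  structure(
    list(stumps = stumps, trace = payload$trace,
         weight_history = NULL,
         views = payload$views),
    class = "boost_model"
  )
}
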