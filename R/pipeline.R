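#' Run the full three-step layout analysis
#'
#' Orchestrates scan -> select -> cluster/score -> map for one feature set
#' and writes a results bundle: the periodobar table, one clustergram table
#' per significant period, the chromogram table, and a run manifest
#' recording every parameter, seed and output digest.
#'
#' @param fs a \code{\link{feature_set}} (or a path plus \code{format} and
#'   \code{genome_length} to read one).
#' @param out_dir output directory (created if needed).
#' @param alpha significance threshold for periods.
#' @param proximity proximity-filter threshold in bp.
#' @param mode scan mode, \code{"DOM"} or \code{"CIRC"}.
#' @param p_min,p_max,step scan grid (see \code{\link{scan_periods}}).
#' @param clustering_exponent,min_cluster_size clustergram parameters.
#' @param map_cutoff corrected p-value cutoff of the region mapping.
#' @param map_regions run the sliding-window region mapping?
#' @param macrodomain_boundaries optional boundary overlay for the
#'   chromogram.
#' @param seed seed governing all Monte-Carlo calibrations.
#' @param format,genome_length,circular used only when \code{fs} is a file
#'   path.
#' @return invisibly, a list with the scan result, significant periods,
#'   clustergram tables, regions and the manifest path.
#' @export
run_patterns <- function(fs, out_dir, alpha = 0.05, proximity = 1000,
                         mode = "DOM", p_min = 10000, p_max = NULL,
                         step = 3, clustering_exponent = 0.5,
                         min_cluster_size = 2, map_cutoff = 5e-4,
                         map_regions = TRUE,
                         macrodomain_boundaries = NULL, seed = 1,
                         format = "tsv", genome_length = NULL,
                         circular = TRUE) {
  if (is.character(fs)) {
    fs <- read_feature_table(fs, format = format,
                             genome_length = genome_length,
                             circular = circular)
  }
  stopifnot(inherits(fs, "feature_set"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_line <- make_logger(file.path(out_dir, "run.log"))

  log_line("stage scan: %d features, mode %s, proximity %d bp",
           n_features(fs), mode, proximity)
  scan <- run_stage("scan", scan_periods(
    fs, mode = mode, p_min = p_min, p_max = p_max, step = step,
    proximity = proximity, seed = seed))
  log_line("stage scan: %d features used after proximity filter",
           scan$params$n_used)
  periodobar_table(scan, alpha, path = file.path(out_dir,
                                                 "periodobar.tsv"))
  sig <- run_stage("select", select_significant(scan, alpha))
  log_line("stage select: %d significant period(s) at alpha %g",
           nrow(sig), alpha)

  fs_used <- remove_proximal(fs, proximity)
  clustergrams <- list()
  for (i in seq_len(nrow(sig))) {
    P <- sig$period[i]
    params <- cluster_params(P, proximity = max(proximity, 1),
                             clustering_exponent = clustering_exponent,
                             min_cluster_size = min_cluster_size)
    tbl <- run_stage("cluster", clustergram_table(
      fs_used, params,
      path = file.path(out_dir, sprintf("clustergram_P%.0f.tsv", P))))
    clustergrams[[sprintf("P%.0f", P)]] <- tbl
  }

  regions <- NULL
  if (map_regions) {
    regions <- run_stage("map", map_periodic_regions(
      fs, p_cutoff = map_cutoff, proximity = proximity, seed = seed))
    chromogram_table(regions, macrodomain_boundaries,
                     path = file.path(out_dir, "chromogram.tsv"))
    log_line("stage map: %d periodic region(s) at cutoff %g",
             nrow(regions), map_cutoff)
  }

  manifest <- write_run_manifest(
    out_dir, command = "patterns",
    params = list(alpha = alpha, proximity = proximity, mode = mode,
                  p_min = p_min, p_max = p_max %||% (fs$genome_length / 2),
                  step = step, clustering_exponent = clustering_exponent,
                  min_cluster_size = min_cluster_size,
                  map_cutoff = map_cutoff,
                  macrodomain_boundaries = macrodomain_boundaries,
                  genome_length = fs$genome_length,
                  circular = fs$circular, n_features = n_features(fs)),
    seed = seed)
  invisible(list(scan = scan, significant = sig,
                 clustergrams = clustergrams, regions = regions,
                 manifest = manifest))
}

#' Train, predict or analyse the multi-view target classifier
#'
#' \code{task = "train"} fits the boosting model on labelled genes and
#' writes the model file plus the view-selection trace;
#' \code{task = "predict"} scores genes with a trained model and writes a
#' ranked prediction table with per-view partial sums;
#' \code{task = "interplay"} extracts the per-iteration classifier scores of
#' the two views and writes their canonical correlations and loadings.
#'
#' @param task one of \code{"train"}, \code{"predict"},
#'   \code{"interplay"}.
#' @param genes data frame with \code{name}, \code{position},
#'   \code{sequence} and (for training) \code{label} columns.
#' @param motif a \code{\link{motif_matrix}}.
#' @param periods significant periods for the position view (e.g. from
#'   \code{\link{scan_periods}}).
#' @param genome_length chromosome length.
#' @param out_dir output directory.
#' @param model a trained model or a model-file path (predict/interplay).
#' @param n_iter boosting iterations (train).
#' @param n_trim trimmed motif variants (train).
#' @param lambda CCA ridge (interplay); \code{NULL} for the automatic
#'   default.
#' @param seed recorded in the manifest.
#' @return invisibly, a task-dependent list (model / predictions / CCA).
#' @export
run_precision <- function(task = c("train", "predict", "interplay"),
                          genes, motif, periods, genome_length, out_dir,
                          model = NULL, n_iter = 10, n_trim = 2,
                          lambda = NULL, seed = 1) {
  task <- match.arg(task)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  variants <- motif_variants(motif, n_trim = n_trim)
  views <- run_stage("features", build_view_features(
    genes, variants, periods, genome_length))
  if (task != "train") {
    if (is.character(model)) model <- read_boost_model(model)
    stopifnot(inherits(model, "boost_model"))
  }
  out <- switch(task,
    train = {
      labels <- genes$label
      fit <- run_stage("boost", train_multiview_boost(
        views, labels, n_iter = n_iter, seed = seed))
      write_boost_model(fit, file.path(out_dir, "boost_model.json"))
      write.table(
        fit$stumps, file.path(out_dir, "selection_trace.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      list(model = fit, views = views)
    },
    predict = {
      preds <- run_stage("predict", predict_scores(model, views))
      preds <- preds[order(-preds$score), , drop = FALSE]
      write.table(preds, file.path(out_dir, "predictions.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      list(predictions = preds)
    },
    interplay = {
      iter <- run_stage("interplay", suppressWarnings(
        extract_iteration_scores(model, views)))
      blocks <- iter[vapply(iter, ncol, 1L) > 0]
      if (length(blocks) < 2) {
        warning("interplay needs both views selected by the model; ",
                "found: ", paste(names(blocks), collapse = ", "),
                call. = FALSE)
        return(invisible(list(cca = NULL, iteration_scores = iter)))
      }
      cca <- run_stage("cca", canonical_correlations(
        blocks$position, blocks$sequence, lambda = lambda))
      write.table(
        data.frame(variate = seq_along(cca$cor), correlation = cca$cor),
        file.path(out_dir, "cca_correlations.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      loads <- rbind(
        data.frame(block = "position", variable = rownames(cca$loadings$X),
                   cca$loadings$X, row.names = NULL),
        data.frame(block = "sequence", variable = rownames(cca$loadings$Y),
                   cca$loadings$Y, row.names = NULL))
      write.table(loads, file.path(out_dir, "cca_loadings.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      list(cca = cca, iteration_scores = iter)
    })
  manifest <- write_run_manifest(
    out_dir, command = paste0("precision ", task),
    params = list(n_iter = n_iter, n_trim = n_trim,
                  periods = periods, genome_length = genome_length,
                  lambda = lambda, n_genes = nrow(genes)),
    seed = seed)
  out$manifest <- manifest
  invisible(out)
}

# Abort with the stage name and the underlying cause on any stage error.
run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

make_logger <- function(path) {
  function(fmt, ...) {
    line <- sprintf(fmt, ...)
    message(line)
    cat(line, "\n", file = path, append = TRUE)
  }
}

# Manifest: everything needed to re-run the command bit-identically for the
# deterministic parts (command, parameters, seed, inputs, outputs, digests).
write_run_manifest <- function(out_dir, command, params, seed) {
  outputs <- setdiff(list.files(out_dir), "run_manifest.json")
  digests <- as.character(tools::md5sum(file.path(out_dir, outputs)))
  manifest <- list(
    command = command,
    tool_version = as.character(packageVersion("periscan")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    params = params,
    outputs = data.frame(file = outputs, md5 = digests,
                         stringsAsFactors = FALSE)
  )
  path <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}
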