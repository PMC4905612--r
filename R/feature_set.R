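#' Construct a set of genomic features on one chromosome
#'
#' A feature set holds named reference points (typically gene or operon start
#' sites) on a single chromosome of known length.  Positions are 1-based and
#' features are stored sorted by position.
#'
#' @param name character vector of unique, non-empty feature names.
#' @param position integer-valued vector of 1-based coordinates in bp.
#' @param strand optional character vector over \code{"+"}, \code{"-"},
#'   \code{"*"} (unknown); recycled if length 1.  Default \code{"*"}.
#' @param genome_length chromosome length G in bp.
#' @param circular is the chromosome circular?  Affects proximity filtering,
#'   window sliding and region reporting.
#' @return An object of class \code{feature_set}: a list with elements
#'   \code{features} (data frame with columns \code{name}, \code{position},
#'   \code{strand}, sorted by position), \code{genome_length} and
#'   \code{circular}.
#' @examples
#' fs <- feature_set(c("a", "b"), c(120, 40), genome_length = 1000)
#' fs$features$name   # "b" first: sorted by position
#' @export
feature_set <- function(name, position, strand = NULL, genome_length,
                        circular = TRUE) {
  name <- as.character(name)
  position <- as.numeric(position)
  if (length(name) != length(position)) {
    stop("`name` and `position` must have the same length", call. = FALSE)
  }
  if (!is.numeric(genome_length) || length(genome_length) != 1 ||
      !is.finite(genome_length) || genome_length <= 0) {
    stop("`genome_length` must be a single positive number", call. = FALSE)
  }
  if (any(is.na(position)) || any(position != floor(position))) {
    stop("positions must be whole numbers", call. = FALSE)
  }
  if (any(position < 1) || any(position > genome_length)) {
    bad <- name[position < 1 | position > genome_length]
    stop("validation error: position of ", paste(bad, collapse = ", "),
         " outside [1, ", genome_length, "]", call. = FALSE)
  }
  if (any(!nzchar(name)) || anyNA(name)) {
    stop("validation error: feature names must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(name)) {
    stop("validation error: duplicate feature name(s): ",
         paste(unique(name[duplicated(name)]), collapse = ", "),
         call. = FALSE)
  }
  strand <- strand %||% "*"
  strand <- rep_len(as.character(strand), length(name))
  if (!all(strand %in% c("+", "-", "*"))) {
    stop("strand must be one of '+', '-', '*'", call. = FALSE)
  }
  ord <- order(position, name)
  structure(
    list(
      features = data.frame(name = name[ord], position = position[ord],
                            strand = strand[ord], stringsAsFactors = FALSE),
      genome_length = as.numeric(genome_length),
      circular = isTRUE(circular)
    ),
    class = "feature_set"
  )
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d features on a %s chromosome of %s bp\n",
              nrow(x$features), if (x$circular) "circular" else "linear",
              format(x$genome_length, big.mark = ",")))
  print(head(x$features, 6), row.names = FALSE)
  if (nrow(x$features) > 6) cat("  ...\n")
  invisible(x)
}

#' @export
as.data.frame.feature_set <- function(x, ...) x$features

#' Number of features in a feature set
#' @param fs a \code{\link{feature_set}}.
#' @return integer count.
#' @export
n_features <- function(fs) {
  stopifnot(inherits(fs, "feature_set"))
  nrow(fs$features)
}

#' Write a feature set as a two/three-column TSV
#'
#' The format written is the same one \code{\link{read_feature_table}} reads
#' back (\code{format = "tsv"}): name, position and, when any strand is known,
#' a strand column.  Reading the file back reproduces names and positions
#' exactly.
#'
#' @param fs a \code{\link{feature_set}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_feature_table <- function(fs, path) {
  stopifnot(inherits(fs, "feature_set"))
  df <- fs$features
  if (all(df$strand == "*")) df$strand <- NULL
  df$position <- format(df$position, scientific = FALSE, trim = TRUE)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}
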