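#' Read a genomic feature table into a feature set
#'
#' Supported formats:
#' \describe{
#'   \item{\code{tsv}}{two columns (name, position) with an optional third
#'     strand column; an optional header line; \code{#} comment lines.
#'     Positions are taken verbatim as 1-based reference points.}
#'   \item{\code{bed}}{BED with at least 4 columns (0-based, half-open
#'     intervals).  Each interval is reduced to its 5' end with respect to
#'     strand and converted to a 1-based coordinate.}
#'   \item{\code{gff3}}{GFF3 (1-based, closed intervals), reduced to the 5'
#'     end; the feature name is taken from the \code{Name} attribute, falling
#'     back to \code{ID}.}
#' }
#'
#' For BED and GFF3 records of unknown strand the interval start is used.
#'
#' @param path input file.
#' @param format one of \code{"tsv"}, \code{"bed"}, \code{"gff3"}.
#' @param genome_length chromosome length G in bp.
#' @param circular is the chromosome circular?
#' @return a validated, position-sorted \code{\link{feature_set}}.
#' @export
read_feature_table <- function(path, format = c("tsv", "bed", "gff3"),
                               genome_length, circular = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  parsed <- switch(format,
    tsv  = read_tsv_features(path),
    bed  = read_bed_features(path),
    gff3 = read_gff3_features(path)
  )
  feature_set(parsed$name, parsed$position, parsed$strand,
              genome_length = genome_length, circular = circular)
}

read_tsv_features <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0) stop("parse error: no data lines in ", path,
                             call. = FALSE)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  # Optional header: first retained line whose second field is not numeric.
  first <- fields[[1]]
  has_header <- length(first) >= 2 &&
    is.na(suppressWarnings(as.numeric(first[2])))
  if (has_header) {
    fields <- fields[-1]
    idx <- idx[-1]
  }
  if (length(fields) == 0) stop("parse error: no data lines in ", path,
                                call. = FALSE)
  name <- character(length(fields))
  pos <- numeric(length(fields))
  strand <- rep("*", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 2) {
      stop("parse error at line ", idx[i], ": expected at least 2 ",
           "tab-separated fields", call. = FALSE)
    }
    p <- suppressWarnings(as.numeric(f[2]))
    if (is.na(p)) {
      stop("parse error at line ", idx[i], ": position '", f[2],
           "' is not numeric", call. = FALSE)
    }
    name[i] <- f[1]
    pos[i] <- p
    if (length(f) >= 3 && f[3] %in% c("+", "-", "*")) strand[i] <- f[3]
  }
  list(name = name, position = pos, strand = strand)
}

read_bed_features <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- S4Vectors::mcols(gr)$name
  if (is.null(nm) || anyNA(nm)) {
    stop("parse error: BED input needs a name column (>= 4 columns)",
         call. = FALSE)
  }
  five_prime(gr, nm)
}

read_gff3_features <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  md <- S4Vectors::mcols(gr)
  nm <- md$Name
  if (is.null(nm)) nm <- rep(NA_character_, length(gr))
  if (anyNA(nm) && !is.null(md$ID)) nm[is.na(nm)] <- md$ID[is.na(nm)]
  if (anyNA(nm)) {
    stop("parse error: GFF3 records without Name= or ID= attribute",
         call. = FALSE)
  }
  five_prime(gr, nm)
}

# Reduce 1-based closed intervals (as GRanges) to strand-aware 5' ends.
five_prime <- function(gr, nm) {
  st <- as.character(BiocGenerics::strand(gr))
  pos <- ifelse(st == "-", BiocGenerics::end(gr), BiocGenerics::start(gr))
  st[st == "*"] <- "*"
  list(name = as.character(nm), position = as.numeric(pos), strand = st)
}

#' Drop features that lie too close to their neighbours
#'
#' Tightly packed features (e.g. genes of one operon) inflate the apparent
#' concentration of phases and hence the significance of short periods.  This
#' pre-filter scans features in coordinate order and drops a feature whenever
#' its distance to the last \emph{kept} feature is below \code{threshold}.  On
#' a circular chromosome the wrap-around gap between the last and the first
#' kept feature is also checked, dropping the later-coordinate one.
#'
#' The rule is greedy keep-first, hence deterministic, and idempotent: a
#' second application changes nothing because all surviving gaps are at least
#' \code{threshold}.
#'
#' @param fs a \code{\link{feature_set}}.
#' @param threshold minimum separation in bp; \code{0} disables filtering.
#' @param verbose message the number of removed features?
#' @return a \code{feature_set} containing the surviving subset, in the same
#'   order.
#' @examples
#' fs <- feature_set(c("a", "b", "c"), c(100, 150, 5000), genome_length = 1e4,
#'                   circular = FALSE)
#' n_features(remove_proximal(fs, 200))  # 2: the feature at 150 is dropped
#' @export
remove_proximal <- function(fs, threshold, verbose = FALSE) {
  stopifnot(inherits(fs, "feature_set"))
  if (!is.numeric(threshold) || length(threshold) != 1 || is.na(threshold) ||
      threshold < 0) {
    stop("`threshold` must be a single non-negative number", call. = FALSE)
  }
  df <- fs$features
  n <- nrow(df)
  if (n == 0 || threshold == 0) return(fs)
  keep <- logical(n)
  last <- -Inf
  for (i in seq_len(n)) {
    if (df$position[i] - last < threshold) next
    keep[i] <- TRUE
    last <- df$position[i]
  }
  if (fs$circular) {
    # Drop the later-coordinate member of any wrap-around violation.
    repeat {
      ki <- which(keep)
      if (length(ki) < 2) break
      wrap <- fs$genome_length - df$position[ki[length(ki)]] +
        df$position[ki[1]]
      if (wrap >= threshold) break
      keep[ki[length(ki)]] <- FALSE
    }
  }
  if (verbose) {
    message(sum(!keep), " of ", n, " features removed by the ",
            threshold, "-bp proximity filter")
  }
  out <- fs
  out$features <- df[keep, , drop = FALSE]
  rownames(out$features) <- NULL
  out
}
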