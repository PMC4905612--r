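#' Build a position weight matrix from nucleotide counts
#'
#' Counts plus a pseudocount are converted to per-column probabilities and
#' then to log2 odds against a background distribution.
#'
#' @param counts 4 x w numeric matrix of non-negative counts, rows in the
#'   order A, C, G, T.
#' @param pseudocount added to every cell before normalisation.  With
#'   \code{pseudocount = 0}, bases absent from a column get \code{-Inf}
#'   log-odds (hard exclusion).
#' @param background vector of 4 background probabilities (A, C, G, T);
#'   must be positive and sum to 1.
#' @return an object of class \code{motif_matrix}: list with \code{width},
#'   \code{probs} (4 x w), \code{log_odds} (4 x w, log2 scale),
#'   \code{background} and \code{consensus}.
#' @export
motif_matrix <- function(counts, pseudocount = 0.5,
                         background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stop("`counts` must have 4 rows (A, C, G, T)",
                              call. = FALSE)
  if (ncol(counts) < 1) stop("motif width must be >= 1", call. = FALSE)
  if (any(counts < 0) || anyNA(counts)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (length(background) != 4 || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-9) {
    stop("`background` must be 4 positive probabilities summing to 1",
         call. = FALSE)
  }
  if (pseudocount < 0) stop("`pseudocount` must be >= 0", call. = FALSE)
  rownames(counts) <- c("A", "C", "G", "T")
  cc <- counts + pseudocount
  probs <- sweep(cc, 2, colSums(cc), "/")
  log_odds <- log2(sweep(probs, 1, background, "/"))
  consensus <- paste(rownames(probs)[apply(probs, 2, which.max)],
                     collapse = "")
  if (all(abs(log_odds[is.finite(log_odds)]) < 1e-9)) {
    warning("zero-information motif: log-odds are 0 everywhere",
            call. = FALSE)
  }
  structure(
    list(width = ncol(counts), probs = probs, log_odds = log_odds,
         background = as.numeric(background), consensus = consensus),
    class = "motif_matrix"
  )
}

#' @export
print.motif_matrix <- function(x, ...) {
  cat(sprintf("<motif_matrix> width %d, consensus %s\n", x$width,
              x$consensus))
  invisible(x)
}

#' Read a binding-site motif from disk
#'
#' @param path input file.
#' @param format \code{"jaspar_pfm"} for a JASPAR-style plain 4-row count
#'   matrix (optionally with a \code{>} header and \code{A [ ... ]} row
#'   decorations), or \code{"aligned_fasta"} for a FASTA file of aligned
#'   binding sites of equal width.
#' @param pseudocount,background passed to \code{\link{motif_matrix}}.
#' @return a \code{\link{motif_matrix}}.
#' @export
read_motif <- function(path, format = c("jaspar_pfm", "aligned_fasta"),
                       pseudocount = 0.5, background = rep(0.25, 4)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  counts <- switch(format,
    jaspar_pfm = {
      lines <- readLines(path, warn = FALSE)
      lines <- lines[!grepl("^\\s*(>|#|$)", lines)]
      rows <- lapply(lines, function(l) {
        l <- gsub("[^0-9.]", " ", l)
        as.numeric(strsplit(trimws(l), "\\s+")[[1]])
      })
      rows <- rows[vapply(rows, length, 1L) > 0]
      if (length(rows) != 4) {
        stop("parse error: expected 4 count rows (A, C, G, T), found ",
             length(rows), call. = FALSE)
      }
      if (length(unique(vapply(rows, length, 1L))) != 1) {
        stop("parse error: count rows have unequal lengths", call. = FALSE)
      }
      do.call(rbind, rows)
    },
    aligned_fasta = {
      sites <- Biostrings::readDNAStringSet(path)
      if (length(sites) < 1) stop("no sites in ", path, call. = FALSE)
      if (length(unique(Biostrings::width(sites))) != 1) {
        stop("ragged alignment: sites have unequal widths", call. = FALSE)
      }
      Biostrings::consensusMatrix(sites)[c("A", "C", "G", "T"), ,
                                         drop = FALSE]
    }
  )
  motif_matrix(counts, pseudocount = pseudocount, background = background)
}

#' Motif variants: the full matrix plus information-trimmed versions
#'
#' Produces the full motif together with versions whose least-informative
#' flanking columns have been dropped, giving a small family of consensus
#' models of decreasing width for use as alternative sequence classifiers.
#'
#' @param motif a \code{\link{motif_matrix}}.
#' @param n_trim how many trimmed variants to produce (each drops one more
#'   flank column than the previous; variants narrower than 4 columns are not
#'   produced).
#' @return named list of \code{motif_matrix} objects (\code{full},
#'   \code{trim1}, ...).
#' @export
motif_variants <- function(motif, n_trim = 2) {
  stopifnot(inherits(motif, "motif_matrix"))
  info <- column_information(motif$probs)
  out <- list(full = motif)
  probs <- motif$probs
  lo <- 1L
  hi <- motif$width
  for (t in seq_len(n_trim)) {
    if (hi - lo + 1 <= 4) break
    # drop the less informative of the two current flank columns
    if (info[lo] <= info[hi]) lo <- lo + 1L else hi <- hi - 1L
    sub <- probs[, lo:hi, drop = FALSE]
    m <- motif
    m$probs <- sub
    m$log_odds <- motif$log_odds[, lo:hi, drop = FALSE]
    m$width <- ncol(sub)
    m$consensus <- substr(motif$consensus, lo, hi)
    out[[paste0("trim", t)]] <- m
  }
  out
}

column_information <- function(probs) {
  apply(probs, 2, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
}

#' Build a motif from a consensus string
#'
#' Convenience constructor used mainly by the synthetic-data generators: each
#' consensus base receives probability \code{strength}, the other three split
#' the remainder equally; \code{N} columns are uniform.
#'
#' @param consensus string over A, C, G, T, N.
#' @param strength probability of the consensus base per column, in
#'   (0.25, 1).
#' @param background background probabilities for the log-odds.
#' @return a \code{\link{motif_matrix}}.
#' @export
motif_from_consensus <- function(consensus, strength = 0.85,
                                 background = rep(0.25, 4)) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "T", "N"))) {
    stop("consensus must be over A, C, G, T, N", call. = FALSE)
  }
  if (strength <= 0.25 || strength >= 1) {
    stop("`strength` must be in (0.25, 1)", call. = FALSE)
  }
  probs <- vapply(bases, function(b) {
    if (b == "N") return(rep(0.25, 4))
    p <- rep((1 - strength) / 3, 4)
    p[match(b, c("A", "C", "G", "T"))] <- strength
    p
  }, numeric(4))
  # feed probabilities as pseudo-counts; pseudocount 0 keeps them verbatim
  motif_matrix(probs * 1000, pseudocount = 0, background = background)
}
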