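#' Generate feature positions with a planted period
#'
#' Emulates the statistical structure the layout analysis assumes: a lattice
#' of sites at multiples of a period \code{period} (with Gaussian jitter and
#' a uniformly drawn lattice offset) superimposed on a uniform background.
#' The defaults mirror the benchmark conditions used throughout the package:
#' a 4.64-Mbp circular chromosome, a 93-kbp period, 40 lattice sites with
#' 2-kbp jitter and 30 background sites.
#'
#' Positions are integers in [1, G]; collisions are resolved by +1 bp
#' shifts.  Given a seed the generator is a pure function of its arguments.
#'
#' @param genome_length chromosome length G in bp.
#' @param period planted period in bp.
#' @param n_lattice number of lattice members (requires
#'   \code{n_lattice * period <= genome_length} when \code{region} is
#'   absent).
#' @param jitter_sd Gaussian jitter (bp) around each lattice point, >= 0.
#' @param n_background number of uniform background sites.
#' @param region optional \code{c(start, end)}: restrict the lattice to this
#'   interval, with the background drawn uniformly over the whole genome.
#' @param circular circularity flag of the generated feature set.
#' @param seed optional seed.
#' @return list with \code{fs} (a \code{\link{feature_set}}) and
#'   \code{truth} (data frame: \code{name}, \code{is_lattice}).
#' @export
generate_periodic_positions <- function(genome_length = 4641652,
                                        period = 93000, n_lattice = 40,
                                        jitter_sd = 2000, n_background = 30,
                                        region = NULL, circular = TRUE,
                                        seed = NULL) {
  stopifnot(jitter_sd >= 0, n_lattice >= 0, n_background >= 0,
            n_lattice + n_background >= 1)
  if (is.null(region)) {
    if (n_lattice * period > genome_length) {
      stop("impossible configuration: n_lattice * period exceeds the ",
           "genome length", call. = FALSE)
    }
  } else {
    stopifnot(length(region) == 2, region[1] >= 1,
              region[2] <= genome_length, region[1] < region[2])
    span <- region[2] - region[1] + 1
    if ((n_lattice - 1) * period >= span) {
      stop("impossible configuration: lattice does not fit in the region",
           call. = FALSE)
    }
  }
  with_seed(seed, {
    if (n_lattice > 0) {
      if (is.null(region)) {
        offset <- runif(1, 0, period)
        lat <- (offset + (seq_len(n_lattice) - 1) * period +
                  rnorm(n_lattice, 0, jitter_sd)) %% genome_length
        lat <- floor(lat) + 1
      } else {
        span <- region[2] - region[1] + 1
        slack <- span - (n_lattice - 1) * period - 1
        offset <- runif(1, 0, max(slack, 1))
        lat <- offset + (seq_len(n_lattice) - 1) * period +
          rnorm(n_lattice, 0, jitter_sd)
        lat <- region[1] + (floor(lat) %% span)
      }
    } else {
      lat <- numeric(0)
    }
    bg <- if (n_background > 0) {
      floor(runif(n_background, 0, genome_length)) + 1
    } else {
      numeric(0)
    }
    pos <- c(lat, bg)
    pos <- resolve_collisions(pos, genome_length)
    name <- c(sprintf("L%03d", seq_len(n_lattice)),
              sprintf("B%03d", seq_len(n_background)))
    fs <- feature_set(name, pos, genome_length = genome_length,
                      circular = circular)
    truth <- data.frame(name = name,
                        is_lattice = c(rep(TRUE, n_lattice),
                                       rep(FALSE, n_background)),
                        stringsAsFactors = FALSE)
    list(fs = fs, truth = truth)
  })
}

resolve_collisions <- function(pos, genome_length) {
  while (anyDuplicated(pos)) {
    d <- duplicated(pos)
    pos[d] <- (pos[d] %% genome_length) + 1
  }
  pos
}

#' Generate a fully uniform (null) feature set
#'
#' Positions are drawn uniformly on [1, G] — the null model the period
#' scan's p-values are calibrated against.
#'
#' @param n number of features (>= 2).
#' @param genome_length chromosome length G.
#' @param circular circularity flag.
#' @param seed optional seed.
#' @return a \code{\link{feature_set}}.
#' @export
generate_null_positions <- function(n, genome_length = 4641652,
                                    circular = TRUE, seed = NULL) {
  stopifnot(n >= 2)
  with_seed(seed, {
    pos <- resolve_collisions(floor(runif(n, 0, genome_length)) + 1,
                              genome_length)
    feature_set(sprintf("F%04d", seq_len(n)), pos,
                genome_length = genome_length, circular = circular)
  })
}

sample_background_seq <- function(n, len, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = p),
          collapse = "")
  }, character(1))
}

sample_motif_instance <- function(motif, degrade = 0) {
  bases <- c("A", "C", "G", "T")
  draw <- vapply(seq_len(motif$width), function(j) {
    sample(bases, 1, prob = motif$probs[, j])
  }, character(1))
  if (degrade > 0) {
    mut <- runif(motif$width) < degrade
    draw[mut] <- sample(bases, sum(mut), replace = TRUE)
  }
  paste(draw, collapse = "")
}

#' Generate a labelled synthetic regulon
#'
#' Builds the inputs of the target-prediction half with known ground truth:
#' target genes sit on a planted positional lattice and carry a binding-site
#' motif in their regulatory sequence; non-targets have uniform positions
#' and background sequences.
#'
#' With \code{coupling = "independent"} every target is implanted with
#' probability \code{implant_prob} and jittered around the lattice with
#' \code{jitter_sd}.  With \code{coupling = "negative"} each target gets a
#' lattice fidelity of 0 or 1 (balanced): fidelity-1 targets sit tightly on
#' the lattice and carry no binding site, while fidelity-0 targets are
#' implanted (with probability \code{implant_prob}) at uniform positions —
#' the implant probability decreases with lattice fidelity, the
#' anti-correlated regime in which sequence and position information trade
#' off.
#'
#' @param n_targets,n_nontargets class sizes.
#' @param motif a \code{\link{motif_matrix}}; default a strong 16-bp
#'   palindromic consensus.
#' @param implant_prob probability a target receives a motif instance
#'   (independent coupling), in [0, 1].
#' @param seq_length regulatory-sequence length in bp (>= motif width).
#' @param genome_length,period,jitter_sd positional lattice parameters (see
#'   \code{\link{generate_periodic_positions}}).
#' @param coupling \code{"independent"} or \code{"negative"}.
#' @param gc background GC content of the sequences.
#' @param seed optional seed.
#' @return list with \code{genes} (data frame: \code{name},
#'   \code{position}, \code{sequence}, \code{label} in +1/-1,
#'   \code{fidelity}), \code{fs} (feature set over all genes) and
#'   \code{motif}.
#' @export
generate_regulon_dataset <- function(n_targets = 40, n_nontargets = 80,
                                     motif = NULL, implant_prob = 0.9,
                                     seq_length = 200,
                                     genome_length = 4641652,
                                     period = 93000, jitter_sd = 2000,
                                     coupling = c("independent",
                                                  "negative"),
                                     gc = 0.5, seed = NULL) {
  coupling <- match.arg(coupling)
  motif <- motif %||% motif_from_consensus("TGTGATCTAGATCACA",
                                           strength = 0.9)
  stopifnot(implant_prob >= 0, implant_prob <= 1,
            motif$width <= seq_length, n_targets >= 1, n_nontargets >= 1)
  with_seed(seed, {
    offset <- runif(1, 0, period)
    if (coupling == "independent") {
      fidelity <- rep(1, n_targets)
      jit <- rnorm(n_targets, 0, jitter_sd)
      implant <- runif(n_targets) < implant_prob
      degrade <- rep(0, n_targets)
    } else {
      # the anti-correlated limit: lattice-faithful targets carry no site,
      # motif-carrying targets sit anywhere (implant probability decreases
      # with lattice fidelity)
      fidelity <- sample(rep(c(0, 1), length.out = n_targets))
      jit <- rnorm(n_targets, 0, jitter_sd + (1 - fidelity) * period)
      implant <- runif(n_targets) < implant_prob * (1 - fidelity)
      degrade <- rep(0, n_targets)
    }
    k <- sample.int(max(n_targets, floor(genome_length / period)),
                    n_targets)
    t_pos <- floor((offset + (k - 1) * period + jit) %% genome_length) + 1
    nt_pos <- floor(runif(n_nontargets, 0, genome_length)) + 1
    pos <- resolve_collisions(c(t_pos, nt_pos), genome_length)

    seqs <- sample_background_seq(n_targets + n_nontargets, seq_length,
                                  gc = gc)
    for (i in seq_len(n_targets)) {
      if (!implant[i]) next
      inst <- sample_motif_instance(motif, degrade = degrade[i])
      at <- sample.int(seq_length - motif$width + 1, 1)
      substr(seqs[i], at, at + motif$width - 1) <- inst
    }
    name <- c(sprintf("T%03d", seq_len(n_targets)),
              sprintf("N%03d", seq_len(n_nontargets)))
    genes <- data.frame(
      name = name, position = pos, sequence = seqs,
      label = c(rep(1, n_targets), rep(-1, n_nontargets)),
      fidelity = c(fidelity, rep(NA_real_, n_nontargets)),
      stringsAsFactors = FALSE)
    fs <- feature_set(genes$name, genes$position,
                      genome_length = genome_length, circular = TRUE)
    list(genes = genes, fs = fs, motif = motif)
  })
}

#' Write gene regulatory sequences as FASTA
#'
#' @param genes data frame with \code{name} and \code{sequence} columns.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_regulon_fasta <- function(genes, path) {
  x <- Biostrings::DNAStringSet(genes$sequence)
  names(x) <- genes$name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
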