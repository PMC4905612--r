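# shared fixtures and independent oracles

ECOLI_G <- 4641652

make_fs <- function(positions, G = 10000, circular = TRUE,
                    names = sprintf("f%03d", seq_along(positions))) {
  feature_set(names, positions, genome_length = G, circular = circular)
}

# brute-force complex-sum oracle for the concentration score
score_oracle <- function(phases, period) {
  z <- sum(exp(2i * pi * phases / period))
  Mod(z)^2 / length(phases)
}

jaccard_interval <- function(a, b) {
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
  inter / (max(a[2], b[2]) - min(a[1], b[1]))
}

# two tight phase clusters (0.2P, 0.7P) plus uniform noise, embedded at
# random multiples of the period along the genome
make_two_cluster_fs <- function(seed, P = 93000, G = ECOLI_G,
                                sd_phase = 1500, n_noise = 5) {
  set.seed(seed)
  phases <- c(rnorm(10, 0.2 * P, sd_phase) %% P,
              rnorm(10, 0.7 * P, sd_phase) %% P,
              runif(n_noise, 0, P))
  pos <- floor(phases + P * sample(0:40, 20 + n_noise, TRUE)) %% G + 1
  truth <- c(rep(1, 10), rep(2, 10), rep(0, n_noise))
  list(fs = make_fs(pos, G = G), truth = truth,
       names = sprintf("f%03d", seq_along(pos)))
}

auc_of <- function(score, labels) {
  as.numeric(suppressMessages(pROC::auc(labels, score, quiet = TRUE,
                                        direction = "<")))
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
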