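test_that("feature_set validates and sorts its features", {
  fs <- make_fs(c(120, 40, 700), G = 1000)
  expect_s3_class(fs, "feature_set")
  expect_equal(fs$features$position, c(40, 120, 700))
  expect_equal(n_features(fs), 3L)

  expect_error(feature_set(c("a", "a"), c(1, 2), genome_length = 10),
               "duplicate")
  expect_error(feature_set("a", 5000, genome_length = 4000), "outside")
  expect_error(feature_set("", 10, genome_length = 100), "non-empty")
  expect_error(feature_set("a", 10, genome_length = -5), "positive")
})

test_that("TSV reader takes positions verbatim and flags bad input", {
  path <- write_lines_tmp(c("# comment", "name\tposition",
                            "geneB\t300", "geneA\t100"))
  fs <- read_feature_table(path, "tsv", genome_length = 1000)
  expect_equal(fs$features$name, c("geneA", "geneB"))
  expect_equal(fs$features$position, c(100, 300))

  bad <- write_lines_tmp(c("geneA\t100", "geneB"))
  expect_error(read_feature_table(bad, "tsv", genome_length = 1000),
               "line 2")
  bad2 <- write_lines_tmp(c("geneA\t100", "geneB\tzzz"))
  expect_error(read_feature_table(bad2, "tsv", genome_length = 1000),
               "not numeric")
  over <- write_lines_tmp("geneC\t5000")
  expect_error(read_feature_table(over, "tsv", genome_length = 4000),
               "outside")
})

test_that("BED intervals reduce to strand-aware 5' ends, 1-based", {
  path <- write_lines_tmp(c("chr\t99\t200\tgeneA\t0\t+",
                            "chr\t99\t200\tgeneB\t0\t-"), ext = ".bed")
  fs <- read_feature_table(path, "bed", genome_length = 1000)
  expect_equal(fs$features$position[fs$features$name == "geneA"], 100)
  expect_equal(fs$features$position[fs$features$name == "geneB"], 200)
})

test_that("GFF3 records use Name/ID and strand-aware 5' ends", {
  gff <- c("##gff-version 3",
           "chr\tsrc\tgene\t100\t220\t.\t+\t.\tID=g1;Name=alpha",
           "chr\tsrc\tgene\t300\t420\t.\t-\t.\tID=beta")
  path <- write_lines_tmp(gff, ext = ".gff3")
  fs <- read_feature_table(path, "gff3", genome_length = 1000)
  expect_setequal(fs$features$name, c("alpha", "beta"))
  expect_equal(fs$features$position[fs$features$name == "alpha"], 100)
  expect_equal(fs$features$position[fs$features$name == "beta"], 420)
})

test_that("feature tables round-trip through TSV exactly", {
  sim <- generate_periodic_positions(n_lattice = 15, n_background = 10,
                                     seed = 3)
  path <- tempfile(fileext = ".tsv")
  write_feature_table(sim$fs, path)
  back <- read_feature_table(path, "tsv", genome_length = ECOLI_G)
  expect_identical(back$features$name, sim$fs$features$name)
  expect_identical(back$features$position, sim$fs$features$position)
})

test_that("proximity filter keeps the first of each close pair", {
  fs <- make_fs(c(100, 150, 5000), circular = FALSE)
  expect_equal(remove_proximal(fs, 200)$features$position, c(100, 5000))
  # threshold 0 leaves everything
  expect_equal(remove_proximal(fs, 0)$features$position, c(100, 150, 5000))
  # circular wrap: later-coordinate feature of the wrapping pair is dropped
  wrap <- make_fs(c(50, 9950), G = 10000, circular = TRUE)
  expect_equal(remove_proximal(wrap, 200)$features$position, 50)
  expect_error(remove_proximal(fs, -1), "non-negative")
})

test_that("proximity filter is idempotent and returns an ordered subset", {
  for (s in 1:20) {
    fs <- generate_null_positions(40, genome_length = 100000, seed = s)
    out1 <- remove_proximal(fs, 1500)
    out2 <- remove_proximal(out1, 1500)
    expect_identical(out1$features, out2$features)
    expect_true(all(out1$features$name %in% fs$features$name))
    expect_false(is.unsorted(out1$features$position))
    if (n_features(out1) > 1) {
      expect_true(all(diff(out1$features$position) >= 1500))
    }
  }
})

test_that("motif builders produce consistent log-odds", {
  sites <- write_lines_tmp(rep(c(">s", "ACGT"), 4), ext = ".fa")
  m <- read_motif(sites, "aligned_fasta", pseudocount = 0)
  expect_equal(m$width, 4)
  # one strictly positive entry per column (the consensus base)
  expect_true(all(apply(m$log_odds, 2, function(col)
    sum(col > 0) == 1)))
  expect_equal(m$consensus, "ACGT")

  # flat counts against a uniform background carry no information
  flat <- write_lines_tmp(c("A [ 2 2 ]", "C [ 2 2 ]",
                            "G [ 2 2 ]", "T [ 2 2 ]"), ext = ".pfm")
  expect_warning(m0 <- read_motif(flat, "jaspar_pfm"), "zero-information")
  expect_equal(unname(m0$log_odds), matrix(0, 4, 2))

  ragged <- write_lines_tmp(c(">a", "ACGT", ">b", "ACG"), ext = ".fa")
  expect_error(read_motif(ragged, "aligned_fasta"), "ragged")
})

test_that("motif variants trim the least informative flanks", {
  m <- motif_from_consensus("NTGTGATCTAGATCACAN", strength = 0.9)
  v <- motif_variants(m, n_trim = 2)
  expect_named(v, c("full", "trim1", "trim2"))
  expect_equal(v$trim1$width, m$width - 1)
  expect_equal(v$trim2$width, m$width - 2)
  # the uninformative (uniform) flank columns are dropped first
  expect_true(all(periscan:::column_information(v$trim2$probs) > 0.1))
})
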