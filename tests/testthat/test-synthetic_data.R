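test_that("genome simulation is deterministic and motifs occur at background rate", {
  g1 <- simulate_genome(c(s = 30000L), seed = 5)
  g2 <- simulate_genome(c(s = 30000L), seed = 5)
  expect_identical(g1$genome, g2$genome)
  expect_identical(as.data.frame(g1$expected_map),
                   as.data.frame(g2$expected_map))

  # HindIII six-mer: expected sites = (L - 5) / 4^6 per chromosome
  L <- 100000L
  counts <- vapply(1:20, function(s) {
    g <- simulate_genome(c(x = L), seed = 400 + s)
    nrow(g$expected_map) - 1
  }, numeric(1))
  expected <- (L - 5) / 4^6
  se <- sqrt(expected / 20)           # Poisson-ish sd of the mean
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("package digestion reproduces the generator's naive-scan map", {
  g <- simulate_genome(c(a = 40000L, b = 25000L), seed = 9)
  m <- digest_genome(g$genome, enzyme_registry("HindIII"))
  m <- flag_blind_fragments(m, g$genome, enzyme_registry("Csp6I"))
  expect_equal(as.data.frame(m)[c("chrom", "start", "end", "blind")],
               as.data.frame(g$expected_map)[c("chrom", "start", "end",
                                               "blind")])
})

test_that("simulated mean RPKM decays monotonically with distance", {
  cfg <- sim_config(planted_cis = NULL, planted_trans = NULL,
                    diets = "CD", timepoints = "ZT6", n_replicates = 1L)
  acc <- NULL
  for (s in 1:20) {
    map <- simulate_map(cfg, seed = 500 + s)
    sim <- simulate_counts(map, cfg, seed = 500 + s)
    sc <- sim$samples[[1]]
    bid <- bait_fragment(map)
    cis <- sc[sc$chrom == cfg$cis_chrom & !sc$excluded, ]
    brow <- match(bid, sc$fragment_id)
    d <- abs((cis$start + cis$end) / 2 - (sc$start[brow] + sc$end[brow]) / 2)
    acc <- rbind(acc, data.frame(d = d, rpkm = cis$rpkm))
  }
  bins <- cut(log10(acc$d), 10)
  mean_by_bin <- tapply(acc$rpkm, bins, mean)
  expect_true(all(diff(mean_by_bin) < 0))
})

test_that("a planted fold multiplies the expected count by the fold", {
  pc <- data.frame(offset = 25L, fold = 4, conditions = "all")
  cfg <- sim_config(n_cis_fragments = 100L, cis_length = 5e5,
                    n_trans_fragments = 30L, trans_length = 1e5,
                    planted_cis = pc, planted_trans = NULL,
                    diets = "CD", timepoints = "ZT6", n_replicates = 1L)
  cfg0 <- cfg; cfg0$planted_cis <- NULL
  map <- simulate_map(cfg, seed = 1)
  target <- bait_fragment(map) + 25L
  draws <- vapply(1:200, function(s)
    simulate_counts(map, cfg, seed = 600 + s)$samples[[1]]$raw[
      match(target, map$fragment_id)], numeric(1))
  draws0 <- vapply(1:200, function(s)
    simulate_counts(map, cfg0, seed = 600 + s)$samples[[1]]$raw[
      match(target, map$fragment_id)], numeric(1))
  ratio <- mean(draws) / mean(draws0)
  se <- ratio * sqrt(var(draws) / mean(draws)^2 +
                     var(draws0) / mean(draws0)^2) / sqrt(200)
  expect_lt(abs(ratio - 4), 3 * se)
})

test_that("zero dispersion gives Poisson-like variance", {
  cfg <- sim_config(n_cis_fragments = 60L, cis_length = 3e5,
                    n_trans_fragments = 30L, trans_length = 1e5,
                    dispersion = 0, planted_cis = NULL, planted_trans = NULL,
                    diets = "CD", timepoints = "ZT6", n_replicates = 1L)
  map <- simulate_map(cfg, seed = 3)
  target <- bait_fragment(map) + 10L
  draws <- vapply(1:300, function(s)
    simulate_counts(map, cfg, seed = 700 + s)$samples[[1]]$raw[
      match(target, map$fragment_id)], numeric(1))
  expect_lt(abs(var(draws) / mean(draws) - 1), 0.35)
})

test_that("blind fragments receive zero counts", {
  cfg <- sim_config(n_cis_fragments = 80L, cis_length = 4e5,
                    n_trans_fragments = 30L, trans_length = 1e5,
                    planted_cis = NULL, planted_trans = NULL,
                    diets = "CD", timepoints = "ZT6")
  map <- simulate_map(cfg, seed = 4)
  map$blind[c(10, 40)] <- TRUE
  sim <- simulate_counts(map, cfg, seed = 4)
  for (s in sim$samples) expect_equal(s$raw[c(10, 40)], c(0L, 0L))
})

test_that("condition masks confine planted effects to active conditions", {
  pc <- data.frame(offset = c(30L, -30L), fold = 8,
                   conditions = c("all", "HF_ZT18"))
  cfg <- sim_config(planted_cis = pc)
  map <- simulate_map(cfg, seed = 8)
  sim <- simulate_counts(map, cfg, seed = 8)
  bait <- bait_config(cfg$bait_name, cfg$cis_chrom, cfg$bait_position)
  cc_cd <- call_cis(sim$samples[c("CD_ZT6_rep1", "CD_ZT6_rep2")], map, bait)
  cc_hf <- call_cis(sim$samples[c("HF_ZT18_rep1", "HF_ZT18_rep2")], map, bait)
  bid <- bait_fragment(map)
  sig_cd <- cc_cd$fragments$fragment_id[cc_cd$fragments$significant]
  sig_hf <- cc_hf$fragments$fragment_id[cc_hf$fragments$significant]
  expect_true((bid + 30L) %in% sig_cd)
  expect_true(all(c(bid + 30L, bid - 30L) %in% sig_hf))
  expect_false((bid - 30L) %in% sig_cd)
})

test_that("fixture bundles are reproducible and carry machine-readable truth", {
  cfg <- sim_config(n_cis_fragments = 300L, cis_length = 1e6,
                    n_trans_fragments = 100L, trans_length = 3e5,
                    planted_cis = data.frame(offset = c(-60L, 20L, 40L),
                                             fold = 4, conditions = "all"),
                    planted_trans = data.frame(start_fragment = 21L,
                                               n_fragments = 40L, fold = 8,
                                               conditions = "all"))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fixture_bundle(cfg, d1, seed = 11)
  write_fixture_bundle(cfg, d2, seed = 11)
  files <- sort(list.files(d1, recursive = TRUE))
  expect_identical(files, sort(list.files(d2, recursive = TRUE)))
  expect_true(all(tools::md5sum(file.path(d1, files)) ==
                  tools::md5sum(file.path(d2, files))))

  truth <- utils::read.table(file.path(d1, "truth.tsv"), header = TRUE,
                             sep = "\t")
  expect_equal(sum(truth$type == "cis"), nrow(cfg$planted_cis))
  expect_equal(sum(truth$type == "trans"), nrow(cfg$planted_trans))

  fx <- read_fixture_bundle(d1)
  expect_equal(nrow(fx$map), 400)
  expect_length(fx$samples, 8)
  expect_equal(fx$manifest$seed, 11)
  expect_false(is.na(bait_fragment(fx$map)))
})

test_that("caller sensitivity is non-decreasing in the planted fold", {
  sens_at_fold <- function(fold, seeds = 1:3) {
    pc <- default_planted_cis(); pc$fold <- fold
    cfg <- sim_config(planted_cis = pc, diets = "CD", timepoints = "ZT6")
    mean(vapply(seeds, function(s) {
      x <- sim_one_condition(cfg, seed = s)
      cc <- call_cis(x$reps, x$map, x$bait)
      tid <- x$sim$truth$fragment_id[x$sim$truth$type == "cis"]
      mean(tid %in% cc$fragments$fragment_id[cc$fragments$significant])
    }, numeric(1)))
  }
  s <- vapply(c(1.5, 2, 4, 8), sens_at_fold, numeric(1))
  expect_true(all(diff(s) >= 0))
  expect_gte(s[3], 0.8)
})
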