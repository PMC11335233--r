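test_that("the variance-stabilizing transform is log2(x + 1)", {
  expect_equal(transform_counts(c(0, 3, 7)), c(0, 2, 3))
  expect_error(transform_counts(-1), "negative")
  expect_equal(transform_counts(4, method = "sqrt"), 2)
})

test_that("feasible monotone input is fitted exactly; violations pool", {
  d <- c(10, 100, 1000, 10000)
  f <- fit_decay(c(5, 4, 4, 3), d, min_fragments = 4)
  expect_equal(f$fitted, c(5, 4, 4, 3))
  expect_equal(f$residuals, rep(0, 4))

  f2 <- fit_decay(c(3, 5), c(10, 100), min_fragments = 2)
  expect_equal(f2$fitted, c(4, 4))
  expect_error(fit_decay(1:5, c(1, 2, 3, 4, 5)), "at least")
  expect_error(fit_decay(c(1, 2), c(0, 5), min_fragments = 2), "> 0")
})

test_that("the isotonic fit matches a PAVA reference on random instances", {
  set.seed(21)
  for (i in 1:100) {
    n <- sample(10:12, 1)
    d <- sort(10^runif(n, 1, 6))
    v <- rnorm(n, 5 - log10(d) / 2, 0.5)
    f <- fit_decay(v, d, min_fragments = 10)
    expect_equal(f$fitted, pava_nonincreasing(v), tolerance = 1e-10)
    expect_equal(f$sigma,
                 max(1.4826 * median(abs(v - pava_nonincreasing(v))), 1e-6))
  }
})

test_that("the fit recovers a known decay law from noisy data", {
  set.seed(33)
  d <- sort(10^runif(500, 3, 6.3))
  truth <- 6 - log10(d) / 2
  v <- truth + rnorm(500, 0, 0.3)
  f <- fit_decay(v, d)
  expect_lt(mean(abs(f$fitted - truth)), 0.15)
  # prediction interpolates between knots and is monotone non-increasing
  grid <- 10^seq(3.1, 6.2, length.out = 50)
  pred <- predict(f, grid)
  expect_true(all(diff(pred) <= 1e-12))
})

test_that("z-scores and one-sided p-values follow the residual model", {
  f <- fit_decay(rep(5, 10), sort(10^runif(10, 2, 5)), min_fragments = 10)
  f$sigma <- 1.5
  zp <- compute_z(8, f, distances = 1e3)
  expect_equal(zp$z, 2)
  zp0 <- compute_z(5, f, distances = 1e4)
  expect_equal(zp0$z, 0)
  expect_equal(zp0$p, 0.5)
  # z = 1.6449 -> p ~= 0.05 (normal upper tail by numerical integration)
  f$sigma <- 1
  z <- 1.6449
  p_num <- integrate(dnorm, lower = z, upper = Inf)$value
  expect_equal(compute_z(5 + z, f, distances = 1e3)$p, p_num,
               tolerance = 1e-6)
  expect_equal(p_num, 0.05, tolerance = 1e-3)
  f$sigma <- 0
  expect_error(compute_z(5, f, distances = 1e3), "sigma")
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_equal(bh_fdr(rep(1, 4)), rep(1, 4))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(4)
  for (i in 1:50) {
    p <- runif(sample(1:8, 1))
    expect_equal(bh_fdr(p), bh_stepup(p))
  }
})

test_that("significance requires z and FDR thresholds in every replicate", {
  cfg <- sim_config()
  x <- sim_one_condition(cfg, seed = 6)
  cc <- call_cis(x$reps, x$map, x$bait)
  fr <- cc$fragments
  pass1 <- fr$z_rep1 >= 2 & fr$fdr_rep1 <= 0.05
  pass2 <- fr$z_rep2 >= 2 & fr$fdr_rep2 <= 0.05
  expect_identical(fr$significant, pass1 & pass2)
  # fragments passing in exactly one replicate are never significant
  expect_true(any(xor(pass1, pass2)))
  expect_false(any(fr$significant[xor(pass1, pass2)]))
  # all fragments lie within the window and the universe excludes the bait
  expect_true(all(abs(fr$distance) <= cc$window_bp))
  expect_false(bait_fragment(x$map) %in% fr$fragment_id)
})

test_that("the relaxed z threshold used for weak baits admits more calls", {
  cfg <- sim_config()
  x <- sim_one_condition(cfg, seed = 13)
  strict <- call_cis(x$reps, x$map, x$bait, z_threshold = 2.0)
  relaxed <- call_cis(x$reps, x$map, x$bait, z_threshold = 1.5)
  expect_true(all(strict$fragments$fragment_id[strict$fragments$significant]
                  %in% relaxed$fragments$fragment_id[relaxed$fragments$significant]))
  expect_gte(sum(relaxed$fragments$significant),
             sum(strict$fragments$significant))
})

test_that("raising thresholds never increases calls (monotonicity)", {
  cfg <- sim_config()
  x <- sim_one_condition(cfg, seed = 17)
  n_sig <- function(z, fdr) {
    cc <- call_cis(x$reps, x$map, x$bait, z_threshold = z,
                   fdr_threshold = fdr)
    c(sum(cc$fragments$significant), nrow(cc$intervals))
  }
  base <- n_sig(2, 0.05)
  expect_true(all(n_sig(3, 0.05) <= base))
  expect_true(all(n_sig(2, 0.01) <= base))
})

test_that("merged intervals are disjoint and cover the significant fragments", {
  cfg <- sim_config()
  x <- sim_one_condition(cfg, seed = 19)
  cc <- call_cis(x$reps, x$map, x$bait)
  iv <- cc$intervals
  expect_gt(nrow(iv), 0)
  if (nrow(iv) > 1) {
    o <- order(iv$start)
    expect_true(all(iv$start[o][-1] >= iv$end[o][-nrow(iv)]))
  }
  sig_ids <- cc$fragments$fragment_id[cc$fragments$significant]
  rows <- match(sig_ids, x$map$fragment_id)
  covered <- vapply(rows, function(r)
    any(x$map$start[r] >= iv$start - 1e-9 & x$map$end[r] <= iv$end + 1e-9),
    logical(1))
  expect_true(all(covered))
  expect_equal(sum(iv$n_fragments), length(sig_ids))
})

test_that("replicate universes must agree", {
  cfg <- sim_config()
  x <- sim_one_condition(cfg, seed = 23)
  broken <- x$reps
  drop_id <- bait_fragment(x$map) + 50L   # inside the analysis window
  broken[[2]] <- broken[[2]][broken[[2]]$fragment_id != drop_id, ]
  expect_error(call_cis(broken, x$map, x$bait), "universes differ")
})
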