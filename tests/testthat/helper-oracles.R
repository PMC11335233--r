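# Independent reference implementations used as oracles. These are written
# against the definitions, not against the package internals.

# every cut position of `motif` in `seq` by checking each start offset with
# substring comparison (0-based cuts)
oracle_cuts <- function(seq, motif, cut_offset) {
  n <- nchar(seq); L <- nchar(motif)
  if (n < L) return(numeric(0))
  starts <- which(vapply(seq_len(n - L + 1L), function(i)
    substring(seq, i, i + L - 1L) == motif, logical(1L)))
  (starts - 1) + cut_offset
}

# fragments implied by a cut set on [0, len)
oracle_fragments <- function(cuts, len) {
  bounds <- sort(unique(c(0, cuts[cuts > 0 & cuts < len], len)))
  data.frame(start = bounds[-length(bounds)], end = bounds[-1L])
}

# pool-adjacent-violators for a NON-INCREASING fit of y (in ascending-x
# order), explicit block merging
pava_nonincreasing <- function(y, w = rep(1, length(y))) {
  blocks <- lapply(seq_along(y), function(i)
    list(sum = y[i] * w[i], w = w[i], n = 1L))
  i <- 1L
  while (i < length(blocks)) {
    a <- blocks[[i]]; b <- blocks[[i + 1L]]
    if (a$sum / a$w < b$sum / b$w) {   # violation of non-increasing
      blocks[[i]] <- list(sum = a$sum + b$sum, w = a$w + b$w, n = a$n + b$n)
      blocks[[i + 1L]] <- NULL
      if (i > 1L) i <- i - 1L
    } else i <- i + 1L
  }
  unlist(lapply(blocks, function(b) rep(b$sum / b$w, b$n)))
}

# Benjamini-Hochberg step-up from the definition:
# adj_(i) = min_{j >= i} min(1, p_(j) * m / j), in the original order
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- pmin(1, ps * m / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# exact Viterbi by plain dynamic programming with explicit state loops
viterbi_dp <- function(x, means, sds, trans, init) {
  n <- length(x); S <- length(means)
  logd <- function(t, s) dnorm(x[t], means[s], sds[s], log = TRUE)
  V <- matrix(-Inf, n, S); back <- matrix(0L, n, S)
  for (s in 1:S) V[1, s] <- log(init[s]) + logd(1, s)
  for (t in 2:n) for (s in 1:S) {
    best <- -Inf; arg <- 1L
    for (r in 1:S) {
      v <- V[t - 1, r] + log(trans[r, s])
      if (v > best) { best <- v; arg <- r }
    }
    V[t, s] <- best + logd(t, s); back[t, s] <- arg
  }
  path <- integer(n)
  path[n] <- which.max(V[n, ])
  for (t in (n - 1):1) path[t] <- back[t + 1, path[t + 1]]
  path
}

# build a minimal interaction_call object for rule-level tests
fake_call <- function(fragment_id, mean_z, significant,
                      intervals = NULL, bait = "bait", diet = "CD",
                      timepoint = "ZT6") {
  frag <- data.frame(fragment_id = fragment_id, distance = fragment_id * 1000,
                     mean_z = mean_z, significant = significant)
  if (is.null(intervals))
    intervals <- data.frame(chrom = character(0), start = numeric(0),
                            end = numeric(0), n_fragments = integer(0),
                            mean_z = numeric(0))
  structure(list(bait_name = bait, chrom = "chrT", diet = diet,
                 timepoint = timepoint, n_replicates = 2L,
                 z_threshold = 2, fdr_threshold = 0.05, window_bp = 2e6,
                 merge_gap_fragments = 1L, fragments = frag,
                 intervals = intervals),
            class = "interaction_call")
}

# brute-force reimplementation of the diet-differential rule
differential_ref <- function(mean_z_hf, mean_z_cd, sig_hf, sig_cd,
                             ratio_threshold = 1.5, eps = 0.1) {
  n <- length(mean_z_hf)
  dir <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    r_hf <- max(mean_z_hf[i], eps) / max(mean_z_cd[i], eps)
    r_cd <- max(mean_z_cd[i], eps) / max(mean_z_hf[i], eps)
    if (r_hf >= ratio_threshold && sig_hf[i]) dir[i] <- "HF_gain"
    else if (r_cd >= ratio_threshold && sig_cd[i]) dir[i] <- "CD_gain"
  }
  dir
}

# random DNA string
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# shared small simulation: two replicates of one condition
sim_one_condition <- function(cfg, seed) {
  map <- simulate_map(cfg, seed = seed)
  sim <- simulate_counts(map, cfg, seed = seed)
  bait <- bait_config(cfg$bait_name, cfg$cis_chrom, cfg$bait_position)
  reps <- sim$samples[grep("CD_ZT6_rep", names(sim$samples))]
  list(map = map, sim = sim, bait = bait, reps = reps)
}
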