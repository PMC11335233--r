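#' Smooth trans-chromosome counts into fixed fragment windows
#'
#' Trans contacts are sparse at single-fragment resolution; signal is
#' summed over consecutive blocks of \code{k} non-excluded, non-blind
#' fragments (the last window may span fewer) before segmentation. The
#' window log-signal is \code{log2(summed RPKM + 1)}.
#'
#' @param counts A \code{sample_counts} (RPKM-normalized).
#' @param chrom The trans chromosome to window.
#' @param k Fragments per window (default 20, the smoothing used for
#'   trans-contact analysis).
#' @return A \code{window_track}: data frame with \code{start}, \code{end},
#'   \code{summed_rpkm}, \code{log_signal}; attributes \code{chrom},
#'   \code{k} and the member fragment ids per window.
#' @export
make_windows <- function(counts, chrom, k = 20L) {
  stopifnot(inherits(counts, "sample_counts"))
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  blind <- attr(counts, "blind")
  keep <- counts$chrom == chrom & !counts$excluded & !(blind %in% TRUE)
  sub <- counts[keep, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no usable fragments on ", chrom)
  if (all(is.na(sub$rpkm))) stop("counts not RPKM-normalized")
  sub <- sub[order(sub$start), , drop = FALSE]
  if (nrow(sub) < k)
    warning("fewer than k = ", k, " fragments on ", chrom,
            "; a single window covers them all")
  grp <- (seq_len(nrow(sub)) - 1L) %/% k + 1L
  agg <- function(f, v) as.numeric(tapply(v, grp, f))
  track <- data.frame(start = agg(min, sub$start), end = agg(max, sub$end),
                      summed_rpkm = agg(sum, sub$rpkm))
  track$log_signal <- log2(track$summed_rpkm + 1)
  structure(track, chrom = chrom, k = k,
            members = split(sub$fragment_id, grp),
            class = c("window_track", "data.frame"))
}

#' Viterbi path of a univariate Gaussian hidden Markov model
#'
#' Exact maximum-probability state path by dynamic programming in log
#' space. Exposed so segmentations can be recomputed or checked with
#' explicit parameters.
#'
#' @param x Observations.
#' @param means,sds State emission means and standard deviations.
#' @param trans Transition probability matrix (rows sum to 1).
#' @param init Initial state probabilities.
#' @return Integer state path (1-based).
#' @export
viterbi_path <- function(x, means, sds, trans, init) {
  n <- length(x); S <- length(means)
  stopifnot(length(sds) == S, nrow(trans) == S, ncol(trans) == S,
            length(init) == S)
  emis <- vapply(seq_len(S), function(s)
    stats::dnorm(x, means[s], sds[s], log = TRUE), numeric(n))
  lt <- log(trans); li <- log(init)
  delta <- matrix(-Inf, n, S); psi <- matrix(0L, n, S)
  delta[1L, ] <- li + emis[1L, ]
  for (t in 2L:n) {
    for (s in seq_len(S)) {
      cand <- delta[t - 1L, ] + lt[, s]
      psi[t, s] <- which.max(cand)
      delta[t, s] <- cand[psi[t, s]] + emis[t, s]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  for (t in (n - 1L):1L) path[t] <- psi[t + 1L, path[t + 1L]]
  path
}

# one EM run from a given initialization; scaled forward-backward
.ghmm_em <- function(x, means, sds, trans, init, max_iter = 200L,
                     tol = 1e-6, sd_floor) {
  n <- length(x); S <- length(means)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    emis <- vapply(seq_len(S), function(s)
      stats::dnorm(x, means[s], sds[s]), numeric(n))
    emis[emis < 1e-300] <- 1e-300
    alpha <- matrix(0, n, S); beta <- matrix(0, n, S); cscale <- numeric(n)
    a <- init * emis[1L, ]; cscale[1L] <- sum(a); alpha[1L, ] <- a / cscale[1L]
    for (t in 2L:n) {
      a <- (alpha[t - 1L, ] %*% trans) * emis[t, ]
      cscale[t] <- sum(a); alpha[t, ] <- a / cscale[t]
    }
    beta[n, ] <- 1
    for (t in (n - 1L):1L)
      beta[t, ] <- (trans %*% (emis[t + 1L, ] * beta[t + 1L, ])) / cscale[t + 1L]
    ll <- sum(log(cscale))
    gamma <- alpha * beta
    gamma <- gamma / rowSums(gamma)
    # under the scaled recursions each per-step xi already sums to one
    eb <- emis[-1L, , drop = FALSE] * beta[-1L, , drop = FALSE] / cscale[-1L]
    xi_num <- trans * crossprod(alpha[-n, , drop = FALSE], eb)
    init <- gamma[1L, ]
    trans <- xi_num / pmax(rowSums(xi_num), 1e-300)
    trans[trans < 1e-8] <- 1e-8
    trans <- trans / rowSums(trans)
    w <- colSums(gamma)
    means <- colSums(gamma * x) / pmax(w, 1e-300)
    sds <- sqrt(colSums(gamma * (outer(x, means, "-")^2)) / pmax(w, 1e-300))
    sds <- pmax(sds, sd_floor)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1))
      return(list(means = means, sds = sds, trans = trans, init = init,
                  loglik = ll, converged = TRUE, iterations = iter))
    ll_old <- ll
  }
  list(means = means, sds = sds, trans = trans, init = init,
       loglik = ll_old, converged = FALSE, iterations = max_iter)
}

#' Segment a window track with a Gaussian-emission HMM
#'
#' Fits an \code{n_states}-state hidden Markov model with Gaussian
#' emissions to the window log-signal by EM (several seeded restarts; the
#' maximum-likelihood fit is kept, ties broken by the earliest restart),
#' relabels states by ascending emission mean, and returns the Viterbi
#' path. The top state is the "high" (interaction-domain) state. A
#' degenerate constant track yields a single lowest state for every
#' window. Deterministic given \code{seed}.
#'
#' @param track A \code{window_track} (or numeric log-signal vector).
#' @param n_states Number of emission states (default 3: no / low / high
#'   signal).
#' @param seed Master seed for the EM restarts.
#' @param n_restarts Seeded restarts (default 10).
#' @param min_windows Minimum track length.
#' @return An object of class \code{"hmm_segmentation"}: list with
#'   \code{states} (Viterbi path, 1 = lowest mean), \code{means},
#'   \code{sds}, \code{trans}, \code{init}, \code{loglik},
#'   \code{high_state}.
#' @export
segment_hmm <- function(track, n_states = 3L, seed = 1L, n_restarts = 10L,
                        min_windows = 10L) {
  x <- if (inherits(track, "window_track")) track$log_signal else as.numeric(track)
  n <- length(x)
  if (n < min_windows) stop("need at least ", min_windows, " windows")
  n_states <- as.integer(n_states)
  if (stats::sd(x) < 1e-10) {
    return(structure(list(states = rep(1L, n), means = mean(x),
                          sds = 0, trans = NULL, init = NULL,
                          loglik = NA_real_, high_state = NA_integer_,
                          n_states = n_states),
                     class = "hmm_segmentation"))
  }
  sd_floor <- max(stats::sd(x) * 1e-3, 1e-8)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    q <- stats::quantile(x, probs = (seq_len(n_states) - 0.5) / n_states,
                         names = FALSE)
    means0 <- q + stats::rnorm(n_states) * stats::sd(x) * 0.25
    sds0 <- rep(stats::sd(x), n_states)
    trans0 <- matrix(0.1 / (n_states - 1L), n_states, n_states)
    diag(trans0) <- 0.9
    init0 <- rep(1 / n_states, n_states)
    fit <- .ghmm_em(x, means0, sds0, trans0, init0, sd_floor = sd_floor)
    if (is.null(best) || fit$loglik > best$loglik + 1e-9) best <- fit
  }
  if (is.null(best) || !is.finite(best$loglik))
    stop("HMM estimation failed to produce a finite likelihood")
  ord <- order(best$means)
  relabel <- match(seq_len(n_states), ord)
  means <- best$means[ord]; sds <- best$sds[ord]
  trans <- best$trans[ord, ord, drop = FALSE]; init <- best$init[ord]
  path <- viterbi_path(x, means, sds, trans, init)
  structure(list(states = path, means = means, sds = sds, trans = trans,
                 init = init, loglik = best$loglik,
                 high_state = n_states, n_states = n_states),
            class = "hmm_segmentation")
}

#' @export
print.hmm_segmentation <- function(x, ...) {
  cat("Gaussian-HMM segmentation:", length(x$states), "windows,",
      x$n_states, "states\n  state means:",
      paste(signif(x$means, 4), collapse = ", "), "\n  high-state windows:",
      sum(x$states == x$high_state), "\n")
  invisible(x)
}

#' Call trans interaction domains from replicate segmentations
#'
#' A window is domain-eligible when it is labeled "high" in at least
#' \code{n_required} replicates (default 2, i.e. both biological
#' replicates); maximal runs of eligible windows are merged into domains.
#'
#' @param segmentations List of \code{hmm_segmentation} (or integer state
#'   paths), one per replicate, on the same window grid.
#' @param track The shared \code{window_track}.
#' @param n_required Minimum supporting replicates.
#' @param high_state State index counted as "high" (defaults to the top
#'   state of the first segmentation).
#' @return Data frame of class \code{"trans_domains"}: \code{chrom},
#'   \code{start}, \code{end}, \code{n_windows}, \code{mean_signal},
#'   \code{supported_replicates}.
#' @export
call_trans_domains <- function(segmentations, track, n_required = 2L,
                               high_state = NULL) {
  stopifnot(inherits(track, "window_track"))
  paths <- lapply(segmentations, function(s)
    if (inherits(s, "hmm_segmentation")) s$states else as.integer(s))
  n <- nrow(track)
  if (!all(vapply(paths, length, integer(1L)) == n))
    stop("replicate segmentations do not share the window grid")
  if (is.null(high_state)) {
    s1 <- segmentations[[1L]]
    high_state <- if (inherits(s1, "hmm_segmentation")) s1$high_state
                  else max(unlist(paths))
  }
  support <- Reduce(`+`, lapply(paths, function(p) as.integer(p == high_state)))
  eligible <- support >= n_required
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_windows = integer(0),
                      mean_signal = numeric(0),
                      supported_replicates = integer(0))
  if (!any(eligible))
    return(structure(empty, class = c("trans_domains", "data.frame")))
  r <- rle(eligible)
  stops <- cumsum(r$lengths); starts <- stops - r$lengths + 1L
  runs <- which(r$values)
  out <- do.call(rbind, lapply(runs, function(i) {
    w <- starts[i]:stops[i]
    data.frame(chrom = attr(track, "chrom"),
               start = track$start[w[1L]], end = track$end[w[length(w)]],
               n_windows = length(w),
               mean_signal = mean(track$log_signal[w]),
               supported_replicates = min(support[w]))
  }))
  structure(out, class = c("trans_domains", "data.frame"))
}
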