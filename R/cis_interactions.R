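#' Variance-stabilizing transform for fragment signal
#'
#' \code{log2(x + 1)} applied to RPKM values: monotone, zero at zero, and
#' approximately variance-stabilizing for overdispersed counts whose
#' standard deviation grows with the mean. \code{sqrt} is available as an
#' alternative.
#'
#' @param x Non-negative numeric vector (RPKM).
#' @param method \code{"log2"} (default) or \code{"sqrt"}.
#' @return Transformed values.
#' @examples
#' transform_counts(c(0, 3, 7))  # 0, 2, 3
#' @export
transform_counts <- function(x, method = c("log2", "sqrt")) {
  method <- match.arg(method)
  if (any(x < 0, na.rm = TRUE)) stop("negative values cannot be transformed")
  switch(method, log2 = log2(x + 1), sqrt = sqrt(x))
}

#' Fit the monotone contact distance-decay trend
#'
#' 4C contact frequency decreases monotonically with genomic distance from
#' the bait. The trend is fitted per sample and per side (upstream /
#' downstream) as an isotonic (monotone non-increasing) regression of the
#' transformed signal on log10 distance; the residual scale is a robust
#' MAD estimate, floored to avoid z-score blow-up on degenerate flat
#' profiles.
#'
#' @param values Transformed signal (one per fragment).
#' @param distances Positive distances from the bait, bp.
#' @param side \code{"upstream"} or \code{"downstream"} (label only).
#' @param sigma_floor Lower bound for the residual scale.
#' @param min_fragments Minimum fragments required for a stable fit.
#' @return An object of class \code{"decay_fit"} with components
#'   \code{log10_distance}, \code{fitted} (same order as input),
#'   \code{residuals}, \code{sigma}, \code{side}.
#' @seealso \code{\link{predict.decay_fit}}, \code{\link{compute_z}}
#' @export
fit_decay <- function(values, distances, side = "downstream",
                      sigma_floor = 1e-6, min_fragments = 10L) {
  stopifnot(length(values) == length(distances))
  if (any(distances <= 0)) stop("distances must be > 0")
  if (length(values) < min_fragments)
    stop("need at least ", min_fragments, " fragments to fit the decay trend")
  lx <- log10(distances)
  ord <- order(lx)
  # isoreg fits non-decreasing; negate for the non-increasing decay
  iso <- stats::isoreg(lx[ord], -values[ord])
  fitted <- numeric(length(values))
  fitted[ord] <- -iso$yf
  res <- values - fitted
  sigma <- max(1.4826 * stats::median(abs(res)), sigma_floor)
  structure(list(log10_distance = lx, fitted = fitted, residuals = res,
                 sigma = sigma, side = side),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("Monotone 4C distance-decay fit (", x$side, " side)\n",
      "  ", length(x$fitted), " fragments, residual scale sigma = ",
      signif(x$sigma, 4), "\n", sep = "")
  invisible(x)
}

#' Predict the decay trend at new distances
#'
#' Linear interpolation between the fitted knots on the log10-distance
#' axis; constant extrapolation beyond the fitted range.
#'
#' @param object A \code{decay_fit}.
#' @param distances Distances (bp) at which to evaluate the trend.
#' @param ... Unused.
#' @return Fitted trend values.
#' @export
predict.decay_fit <- function(object, distances, ...) {
  lx <- log10(distances)
  ord <- order(object$log10_distance)
  stats::approx(object$log10_distance[ord], object$fitted[ord],
                xout = lx, rule = 2, ties = mean)$y
}

#' @export
plot.decay_fit <- function(x, values = NULL, ...) {
  ord <- order(x$log10_distance)
  if (!is.null(values))
    plot(x$log10_distance, values, pch = 16, cex = 0.4, col = "grey60",
         xlab = "log10 distance (bp)", ylab = "transformed signal", ...)
  else
    plot(x$log10_distance[ord], x$fitted[ord], type = "n",
         xlab = "log10 distance (bp)", ylab = "fitted trend", ...)
  lines(x$log10_distance[ord], x$fitted[ord], col = "firebrick", lwd = 2)
  invisible(x)
}

#' Per-fragment z-score against the decay trend
#'
#' \code{z = (value - fitted) / sigma}: the number of residual standard
#' deviations by which a fragment's signal exceeds the fitted contact
#' decay trend. The p-value is the one-sided upper-tail standard-normal
#' probability (only enrichment over the trend is called).
#'
#' @param values Transformed signal.
#' @param fit A \code{decay_fit} covering the fragments' distances.
#' @param distances Distances (bp); if omitted, the fit's own fragments
#'   (and exact fitted values) are used.
#' @return A data frame with columns \code{z} and \code{p}.
#' @examples
#' f <- structure(list(log10_distance = log10(c(1e3, 1e4)),
#'                     fitted = c(5, 5), residuals = c(0, 0),
#'                     sigma = 1.5, side = "downstream"),
#'                class = "decay_fit")
#' compute_z(8, f, distances = 1e3)  # z = 2
#' @export
compute_z <- function(values, fit, distances = NULL) {
  stopifnot(inherits(fit, "decay_fit"))
  if (fit$sigma <= 0) stop("sigma must be > 0")
  fitted <- if (is.null(distances)) fit$fitted
            else predict(fit, distances)
  z <- (values - fitted) / fit$sigma
  data.frame(z = z, p = stats::pnorm(z, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment applied per sample within the cis analysis
#' window (excluded fragments are omitted from the family size).
#'
#' @param p Numeric p-values in \code{[0, 1]}.
#' @return Adjusted values, monotone in \code{p}.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.05))  # all 0.05
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call significant cis interactions for one condition
#'
#' The core caller. For each replicate library of one (diet, timepoint)
#' condition: restrict to non-blind, non-excluded fragments within
#' \code{window_bp} of the bait, transform RPKM, fit the monotone decay
#' trend per side, compute z-scores and one-sided p-values, and BH-adjust
#' within the window. A fragment is significant when \code{z >=
#' z_threshold} and \code{FDR <= fdr_threshold} in \emph{every} replicate.
#' Runs of significant fragments separated by at most
#' \code{merge_gap_fragments} non-significant fragments are merged into
#' reported interaction intervals.
#'
#' @param counts_list List of \code{sample_counts}, one per replicate,
#'   RPKM-normalized with bait-proximal exclusion applied.
#' @param map The \code{fragment_map} with the bait located.
#' @param bait A \code{bait_config} (thresholds and window; the Srebp1c
#'   bait conventionally uses \code{z_threshold = 1.5}).
#' @param z_threshold,fdr_threshold,window_bp Overrides for the bait's
#'   thresholds.
#' @param merge_gap_fragments Gap tolerance (fragments) when merging.
#' @param min_fragment_bp Fragments shorter than this are dropped from the
#'   analysis universe (default 100). Fragments shorter than a sequencing
#'   read cannot be uniquely mapped, and a single read on a tiny fragment
#'   produces an explosive RPKM that both replicates reproduce, so they
#'   are removed rather than tested.
#' @param vst Transform passed to \code{\link{transform_counts}}.
#' @return An object of class \code{"interaction_call"}: list with
#'   \code{fragments} (per-fragment statistics: \code{fragment_id},
#'   \code{distance}, \code{z_rep*}, \code{fdr_rep*}, \code{significant}),
#'   \code{intervals} (merged interactions: \code{chrom}, \code{start},
#'   \code{end}, \code{n_fragments}, \code{mean_z}), the condition labels
#'   and the thresholds used.
#' @export
call_cis <- function(counts_list, map, bait,
                     z_threshold = bait$z_threshold,
                     fdr_threshold = bait$fdr_threshold,
                     window_bp = bait$window_bp,
                     merge_gap_fragments = 1L,
                     min_fragment_bp = 100L,
                     vst = "log2") {
  stopifnot(inherits(map, "fragment_map"), inherits(bait, "bait_config"),
            length(counts_list) >= 1L)
  bid <- bait_fragment(map)
  if (is.na(bid)) stop("bait fragment not located on map")
  bait_row <- match(bid, map$fragment_id)
  bait_mid <- (map$start[bait_row] + map$end[bait_row]) / 2

  universe <- NULL
  stats_reps <- vector("list", length(counts_list))
  for (r in seq_along(counts_list)) {
    cts <- counts_list[[r]]
    stopifnot(inherits(cts, "sample_counts"))
    if (all(is.na(cts$rpkm))) stop("counts not RPKM-normalized")
    sel <- cts$chrom == bait$chrom & !cts$excluded &
      (cts$end - cts$start) >= min_fragment_bp
    blind <- map$blind[match(cts$fragment_id, map$fragment_id)]
    sel <- sel & !(blind %in% TRUE)
    mid <- (cts$start + cts$end) / 2
    dist <- mid - bait_mid
    sel <- sel & abs(dist) <= window_bp & dist != 0
    ids <- cts$fragment_id[sel]
    if (is.null(universe)) universe <- ids
    else if (!identical(universe, ids))
      stop("replicate fragment universes differ")
    v <- transform_counts(cts$rpkm[sel], method = vst)
    d <- dist[sel]
    z <- p <- numeric(length(v))
    for (s in c(-1, 1)) {
      sside <- if (s < 0) "upstream" else "downstream"
      k <- if (s < 0) d < 0 else d > 0
      if (!any(k)) next
      zp <- .robust_side_z(v[k], abs(d[k]), sside, z_threshold)
      z[k] <- zp$z; p[k] <- zp$p
    }
    stats_reps[[r]] <- data.frame(z = z, p = p, fdr = bh_fdr(p))
  }

  n_rep <- length(stats_reps)
  frag <- data.frame(fragment_id = universe,
                     distance = (map$start[match(universe, map$fragment_id)] +
                                 map$end[match(universe, map$fragment_id)]) / 2 -
                                bait_mid)
  sig <- rep(TRUE, nrow(frag))
  for (r in seq_len(n_rep)) {
    frag[[paste0("z_rep", r)]] <- stats_reps[[r]]$z
    frag[[paste0("p_rep", r)]] <- stats_reps[[r]]$p
    frag[[paste0("fdr_rep", r)]] <- stats_reps[[r]]$fdr
    sig <- sig & stats_reps[[r]]$z >= z_threshold &
                 stats_reps[[r]]$fdr <= fdr_threshold
  }
  frag$mean_z <- rowMeans(as.matrix(frag[paste0("z_rep", seq_len(n_rep))]))
  frag$significant <- sig
  ord <- order(frag$fragment_id)
  frag <- frag[ord, , drop = FALSE]
  rownames(frag) <- NULL

  intervals <- .merge_significant(frag, map, merge_gap_fragments)
  structure(list(bait_name = bait$name, chrom = bait$chrom,
                 diet = attr(counts_list[[1L]], "diet"),
                 timepoint = attr(counts_list[[1L]], "timepoint"),
                 n_replicates = n_rep,
                 z_threshold = z_threshold, fdr_threshold = fdr_threshold,
                 window_bp = window_bp,
                 merge_gap_fragments = merge_gap_fragments,
                 fragments = frag, intervals = intervals),
            class = "interaction_call")
}

# Outlier-robust z-scores for one side of the bait: an initial isotonic
# fit, then a refit excluding candidate peaks (initial z above the call
# threshold) so enriched fragments do not inflate the background trend
# they are tested against. Falls back to the single pass when too few
# fragments remain.
.robust_side_z <- function(v, d, side, z_threshold, min_fragments = 10L) {
  fit <- fit_decay(v, d, side = side)
  z <- compute_z(v, fit)$z
  out <- z >= z_threshold
  if (any(out) && sum(!out) >= min_fragments) {
    refit <- fit_decay(v[!out], d[!out], side = side)
    fitted <- predict(refit, d)
    z <- (v - fitted) / refit$sigma
  }
  data.frame(z = z, p = stats::pnorm(z, lower.tail = FALSE))
}

# merge runs of significant fragments, tolerating small gaps (in units of
# fragments of the analysis universe)
.merge_significant <- function(frag, map, gap) {
  sig_idx <- which(frag$significant)
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_fragments = integer(0),
                      mean_z = numeric(0))
  if (length(sig_idx) == 0L) return(empty)
  brk <- c(0L, which(diff(sig_idx) > gap + 1L), length(sig_idx))
  out <- vector("list", length(brk) - 1L)
  for (g in seq_len(length(brk) - 1L)) {
    members <- sig_idx[(brk[g] + 1L):brk[g + 1L]]
    ids <- frag$fragment_id[members]
    rows <- match(ids, map$fragment_id)
    out[[g]] <- data.frame(
      chrom = map$chrom[rows[1L]],
      start = min(map$start[rows]), end = max(map$end[rows]),
      n_fragments = length(ids),
      mean_z = mean(frag$mean_z[members]))
  }
  do.call(rbind, out)
}

#' @export
print.interaction_call <- function(x, ...) {
  cat("4C cis-interaction call:", x$bait_name,
      sprintf("(%s %s, %d replicates)\n", x$diet, x$timepoint, x$n_replicates),
      " thresholds: z >=", x$z_threshold, "& FDR <=", x$fdr_threshold,
      "in all replicates; window +/-", format(x$window_bp, big.mark = ","),
      "bp\n ", sum(x$fragments$significant), "significant fragments in",
      nrow(x$intervals), "merged interaction(s)\n")
  invisible(x)
}

#' @export
summary.interaction_call <- function(object, ...) {
  print(object)
  if (nrow(object$intervals)) {
    cat("\nMerged interactions:\n")
    print(object$intervals, row.names = FALSE)
  }
  invisible(object)
}

#' Write per-fragment call statistics and merged interactions
#'
#' \code{write_call_stats} emits the per-fragment TSV; \code{write_call_bedpe}
#' emits merged interactions as BEDPE with the bait fragment as anchor 1
#' and mean cross-replicate z as the score.
#'
#' @param call An \code{interaction_call}.
#' @param map The \code{fragment_map} (for the bait anchor coordinates).
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_call_stats <- function(call, path) {
  df <- call$fragments
  df$significant <- as.integer(df$significant)
  num <- vapply(df, is.numeric, logical(1L)) & names(df) != "fragment_id"
  df[num] <- lapply(df[num], function(v) formatC(v, digits = 8, format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_call_stats
#' @export
write_call_bedpe <- function(call, map, path) {
  bid <- bait_fragment(map)
  row <- match(bid, map$fragment_id)
  iv <- call$intervals
  if (nrow(iv) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  out <- data.frame(map$chrom[row], .fmt_bp(map$start[row]), .fmt_bp(map$end[row]),
                    iv$chrom, .fmt_bp(iv$start), .fmt_bp(iv$end),
                    paste0(call$bait_name, "_", call$diet, "_", call$timepoint,
                           "_", seq_len(nrow(iv))),
                    formatC(iv$mean_z, digits = 6, format = "g"),
                    ".", ".")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.fmt_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)
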