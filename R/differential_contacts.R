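#' Average z-score across replicates
#'
#' @param z Numeric vector of per-replicate z-scores for one fragment.
#' @return Arithmetic mean.
#' @examples
#' average_z(c(2, 4))  # 3
#' @export
average_z <- function(z) {
  if (length(z) == 0L) stop("no replicate z-scores supplied")
  mean(z)
}

#' Average z-score ratio between two conditions
#'
#' \code{ratio = max(mean_z_num, epsilon) / max(mean_z_den, epsilon)}. The
#' epsilon clip guards against non-positive mean z-scores, for which a raw
#' ratio is undefined or misleading; with the default \code{epsilon = 0.1}
#' a strong positive signal over a null (or depleted) fragment yields a
#' large finite ratio.
#'
#' @param mean_z_num,mean_z_den Mean z-scores of the two conditions.
#' @param epsilon Positive clip value.
#' @return The clipped ratio (always > 0).
#' @examples
#' zscore_ratio(3, 2)       # 1.5
#' zscore_ratio(3, -1)      # 30 with the default epsilon
#' @export
zscore_ratio <- function(mean_z_num, mean_z_den, epsilon = 0.1) {
  stopifnot(epsilon > 0)
  pmax(mean_z_num, epsilon) / pmax(mean_z_den, epsilon)
}

#' Call diet-differential contacts (HF vs CD)
#'
#' Applies the average z-score-ratio rule at a matched timepoint: a
#' fragment is an HF gain when the HF/CD mean-z ratio is at least
#' \code{ratio_threshold} \emph{and} the fragment is a significant
#' interaction in HF (z and FDR thresholds met in every HF replicate);
#' symmetrically for CD gains. Fragments significant in neither condition
#' are never differential — the rule compares called contacts, not noise.
#'
#' @param calls_hf,calls_cd \code{interaction_call} objects for the same
#'   bait and timepoint under the two diets.
#' @param ratio_threshold Minimum mean-z ratio (default 1.5).
#' @param epsilon Clip for \code{\link{zscore_ratio}}.
#' @return An object of class \code{"differential_call"}: data frame with
#'   \code{fragment_id}, \code{mean_z_HF}, \code{mean_z_CD}, \code{ratio}
#'   (in the gaining orientation, HF/CD when neither gains),
#'   \code{direction} (\code{"HF_gain"}, \code{"CD_gain"} or \code{NA}),
#'   \code{differential}.
#' @export
call_differential <- function(calls_hf, calls_cd, ratio_threshold = 1.5,
                              epsilon = 0.1) {
  stopifnot(inherits(calls_hf, "interaction_call"),
            inherits(calls_cd, "interaction_call"))
  if (!identical(calls_hf$bait_name, calls_cd$bait_name))
    stop("bait mismatch between conditions")
  if (!identical(calls_hf$fragments$fragment_id,
                 calls_cd$fragments$fragment_id))
    stop("fragment universes differ between conditions")
  fh <- calls_hf$fragments; fc <- calls_cd$fragments
  r_hf <- zscore_ratio(fh$mean_z, fc$mean_z, epsilon)
  r_cd <- zscore_ratio(fc$mean_z, fh$mean_z, epsilon)
  hf_gain <- r_hf >= ratio_threshold & fh$significant
  cd_gain <- r_cd >= ratio_threshold & fc$significant & !hf_gain
  direction <- ifelse(hf_gain, "HF_gain", ifelse(cd_gain, "CD_gain", NA))
  out <- data.frame(fragment_id = fh$fragment_id,
                    mean_z_HF = fh$mean_z, mean_z_CD = fc$mean_z,
                    ratio = ifelse(cd_gain, r_cd, r_hf),
                    direction = direction,
                    differential = hf_gain | cd_gain)
  structure(out, bait_name = calls_hf$bait_name,
            timepoint = calls_hf$timepoint,
            ratio_threshold = ratio_threshold, epsilon = epsilon,
            class = c("differential_call", "data.frame"))
}

#' @export
print.differential_call <- function(x, ...) {
  cat("Diet-differential 4C contacts:", attr(x, "bait_name"),
      "at", attr(x, "timepoint"),
      sprintf("(ratio >= %s)\n", attr(x, "ratio_threshold")),
      " HF gains:", sum(x$direction %in% "HF_gain"),
      " CD gains:", sum(x$direction %in% "CD_gain"),
      "of", nrow(x), "fragments\n")
  NextMethod()
}

#' Write differential calls as TSV
#'
#' Columns: fragment_id, mean_z_HF, mean_z_CD, ratio, direction,
#' differential (0/1).
#'
#' @param diff A \code{differential_call}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_differential_table <- function(diff, path) {
  df <- as.data.frame(diff)
  df$differential <- as.integer(df$differential)
  for (v in c("mean_z_HF", "mean_z_CD", "ratio"))
    df[[v]] <- formatC(df[[v]], digits = 8, format = "g")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
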