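#' Read TAD intervals from a BED file
#'
#' TADs and subTADs may nest; containment queries never assume
#' disjointness.
#'
#' @param path BED file (3+ columns; a 4th column is used as the TAD name).
#' @return Data frame with \code{chrom}, \code{start}, \code{end},
#'   \code{name} (0-based half-open coordinates).
#' @export
read_tads <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- as.data.frame(gr)
  name <- if ("name" %in% names(df) && !all(is.na(df$name))) df$name
          else sprintf("TAD_%d", seq_len(nrow(df)))
  out <- data.frame(chrom = as.character(df$seqnames),
                    start = df$start - 1L,   # back to 0-based
                    end = df$end, name = name,
                    stringsAsFactors = FALSE)
  if (any(out$start >= out$end)) stop("malformed TAD intervals")
  out
}

#' TADs containing an interaction, with tolerance
#'
#' An interaction interval is assigned to a TAD when it is contained in
#' the TAD expanded by \code{tolerance_bp} on each side:
#' \code{interaction in [TAD.start - tol, TAD.end + tol]}. TADs are
#' insulating containers for cis contacts, so containment (not 1-bp
#' intersection) is the default rule; set \code{rule = "intersect"} for
#' plain overlap.
#'
#' @param interval Numeric \code{c(start, end)} or a one-row data frame /
#'   list with \code{chrom}, \code{start}, \code{end}.
#' @param tads TAD data frame from \code{\link{read_tads}}.
#' @param tolerance_bp Tolerance distance (default 200 kb).
#' @param chrom Interaction chromosome when \code{interval} is a bare
#'   numeric pair.
#' @param rule \code{"contain"} (default) or \code{"intersect"}.
#' @return Character vector of qualifying TAD names (possibly several,
#'   since TADs nest); empty (with a warning) when the chromosome is
#'   absent from the TAD set.
#' @export
tad_overlap <- function(interval, tads, tolerance_bp = 2e5, chrom = NULL,
                        rule = c("contain", "intersect")) {
  rule <- match.arg(rule)
  if (is.numeric(interval) && length(interval) == 2L) {
    if (is.null(chrom)) stop("chrom required for a bare interval")
    interval <- list(chrom = chrom, start = interval[1L], end = interval[2L])
  }
  sel <- tads$chrom == interval$chrom
  if (!any(sel)) {
    warning("chromosome ", interval$chrom, " absent from TAD set")
    return(character(0))
  }
  t <- tads[sel, , drop = FALSE]
  hit <- if (rule == "contain")
    interval$start >= t$start - tolerance_bp &
    interval$end <= t$end + tolerance_bp
  else
    interval$start < t$end + tolerance_bp &
    interval$end > t$start - tolerance_bp
  t$name[hit]
}

#' Construct a binned contact matrix
#'
#' @param values Square (intra-chromosomal) or rectangular non-negative
#'   numeric matrix.
#' @param bins Data frame of bin intervals (\code{chrom}, \code{start},
#'   \code{end}) matching the matrix rows (and columns when square).
#' @param bin_size Bin width in bp.
#' @return A \code{contact_matrix}.
#' @export
contact_matrix <- function(values, bins = NULL, bin_size = NA_real_) {
  values <- as.matrix(values)
  if (any(values < 0, na.rm = TRUE)) stop("contact values must be >= 0")
  if (!is.null(bins) && nrow(bins) != nrow(values))
    stop("bin list does not match matrix dimension")
  structure(list(values = values, bins = bins, bin_size = bin_size),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("Contact matrix:", nrow(x$values), "x", ncol(x$values), "bins")
  if (!is.na(x$bin_size)) cat(" at", format(x$bin_size, big.mark = ","), "bp")
  cat("\n")
  invisible(x)
}

#' Read a contact matrix from dense or COO TSV
#'
#' Dense: a numeric grid, one row per line. COO: three columns
#' \code{bin_i, bin_j, value} (1-based bins); missing entries are zero and
#' intra-chromosomal matrices are symmetrized.
#'
#' @param path Matrix TSV.
#' @param format \code{"dense"} or \code{"coo"}.
#' @param bins Optional sidecar bin BED (read with
#'   \code{\link{read_tads}}-style 0-based coordinates).
#' @param n_bins Grid size for COO input (inferred from the data when
#'   missing).
#' @return A \code{contact_matrix}.
#' @export
read_contact_matrix <- function(path, format = c("dense", "coo"),
                                bins = NULL, n_bins = NULL) {
  format <- match.arg(format)
  if (format == "dense") {
    vals <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
    dimnames(vals) <- NULL
  } else {
    coo <- utils::read.table(path, sep = "\t", header = FALSE,
                             col.names = c("bin_i", "bin_j", "value"))
    n <- n_bins %||% max(coo$bin_i, coo$bin_j)
    vals <- matrix(0, n, n)
    vals[cbind(coo$bin_i, coo$bin_j)] <- coo$value
    vals[cbind(coo$bin_j, coo$bin_i)] <- coo$value
  }
  bin_df <- if (is.character(bins)) read_tads(bins)[, c("chrom", "start", "end")]
            else bins
  bsize <- if (!is.null(bin_df)) stats::median(bin_df$end - bin_df$start)
           else NA_real_
  contact_matrix(vals, bins = bin_df, bin_size = bsize)
}

#' Log2 ratio of two contact matrices
#'
#' Elementwise \code{log2((A + pc) / (B + pc))} on a shared bin grid, the
#' standard comparison of two normalized (e.g. ICED) Hi-C matrices such
#' as WT vs KO. Anti-symmetric in its arguments; bins enriched in A over
#' B are positive.
#'
#' @param A,B \code{contact_matrix} objects (or bare matrices) on
#'   identical bin grids.
#' @param pseudocount Added to both matrices; must be > 0 when either
#'   matrix contains zeros.
#' @return Signed numeric matrix of log2 ratios.
#' @export
log2_ratio <- function(A, B, pseudocount = 1.0) {
  va <- if (inherits(A, "contact_matrix")) A$values else as.matrix(A)
  vb <- if (inherits(B, "contact_matrix")) B$values else as.matrix(B)
  if (!identical(dim(va), dim(vb))) stop("matrix dimensions differ")
  if (inherits(A, "contact_matrix") && inherits(B, "contact_matrix") &&
      !is.null(A$bins) && !is.null(B$bins) && !identical(A$bins, B$bins))
    stop("bin grids differ")
  if (pseudocount <= 0 && (any(va == 0) || any(vb == 0)))
    stop("pseudocount must be > 0 when matrices contain zero entries")
  log2((va + pseudocount) / (vb + pseudocount))
}

#' Mark increased-contact bins in a log2-ratio grid
#'
#' A configurable stand-in definition: bins whose log2 ratio meets
#' \code{threshold} (default 1, i.e. 2-fold) are marked increased.
#'
#' @param ratio Log2-ratio matrix from \code{\link{log2_ratio}}.
#' @param threshold Minimum log2 ratio.
#' @return Logical matrix.
#' @export
increased_bins <- function(ratio, threshold = 1.0) ratio >= threshold

#' Fraction of called interactions inside the bait's TAD
#'
#' Of the merged significant interaction intervals of a call, the
#' fraction contained (with tolerance) in any TAD containing the bait
#' position.
#'
#' @param call An \code{interaction_call}.
#' @param tads TAD data frame.
#' @param bait A \code{bait_config}.
#' @param tolerance_bp Containment tolerance (default 200 kb).
#' @return Fraction in \code{[0, 1]} (\code{NaN} when the call has no
#'   intervals).
#' @export
fraction_in_bait_tad <- function(call, tads, bait, tolerance_bp = 2e5) {
  stopifnot(inherits(call, "interaction_call"), inherits(bait, "bait_config"))
  sel <- tads$chrom == bait$chrom & tads$start <= bait$position &
         bait$position < tads$end
  if (!any(sel)) stop("bait position lies in no TAD")
  bait_tads <- tads[sel, , drop = FALSE]
  iv <- call$intervals
  if (nrow(iv) == 0L) return(NaN)
  inside <- vapply(seq_len(nrow(iv)), function(i) {
    any(iv$start[i] >= bait_tads$start - tolerance_bp &
        iv$end[i] <= bait_tads$end + tolerance_bp &
        iv$chrom[i] == bait_tads$chrom)
  }, logical(1L))
  mean(inside)
}

#' Write a dense matrix as TSV
#' @param m Numeric matrix (or \code{contact_matrix}).
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_dense_matrix <- function(m, path) {
  v <- if (inherits(m, "contact_matrix")) m$values else m
  utils::write.table(v, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
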