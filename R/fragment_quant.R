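#' Count reads per restriction fragment
#'
#' Assigns each mapped read to the fragment containing its 5' alignment
#' position (4C reads start at restriction sites, so the 5' end is the
#' unambiguous anchor). Reads on chromosomes absent from the map are
#' tallied as off-map; unmapped reads count toward the QC total only.
#' Blind fragments receive counts here and are excluded downstream.
#'
#' @param alignments A data frame with columns \code{chrom}, \code{pos}
#'   (0-based 5' position) and optionally \code{mapped} (logical, default
#'   all \code{TRUE}); or a BAM file path (requires Rsamtools).
#' @param map A \code{fragment_map} tiling the genome.
#' @param sample_id,diet,timepoint,replicate,bait_name Library metadata
#'   attached to the result.
#' @return A \code{sample_counts}: data frame with \code{fragment_id},
#'   \code{chrom}, \code{start}, \code{end}, \code{raw}, \code{rpkm}
#'   (\code{NA} until \code{\link{normalize_rpkm}}), \code{excluded};
#'   attributes carry the metadata, \code{total_mapped_reads} and
#'   \code{off_map_reads}.
#' @export
count_reads <- function(alignments, map, sample_id = "sample",
                        diet = NA_character_, timepoint = NA_character_,
                        replicate = NA_integer_, bait_name = NA_character_) {
  stopifnot(inherits(map, "fragment_map"))
  if (is.character(alignments) && length(alignments) == 1L)
    alignments <- .read_bam_positions(alignments)
  stopifnot(is.data.frame(alignments),
            all(c("chrom", "pos") %in% names(alignments)))
  mapped <- if ("mapped" %in% names(alignments)) alignments$mapped else
    rep(TRUE, nrow(alignments))
  al <- alignments[mapped, , drop = FALSE]
  raw <- integer(nrow(map))
  off_map <- 0L
  for (chrom in unique(al$chrom)) {
    pos <- al$pos[al$chrom == chrom]
    idx <- which(map$chrom == chrom)
    if (length(idx) == 0L) { off_map <- off_map + length(pos); next }
    k <- findInterval(pos, map$start[idx])
    inside <- k >= 1L & pos < map$end[idx][pmax(k, 1L)] & pos >= map$start[idx][1L]
    off_map <- off_map + sum(!inside)
    tab <- tabulate(k[inside], nbins = length(idx))
    raw[idx] <- raw[idx] + tab
  }
  df <- data.frame(fragment_id = map$fragment_id, chrom = map$chrom,
                   start = map$start, end = map$end,
                   raw = raw, rpkm = NA_real_,
                   excluded = FALSE, stringsAsFactors = FALSE)
  new_sample_counts(df, sample_id = sample_id, diet = diet,
                    timepoint = timepoint, replicate = replicate,
                    bait_name = bait_name,
                    total_mapped_reads = sum(raw) + off_map,
                    off_map_reads = off_map,
                    blind = map$blind,
                    bait_fragment_id = attr(map, "bait_fragment_id"))
}

.read_bam_positions <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("reading BAM requires the Rsamtools package; ",
         "alternatively supply a data frame or count table")
  p <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "strand", "qwidth"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  b <- Rsamtools::scanBam(path, param = p)[[1L]]
  # 5' position: leftmost-1 on +, rightmost-1 on -
  pos0 <- ifelse(as.character(b$strand) == "-",
                 b$pos + b$qwidth - 2L, b$pos - 1L)
  data.frame(chrom = as.character(b$rname), pos = pos0,
             mapped = TRUE, stringsAsFactors = FALSE)
}

new_sample_counts <- function(df, sample_id, diet = NA, timepoint = NA,
                              replicate = NA, bait_name = NA,
                              total_mapped_reads, off_map_reads = 0L,
                              blind = NULL, bait_fragment_id = NA_integer_,
                              excluded_fragment_ids = integer(0)) {
  structure(df, sample_id = sample_id, diet = diet, timepoint = timepoint,
            replicate = replicate, bait_name = bait_name,
            total_mapped_reads = total_mapped_reads,
            off_map_reads = off_map_reads,
            blind = if (is.null(blind)) rep(NA, nrow(df)) else blind,
            bait_fragment_id = bait_fragment_id,
            excluded_fragment_ids = excluded_fragment_ids,
            class = c("sample_counts", "data.frame"))
}

#' @export
print.sample_counts <- function(x, ...) {
  cat("4C sample counts:", attr(x, "sample_id"),
      sprintf("(%s %s rep%s)", attr(x, "diet"), attr(x, "timepoint"),
              attr(x, "replicate")), "\n",
      nrow(x), "fragments,", attr(x, "total_mapped_reads"), "mapped reads,",
      length(attr(x, "excluded_fragment_ids")), "excluded\n")
  NextMethod()
}

#' RPKM normalization
#'
#' \code{rpkm = raw / (fragment length in kb) / (total mapped reads in
#' millions)}. Raw counts are preserved.
#'
#' @param counts A \code{sample_counts}.
#' @param total_mapped_reads Override for the library total (defaults to
#'   the value recorded by \code{\link{count_reads}}).
#' @param length_normalize If \code{FALSE}, fragments are treated as unit
#'   length (per-million scaling only).
#' @return The \code{sample_counts} with \code{rpkm} filled.
#' @export
normalize_rpkm <- function(counts, total_mapped_reads = NULL,
                           length_normalize = TRUE) {
  stopifnot(inherits(counts, "sample_counts"))
  total <- if (is.null(total_mapped_reads))
    attr(counts, "total_mapped_reads") else total_mapped_reads
  if (is.null(total) || is.na(total) || total <= 0)
    stop("total mapped reads must be > 0 for RPKM normalization")
  len_kb <- if (length_normalize) (counts$end - counts$start) / 1000 else 1
  if (any(len_kb <= 0)) stop("non-positive fragment length")
  counts$rpkm <- counts$raw / len_kb / (total / 1e6)
  attr(counts, "total_mapped_reads") <- total
  counts
}

#' Exclude bait-proximal fragments
#'
#' The bait fragment itself and the \code{n_exclude} fragments immediately
#' up- and downstream are dominated by self-ligation and re-ligation
#' products; they are removed from all downstream statistics (decay fit,
#' z-scores, calls). The default \code{n_exclude = 2} drops the first two
#' fragments on each side of the bait.
#'
#' @param counts A \code{sample_counts} with a located bait.
#' @param n_exclude Fragments to drop on each side of the bait.
#' @return The \code{sample_counts} with \code{excluded} set and the id set
#'   recorded in attribute \code{excluded_fragment_ids}.
#' @export
exclude_bait_proximal <- function(counts, n_exclude = 2L) {
  stopifnot(inherits(counts, "sample_counts"))
  bid <- attr(counts, "bait_fragment_id")
  if (is.null(bid) || is.na(bid))
    stop("bait fragment not located; run locate_bait() before counting")
  n_exclude <- as.integer(n_exclude)
  if (n_exclude < 0L) stop("n_exclude must be >= 0")
  bait_chrom <- counts$chrom[match(bid, counts$fragment_id)]
  ids <- (bid - n_exclude):(bid + n_exclude)
  on_chrom <- counts$fragment_id[counts$chrom == bait_chrom]
  ids <- intersect(ids, on_chrom)   # silently truncated at chromosome ends
  counts$excluded <- counts$fragment_id %in% ids
  attr(counts, "excluded_fragment_ids") <- as.integer(sort(ids))
  counts
}

#' Cis-mapped read fraction (QC)
#'
#' Fraction of mapped reads landing on the bait chromosome. Libraries in
#' which this fraction falls below \code{floor} (default 40\%) indicate a
#' failed 4C template and are flagged.
#'
#' @param counts A \code{sample_counts} spanning all chromosomes.
#' @param bait_chrom Chromosome carrying the bait.
#' @param floor QC floor on the cis fraction.
#' @return Numeric fraction in \code{[0, 1]} with attribute \code{pass}.
#' @export
cis_fraction <- function(counts, bait_chrom, floor = 0.40) {
  stopifnot(inherits(counts, "sample_counts"))
  total <- sum(counts$raw) + attr(counts, "off_map_reads")
  if (total <= 0) stop("no mapped reads; cis fraction undefined")
  frac <- sum(counts$raw[counts$chrom == bait_chrom]) / total
  structure(frac, pass = frac >= floor)
}

#' Write / read per-sample fragment count tables
#'
#' TSV with header \code{fragment_id, chrom, start, end, raw, rpkm,
#' excluded}; sample metadata in \code{#}-prefixed header lines, so a table
#' round-trips losslessly. \code{read_count_table} also accepts the minimal
#' format \code{(fragment_id, raw_count)} plus a fragment map, bypassing
#' BAM entirely.
#'
#' @param counts A \code{sample_counts}.
#' @param path File path.
#' @param map Optional \code{fragment_map}, required for minimal two-column
#'   tables.
#' @return \code{write_count_table} returns \code{path} invisibly;
#'   \code{read_count_table} a \code{sample_counts}.
#' @export
write_count_table <- function(counts, path) {
  stopifnot(inherits(counts, "sample_counts"))
  meta <- c(sample_id = attr(counts, "sample_id"),
            diet = attr(counts, "diet"),
            timepoint = attr(counts, "timepoint"),
            replicate = attr(counts, "replicate"),
            bait_name = attr(counts, "bait_name"),
            total_mapped_reads = attr(counts, "total_mapped_reads"),
            off_map_reads = attr(counts, "off_map_reads"),
            bait_fragment_id = attr(counts, "bait_fragment_id"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#%s=%s", names(meta), as.character(meta)), con)
  df <- as.data.frame(counts)
  df$excluded <- as.integer(df$excluded)
  df$rpkm <- formatC(df$rpkm, digits = 10, format = "g")
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path, map = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (l in lines[hdr]) {
    kv <- strsplit(sub("^#", "", l), "=", fixed = TRUE)[[1L]]
    meta[[kv[1L]]] <- kv[2L]
  }
  df <- utils::read.table(text = lines[setdiff(seq_along(lines), hdr)],
                          header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!"chrom" %in% names(df)) {
    if (is.null(map))
      stop("minimal count table requires a fragment map")
    m <- match(df$fragment_id, map$fragment_id)
    if (anyNA(m)) stop("count table fragment ids absent from map")
    full <- data.frame(fragment_id = map$fragment_id, chrom = map$chrom,
                       start = map$start, end = map$end,
                       raw = 0L, rpkm = NA_real_, excluded = FALSE,
                       stringsAsFactors = FALSE)
    full$raw[m] <- if ("raw" %in% names(df)) df$raw else df$raw_count
    df <- full
  }
  df$excluded <- as.logical(as.integer(df$excluded))
  num <- suppressWarnings(as.numeric(meta$total_mapped_reads))
  new_sample_counts(df,
    sample_id = meta$sample_id %||% "sample",
    diet = meta$diet %||% NA, timepoint = meta$timepoint %||% NA,
    replicate = suppressWarnings(as.integer(meta$replicate %||% NA)),
    bait_name = meta$bait_name %||% NA,
    total_mapped_reads = if (length(num) && !is.na(num)) num else sum(df$raw),
    off_map_reads = suppressWarnings(as.numeric(meta$off_map_reads %||% 0)),
    bait_fragment_id = suppressWarnings(as.integer(meta$bait_fragment_id %||% NA)),
    excluded_fragment_ids = df$fragment_id[df$excluded])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
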