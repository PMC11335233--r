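#' Classify interactions as time-of-day specific or stable
#'
#' Merged interaction intervals called at ZT6 and at ZT18 (same bait and
#' diet) are matched by at-least-1-bp overlap: overlapping calls at both
#' timepoints form a \emph{stable} contact, the rest are ZT6- or
#' ZT18-specific. Classification operates on the union of the two call
#' sets, so the three class counts always partition it.
#'
#' @param calls_zt6,calls_zt18 \code{interaction_call} objects for the
#'   two timepoints.
#' @return Data frame with \code{chrom}, \code{start}, \code{end} (the
#'   union entity), \code{class} in \code{{"ZT6_only", "ZT18_only",
#'   "stable"}}.
#' @export
classify_temporal <- function(calls_zt6, calls_zt18) {
  stopifnot(inherits(calls_zt6, "interaction_call"),
            inherits(calls_zt18, "interaction_call"))
  if (!identical(calls_zt6$bait_name, calls_zt18$bait_name))
    stop("bait mismatch between timepoints")
  a <- calls_zt6$intervals; b <- calls_zt18$intervals
  iv <- rbind(
    if (nrow(a)) data.frame(chrom = a$chrom, start = a$start, end = a$end,
                            src = "ZT6") else NULL,
    if (nrow(b)) data.frame(chrom = b$chrom, start = b$start, end = b$end,
                            src = "ZT18") else NULL)
  if (is.null(iv) || nrow(iv) == 0L)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), class = character(0)))
  iv <- iv[order(iv$chrom, iv$start, iv$end), , drop = FALSE]
  # merge touching-by->=1bp-overlap intervals into union entities
  ent <- integer(nrow(iv)); cur <- 0L; cur_end <- -Inf; cur_chrom <- ""
  for (i in seq_len(nrow(iv))) {
    if (iv$chrom[i] != cur_chrom || iv$start[i] >= cur_end) {
      cur <- cur + 1L; cur_chrom <- iv$chrom[i]; cur_end <- iv$end[i]
    } else cur_end <- max(cur_end, iv$end[i])
    ent[i] <- cur
  }
  out <- do.call(rbind, lapply(split(seq_len(nrow(iv)), ent), function(ix) {
    srcs <- unique(iv$src[ix])
    data.frame(chrom = iv$chrom[ix[1L]], start = min(iv$start[ix]),
               end = max(iv$end[ix]),
               class = if (length(srcs) == 2L) "stable"
                       else paste0(srcs, "_only"))
  }))
  rownames(out) <- NULL
  out
}

#' Run the full comparative 4C study on one bait
#'
#' Ties the pipeline stages into the comparative design (diets x
#' timepoints x replicates): per-sample QC (cis-mapped fraction),
#' replicate-concordant cis calls per condition, HF-vs-CD differential
#' contacts per timepoint, temporal (ZT6/ZT18) classification per diet,
#' and trans-domain segmentation per condition. All thresholds and seeds
#' used are echoed in the returned object.
#'
#' @param samples Named list of RPKM-normalized, exclusion-applied
#'   \code{sample_counts} (names \code{"<diet>_<tp>_rep<r>"}, as produced
#'   by \code{\link{simulate_counts}} or loaded from count tables).
#' @param map The \code{fragment_map} with the bait located.
#' @param bait A \code{bait_config}.
#' @param diets,timepoints Condition levels (inferred from the samples by
#'   default).
#' @param k Fragments per trans window (default 20).
#' @param n_required Replicate support for trans domains (default 2).
#' @param seed Master seed (drives the HMM restarts deterministically).
#' @param trans_chroms Chromosomes to segment (default: all non-bait
#'   chromosomes in the map).
#' @param ratio_threshold Differential mean-z ratio threshold.
#' @return An object of class \code{"study_result"} with elements
#'   \code{qc}, \code{calls}, \code{differential}, \code{temporal},
#'   \code{trans}, \code{summary}, \code{config}.
#' @export
run_study <- function(samples, map, bait, diets = NULL, timepoints = NULL,
                      k = 20L, n_required = 2L, seed = 1L,
                      trans_chroms = NULL, ratio_threshold = 1.5) {
  stopifnot(inherits(map, "fragment_map"), inherits(bait, "bait_config"))
  meta <- data.frame(
    name = names(samples),
    diet = vapply(samples, function(s) as.character(attr(s, "diet")), ""),
    timepoint = vapply(samples, function(s)
      as.character(attr(s, "timepoint")), ""),
    replicate = vapply(samples, function(s)
      as.integer(attr(s, "replicate")), 0L),
    stringsAsFactors = FALSE)
  diets <- diets %||% unique(meta$diet)
  timepoints <- timepoints %||% unique(meta$timepoint)
  cells <- expand.grid(diet = diets, timepoint = timepoints,
                       stringsAsFactors = FALSE)
  n_rep <- max(meta$replicate)
  for (i in seq_len(nrow(cells))) {
    got <- sum(meta$diet == cells$diet[i] & meta$timepoint == cells$timepoint[i])
    if (got != n_rep)
      stop("design cell ", cells$diet[i], "/", cells$timepoint[i],
           " has ", got, " samples, expected ", n_rep)
  }

  qc <- data.frame(sample = meta$name,
                   cis_fraction = vapply(samples, function(s)
                     as.numeric(cis_fraction(s, bait$chrom)), 0),
                   row.names = NULL)
  qc$pass <- qc$cis_fraction >= 0.40

  calls <- list()
  for (i in seq_len(nrow(cells))) {
    lab <- .cond_label(cells$diet[i], cells$timepoint[i])
    reps <- samples[meta$diet == cells$diet[i] &
                    meta$timepoint == cells$timepoint[i]]
    reps <- reps[order(vapply(reps, function(s)
      as.integer(attr(s, "replicate")), 0L))]
    calls[[lab]] <- call_cis(reps, map, bait)
  }

  differential <- list()
  if (all(c("HF", "CD") %in% diets)) {
    for (tp in timepoints)
      differential[[tp]] <- call_differential(
        calls[[.cond_label("HF", tp)]], calls[[.cond_label("CD", tp)]],
        ratio_threshold = ratio_threshold)
  }

  temporal <- list()
  if (length(timepoints) == 2L) {
    for (diet in diets)
      temporal[[diet]] <- classify_temporal(
        calls[[.cond_label(diet, timepoints[1L])]],
        calls[[.cond_label(diet, timepoints[2L])]])
  }

  trans_chroms <- trans_chroms %||% setdiff(unique(map$chrom), bait$chrom)
  trans <- list()
  si <- 0L
  for (i in seq_len(nrow(cells))) {
    lab <- .cond_label(cells$diet[i], cells$timepoint[i])
    reps <- samples[meta$diet == cells$diet[i] &
                    meta$timepoint == cells$timepoint[i]]
    reps <- reps[order(vapply(reps, function(s)
      as.integer(attr(s, "replicate")), 0L))]
    for (chrom in trans_chroms) {
      tracks <- lapply(reps, make_windows, chrom = chrom, k = k)
      segs <- lapply(seq_along(tracks), function(r) {
        si <<- si + 1L
        segment_hmm(tracks[[r]], seed = seed + si)
      })
      trans[[paste(lab, chrom, sep = ".")]] <-
        call_trans_domains(segs, tracks[[1L]], n_required = n_required)
    }
  }

  summary <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    lab <- .cond_label(cells$diet[i], cells$timepoint[i])
    cc <- calls[[lab]]
    td <- trans[grepl(paste0("^", lab, "\\."), names(trans))]
    data.frame(diet = cells$diet[i], timepoint = cells$timepoint[i],
               n_significant_fragments = sum(cc$fragments$significant),
               n_interactions = nrow(cc$intervals),
               n_trans_domains = sum(vapply(td, nrow, 0L)),
               stringsAsFactors = FALSE)
  }))
  if (length(differential)) {
    summary$n_HF_gain <- vapply(seq_len(nrow(summary)), function(i) {
      d <- differential[[summary$timepoint[i]]]
      sum(d$direction %in% "HF_gain")
    }, 0L)
    summary$n_CD_gain <- vapply(seq_len(nrow(summary)), function(i) {
      d <- differential[[summary$timepoint[i]]]
      sum(d$direction %in% "CD_gain")
    }, 0L)
  }

  structure(list(qc = qc, calls = calls, differential = differential,
                 temporal = temporal, trans = trans, summary = summary,
                 config = list(bait = bait, k = k, n_required = n_required,
                               seed = seed,
                               ratio_threshold = ratio_threshold,
                               z_threshold = bait$z_threshold,
                               fdr_threshold = bait$fdr_threshold,
                               window_bp = bait$window_bp)),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat("4C study:", x$config$bait$name, "-",
      nrow(x$qc), "libraries, thresholds z >=", x$config$z_threshold,
      "FDR <=", x$config$fdr_threshold, "\n\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write study summary tables and a run log
#'
#' Emits \code{summary.tsv}, \code{qc.tsv}, per-timepoint differential
#' tables, per-diet temporal classifications, trans-domain BEDs and
#' \code{run_log.txt} (the full effective configuration). Deterministic:
#' identical inputs yield byte-identical files.
#'
#' @param study A \code{study_result}.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_study_report <- function(study, dir) {
  stopifnot(inherits(study, "study_result"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create ", dir)
  paths <- character(0)
  w <- function(df, name, num_digits = 8) {
    p <- file.path(dir, name)
    num <- vapply(df, is.numeric, logical(1L)) &
      !vapply(df, is.integer, logical(1L))
    df[num] <- lapply(df[num], function(v)
      formatC(v, digits = num_digits, format = "g"))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  w(study$summary, "summary.tsv")
  w(study$qc, "qc.tsv")
  for (tp in names(study$differential)) {
    d <- as.data.frame(study$differential[[tp]])
    d$differential <- as.integer(d$differential)
    w(d[d$differential == 1L, , drop = FALSE],
      paste0("differential_", tp, ".tsv"))
  }
  for (diet in names(study$temporal))
    w(study$temporal[[diet]], paste0("temporal_", diet, ".tsv"))
  for (nm in names(study$trans))
    w(as.data.frame(study$trans[[nm]]), paste0("trans_", nm, ".tsv"))
  cfg <- study$config
  log <- c("loop4c study run log",
           paste0("bait: ", cfg$bait$name, " @ ", cfg$bait$chrom, ":",
                  .fmt_bp(cfg$bait$position)),
           paste0("enzymes: ", cfg$bait$primary_enzyme$name, " / ",
                  cfg$bait$secondary_enzyme$name),
           paste0("z_threshold: ", cfg$z_threshold),
           paste0("fdr_threshold: ", cfg$fdr_threshold),
           paste0("window_bp: ", .fmt_bp(cfg$window_bp)),
           paste0("ratio_threshold: ", cfg$ratio_threshold),
           paste0("trans k: ", cfg$k, ", n_required: ", cfg$n_required),
           paste0("seed: ", cfg$seed))
  lp <- file.path(dir, "run_log.txt")
  writeLines(log, lp)
  invisible(c(paths, lp))
}

#' Load a fixture bundle written by \code{write_fixture_bundle}
#'
#' @param dir Bundle directory.
#' @return List with \code{map}, \code{samples}, \code{truth},
#'   \code{tads}, \code{manifest}.
#' @export
read_fixture_bundle <- function(dir) {
  map <- read_fragment_bed(file.path(dir, "fragments.bed"))
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  files <- sort(list.files(file.path(dir, "counts"), full.names = TRUE))
  samples <- lapply(files, read_count_table, map = map)
  names(samples) <- sub("\\.tsv$", "", basename(files))
  bid <- attr(samples[[1L]], "bait_fragment_id")
  attr(map, "bait_fragment_id") <- bid
  attr(map, "bait_name") <- manifest$bait
  truth <- utils::read.table(file.path(dir, "truth.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  tads <- read_tads(file.path(dir, "tads.bed"))
  # restore blind flags onto samples (map carries them)
  samples <- lapply(samples, function(s) {
    attr(s, "blind") <- map$blind; s
  })
  list(map = map, samples = samples, truth = truth, tads = tads,
       manifest = manifest)
}
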