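#' Configuration for the synthetic 4C data generator
#'
#' Describes a bait-anchored 4C study emulating the structure of the real
#' experiment: one cis chromosome carrying the bait, one trans chromosome,
#' two replicates for each of the four (diet, timepoint) conditions,
#' power-law distance decay of the mean signal, negative-binomial
#' overdispersion, and planted enriched cis fragments / trans window runs
#' with known fold effects.
#'
#' The mean model for a cis fragment at distance \code{d} bp from the bait
#' is \code{mean_rpkm(d) = decay_a * (d / 1000) ^ (-decay_alpha)}, with
#' the distance floored at 1 kb; trans fragments sit at a flat background
#' RPKM. Expected raw counts are
#' \code{mean_rpkm * fragment_kb * library_size / 1e6}, multiplied by the
#' planted fold where active, and drawn from a negative binomial with
#' \code{var = mu + dispersion * mu^2} (Poisson when \code{dispersion =
#' 0}).
#'
#' @param cis_length,n_cis_fragments Cis chromosome size and fragment
#'   count (defaults 5 Mb, 2000).
#' @param trans_length,n_trans_fragments Trans chromosome size and
#'   fragment count (defaults 2 Mb, 800).
#' @param bait_position Bait anchor on the cis chromosome (default: its
#'   midpoint).
#' @param decay_a RPKM of the decay law at 1 kb (default 20000; near-bait
#'   4C signal is orders of magnitude above distal background).
#' @param decay_alpha Power-law exponent (> 0; default 1).
#' @param dispersion Negative-binomial dispersion (default 0.05,
#'   replicate-level dispersion of a good 4C library).
#' @param library_size Nominal mapped reads per library (default 1e6).
#' @param trans_background_rpkm Flat trans background (default 0.5).
#' @param planted_cis Data frame \code{(offset, fold, conditions)}:
#'   fragment offset from the bait (fragments, signed), fold multiplier
#'   (> 1), and the conditions in which the effect is active
#'   (\code{"all"} or comma-separated \code{"CD_ZT6,HF_ZT18"} labels).
#'   Default: 20 fragments at fold 4 spread over both sides, active in
#'   every condition.
#' @param planted_trans Data frame \code{(start_fragment, n_fragments,
#'   fold, conditions)} in trans-fragment indices. Default: one run of
#'   120 fragments (six 20-fragment windows) at fold 8.
#' @param n_replicates,diets,timepoints Study design (defaults 2,
#'   CD/HF, ZT6/ZT18).
#' @param n_exclude Bait-proximal fragments excluded per side (default 2).
#' @param bait_name Name given to the synthetic bait.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(cis_length = 5e6, n_cis_fragments = 2000L,
                       trans_length = 2e6, n_trans_fragments = 800L,
                       bait_position = cis_length / 2,
                       decay_a = 20000, decay_alpha = 1,
                       dispersion = 0.05, library_size = 1e6,
                       trans_background_rpkm = 0.5,
                       planted_cis = default_planted_cis(),
                       planted_trans = default_planted_trans(),
                       n_replicates = 2L,
                       diets = c("CD", "HF"),
                       timepoints = c("ZT6", "ZT18"),
                       n_exclude = 2L,
                       bait_name = "SimBait") {
  if (decay_alpha <= 0) stop("decay_alpha must be > 0")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (!is.null(planted_cis) && nrow(planted_cis) &&
      any(planted_cis$fold <= 1))
    stop("planted folds must exceed 1")
  if (!is.null(planted_trans) && nrow(planted_trans) &&
      any(planted_trans$fold <= 1))
    stop("planted folds must exceed 1")
  structure(list(cis_chrom = "chrSimCis", cis_length = cis_length,
                 n_cis_fragments = as.integer(n_cis_fragments),
                 trans_chrom = "chrSimTrans", trans_length = trans_length,
                 n_trans_fragments = as.integer(n_trans_fragments),
                 bait_position = bait_position,
                 decay_a = decay_a, decay_alpha = decay_alpha,
                 dispersion = dispersion, library_size = library_size,
                 trans_background_rpkm = trans_background_rpkm,
                 planted_cis = planted_cis, planted_trans = planted_trans,
                 n_replicates = as.integer(n_replicates),
                 diets = diets, timepoints = timepoints,
                 n_exclude = as.integer(n_exclude),
                 bait_name = bait_name),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_planted_cis <- function() {
  off <- c(40L, 80L, 120L, 160L, 200L, 280L, 360L, 440L, 520L, 600L)
  data.frame(offset = c(off, -off), fold = 4, conditions = "all",
             stringsAsFactors = FALSE)
}

#' @rdname sim_config
#' @export
default_planted_trans <- function() {
  data.frame(start_fragment = 301L, n_fragments = 120L, fold = 8,
             conditions = "all", stringsAsFactors = FALSE)
}

#' Simulate a fragment map directly (no genome sequence)
#'
#' Draws \code{n_fragments - 1} distinct internal cut positions uniformly
#' on the chromosome, mimicking the spacing of a restriction digest
#' without generating sequence. All fragments are non-blind (at the
#' typical six-cutter fragment size a missing four-cutter site is
#' vanishingly rare).
#'
#' @param chrom Chromosome name.
#' @param length_bp Chromosome length.
#' @param n_fragments Number of fragments.
#' @param seed RNG seed.
#' @param first_id First fragment id (ids run consecutively).
#' @return A \code{fragment_map}.
#' @export
simulate_fragment_map <- function(chrom, length_bp, n_fragments, seed = 1L,
                                  first_id = 1L) {
  set.seed(seed)
  cuts <- sort(sample.int(length_bp - 1L, n_fragments - 1L))
  bounds <- c(0, cuts, length_bp)
  new_fragment_map(data.frame(
    chrom = chrom, start = bounds[-length(bounds)], end = bounds[-1L],
    fragment_id = seq.int(first_id, length.out = n_fragments),
    blind = FALSE, stringsAsFactors = FALSE))
}

#' Simulate a random genome with its expected digestion
#'
#' Uniform-composition random DNA in which enzyme motifs occur at their
#' background rate (\code{4^-motif_length} per position). The expected
#' fragment map is computed by this module's own position-by-position
#' naive scan, so it can serve as an independent oracle for
#' \code{\link{digest_genome}}.
#'
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param primary,secondary \code{enzyme_spec}s (defaults HindIII /
#'   Csp6I).
#' @param seed RNG seed (same seed, byte-identical output).
#' @return List with \code{genome} (named character vector) and
#'   \code{expected_map} (a \code{fragment_map} with blind flags).
#' @export
simulate_genome <- function(chrom_lengths = c(simA = 60000L, simB = 40000L),
                            primary = enzyme_registry("HindIII"),
                            secondary = enzyme_registry("Csp6I"),
                            seed = 1L) {
  set.seed(seed)
  genome <- vapply(chrom_lengths, function(n)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
    character(1L))
  pieces <- vector("list", length(genome))
  for (i in seq_along(genome)) {
    seq <- genome[i]; len <- nchar(seq)
    cuts <- naive_cut_scan(seq, primary$motif, primary$cut_offset)
    bounds <- sort(unique(c(0, cuts[cuts > 0 & cuts < len], len)))
    start <- bounds[-length(bounds)]; end <- bounds[-1L]
    sec0 <- naive_cut_scan(seq, secondary$motif, 0L)  # motif starts
    wid <- nchar(secondary$motif)
    blind <- vapply(seq_along(start), function(j)
      !any(sec0 >= start[j] & sec0 + wid <= end[j]), logical(1L))
    pieces[[i]] <- data.frame(chrom = names(genome)[i], start = start,
                              end = end, blind = blind,
                              stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, pieces)
  df$fragment_id <- seq_len(nrow(df))
  df <- df[, c("chrom", "start", "end", "fragment_id", "blind")]
  list(genome = genome,
       expected_map = new_fragment_map(df, primary = primary$name,
                                       secondary = secondary$name))
}

#' Naive motif scan (reference implementation)
#'
#' Checks every start offset of a sequence for an exact motif match and
#' returns 0-based cut positions (\code{motif start + cut_offset}).
#' Quadratic-minded and deliberately simple; used by
#' \code{\link{simulate_genome}} to produce digestion oracles.
#'
#' @param seq Character scalar DNA sequence.
#' @param motif Uppercase ACGT motif.
#' @param cut_offset Offset of the cut from the motif start.
#' @return Numeric vector of 0-based cut positions (motif starts when
#'   \code{cut_offset = 0}).
#' @export
naive_cut_scan <- function(seq, motif, cut_offset) {
  n <- nchar(seq); L <- nchar(motif)
  if (n < L) return(numeric(0))
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  mot <- strsplit(motif, "", fixed = TRUE)[[1L]]
  hit <- rep(TRUE, n - L + 1L)
  for (j in seq_len(L))
    hit <- hit & chars[j:(n - L + j)] == mot[j]
  (which(hit) - 1) + cut_offset
}

# condition label helper
.cond_label <- function(diet, timepoint) paste(diet, timepoint, sep = "_")

# labels (subset of all_labels) in which one planted element is active
.active_labels <- function(conditions, all_labels) {
  if (identical(conditions, "all")) return(all_labels)
  intersect(all_labels, trimws(strsplit(conditions, ",", fixed = TRUE)[[1L]]))
}

#' Build the combined cis + trans fragment map of a simulation
#'
#' @param config A \code{sim_config}.
#' @param seed RNG seed.
#' @return A \code{fragment_map} over the cis and trans chromosomes with
#'   the bait located.
#' @export
simulate_map <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  cis <- simulate_fragment_map(config$cis_chrom, config$cis_length,
                               config$n_cis_fragments, seed = seed)
  trans <- simulate_fragment_map(config$trans_chrom, config$trans_length,
                                 config$n_trans_fragments, seed = seed + 1L,
                                 first_id = config$n_cis_fragments + 1L)
  map <- new_fragment_map(rbind(as.data.frame(cis), as.data.frame(trans)))
  bait <- bait_config(config$bait_name, config$cis_chrom,
                      config$bait_position)
  locate_bait(map, bait)
}

#' Simulate 4C count libraries with planted interactions
#'
#' Draws one \code{sample_counts} per (diet, timepoint, replicate) cell
#' from the generative model described in \code{\link{sim_config}},
#' RPKM-normalizes each library against its realized total, and applies
#' the bait-proximal exclusion. Replicates are independent draws; planted
#' effects multiply the mean only in their active conditions; blind
#' fragments receive zero counts.
#'
#' @param map A \code{fragment_map} from \code{\link{simulate_map}} (bait
#'   located).
#' @param config The \code{sim_config}.
#' @param seed RNG seed; the full output is a pure function of
#'   \code{(config, seed)}.
#' @return List with \code{samples} (named list of \code{sample_counts},
#'   names like \code{"CD_ZT6_rep1"}) and \code{truth} (data frame of
#'   planted elements: \code{type}, \code{chrom}, \code{start},
#'   \code{end}, \code{fragment_id}, \code{fold}, \code{conditions}).
#' @export
simulate_counts <- function(map, config, seed = 1L) {
  stopifnot(inherits(map, "fragment_map"), inherits(config, "sim_config"))
  if (config$dispersion < 0) stop("invalid dispersion")
  bid <- bait_fragment(map)
  if (is.na(bid)) stop("bait not located on map")
  bait_row <- match(bid, map$fragment_id)
  bait_mid <- (map$start[bait_row] + map$end[bait_row]) / 2
  mid <- (map$start + map$end) / 2
  len_kb <- (map$end - map$start) / 1000
  is_cis <- map$chrom == config$cis_chrom
  d_kb <- pmax(abs(mid - bait_mid) / 1000, 1)
  base_rpkm <- ifelse(is_cis, config$decay_a * d_kb^(-config$decay_alpha),
                      config$trans_background_rpkm)
  base_mu <- base_rpkm * len_kb * config$library_size / 1e6

  # per-condition fold vectors
  conds <- as.vector(outer(config$diets, config$timepoints, .cond_label))
  fold <- matrix(1, nrow(map), length(conds), dimnames = list(NULL, conds))
  truth <- list()
  pc <- config$planted_cis
  if (!is.null(pc) && nrow(pc)) {
    rows <- match(bid + pc$offset, map$fragment_id)
    if (anyNA(rows)) stop("planted cis offset falls outside the map")
    for (i in seq_len(nrow(pc))) {
      act <- .active_labels(pc$conditions[i], conds)
      fold[rows[i], act] <- fold[rows[i], act] * pc$fold[i]
      truth[[length(truth) + 1L]] <- data.frame(
        type = "cis", chrom = map$chrom[rows[i]],
        start = map$start[rows[i]], end = map$end[rows[i]],
        fragment_id = map$fragment_id[rows[i]], fold = pc$fold[i],
        conditions = pc$conditions[i], stringsAsFactors = FALSE)
    }
  }
  pt <- config$planted_trans
  trans_rows <- which(!is_cis)
  if (!is.null(pt) && nrow(pt)) {
    for (i in seq_len(nrow(pt))) {
      run <- trans_rows[pt$start_fragment[i]:(pt$start_fragment[i] +
                                              pt$n_fragments[i] - 1L)]
      if (anyNA(run)) stop("planted trans run falls outside the map")
      act <- .active_labels(pt$conditions[i], conds)
      fold[run, act] <- fold[run, act] * pt$fold[i]
      truth[[length(truth) + 1L]] <- data.frame(
        type = "trans", chrom = map$chrom[run[1L]],
        start = map$start[run[1L]], end = map$end[run[length(run)]],
        fragment_id = NA_integer_, fold = pt$fold[i],
        conditions = pt$conditions[i], stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(type = character(0), chrom = character(0), start = numeric(0),
               end = numeric(0), fragment_id = integer(0), fold = numeric(0),
               conditions = character(0))

  set.seed(seed)
  samples <- list()
  for (diet in config$diets) for (tp in config$timepoints)
    for (rep in seq_len(config$n_replicates)) {
      lab <- .cond_label(diet, tp)
      mu <- base_mu * fold[, lab]
      raw <- if (config$dispersion < 1e-12) stats::rpois(length(mu), mu)
             else stats::rnbinom(length(mu), mu = mu,
                                 size = 1 / config$dispersion)
      raw[map$blind %in% TRUE] <- 0L
      df <- data.frame(fragment_id = map$fragment_id, chrom = map$chrom,
                       start = map$start, end = map$end, raw = raw,
                       rpkm = NA_real_, excluded = FALSE,
                       stringsAsFactors = FALSE)
      sc <- new_sample_counts(df,
        sample_id = paste0(lab, "_rep", rep), diet = diet, timepoint = tp,
        replicate = rep, bait_name = config$bait_name,
        total_mapped_reads = sum(raw), off_map_reads = 0L,
        blind = map$blind, bait_fragment_id = bid)
      sc <- normalize_rpkm(sc)
      sc <- exclude_bait_proximal(sc, config$n_exclude)
      samples[[paste0(lab, "_rep", rep)]] <- sc
    }
  list(samples = samples, truth = truth)
}

#' Write a complete synthetic fixture bundle
#'
#' Emits, under \code{dir}: a small demo genome FASTA with its
#' naive-scan fragment map (\code{genome.fa},
#' \code{genome_fragments.bed}); the count-level fragment map
#' (\code{fragments.bed}); one count TSV per library under
#' \code{counts/}; machine-readable planted truth (\code{truth.tsv},
#' plus \code{truth_cis.bed} / \code{truth_trans.bed}); synthetic TADs
#' (\code{tads.bed}: the bait TAD spans the planted region, flanked by
#' neighbours); and \code{manifest.yaml} recording the seed and
#' parameters. Byte-identical across re-runs with the same
#' \code{(config, seed)}.
#'
#' @param config A \code{sim_config}.
#' @param dir Output directory (created if needed).
#' @param seed Master seed.
#' @return Invisibly, a list with the map, samples, truth and file paths.
#' @export
write_fixture_bundle <- function(config = sim_config(), dir, seed = 1L) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create ", dir)
  sg <- simulate_genome(seed = seed)
  fa <- file.path(dir, "genome.fa")
  writeLines(paste0(">", names(sg$genome), "\n",
                    vapply(sg$genome, function(s)
                      paste(substring(s, seq(1, nchar(s), 70),
                                      pmin(seq(1, nchar(s), 70) + 69, nchar(s))),
                            collapse = "\n"), character(1L))), fa)
  write_fragment_bed(sg$expected_map, file.path(dir, "genome_fragments.bed"))

  map <- simulate_map(config, seed = seed)
  write_fragment_bed(map, file.path(dir, "fragments.bed"))
  sim <- simulate_counts(map, config, seed = seed)
  cdir <- file.path(dir, "counts")
  if (!dir.exists(cdir)) dir.create(cdir)
  for (nm in names(sim$samples))
    write_count_table(sim$samples[[nm]], file.path(cdir, paste0(nm, ".tsv")))

  tr <- sim$truth
  utils::write.table(tr, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (ty in c("cis", "trans")) {
    sub <- tr[tr$type == ty, , drop = FALSE]
    bed <- data.frame(sub$chrom, .fmt_bp(sub$start), .fmt_bp(sub$end),
                      paste0("planted_", ty, "_", seq_len(nrow(sub))),
                      sub$fold, ".")
    utils::write.table(bed, file.path(dir, paste0("truth_", ty, ".bed")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }

  half <- 1.5e6
  tads <- data.frame(
    chrom = config$cis_chrom,
    start = c(0, max(0, config$bait_position - half),
              min(config$bait_position + half, config$cis_length)),
    end = c(max(0, config$bait_position - half),
            min(config$bait_position + half, config$cis_length),
            config$cis_length),
    name = c("TAD_left", "TAD_bait", "TAD_right"))
  tads <- tads[tads$end > tads$start, ]
  utils::write.table(data.frame(tads$chrom, .fmt_bp(tads$start),
                                .fmt_bp(tads$end), tads$name),
                     file.path(dir, "tads.bed"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  manifest <- list(seed = as.integer(seed),
                   bait = config$bait_name,
                   cis_chrom = config$cis_chrom,
                   n_cis_fragments = config$n_cis_fragments,
                   trans_chrom = config$trans_chrom,
                   n_trans_fragments = config$n_trans_fragments,
                   decay = list(a = config$decay_a,
                                alpha = config$decay_alpha),
                   dispersion = config$dispersion,
                   library_size = config$library_size,
                   n_planted_cis = nrow(tr[tr$type == "cis", ]),
                   n_planted_trans = nrow(tr[tr$type == "trans", ]),
                   samples = names(sim$samples))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(list(map = map, samples = sim$samples, truth = sim$truth,
                 dir = dir))
}
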