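#' Restriction enzyme specification
#'
#' Defines a restriction enzyme by its recognition motif and the offset of
#' the cut position from the motif start. Only unambiguous, palindromic
#' recognition sites are supported: 4C digestion uses Type II enzymes whose
#' sites read identically on both strands, so a forward-strand scan finds
#' every cut.
#'
#' @param name Enzyme name, e.g. \code{"HindIII"}.
#' @param motif Recognition sequence, uppercase ACGT only (no IUPAC
#'   ambiguity codes).
#' @param cut_offset Bases from the motif start to the cut position
#'   (\code{0 <= cut_offset <= nchar(motif)}).
#' @return An object of class \code{"enzyme_spec"}.
#' @examples
#' restriction_enzyme("EcoRI", "GAATTC", 1L)
#' @export
restriction_enzyme <- function(name, motif, cut_offset) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(motif), length(motif) == 1L)
  if (!grepl("^[ACGT]+$", motif))
    stop("motif must contain only uppercase A, C, G, T: ", motif)
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0L || cut_offset > nchar(motif))
    stop("cut_offset must lie in [0, nchar(motif)]")
  if (!.is_palindromic(motif))
    stop("non-palindromic motif '", motif,
         "': reverse-strand sites would be missed by a forward-strand scan")
  structure(list(name = name, motif = motif, cut_offset = cut_offset),
            class = "enzyme_spec")
}

.is_palindromic <- function(motif) {
  comp <- chartr("ACGT", "TGCA", motif)
  rc <- paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
  identical(rc, motif)
}

#' Built-in enzyme registry
#'
#' Canonical REBASE specificities for the enzymes used in liver 4C-seq
#' designs: HindIII (A^AGCTT), EcoRI (G^AATTC) as primary six-cutters and
#' Csp6I (G^TAC) as the secondary four-cutter.
#'
#' @param name Optional enzyme name; if missing, the full registry (a named
#'   list) is returned.
#' @return An \code{enzyme_spec}, or a named list of them.
#' @examples
#' enzyme_registry("HindIII")
#' names(enzyme_registry())
#' @export
enzyme_registry <- function(name) {
  reg <- list(
    HindIII = restriction_enzyme("HindIII", "AAGCTT", 1L),
    EcoRI   = restriction_enzyme("EcoRI",   "GAATTC", 1L),
    Csp6I   = restriction_enzyme("Csp6I",   "GTAC",   1L)
  )
  if (missing(name)) return(reg)
  if (!name %in% names(reg)) stop("unknown enzyme: ", name)
  reg[[name]]
}

#' @export
print.enzyme_spec <- function(x, ...) {
  cut <- paste0(substr(x$motif, 1L, x$cut_offset), "^",
                substr(x$motif, x$cut_offset + 1L, nchar(x$motif)))
  cat("Restriction enzyme", x$name, "(", cut, ")\n")
  invisible(x)
}

#' Bait (viewpoint) configuration
#'
#' Describes one 4C bait: its genomic anchor, the enzyme pair used for the
#' experiment, the z-score threshold for significance and the size of the
#' cis analysis window around the bait.
#'
#' @param name Bait name (e.g. \code{"Dbp"}, \code{"Pparg2"},
#'   \code{"Ppara"}, \code{"Srebp1c"}).
#' @param chrom Chromosome carrying the bait.
#' @param position 0-based genomic position of the bait anchor.
#' @param primary_enzyme,secondary_enzyme \code{enzyme_spec} objects (or
#'   registry names). Defaults: HindIII / Csp6I.
#' @param z_threshold z-score significance threshold. The default 2.0 is
#'   used for all baits except Srebp1c, which uses 1.5.
#' @param fdr_threshold BH-adjusted p-value threshold (default 0.05).
#' @param window_bp Half-width of the symmetric cis analysis window around
#'   the bait, in bp (default 2 Mb).
#' @return An object of class \code{"bait_config"}.
#' @examples
#' bait_config("Dbp", "chr7", 45000000)
#' bait_config("Srebp1c", "chr11", 60000000, z_threshold = 1.5)
#' @export
bait_config <- function(name, chrom, position,
                        primary_enzyme = enzyme_registry("HindIII"),
                        secondary_enzyme = enzyme_registry("Csp6I"),
                        z_threshold = 2.0, fdr_threshold = 0.05,
                        window_bp = 2e6L) {
  if (is.character(primary_enzyme))
    primary_enzyme <- enzyme_registry(primary_enzyme)
  if (is.character(secondary_enzyme))
    secondary_enzyme <- enzyme_registry(secondary_enzyme)
  stopifnot(inherits(primary_enzyme, "enzyme_spec"),
            inherits(secondary_enzyme, "enzyme_spec"))
  position <- as.numeric(position)
  if (position < 0) stop("bait position must be >= 0")
  if (z_threshold <= 0) stop("z_threshold must be > 0")
  if (window_bp <= 0) stop("window_bp must be > 0")
  structure(list(name = name, chrom = chrom, position = position,
                 primary_enzyme = primary_enzyme,
                 secondary_enzyme = secondary_enzyme,
                 z_threshold = z_threshold, fdr_threshold = fdr_threshold,
                 window_bp = as.numeric(window_bp)),
            class = "bait_config")
}

#' @export
print.bait_config <- function(x, ...) {
  cat("4C bait", x$name, "at", x$chrom, ":", format(x$position, big.mark = ","),
      "\n  enzymes:", x$primary_enzyme$name, "/", x$secondary_enzyme$name,
      "\n  thresholds: z >=", x$z_threshold, ", FDR <=", x$fdr_threshold,
      "\n  window: +/-", format(x$window_bp, big.mark = ","), "bp\n")
  invisible(x)
}
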