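#' In-silico digestion of a genome
#'
#' Cuts every chromosome at each occurrence of the enzyme's recognition
#' motif (cut position = motif start + \code{cut_offset}) and returns the
#' resulting restriction fragments, which tile each chromosome without gaps
#' or overlaps. This fragment grid is the coordinate system all downstream
#' 4C counts live on. Overlapping motif occurrences are found (every start
#' offset is scanned).
#'
#' Coordinates are 0-based, half-open (BED convention).
#'
#' @param genome Named character vector of chromosome sequences, a
#'   \code{Biostrings::DNAStringSet}, or a path to a FASTA file.
#' @param enzyme An \code{enzyme_spec} (see \code{\link{restriction_enzyme}}).
#' @return A \code{fragment_map}: a data frame with columns \code{chrom},
#'   \code{start}, \code{end}, \code{fragment_id} (strictly increasing in
#'   coordinate order), \code{blind} (all \code{NA} until
#'   \code{\link{flag_blind_fragments}} is applied).
#' @examples
#' digest_genome(c(chrA = "CCGAATTCAAGAATTCGG"), enzyme_registry("EcoRI"))
#' @seealso \code{\link{flag_blind_fragments}}, \code{\link{locate_bait}}
#' @export
digest_genome <- function(genome, enzyme) {
  stopifnot(inherits(enzyme, "enzyme_spec"))
  genome <- .as_genome(genome)
  if (length(genome) == 0L) stop("genome is empty")
  pieces <- vector("list", length(genome))
  for (i in seq_along(genome)) {
    chrom <- names(genome)[i]
    len <- Biostrings::width(genome)[i]
    if (len == 0L) stop("empty chromosome: ", chrom)
    cuts <- .cut_positions(genome[[i]], enzyme)
    bounds <- unique(c(0, cuts[cuts > 0 & cuts < len], len))
    bounds <- sort(bounds)
    pieces[[i]] <- data.frame(
      chrom = chrom,
      start = bounds[-length(bounds)],
      end = bounds[-1L],
      stringsAsFactors = FALSE)
  }
  frags <- do.call(rbind, pieces)
  frags$fragment_id <- seq_len(nrow(frags))
  frags$blind <- NA
  new_fragment_map(frags, primary = enzyme$name)
}

# all cut positions on one chromosome (DNAString), 0-based
.cut_positions <- function(seq, enzyme) {
  m <- Biostrings::matchPattern(enzyme$motif, seq)
  if (length(m) == 0L) return(numeric(0))
  as.numeric(Biostrings::start(m)) - 1 + enzyme$cut_offset
}

.as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
  } else if (is.character(genome) && length(genome) == 1L &&
             !grepl("^[ACGTNacgtn]+$", genome) && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  } else if (is.character(genome)) {
    if (is.null(names(genome)) || anyNA(names(genome)))
      stop("genome character vector must be named by chromosome")
    genome <- Biostrings::DNAStringSet(genome)
  } else stop("unsupported genome input")
  genome
}

new_fragment_map <- function(df, primary = NA_character_,
                             secondary = NA_character_,
                             bait_fragment_id = NA_integer_,
                             bait_name = NA_character_) {
  structure(df,
            primary_enzyme = primary, secondary_enzyme = secondary,
            bait_fragment_id = bait_fragment_id, bait_name = bait_name,
            class = c("fragment_map", "data.frame"))
}

#' @export
print.fragment_map <- function(x, ...) {
  cat("Restriction fragment map:", nrow(x), "fragments on",
      length(unique(x$chrom)), "chromosome(s)\n")
  if (!is.na(attr(x, "primary_enzyme")))
    cat("  primary enzyme:", attr(x, "primary_enzyme"), "\n")
  if (!all(is.na(x$blind)))
    cat("  blind fragments:", sum(x$blind), "\n")
  bid <- attr(x, "bait_fragment_id")
  if (!is.na(bid))
    cat("  bait", attr(x, "bait_name"), "in fragment", bid, "\n")
  NextMethod()
}

#' Flag blind fragments
#'
#' A primary-enzyme fragment is \emph{blind} when it contains no secondary
#' enzyme site: the nested re-digestion/ligation cannot produce a valid 4C
#' product from it, so it yields no usable signal. Flags each fragment by
#' testing whether a complete secondary motif occurrence lies within it;
#' coordinates are unchanged.
#'
#' @param map A \code{fragment_map} from \code{\link{digest_genome}}.
#' @param genome The same genome the map was digested from.
#' @param secondary \code{enzyme_spec} for the secondary (four-cutter) enzyme.
#' @return The map with the \code{blind} column filled.
#' @export
flag_blind_fragments <- function(map, genome, secondary) {
  stopifnot(inherits(map, "fragment_map"), inherits(secondary, "enzyme_spec"))
  genome <- .as_genome(genome)
  chroms <- unique(map$chrom)
  if (!all(chroms %in% names(genome)))
    stop("fragment map references chromosomes absent from genome: ",
         paste(setdiff(chroms, names(genome)), collapse = ", "))
  wid <- nchar(secondary$motif)
  map$blind <- TRUE
  for (chrom in chroms) {
    idx <- which(map$chrom == chrom)
    len <- Biostrings::width(genome)[match(chrom, names(genome))]
    if (max(map$end[idx]) != len)
      stop("fragment map does not match genome on ", chrom)
    m <- Biostrings::matchPattern(secondary$motif, genome[[chrom]])
    if (length(m) == 0L) next
    ms <- as.numeric(Biostrings::start(m)) - 1   # 0-based motif starts
    # motif [ms, ms + wid) fully inside fragment [start, end)
    hit <- findInterval(ms, map$start[idx])       # fragment rank of motif start
    ok <- hit >= 1L & (ms + wid) <= map$end[idx][pmax(hit, 1L)]
    map$blind[idx[unique(hit[ok])]] <- FALSE
  }
  attr(map, "secondary_enzyme") <- secondary$name
  map
}

#' Locate the bait fragment
#'
#' Marks the unique fragment containing the bait position
#' (\code{start <= position < end}) on the bait chromosome.
#'
#' @param map A \code{fragment_map}.
#' @param bait A \code{bait_config}.
#' @return The map with attributes \code{bait_fragment_id} and
#'   \code{bait_name} set (query with \code{\link{bait_fragment}}).
#' @export
locate_bait <- function(map, bait) {
  stopifnot(inherits(map, "fragment_map"), inherits(bait, "bait_config"))
  idx <- which(map$chrom == bait$chrom)
  if (length(idx) == 0L)
    stop("bait chromosome ", bait$chrom, " not present in fragment map")
  if (bait$position < min(map$start[idx]) || bait$position >= max(map$end[idx]))
    stop("bait position ", bait$position, " outside ", bait$chrom, " bounds")
  k <- findInterval(bait$position, map$start[idx])
  fid <- map$fragment_id[idx[k]]
  stopifnot(map$start[idx[k]] <= bait$position, bait$position < map$end[idx[k]])
  attr(map, "bait_fragment_id") <- as.integer(fid)
  attr(map, "bait_name") <- bait$name
  map
}

#' Bait fragment id of a map
#' @param map A \code{fragment_map}.
#' @return Integer fragment id, or \code{NA} if no bait has been located.
#' @export
bait_fragment <- function(map) attr(map, "bait_fragment_id")

#' Write / read a fragment map as BED-like TSV
#'
#' Six columns: chrom, start, end, fragment_id, blind (0/1, \code{.} when
#' unset), strand (always \code{.}). No header.
#'
#' @param map A \code{fragment_map}.
#' @param path Output file.
#' @return \code{write_fragment_bed} returns \code{path} invisibly;
#'   \code{read_fragment_bed} returns a \code{fragment_map}.
#' @export
write_fragment_bed <- function(map, path) {
  blind <- ifelse(is.na(map$blind), ".", as.integer(map$blind))
  out <- data.frame(map$chrom, format(map$start, scientific = FALSE, trim = TRUE),
                    format(map$end, scientific = FALSE, trim = TRUE),
                    map$fragment_id, blind, ".")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_fragment_bed
#' @export
read_fragment_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end",
                                        "fragment_id", "blind", "strand"),
                          colClasses = c("character", "numeric", "numeric",
                                         "integer", "character", "character"))
  blind <- ifelse(df$blind == ".", NA, df$blind == "1")
  new_fragment_map(data.frame(chrom = df$chrom, start = df$start,
                              end = df$end, fragment_id = df$fragment_id,
                              blind = blind, stringsAsFactors = FALSE))
}

# internal consistency check used after digestion
.check_tiling <- function(map, genome) {
  genome <- .as_genome(genome)
  for (chrom in unique(map$chrom)) {
    idx <- which(map$chrom == chrom)
    len <- Biostrings::width(genome)[match(chrom, names(genome))]
    if (sum(map$end[idx] - map$start[idx]) != len)
      stop("tiling violated on ", chrom)
  }
  invisible(TRUE)
}
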