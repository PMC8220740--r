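#' Oriented genomic intervals
#'
#' Intervals are plain data frames with columns `contig`, `strand`
#' (`"+"`/`"-"`), `start`, `end`. Coordinates are 0-based half-open
#' throughout the package; on-disk GFF3 is 1-based inclusive and BED is
#' 0-based half-open, and the readers/writers do the conversion. For
#' circular contigs an interval that crosses the origin is stored with
#' `end > contig length`; positions are interpreted modulo the length.
#'
#' @param contig contig identifier(s).
#' @param strand `"+"` or `"-"`.
#' @param start,end 0-based half-open bounds, `start < end`.
#' @return a data.frame of class `oriented_interval` with one row per input.
#' @export
oriented_interval <- function(contig, strand, start, end) {
  n <- max(length(contig), length(strand), length(start), length(end))
  iv <- data.frame(
    contig = rep_len(as.character(contig), n),
    strand = rep_len(as.character(strand), n),
    start = rep_len(as.numeric(start), n),
    end = rep_len(as.numeric(end), n),
    stringsAsFactors = FALSE
  )
  if (!all(iv$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  if (any(!is.finite(iv$start) | !is.finite(iv$end) | iv$start >= iv$end)) {
    stop("intervals require finite start < end")
  }
  class(iv) <- c("oriented_interval", "data.frame")
  iv
}

interval_length <- function(iv) iv$end - iv$start

#' Overlap length of two oriented intervals
#'
#' Returns the length (nt) of the intersection of two intervals on the same
#' contig; 0 if disjoint (half-open intervals that merely touch do not
#' overlap) or if `require_same_strand` and the strands differ.
#'
#' @param a,b single-row oriented intervals (or lists with
#'   `contig`/`strand`/`start`/`end`).
#' @param require_same_strand if `TRUE` (default) strand mismatch gives 0.
#' @return overlap length in nt.
#' @export
interval_overlap <- function(a, b, require_same_strand = TRUE) {
  if (a$contig != b$contig) {
    stop("interval_overlap: intervals on different contigs ('",
         a$contig, "' vs '", b$contig, "')")
  }
  if (require_same_strand && a$strand != b$strand) return(0)
  max(0, min(a$end, b$end) - max(a$start, b$start))
}

# vectorized overlap of one query interval against a table of intervals,
# modulo genome length when wrapping intervals are present (end > len)
overlap_many <- function(start, end, tbl, genome_len = NULL) {
  if (nrow(tbl) == 0) return(numeric(0))
  qs <- split_wrapped(start, end, genome_len)
  parts <- split_wrapped(tbl$start, tbl$end, genome_len)
  total <- numeric(nrow(tbl))
  for (qi in seq_len(nrow(qs))) {
    ov <- pmax(0, pmin(qs$end[qi], parts$end) - pmax(qs$start[qi], parts$start))
    hit <- ov > 0
    if (any(hit)) {
      agg <- tapply(ov[hit], parts$idx[hit], sum)
      total[as.integer(names(agg))] <- total[as.integer(names(agg))] + as.numeric(agg)
    }
  }
  total
}

# split possibly wrapped [start,end) (end may exceed genome_len) into linear
# parts; returns data.frame(start, end, idx)
split_wrapped <- function(start, end, genome_len = NULL) {
  idx <- seq_along(start)
  if (is.null(genome_len)) {
    return(data.frame(start = start, end = end, idx = idx))
  }
  wraps <- end > genome_len
  out <- data.frame(
    start = c(start[!wraps], start[wraps], rep(0, sum(wraps))),
    end = c(end[!wraps], rep(genome_len, sum(wraps)), end[wraps] - genome_len),
    idx = c(idx[!wraps], idx[wraps], idx[wraps])
  )
  out
}

#' Reconstruct sequencing fragments from read pairs
#'
#' Emulates insert fill-in for paired-end data: the fragment spans from the
#' leftmost mate start to the rightmost mate end. Strand is taken from the
#' first mate by default (`strand_from = "mate1"`), or from the second.
#'
#' @param mate1,mate2 oriented intervals with equal row counts.
#' @param strand_from `"mate1"` or `"mate2"`; which mate's orientation the
#'   fragment inherits.
#' @return oriented intervals, one fragment per pair.
#' @export
fragments_from_pairs <- function(mate1, mate2, strand_from = c("mate1", "mate2")) {
  strand_from <- match.arg(strand_from)
  if (nrow(mate1) != nrow(mate2)) stop("mate tables must have equal rows")
  bad <- which(mate1$contig != mate2$contig)
  if (length(bad)) {
    stop("mates on different contigs for pair(s): ",
         paste(head(bad, 5), collapse = ", "))
  }
  oriented_interval(
    contig = mate1$contig,
    strand = if (strand_from == "mate1") mate1$strand else mate2$strand,
    start = pmin(mate1$start, mate2$start),
    end = pmax(mate1$end, mate2$end)
  )
}
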