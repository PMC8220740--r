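#' Genome record
#'
#' A single contig with its sequence and replication geometry. Sequences are
#' DNA-alphabet uppercase (`A/C/G/T`, `N` allowed and flagged); `U` is
#' normalized to `T` at parse time. `origin_hint`/`terminus_hint`, when set,
#' are 0-based positions of the replication origin/terminus and take
#' precedence over skew-based estimation in [estimate_replichores()].
#'
#' @param contig_id contig name.
#' @param sequence character scalar over A/C/G/T/N (U accepted, converted).
#' @param circular is the contig circular?
#' @param origin_hint,terminus_hint optional 0-based positions in
#'   `[0, length)`.
#' @return a `genome_record` (list with fields above plus `length`,
#'   `has_n`).
#' @export
genome_record <- function(contig_id, sequence, circular = FALSE,
                          origin_hint = NULL, terminus_hint = NULL) {
  sequence <- chartr("u", "U", toupper(sequence))
  sequence <- chartr("U", "T", sequence)
  if (nchar(sequence) == 0) stop("empty sequence for contig '", contig_id, "'")
  bad <- regexpr("[^ACGTN]", sequence)
  if (bad > 0) {
    stop("illegal character '", substr(sequence, bad, bad),
         "' at position ", bad, " of contig '", contig_id, "'")
  }
  len <- nchar(sequence)
  for (h in list(origin_hint, terminus_hint)) {
    if (!is.null(h) && (h < 0 || h >= len)) {
      stop("origin/terminus hint outside [0, length)")
    }
  }
  structure(
    list(contig_id = contig_id, sequence = sequence, length = len,
         circular = circular, has_n = grepl("N", sequence, fixed = TRUE),
         origin_hint = origin_hint, terminus_hint = terminus_hint),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat("<genome_record> ", x$contig_id, ": ", x$length, " nt, ",
      if (x$circular) "circular" else "linear",
      if (x$has_n) ", contains N" else "", "\n", sep = "")
  invisible(x)
}

#' Read genome sequences from FASTA
#'
#' @param path FASTA file (plain text). May contain several records.
#' @param circular logical, recycled over records.
#' @return list of [genome_record()]s, in file order.
#' @export
read_genome_fasta <- function(path, circular = FALSE) {
  seqs <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("failed to read FASTA '", path, "': ",
                             conditionMessage(e))
  )
  if (length(seqs) == 0) stop("FASTA file '", path, "' contains no records")
  circular <- rep_len(circular, length(seqs))
  ids <- sub("\\s.*$", "", names(seqs))
  lapply(seq_along(seqs), function(i) {
    genome_record(ids[i], as.character(seqs[[i]]), circular = circular[i])
  })
}

#' Write genome records (or any named sequences) to FASTA
#'
#' @param records list of `genome_record`s, or a named character vector of
#'   sequences.
#' @param path output file.
#' @export
write_fasta <- function(records, path) {
  if (is.list(records) && length(records) &&
      inherits(records[[1]], "genome_record")) {
    seqs <- vapply(records, `[[`, "", "sequence")
    names(seqs) <- vapply(records, `[[`, "", "contig_id")
  } else {
    seqs <- records
  }
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read CDS (or other) features from GFF3
#'
#' On-disk GFF3 coordinates are 1-based inclusive; internally features are
#' 0-based half-open, so disk `1001..2000` becomes `[1000, 2000)`.
#'
#' @param path GFF3 file.
#' @param kind_filter feature types to keep (default `"CDS"`).
#' @return data.frame with columns `feature_id`, `contig`, `strand`,
#'   `start`, `end`, `kind`.
#' @export
read_cds_gff3 <- function(path, kind_filter = "CDS") {
  gr <- rtracklayer::import(path, format = "gff3")
  kind <- as.character(gr$type)
  keep <- kind %in% kind_filter
  gr <- gr[keep]
  kind <- kind[keep]
  strands <- as.character(GenomicRanges::strand(gr))
  if (any(!strands %in% c("+", "-"))) {
    stop("unknown strand symbol in '", path, "' (only +/- supported)")
  }
  ids <- as.character(gr$ID)
  if (length(ids) == 0 || all(is.na(ids))) ids <- rep(NA_character_, length(gr))
  ids[is.na(ids)] <- paste0("feature_", which(is.na(ids)))
  feats <- data.frame(
    feature_id = ids,
    contig = as.character(GenomicRanges::seqnames(gr)),
    strand = strands,
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    kind = kind,
    stringsAsFactors = FALSE
  )
  if (any(feats$start >= feats$end)) stop("GFF3 row with start > end in '", path, "'")
  rownames(feats) <- NULL
  feats
}

#' Write features to GFF3
#'
#' @param features data.frame as returned by [read_cds_gff3()].
#' @param path output file.
#' @param source source field (column 2).
#' @export
write_gff3 <- function(features, path, source = "srnakit") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(features)) {
    lines <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                     features$contig, source, features$kind,
                     as.integer(features$start + 1L), as.integer(features$end),
                     features$strand, features$feature_id)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read/write the strand-split bedGraph coverage dialect
#'
#' Coverage is exchanged as 4-column bedGraph (`contig`, `start`, `end`,
#' `depth`; 0-based half-open runs), one file per strand per replicate.
#'
#' @param path bedGraph file.
#' @param genome the [genome_record()] the track belongs to.
#' @param strand `"+"`/`"-"` of this track.
#' @param replicate_id,library_id track labels.
#' @return a `coverage_track` (see [coverage_track()]).
#' @export
read_coverage_bedgraph <- function(path, genome, strand,
                                   replicate_id = NA, library_id = NA) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("contig", "start", "end", "depth"),
                   colClasses = c("character", "integer", "integer", "numeric"))
  depth <- numeric(genome$length)
  for (i in seq_len(nrow(df))) {
    if (df$end[i] > genome$length) stop("bedGraph run exceeds contig length")
    if (df$start[i] < df$end[i]) {
      depth[(df$start[i] + 1):df$end[i]] <- df$depth[i]
    }
  }
  coverage_track(genome$contig_id, strand, depth,
                 replicate_id = replicate_id, library_id = library_id)
}

#' @rdname read_coverage_bedgraph
#' @param track a `coverage_track`.
#' @export
write_coverage_bedgraph <- function(track, path) {
  d <- track$depth
  r <- rle(d)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0
  df <- data.frame(contig = track$contig, start = starts[keep],
                   end = ends[keep], depth = r$values[keep])
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export sRNA candidates as BED6
#'
#' Score column is the candidate's mean CPM times 10, rounded (capped at
#' 1000 as BED requires).
#'
#' @param candidates candidate table with `contig`, `start`, `end`,
#'   `strand`, `id`, and optionally `mean_cpm` columns.
#' @param path output file.
#' @export
write_bed6 <- function(candidates, path) {
  cpm <- candidates$mean_cpm %||% rep(0, nrow(candidates))
  score <- pmin(1000L, as.integer(round(cpm * 10)))
  df <- data.frame(candidates$contig, as.integer(candidates$start),
                   as.integer(candidates$end),
                   candidates$id %||% sprintf("srna_%04d", seq_len(nrow(candidates))),
                   score, candidates$strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read/write feature-by-sample count tables as TSV
#'
#' @param table a `count_table` (see [count_features()]).
#' @param path file path.
#' @export
write_count_tsv <- function(table, path) {
  df <- data.frame(feature_id = rownames(table$counts), table$counts,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_tsv
#' @export
read_count_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1]]
  storage.mode(counts) <- "integer"
  list(counts = counts, lib_sizes = colSums(counts),
       norm_factors = rep(1, ncol(counts)))
}
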