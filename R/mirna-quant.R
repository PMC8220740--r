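#' Filter and deduplicate raw short-RNA reads
#'
#' Applies the read-level filter rules of the quantification pipeline:
#' reads shorter than `min_len` nt, reads containing any `N`, and reads
#' whose 3' adapter was not found are removed; survivors are collapsed to
#' one record per distinct sequence (`count = 1`, the raw multiplicity kept
#' in `raw_count` for diagnostics) and finally restricted to the
#' `size_range` length window (15-34 nt inclusive by default).
#'
#' @param reads data.frame with `sequence` and optionally `count`
#'   (multiplicities of already-collapsed input).
#' @param has_adapter logical vector (recycled): was a 3' adapter found by
#'   upstream trimming? Defaults to all-`TRUE` for pre-trimmed input.
#' @param min_len minimum raw read length (default 10).
#' @param size_range inclusive length window applied after dedup.
#' @return data.frame with `sequence`, `count` (all 1), `raw_count`.
#'   Warns (not errors) when nothing survives.
#' @export
preprocess_reads <- function(reads, has_adapter = TRUE, min_len = 10,
                             size_range = c(15, 34)) {
  if (is.character(reads)) reads <- data.frame(sequence = reads)
  cnt <- reads$count %||% rep(1L, nrow(reads))
  has_adapter <- rep_len(has_adapter, nrow(reads))
  seqs <- toupper(reads$sequence)
  seqs <- chartr("U", "T", seqs)
  keep <- nchar(seqs) >= min_len & !grepl("N", seqs, fixed = TRUE) & has_adapter
  seqs <- seqs[keep]
  cnt <- cnt[keep]
  if (length(seqs)) {
    raw <- tapply(cnt, seqs, sum)
    out <- data.frame(sequence = names(raw), count = 1L,
                      raw_count = as.integer(raw), stringsAsFactors = FALSE)
  } else {
    out <- data.frame(sequence = character(0), count = integer(0),
                      raw_count = integer(0))
  }
  len <- nchar(out$sequence)
  out <- out[len >= size_range[1] & len <= size_range[2], , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0) warning("no reads survived preprocessing")
  out
}

#' Build a 3'-cropped exact-match reference library
#'
#' Each pool species is cropped by `x` nt from its 3' end; species whose
#' cropped sequence collides with any other species' cropped sequence at
#' this level are excluded, so the remaining entries map one-to-one onto
#' parent species.
#'
#' @param pool a `reference_pool` (`name`, `sequence`).
#' @param x crop level, 0-5.
#' @return a `cropped_library`: list with `x`, `entries` (named character:
#'   cropped sequence -> parent name), `excluded` (ambiguous species names).
#' @export
build_cropped_reference <- function(pool, x) {
  if (x < 0 || x > 5) stop("crop level x must be in 0..5")
  lens <- nchar(pool$sequence)
  if (any(lens <= x)) stop("crop level ", x, " >= length of some species")
  cropped <- substr(pool$sequence, 1, lens - x)
  dup <- cropped %in% cropped[duplicated(cropped)]
  entries <- setNames(pool$name[!dup], cropped[!dup])
  structure(
    list(x = x, entries = entries, excluded = pool$name[dup]),
    class = "cropped_library"
  )
}

#' Count reads against nested cropped-reference libraries by exact match
#'
#' Each read is assigned to a species at the smallest crop level `x` at
#' which its sequence exactly equals a level-`x` library entry; no
#' mismatches are tolerated at any level. Counts accumulate read
#' multiplicities; both the deduplicated (`count`) and raw (`raw_count`)
#' weightings are tallied. Reads matching no level are reported as
#' unassigned.
#'
#' @param reads output of [preprocess_reads()] (or any data.frame with
#'   `sequence`, `count`, optionally `raw_count`).
#' @param libraries list of [build_cropped_reference()] results at
#'   consecutive levels 0, 1, ..., built from one pool.
#' @param pool the `reference_pool` the libraries came from.
#' @return a `species_counts`: list with matrices `counts` and `raw_counts`
#'   (species x level), `totals` per level, `unassigned` and
#'   `unassigned_raw` read mass.
#' @export
count_exact <- function(reads, libraries, pool) {
  levels_x <- vapply(libraries, `[[`, 0, "x")
  if (!identical(as.integer(levels_x), seq_along(libraries) - 1L)) {
    stop("libraries must be at consecutive crop levels starting at 0")
  }
  n <- nrow(pool)
  cn <- paste0("x", levels_x)
  counts <- matrix(0L, n, length(libraries), dimnames = list(pool$name, cn))
  raw_counts <- counts
  rc <- reads$raw_count %||% reads$count
  remaining <- seq_len(nrow(reads))
  for (li in seq_along(libraries)) {
    lib <- libraries[[li]]
    hit <- match(reads$sequence[remaining], names(lib$entries))
    got <- !is.na(hit)
    if (any(got)) {
      sp <- lib$entries[hit[got]]
      idx <- remaining[got]
      counts[, li] <- counts[, li] +
        as.integer(rowsum_by(reads$count[idx], sp, pool$name))
      raw_counts[, li] <- raw_counts[, li] +
        as.integer(rowsum_by(rc[idx], sp, pool$name))
      remaining <- remaining[!got]
    }
  }
  structure(
    list(counts = counts, raw_counts = raw_counts,
         totals = colSums(counts), raw_totals = colSums(raw_counts),
         unassigned = sum(reads$count[remaining]),
         unassigned_raw = sum(rc[remaining]),
         pool_size = n),
    class = "species_counts"
  )
}

rowsum_by <- function(x, group, all_levels) {
  agg <- tapply(x, factor(group, levels = all_levels), sum)
  agg[is.na(agg)] <- 0
  agg
}

#' Cumulative fraction of species detected by crop level
#'
#' At level `x` a species counts as detected if its summed counts over
#' levels `0..x` reach `min_cpm` counts per million of the total assigned
#' mass. The detected fraction is non-decreasing in `x`: cropping the
#' reference recovers species whose reads are 3'-truncated.
#'
#' @param counts a `species_counts`.
#' @param min_cpm detection threshold in CPM (default 1).
#' @param weighting `"raw"` (multiplicity-weighted, default) or `"dedup"`.
#' @return data.frame with `x` and `detected_fraction`.
#' @export
species_detection_by_crop <- function(counts, min_cpm = 1,
                                      weighting = c("raw", "dedup")) {
  weighting <- match.arg(weighting)
  m <- if (weighting == "raw") counts$raw_counts else counts$counts
  total <- sum(m)
  cum <- t(apply(m, 1, cumsum))
  if (total == 0) {
    frac <- rep(0, ncol(m))
  } else {
    cpm <- cum / total * 1e6
    frac <- colSums(cpm >= min_cpm) / counts$pool_size
  }
  data.frame(x = seq_len(ncol(m)) - 1L, detected_fraction = frac)
}

#' Fold-deviation from the equimolar expectation
#'
#' For each species, `log2(observed share / expected share)` where the
#' expected share is `1/pool_size`. Species are included in the unbiased
#' fraction when they meet the CPM inclusion rule (at least `min_cpm` CPM
#' in every library when `counts` is a matrix with one column per library;
#' a single vector degenerates to the one-library rule). A species within
#' `fold_bound` log2-folds of expectation (default 1, i.e. within two fold)
#' counts as unbiased. Zero-count species are excluded from deviations and
#' reported separately.
#'
#' @param counts numeric vector (one library) or matrix (species x
#'   libraries) of per-species counts, e.g. cumulative counts through a
#'   chosen crop level.
#' @param pool_size number of species in the pool.
#' @param min_cpm inclusion threshold (CPM in each library), default 1.
#' @param fold_bound unbiasedness bound on |log2 deviation|, default 1.
#' @return list with `deviation` (per species, per library; NA for
#'   excluded), `included` (logical), `unbiased_fraction` (per library),
#'   `absent` (names/indices with zero counts anywhere).
#' @export
fold_deviation <- function(counts, pool_size, min_cpm = 1, fold_bound = 1) {
  m <- as.matrix(counts)
  if (sum(m) == 0) stop("no assigned counts")
  totals <- colSums(m)
  if (any(totals == 0)) stop("a library has no assigned counts")
  share <- sweep(m, 2, totals, "/")
  dev <- log2(share * pool_size)
  dev[m == 0] <- NA
  cpm <- sweep(m, 2, totals, "/") * 1e6
  included <- rowSums(cpm >= min_cpm) == ncol(m)
  unbiased <- vapply(seq_len(ncol(m)), function(j) {
    d <- dev[included, j]
    mean(abs(d) <= fold_bound)
  }, 0)
  list(
    deviation = dev,
    included = included,
    unbiased_fraction = unbiased,
    absent = rownames(m)[rowSums(m == 0) > 0] %||%
      which(rowSums(m == 0) > 0)
  )
}

#' Rank 3'-adapter sequence variants and build a position frequency matrix
#'
#' Reads demultiplexed by adapter variant (bases at the three variable 5'
#' positions of the 3' adapter) are tallied; the top `k` variants by read
#' count (ties broken lexicographically) are reported together with an
#' unweighted per-position base-frequency matrix over those top variants,
#' as used for a sequence logo.
#'
#' @param variants character vector of 3-base variant tags per read (or per
#'   aggregated record).
#' @param counts read counts per record (default 1 each).
#' @param k how many top variants to keep (default 30); if more than the
#'   number of observed variants, all are returned.
#' @return list with `ranking` (data.frame `variant`, `count`, in rank
#'   order) and `pfm` (4 x 3 matrix, rows A/C/G/T, columns the variable
#'   positions).
#' @export
demux_adapter_variants <- function(variants, counts = NULL, k = 30) {
  counts <- counts %||% rep(1L, length(variants))
  tot <- tapply(counts, variants, sum)
  ord <- order(-as.numeric(tot), names(tot))
  ranking <- data.frame(variant = names(tot)[ord],
                        count = as.numeric(tot)[ord],
                        stringsAsFactors = FALSE)
  top <- head(ranking$variant, k)
  mat <- do.call(rbind, strsplit(top, ""))
  pfm <- vapply(seq_len(ncol(mat)), function(j) {
    tab <- table(factor(mat[, j], levels = c("A", "C", "G", "T")))
    as.numeric(tab) / length(top)
  }, numeric(4))
  dimnames(pfm) <- list(c("A", "C", "G", "T"), paste0("pos", seq_len(ncol(mat))))
  list(ranking = ranking, pfm = pfm)
}

#' Positional nucleotide deviation over the 3'-terminal section
#'
#' Compares base composition of a (possibly count-weighted) subset of
#' sequences against a background pool over the last `n_pos` positions
#' counted from the 3' end (position 1 = 3'-terminal base). Sequences
#' shorter than `n_pos` contribute only to the positions they cover.
#' Deviation = observed frequency (subset, weighted) minus expected
#' frequency (background, unweighted); the four base deviations sum to
#' zero at every position.
#'
#' @param sequences subset sequences.
#' @param background background pool sequences.
#' @param weights optional per-sequence weights (e.g. read counts).
#' @param n_pos positions from the 3' end (default 16).
#' @return 4 x `n_pos` matrix (rows A/C/G/T, column `p1` = 3' terminus).
#' @export
positional_deviation <- function(sequences, background, weights = NULL,
                                 n_pos = 16) {
  if (length(sequences) == 0) stop("empty subset")
  obs <- positional_freqs(sequences, weights, n_pos)
  exp_ <- positional_freqs(background, NULL, n_pos)
  dev <- obs - exp_
  colnames(dev) <- paste0("p", seq_len(n_pos))
  dev
}

positional_freqs <- function(seqs, weights, n_pos) {
  weights <- weights %||% rep(1, length(seqs))
  freq <- matrix(0, 4, n_pos, dimnames = list(c("A", "C", "G", "T"), NULL))
  wtot <- numeric(n_pos)
  lens <- nchar(seqs)
  for (i in seq_along(seqs)) {
    span <- seq_len(min(n_pos, lens[i]))
    bases <- substring(seqs[i], lens[i] - span + 1, lens[i] - span + 1)
    ok <- bases %in% rownames(freq)
    for (p in span[ok]) {
      freq[bases[p], p] <- freq[bases[p], p] + weights[i]
    }
    wtot[span[ok]] <- wtot[span[ok]] + weights[i]
  }
  sweep(freq, 2, pmax(wtot, 1e-300), "/")
}
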