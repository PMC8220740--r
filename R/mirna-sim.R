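#' Number of distinct sequences in a randomized RNA pool
#'
#' Complexity of a fully randomized k-mer pool: `4^k`. A randomized 21-mer
#' pool contains about 4.4e12 sequence variants.
#'
#' @param k oligonucleotide length.
#' @return `4^k` as a double.
#' @export
random_pool_size <- function(k) 4^k

#' Simulate an equimolar reference pool of short RNA species
#'
#' Emulates a commercial equimolar calibration pool: `n_species` distinct
#' sequences with lengths uniform over `len_range`, named `mir_0001`, ...
#' Species are unique at full length (resampling on collision; an error is
#' raised if the requested count exceeds the number of distinct sequences
#' available).
#'
#' @param n_species number of species (the emulated pool has 1005).
#' @param len_range integer length range, default 16-28 nt.
#' @param seed RNG seed (required; all generators are seed-deterministic).
#' @return a `reference_pool`: data.frame with `name`, `sequence`.
#' @export
simulate_mirna_pool <- function(n_species, len_range = c(16, 28), seed) {
  stopifnot(n_species >= 1, len_range[1] >= 1, len_range[2] <= 50,
            len_range[1] <= len_range[2])
  n_avail <- sum(4^(len_range[1]:len_range[2]))
  if (n_species > n_avail) {
    stop("requested ", n_species, " species but only ", n_avail,
         " distinct sequences exist in the length range")
  }
  with_seed(derive_seed(seed, 101), {
    seqs <- character(0)
    while (length(seqs) < n_species) {
      need <- n_species - length(seqs)
      lens <- sample(seq(len_range[1], len_range[2]), need, replace = TRUE)
      new <- vapply(lens, function(l) {
        paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
      }, "")
      seqs <- unique(c(seqs, new))
    }
    seqs <- seqs[seq_len(n_species)]
  })
  pool <- data.frame(
    name = sprintf("mir_%04d", seq_len(n_species)),
    sequence = seqs,
    stringsAsFactors = FALSE
  )
  class(pool) <- c("reference_pool", "data.frame")
  pool
}

#' Simulate reads from a reference pool with truncation and capture bias
#'
#' Reads are drawn multinomially across species; each read is independently
#' cropped by `x` nt from its 3' end with probability `truncation_probs[x+1]`
#' (`x = 0..5`). Without `bias`, species weights are equimolar. With a
#' [bias_model()], each species' weight is proportional to its capture
#' probability given its structure features — bias acts on whole species,
#' the way ligation bias depletes structured RNAs from a library, not on
#' individual reads.
#'
#' @param pool a `reference_pool`.
#' @param total_reads total read count to distribute.
#' @param truncation_probs 6 probabilities for 3' crops of 0..5 nt; must sum
#'   to 1. Default concentrates >=90% of reads on full length.
#' @param bias optional [bias_model()].
#' @param weights optional explicit per-species relative weights (overrides
#'   both the equimolar default and `bias`); e.g. a planted depletion of
#'   some species.
#' @param seed RNG seed.
#' @return data.frame of reads: `sequence`, `count` (aggregated over
#'   identical sequences), plus attribute `species_truth` (true per-species
#'   read totals).
#' @export
simulate_mirna_reads <- function(pool, total_reads,
                                 truncation_probs = c(0.90, 0.06, 0.02, 0.01, 0.005, 0.005),
                                 bias = NULL, weights = NULL, seed = 1) {
  stopifnot(total_reads >= 1, length(truncation_probs) == 6)
  if (abs(sum(truncation_probs) - 1) > 1e-9) {
    stop("truncation_probs must sum to 1")
  }
  n <- nrow(pool)
  w <- weights %||% rep(1, n)
  if (!is.null(weights) && (length(weights) != n || any(weights <= 0))) {
    stop("weights must be positive, one per species")
  }
  if (is.null(weights) && !is.null(bias) &&
      !(bias$beta_mfe == 0 && bias$beta_tail == 0)) {
    feats <- structure_features(pool$sequence)
    w <- plogis(bias$intercept + bias$beta_mfe * feats$mfe_score +
                  bias$beta_tail * feats$tail3_len)
  }
  # one multinomial draw over (species x crop level) cells
  cellp <- outer(w / sum(w), truncation_probs)
  counts <- with_seed(derive_seed(seed, 202), {
    rmultinom(1, total_reads, as.vector(cellp))[, 1]
  })
  cell <- which(counts > 0)
  sp <- ((cell - 1) %% n) + 1
  crop <- ((cell - 1) %/% n)
  lens <- nchar(pool$sequence[sp])
  if (any(lens <= crop)) stop("crop level exceeds species length")
  seqs <- substr(pool$sequence[sp], 1, lens - crop)
  agg <- tapply(counts[cell], seqs, sum)
  reads <- data.frame(sequence = names(agg), count = as.integer(agg),
                      stringsAsFactors = FALSE)
  rownames(reads) <- NULL
  truth <- tapply(counts, rep(seq_len(n), 6), sum)
  attr(reads, "species_truth") <- setNames(as.integer(truth), pool$name)
  reads
}
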