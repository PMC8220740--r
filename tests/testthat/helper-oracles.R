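# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: exhaustive recursion instead of dynamic
# programming, literal formula transcriptions instead of shared helpers.

# maximal base-pair count by exhaustive recursion over all nested
# structures (exponential; fine for n <= 12)
oracle_maxpairs <- function(seq, min_loop = 3) {
  s <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  ok <- c("AU", "UA", "GC", "CG", "GU", "UG")
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0)
    best <- rec(i + 1, j)
    for (k in (i + min_loop + 1):j) {
      if (paste0(s[i], s[k]) %in% ok) {
        best <- max(best, 1 + rec(i + 1, k - 1) + rec(k + 1, j))
      }
    }
    best
  }
  if (length(s) < 2) 0 else rec(1, length(s))
}

# all-pairs exact-match assignment: for each read, the smallest crop level
# at which exactly one species' cropped sequence equals the read
oracle_assign <- function(read, pool, max_x = 5) {
  for (x in 0:max_x) {
    lens <- nchar(pool$sequence)
    if (any(lens <= x)) next
    cropped <- substr(pool$sequence, 1, lens - x)
    m <- which(cropped == read)
    if (length(m) == 1) return(list(species = pool$name[m], x = x))
  }
  NULL
}

# literal transcription of the published TMM formula (reference = given)
oracle_tmm_pair <- function(obs, ref, nO, nR, lt = 0.3, st = 0.05) {
  pos <- obs > 0 & ref > 0
  obs <- obs[pos]; ref <- ref[pos]
  M <- log2((obs / nO) / (ref / nR))
  A <- 0.5 * log2((obs / nO) * (ref / nR))
  w <- 1 / ((nO - obs) / (nO * obs) + (nR - ref) / (nR * ref))
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  keep <- rank(M) >= floor(n * lt) + 1 & rank(M) <= n - floor(n * lt) &
    rank(A) >= floor(n * st) + 1 & rank(A) <= n - floor(n * st)
  2^(sum(w[keep] * M[keep]) / sum(w[keep]))
}

random_rna <- function(n, len_range = c(16, 28)) {
  lens <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  vapply(lens, function(l) {
    paste(sample(c("A", "C", "G", "U"), l, replace = TRUE), collapse = "")
  }, "")
}

# negative binomial toy count table
toy_count_table <- function(genes = 50, samples = 4, seed = 1) {
  set.seed(seed)
  y <- matrix(rnbinom(genes * samples, mu = sample(c(5, 50, 500), genes * samples,
                                                   replace = TRUE), size = 2),
              genes, samples,
              dimnames = list(paste0("g", seq_len(genes)),
                              paste0("s", seq_len(samples))))
  list(counts = y, lib_sizes = colSums(y))
}

# independent negative log-likelihood for the 2-feature logistic model
oracle_logistic_nll <- function(beta, y, x1, x2) {
  eta <- beta[1] + beta[2] * x1 + beta[3] * x2
  sum(log(1 + exp(eta))) - sum(y * eta)
}
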