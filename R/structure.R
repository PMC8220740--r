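#' Fold a short RNA by base-pair maximization
#'
#' Nested secondary structure maximizing the number of Watson-Crick plus
#' G·U pairs, with hairpin loops of at least `min_loop` unpaired bases
#' (Nussinov-style dynamic programming). The score is a structure-stability
#' proxy: `mfe_score = -pair_count`, more negative meaning more structured.
#' Ties are broken deterministically (a position is left unpaired whenever
#' optimal; otherwise it pairs with the leftmost admissible partner), so
#' pairing strings are reproducible across platforms.
#'
#' A thermodynamic folding program can be plugged in through `engine`: any
#' function taking a sequence and returning `list(pairing=, energy=)`
#' (dot-bracket and a free energy, e.g. kcal/mol) replaces the default and
#' its energy is used as `mfe_score`.
#'
#' @param sequence RNA or DNA sequence (`T` is read as `U`).
#' @param min_loop minimum hairpin loop length in nt (default 3).
#' @param engine optional external folding function (see Details).
#' @return a `structure_profile`: list with `sequence`, `pairing`
#'   (dot-bracket), `pair_count`, `mfe_score`, `tail3_len` (unpaired run at
#'   the 3' end).
#' @export
fold_maxpair <- function(sequence, min_loop = 3, engine = NULL) {
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1) stop("empty sequence")
  if (is.null(engine)) {
    res <- .nussinov_fold(sequence, as.integer(min_loop))
    pairing <- res$pairing
    pair_count <- res$pair_count
    mfe <- -as.numeric(pair_count)
  } else {
    res <- engine(sequence)
    pairing <- res$pairing
    pair_count <- sum(strsplit(pairing, "")[[1]] == "(")
    mfe <- as.numeric(res$energy)
  }
  structure(
    list(sequence = sequence, pairing = pairing, pair_count = pair_count,
         mfe_score = mfe, tail3_len = tail3_length(pairing)),
    class = "structure_profile"
  )
}

#' @export
print.structure_profile <- function(x, ...) {
  cat(x$sequence, "\n", x$pairing, "\n", sep = "")
  cat("pairs: ", x$pair_count, "  score: ", x$mfe_score,
      "  3' tail: ", x$tail3_len, " nt\n", sep = "")
  invisible(x)
}

#' Length of the unstructured 3' end
#'
#' Number of consecutive unpaired positions (`.`) at the right end of a
#' dot-bracket string. This is the stretch a 3'-acting enzyme (ligase,
#' methyltransferase) can reach without melting structure.
#'
#' @param pairing dot-bracket string.
#' @return integer nt count.
#' @export
tail3_length <- function(pairing) {
  chars <- strsplit(pairing, "")[[1]]
  if (!all(chars %in% c(".", "(", ")"))) stop("invalid dot-bracket string")
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (length(depth) && (any(depth < 0) || depth[length(depth)] != 0)) {
    stop("unbalanced brackets in dot-bracket string")
  }
  m <- regexpr("\\.*$", pairing)
  attr(m, "match.length")
}

#' Structure features for a set of sequences
#'
#' Convenience wrapper folding each sequence and collecting the two
#' capture-relevant features.
#'
#' @param sequences character vector.
#' @inheritParams fold_maxpair
#' @return data.frame with `mfe_score` and `tail3_len`, one row per input.
#' @export
structure_features <- function(sequences, min_loop = 3, engine = NULL) {
  profs <- lapply(sequences, fold_maxpair, min_loop = min_loop, engine = engine)
  data.frame(
    mfe_score = vapply(profs, `[[`, 0, "mfe_score"),
    tail3_len = vapply(profs, `[[`, 0, "tail3_len")
  )
}

#' Logistic capture-bias model
#'
#' Linear model on the log-odds of a species being captured during library
#' preparation: `logit p = intercept + beta_mfe * mfe_score +
#' beta_tail * tail3_len`. Used forwards to simulate structure-dependent
#' depletion of whole species and backwards (via [logistic_compare()]) to
#' infer it.
#'
#' @param intercept log-odds intercept.
#' @param beta_mfe log-odds per unit of structure score.
#' @param beta_tail log-odds per nt of unstructured 3' end.
#' @return a `bias_model`.
#' @export
bias_model <- function(intercept = 0, beta_mfe = 0, beta_tail = 0) {
  vals <- c(intercept, beta_mfe, beta_tail)
  if (!all(is.finite(vals))) stop("bias model coefficients must be finite")
  structure(list(intercept = intercept, beta_mfe = beta_mfe,
                 beta_tail = beta_tail), class = "bias_model")
}

#' Simulate captured vs dropped species under a capture-bias model
#'
#' Generates random RNA species, folds them, draws capture outcomes
#' Bernoulli(capture probability under `model`), and returns the structure
#' features of the first `n_per_group` captured and `n_per_group` dropped
#' species — a case-control sample, which preserves the logistic slopes
#' (only the intercept shifts), so [logistic_compare()] on the two groups
#' recovers the planted coefficient signs.
#'
#' @param n_per_group species per group.
#' @param model a [bias_model()].
#' @param seed RNG seed.
#' @param len_range species length range (default 16-28 nt).
#' @param batch species generated per batch while filling the groups.
#' @param max_batches bound on simulation effort; exceeding it errors
#'   (capture probabilities too extreme for the requested group sizes).
#' @return list with `captured` and `dropped` feature data.frames
#'   (`mfe_score`, `tail3_len`).
#' @export
simulate_capture_groups <- function(n_per_group, model, seed,
                                    len_range = c(16, 28), batch = 2000,
                                    max_batches = 50) {
  cap <- list(); drop <- list()
  ncap <- 0; ndrop <- 0
  for (b in seq_len(max_batches)) {
    if (ncap >= n_per_group && ndrop >= n_per_group) break
    feats <- with_seed(derive_seed(seed, 7000 + b), {
      lens <- sample(seq(len_range[1], len_range[2]), batch, replace = TRUE)
      seqs <- vapply(lens, function(l) {
        paste(sample(c("A", "C", "G", "U"), l, replace = TRUE), collapse = "")
      }, "")
      f <- structure_features(seqs)
      p <- plogis(model$intercept + model$beta_mfe * f$mfe_score +
                    model$beta_tail * f$tail3_len)
      f$captured <- rbinom(batch, 1, p) == 1
      f
    })
    cap[[b]] <- feats[feats$captured, c("mfe_score", "tail3_len")]
    drop[[b]] <- feats[!feats$captured, c("mfe_score", "tail3_len")]
    ncap <- ncap + nrow(cap[[b]])
    ndrop <- ndrop + nrow(drop[[b]])
  }
  if (ncap < n_per_group || ndrop < n_per_group) {
    stop("could not fill both groups: capture probabilities too extreme")
  }
  list(captured = head(do.call(rbind, cap), n_per_group),
       dropped = head(do.call(rbind, drop), n_per_group))
}

#' Capture probability of a species under a bias model
#'
#' @param profile a `structure_profile` (or list with `mfe_score`,
#'   `tail3_len`).
#' @param model a [bias_model()].
#' @return probability in (0, 1); strictly monotone in each feature.
#' @export
capture_probability <- function(profile, model) {
  plogis(model$intercept +
           model$beta_mfe * profile$mfe_score +
           model$beta_tail * profile$tail3_len)
}
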