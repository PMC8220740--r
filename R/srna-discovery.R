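#' Segment replicate-pooled coverage into sRNA candidates
#'
#' Per strand, finds maximal runs of positions whose mean depth across the
#' library's replicates reaches `min_cov`, allowing internal gaps of up to
#' `max_gap` nt; runs are trimmed so both ends sit on positions that meet
#' the threshold, then filtered to `len_range`. On a circular genome a run
#' touching both contig ends is joined across the origin (the candidate is
#' stored with `end > genome length`). This detector is deliberately
#' simple plumbing: the scientific filter is [refine_candidates()].
#'
#' @param tracks list of `coverage_track`s for ONE library (all
#'   replicates, both strands).
#' @param min_cov minimum replicate-mean depth (default 5).
#' @param max_gap maximum internal gap below threshold, nt (default 5).
#' @param len_range candidate length window, nt (default 50-500, the size
#'   selection used for bacterial sRNA libraries).
#' @param circular wrap runs across the origin?
#' @return candidate data.frame: `id`, `contig`, `strand`, `start`, `end`,
#'   `library`.
#' @export
segment_coverage <- function(tracks, min_cov = 5, max_gap = 5,
                             len_range = c(50, 500), circular = TRUE) {
  if (min_cov < 1) stop("min_cov must be >= 1")
  lib <- unique(vapply(tracks, `[[`, "", "library_id"))
  if (length(lib) > 1) stop("tracks from more than one library")
  contig <- unique(vapply(tracks, `[[`, "", "contig"))
  if (length(contig) > 1) stop("tracks from more than one contig")
  out <- list()
  for (st in c("+", "-")) {
    reps <- Filter(function(t) t$strand == st, tracks)
    if (length(reps) == 0) next
    depth <- Reduce(`+`, lapply(reps, `[[`, "depth")) / length(reps)
    ok <- depth >= min_cov
    if (!any(ok)) next
    idx <- which(ok)
    gaps <- diff(idx)
    brk <- which(gaps > max_gap + 1)
    run_start <- idx[c(1, brk + 1)]
    run_end <- idx[c(brk, length(idx))]
    starts <- run_start - 1
    ends <- run_end # half-open
    if (circular && length(starts) > 1) {
      L <- length(depth)
      # join first and last runs across the origin when the wrap gap is small
      wrap_gap <- (starts[1] + L) - ends[length(ends)]
      if (wrap_gap <= max_gap) {
        ends[length(ends)] <- ends[1] + L
        starts <- starts[-1]
        ends <- ends[-1]
      }
    }
    len <- ends - starts
    keep <- len >= len_range[1] & len <= len_range[2]
    if (any(keep)) {
      out[[st]] <- data.frame(contig = contig, strand = st,
                              start = starts[keep], end = ends[keep],
                              stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(id = character(0), contig = character(0),
                      strand = character(0), start = numeric(0),
                      end = numeric(0), library = character(0),
                      stringsAsFactors = FALSE))
  }
  cand <- do.call(rbind, out)
  cand <- cand[order(cand$start, cand$strand), , drop = FALSE]
  cand <- data.frame(id = sprintf("%s_cand_%03d", lib, seq_len(nrow(cand))),
                     cand, library = lib, stringsAsFactors = FALSE)
  rownames(cand) <- NULL
  cand
}

#' Boundary step ratios of a candidate on one coverage track
#'
#' `r5 = (mean depth over the w positions just inside the 5' boundary +
#' 0.5) / (mean depth over the w positions just outside + 0.5)`, and `r3`
#' analogously at the 3' boundary. The 5'/3' assignment respects strand
#' (for a reverse-strand candidate the 5' boundary is the high-coordinate
#' end). Positions beyond a linear contig count as depth 0; circular
#' contigs wrap. The symmetric pseudocount keeps the ratio defined over
#' zero background and monotone in the inside depth.
#'
#' @param track a `coverage_track` on the candidate's strand.
#' @param candidate one-row interval (`start`, `end`, `strand`).
#' @param w window width in nt (default 2, "within 2 nt").
#' @param circular wrap outside windows around the origin?
#' @return named numeric `c(r5, r3)`.
#' @export
boundary_ratios <- function(track, candidate, w = 2, circular = TRUE) {
  if (w < 1) stop("w must be >= 1")
  len <- candidate$end - candidate$start
  if (len < w) stop("candidate shorter than window w")
  L <- length(track$depth)
  depth_at <- function(pos) {
    # pos are 0-based, possibly outside [0, L)
    if (circular) {
      track$depth[(pos %% L) + 1]
    } else {
      d <- rep(0, length(pos))
      inb <- pos >= 0 & pos < L
      d[inb] <- track$depth[pos[inb] + 1]
      d
    }
  }
  s <- candidate$start
  e <- candidate$end
  in_left <- mean(depth_at(s + 0:(w - 1)))
  out_left <- mean(depth_at(s - (1:w)))
  in_right <- mean(depth_at(e - (1:w)))
  out_right <- mean(depth_at(e + 0:(w - 1)))
  r_left <- (in_left + 0.5) / (out_left + 0.5)
  r_right <- (in_right + 0.5) / (out_right + 0.5)
  if (candidate$strand == "+") {
    c(r5 = r_left, r3 = r_right)
  } else {
    c(r5 = r_right, r3 = r_left)
  }
}

#' Boundary crosscheck filter for sRNA candidates
#'
#' A candidate is a credible transcript when its read coverage steps up at
#' least `t`-fold within `w` nt at BOTH its 5' and 3' ends, in at least
#' `min_replicates` replicates. By default both ends must pass within the
#' same replicate (`same_replicate = TRUE`); the alternative reading — each
#' end may pass in a different replicate — is available via the switch.
#'
#' @param candidates candidate table from [segment_coverage()].
#' @param tracks replicate `coverage_track`s of the candidates' library.
#' @param t ratio threshold; the pass rule is `ratio >= t` (default 3).
#' @param w boundary window, nt (default 2).
#' @param min_replicates replicates that must pass (default 1).
#' @param same_replicate must both ends pass in one and the same replicate?
#' @param circular wrap boundary windows around the origin?
#' @return the candidate table with `passed_refinement` plus per-replicate
#'   ratio columns `r5_rep<i>`, `r3_rep<i>`; filtered rows retained (all
#'   rows returned, flag set).
#' @export
refine_candidates <- function(candidates, tracks, t = 3, w = 2,
                              min_replicates = 1, same_replicate = TRUE,
                              circular = TRUE) {
  reps <- sort(unique(vapply(tracks, `[[`, 0, "replicate_id")))
  if (length(reps) < min_replicates) stop("fewer tracks than min_replicates")
  n <- nrow(candidates)
  r5m <- matrix(NA_real_, n, length(reps))
  r3m <- matrix(NA_real_, n, length(reps))
  for (j in seq_along(reps)) {
    for (i in seq_len(n)) {
      tr <- Filter(function(x) x$replicate_id == reps[j] &&
                     x$strand == candidates$strand[i], tracks)
      if (length(tr) == 0) next
      rr <- boundary_ratios(tr[[1]], candidates[i, ], w = w,
                            circular = circular)
      r5m[i, j] <- rr["r5"]
      r3m[i, j] <- rr["r3"]
    }
  }
  if (same_replicate) {
    pass_reps <- (r5m >= t) & (r3m >= t)
    passed <- rowSums(pass_reps, na.rm = TRUE) >= min_replicates
  } else {
    passed <- rowSums(r5m >= t, na.rm = TRUE) >= min_replicates &
      rowSums(r3m >= t, na.rm = TRUE) >= min_replicates
  }
  out <- candidates
  out$passed_refinement <- passed
  colnames(r5m) <- paste0("r5_rep", reps)
  colnames(r3m) <- paste0("r3_rep", reps)
  cbind(out, r5m, r3m)
}

#' Merge candidate lists across libraries, keeping the widest coordinates
#'
#' Same-strand candidates whose 5' ends differ by at most `delta` nt and
#' whose 3' ends differ by at most `delta` nt are grouped (transitively);
#' each group is replaced by its widest extent (minimum start, maximum
#' end) and records which libraries contributed — the per-library source
#' sets feed the Venn tally of shared vs library-specific sRNAs.
#'
#' @param candidate_lists list of candidate tables (one per library), each
#'   with a `library` column.
#' @param delta coordinate tolerance in nt (default 5).
#' @return merged table: `id`, `contig`, `strand`, `start`, `end`,
#'   `sources` (comma-separated library ids), `n_members`.
#' @export
merge_across_libraries <- function(candidate_lists, delta = 5) {
  all <- do.call(rbind, lapply(candidate_lists, function(x) {
    x[, c("contig", "strand", "start", "end", "library")]
  }))
  n <- nrow(all)
  if (n == 0) {
    return(data.frame(id = character(0), contig = character(0),
                      strand = character(0), start = numeric(0),
                      end = numeric(0), sources = character(0),
                      n_members = integer(0), stringsAsFactors = FALSE))
  }
  # union-find over the pairwise closeness relation
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (all$strand[i] == all$strand[j] &&
          all$contig[i] == all$contig[j] &&
          abs(all$start[i] - all$start[j]) <= delta &&
          abs(all$end[i] - all$end[j]) <= delta) {
        parent[find(j)] <- find(i)
      }
    }
  }
  root <- vapply(seq_len(n), find, 0L)
  groups <- split(seq_len(n), root)
  merged <- lapply(groups, function(ix) {
    data.frame(contig = all$contig[ix[1]], strand = all$strand[ix[1]],
               start = min(all$start[ix]), end = max(all$end[ix]),
               sources = paste(sort(unique(all$library[ix])), collapse = ","),
               n_members = length(ix), stringsAsFactors = FALSE)
  })
  merged <- do.call(rbind, merged)
  merged <- merged[order(merged$start, merged$strand), , drop = FALSE]
  merged <- data.frame(id = sprintf("srna_%03d", seq_len(nrow(merged))),
                       merged, stringsAsFactors = FALSE)
  rownames(merged) <- NULL
  merged
}

#' Tally merged sRNAs by library source set
#'
#' @param merged output of [merge_across_libraries()].
#' @return table of counts per source combination (Venn cells).
#' @export
venn_counts <- function(merged) {
  table(merged$sources)
}

#' Count fragments overlapping each candidate (strand-aware)
#'
#' A fragment counts toward EVERY candidate it overlaps by at least 1 nt
#' on the same strand (multi-overlap counts to each; set `multi = FALSE`
#' to drop fragments hitting more than one candidate). Library sizes are
#' the total fragment counts per sample.
#'
#' @param fragments fragment table (`strand`, `start`, `end`, `library`,
#'   `replicate`), e.g. from [simulate_coverage()] or
#'   [fragments_from_pairs()].
#' @param candidates merged candidate table (`id`, `strand`, `start`,
#'   `end`).
#' @param genome_len genome length (for wrapped candidates); `NULL` for
#'   linear.
#' @param multi count multi-overlap fragments to every candidate?
#' @return a `count_table`: list with `counts` (candidate x sample),
#'   `lib_sizes`, `norm_factors` (unity), `samples` (library/replicate
#'   map).
#' @export
count_features <- function(fragments, candidates, genome_len = NULL,
                           multi = TRUE) {
  sample_id <- paste(fragments$library, fragments$replicate, sep = "_rep")
  samples <- sort(unique(sample_id))
  counts <- matrix(0L, nrow(candidates), length(samples),
                   dimnames = list(candidates$id, samples))
  lib_sizes <- setNames(as.numeric(table(factor(sample_id, levels = samples))),
                        samples)
  for (st in c("+", "-")) {
    cs <- which(candidates$strand == st)
    fs <- which(fragments$strand == st)
    if (length(cs) == 0 || length(fs) == 0) next
    for (ci in cs) {
      ov <- overlap_many(candidates$start[ci], candidates$end[ci],
                         fragments[fs, c("start", "end")], genome_len)
      hit <- fs[ov > 0]
      if (length(hit)) {
        tab <- table(factor(sample_id[hit], levels = samples))
        counts[ci, ] <- counts[ci, ] + as.integer(tab)
      }
    }
    if (!multi) {
      # drop fragments overlapping >1 candidate: recount exclusively
      nhit <- numeric(length(fs))
      for (ci in cs) {
        ov <- overlap_many(candidates$start[ci], candidates$end[ci],
                           fragments[fs, c("start", "end")], genome_len)
        nhit <- nhit + (ov > 0)
      }
      multi_f <- fs[nhit > 1]
      for (ci in cs) {
        ov <- overlap_many(candidates$start[ci], candidates$end[ci],
                           fragments[fs, c("start", "end")], genome_len)
        bad <- intersect(fs[ov > 0], multi_f)
        if (length(bad)) {
          tab <- table(factor(sample_id[bad], levels = samples))
          counts[ci, ] <- counts[ci, ] - as.integer(tab)
        }
      }
    }
  }
  lib_of <- sub("_rep[0-9]+$", "", samples)
  structure(
    list(counts = counts, lib_sizes = lib_sizes,
         norm_factors = setNames(rep(1, length(samples)), samples),
         samples = data.frame(sample = samples, library = lib_of,
                              stringsAsFactors = FALSE)),
    class = "count_table"
  )
}

#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Between-sample normalization for count tables, computed from the
#' published definition: the reference sample is the one whose
#' upper-quartile count fraction is closest to the mean; for each sample,
#' genes with a zero count in either the sample or the reference are
#' excluded; M-values (log2 ratio of relative abundance) are trimmed by
#' `logratio_trim` (both tails) and A-values (average log2 abundance) by
#' `sum_trim`; the factor is 2 to the inverse-variance-weighted mean of
#' the surviving M-values, using the asymptotic binomial variance weights.
#' Factors are rescaled so their geometric mean is 1. Scaling one sample's
#' counts by a constant leaves its factor unchanged (the scale is absorbed
#' by the library size).
#'
#' @param table a `count_table` (or list with `counts`, `lib_sizes`).
#' @param logratio_trim trim fraction for M (default 0.3).
#' @param sum_trim trim fraction for A (default 0.05).
#' @return named numeric vector of normalization factors.
#' @export
tmm_factors <- function(table, logratio_trim = 0.3, sum_trim = 0.05) {
  y <- table$counts
  if (ncol(y) < 2) stop("TMM needs at least 2 samples")
  N <- table$lib_sizes %||% colSums(y)
  zero_samples <- colnames(y)[colSums(y) == 0]
  if (length(zero_samples)) {
    stop("sample(s) with all-zero counts: ",
         paste(zero_samples, collapse = ", "))
  }
  f75 <- vapply(seq_len(ncol(y)), function(j) {
    quantile(y[, j], 0.75, names = FALSE) / N[j]
  }, 0)
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(y)), function(j) {
    tmm_pair(y[, j], y[, ref], N[j], N[ref], logratio_trim, sum_trim)
  }, 0)
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(y))
}

# TMM factor of obs vs ref, published definition
tmm_pair <- function(obs, ref, nO, nR, logratio_trim, sum_trim) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (length(obs) == 0) return(1)
  M <- log2((obs / nO) / (ref / nR))
  A <- 0.5 * log2((obs / nO) * (ref / nR))
  v <- (nO - obs) / (nO * obs) + (nR - ref) / (nR * ref)
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1
  hiM <- n + 1 - loM
  loA <- floor(n * sum_trim) + 1
  hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep2)) return(1)
  2^(sum(M[keep2] / v[keep2]) / sum(1 / v[keep2]))
}

#' CPM filter for candidate retention
#'
#' `CPM = count / (library size x normalization factor) x 1e6`; the
#' per-library mean over replicates must reach `threshold` (inclusive) in
#' at least one library for a candidate to be retained.
#'
#' @param table a `count_table`.
#' @param factors normalization factors (e.g. [tmm_factors()]); default
#'   unity.
#' @param threshold mean-CPM retention threshold (default 15).
#' @return list with `retained` (candidate ids), `cpm` (full CPM matrix),
#'   `library_means` (candidate x library), `keep` (logical per
#'   candidate).
#' @export
cpm_filter <- function(table, factors = NULL, threshold = 15) {
  factors <- factors %||% table$norm_factors
  eff <- table$lib_sizes * factors[names(table$lib_sizes)]
  cpm <- sweep(table$counts, 2, eff, "/") * 1e6
  libs <- table$samples$library
  ulibs <- unique(libs)
  lib_means <- vapply(ulibs, function(l) {
    rowMeans(cpm[, libs == l, drop = FALSE])
  }, numeric(nrow(cpm)))
  if (is.null(dim(lib_means))) {
    lib_means <- matrix(lib_means, ncol = length(ulibs),
                        dimnames = list(rownames(cpm), ulibs))
  }
  keep <- apply(lib_means >= threshold, 1, any)
  list(retained = rownames(table$counts)[keep], cpm = cpm,
       library_means = lib_means, keep = keep)
}
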