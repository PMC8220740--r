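make_track <- function(depth, strand = "+", rep_id = 1, lib = "C",
                       contig = "chr") {
  coverage_track(contig, strand, depth, replicate_id = rep_id,
                 library_id = lib)
}

test_that("segmentation finds threshold runs, merges gaps, filters length", {
  d <- c(0, 0, 5, 5, 5, 0, 0)
  tr <- make_track(d)
  cand <- segment_coverage(list(tr), min_cov = 1, max_gap = 0,
                           len_range = c(1, 100), circular = FALSE)
  expect_equal(nrow(cand), 1)
  expect_equal(c(cand$start, cand$end), c(2, 5))

  # runs [2,5) and [7,9) with a 2-nt gap merge at max_gap = 2
  d2 <- c(0, 0, 5, 5, 5, 0, 0, 5, 5, 0)
  cand2 <- segment_coverage(list(make_track(d2)), min_cov = 1, max_gap = 2,
                            len_range = c(1, 100), circular = FALSE)
  expect_equal(nrow(cand2), 1)
  expect_equal(c(cand2$start, cand2$end), c(2, 9))
  # ...but stay separate at max_gap = 1
  cand3 <- segment_coverage(list(make_track(d2)), min_cov = 1, max_gap = 1,
                            len_range = c(1, 100), circular = FALSE)
  expect_equal(nrow(cand3), 2)

  # a 40-nt run dies on the 50-500 length filter
  d4 <- c(rep(0, 10), rep(9, 40), rep(0, 10))
  expect_equal(nrow(segment_coverage(list(make_track(d4)), min_cov = 5,
                                     circular = FALSE)), 0)
  expect_error(segment_coverage(list(tr), min_cov = 0), "min_cov")
})

test_that("segmentation pools replicates by mean depth", {
  d1 <- c(0, 0, 9, 9, 9, 0, 0)
  d2 <- c(0, 0, 0, 0, 0, 0, 0)
  cand <- segment_coverage(list(make_track(d1, rep_id = 1),
                                make_track(d2, rep_id = 2)),
                           min_cov = 5, max_gap = 0, len_range = c(1, 10),
                           circular = FALSE)
  expect_equal(nrow(cand), 0) # mean 4.5 < 5
  cand <- segment_coverage(list(make_track(d1, rep_id = 1),
                                make_track(d1, rep_id = 2)),
                           min_cov = 5, max_gap = 0, len_range = c(1, 10),
                           circular = FALSE)
  expect_equal(nrow(cand), 1)
})

test_that("segmentation joins runs across the origin of circular contigs", {
  d <- c(rep(7, 30), rep(0, 40), rep(7, 30))
  cand <- segment_coverage(list(make_track(d)), min_cov = 5, max_gap = 5,
                           len_range = c(50, 500), circular = TRUE)
  expect_equal(nrow(cand), 1)
  expect_equal(c(cand$start, cand$end), c(70, 130)) # wraps: end > L
})

test_that("boundary ratios match hand arithmetic with the 0.5 pseudocount", {
  d <- c(0, 0, 1, 0, 10, 10, 10, 10, 10, 10, 0, 0)
  tr <- make_track(d)
  cand <- data.frame(contig = "chr", strand = "+", start = 4, end = 10)
  r <- boundary_ratios(tr, cand, w = 2)
  expect_equal(unname(r["r5"]), 10.5)
  expect_equal(unname(r["r3"]), 21)

  # linear ramp fails threshold 3
  ramp <- make_track(c(2, 3, 4, 5, 6, 7, 8, 9))
  r2 <- boundary_ratios(ramp, data.frame(contig = "chr", strand = "+",
                                         start = 4, end = 8),
                        w = 2, circular = FALSE)
  expect_equal(unname(r2["r5"]), 1.4)

  # reverse strand swaps which end is 5'
  trm <- make_track(d, strand = "-")
  rm_ <- boundary_ratios(trm, data.frame(contig = "chr", strand = "-",
                                         start = 4, end = 10), w = 2)
  expect_equal(unname(rm_["r5"]), 21)
  expect_equal(unname(rm_["r3"]), 10.5)

  # zero outside, inside >= 2 always passes the 3x rule
  d3 <- c(rep(0, 4), rep(2, 6), rep(0, 4))
  r3 <- boundary_ratios(make_track(d3),
                        data.frame(contig = "chr", strand = "+",
                                   start = 4, end = 10), w = 2)
  expect_true(all(r3 >= 3))
  expect_error(
    boundary_ratios(tr, data.frame(contig = "chr", strand = "+",
                                   start = 4, end = 5), w = 2),
    "shorter than"
  )
})

test_that("boundary windows wrap on circular contigs and zero-fill on linear", {
  d <- c(9, 9, 9, rep(0, 14), 9, 9, 9) # run wrapping the origin (L = 20)
  cand <- data.frame(contig = "chr", strand = "+", start = 17, end = 23)
  r_circ <- boundary_ratios(make_track(d), cand, w = 2, circular = TRUE)
  # inside-3' positions 21,22 wrap to 1,2 (depth 9); outside 23,24 -> 3,4 (0)
  expect_equal(unname(r_circ["r3"]), 9.5 / 0.5)
  expect_equal(unname(r_circ["r5"]), 9.5 / 0.5)
  # linear contig: windows beyond the edge count as depth 0
  d2 <- c(rep(9, 6), rep(0, 14))
  r_lin <- boundary_ratios(make_track(d2),
                           data.frame(contig = "chr", strand = "+",
                                      start = 0, end = 6),
                           w = 2, circular = FALSE)
  expect_equal(unname(r_lin["r5"]), 9.5 / 0.5)
})

test_that("refinement demands both ends pass in one replicate by default", {
  L <- 120
  base <- rep(0, L)
  sharp5 <- base; sharp5[31:90] <- 30; sharp5[86:95] <- 2 # no 3' step
  sharp3 <- base; sharp3[31:90] <- 30; sharp3[26:35] <- 2 # no 5' step
  cand <- data.frame(id = "c1", contig = "chr", strand = "+",
                     start = 30, end = 90, library = "C")
  tr1 <- make_track(sharp5, rep_id = 1)
  tr2 <- make_track(sharp3, rep_id = 2)
  ref <- refine_candidates(cand, list(tr1, tr2), t = 3, w = 2,
                           circular = FALSE)
  expect_false(ref$passed_refinement) # r5 passes only in rep1, r3 only in rep2
  ref2 <- refine_candidates(cand, list(tr1, tr2), t = 3, w = 2,
                            same_replicate = FALSE, circular = FALSE)
  expect_true(ref2$passed_refinement)

  good <- base; good[31:90] <- 30
  ref3 <- refine_candidates(cand, list(make_track(good)), t = 3, w = 2,
                            circular = FALSE)
  expect_true(ref3$passed_refinement)
})

test_that("refinement is monotone in the threshold t", {
  st <- simulate_srna_study(seed = 31, genome_length = 40000, n_cds = 30,
                            sharp_counts = c(intergenic = 5, antisense = 3),
                            ramped_counts = c(intergenic = 3))
  ltr <- Filter(function(x) x$library_id == "C", st$tracks)
  cand <- segment_coverage(ltr)
  pass3 <- refine_candidates(cand, ltr, t = 3)$passed_refinement
  pass4 <- refine_candidates(cand, ltr, t = 4)$passed_refinement
  expect_true(all(which(pass4) %in% which(pass3)))
})

test_that("cross-library merging groups nearby calls and keeps the widest", {
  a <- data.frame(id = "a1", contig = "chr", strand = "+", start = 100,
                  end = 200, library = "C")
  b <- data.frame(id = "b1", contig = "chr", strand = "+", start = 98,
                  end = 203, library = "N")
  m <- merge_across_libraries(list(a, b), delta = 5)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(98, 203))
  expect_equal(m$sources, "C,N")

  # ends differing by 50 nt do not merge
  c_ <- data.frame(id = "c1", contig = "chr", strand = "+", start = 150,
                   end = 250, library = "U")
  m2 <- merge_across_libraries(list(a, c_), delta = 5)
  expect_equal(nrow(m2), 2)

  # identical candidate in three libraries: one group, all sources
  u <- a; u$library <- "U"; n <- a; n$library <- "N"
  m3 <- merge_across_libraries(list(a, u, n), delta = 5)
  expect_equal(m3$sources, "C,N,U")
  expect_equal(unname(venn_counts(m3)["C,N,U"]), 1L)

  # merged intervals contain every member of their group
  set.seed(41)
  lists <- lapply(c("C", "U", "N"), function(l) {
    k <- 12
    s <- sample(seq(0, 5000, by = 40), k)
    data.frame(id = paste0(l, 1:k), contig = "chr",
               strand = sample(c("+", "-"), k, TRUE),
               start = s + sample(-2:2, k, TRUE),
               end = s + 100 + sample(-2:2, k, TRUE),
               library = l)
  })
  mm <- merge_across_libraries(lists, delta = 5)
  allc <- do.call(rbind, lists)
  for (i in seq_len(nrow(allc))) {
    hit <- mm$strand == allc$strand[i] & mm$start <= allc$start[i] &
      mm$end >= allc$end[i]
    expect_true(any(hit))
  }
  expect_equal(sum(mm$n_members), nrow(allc))
})

test_that("venn tally equals a brute-force set computation", {
  st <- simulate_srna_study(seed = 33, genome_length = 40000, n_cds = 30,
                            sharp_counts = c(intergenic = 6, antisense = 4),
                            ramped_counts = c(intergenic = 0),
                            libraries = c("C", "U", "N"))
  res <- run_srna_pipeline(st$tracks, st$fragments, st$genome, st$features)
  # brute force from per-library passing candidate coordinates
  per_lib <- lapply(res$per_library, function(x) {
    x <- x[x$passed_refinement, ]
    paste(x$strand, x$start, x$end)
  })
  keys <- sort(unique(unlist(per_lib)))
  brute <- table(vapply(keys, function(k) {
    paste(sort(names(per_lib)[vapply(per_lib, function(v) k %in% v, TRUE)]),
          collapse = ",")
  }, ""))
  vn <- venn_counts(res$merged)
  expect_equal(sort(as.integer(vn)), sort(as.integer(brute)))
  expect_equal(sum(vn), nrow(res$merged))
})

test_that("fragment counting is strand-aware with a 1-nt overlap rule", {
  cand <- data.frame(id = c("s1", "s2"), contig = "chr",
                     strand = c("+", "+"), start = c(100, 300),
                     end = c(200, 400))
  frags <- data.frame(
    contig = "chr",
    strand = c("+", "+", "-", "+", "+"),
    start = c(120, 90, 150, 250, 199),
    end = c(180, 101, 180, 260, 320),
    library = "C", replicate = 1
  )
  tab <- count_features(frags, cand)
  expect_equal(unname(tab$counts["s1", ]), 3L) # inside, 1-nt, straddler
  expect_equal(unname(tab$counts["s2", ]), 1L) # straddler counts to both
  expect_equal(unname(tab$lib_sizes), 5)
  tab2 <- count_features(frags, cand, multi = FALSE)
  expect_equal(unname(tab2$counts["s1", ]), 2L)
  expect_equal(unname(tab2$counts["s2", ]), 0L)
})

test_that("TMM matches edgeR and the literal formula on toy tables", {
  library(edgeR)
  for (sd in 1:6) {
    tab <- toy_count_table(genes = 60, samples = 4, seed = sd)
    mine <- tmm_factors(tab)
    ed <- edgeR::calcNormFactors(tab$counts, method = "TMM")
    expect_lt(max(abs(mine - ed)), 1e-10)
  }
  # 6-gene toy table vs the literal formula transcription
  y <- matrix(c(10, 20, 30, 5, 80, 40,
                20, 35, 70, 8, 150, 90), 6, 2,
              dimnames = list(paste0("g", 1:6), c("a", "b")))
  tab <- list(counts = y, lib_sizes = colSums(y))
  mine <- tmm_factors(tab)
  # reference selection: f75 closest to mean
  N <- colSums(y)
  f75 <- apply(y, 2, quantile, 0.75) / N
  ref <- which.min(abs(f75 - mean(f75)))
  raw <- vapply(1:2, function(j) {
    oracle_tmm_pair(y[, j], y[, ref], N[j], N[ref])
  }, 0)
  raw <- raw / exp(mean(log(raw)))
  expect_equal(unname(mine), unname(raw), tolerance = 1e-10)
})

test_that("TMM identities: equal samples and proportional samples give unity", {
  y <- matrix(c(10, 50, 200, 7, 90, 10, 50, 200, 7, 90), 5, 2,
              dimnames = list(paste0("g", 1:5), c("a", "b")))
  expect_equal(unname(tmm_factors(list(counts = y, lib_sizes = colSums(y)))),
               c(1, 1))
  y2 <- y; y2[, 2] <- y2[, 2] * 2
  expect_equal(unname(tmm_factors(list(counts = y2, lib_sizes = colSums(y2)))),
               c(1, 1))
  # scaling one sample is absorbed by its library size: the factor moves
  # far less than the scale itself (only the variance weights shift; the
  # M-values are scale-free). edgeR behaves identically (same weights).
  tab <- toy_count_table(genes = 80, samples = 3, seed = 7)
  f1 <- tmm_factors(tab)
  tab$counts[, 2] <- tab$counts[, 2] * 4L
  tab$lib_sizes <- colSums(tab$counts)
  f2 <- tmm_factors(tab)
  expect_lt(max(abs(log2(f2 / f1))), 0.3) # scale itself would be log2(4) = 2
  expect_lt(max(abs(f2 - edgeR::calcNormFactors(tab$counts, method = "TMM"))),
            1e-10)
  # all-zero sample is refused by name
  bad <- list(counts = cbind(a = c(1, 2), b = c(0, 0)),
              lib_sizes = c(3, 0))
  expect_error(tmm_factors(bad), "b")
})

test_that("CPM filter retains >= 15 mean CPM in at least one library", {
  counts <- rbind(
    keep_exact = c(15, 15, 2, 2),   # exactly 15 CPM in library C
    drop_low = c(14, 14, 14, 14),   # 14 CPM everywhere
    keep_one = c(400, 420, 0, 0)    # high in C only
  )
  colnames(counts) <- c("C_rep1", "C_rep2", "N_rep1", "N_rep2")
  tab <- structure(list(
    counts = counts,
    lib_sizes = setNames(rep(1e6, 4), colnames(counts)),
    norm_factors = setNames(rep(1, 4), colnames(counts)),
    samples = data.frame(sample = colnames(counts),
                         library = c("C", "C", "N", "N"))
  ), class = "count_table")
  flt <- cpm_filter(tab, threshold = 15)
  expect_setequal(flt$retained, c("keep_exact", "keep_one"))
  expect_equal(unname(flt$library_means["keep_exact", "C"]), 15)
})
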