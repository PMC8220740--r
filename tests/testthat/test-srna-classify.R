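lin_genome <- function(len = 5000, circular = FALSE) {
  genome_record("chr", strrep("ACGT", ceiling(len / 4)), circular = circular)
}

test_that("UTR windows flank CDSs and truncate at neighbours", {
  g <- lin_genome(5000)
  f <- data.frame(feature_id = "c1", contig = "chr", strand = "+",
                  start = 1000, end = 2000, kind = "CDS")
  ctx <- build_context_map(f, g, u5 = 150, u3 = 150)
  expect_equal(c(ctx$utr5$start, ctx$utr5$end), c(850, 1000))
  expect_equal(c(ctx$utr3$start, ctx$utr3$end), c(2000, 2150))

  # an upstream CDS ending at 950 truncates the 5' window
  f2 <- rbind(f, data.frame(feature_id = "c0", contig = "chr", strand = "+",
                            start = 500, end = 950, kind = "CDS"))
  ctx2 <- build_context_map(f2, g, u5 = 150, u3 = 150)
  w5 <- ctx2$utr5[ctx2$utr5$feature_id == "c1", ]
  expect_equal(c(w5$start, w5$end), c(950, 1000))

  # reverse-strand CDS: 5' window downstream, 3' window upstream
  fm <- data.frame(feature_id = "m1", contig = "chr", strand = "-",
                   start = 1000, end = 2000, kind = "CDS")
  ctxm <- build_context_map(fm, g, u5 = 150, u3 = 150)
  expect_equal(c(ctxm$utr5$start, ctxm$utr5$end), c(2000, 2150))
  expect_equal(c(ctxm$utr3$start, ctxm$utr3$end), c(850, 1000))
})

test_that("windows wrap across the origin of circular genomes", {
  g <- lin_genome(5000, circular = TRUE)
  f <- data.frame(feature_id = "c1", contig = "chr", strand = "+",
                  start = 40, end = 600, kind = "CDS")
  ctx <- build_context_map(f, g, u5 = 150, u3 = 150)
  # 5' window [40-150, 40) wraps: stored as [4890, 5040)
  expect_equal(c(ctx$utr5$start, ctx$utr5$end), c(4890, 5040))
  # and a candidate inside the wrapped part is classified utr5
  cand <- data.frame(contig = "chr", strand = "+", start = 4900, end = 4990)
  lab <- classify_candidates(cand, ctx, g)
  expect_equal(lab$primary, "utr5")
})

test_that("classification fires labels by overlap fraction", {
  g <- lin_genome(5000)
  f <- data.frame(feature_id = "c1", contig = "chr", strand = "+",
                  start = 1000, end = 2000, kind = "CDS")
  ctx <- build_context_map(f, g)
  classify1 <- function(s, e, strand) {
    classify_candidates(data.frame(contig = "chr", strand = strand,
                                   start = s, end = e), ctx, g)$primary
  }
  expect_equal(classify1(860, 1000, "+"), "utr5")
  expect_equal(classify1(1200, 1300, "-"), "antisense")
  expect_equal(classify1(1200, 1300, "+"), "intragenic")
  expect_equal(classify1(2010, 2100, "+"), "utr3")
  expect_equal(classify1(3000, 3100, "+"), "intergenic")
  # straddling the 3' boundary half-and-half: mixed utr3/intragenic
  expect_equal(classify1(1950, 2050, "+"), "mixed")
  lab <- classify_candidates(data.frame(contig = "chr", strand = "+",
                                        start = 1950, end = 2050), ctx, g)
  expect_setequal(strsplit(lab$constituents, "/")[[1]],
                  c("utr3", "intragenic"))
  # below min_frac nothing fires: 42% over the 5'UTR window, 0% CDS
  expect_equal(classify1(780, 900, "+"), "intergenic")
  # majority over the CDS body fires intragenic even when straddling
  expect_equal(classify1(960, 1060, "+"), "intragenic")
  # antisense includes opposite-strand UTR windows by default, not when off
  expect_equal(classify1(880, 990, "-"), "antisense")
  lab2 <- classify_candidates(data.frame(contig = "chr", strand = "-",
                                         start = 880, end = 990), ctx, g,
                              antisense_includes_utr = FALSE)
  expect_equal(lab2$primary, "intergenic")
})

test_that("every candidate gets exactly one primary label (partition)", {
  g <- make_genome(seed = 19, length = 50000, n_cds = 40)
  ctx <- build_context_map(g$features, g$genome)
  set.seed(20)
  cand <- data.frame(contig = "synthetic_chr",
                     strand = sample(c("+", "-"), 200, TRUE),
                     start = sample(0:49000, 200))
  cand$end <- cand$start + sample(50:400, 200, TRUE)
  cand <- cand[cand$end <= 50000, ]
  lab <- classify_candidates(cand, ctx, g$genome)
  valid <- c("intergenic", "utr5", "utr3", "antisense", "intragenic", "mixed")
  expect_true(all(lab$primary %in% valid))
  expect_equal(sum(table(lab$primary)), nrow(cand))
  expect_true(all((lab$primary == "mixed") == (nchar(lab$constituents) > 0)))
})

test_that("GC skew matches hand counts and stays in [-1, 1]", {
  g <- genome_record("chr", strrep("G", 500))
  expect_equal(gc_skew(g, window = 100, step = 100)$skew[1], 1)
  g2 <- genome_record("chr", strrep("GGCC", 25))
  expect_equal(gc_skew(g2, window = 100, step = 100)$skew[1], 0)
  g3 <- genome_record("chr", "GCGGG")
  sk <- gc_skew(g3, window = 5, step = 5)
  expect_equal(sk$skew[1], 0.6) # (4-1)/(4+1)
  expect_equal(sk$gc_percent[1], 100)
  # windows of pure A/T give NA skew; N positions are excluded from GC%
  g4 <- genome_record("chr", strrep("AT", 50))
  expect_true(is.na(gc_skew(g4, window = 100, step = 100)$skew[1]))
  g5 <- genome_record("chr", paste0(strrep("GN", 25), strrep("AT", 25)))
  sk5 <- gc_skew(g5, window = 100, step = 100)
  expect_equal(sk5$gc_percent[1], 25 / 75 * 100)
  expect_error(gc_skew(g3, window = 0), "window")

  gg <- make_genome(seed = 22, length = 30000, n_cds = 5)$genome
  sk <- gc_skew(gg, window = 5000, step = 500)
  expect_true(all(sk$skew >= -1 & sk$skew <= 1))
})

test_that("reverse complement negates the mirrored window skew", {
  gg <- make_genome(seed = 23, length = 20000, n_cds = 5)$genome
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", gg$sequence), "")[[1]]),
              collapse = "")
  grc <- genome_record("chr_rc", rc)
  gg_lin <- genome_record("chr", gg$sequence) # compare on linear windows
  L <- gg$length; win <- 4000
  sk_f <- gc_skew(gg_lin, window = win, step = 1000)
  sk_r <- gc_skew(grc, window = win, step = 1000)
  # window starting at p forward corresponds to window at L - win - p on rc
  for (i in seq_len(nrow(sk_f))) {
    p <- sk_f$position[i]
    j <- which(sk_r$position == L - win - p)
    if (length(j) == 1) {
      expect_equal(sk_f$skew[i], -sk_r$skew[j])
    }
  }
})

test_that("replichore estimation finds the planted origin and terminus", {
  g <- make_genome(seed = 24, length = 60000, n_cds = 10,
                   skew_strength = 0.25)
  # hints present: returned verbatim
  est <- estimate_replichores(g$genome)
  expect_equal(est$origin, 0)
  expect_equal(est$terminus, 30000)
  # without hints: cumulative-skew extrema within 2% of genome length
  g2 <- g$genome; g2$origin_hint <- NULL; g2$terminus_hint <- NULL
  est2 <- estimate_replichores(g2)
  circ_dist <- function(a, b, L) min((a - b) %% L, (b - a) %% L)
  expect_lte(circ_dist(est2$origin, 0, 60000), 1200)
  expect_lte(circ_dist(est2$terminus, 30000, 60000), 1200)
  # flat skew errors with advice
  flat <- genome_record("chr", strrep("AT", 500))
  expect_error(estimate_replichores(flat), "hints")
})

test_that("leading-strand fraction follows the replichore arcs", {
  iv <- data.frame(strand = "+", start = c(100, 200), end = c(150, 260))
  expect_equal(leading_strand_fraction(iv, 0, 500, 1000), 1)
  iv2 <- data.frame(strand = "-", start = c(100, 200), end = c(150, 260))
  expect_equal(leading_strand_fraction(iv2, 0, 500, 1000), 0)
  # random placement on both strands converges to 1/2
  set.seed(25)
  n <- 2000
  s <- sample(0:9000, n, TRUE)
  ivr <- data.frame(strand = sample(c("+", "-"), n, TRUE), start = s,
                    end = s + 50)
  lf <- leading_strand_fraction(ivr, 0, 5000, 10000)
  expect_lt(abs(lf - 0.5), 3 * sqrt(0.25 / n))
  expect_error(leading_strand_fraction(ivr[0, ], 0, 5000, 10000), "empty")
  expect_error(leading_strand_fraction(ivr, 5, 5, 10000), "differ")
})

test_that("classification is invariant under genome rotation", {
  g <- make_genome(seed = 26, length = 40000, n_cds = 30)
  pl <- plant_srnas(g$genome, g$features,
                    c(intergenic = 2, utr5 = 2, antisense = 2,
                      intragenic = 2), seed = 6)
  ctx <- build_context_map(g$features, g$genome)
  lab0 <- classify_candidates(pl, ctx, g$genome)$primary
  # rotate everything by 13000 nt (re-origin the circular genome)
  rot <- 13000; L <- g$genome$length
  seq_rot <- paste0(substr(g$genome$sequence, rot + 1, L),
                    substr(g$genome$sequence, 1, rot))
  g_rot <- genome_record(g$genome$contig_id, seq_rot, circular = TRUE)
  f_rot <- g$features
  f_rot$start <- (f_rot$start - rot) %% L
  f_rot$end <- f_rot$start + (g$features$end - g$features$start)
  pl_rot <- pl
  pl_rot$start <- (pl$start - rot) %% L
  pl_rot$end <- pl_rot$start + (pl$end - pl$start)
  ctx_rot <- build_context_map(f_rot, g_rot)
  lab1 <- classify_candidates(pl_rot, ctx_rot, g_rot)$primary
  expect_equal(lab1, lab0)
})

test_that("strand complementation swaps labels consistently", {
  g <- lin_genome(5000)
  f <- data.frame(feature_id = "c1", contig = "chr", strand = "+",
                  start = 1000, end = 2000, kind = "CDS")
  f_flip <- f; f_flip$strand <- "-"
  ctx <- build_context_map(f, g, u5 = 0, u3 = 0)
  ctx_flip <- build_context_map(f_flip, g, u5 = 0, u3 = 0)
  cand <- data.frame(contig = "chr", strand = "+", start = 1100, end = 1200)
  cand_flip <- cand; cand_flip$strand <- "-"
  expect_equal(classify_candidates(cand, ctx, g)$primary, "intragenic")
  expect_equal(classify_candidates(cand_flip, ctx_flip, g)$primary,
               "intragenic")
  expect_equal(classify_candidates(cand_flip, ctx, g)$primary, "antisense")
  expect_equal(classify_candidates(cand, ctx_flip, g)$primary, "antisense")
})
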