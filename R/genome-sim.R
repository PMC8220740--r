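#' Generate a toy circular bacterial genome with CDS annotation
#'
#' The genome has its replication origin at position 0 and terminus at
#' `length/2`, giving two replichores. Base composition is skewed so that
#' the leading strand shows positive GC skew `(G - C)/(G + C)`
#' proportional to `skew_strength`, as real bacterial chromosomes do, and
#' a configurable fraction of CDSs is placed on the leading strand
#' (bacteria favour co-orientation of genes with replication; the emulated
#' organism has about 72% of CDSs leading).
#'
#' @param seed RNG seed.
#' @param length genome length in nt (must be at least 10x the mean CDS
#'   length).
#' @param n_cds number of non-overlapping CDSs to place.
#' @param gc_fraction genome GC content in (0, 1).
#' @param skew_strength G-vs-C asymmetry on the leading strand; 0 gives a
#'   skew-free genome.
#' @param leading_fraction probability a CDS is placed on the leading
#'   strand (default 0.72).
#' @param cds_len_range CDS length range, nt.
#' @return list with `genome` (a [genome_record()], `circular = TRUE`,
#'   origin/terminus hints set) and `features` (CDS data.frame).
#' @export
make_genome <- function(seed, length = 50000, n_cds = 50,
                        gc_fraction = 0.46, skew_strength = 0.2,
                        leading_fraction = 0.72,
                        cds_len_range = c(300, 700)) {
  stopifnot(gc_fraction > 0, gc_fraction < 1,
            skew_strength >= 0, skew_strength <= 1)
  if (length < 10 * mean(cds_len_range)) {
    stop("genome length must be at least 10x the mean CDS length")
  }
  ter <- floor(length / 2)
  with_seed(derive_seed(seed, 11), {
    # replichore 1 = [0, ter): leading strand is '+' there
    leading_plus <- c(rep(TRUE, ter), rep(FALSE, length - ter))
    p_g_given_gc <- ifelse(leading_plus, 0.5 * (1 + skew_strength),
                           0.5 * (1 - skew_strength))
    is_gc <- runif(length) < gc_fraction
    u <- runif(length)
    base <- ifelse(is_gc, ifelse(u < p_g_given_gc, "G", "C"),
                   ifelse(u < 0.5, "A", "T"))
    sequence <- paste(base, collapse = "")

    # non-overlapping CDS placement by rejection sampling
    starts <- integer(0); ends <- integer(0)
    tries <- 0
    while (base::length(starts) < n_cds) {
      tries <- tries + 1
      if (tries > n_cds * 500) {
        stop("infeasible packing: could not place ", n_cds,
             " CDSs in ", length, " nt")
      }
      len <- sample(cds_len_range[1]:cds_len_range[2], 1)
      s <- sample.int(length - len, 1) - 1L
      e <- s + len
      if (all(e + 2 <= starts | s >= ends + 2)) {
        starts <- c(starts, s); ends <- c(ends, e)
      }
    }
    ord <- order(starts)
    starts <- starts[ord]; ends <- ends[ord]
    mid <- (starts + ends) / 2
    leading_strand <- ifelse(mid < ter, "+", "-")
    lagging_strand <- ifelse(mid < ter, "-", "+")
    on_leading <- runif(n_cds) < leading_fraction
    strand <- ifelse(on_leading, leading_strand, lagging_strand)
  })
  features <- data.frame(
    feature_id = sprintf("cds_%04d", seq_len(n_cds)),
    contig = "synthetic_chr",
    strand = strand,
    start = as.numeric(starts),
    end = as.numeric(ends),
    kind = "CDS",
    stringsAsFactors = FALSE
  )
  genome <- genome_record("synthetic_chr", sequence, circular = TRUE,
                          origin_hint = 0, terminus_hint = ter)
  list(genome = genome, features = features)
}

#' Plant sRNAs of known genomic context into an annotated genome
#'
#' Places oriented intervals whose true context class (intergenic, 5'/3'
#' UTR-derived, antisense, intragenic, or mixed) is guaranteed: every
#' planted interval is verified against [classify_candidates()] under the
#' same window/threshold settings, so generator and classifier are
#' contractually consistent. Planted sRNAs on the same strand keep at
#' least `min_gap` nt of clearance so coverage segmentation can separate
#' them. Abundances are drawn log-normal.
#'
#' @param genome,features output of [make_genome()] (or equivalents).
#' @param class_counts named integer vector over
#'   `intergenic/utr5/utr3/antisense/intragenic/mixed`.
#' @param seed RNG seed.
#' @param len_range sRNA length range (default 50-500 nt).
#' @param sharpness `"sharp"` or `"ramped"` boundary type, recycled over
#'   planted sRNAs.
#' @param u5,u3,min_frac classifier settings (see [build_context_map()],
#'   [classify_candidates()]).
#' @param abund_meanlog,abund_sdlog log-normal abundance parameters.
#' @param min_gap same-strand clearance between planted sRNAs, nt.
#' @param avoid optional interval table (`strand`, `start`, `end`) that
#'   planted sRNAs must also keep `min_gap` clearance from (e.g. an
#'   earlier truth set).
#' @param max_tries proposals per sRNA before giving up.
#' @return data.frame (`planted_srnas`): `id`, `contig`, `strand`,
#'   `start`, `end`, `true_class`, `abundance`, `sharpness`.
#' @export
plant_srnas <- function(genome, features, class_counts, seed,
                        len_range = c(50, 500), sharpness = "sharp",
                        u5 = 150, u3 = 150, min_frac = 0.5,
                        abund_meanlog = 0, abund_sdlog = 0.25,
                        min_gap = 30, max_tries = 1000, avoid = NULL) {
  classes <- c("intergenic", "utr5", "utr3", "antisense", "intragenic", "mixed")
  class_counts <- class_counts[class_counts > 0]
  if (!all(names(class_counts) %in% classes)) {
    stop("unknown class in class_counts")
  }
  ctx <- build_context_map(features, genome, u5 = u5, u3 = u3)
  L <- genome$length
  planted <- data.frame(contig = character(0), strand = character(0),
                        start = numeric(0), end = numeric(0),
                        true_class = character(0), stringsAsFactors = FALSE)
  clear_of_planted <- function(s, e, strand) {
    same <- planted[planted$strand == strand, c("start", "end"), drop = FALSE]
    if (!is.null(avoid)) {
      same <- rbind(same, avoid[avoid$strand == strand, c("start", "end"),
                                drop = FALSE])
    }
    if (nrow(same) == 0) return(TRUE)
    all(pmin(e + min_gap, same$end) <= pmax(s - min_gap, same$start))
  }
  propose <- list(
    intergenic = function() {
      len <- sample(len_range[1]:min(len_range[2], 300), 1)
      s <- sample.int(L - len, 1) - 1
      list(s = s, e = s + len, strand = sample(c("+", "-"), 1))
    },
    utr5 = function() {
      if (nrow(ctx$utr5) == 0) stop("no 5'UTR windows available")
      w <- ctx$utr5[sample.int(nrow(ctx$utr5), 1), ]
      wl <- w$end - w$start
      if (wl < len_range[1]) return(NULL)
      len <- sample(len_range[1]:wl, 1)
      s <- w$start + sample.int(wl - len + 1, 1) - 1
      list(s = s, e = s + len, strand = w$strand)
    },
    utr3 = function() {
      if (nrow(ctx$utr3) == 0) stop("no 3'UTR windows available")
      w <- ctx$utr3[sample.int(nrow(ctx$utr3), 1), ]
      wl <- w$end - w$start
      if (wl < len_range[1]) return(NULL)
      len <- sample(len_range[1]:wl, 1)
      s <- w$start + sample.int(wl - len + 1, 1) - 1
      list(s = s, e = s + len, strand = w$strand)
    },
    antisense = function() {
      f <- features[sample.int(nrow(features), 1), ]
      flen <- f$end - f$start
      if (flen < len_range[1]) return(NULL)
      len <- sample(len_range[1]:min(len_range[2], flen), 1)
      s <- f$start + sample.int(flen - len + 1, 1) - 1
      list(s = s, e = s + len, strand = if (f$strand == "+") "-" else "+")
    },
    intragenic = function() {
      f <- features[sample.int(nrow(features), 1), ]
      flen <- f$end - f$start
      if (flen < len_range[1]) return(NULL)
      len <- sample(len_range[1]:min(len_range[2], flen), 1)
      s <- f$start + sample.int(flen - len + 1, 1) - 1
      list(s = s, e = s + len, strand = f$strand)
    },
    mixed = function() {
      # straddle a CDS 3' end: half intragenic, half 3'UTR-derived
      f <- features[sample.int(nrow(features), 1), ]
      w <- ctx$utr3[ctx$utr3$feature_id == f$feature_id, , drop = FALSE]
      if (nrow(w) == 0) return(NULL)
      wl <- w$end[1] - w$start[1]
      half <- min(wl, floor((f$end - f$start) / 2), 120)
      if (2 * half < len_range[1]) return(NULL)
      if (f$strand == "+") {
        list(s = f$end - half, e = f$end + half, strand = "+")
      } else {
        list(s = f$start - half, e = f$start + half, strand = "-")
      }
    }
  )
  with_seed(derive_seed(seed, 23), {
    for (cls in names(class_counts)) {
      for (i in seq_len(class_counts[[cls]])) {
        ok <- FALSE
        for (tr in seq_len(max_tries)) {
          cand <- propose[[cls]]()
          if (is.null(cand) || cand$s < 0 || cand$e > L) next
          if (!clear_of_planted(cand$s, cand$e, cand$strand)) next
          iv <- data.frame(contig = genome$contig_id, strand = cand$strand,
                           start = cand$s, end = cand$e)
          lab <- classify_candidates(iv, ctx, genome, min_frac = min_frac)
          if (lab$primary != cls) next
          if (cls == "intergenic") {
            # planted intergenic sRNAs carry strictly zero annotation
            # overlap, not merely sub-threshold overlap
            regions <- rbind(features[, c("start", "end")],
                             ctx$utr5[, c("start", "end")],
                             ctx$utr3[, c("start", "end")])
            if (union_overlap(cand$s, cand$e, regions, L) > 0) next
          }
          planted <- rbind(planted, data.frame(
            contig = genome$contig_id, strand = cand$strand,
            start = cand$s, end = cand$e, true_class = cls,
            stringsAsFactors = FALSE))
          ok <- TRUE
          break
        }
        if (!ok) stop("geometry exhaustion while planting class '", cls, "'")
      }
    }
    n <- nrow(planted)
    planted$abundance <- if (n) rlnorm(n, abund_meanlog, abund_sdlog) else numeric(0)
  })
  planted$id <- if (nrow(planted)) sprintf("srna_%03d", seq_len(nrow(planted))) else character(0)
  planted$sharpness <- rep_len(sharpness, nrow(planted))
  planted[, c("id", "contig", "strand", "start", "end", "true_class",
              "abundance", "sharpness")]
}
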