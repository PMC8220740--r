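#' Build a genomic-context map (CDS bodies plus flanking UTR windows)
#'
#' Bacterial annotations rarely include UTRs, so UTR-derived context is
#' approximated by fixed windows: `u5` nt upstream of each CDS start and
#' `u3` nt downstream of each CDS end, on the CDS strand, truncated at the
#' first base of any annotated CDS encountered. Windows wrap across the
#' origin on circular genomes (wrapped intervals carry `end > genome
#' length`).
#'
#' @param features CDS table (`feature_id`, `contig`, `strand`, `start`,
#'   `end`).
#' @param genome the [genome_record()].
#' @param u5,u3 window lengths in nt (defaults 150).
#' @return a `context_map`: list with `cds`, `utr5`, `utr3` tables,
#'   `genome_len`, `circular`.
#' @export
build_context_map <- function(features, genome, u5 = 150, u3 = 150) {
  L <- genome$length
  circ <- genome$circular
  cut_ends <- sort(c(features$end, features$end + L))
  cut_starts <- sort(c(features$start, features$start + L))

  # window extending left (to lower coordinates) from anchor `a`, length u,
  # truncated at the nearest CDS end; computed in [L, 2L) shifted frame
  win_left <- function(a, u) {
    A <- a + L
    lo <- A - u
    cuts <- cut_ends[cut_ends > lo & cut_ends <= A]
    if (length(cuts)) lo <- max(cuts)
    if (!circ) lo <- max(lo, L)
    c(lo - L, a)
  }
  win_right <- function(a, u) {
    hi <- a + u
    cuts <- cut_starts[cut_starts >= a & cut_starts < hi]
    if (length(cuts)) hi <- min(cuts)
    if (!circ) hi <- min(hi, L)
    c(a, hi)
  }
  u5_list <- list()
  u3_list <- list()
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    if (f$strand == "+") {
      w5 <- win_left(f$start, u5)
      w3 <- win_right(f$end, u3)
    } else {
      w5 <- win_right(f$end, u5)
      w3 <- win_left(f$start, u3)
    }
    for (w in list(list(w5, "u5"), list(w3, "u3"))) {
      b <- w[[1]]
      if (b[2] <= b[1]) next
      row <- data.frame(feature_id = f$feature_id, contig = f$contig,
                        strand = f$strand,
                        start = if (b[1] < 0) b[1] + L else b[1],
                        end = if (b[1] < 0) b[2] + L else b[2],
                        stringsAsFactors = FALSE)
      if (w[[2]] == "u5") u5_list[[length(u5_list) + 1]] <- row
      else u3_list[[length(u3_list) + 1]] <- row
    }
  }
  empty <- data.frame(feature_id = character(0), contig = character(0),
                      strand = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE)
  structure(
    list(cds = features,
         utr5 = if (length(u5_list)) do.call(rbind, u5_list) else empty,
         utr3 = if (length(u3_list)) do.call(rbind, u3_list) else empty,
         genome_len = L, circular = circ, u5 = u5, u3 = u3),
    class = "context_map"
  )
}

# total overlap of [s,e) with the union of intervals in tbl (mod L when
# intervals wrap)
union_overlap <- function(s, e, tbl, L) {
  if (nrow(tbl) == 0) return(0)
  parts <- split_wrapped(tbl$start, tbl$end, L)
  q <- split_wrapped(s, e, L)
  # merge parts into disjoint runs
  ord <- order(parts$start)
  ps <- parts$start[ord]; pe <- parts$end[ord]
  ms <- numeric(0); me <- numeric(0)
  for (i in seq_along(ps)) {
    if (length(ms) && ps[i] <= me[length(me)]) {
      me[length(me)] <- max(me[length(me)], pe[i])
    } else {
      ms <- c(ms, ps[i]); me <- c(me, pe[i])
    }
  }
  tot <- 0
  for (qi in seq_len(nrow(q))) {
    tot <- tot + sum(pmax(0, pmin(q$end[qi], me) - pmax(q$start[qi], ms)))
  }
  tot
}

#' Classify sRNA candidates by genomic context
#'
#' A context label fires when at least `min_frac` of the candidate's length
#' overlaps the corresponding region set: same-strand 5'UTR window
#' (`utr5`), same-strand 3'UTR window (`utr3`), same-strand CDS body
#' (`intragenic`), or opposite-strand CDS — including its UTR windows by
#' default (`antisense`). No label fired gives `intergenic`; one label
#' gives that class; two or more give `mixed`, with the constituents
#' recorded (e.g. `"utr3/antisense"`). Labels partition the candidate set:
#' every candidate receives exactly one primary class.
#'
#' @param candidates interval table (`contig`, `strand`, `start`, `end`).
#' @param context a [build_context_map()] result.
#' @param genome the [genome_record()].
#' @param min_frac minimum overlap fraction of the candidate length for a
#'   label to fire (default 0.5).
#' @param antisense_includes_utr count opposite-strand UTR windows towards
#'   the antisense label (default `TRUE`).
#' @return data.frame with `primary` and `constituents` per candidate.
#' @export
classify_candidates <- function(candidates, context, genome, min_frac = 0.5,
                                antisense_includes_utr = TRUE) {
  L <- context$genome_len
  cds <- context$cds
  out <- data.frame(primary = character(nrow(candidates)),
                    constituents = character(nrow(candidates)),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, ]
    len <- cand$end - cand$start
    opp <- if (cand$strand == "+") "-" else "+"
    same_sel <- function(tbl) tbl[tbl$strand == cand$strand, , drop = FALSE]
    opp_sel <- function(tbl) tbl[tbl$strand == opp, , drop = FALSE]
    f_u5 <- union_overlap(cand$start, cand$end, same_sel(context$utr5), L) / len
    f_u3 <- union_overlap(cand$start, cand$end, same_sel(context$utr3), L) / len
    f_cds <- union_overlap(cand$start, cand$end, same_sel(cds), L) / len
    anti_tbl <- opp_sel(cds)[, c("start", "end")]
    if (antisense_includes_utr) {
      anti_tbl <- rbind(anti_tbl, opp_sel(context$utr5)[, c("start", "end")],
                        opp_sel(context$utr3)[, c("start", "end")])
    }
    f_anti <- union_overlap(cand$start, cand$end, anti_tbl, L) / len
    fired <- c(utr5 = f_u5 >= min_frac, utr3 = f_u3 >= min_frac,
               antisense = f_anti >= min_frac, intragenic = f_cds >= min_frac)
    labs <- names(fired)[fired]
    if (length(labs) == 0) {
      out$primary[i] <- "intergenic"
    } else if (length(labs) == 1) {
      out$primary[i] <- labs
    } else {
      out$primary[i] <- "mixed"
      out$constituents[i] <- paste(labs, collapse = "/")
    }
  }
  out
}

#' Windowed GC skew and GC content along a genome
#'
#' `skew = (G - C) / (G + C)` over sliding windows on the forward strand;
#' windows start on the `step` grid and wrap on circular genomes. Windows
#' with no G or C yield `NA`. `N` positions are excluded from both
#' statistics. Cumulative-skew extrema of such series locate the
#' replication origin and terminus, which in turn define the leading
#' strands.
#'
#' @param genome a [genome_record()].
#' @param window window size in nt (default 10000).
#' @param step step size in nt (default 200).
#' @return data.frame with `position` (0-based window start), `skew`,
#'   `gc_percent`.
#' @export
gc_skew <- function(genome, window = 10000, step = 200) {
  if (window < 1 || step < 1) stop("window and step must be >= 1")
  L <- genome$length
  if (window > L) stop("window exceeds genome length")
  b <- strsplit(genome$sequence, "")[[1]]
  if (genome$circular) {
    starts <- seq(0, L - 1, by = step)
    b2 <- c(b, b)
  } else {
    starts <- seq(0, L - window, by = step)
    b2 <- b
  }
  cg <- cumsum(c(0, b2 == "G"))
  cc <- cumsum(c(0, b2 == "C"))
  cn <- cumsum(c(0, b2 == "N"))
  g <- cg[starts + window + 1] - cg[starts + 1]
  ccount <- cc[starts + window + 1] - cc[starts + 1]
  nn <- cn[starts + window + 1] - cn[starts + 1]
  gc <- g + ccount
  skew <- ifelse(gc == 0, NA_real_, (g - ccount) / gc)
  valid <- window - nn
  gc_percent <- ifelse(valid == 0, NA_real_, gc / valid * 100)
  data.frame(position = starts, skew = skew, gc_percent = gc_percent)
}

#' Locate the replication origin and terminus from cumulative GC skew
#'
#' Computes the per-base cumulative skew (+1 for G, -1 for C) and returns
#' the position of its global minimum as the origin and of its global
#' maximum as the terminus — the standard replichore construction. Hints
#' stored on the genome record take precedence.
#'
#' @param genome a [genome_record()] (circular).
#' @return list with `origin` and `terminus` (0-based positions).
#' @export
estimate_replichores <- function(genome) {
  if (!is.null(genome$origin_hint) && !is.null(genome$terminus_hint)) {
    return(list(origin = genome$origin_hint, terminus = genome$terminus_hint))
  }
  b <- strsplit(genome$sequence, "")[[1]]
  cum <- cumsum((b == "G") - (b == "C"))
  if (max(cum) == min(cum)) {
    stop("flat cumulative skew: no replichore structure detectable; ",
         "set origin/terminus hints on the genome record")
  }
  list(origin = which.min(cum) %% genome$length,
       terminus = which.max(cum) %% genome$length)
}

#' Fraction of features on the leading strand
#'
#' A forward-strand feature is leading when its midpoint lies on the arc
#' from origin to terminus (increasing coordinates, wrapping); a
#' reverse-strand feature is leading on the complementary arc.
#'
#' @param intervals table with `strand`, `start`, `end`.
#' @param origin,terminus 0-based replichore positions (distinct).
#' @param genome_len genome length for midpoint wrapping.
#' @return fraction in \[0, 1\].
#' @export
leading_strand_fraction <- function(intervals, origin, terminus, genome_len) {
  if (nrow(intervals) == 0) stop("empty feature set")
  if (origin == terminus) stop("origin and terminus must differ")
  mid <- ((intervals$start + intervals$end) / 2) %% genome_len
  in_arc <- if (origin < terminus) {
    mid >= origin & mid < terminus
  } else {
    mid >= origin | mid < terminus
  }
  leading <- ifelse(intervals$strand == "+", in_arc, !in_arc)
  mean(leading)
}
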