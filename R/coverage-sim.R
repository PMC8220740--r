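#' Strand-specific per-base coverage track
#'
#' @param contig contig id.
#' @param strand `"+"` or `"-"`.
#' @param depth numeric vector of per-position depths (length = contig
#'   length).
#' @param replicate_id,library_id labels.
#' @return a `coverage_track`.
#' @export
coverage_track <- function(contig, strand, depth, replicate_id = NA,
                           library_id = NA) {
  if (any(depth < 0)) stop("negative depth")
  structure(
    list(contig = contig, strand = strand, depth = as.numeric(depth),
         replicate_id = replicate_id, library_id = library_id),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("<coverage_track> ", x$contig, " (", x$strand, ") lib=",
      x$library_id, " rep=", x$replicate_id, ", ", length(x$depth),
      " nt, mean depth ", round(mean(x$depth), 2), "\n", sep = "")
  invisible(x)
}

pileup <- function(starts, ends, L) {
  # fragment pileup via a difference array; fragments may wrap (end > L)
  d <- numeric(L + 1)
  if (length(starts)) {
    wrap <- ends > L
    s1 <- c(starts[!wrap], starts[wrap], rep(0, sum(wrap)))
    e1 <- c(ends[!wrap], rep(L, sum(wrap)), ends[wrap] - L)
    for (i in seq_along(s1)) {
      d[s1[i] + 1] <- d[s1[i] + 1] + 1
      d[e1[i] + 1] <- d[e1[i] + 1] - 1
    }
  }
  cumsum(d)[seq_len(L)]
}

#' Simulate replicate coverage tracks (and fragments) for planted sRNAs
#'
#' For each library and replicate, each planted sRNA emits a Poisson number
#' of fragments (mean `depth * abundance`). Fragments of a `sharp` sRNA
#' span exactly its interval, so coverage steps exactly at the boundaries;
#' for a `ramped` sRNA both fragment ends are displaced inward by
#' geometric amounts with mean about `ramp` nt, producing a gradual
#' coverage ramp that the boundary crosscheck filter is designed to
#' reject. Background is modeled as random fragments (geometric lengths,
#' mean `bg_frag_len`) at a rate giving mean per-base coverage
#' `background_rate`. Everything is deterministic under `seed`, with
#' independent substreams per library and replicate.
#'
#' @param planted [plant_srnas()] table.
#' @param genome the [genome_record()].
#' @param depth mean fragments per planted sRNA per replicate.
#' @param background_rate mean background coverage per nt per replicate.
#' @param replicates replicates per library.
#' @param libraries character vector of library ids.
#' @param ramp geometric ramp scale for `ramped` boundaries, nt.
#' @param bg_frag_len mean background fragment length, nt.
#' @param seed RNG seed.
#' @return list with `tracks` (list of `coverage_track`, one per library x
#'   replicate x strand) and `fragments` (data.frame with `contig`,
#'   `strand`, `start`, `end`, `library`, `replicate`).
#' @export
simulate_coverage <- function(planted, genome, depth = 50,
                              background_rate = 1, replicates = 3,
                              libraries = "lib1", ramp = 15,
                              bg_frag_len = 75, seed = 1) {
  stopifnot(replicates >= 1, depth >= 0, background_rate >= 0)
  L <- genome$length
  tracks <- list()
  frags <- list()
  for (li in seq_along(libraries)) {
    for (r in seq_len(replicates)) {
      sub <- derive_seed(seed, 1000 * li + r)
      fr <- with_seed(sub, {
        fs <- numeric(0); fe <- numeric(0); fstrand <- character(0)
        for (k in seq_len(nrow(planted))) {
          p <- planted[k, ]
          n <- rpois(1, depth * p$abundance)
          if (n == 0) next
          if (identical(p$sharpness, "ramped")) {
            # symmetric geometric end displacement: coverage rises and
            # falls over ~ramp nt with no sharp step anywhere
            len <- p$end - p$start
            dmax_in <- max(0, floor((len - 10) / 2))
            d5 <- sample(c(-1, 1), n, replace = TRUE) * rgeom(n, 1 / ramp)
            d3 <- sample(c(-1, 1), n, replace = TRUE) * rgeom(n, 1 / ramp)
            d5 <- pmin(d5, dmax_in)
            d3 <- pmin(d3, dmax_in)
            s <- pmax(p$start + d5, 0)
            e <- pmin(p$end - d3, L)
          } else {
            s <- rep(p$start, n)
            e <- rep(p$end, n)
          }
          fs <- c(fs, s); fe <- c(fe, e)
          fstrand <- c(fstrand, rep(p$strand, n))
        }
        if (background_rate > 0) {
          n_bg <- rpois(2, L * background_rate / bg_frag_len)
          for (si in 1:2) {
            st <- c("+", "-")[si]
            if (n_bg[si] == 0) next
            blen <- pmax(20, rgeom(n_bg[si], 1 / bg_frag_len))
            bs <- vapply(blen, function(l) {
              sample.int(max(1, L - l), 1) - 1
            }, 0)
            fs <- c(fs, bs); fe <- c(fe, bs + blen)
            fstrand <- c(fstrand, rep(st, n_bg[si]))
          }
        }
        data.frame(contig = genome$contig_id, strand = fstrand,
                   start = fs, end = fe, stringsAsFactors = FALSE)
      })
      fr$library <- libraries[li]
      fr$replicate <- r
      frags[[length(frags) + 1]] <- fr
      for (st in c("+", "-")) {
        sel <- fr$strand == st
        tracks[[length(tracks) + 1]] <- coverage_track(
          genome$contig_id, st, pileup(fr$start[sel], fr$end[sel], L),
          replicate_id = r, library_id = libraries[li]
        )
      }
    }
  }
  list(tracks = tracks, fragments = do.call(rbind, frags))
}

#' Simulate a complete two-library, multi-replicate sRNA study
#'
#' Builds a circular genome with CDS annotation, plants sRNAs of all six
#' context classes (a sharp-boundary truth set plus ramped-boundary
#' decoys), and simulates strand-specific replicate coverage for each
#' library. The defaults are the package's reference study conditions: 30
#' sharp + 10 ramped sRNAs, fragment depth 50, background coverage 1 per
#' nt, 3 replicates in each of 2 libraries.
#'
#' @param seed RNG seed driving every stage.
#' @param genome_length,n_cds genome geometry.
#' @param sharp_counts,ramped_counts named class-count vectors for the
#'   truth set and the ramped decoys.
#' @param depth,background_rate,replicates,libraries,ramp coverage
#'   parameters (see [simulate_coverage()]).
#' @return list with `genome`, `features`, `planted` (truth table),
#'   `tracks`, `fragments`.
#' @export
simulate_srna_study <- function(seed,
                                genome_length = 80000, n_cds = 60,
                                sharp_counts = c(intergenic = 7, utr5 = 5,
                                                 utr3 = 5, antisense = 6,
                                                 intragenic = 4, mixed = 3),
                                ramped_counts = c(intergenic = 4, utr5 = 2,
                                                  antisense = 3,
                                                  intragenic = 1),
                                depth = 50, background_rate = 1,
                                replicates = 3, libraries = c("C", "N"),
                                ramp = 15) {
  gen <- make_genome(derive_seed(seed, 1), length = genome_length,
                     n_cds = n_cds)
  sharp <- plant_srnas(gen$genome, gen$features, sharp_counts,
                       seed = derive_seed(seed, 2), sharpness = "sharp")
  ramped <- plant_srnas(gen$genome, gen$features, ramped_counts,
                        seed = derive_seed(seed, 3), sharpness = "ramped",
                        avoid = sharp)
  if (nrow(ramped)) ramped$id <- sprintf("decoy_%03d", seq_len(nrow(ramped)))
  planted <- rbind(sharp, ramped)
  cov <- simulate_coverage(planted, gen$genome, depth = depth,
                           background_rate = background_rate,
                           replicates = replicates, libraries = libraries,
                           ramp = ramp, seed = derive_seed(seed, 4))
  list(genome = gen$genome, features = gen$features, planted = planted,
       tracks = cov$tracks, fragments = cov$fragments)
}
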