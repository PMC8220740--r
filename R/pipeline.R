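#' Run the full sRNA discovery pipeline on a set of coverage tracks
#'
#' Per library: segment replicate-mean coverage, apply the boundary
#' crosscheck filter, keep passing candidates; then merge candidates
#' across libraries (widest coordinates), count fragments, normalize
#' (TMM), apply the mean-CPM retention filter, and classify the retained
#' sRNAs by genomic context.
#'
#' @param tracks list of `coverage_track`s (all libraries/replicates).
#' @param fragments fragment table for counting.
#' @param genome the [genome_record()].
#' @param features CDS annotation.
#' @param min_cov,max_gap,len_range segmentation settings
#'   ([segment_coverage()]).
#' @param t,w,min_replicates,same_replicate refinement settings
#'   ([refine_candidates()]).
#' @param delta merge tolerance ([merge_across_libraries()]).
#' @param cpm_threshold retention threshold ([cpm_filter()]).
#' @param u5,u3,min_frac classification settings.
#' @return list with `per_library` (refined candidate tables), `merged`,
#'   `count_table`, `norm_factors`, `cpm`, `srnas` (final table with
#'   class labels and per-library mean CPMs), `venn`.
#' @export
run_srna_pipeline <- function(tracks, fragments, genome, features,
                              min_cov = 5, max_gap = 5,
                              len_range = c(50, 500),
                              t = 3, w = 2, min_replicates = 1,
                              same_replicate = TRUE, delta = 5,
                              cpm_threshold = 15,
                              u5 = 150, u3 = 150, min_frac = 0.5) {
  libs <- unique(vapply(tracks, `[[`, "", "library_id"))
  per_library <- list()
  for (l in libs) {
    ltr <- Filter(function(x) x$library_id == l, tracks)
    cand <- segment_coverage(ltr, min_cov = min_cov, max_gap = max_gap,
                             len_range = len_range,
                             circular = genome$circular)
    ref <- refine_candidates(cand, ltr, t = t, w = w,
                             min_replicates = min_replicates,
                             same_replicate = same_replicate,
                             circular = genome$circular)
    per_library[[l]] <- ref
  }
  passing <- lapply(per_library, function(x) {
    x[x$passed_refinement, , drop = FALSE]
  })
  merged <- merge_across_libraries(passing, delta = delta)
  if (nrow(merged) == 0) {
    return(list(per_library = per_library, merged = merged,
                count_table = NULL, norm_factors = NULL, cpm = NULL,
                srnas = merged, venn = venn_counts(merged)))
  }
  tab <- count_features(fragments, merged, genome_len = genome$length)
  nf <- tmm_factors(tab)
  flt <- cpm_filter(tab, nf, threshold = cpm_threshold)
  srnas <- merged[flt$keep, , drop = FALSE]
  ctx <- build_context_map(features, genome, u5 = u5, u3 = u3)
  cls <- classify_candidates(srnas, ctx, genome, min_frac = min_frac)
  srnas$primary <- cls$primary
  srnas$constituents <- cls$constituents
  srnas$mean_cpm <- rowMeans(flt$library_means)[flt$keep]
  list(per_library = per_library, merged = merged, count_table = tab,
       norm_factors = nf, cpm = flt$cpm, srnas = srnas,
       venn = venn_counts(srnas))
}

#' Compare called sRNAs with a planted truth set
#'
#' A call matches a truth entry when strand agrees and both boundaries are
#' within `tol` nt. Precision and recall are computed against the subset
#' of the truth with `sharpness == "sharp"` (the ramped decoys are
#' expected to be rejected and are reported separately).
#'
#' @param called candidate table (`strand`, `start`, `end`).
#' @param truth [plant_srnas()] table with `sharpness`.
#' @param tol boundary tolerance, nt (default 2).
#' @return list with `precision`, `recall`, `matched` (logical per call),
#'   `recovered` (logical per sharp truth row), `ramped_called` (how many
#'   ramped decoys were called), `ramped_total`.
#' @export
evaluate_calls <- function(called, truth, tol = 2) {
  sharp <- truth[truth$sharpness == "sharp", , drop = FALSE]
  ramped <- truth[truth$sharpness == "ramped", , drop = FALSE]
  match_one <- function(s, e, st, tbl) {
    any(tbl$strand == st & abs(tbl$start - s) <= tol &
          abs(tbl$end - e) <= tol)
  }
  matched <- vapply(seq_len(nrow(called)), function(i) {
    match_one(called$start[i], called$end[i], called$strand[i], sharp)
  }, TRUE)
  recovered <- vapply(seq_len(nrow(sharp)), function(i) {
    match_one(sharp$start[i], sharp$end[i], sharp$strand[i], called)
  }, TRUE)
  ramped_called <- if (nrow(ramped)) {
    sum(vapply(seq_len(nrow(ramped)), function(i) {
      any(called$strand == ramped$strand[i] &
            pmin(called$end, ramped$end[i]) >
            pmax(called$start, ramped$start[i]))
    }, TRUE))
  } else 0L
  list(
    precision = if (nrow(called)) mean(matched) else NA_real_,
    recall = if (nrow(sharp)) mean(recovered) else NA_real_,
    matched = matched, recovered = recovered,
    ramped_called = ramped_called, ramped_total = nrow(ramped)
  )
}
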