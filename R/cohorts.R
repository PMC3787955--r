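#' Cohort-wise CNVR comparison
#'
#' The pipeline is run per cohort (founder breeds separately, F2 cross);
#' breed-unique CNVRs are those overlapping no CNVR of any other cohort,
#' and founder-to-F2 sharing is an overlap count — set overlap, not a
#' pedigree transmission analysis.
#'
#' @name cohort_comparison
NULL

#' Build one cohort's CNVR set through the full pipeline
#'
#' Filters each algorithm's calls (restricted to the cohort's samples),
#' merges them to per-algorithm CNVRs, screens gaps, and builds the
#' >= `min_support`-algorithm consensus. The identical [filter_policy()]
#' is applied to every cohort, including small founder cohorts (logged in
#' provenance: small cohorts lose power under min_carriers >= 2).
#'
#' @param calls_by_algorithm named list: algorithm id -> raw call data
#'   frame (all cohorts mixed).
#' @param sample_ids the cohort's sample ids.
#' @param cohort_id label stored in the result.
#' @param policy a [filter_policy()].
#' @param gaps optional gap feature data frame.
#' @param min_support consensus support (default 2).
#' @return list of class `cnvr_cohort_set`: `cohort_id`, `cnvrs`
#'   (consensus data frame), `per_algorithm` (list of CNVR sets),
#'   `provenance`.
#' @export
cohort_cnvr_set <- function(calls_by_algorithm, sample_ids, cohort_id,
                            policy = filter_policy(), gaps = NULL,
                            min_support = 2) {
  per_alg <- lapply(calls_by_algorithm, function(calls) {
    sub <- calls[calls$sample_id %in% sample_ids, , drop = FALSE]
    screen_gaps(merge_to_cnvrs(filter_calls(sub, policy)), gaps)$kept
  })
  cons <- build_consensus(per_alg, min_support = min_support)
  structure(list(cohort_id = cohort_id, cnvrs = cons,
                 per_algorithm = per_alg,
                 provenance = list(policy = policy,
                                   min_support = min_support,
                                   n_samples = length(sample_ids),
                                   small_cohort = length(sample_ids) < 10)),
            class = "cnvr_cohort_set")
}

#' CNVRs unique to one cohort
#'
#' Returns the target cohort's CNVRs overlapping (1-bp rule) no CNVR in
#' any other cohort's set. Uniqueness is by overlap, not coordinate
#' identity, since boundaries differ between cohorts.
#'
#' @param target CNVR data frame or `cnvr_cohort_set` of the cohort of
#'   interest.
#' @param others list of CNVR data frames / `cnvr_cohort_set`s to compare
#'   against.
#' @return the unique subset of the target CNVR data frame.
#' @export
unique_cnvrs <- function(target, others) {
  as_df <- function(x) if (inherits(x, "cnvr_cohort_set")) x$cnvrs else x
  tgt <- as_df(target)
  if (!length(others)) return(tgt)
  hit <- rep(FALSE, nrow(tgt))
  for (o in others) hit <- hit | .count_overlapping(tgt, as_df(o))
  tgt[!hit, , drop = FALSE]
}

#' Founder-to-F2 CNVR sharing
#'
#' Pools founder (F0) CNVRs across breeds — kept as separate records, not
#' re-merged — and counts those overlapping at least one F2 CNVR.
#'
#' @param f0_sets list of founder CNVR data frames / `cnvr_cohort_set`s.
#' @param f2_set the F2 CNVR data frame / `cnvr_cohort_set`.
#' @return list: `n_f0_total`, `n_f0_overlapping_f2`, `fraction_pct`.
#' @export
generation_overlap <- function(f0_sets, f2_set) {
  as_df <- function(x) if (inherits(x, "cnvr_cohort_set")) x$cnvrs else x
  pool <- do.call(rbind, lapply(f0_sets, as_df))
  if (is.null(pool) || nrow(pool) == 0)
    stop("generation_overlap: empty F0 pool")
  n_ov <- sum(.count_overlapping(pool, as_df(f2_set)))
  list(n_f0_total = nrow(pool), n_f0_overlapping_f2 = n_ov,
       fraction_pct = percent_of(n_ov, nrow(pool)))
}
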