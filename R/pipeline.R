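#' End-to-end CNVR pipeline
#'
#' Convenience wrapper chaining the post-calling stages: per-algorithm
#' call filtering, aggregation into CNVRs, assembly-gap screening, and
#' the >= 2-program consensus with agreement fractions.
#'
#' @param calls_by_algorithm named list: algorithm id -> raw call data
#'   frame.
#' @param policy a [filter_policy()].
#' @param gaps optional gap feature data frame.
#' @param min_support consensus support (default 2).
#' @return list: `per_algorithm` (CNVR sets after filtering/merging/gap
#'   screening), `discarded_by_gaps`, `consensus`, `agreement`.
#' @export
run_cnvr_pipeline <- function(calls_by_algorithm,
                              policy = filter_policy(), gaps = NULL,
                              min_support = 2) {
  per_alg <- list()
  discarded <- list()
  for (a in names(calls_by_algorithm)) {
    filt <- filter_calls(calls_by_algorithm[[a]], policy)
    scr <- screen_gaps(merge_to_cnvrs(filt), gaps)
    per_alg[[a]] <- scr$kept
    discarded[[a]] <- scr$discarded
  }
  cons <- build_consensus(per_alg, min_support = min_support)
  list(per_algorithm = per_alg, discarded_by_gaps = discarded,
       consensus = cons,
       agreement = algorithm_agreement(per_alg, cons))
}
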