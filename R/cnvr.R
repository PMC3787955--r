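#' CNVR construction from per-algorithm CNV calls
#'
#' Post-calling rules: drop segments supported by fewer than `min_snps`
#' probes, drop events carried by fewer than `min_carriers` distinct
#' individuals (recurrence judged on the transitive 1-bp overlap cluster),
#' then aggregate overlapping calls into copy number variable regions
#' (CNVRs) and screen out CNVRs that touch assembly gaps.
#'
#' @name cnvr_construction
NULL

#' Call filtering policy
#'
#' @param min_snps minimum probes per segment (default 3).
#' @param min_carriers minimum distinct carrier individuals per overlap
#'   cluster (default 2: singleton events are dropped).
#' @param same_state_recurrence if TRUE, recurrence is counted within one
#'   state only (gain clusters and loss clusters separately); default
#'   FALSE, counting carriers across states.
#' @export
filter_policy <- function(min_snps = 3, min_carriers = 2,
                          same_state_recurrence = FALSE) {
  if (min_snps < 1 || min_carriers < 1)
    stop("filter_policy: min_snps and min_carriers must be >= 1")
  list(min_snps = min_snps, min_carriers = min_carriers,
       same_state_recurrence = same_state_recurrence)
}

#' Filter raw calls of one algorithm
#'
#' Order is fixed: the probe-count filter first, then the recurrence
#' filter on the overlap clusters of what remains. Input row order is
#' preserved in the output.
#'
#' @param calls call data frame (one algorithm only; see
#'   [read_cnv_calls()]).
#' @param policy a [filter_policy()].
#' @return the surviving calls, original order.
#' @export
filter_calls <- function(calls, policy = filter_policy()) {
  if (nrow(calls) == 0) return(calls)
  if (length(unique(calls$algorithm_id)) > 1)
    stop("filter_calls: mixed algorithm_ids; recurrence is per-algorithm")
  keep_snps <- calls$n_snps >= policy$min_snps
  kept <- calls[keep_snps, , drop = FALSE]
  if (nrow(kept) == 0) return(kept)
  if (policy$same_state_recurrence) {
    comp <- integer(nrow(kept))
    for (st in unique(kept$state)) {
      idx <- kept$state == st
      comp[idx] <- overlap_components(kept[idx, , drop = FALSE]) +
        max(comp, 0L)
    }
  } else {
    comp <- overlap_components(kept)
  }
  carriers <- vapply(split(kept$sample_id, comp),
                     function(s) length(unique(s)), integer(1))
  kept[carriers[as.character(comp)] >= policy$min_carriers, , drop = FALSE]
}

.merge_status <- function(states) {
  has_gain <- any(states == "gain")
  has_loss <- any(states == "loss" )
  has_gl <- any(states == "gain-loss")
  if ((has_gain && has_loss) || has_gl) {
    if (has_gl && !has_gain && !has_loss) "gain-loss"
    else if (has_gl || (has_gain && has_loss)) "gain-loss"
    else "gain-loss"
  } else if (has_gain) "gain" else "loss"
}

#' Aggregate overlapping calls into CNVRs
#'
#' CNVRs are the connected components of the per-chromosome 1-bp overlap
#' graph; each spans `[min start, max end]` of its component. Status is
#' `gain` iff all member states are gain, `loss` iff all loss, otherwise
#' `gain-loss`. Output is sorted by chromosome then start and numbered
#' from 1 (numbering is per run; cross-run identity is by coordinates).
#'
#' @param calls call data frame; may mix algorithms (used by the consensus
#'   stage), needs columns `chrom`, `start`, `end`, `state`, and
#'   optionally `sample_id`, `algorithm_id`.
#' @return CNVR data frame: `cnvr_id`, `chrom`, `start`, `end`, `status`,
#'   `n_calls`, `samples`, `algorithms` (comma-joined), `n_samples`,
#'   `n_algorithms`.
#' @export
merge_to_cnvrs <- function(calls) {
  if (nrow(calls) == 0)
    return(data.frame(cnvr_id = integer(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      status = character(0), n_calls = integer(0),
                      samples = character(0), algorithms = character(0),
                      n_samples = integer(0), n_algorithms = integer(0),
                      stringsAsFactors = FALSE))
  calls <- validate_intervals(calls, "merge_to_cnvrs")
  comp <- overlap_components(calls)
  sample_col <- if ("sample_id" %in% names(calls)) calls$sample_id
                else rep("", nrow(calls))
  algo_col <- if ("algorithm_id" %in% names(calls)) calls$algorithm_id
              else rep("", nrow(calls))
  idx <- split(seq_len(nrow(calls)), comp)
  rows <- lapply(idx, function(i) {
    samples <- sort(unique(sample_col[i]))
    algos <- sort(unique(algo_col[i]))
    data.frame(chrom = calls$chrom[i[1]],
               start = min(calls$start[i]), end = max(calls$end[i]),
               status = .merge_status(calls$state[i]),
               n_calls = length(i),
               samples = paste(samples, collapse = ","),
               algorithms = paste(algos, collapse = ","),
               n_samples = length(samples[nzchar(samples)]),
               n_algorithms = length(algos[nzchar(algos)]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(chrom_rank(out$chrom), out$start), , drop = FALSE]
  out <- cbind(cnvr_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Screen CNVRs against assembly gaps
#'
#' A CNVR is discarded iff it overlaps (>= 1 bp) at least one declared gap
#' interval — a gap inside a CNVR means the region spans more than one
#' contig of the assembly.
#'
#' @param cnvrs CNVR data frame.
#' @param gaps feature data frame of kind `gap` (may be empty or NULL).
#' @return list with `kept` and `discarded` CNVR data frames; `discarded`
#'   gains a `gap_hit` column naming the first triggering gap.
#' @export
screen_gaps <- function(cnvrs, gaps = NULL) {
  if (is.null(gaps) || nrow(gaps) == 0 || nrow(cnvrs) == 0)
    return(list(kept = cnvrs,
                discarded = cbind(cnvrs[0, , drop = FALSE],
                                  gap_hit = character(0))))
  hit <- character(nrow(cnvrs))
  for (i in seq_len(nrow(cnvrs))) {
    g <- gaps[gaps$chrom == cnvrs$chrom[i] &
                intervals_overlap(gaps$start, gaps$end,
                                  cnvrs$start[i], cnvrs$end[i]), ,
              drop = FALSE]
    if (nrow(g)) hit[i] <- g$feature_id[1]
  }
  disc <- cnvrs[nzchar(hit), , drop = FALSE]
  if (nrow(disc)) disc$gap_hit <- hit[nzchar(hit)]
  else disc <- cbind(disc, gap_hit = character(0))
  list(kept = cnvrs[!nzchar(hit), , drop = FALSE], discarded = disc)
}

#' Summarize a CNVR set
#'
#' Lengths use the published kb convention `(end - start)/1000`; coverage
#' is non-redundant (overlapping CNVRs counted once) in Mb, with a
#' coverage fraction when a genome size is supplied.
#'
#' @param cnvrs non-empty CNVR data frame.
#' @param genome_size_bp optional total genome size for the coverage
#'   percentage.
#' @return list: `n`, `n_by_status`, `min_kb`, `median_kb`, `mean_kb`,
#'   `max_kb`, `coverage_mb`, `coverage_pct` (NA without genome size).
#' @export
summarize_cnvrs <- function(cnvrs, genome_size_bp = NULL) {
  if (nrow(cnvrs) == 0) stop("summarize_cnvrs: empty CNVR set")
  kb <- length_kb_published(cnvrs$start, cnvrs$end)
  merged <- merge_to_cnvrs(transform(cnvrs, state = "gain"))
  cov_bp <- sum(length_bp(merged$start, merged$end))
  list(n = nrow(cnvrs),
       n_by_status = table(factor(cnvrs$status,
                                  levels = c("gain", "loss", "gain-loss"))),
       min_kb = min(kb), median_kb = stats::median(kb),
       mean_kb = mean(kb), max_kb = max(kb),
       coverage_mb = cov_bp / 1e6,
       coverage_pct = if (is.null(genome_size_bp)) NA_real_
                      else percent_of(cov_bp, genome_size_bp))
}
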