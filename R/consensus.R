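#' Multi-algorithm consensus CNVR map
#'
#' Per-algorithm CNVR sets are pooled, overlap components formed across
#' algorithms (1-bp, transitive), and components whose members span at
#' least `min_support` distinct algorithms become consensus CNVRs. The
#' consensus span is the union of member CNVRs (an `intersection` mode
#' exists for sensitivity analysis).
#'
#' @name consensus
NULL

#' Build the consensus CNVR set
#'
#' @param per_algorithm_cnvrs named list: algorithm id -> CNVR data frame
#'   (as from [merge_to_cnvrs()]).
#' @param min_support minimum distinct supporting algorithms (default 2).
#' @param span `"union"` (default) or `"intersection"`: how the consensus
#'   interval is derived from the member CNVRs of a component.
#' @return consensus CNVR data frame: `cnvr_id`, `chrom`, `start`, `end`,
#'   `status`, `n_algorithms`, `algorithms`, `member_cnvrs`
#'   (comma-joined `algo:id` tokens), `n_members`.
#' @export
build_consensus <- function(per_algorithm_cnvrs, min_support = 2,
                            span = c("union", "intersection")) {
  span <- match.arg(span)
  if (length(per_algorithm_cnvrs) < 2)
    stop("build_consensus: need CNVR sets from >= 2 algorithms")
  if (min_support < 2)
    stop("build_consensus: min_support must be >= 2")
  if (min_support > length(per_algorithm_cnvrs))
    stop("build_consensus: min_support exceeds number of algorithms")
  pool <- do.call(rbind, lapply(names(per_algorithm_cnvrs), function(a) {
    x <- per_algorithm_cnvrs[[a]]
    if (nrow(x) == 0) return(NULL)
    data.frame(algorithm_id = a, member_id = paste0(a, ":", x$cnvr_id),
               chrom = x$chrom, start = x$start, end = x$end,
               status = x$status, stringsAsFactors = FALSE)
  }))
  empty <- data.frame(cnvr_id = integer(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      status = character(0), n_algorithms = integer(0),
                      algorithms = character(0),
                      member_cnvrs = character(0), n_members = integer(0),
                      stringsAsFactors = FALSE)
  if (is.null(pool) || nrow(pool) == 0) return(empty)
  comp <- overlap_components(pool)
  idx <- split(seq_len(nrow(pool)), comp)
  rows <- lapply(idx, function(i) {
    algos <- sort(unique(pool$algorithm_id[i]))
    if (length(algos) < min_support) return(NULL)
    if (span == "union") {
      s <- min(pool$start[i]); e <- max(pool$end[i])
    } else {
      s <- max(pool$start[i]); e <- min(pool$end[i])
      if (e < s) return(NULL)  # members overlap pairwise-transitively only
    }
    data.frame(chrom = pool$chrom[i[1]], start = s, end = e,
               status = .merge_status(pool$status[i]),
               n_algorithms = length(algos),
               algorithms = paste(algos, collapse = ","),
               member_cnvrs = paste(sort(pool$member_id[i]),
                                    collapse = ","),
               n_members = length(i), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(chrom_rank(out$chrom), out$start), , drop = FALSE]
  out <- cbind(cnvr_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

.count_overlapping <- function(a, b) {
  # rows of a overlapping >= 1 row of b (1-bp, same chromosome)
  if (nrow(a) == 0) return(logical(0))
  if (nrow(b) == 0) return(rep(FALSE, nrow(a)))
  vapply(seq_len(nrow(a)), function(i) {
    j <- b$chrom == a$chrom[i]
    any(intervals_overlap(b$start[j], b$end[j], a$start[i], a$end[i]))
  }, logical(1))
}

#' Per-algorithm agreement with the consensus map
#'
#' @param per_algorithm_cnvrs named list of per-algorithm CNVR sets.
#' @param consensus consensus CNVR data frame.
#' @return data frame: `algorithm`, `n_total`, `n_overlapping`,
#'   `fraction_pct` (half-up, 2 decimals).
#' @export
algorithm_agreement <- function(per_algorithm_cnvrs, consensus) {
  if (!length(per_algorithm_cnvrs))
    stop("algorithm_agreement: empty algorithm set")
  rows <- lapply(names(per_algorithm_cnvrs), function(a) {
    x <- per_algorithm_cnvrs[[a]]
    n_ov <- sum(.count_overlapping(x, consensus))
    data.frame(algorithm = a, n_total = nrow(x), n_overlapping = n_ov,
               fraction_pct = if (nrow(x)) percent_of(n_ov, nrow(x))
                              else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Overlap of one CNVR set with another (cross-study comparison)
#'
#' @param cnvrs_a query set (counted).
#' @param cnvrs_b reference set.
#' @return list: `n_total`, `n_overlapping` (rows of A overlapping >= 1
#'   row of B), `fraction_pct`.
#' @export
cross_study_overlap <- function(cnvrs_a, cnvrs_b) {
  n_ov <- sum(.count_overlapping(cnvrs_a, cnvrs_b))
  list(n_total = nrow(cnvrs_a), n_overlapping = n_ov,
       fraction_pct = if (nrow(cnvrs_a)) percent_of(n_ov, nrow(cnvrs_a))
                      else 0)
}
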