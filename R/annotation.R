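#' Interval-overlap annotation of CNVRs
#'
#' Joins a CNVR set against feature tables (genes with biotype, QTLs with
#' trait class, GWAS SNPs, cross-species variant regions) by shared-base
#' overlap, and summarizes hit counts the way published CNVR surveys
#' report them.
#'
#' @name annotation_overlap
NULL

#' Overlap join of CNVRs against features
#'
#' One hit per (cnvr, feature) pair sharing >= `min_overlap_bp` bases on
#' the same chromosome. Point features (SNPs) hit iff the position lies
#' within the CNVR. Output is ordered by cnvr then feature.
#'
#' @param cnvrs CNVR data frame (`cnvr_id`, `chrom`, `start`, `end`).
#' @param features feature data frame (see [read_features()]).
#' @param min_overlap_bp minimum shared bases (default 1).
#' @return data frame: `cnvr_id`, `feature_id`, `kind`, `overlap_bp`,
#'   `containment` in `{feature_within_cnvr, cnvr_within_feature,
#'   partial}`, plus any attribute columns of `features`.
#' @export
overlap_join <- function(cnvrs, features, min_overlap_bp = 1) {
  attr_cols <- setdiff(names(features),
                       c("feature_id", "chrom", "start", "end", "kind"))
  empty <- data.frame(cnvr_id = integer(0), feature_id = character(0),
                      kind = character(0), overlap_bp = numeric(0),
                      containment = character(0), stringsAsFactors = FALSE)
  for (nm in attr_cols) empty[[nm]] <- features[[nm]][0]
  if (nrow(cnvrs) == 0 || nrow(features) == 0) return(empty)
  rows <- lapply(seq_len(nrow(cnvrs)), function(i) {
    j <- which(features$chrom == cnvrs$chrom[i])
    if (!length(j)) return(NULL)
    ov <- overlap_bp(features$start[j], features$end[j],
                     cnvrs$start[i], cnvrs$end[i])
    j <- j[ov >= min_overlap_bp]
    ov <- ov[ov >= min_overlap_bp]
    if (!length(j)) return(NULL)
    cont <- ifelse(
      features$start[j] >= cnvrs$start[i] & features$end[j] <= cnvrs$end[i],
      "feature_within_cnvr",
      ifelse(cnvrs$start[i] >= features$start[j] &
               cnvrs$end[i] <= features$end[j],
             "cnvr_within_feature", "partial"))
    out <- data.frame(cnvr_id = cnvrs$cnvr_id[i],
                      feature_id = features$feature_id[j],
                      kind = features$kind[j], overlap_bp = ov,
                      containment = cont, stringsAsFactors = FALSE)
    for (nm in attr_cols) out[[nm]] <- features[[nm]][j]
    out[order(out$feature_id), , drop = FALSE]
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize an annotation join
#'
#' @param hits output of [overlap_join()].
#' @param cnvrs the CNVR set used as denominator.
#' @param features the feature table joined (for per-attribute totals).
#' @param digits decimal places for printed percentages (default 2).
#' @return list: `n_cnvrs_with_hits`, `pct_cnvrs_with_hits`,
#'   `n_features_hit`, `by_biotype` (genes), `by_trait` (QTLs),
#'   `n_fully_contained` (hits with the feature wholly inside a CNVR).
#' @export
summarize_annotation <- function(hits, cnvrs, features, digits = 2) {
  n_hit <- length(unique(hits$cnvr_id))
  feat_hit <- unique(hits$feature_id)
  by_biotype <- NULL
  if ("biotype" %in% names(features)) {
    g <- features[features$feature_id %in% feat_hit &
                    features$kind == "gene", , drop = FALSE]
    by_biotype <- table(g$biotype)
  }
  by_trait <- NULL
  if ("trait" %in% names(features)) {
    q <- features[features$feature_id %in% feat_hit &
                    features$kind == "qtl", , drop = FALSE]
    by_trait <- table(q$trait)
  }
  list(n_cnvrs_with_hits = n_hit,
       pct_cnvrs_with_hits = if (nrow(cnvrs))
         percent_of(n_hit, nrow(cnvrs), digits) else 0,
       n_features_hit = length(feat_hit),
       by_biotype = by_biotype, by_trait = by_trait,
       n_fully_contained =
         length(unique(hits$feature_id[hits$containment ==
                                         "feature_within_cnvr"])))
}

#' Per-trait co-location of significant SNPs with CNVRs
#'
#' @param cnvrs CNVR data frame.
#' @param snp_features SNP feature data frame with a `trait` attribute
#'   column (point features, start == end).
#' @return data frame: `trait`, `n_in_cnvrs`, `n_total`, `fraction_pct`.
#' @export
snp_colocation <- function(cnvrs, snp_features) {
  if (!"trait" %in% names(snp_features))
    stop("snp_colocation: no trait column in SNP feature table")
  bad <- is.na(snp_features$trait) | !nzchar(snp_features$trait)
  if (any(bad))
    stop("snp_colocation: trait attribute missing for feature(s): ",
         paste(utils::head(snp_features$feature_id[bad], 5),
               collapse = ", "))
  inside <- .count_overlapping(
    data.frame(chrom = snp_features$chrom, start = snp_features$start,
               end = snp_features$end, stringsAsFactors = FALSE), cnvrs)
  agg <- lapply(split(inside, snp_features$trait), function(x)
    c(n_in = sum(x), n_total = length(x)))
  out <- data.frame(trait = names(agg),
                    n_in_cnvrs = vapply(agg, `[[`, numeric(1), "n_in"),
                    n_total = vapply(agg, `[[`, numeric(1), "n_total"),
                    stringsAsFactors = FALSE)
  out$fraction_pct <- percent_of(out$n_in_cnvrs, out$n_total)
  rownames(out) <- NULL
  out
}
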