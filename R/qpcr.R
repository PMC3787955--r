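#' qPCR copy-number validation via relative quantification
#'
#' Relative quantification (RQ) from CT replicates by the 2^-ddCt method:
#' dCt = mean target CT - mean control CT (the control being a single-copy
#' gene), ddCt = dCt(test) - dCt(calibrator), RQ = 2^-ddCt. For a two-copy
#' calibrator, RQ is near 1 for two copies, near 0.5 for one, near 1.5 for
#' three; classification uses the RQ midpoints on the log2 scale —
#' log2(1.5) ~= 0.59 and log2(3) ~= 1.59 — as the loss/gain cutoffs.
#' PCR efficiency is assumed 100% (base 2); no efficiency correction.
#'
#' @name qpcr_validation
NULL

#' RQ classification thresholds
#'
#' @param loss_below RQ strictly below this is a loss (default 0.59).
#' @param gain_at_or_above RQ at or above this is a gain (default 1.59).
#' @export
rq_thresholds <- function(loss_below = 0.59, gain_at_or_above = 1.59) {
  if (!(loss_below > 0 && loss_below < gain_at_or_above))
    stop("rq_thresholds: need 0 < loss_below < gain_at_or_above")
  list(loss_below = loss_below, gain_at_or_above = gain_at_or_above)
}

.mean_ct <- function(ct, label, trim_outliers = FALSE) {
  ct <- ct[is.finite(ct)]
  if (trim_outliers && length(ct) > 2)
    ct <- ct[abs(ct - stats::median(ct)) <= 1]
  if (!length(ct)) stop("compute_rq: no usable CT replicates in well ", label)
  c(mean = mean(ct), sd = if (length(ct) > 1) stats::sd(ct) else 0)
}

#' Compute RQ for one sample/CNVR assay
#'
#' @param target_ct,control_ct CT replicates for the test sample's target
#'   region and single-copy control gene.
#' @param calibrator_target_ct,calibrator_control_ct the same wells for
#'   the no-CNV calibrator sample.
#' @param sample_id,cnvr_id identifiers carried into the result.
#' @param thresholds an [rq_thresholds()] list.
#' @param trim_outliers drop replicates more than 1 CT from the well
#'   median (default FALSE).
#' @return one-row data frame: `sample_id`, `cnvr_id`, `delta_ct_test`,
#'   `delta_ct_calibrator`, `delta_delta_ct`, `rq`, `copy_state`, and
#'   per-well replicate SDs.
#' @export
compute_rq <- function(target_ct, control_ct, calibrator_target_ct,
                       calibrator_control_ct, sample_id = "sample",
                       cnvr_id = NA, thresholds = rq_thresholds(),
                       trim_outliers = FALSE) {
  tt <- .mean_ct(target_ct, paste0(sample_id, "/target"), trim_outliers)
  tc <- .mean_ct(control_ct, paste0(sample_id, "/control"), trim_outliers)
  ct_t <- .mean_ct(calibrator_target_ct, "calibrator/target", trim_outliers)
  ct_c <- .mean_ct(calibrator_control_ct, "calibrator/control",
                   trim_outliers)
  d_test <- tt["mean"] - tc["mean"]
  d_cal <- ct_t["mean"] - ct_c["mean"]
  ddct <- unname(d_test - d_cal)
  rq <- 2^(-ddct)
  data.frame(sample_id = sample_id, cnvr_id = cnvr_id,
             delta_ct_test = unname(d_test),
             delta_ct_calibrator = unname(d_cal),
             delta_delta_ct = ddct, rq = rq,
             copy_state = classify_state(rq, thresholds),
             sd_target = unname(tt["sd"]), sd_control = unname(tc["sd"]),
             stringsAsFactors = FALSE)
}

#' Classify copy state from RQ
#'
#' loss iff `rq < loss_below` (strict); gain iff
#' `rq >= gain_at_or_above` (non-strict, "or more"); otherwise normal.
#'
#' @param rq positive RQ value(s).
#' @param thresholds an [rq_thresholds()] list.
#' @return character vector in `{loss, normal, gain}`.
#' @export
classify_state <- function(rq, thresholds = rq_thresholds()) {
  if (any(!is.finite(rq) | rq <= 0)) stop("classify_state: rq must be > 0")
  ifelse(rq < thresholds$loss_below, "loss",
         ifelse(rq >= thresholds$gain_at_or_above, "gain", "normal"))
}

#' Compute RQ for a long-format assay table
#'
#' @param ct_long data frame from [read_qpcr()] (columns `cnvr_id`,
#'   `sample_id`, `well`, `ct`).
#' @param calibrator sample id of the no-CNV calibrator (one per table;
#'   must be present for every assayed CNVR).
#' @param thresholds an [rq_thresholds()] list.
#' @param trim_outliers see [compute_rq()].
#' @return data frame of per-(cnvr, sample) RQ results, calibrator rows
#'   excluded.
#' @export
rq_table <- function(ct_long, calibrator, thresholds = rq_thresholds(),
                     trim_outliers = FALSE) {
  rows <- list()
  for (cid in unique(ct_long$cnvr_id)) {
    sub <- ct_long[ct_long$cnvr_id == cid, , drop = FALSE]
    cal <- sub[sub$sample_id == calibrator, , drop = FALSE]
    if (nrow(cal) == 0)
      stop("rq_table: calibrator '", calibrator,
           "' has no wells for cnvr ", cid)
    for (sid in setdiff(unique(sub$sample_id), calibrator)) {
      s <- sub[sub$sample_id == sid, , drop = FALSE]
      rows[[length(rows) + 1L]] <- compute_rq(
        s$ct[s$well == "target"], s$ct[s$well == "control"],
        cal$ct[cal$well == "target"], cal$ct[cal$well == "control"],
        sample_id = sid, cnvr_id = cid, thresholds = thresholds,
        trim_outliers = trim_outliers)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Score qPCR concordance against predicted CNVR status
#'
#' A CNVR is validated (YES) iff at least one assayed sample is
#' non-normal. The validated type is `gain` if only gains occur among
#' non-normal samples, `loss` if only losses, `gain-loss` if both. The
#' relation to the predicted status is `match` (equal), `extends`
#' (validated type strictly contains the predicted state, e.g. predicted
#' loss but gain-loss observed), or `contradicts` otherwise.
#'
#' @param rq_results data frame from [rq_table()].
#' @param predicted data frame with `cnvr_id` and `status` (the pipeline's
#'   predicted CNVR status).
#' @return list: `table` (per-CNVR: `cnvr_id`, `n_samples`, `validated`,
#'   `validated_type`, `predicted_status`, `relation`), `n_tested`,
#'   `n_validated`, `validated_pct`; CNVRs in `predicted` with no assays
#'   are listed in `untested` and excluded from the fraction.
#' @export
qpcr_concordance <- function(rq_results, predicted) {
  tested <- intersect(predicted$cnvr_id, rq_results$cnvr_id)
  untested <- setdiff(predicted$cnvr_id, tested)
  rows <- lapply(tested, function(cid) {
    states <- rq_results$copy_state[rq_results$cnvr_id == cid]
    nn <- states[states != "normal"]
    vtype <- if (!length(nn)) NA_character_
             else if (all(nn == "gain")) "gain"
             else if (all(nn == "loss")) "loss" else "gain-loss"
    pred <- predicted$status[match(cid, predicted$cnvr_id)]
    relation <- if (is.na(vtype)) "not_validated"
      else if (vtype == pred) "match"
      else if (vtype == "gain-loss" && pred %in% c("gain", "loss"))
        "extends"
      else "contradicts"
    data.frame(cnvr_id = cid, n_samples = length(states),
               validated = if (length(nn)) "YES" else "NO",
               validated_type = vtype, predicted_status = pred,
               relation = relation, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  n_val <- sum(tab$validated == "YES")
  list(table = tab, n_tested = length(tested), n_validated = n_val,
       validated_pct = if (length(tested))
         percent_of(n_val, length(tested)) else NA_real_,
       untested = untested)
}
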