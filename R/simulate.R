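#' Seeded synthetic data for the whole pipeline
#'
#' Generates every input the pipeline consumes: a planted-truth CNVR
#' landscape on a pig-scale genome, emulated outputs of four CNV-calling
#' algorithms with distinct error profiles, genotype matrices with
#' controllable QC failures, cohort structure, and qPCR CT tables. All
#' randomness flows from an explicit seed; identical seeds give identical
#' output.
#'
#' @name synthetic_data
NULL

#' Default simulated genome
#'
#' 18 autosomes plus X, 140 Mb each (2.66 Gb total, the scale of the pig
#' genome), with a uniformly spaced SNP map of ~1 probe per 40 kb
#' (~66,000 probes, the 60K-chip scale).
#'
#' @param chrom_size_bp per-chromosome size (default 140 Mb).
#' @return named numeric vector of chromosome sizes.
#' @export
default_genome <- function(chrom_size_bp = 140e6) {
  stats::setNames(rep(chrom_size_bp, 19), c(as.character(1:18), "X"))
}

#' Uniform SNP probe map for a genome
#'
#' @param genome named chromosome-size vector.
#' @param spacing_bp probe spacing (default 40 kb).
#' @return data frame `snp_id`, `chrom`, `pos`.
#' @export
uniform_snp_map <- function(genome, spacing_bp = 40e3) {
  rows <- lapply(names(genome), function(ch) {
    pos <- seq(spacing_bp / 2, genome[[ch]], by = spacing_bp)
    data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- cbind(snp_id = paste0("probe", seq_len(nrow(out))), out)
  out
}

.count_probes <- function(snp_map_by_chrom, chrom, start, end) {
  pos <- snp_map_by_chrom[[chrom]]
  if (is.null(pos)) return(0L)
  sum(pos >= start & pos <= end)
}

#' Default cohort layout
#'
#' The founder/F2 structure of a two-breed intercross resource
#' population: 19 Minzhu F0 sows, 5 Large White F0 boars, 506 F2.
#' @return data frame `breed`, `generation`, `n`.
#' @export
default_cohorts <- function() {
  data.frame(breed = c("Minzhu", "LargeWhite", "F2cross"),
             generation = c("F0", "F0", "F2"),
             n = c(19, 5, 506), stringsAsFactors = FALSE)
}

#' Default emulated caller profiles
#'
#' Four callers, each with per-true-CNV sensitivity 0.9, 0.05 false
#' segments per Mb per sample, 5 kb boundary jitter, 2% state-flip
#' probability and a 3-probe emission floor.
#'
#' @param algorithm_ids caller names.
#' @param sensitivity,fp_rate,boundary_jitter_sd,state_flip_prob,min_snps_emitted
#'   shared profile parameters (vectors recycle across callers).
#' @return named list of profile lists.
#' @export
default_caller_profiles <- function(
    algorithm_ids = c("gada", "penncnv", "quantisnp", "cnvpartition"),
    sensitivity = 0.9, fp_rate = 0.05, boundary_jitter_sd = 5e3,
    state_flip_prob = 0.02, min_snps_emitted = 3) {
  n <- length(algorithm_ids)
  args <- data.frame(sensitivity = rep_len(sensitivity, n),
                     fp_rate = rep_len(fp_rate, n),
                     boundary_jitter_sd = rep_len(boundary_jitter_sd, n),
                     state_flip_prob = rep_len(state_flip_prob, n),
                     min_snps_emitted = rep_len(min_snps_emitted, n))
  profs <- lapply(seq_len(n), function(i) {
    p <- c(list(algorithm_id = algorithm_ids[i]), as.list(args[i, ]))
    stopifnot(p$sensitivity >= 0, p$sensitivity <= 1,
              p$state_flip_prob >= 0, p$state_flip_prob <= 1,
              p$boundary_jitter_sd >= 0, p$fp_rate >= 0)
    p
  })
  stats::setNames(profs, algorithm_ids)
}

#' Plant a truth CNVR landscape
#'
#' CNVR lengths are log-uniform over `size_range` (defaults spanning the
#' published 29.2 kb – 27.29 Mb range); statuses follow `status_mix`
#' (default the published 70:43:136 gain:loss:gain-loss mix); regions are
#' placed non-overlapping genome-wide. Carriers are drawn per cohort at a
#' per-region carrier frequency; a fraction of regions is restricted to a
#' single cohort (breed-specific events).
#'
#' @param genome named chromosome-size vector.
#' @param n_cnvrs number of regions to plant.
#' @param size_range length bounds in bp.
#' @param status_mix unnormalized weights named gain/loss/gain-loss.
#' @param cohorts cohort layout data frame (see [default_cohorts()]).
#' @param carrier_freq_range per-region carrier frequency drawn uniformly
#'   from this range.
#' @param breed_specific_frac fraction of regions restricted to one
#'   cohort (default 0.2).
#' @param min_carriers_planted floor on carriers per region (default 2,
#'   so planted events survive the singleton knock-out rule by
#'   construction; set to 1 for single-carrier designs).
#' @param snp_spacing_bp probe spacing for the SNP map.
#' @param seed integer seed; all downstream randomness derives from it.
#' @return list of class `cnvr_truth`: `genome`, `snp_map`, `samples`
#'   (sample sheet), `regions` (truth CNVRs with `region_id`, interval,
#'   `status`, `cohort_scope`, `carrier_freq`), `carriers` (long table
#'   `region_id`, `sample_id`, `state`, `copy_number`), `seed`.
#' @export
simulate_truth <- function(genome = default_genome(), n_cnvrs = 200,
                           size_range = c(29.2e3, 27.29e6),
                           status_mix = c(gain = 70, loss = 43,
                                          "gain-loss" = 136),
                           cohorts = default_cohorts(),
                           carrier_freq_range = c(0.1, 0.4),
                           breed_specific_frac = 0.2,
                           min_carriers_planted = 2,
                           snp_spacing_bp = 40e3, seed) {
  if (missing(seed)) stop("simulate_truth: seed must be supplied")
  if (!length(genome)) stop("simulate_truth: empty genome")
  set.seed(seed)
  snp_map <- uniform_snp_map(genome, snp_spacing_bp)
  pos_by_chrom <- split(snp_map$pos, snp_map$chrom)

  samples <- do.call(rbind, lapply(seq_len(nrow(cohorts)), function(i) {
    data.frame(sample_id = sprintf("%s_%s_%03d", cohorts$breed[i],
                                   cohorts$generation[i],
                                   seq_len(cohorts$n[i])),
               generation = cohorts$generation[i],
               breed = cohorts$breed[i],
               sex = rep_len(c("F", "M"), cohorts$n[i]),
               stringsAsFactors = FALSE)
  }))
  cohort_ids <- paste(cohorts$breed, cohorts$generation, sep = "_")

  regions <- data.frame(region_id = integer(0), chrom = character(0),
                        start = numeric(0), end = numeric(0),
                        status = character(0), cohort_scope = character(0),
                        carrier_freq = numeric(0), stringsAsFactors = FALSE)
  carriers <- NULL
  if (n_cnvrs > 0) {
    if (n_cnvrs * exp(mean(log(size_range))) > 0.9 * sum(genome))
      stop("simulate_truth: requested coverage exceeds genome capacity")
    lens <- round(exp(stats::runif(n_cnvrs, log(size_range[1]),
                                   log(size_range[2]))))
    statuses <- sample(names(status_mix), n_cnvrs, replace = TRUE,
                       prob = status_mix / sum(status_mix))
    placed <- list()  # per chrom: matrix of [start,end]
    chrom_names <- names(genome)
    chrom_prob <- genome / sum(genome)
    rows <- vector("list", n_cnvrs)
    for (k in seq_len(n_cnvrs)) {
      ok <- FALSE
      for (try in 1:200) {
        ch <- sample(chrom_names, 1, prob = chrom_prob)
        if (lens[k] >= genome[[ch]]) next
        s <- floor(stats::runif(1, 1, genome[[ch]] - lens[k]))
        e <- s + lens[k] - 1
        prev <- placed[[ch]]
        if (is.null(prev) ||
            !any(intervals_overlap(prev[, 1], prev[, 2], s, e))) {
          placed[[ch]] <- rbind(prev, c(s, e))
          rows[[k]] <- data.frame(region_id = k, chrom = ch, start = s,
                                  end = e, status = statuses[k],
                                  stringsAsFactors = FALSE)
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("simulate_truth: could not place region ", k,
                    " without overlap; genome too full")
    }
    regions <- do.call(rbind, rows)
    n_spec <- round(breed_specific_frac * n_cnvrs)
    scope <- rep("all", n_cnvrs)
    if (n_spec > 0)
      scope[sample.int(n_cnvrs, n_spec)] <-
        sample(cohort_ids, n_spec, replace = TRUE)
    regions$cohort_scope <- scope
    regions$carrier_freq <- stats::runif(n_cnvrs, carrier_freq_range[1],
                                         carrier_freq_range[2])

    sample_cohort <- paste(samples$breed, samples$generation, sep = "_")
    carr_rows <- vector("list", n_cnvrs)
    for (k in seq_len(n_cnvrs)) {
      pool <- if (regions$cohort_scope[k] == "all") samples$sample_id
              else samples$sample_id[sample_cohort ==
                                       regions$cohort_scope[k]]
      n_carry <- max(min_carriers_planted,
                     stats::rbinom(1, length(pool),
                                   regions$carrier_freq[k]))
      n_carry <- min(n_carry, length(pool))
      ids <- sample(pool, n_carry)
      st <- switch(regions$status[k],
                   gain = rep("gain", n_carry),
                   loss = rep("loss", n_carry),
                   "gain-loss" = {
                     # both states guaranteed present among carriers
                     s <- sample(c("gain", "loss"), n_carry, replace = TRUE)
                     s[1] <- "gain"; if (n_carry > 1) s[2] <- "loss"
                     s
                   })
      cn <- ifelse(st == "gain",
                   3L + stats::rbinom(n_carry, 1, 0.2),
                   1L - stats::rbinom(n_carry, 1, 0.1))
      carr_rows[[k]] <- data.frame(region_id = k, sample_id = ids,
                                   state = st, copy_number = cn,
                                   stringsAsFactors = FALSE)
    }
    carriers <- do.call(rbind, carr_rows)
  }
  structure(list(genome = genome, snp_map = snp_map,
                 pos_by_chrom = pos_by_chrom, samples = samples,
                 regions = regions,
                 carriers = if (is.null(carriers))
                   data.frame(region_id = integer(0),
                              sample_id = character(0),
                              state = character(0),
                              copy_number = integer(0)) else carriers,
                 seed = seed),
            class = "cnvr_truth")
}

#' Emit one emulated caller's CNV calls
#'
#' Each (carrier, planted region) pair is detected with probability
#' `sensitivity`; detected calls get normal boundary jitter (rounded,
#' clipped to the chromosome), state flips with `state_flip_prob`, and
#' `n_snps` counted from the truth SNP map over the emitted interval.
#' Calls with fewer than `min_snps_emitted` probes are suppressed (the
#' caller would not emit them). False segments arrive at `fp_rate` per Mb
#' per sample with log-uniform lengths over `fp_len_range` and random
#' state. The default FP lengths (10–100 kb) are short on the probe
#' spacing scale: chip-caller false segments are predominantly
#' low-probe-count artifacts — the very reason CNV studies impose a
#' minimum-probe filter — so most simulated FPs fall below the emission
#' floor, leaving a per-sample surviving call count on the order seen in
#' real 60K-chip studies (a few calls per sample per caller).
#'
#' @param truth a [simulate_truth()] object.
#' @param profile one profile from [default_caller_profiles()].
#' @param fp_len_range false-segment length bounds in bp.
#' @param seed integer seed.
#' @return call data frame in [read_cnv_calls()] layout plus
#'   `truth_region` (region_id, NA for false calls).
#' @export
emit_caller_calls <- function(truth, profile, fp_len_range = c(10e3, 100e3),
                              seed) {
  set.seed(seed)
  reg <- truth$regions
  carr <- truth$carriers
  rows <- list()
  if (nrow(carr)) {
    det <- stats::runif(nrow(carr)) < profile$sensitivity
    idx <- which(det)
    if (length(idx)) {
      r <- reg[match(carr$region_id[idx], reg$region_id), ]
      j1 <- round(stats::rnorm(length(idx), 0, profile$boundary_jitter_sd))
      j2 <- round(stats::rnorm(length(idx), 0, profile$boundary_jitter_sd))
      s <- pmax(1, r$start + j1)
      e <- pmin(truth$genome[r$chrom], r$end + j2)
      swap <- e < s
      if (any(swap)) { tmp <- s[swap]; s[swap] <- e[swap]; e[swap] <- tmp }
      st <- carr$state[idx]
      flip <- stats::runif(length(idx)) < profile$state_flip_prob
      st[flip] <- ifelse(st[flip] == "gain", "loss", "gain")
      n_snps <- mapply(.count_probes, chrom = r$chrom, start = s, end = e,
                       MoreArgs = list(snp_map_by_chrom =
                                         truth$pos_by_chrom))
      rows[[1]] <- data.frame(sample_id = carr$sample_id[idx],
                              algorithm_id = profile$algorithm_id,
                              chrom = r$chrom, start = s, end = e,
                              state = st, n_snps = as.integer(n_snps),
                              truth_region = carr$region_id[idx],
                              stringsAsFactors = FALSE)
    }
  }
  genome_mb <- sum(truth$genome) / 1e6
  n_fp_per_sample <- stats::rpois(nrow(truth$samples),
                                  profile$fp_rate * genome_mb)
  fp_total <- sum(n_fp_per_sample)
  if (fp_total > 0) {
    sid <- rep(truth$samples$sample_id, n_fp_per_sample)
    ch <- sample(names(truth$genome), fp_total, replace = TRUE,
                 prob = truth$genome / sum(truth$genome))
    len <- round(exp(stats::runif(fp_total, log(fp_len_range[1]),
                                  log(fp_len_range[2]))))
    s <- floor(stats::runif(fp_total, 1, truth$genome[ch] - len))
    e <- s + len - 1
    n_snps <- mapply(.count_probes, chrom = ch, start = s, end = e,
                     MoreArgs = list(snp_map_by_chrom =
                                       truth$pos_by_chrom))
    rows[[length(rows) + 1L]] <-
      data.frame(sample_id = sid, algorithm_id = profile$algorithm_id,
                 chrom = ch, start = s, end = e,
                 state = sample(c("gain", "loss"), fp_total,
                                replace = TRUE),
                 n_snps = as.integer(n_snps),
                 truth_region = NA_integer_, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(sample_id = character(0),
                      algorithm_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      state = character(0), n_snps = integer(0),
                      truth_region = integer(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[out$n_snps >= profile$min_snps_emitted, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Emit all four callers' outputs
#'
#' @param truth a [simulate_truth()] object.
#' @param profiles list from [default_caller_profiles()].
#' @param seed base seed; caller i uses `seed + i` (kept below 2^31).
#' @return named list of call data frames.
#' @export
emit_all_callers <- function(truth, profiles = default_caller_profiles(),
                             seed) {
  out <- lapply(seq_along(profiles), function(i)
    emit_caller_calls(truth, profiles[[i]], seed = (seed + i) %% 2147483647))
  stats::setNames(out, names(profiles))
}

#' Emit a genotype matrix with planted QC failures
#'
#' Background SNPs are drawn under Hardy-Weinberg proportions at a MAF
#' sampled uniformly from `maf_range`, with uniform missingness. Planted
#' failure SNPs each violate exactly one rule: low call rate (25%
#' missing), low MAF (monomorphic but for one heterozygote), HWE
#' violation (every typed genotype heterozygous). Planted low-call-rate
#' samples get 12% missing entries.
#'
#' @param n_samples,n_snps matrix dimensions (background SNPs; planted
#'   SNPs are added on top).
#' @param maf_range background MAF range (default 0.05–0.5).
#' @param missingness background per-entry missing probability.
#' @param n_bad_callrate_snps,n_bad_maf_snps,n_bad_hwe_snps planted SNP
#'   failures of each kind.
#' @param n_bad_samples planted low-call-rate samples.
#' @param seed integer seed.
#' @return list: `genotypes` (matrix, rows = SNPs), `truth` (data frame
#'   `snp_id`, `planted_failure` in
#'   `{none, call_rate, maf, hwe}`), `bad_samples` (ids).
#' @export
emit_genotypes <- function(n_samples = 100, n_snps = 1000,
                           maf_range = c(0.05, 0.5), missingness = 0.02,
                           n_bad_callrate_snps = 0, n_bad_maf_snps = 0,
                           n_bad_hwe_snps = 0, n_bad_samples = 0, seed) {
  set.seed(seed)
  stopifnot(n_bad_samples <= n_samples)
  draw_snp <- function(maf, miss) {
    g <- sample(c("BB", "AB", "AA"), n_samples, replace = TRUE,
                prob = c(maf^2, 2 * maf * (1 - maf), (1 - maf)^2))
    g[stats::runif(n_samples) < miss] <- NA
    g
  }
  mafs <- stats::runif(n_snps, maf_range[1], maf_range[2])
  m <- t(vapply(mafs, draw_snp, character(n_samples), miss = missingness))
  labels <- rep("none", n_snps)
  add <- function(mat, lab, maker, k) {
    if (k == 0) return(list(mat, lab))
    extra <- t(vapply(seq_len(k), function(i) maker(), character(n_samples)))
    list(rbind(mat, extra), c(lab, rep(attr(maker, "label"), k)))
  }
  mk_cr <- function() {
    g <- draw_snp(stats::runif(1, 0.1, 0.5), 0)
    g[sample.int(n_samples, ceiling(0.25 * n_samples))] <- NA
    g
  }
  attr(mk_cr, "label") <- "call_rate"
  mk_maf <- function() {
    g <- rep("AA", n_samples); g[sample.int(n_samples, 1)] <- "AB"; g
  }
  attr(mk_maf, "label") <- "maf"
  mk_hwe <- function() rep("AB", n_samples)
  attr(mk_hwe, "label") <- "hwe"
  r <- add(m, labels, mk_cr, n_bad_callrate_snps)
  r <- add(r[[1]], r[[2]], mk_maf, n_bad_maf_snps)
  r <- add(r[[1]], r[[2]], mk_hwe, n_bad_hwe_snps)
  m <- r[[1]]; labels <- r[[2]]
  rownames(m) <- paste0("snp", seq_len(nrow(m)))
  colnames(m) <- paste0("s", seq_len(n_samples))
  bad_samples <- character(0)
  if (n_bad_samples > 0) {
    bad_samples <- sample(colnames(m), n_bad_samples)
    for (sid in bad_samples) {
      drop_idx <- sample.int(nrow(m), ceiling(0.12 * nrow(m)))
      m[drop_idx, sid] <- NA
    }
  }
  list(genotypes = m,
       truth = data.frame(snp_id = rownames(m), planted_failure = labels,
                          stringsAsFactors = FALSE),
       bad_samples = bad_samples)
}

#' Emit qPCR CT replicates for selected truth regions
#'
#' The ideal model at 100% efficiency: a sample with copy number `cn`
#' shifts its target CT by `-log2(cn / 2)` relative to the two-copy
#' calibrator; replicate CTs add Gaussian noise. The calibrator is a
#' designated non-carrier; `n_normal` additional non-carriers are assayed
#' alongside the carriers.
#'
#' @param truth a [simulate_truth()] object.
#' @param region_ids truth regions to assay.
#' @param ct_noise_sd replicate CT noise SD (default 0.1).
#' @param n_replicates wells per sample (default 4, quadruplicate).
#' @param n_normal non-carrier samples per region (default 3).
#' @param base_target_ct,base_control_ct two-copy baseline CTs.
#' @param seed integer seed.
#' @return list: `ct_long` (columns `cnvr_id`, `sample_id`, `well`,
#'   `ct`), `calibrator` (sample id), `truth_states` (per region/sample
#'   planted state).
#' @export
emit_qpcr <- function(truth, region_ids, ct_noise_sd = 0.1,
                      n_replicates = 4, n_normal = 3,
                      base_target_ct = 28, base_control_ct = 25, seed) {
  set.seed(seed)
  stopifnot(all(region_ids %in% truth$regions$region_id))
  all_carriers <- unique(truth$carriers$sample_id)
  noncarriers <- setdiff(truth$samples$sample_id, all_carriers)
  if (!length(noncarriers))
    stop("emit_qpcr: no copy-neutral sample available as calibrator")
  calibrator <- noncarriers[1]
  rows <- list()
  states <- list()
  for (rid in region_ids) {
    carr <- truth$carriers[truth$carriers$region_id == rid, , drop = FALSE]
    normals <- utils::head(setdiff(noncarriers, calibrator), n_normal)
    sdf <- data.frame(sample_id = c(calibrator, carr$sample_id, normals),
                      copy_number = c(2L, carr$copy_number,
                                      rep(2L, length(normals))),
                      stringsAsFactors = FALSE)
    sdf$copy_number[sdf$copy_number == 0L] <- 0L
    for (i in seq_len(nrow(sdf))) {
      cn <- sdf$copy_number[i]
      # a homozygous deletion never amplifies; represent as very late CT
      t_ct <- if (cn == 0) 40 else base_target_ct - log2(cn / 2)
      rows[[length(rows) + 1L]] <- data.frame(
        cnvr_id = rid, sample_id = sdf$sample_id[i],
        well = rep(c("target", "control"), each = n_replicates),
        ct = c(t_ct + stats::rnorm(n_replicates, 0, ct_noise_sd),
               base_control_ct + stats::rnorm(n_replicates, 0,
                                              ct_noise_sd)),
        stringsAsFactors = FALSE)
    }
    states[[length(states) + 1L]] <-
      data.frame(region_id = rid, sample_id = sdf$sample_id,
                 copy_number = sdf$copy_number,
                 state = ifelse(sdf$copy_number > 2, "gain",
                                ifelse(sdf$copy_number < 2, "loss",
                                       "normal")),
                 stringsAsFactors = FALSE)
  }
  list(ct_long = do.call(rbind, rows), calibrator = calibrator,
       truth_states = do.call(rbind, states))
}

#' Score a CNVR set against planted truth by reciprocal overlap
#'
#' A truth region is recovered if some reported CNVR overlaps it with at
#' least `min_reciprocal` of BOTH lengths (50% reciprocal overlap by
#' default — deliberately stricter than the pipeline's 1-bp merge rule,
#' so sprawling unions are not credited). Precision counts reported
#' CNVRs matching some truth region under the same rule.
#'
#' @param cnvrs reported CNVR data frame.
#' @param truth a [simulate_truth()] object (or its `regions`).
#' @param min_reciprocal reciprocal overlap fraction (default 0.5).
#' @return list: `sensitivity`, `precision`, `n_truth`, `n_reported`,
#'   `recovered` (logical per truth region).
#' @export
score_against_truth <- function(cnvrs, truth, min_reciprocal = 0.5) {
  reg <- if (inherits(truth, "cnvr_truth")) truth$regions else truth
  match_pair <- function(a_s, a_e, b_s, b_e) {
    ov <- overlap_bp(a_s, a_e, b_s, b_e)
    ov >= min_reciprocal * length_bp(a_s, a_e) &
      ov >= min_reciprocal * length_bp(b_s, b_e)
  }
  recovered <- vapply(seq_len(nrow(reg)), function(i) {
    j <- cnvrs$chrom == reg$chrom[i]
    any(match_pair(reg$start[i], reg$end[i],
                   cnvrs$start[j], cnvrs$end[j]))
  }, logical(1))
  matched_rep <- vapply(seq_len(nrow(cnvrs)), function(i) {
    j <- reg$chrom == cnvrs$chrom[i]
    any(match_pair(cnvrs$start[i], cnvrs$end[i],
                   reg$start[j], reg$end[j]))
  }, logical(1))
  list(sensitivity = if (nrow(reg)) mean(recovered) else NA_real_,
       precision = if (nrow(cnvrs)) mean(matched_rep) else NA_real_,
       n_truth = nrow(reg), n_reported = nrow(cnvrs),
       recovered = recovered)
}
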