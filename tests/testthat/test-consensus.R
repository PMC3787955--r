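two_sets <- function() {
  list(
    gada = data.frame(cnvr_id = 1:2, chrom = "1",
                      start = c(1000, 9000), end = c(2000, 9500),
                      status = c("gain", "loss"), stringsAsFactors = FALSE),
    penncnv = data.frame(cnvr_id = 1L, chrom = "1", start = 1500,
                         end = 2500, status = "gain",
                         stringsAsFactors = FALSE))
}

test_that("consensus keeps >=2-program components with union spans", {
  cons <- build_consensus(two_sets(), min_support = 2)
  expect_equal(nrow(cons), 1)
  expect_equal(cons$start, 1000)
  expect_equal(cons$end, 2500)
  expect_equal(cons$status, "gain")
  expect_equal(cons$algorithms, "gada,penncnv")
  # the single-algorithm loss CNVR is absent
  expect_false(any(cons$start == 9000))
  expect_error(build_consensus(two_sets(), min_support = 3),
               "exceeds number of algorithms")
  expect_error(build_consensus(two_sets()["gada"]), ">= 2 algorithms")
})

test_that("intersection span mode shrinks to the shared core", {
  cons <- build_consensus(two_sets(), span = "intersection")
  expect_equal(cons$start, 1500)
  expect_equal(cons$end, 2000)
})

test_that("consensus matches the per-base >=2-algorithm vote oracle", {
  set.seed(21)
  max_pos <- 3000
  sets <- lapply(stats::setNames(nm = c("a", "b", "c", "d")), function(x) {
    calls <- random_calls(60, max_pos = max_pos - 100, seed = sample.int(1e4, 1))
    merge_to_cnvrs(calls)
  })
  cons <- build_consensus(sets, min_support = 2)
  for (ch in c("1", "2", "X")) {
    votes <- Reduce(`+`, lapply(sets, function(s)
      as.integer(oracle_mask(s, ch, max_pos))))
    # every base voted >=2 must be inside some consensus CNVR (union spans
    # can cover low-vote bases, but never miss a >=2-vote base)
    cons_mask <- oracle_mask(cons, ch, max_pos)
    expect_true(all(cons_mask[votes >= 2]))
    # and every consensus CNVR contains at least one >=2-vote base
    sub <- cons[cons$chrom == ch, ]
    for (i in seq_len(nrow(sub))) {
      expect_gte(max(votes[sub$start[i]:sub$end[i]]), 2)
    }
    # consensus coverage never exceeds the union of all sets
    union_mask <- Reduce(`|`, lapply(sets, function(s)
      oracle_mask(s, ch, max_pos)))
    expect_true(all(union_mask[cons_mask]))
  }
})

test_that("raising min_support never adds CNVRs nor extends spans", {
  set.seed(33)
  sets <- lapply(stats::setNames(nm = c("a", "b", "c", "d")), function(x)
    merge_to_cnvrs(random_calls(80, seed = sample.int(1e4, 1))))
  prev <- build_consensus(sets, min_support = 2)
  for (ms in 3:4) {
    nxt <- build_consensus(sets, min_support = ms)
    expect_lte(nrow(nxt), nrow(prev))
    # every higher-support CNVR coincides with one at lower support
    for (i in seq_len(nrow(nxt))) {
      j <- which(prev$chrom == nxt$chrom[i] & prev$start == nxt$start[i] &
                   prev$end == nxt$end[i])
      expect_length(j, 1)
    }
    prev <- nxt
  }
})

test_that("every consensus CNVR reports >= min_support algorithms", {
  sets <- lapply(stats::setNames(nm = c("a", "b", "c")), function(x)
    merge_to_cnvrs(random_calls(70, seed = nchar(x) + 400)))
  cons <- build_consensus(sets, min_support = 2)
  expect_true(all(cons$n_algorithms >= 2))
})

test_that("agreement fractions equal brute-force overlap counts", {
  sets <- lapply(stats::setNames(nm = c("a", "b", "c", "d")), function(x)
    merge_to_cnvrs(random_calls(60, seed = match(x, letters) + 900)))
  cons <- build_consensus(sets, min_support = 2)
  agr <- algorithm_agreement(sets, cons)
  for (k in seq_along(sets)) {
    s <- sets[[k]]
    want <- sum(vapply(seq_len(nrow(s)), function(i)
      any(cons$chrom == s$chrom[i] & cons$start <= s$end[i] &
            cons$end >= s$start[i]), logical(1)))
    expect_equal(agr$n_overlapping[k], want)
    expect_equal(agr$fraction_pct[k],
                 round_half_up(100 * want / nrow(s)))
  }
  # an algorithm entirely inside the consensus scores 100.00
  full <- algorithm_agreement(list(a = cons, b = cons), cons)
  expect_equal(full$fraction_pct, c(100, 100))
})

test_that("cross-study overlap handles identity and disjoint sets", {
  a <- merge_to_cnvrs(random_calls(50, seed = 2))
  expect_equal(cross_study_overlap(a, a)$fraction_pct, 100)
  b <- transform(a, chrom = "9")
  expect_equal(cross_study_overlap(a, b)$n_overlapping, 0)
  expect_equal(cross_study_overlap(a, b)$fraction_pct, 0)
})

test_that("consensus recovery at sensitivity 0.9 matches the binomial closed form", {
  # single-carrier truth, detectable sizes, no FPs, no jitter:
  # P(region recalled by >=2 of 4 independent callers)
  # = 1 - 0.1^4 - 4 * 0.9 * 0.1^3 = 0.9963
  n_reg <- 500
  truth <- simulate_truth(
    n_cnvrs = n_reg, size_range = c(200e3, 2e6),
    status_mix = c(gain = 1, loss = 1, "gain-loss" = 0),
    cohorts = data.frame(breed = "B", generation = "F2", n = 40),
    carrier_freq_range = c(1e-9, 1e-9), min_carriers_planted = 1,
    breed_specific_frac = 0, seed = 424)
  profs <- default_caller_profiles(sensitivity = 0.9, fp_rate = 0,
                                   boundary_jitter_sd = 0,
                                   state_flip_prob = 0)
  calls <- lapply(seq_along(profs), function(i)
    emit_caller_calls(truth, profs[[i]], seed = 424 + i))
  names(calls) <- names(profs)
  res <- run_cnvr_pipeline(calls, policy = filter_policy(min_carriers = 1))
  sc <- score_against_truth(res$consensus, truth)
  p <- 1 - 0.1^4 - 4 * 0.9 * 0.1^3
  sd3 <- 3 * sqrt(p * (1 - p) / n_reg)
  expect_gte(sc$sensitivity, p - sd3)
  expect_lte(sc$sensitivity, min(1, p + sd3))
})
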