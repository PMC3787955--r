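test_that("filter_calls enforces probe support and recurrence", {
  calls <- data.frame(
    sample_id = c("S1", "S2", "S3", "S4"),
    algorithm_id = "gada", chrom = "1",
    start = c(100, 150, 5000, 9000), end = c(200, 250, 6000, 9500),
    state = "gain", n_snps = c(5L, 5L, 10L, 2L),
    stringsAsFactors = FALSE)
  kept <- filter_calls(calls, filter_policy())
  # overlapping pair kept; isolated singleton dropped; low-probe dropped
  expect_equal(kept$sample_id, c("S1", "S2"))
  expect_error(filter_calls(transform(calls, algorithm_id = c("a", "b", "a", "a"))),
               "mixed algorithm_ids")
})

test_that("recurrence counts carriers, not calls", {
  # two overlapping calls from ONE sample are still a singleton event
  calls <- data.frame(sample_id = "S1", algorithm_id = "x", chrom = "1",
                      start = c(100, 150), end = c(200, 260),
                      state = "gain", n_snps = 5L,
                      stringsAsFactors = FALSE)
  expect_equal(nrow(filter_calls(calls)), 0)
})

test_that("filter_calls survivors match the quadratic clustering oracle", {
  calls <- random_calls(500, seed = 101)
  kept <- filter_calls(calls, filter_policy(min_snps = 3, min_carriers = 2))
  pre <- calls[calls$n_snps >= 3, ]
  comp <- oracle_components(pre)
  carriers <- tapply(pre$sample_id, comp, function(s) length(unique(s)))
  want <- pre[carriers[as.character(comp)] >= 2, ]
  expect_equal(kept$sample_id, want$sample_id)
  expect_equal(kept$start, want$start)
})

test_that("merge_to_cnvrs follows the overlap-component definition", {
  calls <- data.frame(sample_id = c("a", "b"), algorithm_id = "x",
                      chrom = "1", start = c(100, 150),
                      end = c(200, 300),
                      state = c("gain", "loss"), n_snps = 5L,
                      stringsAsFactors = FALSE)
  cnvrs <- merge_to_cnvrs(calls)
  expect_equal(nrow(cnvrs), 1)
  expect_equal(cnvrs$start, 100)
  expect_equal(cnvrs$end, 300)
  expect_equal(cnvrs$status, "gain-loss")
  # abutting intervals stay separate under inclusive coordinates
  ab <- transform(calls, start = c(100, 201), end = c(200, 300))
  expect_equal(nrow(merge_to_cnvrs(ab)), 2)
})

test_that("CNVR coverage equals call coverage (per-base mask oracle)", {
  calls <- random_calls(1000, seed = 77)
  cnvrs <- merge_to_cnvrs(calls)
  for (ch in unique(calls$chrom)) {
    m_calls <- oracle_mask(calls, ch, 2100)
    m_cnvrs <- oracle_mask(cnvrs, ch, 2100)
    expect_identical(m_calls, m_cnvrs)
    # every CNVR is contiguously covered by calls
    sub <- cnvrs[cnvrs$chrom == ch, ]
    for (i in seq_len(nrow(sub)))
      expect_true(all(m_calls[sub$start[i]:sub$end[i]]))
  }
  # spans match the union-find components (abutting CNVRs stay separate)
  comp <- oracle_components(calls)
  spans <- do.call(rbind, lapply(split(seq_len(nrow(calls)), comp),
    function(i) data.frame(chrom = calls$chrom[i[1]],
                           start = min(calls$start[i]),
                           end = max(calls$end[i]))))
  spans <- spans[order(chrom_rank(spans$chrom), spans$start), ]
  expect_equal(cnvrs$start, spans$start)
  expect_equal(cnvrs$end, spans$end)
})

test_that("merge is idempotent, order-invariant, and conserves status counts", {
  calls <- random_calls(300, seed = 13)
  cnvrs <- merge_to_cnvrs(calls)
  again <- merge_to_cnvrs(transform(cnvrs, state = "gain",
                                    sample_id = "x"))
  expect_equal(again[, c("chrom", "start", "end")],
               cnvrs[, c("chrom", "start", "end")])
  perm <- merge_to_cnvrs(calls[sample(nrow(calls)), ])
  expect_equal(perm, cnvrs)
  expect_equal(sum(table(cnvrs$status)), nrow(cnvrs))
  # non-overlap within the output
  expect_equal(length(unique(overlap_components(cnvrs))), nrow(cnvrs))
})

test_that("gap screening discards exactly the gap-touching CNVRs", {
  cnvrs <- merge_to_cnvrs(random_calls(200, seed = 55))
  gaps <- data.frame(feature_id = paste0("gap", 1:8),
                     chrom = sample(c("1", "2", "X"), 8, replace = TRUE),
                     start = sample.int(1900, 8), kind = "gap",
                     stringsAsFactors = FALSE)
  gaps$end <- gaps$start + 20
  res <- screen_gaps(cnvrs, gaps)
  want_discard <- vapply(seq_len(nrow(cnvrs)), function(i)
    any(gaps$chrom == cnvrs$chrom[i] &
          gaps$start <= cnvrs$end[i] & gaps$end >= cnvrs$start[i]),
    logical(1))
  expect_equal(res$discarded$cnvr_id, cnvrs$cnvr_id[want_discard])
  expect_equal(nrow(res$kept) + nrow(res$discarded), nrow(cnvrs))
  expect_equal(screen_gaps(cnvrs, NULL)$kept, cnvrs)
  single <- screen_gaps(data.frame(cnvr_id = 1, chrom = "1", start = 100,
                                   end = 300, status = "gain"),
                        data.frame(feature_id = "g", chrom = "1",
                                   start = 200, end = 210, kind = "gap"))
  expect_equal(nrow(single$kept), 0)
})

test_that("summaries agree with naive recomputation", {
  cnvrs <- merge_to_cnvrs(random_calls(150, seed = 3))
  s <- summarize_cnvrs(cnvrs, genome_size_bp = 6000)
  kb <- (cnvrs$end - cnvrs$start) / 1000
  expect_equal(s$n, nrow(cnvrs))
  expect_equal(s$median_kb, median(kb))
  expect_equal(s$max_kb, max(kb))
  expect_equal(unname(s$coverage_mb),
               sum(cnvrs$end - cnvrs$start + 1) / 1e6)  # already disjoint
  one <- data.frame(cnvr_id = 1, chrom = "1", start = 1000, end = 2000,
                    status = "gain")
  s1 <- summarize_cnvrs(one)
  expect_equal(s1$min_kb, s1$max_kb)
  expect_equal(s1$min_kb, 1)  # published (end - start) convention
  expect_error(summarize_cnvrs(cnvrs[0, ]), "empty")
})
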