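# Independent brute-force oracles. These deliberately use different
# algorithms from the package code paths they check: union-find over all
# pairs instead of sort-and-sweep, per-base boolean masks instead of
# interval arithmetic, and the Wigginton recurrence instead of direct
# log-factorial evaluation.

# O(n^2) pairwise overlap clustering with union-find
oracle_components <- function(df) {
  n <- nrow(df)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && df$chrom[i] == df$chrom[j] &&
        df$start[i] <= df$end[j] && df$start[j] <= df$end[i]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# per-base occupancy mask of an interval set (small coordinates only)
oracle_mask <- function(df, chrom, max_pos) {
  mask <- logical(max_pos)
  sub <- df[df$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(sub)))
    mask[sub$start[i]:sub$end[i]] <- TRUE
  mask
}

# contiguous TRUE runs of a mask -> intervals
oracle_mask_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(start = starts[r$values], end = ends[r$values])
}

# exact HWE test by the heterozygote-count recurrence (Wigginton-style),
# independent of the package's log-factorial evaluation
oracle_hwe <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  nA <- 2 * nAA + nAB
  nr <- min(nA, 2 * n - nA)
  if (nr == 0) return(1)
  hets <- seq(nr %% 2, nr, by = 2)
  probs <- numeric(length(hets))
  probs[1] <- 1
  for (k in seq_along(hets)[-1]) {
    h <- hets[k]  # P(h) = P(h-2) * 4*ra(h-2)*ca(h-2) / (h*(h-1))
    ra_prev <- (nr - (h - 2)) / 2
    ca_prev <- n - (h - 2) - ra_prev
    probs[k] <- probs[k - 1] * 4 * ra_prev * ca_prev / (h * (h - 1))
  }
  probs <- probs / sum(probs)
  obs <- probs[match(nAB, hets)]
  min(1, sum(probs[probs <= obs * (1 + 1e-9)]))
}

# random small-coordinate call table for property tests
random_calls <- function(n, n_samples = 6, max_pos = 2000, seed,
                         algorithms = "algA") {
  set.seed(seed)
  s <- sample.int(max_pos - 60, n, replace = TRUE)
  data.frame(sample_id = paste0("s", sample.int(n_samples, n, TRUE)),
             algorithm_id = sample(algorithms, n, TRUE),
             chrom = sample(c("1", "2", "X"), n, TRUE),
             start = s, end = s + sample.int(60, n, TRUE) - 1,
             state = sample(c("gain", "loss"), n, TRUE),
             n_snps = sample.int(10, n, TRUE),
             stringsAsFactors = FALSE)
}
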