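# Independent oracles used across the suite. These deliberately re-derive
# results by brute force / enumeration, separate from the package code paths
# they check.

# two-sided Fisher p by exhaustive hypergeometric enumeration over all tables
# with the observed margins
enum_fisher_p <- function(a, b, c, d) {
  m <- a + b            # row 1 total
  n <- c + d            # row 2 total
  k <- a + c            # col 1 total
  lo <- max(0L, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# upper-tail overlap p by explicit enumeration of all draws of |B| from the
# universe, with A fixed
enum_overlap_p <- function(nA, nB, universe, k_obs) {
  draws <- utils::combn(universe, nB)
  overlaps <- colSums(draws <= nA)   # treat 1..nA as set A
  mean(overlaps >= k_obs)
}

# O(n^2) coordination-number count
brute_cn <- function(xyz, radius) {
  n <- nrow(xyz)
  cn <- integer(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= radius)
      cn[i] <- cn[i] + 1L
  }
  cn
}

# brute-force disorder-run scanner
brute_regions <- function(scores, cutoff, min_len, max_len = Inf) {
  hits <- which(scores >= cutoff)
  out <- list()
  i <- 1
  while (i <= length(hits)) {
    j <- i
    while (j < length(hits) && hits[j + 1] == hits[j] + 1) j <- j + 1
    len <- hits[j] - hits[i] + 1
    if (len >= min_len && len <= max_len)
      out[[length(out) + 1]] <- c(hits[i], hits[j])
    i <- j + 1
  }
  if (!length(out)) return(data.frame(start = integer(), end = integer()))
  m <- do.call(rbind, out)
  data.frame(start = m[, 1], end = m[, 2])
}

# closed-form 4PL response (independent of the package helper)
ref_4pl <- function(conc, ic50, slope = 1, top = 1, bottom = 0)
  bottom + (top - bottom) / (1 + (conc / ic50)^slope)
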