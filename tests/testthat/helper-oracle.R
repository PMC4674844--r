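# Independent oracles used across the suite. None of these call the
# package's scoring path.

# Exhaustive set-enumeration oracle for the hypergeometric upper tail:
# fix a reference set A = the first n of N elements; enumerate every
# subset B of size m as a bitmask; P(X >= k) is the fraction of those
# subsets sharing at least k elements with A. Returns the full tail table
# for a given N: tails[[n+1]][[m+1]][k+1] = P(X >= k).
enumTailTable <- function(N) {
  masks <- 0:(2^N - 1)
  pc <- integer(2^N)
  if (N > 0)
    for (i in 1:(2^N - 1)) pc[i + 1] <- pc[bitwShiftR(i, 1) + 1] + bitwAnd(i, 1)
  sizes <- pc[masks + 1]
  lapply(0:N, function(n) {
    A <- if (n > 0) bitwShiftL(1L, n) - 1L else 0L
    ov <- pc[bitwAnd(masks, A) + 1]
    lapply(0:N, function(m) {
      sel <- sizes == m
      tot <- sum(sel)
      vapply(0:min(n, m), function(k) sum(sel & ov >= k) / tot, numeric(1))
    })
  })
}

enumTail <- function(N, n, m, k) {
  if (k == 0) return(1)
  enumTailTable(N)[[n + 1]][[m + 1]][k + 1]
}

# Brute-force end-to-end oracle: raw scores straight from set arithmetic
# and phyper (no package scoring code), min-max normalization and OAS by
# direct arithmetic. `catalogSets` is a named list gene -> attribute set;
# N as the caller determines per type.
bruteRawProfile <- function(sets, N, query, universe) {
  cand <- setdiff(universe, query)
  vapply(cand, function(b) {
    n <- length(sets[[query]]); m <- length(sets[[b]])
    k <- length(intersect(sets[[query]], sets[[b]]))
    if (k == 0) return(0)
    -log10(max(phyper(k - 1, n, N - n, m, lower.tail = FALSE), 1e-300))
  }, numeric(1))
}

bruteNormalize <- function(raw) {
  lo <- min(raw); hi <- max(raw)
  if (hi > lo) (raw - lo) / (hi - lo) else raw * 0
}

# Independent OAS over all candidates from in-memory attribute sets.
# setsPerType: named list type -> list(sets = <gene->attrs>, N = <int>).
# epRaw: optional named raw EP vector over candidates.
bruteOAS <- function(setsPerType, query, universe, chosen, epRaw = NULL) {
  cand <- sort(setdiff(universe, query))
  oas <- setNames(numeric(length(cand)), cand)
  for (ty in chosen) {
    raw <- if (ty == "EP") epRaw[cand]
      else bruteRawProfile(setsPerType[[ty]]$sets, setsPerType[[ty]]$N,
                           query, universe)[cand]
    oas <- oas + bruteNormalize(raw)
  }
  oas
}
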