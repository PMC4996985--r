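# Independent brute-force oracles. These deliberately share no code with
# the package: alignment scoring enumerates every gapped alignment as a
# move sequence, and HMM scoring enumerates every state path.

# Exhaustive global alignment score with affine gaps (gap of length L
# costs open + L * ext, opened per maximal run). prev: 0 = start/diagonal,
# 1 = gap in b (consumes a), 2 = gap in a (consumes b).
enum_global_score <- function(a, b, mat, open = 11, ext = 1) {
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  na <- length(ca); nb <- length(cb)
  rec <- function(i, j, prev) {
    if (i == na && j == nb) return(0)
    best <- -Inf
    if (i < na && j < nb)
      best <- max(best, mat[ca[i + 1L], cb[j + 1L]] + rec(i + 1L, j + 1L, 0L))
    if (i < na)
      best <- max(best, -(ext + if (prev != 1L) open else 0) + rec(i + 1L, j, 1L))
    if (j < nb)
      best <- max(best, -(ext + if (prev != 2L) open else 0) + rec(i, j + 1L, 2L))
    best
  }
  rec(0L, 0L, 0L)
}

# Exhaustive path sum / max through a ProfileHMM, in log2 odds bits.
# Walks every path Begin -> ... -> End that emits exactly `res`.
enum_hmm_bits <- function(hmm, seq, mode = c("forward", "viterbi")) {
  mode <- match.arg(mode)
  res <- strsplit(toupper(as.character(seq)), "")[[1L]]
  n <- length(res)
  L <- hmm@nMatch
  bg <- hmm@background
  oddsM <- sweep(hmm@matchEmis, 2, bg, "/")
  oddsI <- sweep(hmm@insEmis, 2, bg, "/")
  tr <- hmm@trans
  comb <- if (mode == "forward") sum else max
  g <- function(type, k, i) {
    vals <- numeric(0)
    if (k == L && i == n)
      vals <- c(vals, tr[L + 1L, type, "M"])
    if (k < L && i < n)
      vals <- c(vals, tr[k + 1L, type, "M"] * oddsM[k + 1L, res[i + 1L]] *
                        g("M", k + 1L, i + 1L))
    if (k < L)
      vals <- c(vals, tr[k + 1L, type, "D"] * g("D", k + 1L, i))
    if (i < n)
      vals <- c(vals, tr[k + 1L, type, "I"] * oddsI[k + 1L, res[i + 1L]] *
                        g("I", k, i + 1L))
    vals <- vals[vals > 0]
    if (!length(vals)) return(0)
    comb(vals)
  }
  p <- g("M", 0L, 0L)
  if (p <= 0) return(-Inf)
  log2(p)
}

# Brute-force degenerate pattern scan: every window of the sequence is
# tested against the pattern with the same semantics as the engine
# (x wildcard; starred positions identity; others identity-or-similarity).
brute_pattern_starts <- function(res, pattern, starred_offsets, mat, cutoff = 1) {
  pch <- strsplit(pattern, "")[[1L]]
  len <- length(pch)
  if (length(res) < len) return(integer(0))
  hits <- integer(0)
  for (s in seq_len(length(res) - len + 1L)) {
    ok <- TRUE
    for (t in seq_len(len)) {
      if (pch[t] == "x") next
      obs <- res[s + t - 1L]
      if (obs == pch[t]) next
      if (t %in% starred_offsets || !(obs %in% rownames(mat)) ||
          mat[obs, pch[t]] < cutoff) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, s)
  }
  hits
}

random_protein <- function(n) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y"), n, replace = TRUE),
        collapse = "")
}
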