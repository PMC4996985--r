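.aln_char_matrix <- function(aln) {
  if (is(aln, "AAMultipleAlignment")) aln <- as.character(aln)
  if (is.matrix(aln)) return(aln)
  rows <- strsplit(toupper(aln), "")
  stopifnot(length(unique(lengths(rows))) == 1L)
  m <- do.call(rbind, rows)
  rownames(m) <- names(aln)
  m
}

#' Build a profile HMM from a multiple alignment
#'
#' Alignment columns whose gap fraction is strictly below `gapThreshold`
#' become match states; the remaining columns feed the insert states.
#' Match and insert emissions are observed residue counts plus
#' background-proportional pseudocounts (weight `pseudocountWeight`),
#' normalized; transitions are counted from each member's implied
#' match/insert/delete path and Laplace-smoothed (+1 on every admissible
#' transition). This is a deliberately simple, fully documented prior —
#' scores are not bit-identical to HMMER's Dirichlet-mixture models.
#'
#' @param aln an `AAMultipleAlignment`, named character vector of gapped
#'   strings, or character matrix.
#' @param pseudocountWeight weight of the background pseudocount
#'   (default 1).
#' @param gapThreshold match-column rule: gap fraction < threshold
#'   (default 0.5, the HMMER-like rule).
#' @param background "uniform" (1/20, the default) or "empirical"
#'   (residue frequencies of the training alignment).
#' @param force allow a single-member alignment (degenerate profile).
#' @return a [ProfileHMM-class].
#' @export
buildProfileHMM <- function(aln, pseudocountWeight = 1, gapThreshold = 0.5,
                            background = c("uniform", "empirical"),
                            force = FALSE) {
  background <- match.arg(background)
  m <- .aln_char_matrix(aln)
  if (nrow(m) < 2L && !force)
    stop("alignment has fewer than 2 members; use force = TRUE for a degenerate profile")
  gapFrac <- colMeans(m == "-")
  is_match <- gapFrac < gapThreshold
  L <- sum(is_match)
  if (L < 1L) stop("no match columns under gapThreshold = ", gapThreshold)
  bg <- if (background == "uniform") rep(1 / 20, 20) else {
    cnt <- table(factor(m[m %in% AA20], levels = AA20))
    as.numeric(cnt + 1) / sum(cnt + 1)
  }
  names(bg) <- AA20

  match_idx <- cumsum(is_match)          # column -> match state index
  mcnt <- matrix(0, L, 20, dimnames = list(NULL, AA20))
  icnt <- matrix(0, L + 1L, 20, dimnames = list(NULL, AA20))
  states <- c("M", "I", "D")
  tcnt <- array(0, dim = c(L + 1L, 3, 3), dimnames = list(NULL, states, states))

  for (r in seq_len(nrow(m))) {
    prev <- "M"; k <- 0L                  # begin state = M0
    for (j in seq_len(ncol(m))) {
      ch <- m[r, j]
      if (is_match[j]) {
        typ <- if (ch == "-") "D" else "M"
        tcnt[k + 1L, prev, typ] <- tcnt[k + 1L, prev, typ] + 1
        k <- k + 1L
        if (ch %in% AA20) mcnt[k, ch] <- mcnt[k, ch] + 1
        prev <- typ
      } else if (ch != "-") {
        tcnt[k + 1L, prev, "I"] <- tcnt[k + 1L, prev, "I"] + 1
        if (ch %in% AA20) icnt[k + 1L, ch] <- icnt[k + 1L, ch] + 1
        prev <- "I"
      }
    }
    tcnt[L + 1L, prev, "M"] <- tcnt[L + 1L, prev, "M"] + 1   # -> end
  }

  norm_rows <- function(cnt) {
    p <- sweep(cnt, 2, pseudocountWeight * bg, "+")
    rs <- rowSums(p)
    empty <- rs == 0                      # no counts, no pseudocounts
    p[empty, ] <- rep(bg, each = sum(empty))
    rs[empty] <- 1
    p / rs
  }
  trans <- array(0, dim = dim(tcnt), dimnames = dimnames(tcnt))
  for (k in seq_len(L + 1L)) {
    allowed <- if (k == L + 1L) c("M", "I") else states
    for (f in states) {
      if (k == 1L && f == "D") next       # no delete state before column 1
      row <- tcnt[k, f, allowed] + 1
      trans[k, f, allowed] <- row / sum(row)
    }
  }
  new("ProfileHMM", nMatch = L, matchEmis = norm_rows(mcnt),
      insEmis = norm_rows(icnt), trans = trans, background = bg)
}

.seq_residues <- function(seq) {
  res <- strsplit(toupper(as.character(seq)), "")[[1L]]
  bad <- setdiff(unique(res), AA_ALPHABET_X)
  if (length(bad)) stop("illegal residue '", bad[1L], "' in sequence")
  res
}

# Per-position log-odds emission lookups; ambiguity code X emits at the
# background rate (log-odds 0).
.emission_odds <- function(emis, bg, res) {
  lo <- log2(emis) - rep(log2(bg), each = nrow(emis))
  out <- matrix(0, nrow(emis), length(res))
  known <- res %in% AA20
  out[, known] <- lo[, res[known], drop = FALSE]
  out
}

.hmm_dp <- function(hmm, seq) {
  mode <- "viterbi"
  res <- .seq_residues(seq)
  n <- length(res)
  if (n == 0L) stop("cannot score an empty sequence")
  L <- hmm@nMatch
  eM <- .emission_odds(hmm@matchEmis, hmm@background, res)   # L x n
  eI <- .emission_odds(hmm@insEmis, hmm@background, res)     # (L+1) x n
  lt <- log2(hmm@trans)                                      # -Inf where 0
  NEG <- -Inf
  comb2 <- if (mode == "viterbi") function(x) max(x) else function(x) {
    mx <- max(x)
    if (!is.finite(mx)) return(NEG)
    mx + log2(sum(2^(x - mx)))
  }
  VM <- matrix(NEG, L + 1L, n + 1L)
  VI <- matrix(NEG, L + 1L, n + 1L)
  VD <- matrix(NEG, L + 1L, n + 1L)
  VM[1L, 1L] <- 0
  ptr <- if (mode == "viterbi")
    list(M = matrix(NA_integer_, L + 1L, n + 1L),
         I = matrix(NA_integer_, L + 1L, n + 1L),
         D = matrix(NA_integer_, L + 1L, n + 1L)) else NULL
  # N-terminal insert state I0 (boundary 1)
  for (i in seq_len(n)) {
    cand <- c(VM[1L, i] + lt[1L, "M", "I"], VI[1L, i] + lt[1L, "I", "I"], NEG)
    VI[1L, i + 1L] <- eI[1L, i] + comb2(cand)
    if (mode == "viterbi" && is.finite(VI[1L, i + 1L]))
      ptr$I[1L, i + 1L] <- which.max(cand)
  }
  for (k in seq_len(L)) {
    for (i in 0:n) {
      # delete: no emission, predecessor at column k-1 with same i
      cand <- c(VM[k, i + 1L] + lt[k, "M", "D"],
                VI[k, i + 1L] + lt[k, "I", "D"],
                VD[k, i + 1L] + lt[k, "D", "D"])
      VD[k + 1L, i + 1L] <- comb2(cand)
      if (mode == "viterbi" && is.finite(VD[k + 1L, i + 1L]))
        ptr$D[k + 1L, i + 1L] <- which.max(cand)
      if (i >= 1L) {
        cand <- c(VM[k, i] + lt[k, "M", "M"],
                  VI[k, i] + lt[k, "I", "M"],
                  VD[k, i] + lt[k, "D", "M"])
        VM[k + 1L, i + 1L] <- eM[k, i] + comb2(cand)
        if (mode == "viterbi" && is.finite(VM[k + 1L, i + 1L]))
          ptr$M[k + 1L, i + 1L] <- which.max(cand)
        cand <- c(VM[k + 1L, i] + lt[k + 1L, "M", "I"],
                  VI[k + 1L, i] + lt[k + 1L, "I", "I"],
                  VD[k + 1L, i] + lt[k + 1L, "D", "I"])
        VI[k + 1L, i + 1L] <- eI[k + 1L, i] + comb2(cand)
        if (mode == "viterbi" && is.finite(VI[k + 1L, i + 1L]))
          ptr$I[k + 1L, i + 1L] <- which.max(cand)
      }
    }
  }
  final <- c(VM[L + 1L, n + 1L] + lt[L + 1L, "M", "M"],
             VI[L + 1L, n + 1L] + lt[L + 1L, "I", "M"],
             VD[L + 1L, n + 1L] + lt[L + 1L, "D", "M"])
  bits <- comb2(final)
  # traceback
  path <- character(0)
  f <- which.max(final); k <- L; i <- n
  states <- c("M", "I", "D")
  while (!(f == 1L && k == 0L && i == 0L)) {
    st <- states[f]
    path <- c(sprintf("%s%d", st, k), path)
    p <- ptr[[st]][k + 1L, i + 1L]
    if (st == "M") { k <- k - 1L; i <- i - 1L }
    else if (st == "I") { i <- i - 1L }
    else { k <- k - 1L }
    f <- p
    if (k < 0L || i < 0L) stop("traceback error")  # defensive
  }
  list(bits = bits, path = path)
}

#' Viterbi score and state path
#'
#' Optimal global path of a sequence through the model, scored in
#' log-odds bits against the background distribution (emission odds plus
#' model transition log-probabilities; the null model has no transition
#' cost). Ties are broken deterministically (match > insert > delete).
#'
#' @param hmm a [ProfileHMM-class].
#' @param seq protein sequence.
#' @return a list with `bits` and `path` (state labels such as "M3",
#'   "I0", "D5").
#' @export
hmmViterbi <- function(hmm, seq) .hmm_dp(hmm, seq)

#' Forward score
#'
#' Log-sum of all global paths, in bits; always at least the Viterbi
#' score.
#'
#' @inheritParams hmmViterbi
#' @return the forward bit score.
#' @export
hmmForward <- function(hmm, seq) {
  res <- .seq_residues(seq)
  n <- length(res)
  if (n == 0L) stop("cannot score an empty sequence")
  L <- hmm@nMatch
  eM <- .emission_odds(hmm@matchEmis, hmm@background, res)
  eI <- .emission_odds(hmm@insEmis, hmm@background, res)
  lt <- log2(hmm@trans)
  lse3 <- function(a, b, c) {           # elementwise log2-sum-exp
    m <- pmax(a, b, c)
    out <- m + log2(2^(a - m) + 2^(b - m) + 2^(c - m))
    out[!is.finite(m)] <- -Inf
    out
  }
  NEG <- -Inf
  vM <- c(0, rep(NEG, n))               # row k = 0 (begin), index i+1
  vI <- rep(NEG, n + 1L)
  vD <- rep(NEG, n + 1L)
  for (i in seq_len(n))                 # N-terminal inserts
    vI[i + 1L] <- eI[1L, i] + lse3(vM[i] + lt[1L, "M", "I"],
                                   vI[i] + lt[1L, "I", "I"], NEG)
  for (k in seq_len(L)) {
    nM <- c(NEG, eM[k, ] + lse3(vM[1:n] + lt[k, "M", "M"],
                                vI[1:n] + lt[k, "I", "M"],
                                vD[1:n] + lt[k, "D", "M"]))
    nD <- lse3(vM + lt[k, "M", "D"], vI + lt[k, "I", "D"], vD + lt[k, "D", "D"])
    nI <- rep(NEG, n + 1L)
    tMI <- lt[k + 1L, "M", "I"]; tII <- lt[k + 1L, "I", "I"]; tDI <- lt[k + 1L, "D", "I"]
    for (i in seq_len(n)) {
      x <- c(nM[i] + tMI, nI[i] + tII, nD[i] + tDI)
      mx <- max(x)
      nI[i + 1L] <- if (is.finite(mx)) eI[k + 1L, i] + mx + log2(sum(2^(x - mx))) else NEG
    }
    vM <- nM; vI <- nI; vD <- nD
  }
  lse3(vM[n + 1L] + lt[L + 1L, "M", "M"],
       vI[n + 1L] + lt[L + 1L, "I", "M"],
       vD[n + 1L] + lt[L + 1L, "D", "M"])
}

#' Per-column logo statistics
#'
#' Computes, for every match column, the information content in bits
#' (relative entropy of the match emission against the background), the
#' occupancy (fraction of training members with a residue in the
#' column), the insert probability (fraction of members with at least
#' one inserted residue before the next match column) and the expected
#' insert length (mean insertion length among inserting members; 0 when
#' none insert) — the three per-column values displayed under an HMM
#' logo.
#'
#' @param hmm a [ProfileHMM-class].
#' @param aln the training alignment the model was built from.
#' @param gapThreshold must match the value used at build time.
#' @return a data.frame with columns column, IC_bits, occupancy,
#'   insert_prob, insert_len.
#' @export
hmmLogo <- function(hmm, aln, gapThreshold = 0.5) {
  m <- .aln_char_matrix(aln)
  is_match <- colMeans(m == "-") < gapThreshold
  L <- sum(is_match)
  if (L != hmm@nMatch)
    stop("alignment implies ", L, " match columns but model has ", hmm@nMatch)
  ic <- vapply(seq_len(L), function(k) {
    p <- hmm@matchEmis[k, ]
    sum(ifelse(p > 0, p * (log2(p) - log2(hmm@background)), 0))
  }, 0)
  mcols_idx <- which(is_match)
  occ <- colMeans(m[, mcols_idx, drop = FALSE] != "-")
  ins_prob <- numeric(L)
  ins_len <- numeric(L)
  bounds <- c(mcols_idx, ncol(m) + 1L)
  for (k in seq_len(L)) {
    reg <- setdiff(seq(bounds[k] + 1L, length.out = max(0L, bounds[k + 1L] - bounds[k] - 1L)),
                   integer(0))
    if (length(reg)) {
      lens <- rowSums(m[, reg, drop = FALSE] != "-")
      ins_prob[k] <- mean(lens > 0)
      ins_len[k] <- if (any(lens > 0)) mean(lens[lens > 0]) else 0
    }
  }
  data.frame(column = seq_len(L), IC_bits = ic, occupancy = occ,
             insert_prob = ins_prob, insert_len = ins_len, row.names = NULL)
}

#' Classify a sequence against a profile HMM
#'
#' @inheritParams hmmViterbi
#' @param bitThreshold minimum forward bit score counted as a hit.
#' @return a list with `hit` and `bits`.
#' @export
hmmClassify <- function(hmm, seq, bitThreshold) {
  bits <- hmmForward(hmm, seq)
  list(hit = bits >= bitThreshold, bits = bits)
}

#' Calibrate a bit-score threshold from training members
#'
#' The default operating point is the minimum training-member self-score
#' minus a safety margin (2 bits): every training member then scores a
#' hit with headroom for near relatives.
#'
#' @param hmm a [ProfileHMM-class].
#' @param seqs the (unaligned) training sequences.
#' @param margin bits subtracted from the minimum self-score.
#' @return the threshold in bits.
#' @export
calibrateBitThreshold <- function(hmm, seqs, margin = 2) {
  scores <- vapply(seq_along(seqs), function(i) hmmForward(hmm, seqs[[i]]), 0)
  min(scores) - margin
}

#' Write a profile HMM as plain text
#'
#' A simple documented format (HMMER3-inspired header plus per-column
#' probability lines); see [readProfileHMM()] for the inverse.
#'
#' @param hmm a [ProfileHMM-class].
#' @param path output path.
#' @export
writeProfileHMM <- function(hmm, path) {
  fmt <- function(x) paste(format(x, digits = 17, scientific = TRUE, trim = TRUE),
                           collapse = " ")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("AMDSCREEN-HMM 1",
               paste("NMATCH", hmm@nMatch),
               paste("ALPHABET", paste(AA20, collapse = " ")),
               paste("BACKGROUND", fmt(hmm@background))), con)
  for (k in seq_len(hmm@nMatch))
    writeLines(paste("MATCH", k, fmt(hmm@matchEmis[k, ])), con)
  for (k in 0:hmm@nMatch)
    writeLines(paste("INSERT", k, fmt(hmm@insEmis[k + 1L, ])), con)
  for (k in seq_len(hmm@nMatch + 1L))
    writeLines(paste("TRANS", k, fmt(as.numeric(t(hmm@trans[k, , ])))), con)
  writeLines("END", con)
  invisible(path)
}

#' Read a profile HMM written by [writeProfileHMM()]
#'
#' @param path model file.
#' @return a [ProfileHMM-class].
#' @export
readProfileHMM <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!startsWith(lines[1L], "AMDSCREEN-HMM"))
    stop("not an amdscreen HMM file")
  toks <- strsplit(lines, "\\s+")
  key <- vapply(toks, `[`, "", 1L)
  nums <- function(t, skip) as.numeric(t[-seq_len(skip)])
  L <- as.integer(toks[[which(key == "NMATCH")]][2L])
  bg <- nums(toks[[which(key == "BACKGROUND")]], 1L)
  names(bg) <- AA20
  matchEmis <- matrix(0, L, 20, dimnames = list(NULL, AA20))
  for (i in which(key == "MATCH")) {
    k <- as.integer(toks[[i]][2L])
    matchEmis[k, ] <- nums(toks[[i]], 2L)
  }
  insEmis <- matrix(0, L + 1L, 20, dimnames = list(NULL, AA20))
  for (i in which(key == "INSERT")) {
    k <- as.integer(toks[[i]][2L])
    insEmis[k + 1L, ] <- nums(toks[[i]], 2L)
  }
  states <- c("M", "I", "D")
  trans <- array(0, dim = c(L + 1L, 3, 3), dimnames = list(NULL, states, states))
  for (i in which(key == "TRANS")) {
    k <- as.integer(toks[[i]][2L])
    trans[k, , ] <- matrix(nums(toks[[i]], 2L), 3, 3, byrow = TRUE)
  }
  new("ProfileHMM", nMatch = L, matchEmis = matchEmis, insEmis = insEmis,
      trans = trans, background = bg)
}

#' Write logo statistics as TSV
#'
#' @param logo data.frame from [hmmLogo()].
#' @param path output path.
#' @export
writeLogoTable <- function(logo, path) {
  utils::write.table(logo, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

setMethod("show", "ProfileHMM", function(object) {
  cat("ProfileHMM with", object@nMatch, "match states\n")
  top <- AA20[apply(object@matchEmis, 1, which.max)]
  cat("  consensus:", paste(utils::head(top, 60L), collapse = ""),
      if (object@nMatch > 60L) "..." else "", "\n")
})
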