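#' Scoring matrix for the screen
#'
#' Returns the BLOSUM62 matrix shipped with Biostrings, modified so that
#' the ambiguity code `X` scores 0 against every residue (neutral
#' ambiguity handling: an `X` can then never satisfy the similarity
#' cutoff, which is at least 1).
#'
#' @param name matrix name; only "BLOSUM62" ships with the package, other
#'   names are looked up in Biostrings' data sets.
#' @return an integer substitution matrix.
#' @export
amdScoringMatrix <- function(name = "BLOSUM62") {
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  mat <- get(name, envir = env)
  if ("X" %in% rownames(mat)) {
    mat["X", ] <- 0L
    mat[, "X"] <- 0L
  }
  mat
}

#' Read an NCBI-format substitution matrix
#'
#' Parses the plain-text matrix format used by NCBI BLAST (`#` comments, a
#' header row of residue letters, one labeled score row per residue).
#'
#' @param path matrix file.
#' @return an integer matrix with residue dimnames.
#' @export
readScoringMatrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  rows <- strsplit(trimws(lines[-1L]), "\\s+")
  lab <- vapply(rows, `[`, "", 1L)
  mat <- t(vapply(rows, function(r) as.integer(r[-1L]), integer(length(header))))
  dimnames(mat) <- list(lab, header)
  if (!isSymmetric(unname(mat[header, header])))
    warning("substitution matrix is not symmetric")
  mat
}

.as_aa_string <- function(s) {
  if (is(s, "AAString")) return(s)
  if (is(s, "AAStringSet")) {
    stopifnot(length(s) == 1L)
    return(s[[1L]])
  }
  Biostrings::AAString(toupper(as.character(s)))
}

.alignment_result <- function(pa, mode) {
  a <- as.character(Biostrings::alignedPattern(pa))
  b <- as.character(Biostrings::alignedSubject(pa))
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  n <- length(ca)
  if (n == 0L) {
    return(new("AlignmentResult", alignedA = "", alignedB = "",
               score = Biostrings::score(pa), identities = 0L,
               alignedColumns = 0L, percentIdentity = 0, mode = mode))
  }
  keep <- rep(TRUE, n)
  if (mode == "global") {
    # drop terminal-gap columns (before both sequences have started or
    # after either has ended) from the identity denominator
    first_a <- which(ca != "-")[1L]; last_a <- rev(which(ca != "-"))[1L]
    first_b <- which(cb != "-")[1L]; last_b <- rev(which(cb != "-"))[1L]
    from <- max(first_a, first_b); to <- min(last_a, last_b)
    keep <- seq_len(n) >= from & seq_len(n) <= to
  }
  ident <- sum(ca == cb & ca != "-" & keep)
  cols <- sum(keep)
  new("AlignmentResult", alignedA = a, alignedB = b,
      score = Biostrings::score(pa), identities = as.integer(ident),
      alignedColumns = as.integer(cols),
      percentIdentity = if (cols > 0L) 100 * ident / cols else 0,
      mode = mode)
}

#' Global (Needleman-Wunsch) pairwise alignment
#'
#' Optimal global alignment with affine gap penalties (gap of length L
#' costs `gapOpen + L * gapExtend`, the BLAST convention). Percent
#' identity is computed over aligned columns excluding terminal-gap
#' columns.
#'
#' @param a,b protein sequences (character or `AAString`).
#' @param matrix substitution matrix (default [amdScoringMatrix()]).
#' @param gapOpen,gapExtend affine gap penalties (defaults 11 and 1, the
#'   BLAST protein defaults).
#' @return an [AlignmentResult-class].
#' @export
globalAlign <- function(a, b, matrix = amdScoringMatrix(),
                        gapOpen = 11, gapExtend = 1) {
  a <- .as_aa_string(a); b <- .as_aa_string(b)
  if (length(a) == 0L || length(b) == 0L)
    stop("cannot align empty sequences")
  pa <- Biostrings::pairwiseAlignment(a, b, substitutionMatrix = matrix,
                                      gapOpening = gapOpen,
                                      gapExtension = gapExtend,
                                      type = "global")
  .alignment_result(pa, "global")
}

#' Local (Smith-Waterman) pairwise alignment
#'
#' Optimal local alignment with affine gaps; the empty alignment with
#' score 0 is returned when no positive-scoring segment pair exists.
#'
#' @inheritParams globalAlign
#' @return an [AlignmentResult-class].
#' @export
localAlign <- function(a, b, matrix = amdScoringMatrix(),
                       gapOpen = 11, gapExtend = 1) {
  a <- .as_aa_string(a); b <- .as_aa_string(b)
  if (length(a) == 0L || length(b) == 0L)
    stop("cannot align empty sequences")
  pa <- Biostrings::pairwiseAlignment(a, b, substitutionMatrix = matrix,
                                      gapOpening = gapOpen,
                                      gapExtension = gapExtend,
                                      type = "local")
  if (Biostrings::score(pa) <= 0) {
    return(new("AlignmentResult", alignedA = "", alignedB = "", score = 0,
               identities = 0L, alignedColumns = 0L, percentIdentity = 0,
               mode = "local"))
  }
  .alignment_result(pa, "local")
}

#' Karlin-Altschul E-value
#'
#' `E = K * m * n * exp(-lambda * S)` for a gapped alignment score S in a
#' search space of query length m and subject length n. Defaults are the
#' standard gapped BLOSUM62 parameters (gap open 11 / extend 1).
#'
#' @param score alignment score.
#' @param m,n query and subject lengths.
#' @param lambda,K Karlin-Altschul parameters (defaults 0.267 and 0.041).
#' @return the expected number of chance hits at or above `score`.
#' @export
karlinAltschulEvalue <- function(score, m, n, lambda = 0.267, K = 0.041) {
  stopifnot(lambda > 0, K > 0)
  K * m * n * exp(-lambda * score)
}

#' Identity/E-value pre-filter
#'
#' Emulates the protein BLAST screen used to shortlist AMDase candidates:
#' a candidate passes when its local alignment to the reference has an
#' E-value of at most `eMax` and a percent identity of at least `idMin`
#' (both thresholds inclusive; defaults 1e-44 and 43).
#'
#' @param candidate,reference protein sequences.
#' @param eMax maximum E-value (default 1e-44).
#' @param idMin minimum percent identity (default 43).
#' @param matrix,gapOpen,gapExtend,lambda,K alignment and E-value
#'   parameters, see [globalAlign()] and [karlinAltschulEvalue()].
#' @details The E-value is computed from the optimal local alignment
#'   score. Percent identity is taken from the global alignment with
#'   terminal-gap columns excluded from the denominator — the
#'   deterministic analogue of a BLAST local-hit identity that cannot be
#'   inflated by a short high-identity segment.
#' @return a list with elements `pass`, `percentIdentity`, `evalue`,
#'   `score` and `reason` (character vector naming the failed tests,
#'   empty on pass).
#' @export
prefilterCandidate <- function(candidate, reference, eMax = 1e-44, idMin = 43,
                               matrix = amdScoringMatrix(),
                               gapOpen = 11, gapExtend = 1,
                               lambda = 0.267, K = 0.041) {
  cand <- .as_aa_string(candidate); ref <- .as_aa_string(reference)
  loc <- localAlign(cand, ref, matrix, gapOpen, gapExtend)
  glob <- globalAlign(cand, ref, matrix, gapOpen, gapExtend)
  ev <- karlinAltschulEvalue(loc@score, length(cand), length(ref), lambda, K)
  reason <- character(0)
  if (ev > eMax) reason <- c(reason, "evalue")
  if (glob@percentIdentity < idMin) reason <- c(reason, "identity")
  list(pass = length(reason) == 0L,
       percentIdentity = glob@percentIdentity,
       evalue = ev, score = loc@score, reason = reason)
}

#' Pairwise identity distance matrix
#'
#' Computes `1 - fractional identity` for every sequence pair from global
#' alignments; the input to neighbor joining.
#'
#' @param seqs an `AAStringSet` (or named character vector).
#' @inheritParams globalAlign
#' @return a symmetric numeric matrix with zero diagonal, values in
#'   \[0, 1\], dimnames from the sequence names.
#' @export
identityDistanceMatrix <- function(seqs, matrix = amdScoringMatrix(),
                                   gapOpen = 11, gapExtend = 1) {
  if (!is(seqs, "AAStringSet")) seqs <- Biostrings::AAStringSet(toupper(seqs))
  n <- length(seqs)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        aln <- globalAlign(seqs[[i]], seqs[[j]], matrix, gapOpen, gapExtend)
        frac <- if (aln@alignedColumns > 0L) aln@identities / aln@alignedColumns else 0
        d[i, j] <- d[j, i] <- 1 - frac
      }
    }
  }
  d
}

setMethod("show", "AlignmentResult", function(object) {
  cat(sprintf("%s AlignmentResult: score %.1f, %d/%d identical (%.1f%%)\n",
              object@mode, object@score, object@identities,
              object@alignedColumns, object@percentIdentity))
  if (nchar(object@alignedA) <= 60L) {
    cat(" ", object@alignedA, "\n ", object@alignedB, "\n")
  }
})
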