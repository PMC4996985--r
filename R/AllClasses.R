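NULL

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
AA_ALPHABET_X <- c(AA20, "X")

#' MotifRuleset: the reference-anchored screening rules
#'
#' Bundles the twelve catalytic criteria and the six degenerate sequence
#' patterns that define the AMDase screen. All coordinates are 1-based
#' positions on the configured reference (by default the numbering of the
#' Bordetella bronchiseptica KU1201 enzyme). The stock ruleset is loaded
#' with [amdaseRuleset()]; both tables ship as editable TSV files under
#' `inst/extdata` so that annotation drift can be accommodated without a
#' code change.
#'
#' @slot criteria data.frame with columns index, kind, positions (list of
#'   integer vectors), residues (list of character vectors),
#'   strict_positions (list of integer vectors) and note.
#' @slot patterns data.frame with columns index, pattern, start, end,
#'   starred (list of integer vectors) and note. Pattern strings use `x`
#'   as a one-residue wildcard.
#' @exportClass MotifRuleset
setClass("MotifRuleset",
         representation(criteria = "data.frame", patterns = "data.frame"))

setValidity("MotifRuleset", function(object) {
  msg <- character()
  if (nrow(object@criteria) != 12L)
    msg <- c(msg, sprintf("criteria table must have exactly 12 rows, has %d",
                          nrow(object@criteria)))
  if (nrow(object@patterns) != 6L)
    msg <- c(msg, sprintf("pattern table must have exactly 6 rows, has %d",
                          nrow(object@patterns)))
  if (nrow(object@patterns)) {
    plen <- nchar(object@patterns$pattern)
    span <- object@patterns$end - object@patterns$start + 1L
    if (any(plen != span))
      msg <- c(msg, "pattern length must equal its reference span")
    crit_pos <- unlist(object@criteria$positions)
    starred <- unlist(object@patterns$starred)
    if (!all(starred %in% crit_pos))
      msg <- c(msg, "every starred pattern position must appear among the criteria positions")
  }
  if (length(msg)) msg else TRUE
})

#' NeighborhoodRecord: the gene context around an amd gene
#'
#' Holds the focal amd gene plus up to `windowGenes` annotated features on
#' each side, ordered by start coordinate (1-based, inclusive; GFF3
#' convention). Product annotation strings are carried verbatim and later
#' matched against the transporter keyword ruleset by [detectFamily()].
#'
#' @slot focalLocus locus tag of the amd gene.
#' @slot features GRanges with metadata columns `locus_tag` and `product`.
#' @slot windowGenes maximum number of genes kept on each side.
#' @exportClass NeighborhoodRecord
setClass("NeighborhoodRecord",
         representation(focalLocus = "character",
                        features = "GRanges",
                        windowGenes = "integer"))

setValidity("NeighborhoodRecord", function(object) {
  msg <- character()
  lt <- object@features$locus_tag
  if (!object@focalLocus %in% lt)
    msg <- c(msg, "focal locus must be present among the features")
  if (is.unsorted(GenomicRanges::start(object@features)))
    msg <- c(msg, "features must be sorted by start coordinate")
  if (object@windowGenes <= 0L)
    msg <- c(msg, "windowGenes must be positive")
  if (length(msg)) msg else TRUE
})

#' AlignmentResult: a scored pairwise alignment
#'
#' @slot alignedA,alignedB equal-length gapped strings.
#' @slot score optimal alignment score (affine gap penalties).
#' @slot identities number of identical aligned residue pairs.
#' @slot alignedColumns denominator used for percent identity. For global
#'   alignments this excludes terminal-gap columns, the closest
#'   deterministic analogue of a local-hit identity.
#' @slot percentIdentity 100 * identities / alignedColumns.
#' @slot mode "global" or "local".
#' @exportClass AlignmentResult
setClass("AlignmentResult",
         representation(alignedA = "character", alignedB = "character",
                        score = "numeric", identities = "integer",
                        alignedColumns = "integer",
                        percentIdentity = "numeric", mode = "character"))

setValidity("AlignmentResult", function(object) {
  msg <- character()
  if (nchar(object@alignedA) != nchar(object@alignedB))
    msg <- c(msg, "aligned strings must have equal length")
  if (object@identities > object@alignedColumns)
    msg <- c(msg, "identities cannot exceed aligned columns")
  if (length(msg)) msg else TRUE
})

#' ProfileHMM: a match/insert/delete profile hidden Markov model
#'
#' A Durbin-style profile HMM with one match (M), insert (I) and delete (D)
#' state per consensus column, built from a multiple alignment by
#' [buildProfileHMM()] and scored in log-odds bits against a background
#' residue distribution by [hmmViterbi()] / [hmmForward()].
#'
#' @slot nMatch number of match states (consensus columns).
#' @slot matchEmis nMatch x 20 matrix of match emission probabilities.
#' @slot insEmis (nMatch + 1) x 20 matrix of insert emission probabilities;
#'   row k is the insert state between match columns k-1 and k (row 1 is
#'   the N-terminal insert state).
#' @slot trans (nMatch + 1) x 3 x 3 array of transition probabilities;
#'   `trans[k, from, to]` is the probability of moving from state `from`
#'   (M/I/D) at column k-1 to state `to` at column k (to = "I" stays at
#'   column k-1; at k = nMatch + 1, "M" denotes the end state and "D" is
#'   disallowed).
#' @slot background length-20 background distribution.
#' @exportClass ProfileHMM
setClass("ProfileHMM",
         representation(nMatch = "integer", matchEmis = "matrix",
                        insEmis = "matrix", trans = "array",
                        background = "numeric"))

setValidity("ProfileHMM", function(object) {
  msg <- character()
  tol <- 1e-9
  if (object@nMatch < 1L) msg <- c(msg, "model needs at least one match state")
  bad_row <- function(m) any(abs(rowSums(m) - 1) > tol)
  if (bad_row(object@matchEmis)) msg <- c(msg, "match emissions must sum to 1")
  if (bad_row(object@insEmis)) msg <- c(msg, "insert emissions must sum to 1")
  if (abs(sum(object@background) - 1) > tol)
    msg <- c(msg, "background must sum to 1")
  for (k in seq_len(dim(object@trans)[1])) {
    for (f in c("M", "I", "D")) {
      if (k == 1L && f == "D") next       # no delete state before column 1
      s <- sum(object@trans[k, f, ])
      if (abs(s - 1) > tol)
        msg <- c(msg, sprintf("transitions out of %s at boundary %d sum to %g", f, k, s))
    }
  }
  if (length(msg)) msg else TRUE
})

#' ScreenVerdict: the full per-candidate screening report
#'
#' Records every stage of the screen: the E-value/identity pre-filter, the
#' twelve-criterion report with racemase discrimination, the six pattern
#' hits, an optional profile-HMM bit score, and the final call.
#'
#' @slot id candidate identifier.
#' @slot prefilter list with elements pass, percentIdentity, evalue, score,
#'   reason.
#' @slot criteria data.frame with one row per criterion (index, status,
#'   observed, candidatePositions).
#' @slot nPass number of criteria scored identical or similar.
#' @slot racemaseFlag TRUE when Cys is observed at reference position 74.
#' @slot patterns data.frame with one row per pattern (index, hit,
#'   candidateStart, matched).
#' @slot hmmBits forward bit score, or NA when no model was supplied.
#' @slot call one of "amdase_candidate", "racemase_like", "reject".
#' @slot reason short explanation for rejected candidates.
#' @exportClass ScreenVerdict
setClass("ScreenVerdict",
         representation(id = "character", prefilter = "list",
                        criteria = "data.frame", nPass = "integer",
                        racemaseFlag = "logical", patterns = "data.frame",
                        hmmBits = "numeric", call = "character",
                        reason = "character"))

setValidity("ScreenVerdict", function(object) {
  msg <- character()
  if (!object@call %in% c("amdase_candidate", "racemase_like", "reject"))
    msg <- c(msg, "unknown final call")
  if (nrow(object@criteria) && nrow(object@criteria) != 12L)
    msg <- c(msg, "criterion report must have 12 rows")
  if (object@nPass > 12L) msg <- c(msg, "nPass cannot exceed 12")
  if (length(msg)) msg else TRUE
})
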