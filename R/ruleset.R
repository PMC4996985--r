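.parse_positions <- function(s) {
  s <- trimws(s)
  if (!nzchar(s)) return(integer(0))
  if (grepl("-", s, fixed = TRUE)) {
    ab <- as.integer(strsplit(s, "-", fixed = TRUE)[[1L]])
    return(ab[1L]:ab[2L])
  }
  as.integer(strsplit(s, ",", fixed = TRUE)[[1L]])
}

#' Load a motif ruleset from TSV files
#'
#' Reads the criterion and pattern tables that define the screen. The
#' criterion table has columns index, kind (single_residue / residue_pair
#' / octamer_motif), positions (`p`, `p,q` or `a-b`), residues,
#' strict_positions and note; the pattern table has columns index,
#' pattern (with `x` wildcards), start, end, starred and note.
#'
#' @param criteriaPath,patternsPath TSV paths.
#' @return a [MotifRuleset-class].
#' @seealso [amdaseRuleset()] for the packaged ruleset.
#' @export
readRuleset <- function(criteriaPath, patternsPath) {
  ct <- utils::read.delim(criteriaPath, stringsAsFactors = FALSE,
                          na.strings = NULL)
  pt <- utils::read.delim(patternsPath, stringsAsFactors = FALSE,
                          na.strings = NULL)
  crit <- data.frame(index = as.integer(ct$index), kind = ct$kind,
                     note = ct$note, stringsAsFactors = FALSE)
  crit$positions <- lapply(ct$positions, .parse_positions)
  crit$residues <- lapply(seq_len(nrow(ct)), function(i) {
    r <- ct$residues[i]
    if (ct$kind[i] == "octamer_motif") strsplit(r, "")[[1L]]
    else strsplit(r, ",", fixed = TRUE)[[1L]]
  })
  crit$strict_positions <- lapply(ct$strict_positions, .parse_positions)
  bad <- which(lengths(crit$positions) != lengths(crit$residues))
  if (length(bad))
    stop("criterion ", crit$index[bad[1L]], ": positions and residues differ in length")
  pat <- data.frame(index = as.integer(pt$index), pattern = pt$pattern,
                    start = as.integer(pt$start), end = as.integer(pt$end),
                    note = pt$note, stringsAsFactors = FALSE)
  pat$starred <- lapply(pt$starred, .parse_positions)
  new("MotifRuleset", criteria = crit, patterns = pat)
}

#' The packaged AMDase ruleset
#'
#' The twelve catalytic criteria and six degenerate sequence patterns of
#' the AMDase screen, anchored on the reference numbering: the large
#' binding pocket (P14, P15), the dioxyanion hole (T75, S76, Y126, G189),
#' the hydrophobic pocket (L40, V43, Y48, V156, M159), the
#' stereochemistry determinants Gly74 and the proton donor Cys188, and
#' the octamer motifs LMGTSLSF (72-79) and ILLSCGGL (184-191).
#'
#' @return a [MotifRuleset-class].
#' @export
amdaseRuleset <- function() {
  readRuleset(system.file("extdata", "amdase_v1_criteria.tsv",
                          package = "amdscreen", mustWork = TRUE),
              system.file("extdata", "amdase_v1_patterns.tsv",
                          package = "amdscreen", mustWork = TRUE))
}

#' @describeIn amdaseRuleset the criterion table of the packaged ruleset.
#' @export
criteriaTable <- function() amdaseRuleset()@criteria

#' @describeIn amdaseRuleset the pattern table of the packaged ruleset.
#' @export
patternTable <- function() amdaseRuleset()@patterns

setMethod("show", "MotifRuleset", function(object) {
  cat("MotifRuleset:", nrow(object@criteria), "criteria,",
      nrow(object@patterns), "patterns\n")
  for (i in seq_len(nrow(object@patterns))) {
    p <- object@patterns[i, ]
    cat(sprintf("  pattern %d: %s (%d-%d)\n", p$index, p$pattern, p$start, p$end))
  }
})
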