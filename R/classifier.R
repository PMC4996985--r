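#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (via ape) on a symmetric, zero-diagonal
#' distance matrix. Taxa are ordered lexicographically before
#' agglomeration so that the result is invariant to input order and ties
#' resolve deterministically. Negative branch-length estimates are
#' clamped to zero and flagged in the `clamped` attribute.
#'
#' @param d symmetric numeric matrix with dimnames (>= 3 taxa).
#' @return an `ape::phylo` tree (unrooted).
#' @export
njTree <- function(d) {
  if (!is.matrix(d) || is.null(rownames(d))) stop("need a named distance matrix")
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 taxa")
  if (!isSymmetric(unname(d))) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have a zero diagonal")
  ord <- order(rownames(d))
  tr <- ape::nj(stats::as.dist(d[ord, ord]))
  clamped <- tr$edge.length < 0
  tr$edge.length[clamped] <- 0
  attr(tr, "clamped") <- any(clamped)
  tr
}

#' Packaged transporter keyword ruleset
#'
#' Case-insensitive keywords matched against gene product annotations to
#' call the transporter/enzyme families seen around amd genes: TTT
#' (tripartite tricarboxylate transporters), TRAP transporters, ABC
#' transporters, MR/MLE (mandelate racemase / muconate lactonizing
#' enzyme) and transposases. Ships as an editable TSV.
#'
#' @return data.frame with columns family and keyword.
#' @export
familyKeywords <- function() {
  utils::read.delim(system.file("extdata", "family_keywords.tsv",
                                package = "amdscreen", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

#' Detect gene families in a neighborhood
#'
#' Scans the product strings of a gene neighborhood (excluding none) for
#' the family keywords, case-insensitively, and records the evidence.
#'
#' @param nb a [NeighborhoodRecord-class].
#' @param rules keyword table (default [familyKeywords()]).
#' @return a list with `families` (character vector; "none" when no
#'   keyword matches) and `evidence` (data.frame: family, locus_tag,
#'   keyword).
#' @export
detectFamily <- function(nb, rules = familyKeywords()) {
  prod <- nb@features$product
  lt <- nb@features$locus_tag
  ev <- list()
  for (i in seq_len(nrow(rules))) {
    hit <- grepl(rules$keyword[i], prod, ignore.case = TRUE, fixed = FALSE)
    if (any(hit))
      ev[[length(ev) + 1L]] <- data.frame(family = rules$family[i],
                                         locus_tag = lt[hit],
                                         keyword = rules$keyword[i],
                                         stringsAsFactors = FALSE)
  }
  if (length(ev)) {
    evidence <- do.call(rbind, ev)
    # one evidence row per (family, gene): keep the first matching keyword
    evidence <- evidence[!duplicated(evidence[c("family", "locus_tag")]), ]
    rownames(evidence) <- NULL
    list(families = unique(evidence$family), evidence = evidence)
  } else {
    list(families = "none",
         evidence = data.frame(family = character(0), locus_tag = character(0),
                               keyword = character(0)))
  }
}

#' The eight AMDase cluster labels
#'
#' Five clusters whose amd genes neighbor tripartite tricarboxylate
#' transporter genes, one ABC-transporter cluster and two TRAP
#' clusters.
#'
#' @return character vector of the eight labels.
#' @export
clusterLabels <- function() c("TTT-I", "TTT-II", "TTT-III", "TTT-IV", "TTT-V",
                              "ABC", "TRAP-I", "TRAP-II")

.coarse_family <- function(cluster) sub("-.*$", "", cluster)

#' Assign a candidate to an enzyme cluster
#'
#' Combines tree distance with neighborhood content: the candidate takes
#' the cluster of its nearest anchored leaf (patristic distance) whose
#' transporter family is compatible with the candidate's own
#' neighborhood. When the neighborhood family disagrees with every
#' anchor, the family wins for the coarse label and the subdivision is
#' reported unresolved. Confidence is reported as the distance to the
#' chosen anchor (no bootstrap).
#'
#' @param candidateId leaf label of the candidate in `tree`.
#' @param tree an `ape::phylo` containing candidate and anchors.
#' @param families character vector of transporter families detected in
#'   the candidate's neighborhood (from [detectFamily()]).
#' @param anchors data.frame with columns id, cluster mapping anchored
#'   leaves to their known cluster label (>= 1 per cluster in use).
#' @return a list with cluster, coarse, nearestAnchor, distance, note.
#' @export
assignCluster <- function(candidateId, tree, families, anchors) {
  if (nrow(anchors) == 0L) stop("no anchors supplied")
  if (!candidateId %in% tree$tip.label) stop("candidate not in tree: ", candidateId)
  missing_anchor <- setdiff(anchors$id, tree$tip.label)
  if (length(missing_anchor))
    stop("anchors not in tree: ", paste(missing_anchor, collapse = ", "))
  pd <- ape::cophenetic.phylo(tree)
  d <- pd[candidateId, anchors$id]
  fam <- intersect(families, c("TTT", "TRAP", "ABC"))
  compat <- if (length(fam)) .coarse_family(anchors$cluster) %in% fam
            else rep(TRUE, nrow(anchors))   # no transporter evidence: tree only
  note <- if (length(fam)) "" else "no neighborhood transporter evidence"
  if (any(compat)) {
    i <- which(compat)[which.min(d[compat])]
    list(cluster = anchors$cluster[i], coarse = .coarse_family(anchors$cluster[i]),
         nearestAnchor = anchors$id[i], distance = unname(d[i]), note = note)
  } else {
    i <- which.min(d)
    list(cluster = paste0(fam[1L], "-unresolved"), coarse = fam[1L],
         nearestAnchor = anchors$id[i], distance = unname(d[i]),
         note = "no compatible anchor; coarse label from neighborhood family")
  }
}

#' Summarize a strain metadata table
#'
#' Tabulates amd genes per taxonomic class, genera per class, strains
#' per genus and habitat percentages (rounded to whole percent).
#'
#' @param meta validated metadata data.frame ([readStrainMetadata()]).
#' @return a list with genesPerClass, generaPerClass, strainsPerGenus,
#'   habitatPct.
#' @export
summarizeStrains <- function(meta) {
  if (nrow(meta) == 0L) {
    return(list(genesPerClass = integer(0), generaPerClass = integer(0),
                strainsPerGenus = integer(0), habitatPct = numeric(0)))
  }
  genes <- table(meta$class)
  genera <- vapply(split(meta$genus, meta$class),
                   function(g) length(unique(g)), 0L)
  strains <- table(meta$genus)
  hab <- table(meta$habitat)
  # integer percentages by largest remainder, so they always sum to 100
  habPct <- .largest_remainder(as.numeric(hab), 100L)
  names(habPct) <- names(hab)
  list(genesPerClass = c(genes), generaPerClass = genera,
       strainsPerGenus = c(strains), habitatPct = habPct)
}

#' Compare gene GC content with the genome average
#'
#' amd genes tend to have a GC content above their genome's average;
#' this helper computes the comparison for one gene.
#'
#' @param geneSeq nucleotide sequence (character or `DNAString`) over
#'   A/C/G/T/N; N is ignored.
#' @param genomeGc genome-average GC fraction in \[0, 1\].
#' @return list with geneGc, delta (gene - genome) and higher.
#' @export
gcCompare <- function(geneSeq, genomeGc) {
  stopifnot(genomeGc >= 0, genomeGc <= 1)
  s <- strsplit(toupper(as.character(geneSeq)), "")[[1L]]
  bad <- setdiff(unique(s), c("A", "C", "G", "T", "N"))
  if (length(bad)) stop("illegal nucleotide '", bad[1L], "'")
  counted <- sum(s %in% c("A", "C", "G", "T"))
  if (counted == 0L) stop("no countable bases")
  gc <- sum(s %in% c("G", "C")) / counted
  list(geneGc = gc, delta = gc - genomeGc, higher = gc > genomeGc)
}
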