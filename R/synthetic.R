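# Synthetic AMDase family generator.
#
# The reference template below is written out independently of the ruleset
# TSVs on purpose: the generator and the screener must remain independent
# code paths so that agreement between generated ground truth and screen
# verdicts is a real check, not a tautology.

.ref_length <- 240L

.ref_template <- local({
  t <- rep(".", .ref_length)
  put <- function(t, start, s) { t[start:(start + nchar(s) - 1L)] <- strsplit(s, "")[[1L]]; t }
  t <- put(t, 10L, "GLIVPPAxGxVPxE")
  t <- put(t, 37L, "GLGLxxVxxxGY")
  t <- put(t, 66L, "GAxxVxLMGTSLSFYRG")
  t <- put(t, 119L, "RVAVxTAY")
  t <- put(t, 151L, "LxIxxVxxM")
  t <- put(t, 182L, "DA")
  t <- put(t, 184L, "ILLSCGGL")
  t
})

# positions whose residue is fixed by the motif tables; never mutated
.constrained_positions <- which(!(.ref_template %in% c(".", "x")))
.free_positions <- which(.ref_template %in% c(".", "x"))

# interior zones where indels may be placed without touching any motif span
.indel_zones <- c(92:115, 196:235)

#' Generate the synthetic reference sequence
#'
#' Builds a deterministic 240-residue sequence that satisfies every
#' criterion and pattern of the packaged ruleset at its printed
#' coordinate: LMGTSLSF occupies 72-79, ILLSCGGL occupies 184-191 (hence
#' Gly74 and Cys188), and all single-residue criteria hold.
#' Unconstrained positions are drawn uniformly from the 20 residues.
#'
#' The packaged reference is synthetic because the true B. bronchiseptica
#' KU1201 sequence is not part of the package; substitute the real
#' sequence (IMG locus tag Ga0077226_10648) for production screening —
#' all coordinates are defined against whichever reference is configured.
#'
#' @param seed RNG seed.
#' @return a length-1 named `AAStringSet`.
#' @export
makeReference <- function(seed = 1L) {
  set.seed(seed)
  res <- .ref_template
  res[.free_positions] <- sample(AA20, length(.free_positions), replace = TRUE)
  out <- Biostrings::AAStringSet(paste(res, collapse = ""))
  names(out) <- "amdase_ref_synthetic"
  out
}

.mutate_member <- function(res, mutationRate) {
  hit <- .free_positions[stats::runif(length(.free_positions)) < mutationRate]
  for (p in hit) res[p] <- sample(setdiff(AA20, res[p]), 1L)
  list(res = res, mutated = hit)
}

#' Generate a synthetic AMDase family
#'
#' Derives `nMembers` sequences from the reference by point mutations at
#' unconstrained positions and (optionally) one short indel per member
#' confined to inter-motif zones, so every member still satisfies all
#' criteria and patterns by construction. The multiple alignment is
#' produced by construction, not by re-alignment.
#'
#' @param nMembers family size (default 50).
#' @param mutationRate per-site substitution probability at unconstrained
#'   positions (default 0.15).
#' @param indelRate probability that a member carries one short indel
#'   (length 1-3; default 0.25).
#' @param seed RNG seed.
#' @param reference reference `AAStringSet` (default [makeReference()]
#'   with the same seed).
#' @return list with `sequences` (AAStringSet), `alignment` (named
#'   character vector of gapped strings including the reference) and
#'   `truth` (data.frame id, class, violations).
#' @export
makeFamily <- function(nMembers = 50L, mutationRate = 0.15, indelRate = 0.25,
                       seed = 1L, reference = makeReference(seed)) {
  stopifnot(mutationRate >= 0, mutationRate <= 1, indelRate >= 0, indelRate <= 1)
  refres <- strsplit(as.character(reference[[1L]]), "")[[1L]]
  stopifnot(length(refres) == .ref_length)
  set.seed(seed + 1L)
  members <- vector("list", nMembers)
  ids <- sprintf("amd_synth_%03d", seq_len(nMembers))
  for (i in seq_len(nMembers)) {
    mut <- .mutate_member(refres, mutationRate)
    res <- mut$res
    del <- integer(0); ins_at <- NA_integer_; ins_str <- ""
    if (stats::runif(1) < indelRate) {
      len <- sample(1:3, 1L)
      if (stats::runif(1) < 0.5) {
        zone <- .indel_zones[.indel_zones + len - 1L <= max(.indel_zones)]
        p <- sample(zone, 1L)
        del <- p:(p + len - 1L)
      } else {
        ins_at <- sample(.indel_zones, 1L)
        ins_str <- paste(sample(AA20, len, replace = TRUE), collapse = "")
      }
    }
    members[[i]] <- list(res = res, del = del, ins_at = ins_at, ins_str = ins_str)
  }
  # alignment by construction: base columns = reference coordinates,
  # plus one padded block per distinct insertion point
  ins_points <- sort(unique(stats::na.omit(vapply(members, `[[`, 0L, "ins_at"))))
  ins_width <- vapply(ins_points, function(p)
    max(nchar(vapply(members, function(m)
      if (!is.na(m$ins_at) && m$ins_at == p) m$ins_str else "", ""))), 0L)
  row_for <- function(res, del, ins_at, ins_str) {
    out <- character(0)
    for (j in seq_len(.ref_length)) {
      out <- c(out, if (j %in% del) "-" else res[j])
      w <- ins_width[match(j, ins_points)]
      if (!is.na(w)) {
        s <- if (!is.na(ins_at) && ins_at == j) ins_str else ""
        out <- c(out, strsplit(sprintf("%-*s", w, s), "")[[1L]])
      }
    }
    paste(gsub(" ", "-", out, fixed = TRUE), collapse = "")
  }
  aln <- c(amdase_ref_synthetic = row_for(refres, integer(0), NA_integer_, ""),
           stats::setNames(vapply(members, function(m)
             row_for(m$res, m$del, m$ins_at, m$ins_str), ""), ids))
  seqs <- Biostrings::AAStringSet(vapply(members, function(m) {
    out <- character(0)
    for (j in seq_len(.ref_length)) {
      if (!j %in% m$del) out <- c(out, m$res[j])
      if (!is.na(m$ins_at) && m$ins_at == j) out <- c(out, m$ins_str)
    }
    paste(out, collapse = "")
  }, ""))
  names(seqs) <- ids
  truth <- data.frame(id = ids, class = "amdase", violations = "",
                      stringsAsFactors = FALSE)
  list(sequences = seqs, alignment = aln, truth = truth)
}

#' Generate decoy sequences
#'
#' Racemase decoys are family members with the stereochemistry
#' determinant Gly74 replaced by Cys — the hallmark of the racemases of
#' the aspartate/glutamate racemase superfamily — leaving every other
#' criterion intact. Unrelated decoys are length-matched sequences drawn
#' from the uniform background composition.
#'
#' @param n number of decoys.
#' @param kind "racemase" or "unrelated".
#' @param seed RNG seed.
#' @param ... for racemase decoys, passed to [makeFamily()].
#' @return list with `sequences` and `truth`.
#' @export
makeDecoys <- function(n = 50L, kind = c("racemase", "unrelated"),
                       seed = 1L, ...) {
  kind <- match.arg(kind)
  if (kind == "racemase") {
    fam <- makeFamily(nMembers = n, seed = seed + 1000L, ...)
    seqs <- as.character(fam$sequences)
    # indel zones start beyond position 74, so sequence position 74 is
    # reference position 74 in every member
    substr(seqs, 74L, 74L) <- "C"
    ids <- sprintf("racemase_synth_%03d", seq_len(n))
    out <- Biostrings::AAStringSet(seqs)
    names(out) <- ids
    truth <- data.frame(id = ids, class = "racemase_decoy",
                        violations = "G74C", stringsAsFactors = FALSE)
  } else {
    set.seed(seed + 2000L)
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(AA20, .ref_length, replace = TRUE), collapse = ""), "")
    ids <- sprintf("unrelated_synth_%03d", seq_len(n))
    out <- Biostrings::AAStringSet(seqs)
    names(out) <- ids
    truth <- data.frame(id = ids, class = "unrelated", violations = "",
                        stringsAsFactors = FALSE)
  }
  list(sequences = out, truth = truth)
}

.archetype_flanks <- function(arch) {
  ttt_bug <- "tripartite tricarboxylate transporter substrate binding protein"
  switch(arch,
    "TTT-I" = list(left = c(ttt_bug),
                   right = c("hypothetical protein")),
    "TTT-II" = list(left = c("hypothetical protein", ttt_bug),
                    right = c("hypothetical protein")),
    "TTT-III" = list(left = c(ttt_bug, "hypothetical protein"),
                     right = c("transposase")),
    "TTT-IV" = list(left = c("tripartite tricarboxylate transporter subunit TctA",
                             "tripartite tricarboxylate transporter subunit TctB",
                             "tripartite tricarboxylate transporter subunit TctC"),
                    right = c("hypothetical protein")),
    "TTT-V" = list(left = c("hypothetical protein"),
                   right = c("tripartite tricarboxylate transporter subunit TctA",
                             "tripartite tricarboxylate transporter subunit TctB",
                             "tripartite tricarboxylate transporter subunit TctC")),
    "ABC" = list(left = c("ABC transporter permease",
                          "putative oxidoreductase",
                          "ABC transporter substrate-binding protein",
                          "ABC transporter ATP-binding protein"),
                 right = c("hypothetical protein")),
    "TRAP-I" = list(left = c("TRAP transporter large permease subunit DctM",
                             "TRAP transporter small permease subunit DctQ"),
                    right = c("TRAP transporter substrate-binding protein DctP")),
    "TRAP-II" = list(left = c("hypothetical protein"),
                     right = c("TRAP transporter large permease subunit DctM",
                               "TRAP transporter small permease subunit DctQ",
                               "TRAP transporter substrate-binding protein DctP")),
    stop("unknown archetype: ", arch))
}

#' Generate neighborhood feature files for the eight cluster archetypes
#'
#' Writes one GFF3 contig per archetype with the amd gene flanked by
#' features whose product strings match the archetype's transporter
#' family: TTT-I to TTT-III carry only the "orphan" periplasmic receptor
#' gene, TTT-IV/V carry all three TctA/B/C subunit genes, the ABC
#' archetype has a putative oxidoreductase ORF inserted between permease
#' and substrate-binding genes, and the TRAP archetypes carry
#' DctM/DctQ/DctP genes. A mandelate racemase / muconate lactonizing
#' enzyme (MR/MLE) gene is added to a `mrmleFraction` of the archetypes
#' (default 0.61).
#'
#' @param dir output directory (created if needed).
#' @param archetypes cluster labels (default all eight).
#' @param seed RNG seed.
#' @param mrmleFraction fraction of archetypes given an MR/MLE gene.
#' @return data.frame truth table: archetype, file, focal_locus,
#'   has_mrmle.
#' @export
makeNeighborhoods <- function(dir, archetypes = clusterLabels(), seed = 1L,
                              mrmleFraction = 0.61) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed + 3000L)
  n_mrmle <- round(mrmleFraction * length(archetypes))
  with_mrmle <- archetypes[sample(length(archetypes), n_mrmle)]
  out <- vector("list", length(archetypes))
  for (a in seq_along(archetypes)) {
    arch <- archetypes[a]
    fl <- .archetype_flanks(arch)
    left <- fl$left
    right <- fl$right
    if (arch %in% with_mrmle)
      right <- c("mandelate racemase/muconate lactonizing enzyme family protein", right)
    products <- c(left, "arylmalonate decarboxylase", right)
    tag_base <- gsub("-", "", arch)
    tags <- sprintf("%s_%04d", tag_base, seq_along(products))
    focal <- tags[length(left) + 1L]
    widths <- sample(600:1500, length(products), replace = TRUE)
    gaps <- sample(50:300, length(products), replace = TRUE)
    starts <- cumsum(c(1L, utils::head(widths + gaps, -1L)))
    gr <- GenomicRanges::GRanges(paste0("ctg_", tag_base),
                                 IRanges::IRanges(starts, starts + widths - 1L),
                                 strand = sample(c("+", "-"), length(products),
                                                 replace = TRUE))
    gr$locus_tag <- tags
    gr$product <- products
    f <- file.path(dir, paste0(tag_base, ".gff3"))
    writeNeighborhoodGff3(gr, f)
    out[[a]] <- data.frame(archetype = arch, file = f, focal_locus = focal,
                           has_mrmle = arch %in% with_mrmle,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

.largest_remainder <- function(weights, total) {
  raw <- weights / sum(weights) * total
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

.default_habitat_mix <- c(soil = 0.32, plant = 0.14, wastewater = 0.10,
                          ocean = 0.12, host = 0.10, air = 0.06,
                          "not specified" = 0.16)

#' Generate a synthetic strain metadata table
#'
#' Emulates a strain/locus-tag supplementary table. Defaults mirror the
#' reported marginals of the AMDase survey: 25 Alpha- / 34 Beta- / 4
#' Gamma-proteobacterial amd genes over 16 / 6 / 3 genera (with 23
#' Variovorax and 7 Alcaligenes strains), and a habitat mix dominated by
#' soil (32%) with 16% of strains lacking a stated isolation source.
#'
#' @param nPerClass named integer vector c(Alpha=, Beta=, Gamma=).
#' @param habitatMix named habitat weights (defaults above); allocated
#'   by largest remainder, deterministically.
#' @param seed RNG seed (used only for locus-tag numbering stability).
#' @param path optional TSV output path.
#' @return the metadata data.frame (written to `path` when given).
#' @export
makeMetadata <- function(nPerClass = c(Alpha = 25L, Beta = 34L, Gamma = 4L),
                         habitatMix = .default_habitat_mix, seed = 1L,
                         path = NULL) {
  genus_sizes <- list()
  if (nPerClass[["Alpha"]] > 0L) {
    n <- nPerClass[["Alpha"]]
    base <- c("Nitratireductor", "Polymorphum", "Chelativorans", "Devosia",
              "Cucumibacter", sprintf("Alphagenus%02d", 6:16))
    sizes <- .largest_remainder(rep(1, length(base)), n)
    genus_sizes$`Alpha-proteobacteria` <- stats::setNames(sizes, base)
  }
  if (nPerClass[["Beta"]] > 0L) {
    n <- nPerClass[["Beta"]]
    base <- c(Variovorax = 23, Alcaligenes = 7, Bordetella = 1,
              Achromobacter = 1, Azoarcus = 1, Pusillimonas = 1)
    genus_sizes$`Beta-proteobacteria` <- stats::setNames(
      .largest_remainder(base, n), names(base))
  }
  if (nPerClass[["Gamma"]] > 0L) {
    n <- nPerClass[["Gamma"]]
    base <- c(Pseudomonas = 2, Halomonas = 1, Marinobacter = 1)
    genus_sizes$`Gamma-proteobacteria` <- stats::setNames(
      .largest_remainder(base, n), names(base))
  }
  rows <- list()
  for (cl in names(genus_sizes)) {
    gs <- genus_sizes[[cl]]
    gs <- gs[gs > 0]
    rows[[cl]] <- data.frame(
      class = cl,
      genus = rep(names(gs), gs),
      strain_no = unlist(lapply(gs, seq_len), use.names = FALSE),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab$strain <- sprintf("%s sp. SYN%02d", tab$genus, tab$strain_no)
  total <- nrow(tab)
  hab_counts <- .largest_remainder(habitatMix, total)
  tab$habitat <- rep(names(habitatMix), hab_counts)
  tab$locus_tag <- sprintf("GaSYN%d_%04d", seed, seq_len(total))
  meta <- tab[, c("strain", "class", "genus", "habitat", "locus_tag")]
  rownames(meta) <- NULL
  if (!is.null(path)) writeStrainMetadata(meta, path)
  meta
}

#' Generate the eight-cluster classification benchmark
#'
#' For each cluster archetype, derives an anchor sequence from the
#' reference by a cluster-specific signature (12 substitutions at
#' unconstrained positions) and one test candidate as the anchor plus 3
#' further substitutions. Within-cluster distances are therefore far
#' smaller than between-cluster distances, and each candidate's
#' neighborhood file matches its cluster's transporter family.
#'
#' @param dir directory for the neighborhood GFF3 files.
#' @param seed RNG seed.
#' @param reference reference `AAStringSet`.
#' @return list with anchors (AAStringSet), anchorTable (id, cluster),
#'   candidates (AAStringSet), neighborhoods (truth table from
#'   [makeNeighborhoods()]), truth (candidate id, cluster).
#' @export
makeClusterBenchmark <- function(dir, seed = 1L, reference = makeReference(seed)) {
  refres <- strsplit(as.character(reference[[1L]]), "")[[1L]]
  labs <- clusterLabels()
  set.seed(seed + 4000L)
  anchors <- character(length(labs)); cands <- character(length(labs))
  for (i in seq_along(labs)) {
    sig <- sample(.free_positions, 12L)
    a <- refres
    for (p in sig) a[p] <- sample(setdiff(AA20, a[p]), 1L)
    extra <- sample(setdiff(.free_positions, sig), 3L)
    cnd <- a
    for (p in extra) cnd[p] <- sample(setdiff(AA20, cnd[p]), 1L)
    anchors[i] <- paste(a, collapse = "")
    cands[i] <- paste(cnd, collapse = "")
  }
  tag_base <- gsub("-", "", labs)
  anchorSet <- Biostrings::AAStringSet(anchors)
  names(anchorSet) <- paste0("anchor_", tag_base)
  candSet <- Biostrings::AAStringSet(cands)
  names(candSet) <- paste0("cand_", tag_base)
  nb <- makeNeighborhoods(dir, archetypes = labs, seed = seed)
  list(anchors = anchorSet,
       anchorTable = data.frame(id = names(anchorSet), cluster = labs,
                                stringsAsFactors = FALSE),
       candidates = candSet,
       neighborhoods = nb,
       truth = data.frame(id = names(candSet), cluster = labs,
                          stringsAsFactors = FALSE))
}

#' Write the full fixture set
#'
#' Generates everything the pipeline consumes: reference, family (FASTA +
#' aligned FASTA), racemase and unrelated decoys, the eight archetype
#' neighborhoods with anchor/candidate sequences, a metadata table, and
#' ground-truth tables.
#'
#' @param dir output directory.
#' @param seed RNG seed.
#' @param nFamily,nRacemase,nUnrelated set sizes.
#' @return (invisibly) a list of the generated objects and file paths.
#' @export
makeFixtures <- function(dir, seed = 1L, nFamily = 50L, nRacemase = 50L,
                         nUnrelated = 20L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- makeReference(seed)
  fam <- makeFamily(nMembers = nFamily, seed = seed, reference = ref)
  rac <- makeDecoys(nRacemase, "racemase", seed = seed, reference = ref)
  unr <- makeDecoys(nUnrelated, "unrelated", seed = seed)
  bench <- makeClusterBenchmark(file.path(dir, "neighborhoods"), seed = seed,
                                reference = ref)
  meta <- makeMetadata(seed = seed, path = file.path(dir, "metadata.tsv"))
  writeProteinFasta(ref, file.path(dir, "reference.faa"))
  writeProteinFasta(fam$sequences, file.path(dir, "family.faa"))
  writeProteinAlignment(fam$alignment, file.path(dir, "family.afa"))
  writeProteinFasta(rac$sequences, file.path(dir, "racemase_decoys.faa"))
  writeProteinFasta(unr$sequences, file.path(dir, "unrelated_decoys.faa"))
  writeProteinFasta(bench$anchors, file.path(dir, "anchors.faa"))
  writeProteinFasta(bench$candidates, file.path(dir, "cluster_candidates.faa"))
  utils::write.table(bench$anchorTable, file.path(dir, "anchors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- rbind(fam$truth, rac$truth, unr$truth)
  utils::write.table(truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(dir = dir, reference = ref, family = fam, racemase = rac,
                 unrelated = unr, benchmark = bench, metadata = meta,
                 truth = truth))
}
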