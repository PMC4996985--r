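test_that("neighbor joining recovers topologies and validates input", {
  d3 <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- njTree(d3)
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B", "C"))

  # additive matrix consistent with ((A,B),(C,D)): NJ must reproduce the
  # distances exactly and recover the split
  dd <- matrix(c(0, 3, 7, 8,
                 3, 0, 6, 7,
                 7, 6, 0, 5,
                 8, 7, 5, 0), 4, 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr4 <- njTree(dd)
  pd <- ape::cophenetic.phylo(tr4)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(unname(pd), unname(dd), tolerance = 1e-9)

  # input order invariance
  perm <- c(3, 1, 4, 2)
  tr4b <- njTree(dd[perm, perm])
  pdb <- ape::cophenetic.phylo(tr4b)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(pdb, pd, tolerance = 1e-9)

  expect_error(njTree(d3[1:2, 1:2]), "at least 3")
  bad <- d3; bad[1, 2] <- 9
  expect_error(njTree(bad), "symmetric")
})

make_nb <- function(products) {
  n <- length(products)
  gr <- GenomicRanges::GRanges("c", IRanges::IRanges(seq(1, by = 100, length.out = n),
                                                     width = 50), strand = "+")
  gr$locus_tag <- paste0("g", seq_len(n))
  gr$product <- products
  new("NeighborhoodRecord", focalLocus = "g1", features = gr,
      windowGenes = 10L)
}

test_that("family detection is keyword-driven, case-insensitive and evidence-backed", {
  nb <- make_nb(c("arylmalonate decarboxylase",
                  "TRIPARTITE TRICARBOXYLATE transporter substrate binding protein"))
  r <- detectFamily(nb)
  expect_equal(r$families, "TTT")
  expect_equal(r$evidence$locus_tag, "g2")

  nb2 <- make_nb(c("amd", "mandelate racemase/muconate lactonizing enzyme",
                   "TRAP transporter DctM"))
  r2 <- detectFamily(nb2)
  expect_setequal(r2$families, c("MRMLE", "TRAP"))

  nb3 <- make_nb(c("hypothetical protein", "hypothetical protein"))
  r3 <- detectFamily(nb3)
  expect_equal(r3$families, "none")
  expect_equal(nrow(r3$evidence), 0)
})

test_that("cluster assignment combines tree distance with neighborhood family", {
  b <- makeClusterBenchmark(withr::local_tempdir(), seed = 2)
  d <- identityDistanceMatrix(c(b$anchors, b$candidates))
  tr <- njTree(d)

  a1 <- assignCluster("cand_TTTI", tr, "TTT", b$anchorTable)
  expect_equal(a1$cluster, "TTT-I")
  expect_equal(a1$nearestAnchor, "anchor_TTTI")

  # incompatible neighborhood: family wins the coarse label
  only_trap <- b$anchorTable[b$anchorTable$cluster %in% c("TRAP-I", "TRAP-II"), ]
  a2 <- assignCluster("cand_ABC", tr, "ABC", only_trap)
  expect_equal(a2$coarse, "ABC")
  expect_match(a2$note, "no compatible anchor")

  # no transporter evidence at all: nearest anchor decides, with a note
  a3 <- assignCluster("cand_TRAPII", tr, "none", b$anchorTable)
  expect_equal(a3$cluster, "TRAP-II")
  expect_match(a3$note, "no neighborhood transporter evidence")

  expect_error(assignCluster("cand_ABC", tr, "ABC", b$anchorTable[0, ]), "no anchors")
})

test_that("all eight synthetic archetypes are recovered", {
  dir <- withr::local_tempdir()
  b <- makeClusterBenchmark(dir, seed = 1)
  d <- identityDistanceMatrix(c(b$anchors, b$candidates))
  tr <- njTree(d)
  got <- vapply(seq_len(nrow(b$truth)), function(i) {
    id <- b$truth$id[i]
    f <- file.path(dir, paste0(sub("^cand_", "", id), ".gff3"))
    nb <- readNeighborhood(f, "gff3", focalLocus = b$neighborhoods$focal_locus[
      b$neighborhoods$archetype == b$truth$cluster[i]])
    assignCluster(id, tr, detectFamily(nb)$families, b$anchorTable)$cluster
  }, "")
  expect_equal(got, b$truth$cluster)
})

test_that("strain summaries count classes, genera and habitats", {
  toy <- data.frame(strain = paste0("s", 1:4),
                    class = rep(c("Alpha-proteobacteria", "Beta-proteobacteria"), each = 2),
                    genus = c("Devosia", "Devosia", "Variovorax", "Alcaligenes"),
                    habitat = c("soil", "soil", "ocean", "soil"),
                    locus_tag = paste0("L", 1:4))
  s <- summarizeStrains(toy)
  expect_equal(unname(s$genesPerClass), c(2L, 2L))
  expect_equal(unname(s$generaPerClass), c(1L, 2L))
  expect_equal(s$habitatPct[["soil"]], 75)
  expect_equal(sum(s$habitatPct), 100)

  empty <- summarizeStrains(toy[0, ])
  expect_length(empty$genesPerClass, 0)

  one <- toy[1, ]; one$habitat <- "not specified"
  expect_equal(summarizeStrains(one)$habitatPct[["not specified"]], 100)
})

test_that("habitat percentages always sum to 100 within rounding", {
  set.seed(71)
  for (i in 1:10) {
    n <- sample(3:80, 1)
    tab <- data.frame(strain = paste0("s", 1:n),
                      class = sample(c("Alpha-proteobacteria", "Beta-proteobacteria",
                                       "Gamma-proteobacteria"), n, replace = TRUE),
                      genus = sample(letters[1:5], n, replace = TRUE),
                      habitat = sample(c("soil", "plant", "ocean", "air",
                                         "not specified"), n, replace = TRUE),
                      locus_tag = paste0("L", 1:n))
    s <- summarizeStrains(tab)
    expect_equal(sum(s$habitatPct), 100)
  }
})

test_that("GC comparison counts bases and flags elevated genes", {
  expect_equal(gcCompare("GGCC", 0.6)$geneGc, 1)
  expect_false(gcCompare("ATAT", 0.5)$higher)
  r <- gcCompare("ACGTN", 0.4)
  expect_equal(r$geneGc, 0.5)       # N is ignored
  expect_true(r$higher)
  expect_error(gcCompare("NNN", 0.5), "no countable bases")
  expect_error(gcCompare("ACGU", 0.5), "illegal")
})
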