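test_that("FASTA reading handles minimal, empty and lowercase records", {
  f <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">r1 desc", "MKT"), f)
  s <- readProteinFasta(f)
  expect_equal(names(s), "r1")
  expect_equal(as.character(s[[1]]), "MKT")
  expect_equal(S4Vectors::mcols(s)$description, "r1 desc")

  writeLines(character(0), f)
  expect_length(readProteinFasta(f), 0)

  writeLines(c(">r1", "mkt"), f)
  expect_equal(as.character(readProteinFasta(f)[[1]]), "MKT")
})

test_that("FASTA reading rejects malformed and illegal input", {
  f <- withr::local_tempfile(fileext = ".faa")
  writeLines(c("MKT", ">r1", "ACD"), f)
  expect_error(readProteinFasta(f), "line 1")
  writeLines(c(">r1", "MK1T"), f)
  expect_error(readProteinFasta(f), "'1'.*r1")
  writeLines(c(">r1", "MKOT"), f)   # O is not in the 20+X alphabet
  expect_error(readProteinFasta(f), "'O'")
})

test_that("FASTA round trip preserves ids, order and residues", {
  f <- withr::local_tempfile(fileext = ".faa")
  fam <- makeFamily(nMembers = 4, seed = 7)
  writeProteinFasta(fam$sequences, f)
  back <- readProteinFasta(f)
  expect_equal(names(back), names(fam$sequences))
  expect_equal(as.character(back), as.character(fam$sequences))
})

test_that("alignment reading normalizes gaps and validates shape", {
  f <- withr::local_tempfile(fileext = ".afa")
  writeLines(c(">s1", "AC-D", ">s2", "ACED"), f)
  aln <- readProteinAlignment(f, "afa")
  expect_equal(ncol(aln), 4)
  expect_equal(unname(as.character(aln)), c("AC-D", "ACED"))

  sto <- withr::local_tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0", "", "s1  A.C", "s2  AEC", "//"), sto)
  a2 <- readProteinAlignment(sto, "stockholm")
  expect_equal(unname(as.character(a2))[1], "A-C")

  writeLines(c(">s1", "ACD", ">s2", "ACED"), f)
  expect_error(readProteinAlignment(f, "afa"), "ragged.*s1")
})

test_that("de-gapped alignment members equal their source sequences", {
  fam <- makeFamily(nMembers = 8, seed = 3)
  degapped <- degapAlignment(fam$alignment[-1])   # first row is the reference
  expect_equal(as.character(degapped), as.character(fam$sequences))
  f <- withr::local_tempfile(fileext = ".afa")
  writeProteinAlignment(fam$alignment, f)
  back <- readProteinAlignment(f, "afa")
  expect_equal(unname(as.character(back)), unname(fam$alignment))
})

test_that("neighborhood windows are extracted, truncated and validated", {
  f <- withr::local_tempfile(fileext = ".tsv")
  tab <- data.frame(contig = "c1", start = c(1, 100, 200, 300, 400),
                    end = c(50, 150, 250, 350, 450), strand = "+",
                    locus_tag = paste0("g", 1:5),
                    product = c("a", "b", "amd", "d", "e"))
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  nb <- readNeighborhood(f, "tsv", "g3", windowGenes = 2)
  expect_length(nb@features, 5)
  expect_equal(nb@features$product[3], "amd")

  nb_edge <- readNeighborhood(f, "tsv", "g1", windowGenes = 10)
  expect_length(nb_edge@features, 5)   # truncated, not padded

  expect_error(readNeighborhood(f, "tsv", "missing"), "not found")
  tab2 <- rbind(tab, tab[3, ])
  write.table(tab2, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readNeighborhood(f, "tsv", "g3"), "ambiguous")
})

test_that("GFF3 neighborhoods round-trip through write and read", {
  gr <- GenomicRanges::GRanges("ctg", IRanges::IRanges(c(1, 100), c(50, 160)),
                               strand = c("+", "-"))
  gr$locus_tag <- c("L1", "L2")
  gr$product <- c("hypothetical protein", "arylmalonate decarboxylase")
  f <- withr::local_tempfile(fileext = ".gff3")
  writeNeighborhoodGff3(gr, f)
  nb <- readNeighborhood(f, "gff3", "L2", windowGenes = 5)
  expect_equal(nb@features$product, gr$product)
  expect_equal(GenomicRanges::start(nb@features), c(1, 100))
})

test_that("metadata tables are validated against the controlled vocabulary", {
  f <- withr::local_tempfile(fileext = ".tsv")
  tab <- data.frame(strain = c("s1", "s2"),
                    class = c("Alpha-proteobacteria", "Beta-proteobacteria"),
                    genus = c("Devosia", "Variovorax"),
                    habitat = c("soil", ""),
                    locus_tag = c("L1", "L2"))
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- readStrainMetadata(f)
  expect_equal(nrow(meta), 2)
  expect_equal(meta$habitat[2], "not specified")  # blank isolation source

  tab$locus_tag <- c("L1", "L1")
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readStrainMetadata(f), "duplicate")

  tab$locus_tag <- c("L1", "L2"); tab$class[1] <- "Firmicutes"
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readStrainMetadata(f), "vocabulary")

  write.table(tab[, -2], f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readStrainMetadata(f), "lacks columns")
})

test_that("metadata round trip reproduces the table", {
  f <- withr::local_tempfile(fileext = ".tsv")
  meta <- makeMetadata(seed = 5, path = f)
  back <- readStrainMetadata(f)
  expect_equal(back, meta)
})
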