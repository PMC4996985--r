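test_that("match-column rule and emissions follow the build contract", {
  h <- buildProfileHMM(c(a = "MKTAG", b = "MKTAG", c = "MKTAG"))
  expect_equal(h@nMatch, 5L)
  top <- colnames(h@matchEmis)[apply(h@matchEmis, 1, which.max)]
  expect_equal(top, c("M", "K", "T", "A", "G"))

  # an all-gap column can never be a match state
  h2 <- buildProfileHMM(c(a = "MK-AG", b = "MK-AG"))
  expect_equal(h2@nMatch, 4L)

  # gap fraction 0.5 is not < 0.5: column 2 becomes an insert column
  h3 <- buildProfileHMM(c(a = "AC", b = "A-"))
  expect_equal(h3@nMatch, 1L)

  expect_error(buildProfileHMM(c(a = "ACD")), "fewer than 2")
  expect_s4_class(buildProfileHMM(c(a = "ACD"), force = TRUE), "ProfileHMM")
})

test_that("a single-sequence model scores its own sequence in closed form", {
  s <- "MKTAG"
  h <- buildProfileHMM(stats::setNames(s, "only"), force = TRUE)
  L <- nchar(s)
  # emissions: (1 + 1/20) / (1 + 1); transitions: Laplace-smoothed counts,
  # M->M (2/4) at interior boundaries and M->End (2/3) at the last
  emis_odds <- log2(((1 + 1 / 20) / 2) / (1 / 20))
  expected <- L * emis_odds + L * log2(2 / 4) + log2(2 / 3)
  v <- hmmViterbi(h, s)
  expect_equal(v$bits, expected, tolerance = 1e-12)
  expect_equal(v$path, paste0("M", 1:L))
})

test_that("forward and Viterbi equal exhaustive path enumeration on tiny models", {
  set.seed(101)
  for (rep in 1:12) {
    L_target <- sample(2:4, 1)
    nmem <- sample(2:4, 1)
    cols <- sample(c("res", "res", "gapish"), L_target + sample(0:2, 1),
                   replace = TRUE)
    aln <- vapply(seq_len(nmem), function(m)
      paste(vapply(cols, function(tp) {
        if (tp == "res") sample(c("A", "C", "G", "T", "M", "K"), 1)
        else sample(c("-", "-", "A"), 1)
      }, ""), collapse = ""), "")
    names(aln) <- paste0("m", seq_len(nmem))
    h <- tryCatch(buildProfileHMM(aln), error = function(e) NULL)
    if (is.null(h) || h@nMatch > 4L) next
    for (j in 1:3) {
      s <- random_protein(sample(1:6, 1))
      expect_equal(hmmForward(h, s), enum_hmm_bits(h, s, "forward"),
                   tolerance = 1e-9, info = paste(aln, collapse = "/"))
      expect_equal(hmmViterbi(h, s)$bits, enum_hmm_bits(h, s, "viterbi"),
                   tolerance = 1e-9, info = paste(aln, collapse = "/"))
    }
  }
})

test_that("forward dominates Viterbi and degenerate edges error", {
  fam <- makeFamily(nMembers = 5, seed = 2)
  h <- buildProfileHMM(fam$alignment)
  set.seed(7)
  for (i in 1:5) {
    s <- random_protein(sample(10:60, 1))
    expect_gte(hmmForward(h, s), hmmViterbi(h, s)$bits)
  }
  expect_error(hmmForward(h, ""), "empty")
  expect_error(hmmViterbi(h, ""), "empty")
})

test_that("training members outscore their shuffles and calibration yields hits", {
  fam <- makeFamily(nMembers = 8, seed = 6)
  h <- buildProfileHMM(fam$alignment)
  s <- as.character(fam$sequences[[1]])
  set.seed(9)
  shuf <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
  expect_gt(hmmViterbi(h, s)$bits, hmmViterbi(h, shuf)$bits)

  thr <- calibrateBitThreshold(h, fam$sequences)
  expect_true(hmmClassify(h, fam$sequences[[3]], thr)$hit)
  decoy <- makeDecoys(1, "unrelated", seed = 3)$sequences[[1]]
  expect_false(hmmClassify(h, decoy, thr)$hit)
  expect_true(hmmClassify(h, decoy, -Inf)$hit)   # -Inf threshold hits all
})

test_that("probability normalizations hold for random builds", {
  set.seed(55)
  for (rep in 1:10) {
    nmem <- sample(2:6, 1)
    len <- sample(5:15, 1)
    aln <- vapply(seq_len(nmem), function(m)
      paste(sample(c("A", "C", "D", "E", "-"), len, replace = TRUE),
            collapse = ""), "")
    names(aln) <- paste0("m", seq_len(nmem))
    h <- tryCatch(buildProfileHMM(aln), error = function(e) NULL)
    if (is.null(h)) next
    expect_true(validObject(h))   # validity enforces all normalizations
  }
})

test_that("logo statistics match their closed forms", {
  # pseudocount weight 0 concentrates each emission on the observed
  # residue: information content hits log2(20) under a uniform background
  h <- buildProfileHMM(c(a = "MKT", b = "MKT", c = "MKT"), pseudocountWeight = 0)
  logo <- hmmLogo(h, c(a = "MKT", b = "MKT", c = "MKT"))
  expect_equal(logo$IC_bits, rep(log2(20), 3), tolerance = 1e-12)
  expect_equal(logo$occupancy, rep(1, 3))
  expect_equal(logo$insert_prob, rep(0, 3))

  # match emission equal to background carries zero information
  h2 <- buildProfileHMM(c(a = "MKT", b = "MKT"))
  h2@matchEmis[1, ] <- h2@background
  logo2 <- hmmLogo(h2, c(a = "MKT", b = "MKT"))
  expect_equal(logo2$IC_bits[1], 0)
  expect_true(all(logo2$IC_bits >= 0))

  # inserted residues show up in insert probability and length
  aln3 <- c(a = "MKTA-G", b = "MKT-AG", c = "MKT--G")
  h3 <- buildProfileHMM(aln3)
  logo3 <- hmmLogo(h3, aln3)
  expect_equal(h3@nMatch, 4L)
  expect_equal(logo3$insert_prob[3], 2 / 3)
  expect_equal(logo3$insert_len[3], 1)
})

test_that("models survive a text serialization round trip", {
  fam <- makeFamily(nMembers = 4, seed = 12)
  h <- buildProfileHMM(fam$alignment)
  f <- withr::local_tempfile(fileext = ".hmm")
  writeProfileHMM(h, f)
  h2 <- readProfileHMM(f)
  expect_equal(h2@nMatch, h@nMatch)
  expect_equal(h2@matchEmis, h@matchEmis)
  expect_equal(h2@insEmis, h@insEmis)
  expect_equal(h2@trans, h@trans)
  s <- as.character(fam$sequences[[1]])
  expect_equal(hmmForward(h2, s), hmmForward(h, s))
})

test_that("adding a mutated training copy perturbs member scores only mildly", {
  fam <- makeFamily(nMembers = 6, seed = 20)
  h <- buildProfileHMM(fam$alignment)
  member <- as.character(fam$sequences[[2]])
  before <- hmmForward(h, member)
  aug <- fam$alignment
  set.seed(21)
  row <- strsplit(aug[[3]], "")[[1]]
  subst <- which(row != "-")[sample(sum(row != "-"), 10)]
  row[subst] <- sample(c("A", "W", "K", "E"), 10, replace = TRUE)
  aug <- c(aug, mutant = paste(row, collapse = ""))
  h2 <- buildProfileHMM(aug)
  after <- hmmForward(h2, member)
  expect_gt(after, before - 25)   # bounded degradation (regression bound)
})
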