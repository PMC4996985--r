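ref <- makeReference(1)
refstr <- as.character(ref[[1]])

mutate_at <- function(s, pos, res) {
  substr(s, pos, pos) <- res
  s
}

test_that("anchoring maps reference coordinates onto the candidate", {
  map <- anchorToReference(ref, ref)
  expect_equal(map, seq_len(nchar(refstr)))

  shifted <- paste0("M", refstr)
  map2 <- anchorToReference(shifted, ref)
  expect_equal(map2, seq_len(nchar(refstr)) + 1L)

  # internal deletion spanning the dioxyanion-hole motif: two reference
  # positions in the motif region lose their image, the rest stay mapped
  del <- paste0(substr(refstr, 1, 74), substr(refstr, 77, nchar(refstr)))
  map3 <- anchorToReference(del, ref)
  expect_equal(sum(is.na(map3)), 2)
  expect_true(all(which(is.na(map3)) %in% 72:80))
  mapped <- map3[!is.na(map3)]
  expect_true(all(diff(mapped) > 0))   # strictly increasing
  expect_error(anchorToReference("", ref), "empty")
})

test_that("criterion evaluation scores identity, similarity and the racemase flag", {
  map <- anchorToReference(ref, ref)
  ev <- evaluateCriteria(ref, map)
  expect_equal(nrow(ev$report), 12)
  expect_equal(ev$nPass, 12)
  expect_false(ev$racemaseFlag)

  rac <- mutate_at(refstr, 74, "C")
  ev2 <- evaluateCriteria(rac, anchorToReference(rac, ref))
  expect_equal(ev2$report$status[10], "fail")
  expect_true(ev2$racemaseFlag)

  y126f <- mutate_at(refstr, 126, "F")
  ev3 <- evaluateCriteria(y126f, anchorToReference(y126f, ref))
  expect_equal(ev3$report$status[3], "similar")   # BLOSUM62(Y, F) = 3

  # strict criterion: C188 -> S is a positive BLOSUM62 pair but must fail
  c188s <- mutate_at(refstr, 188, "S")
  ev4 <- evaluateCriteria(c188s, anchorToReference(c188s, ref))
  expect_equal(ev4$report$status[10], "fail")
})

test_that("criterion evaluation always returns exactly 12 verdicts", {
  set.seed(8)
  for (s in c(random_protein(240), random_protein(100))) {
    ev <- evaluateCriteria(s, anchorToReference(s, ref))
    expect_equal(nrow(ev$report), 12)
    expect_true(all(ev$report$status %in%
                      c("identical", "similar", "fail", "unaligned")))
  }
})

test_that("pattern matching honors wildcards, slack and locality", {
  map <- anchorToReference(ref, ref)
  hits <- matchPatterns(ref, map)
  expect_equal(sum(hits$hit), 6)
  expect_equal(hits$candidateStart, c(10L, 37L, 66L, 119L, 151L, 182L))

  # wildcard semantics: x positions may carry any residue
  rs <- amdaseRuleset()
  p5 <- rs@patterns[5, ]
  expect_equal(p5$pattern, "LxIxxVxxM")
  win <- "LAIQRVTAM"
  starred_off <- p5$starred[[1]] - p5$start + 1L
  expect_equal(brute_pattern_starts(strsplit(win, "")[[1]], p5$pattern,
                                    starred_off, amdScoringMatrix()), 1L)

  # deleting one octamer region breaks only its own pattern
  noct <- paste0(substr(refstr, 1, 71), substr(refstr, 80, nchar(refstr)))
  h2 <- matchPatterns(noct, anchorToReference(noct, ref))
  expect_false(h2$hit[3])
  expect_true(all(h2$hit[-3]))
})

test_that("pattern engine agrees with a brute-force window scan", {
  rs <- amdaseRuleset()
  mat <- amdScoringMatrix()
  set.seed(17)
  cases <- list(refstr,
                mutate_at(refstr, 126, "F"),
                paste0("MSTA", refstr),
                paste0(substr(refstr, 1, 74), substr(refstr, 77, nchar(refstr))))
  for (s in cases) {
    map <- anchorToReference(s, ref)
    hits <- matchPatterns(s, map)
    res <- strsplit(s, "")[[1]]
    for (i in seq_len(nrow(rs@patterns))) {
      p <- rs@patterns[i, ]
      starts <- brute_pattern_starts(res, p$pattern,
                                     p$starred[[1]] - p$start + 1L, mat)
      if (hits$hit[i]) {
        expect_true(hits$candidateStart[i] %in% starts)
      } else {
        # a miss means no admissible window within slack of the mapped span
        refpos <- p$start:p$end
        mapped <- map[refpos]
        if (any(!is.na(mapped))) {
          j <- which(!is.na(mapped))[1]
          s0 <- mapped[j] - (j - 1L)
          expect_false(any(abs(starts - s0) <= 5))
        }
      }
    }
  }
})

test_that("screening calls candidates, racemases and rejects correctly", {
  v <- screenCandidate(ref, ref, id = "ref")
  expect_s4_class(v, "ScreenVerdict")
  expect_equal(v@call, "amdase_candidate")

  rac <- mutate_at(refstr, 74, "C")
  v2 <- screenCandidate(rac, ref, id = "rac")
  expect_equal(v2@call, "racemase_like")
  expect_true(v2@racemaseFlag)

  # racemase flag alone is not enough: a second defect must reject
  racy <- mutate_at(rac, 188, "A")
  v3 <- screenCandidate(racy, ref, id = "racy")
  expect_equal(v3@call, "reject")

  set.seed(5)
  unrel <- random_protein(240)
  v4 <- screenCandidate(unrel, ref, id = "unrel")
  expect_equal(v4@call, "reject")
  expect_match(v4@reason, "^prefilter")
})

test_that("screening is deterministic and ignores mutations off the motifs", {
  v1 <- screenCandidate(ref, ref, id = "x")
  v2 <- screenCandidate(ref, ref, id = "x")
  expect_identical(serialize(v1, NULL), serialize(v2, NULL))

  # positions outside every criterion and pattern span never change
  # criterion verdicts
  spans <- c(10:23, 37:48, 66:82, 119:126, 151:159, 182:191)
  free <- setdiff(seq_len(nchar(refstr)), spans)
  set.seed(13)
  for (i in 1:10) {
    s <- refstr
    for (p in sample(free, 5)) s <- mutate_at(s, p, sample(c("A", "W", "K"), 1))
    ev <- evaluateCriteria(s, anchorToReference(s, ref))
    expect_equal(ev$nPass, 12)
  }
})
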