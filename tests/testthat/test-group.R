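edgeSet <- function(chanA, chanB, slope) {
  data.frame(chanA = chanA, chanB = chanB, slope = slope,
             r2 = 0.5, p = 0.01, stringsAsFactors = FALSE)
}

test_that("prevalence counts subjects per edge, order-invariantly", {
  ins <- list(S1 = edgeSet(c("C3", "F3"), c("C4", "F4"), c(1, 1)),
              S2 = edgeSet("C3", "C4", -1),
              S3 = edgeSet("P3", "P4", 1))
  prev <- prevalence(ins)
  expect_identical(prev$count[prev$chanA == "C3"], 2L)
  expect_equal(prev$fraction[prev$chanA == "C3"], 2 / 3)
  prev2 <- prevalence(rev(ins), nSubjects = 3)
  expect_equal(prev[order(prev$chanA), -match(c("subjects", "slopes"),
                                              names(prev))],
               prev2[order(prev2$chanA), -match(c("subjects", "slopes"),
                                                names(prev2))],
               ignore_attr = TRUE)

  # 10 of 21 subjects is "roughly 50%"
  ins21 <- c(lapply(1:10, function(i) edgeSet("C3", "C4", 1)),
             lapply(11:21, function(i) edgeSet("F3", "F4", 1)))
  p21 <- prevalence(ins21, 21)
  expect_equal(p21$fraction[p21$chanA == "C3"], 10 / 21, tolerance = 1e-12)
  expect_equal(round(p21$fraction[p21$chanA == "C3"], 3), 0.476)

  # disjoint subjects: every fraction 1/n
  expect_true(all(prevalence(list(edgeSet("a1", "b1", 1),
                                  edgeSet("a2", "b2", 1)))$fraction == 0.5))
})

test_that("the 40% rule needs 9 of 21 subjects and tracks consensus signs", {
  mk <- function(counts) {
    ins <- unlist(lapply(seq_along(counts), function(e) {
      lapply(seq_len(counts[e]), function(i)
        edgeSet(paste0("F", e * 2 - 1), paste0("F", e * 2), 1))
    }), recursive = FALSE)
    prevalence(ins, 21)
  }
  prev <- mk(c(9, 8))
  sh <- sharedEdges(prev, 0.40)
  expect_identical(nrow(sh), 1L)          # 9/21 >= 0.40 but 8/21 < 0.40
  expect_identical(sh$count, 9L)
  expect_identical(nrow(sharedEdges(prev, 1.0)), 0L)

  ins <- list(edgeSet("C3", "C4", 0.01), edgeSet("C3", "C4", 0.02),
              edgeSet("C3", "C4", -0.005))
  sh2 <- sharedEdges(prevalence(ins, 3), 0.4)
  expect_identical(sh2$consensusSign, 1)  # mean slope > 0
  tie <- list(edgeSet("C3", "C4", 0.01), edgeSet("C3", "C4", -0.01))
  expect_identical(sharedEdges(prevalence(tie, 2), 0.4)$consensusSign, 0)
})

test_that("slope tallies split shared edges by direction", {
  sh <- data.frame(chanA = paste0("a", 1:33), chanB = paste0("b", 1:33),
                   count = 9L, fraction = 9 / 21,
                   consensusSign = c(rep(1, 24), rep(-1, 9)),
                   meanSlope = c(rep(0.01, 24), rep(-0.01, 9)))
  expect_identical(slopeTally(sh),
                   c(positive = 24L, negative = 9L, tied = 0L))
  empty <- sh[0, ]
  expect_identical(slopeTally(empty),
                   c(positive = 0L, negative = 0L, tied = 0L))
})

test_that("topographic classes partition every edge set", {
  e <- data.frame(chanA = c("C3", "C3", "Fz", "C4", "O2"),
                  chanB = c("P3", "C4", "C3", "P4", "Fpz"))
  cls <- classifyEdges(e)$topography
  expect_identical(as.character(cls),
                   c("intra-left", "interhemispheric", "midline-involving",
                     "intra-right", "midline-involving"))
  expect_false(anyNA(cls))
  expect_error(classifyEdges(data.frame(chanA = "EMG-", chanB = "C3")),
               "classify")
})

test_that("unique node counts collapse shared endpoints", {
  expect_identical(uniqueNodes(data.frame(chanA = c("A1", "B1"),
                                          chanB = c("B1", "C1"))), 3L)
  expect_identical(uniqueNodes(data.frame(chanA = character(),
                                          chanB = character())), 0L)
})

test_that("GN averaging is edge-wise, linear, and grid-checked", {
  labs <- montageLabels(toyMontage(4))
  w1 <- matrix(0.2, 6, 5)
  w2 <- matrix(0.4, 6, 5)
  s1 <- pliStack(w1, labs, 0:4, "S01", "alpha")
  s2 <- pliStack(w2, labs, 0:4, "S02", "alpha")
  gn <- gnAverage(list(s1, s2))
  expect_equal(unname(pliWeights(gn)[1, 1]), 0.3)
  expect_identical(subjectId(gn), "GN")
  expect_equal(pliWeights(gnAverage(list(s1, s1))), pliWeights(s1))

  # linearity: scaling every subject scales the GN
  cs1 <- pliStack(w1 * 0.5, labs, 0:4, "S01", "alpha")
  cs2 <- pliStack(w2 * 0.5, labs, 0:4, "S02", "alpha")
  expect_equal(pliWeights(gnAverage(list(cs1, cs2))),
               pliWeights(gn) * 0.5)

  s3 <- pliStack(w2, labs, c(0:3, 5L), "S03", "alpha")
  expect_error(gnAverage(list(s1, s3)), "grids")
})

test_that("IN/GN overlap uses the GN denominator (Table 1 x Table 2 rule)", {
  et <- edgeTable(makeDefaultMontage())
  gnSet <- et[1:287, ]
  ins <- list(Smax = et[1:92, ],                    # 92 of the 287
              Szero = et[1800:1891, ])              # disjoint from GN
  ov <- inGnOverlap(ins, gnSet)
  expect_equal(unname(ov$perSubject["Smax"]), 100 * 92 / 287,
               tolerance = 1e-12)
  expect_equal(round(unname(ov$perSubject["Smax"]), 2), 32.06)
  expect_equal(unname(ov$perSubject["Szero"]), 0)
  expect_identical(ov$nGn, 287L)
  expect_identical(ov$sdType, "population")
  expect_true(ov$min <= ov$mean && ov$mean <= ov$max)

  # superset subject scores 100%
  full <- inGnOverlap(list(S = gnSet), gnSet)
  expect_equal(unname(full$perSubject["S"]), 100)

  expect_warning(ovE <- inGnOverlap(ins, gnSet[0, ]), "empty")
  expect_true(all(is.na(ovE$perSubject)))
})

test_that("overlap percentages times |GN|/100 are integer counts", {
  set.seed(61)
  et <- edgeTable(toyMontage(8))
  for (i in 1:20) {
    gnSet <- et[sample(nrow(et), sample(3:20, 1)), ]
    ins <- lapply(1:5, function(s) et[sample(nrow(et), sample(1:25, 1)), ])
    ov <- inGnOverlap(ins, gnSet)
    counts <- ov$perSubject * nrow(gnSet) / 100
    expect_lt(max(abs(counts - round(counts))), 1e-9)
  }
})
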