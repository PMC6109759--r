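test_that("permutation assignments are derangements and seeded", {
  # n = 2: the swap is the only derangement
  p2 <- permuteAssignments(2, nRounds = 5, seed = 1)
  expect_true(all(p2[, 1] == 2 & p2[, 2] == 1))

  p5 <- permuteAssignments(5, nRounds = 100, seed = 2)
  expect_false(any(p5 == col(p5)))

  expect_identical(permuteAssignments(6, 10, seed = 3),
                   permuteAssignments(6, 10, seed = 3))
  expect_error(permuteAssignments(1), "2 subjects")
})

test_that("paired equivalence test matches the closed-form and t.test oracles", {
  obs <- data.frame(subject = paste0("s", 1:4), network = "visual",
                    temporalPcc = c(0.7, 0.6, 0.8, 0.65))
  nullRec <- data.frame(subject = paste0("s", 1:4), network = "visual",
                        temporalPcc = c(0.95, 0.9, 0.97, 0.93))
  nd <- new("NullDistribution", records = nullRec,
            permutationMap = matrix(c(2L, 3L, 4L, 1L), 1), nRounds = 1L,
            seed = 1L)
  res <- equivalenceTest(obs, nd, "visual", "temporalPcc")

  d <- obs$temporalPcc - nullRec$temporalPcc
  tOracle <- mean(d) / (sd(d) / sqrt(4))
  expect_equal(res$tStat, tOracle, tolerance = 1e-12)
  tt <- t.test(obs$temporalPcc, nullRec$temporalPcc, paired = TRUE,
               alternative = "less")
  expect_equal(res$tStat, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res$pValue, tt$p.value, tolerance = 1e-12)
  expect_equal(res$dof, 3)
  expect_equal(res$verdict, "altered")

  # observed == null: t = 0, within equivalency
  same <- equivalenceTest(nullRec, nd, "visual", "temporalPcc")
  expect_equal(same$tStat, 0)
  expect_equal(same$verdict, "within_equivalency")

  # constant nonzero difference: capped t, altered when observed < null
  shifted <- nullRec
  shifted$temporalPcc <- nullRec$temporalPcc - 0.1
  capped <- equivalenceTest(shifted, nd, "visual", "temporalPcc")
  expect_equal(capped$tStat, -40)
  expect_equal(capped$verdict, "altered")

  # a similarity INCREASE is never "altered" even if consistent
  up <- nullRec
  up$temporalPcc <- nullRec$temporalPcc + 0.02
  inc <- equivalenceTest(up, nd, "visual", "temporalPcc")
  expect_equal(inc$verdict, "within_equivalency")

  expect_error(equivalenceTest(obs[1:2, ], nd, "visual", "temporalPcc"),
               "3 complete")
})

test_that("null records average across rounds before pairing", {
  obs <- data.frame(subject = paste0("s", 1:3), network = "dmn",
                    temporalPcc = c(0.8, 0.85, 0.9))
  nullRec <- data.frame(
    subject = rep(paste0("s", 1:3), 2), network = "dmn",
    temporalPcc = c(0.9, 0.95, 0.92, 0.7, 0.75, 0.88))
  nd <- new("NullDistribution", records = nullRec,
            permutationMap = matrix(c(2L, 3L, 1L, 3L, 1L, 2L), 2,
                                    byrow = TRUE),
            nRounds = 2L, seed = 1L)
  res <- equivalenceTest(obs, nd, "dmn", "temporalPcc")
  perSubjNull <- c(0.8, 0.85, 0.9)
  expect_equal(res$meanNull, mean(perSubjNull))
  expect_equal(res$tStat, 0)  # observed equals the per-subject null means
})

test_that("null construction is faithful bookkeeping on a small cohort", {
  sc <- tinyScene()
  co <- generateCohort(4, sc, masterSeed = 97)
  refs <- list(visual = co[[1]]$truth@templates[[1]]@spatialMap,
               dmn = co[[1]]$truth@templates[[2]]@spatialMap)
  subjects <- lapply(seq_along(co), function(i) {
    pp <- preprocessSeries(co[[i]]$series)
    k <- estimateModelOrder(co[[i]]$series)
    list(id = sprintf("s%d", i), preprocessed = pp,
         originalDecomposition = spatialICA(pp, k, seed = 100 + i),
         nComponents = k, icaSeed = 100L + i,
         schedules = co[[i]]$schedules, references = refs)
  })
  nd <- buildNull(subjects, nRounds = 1, seed = 11)
  expect_s4_class(nd, "NullDistribution")
  expect_equal(nrow(nd@records), 8)  # 4 subjects x 2 networks
  expect_true(all(nd@records$condition == "null"))
  ok <- !is.na(nd@records$temporalPcc)
  expect_true(all(abs(nd@records$temporalPcc[ok]) <= 1))
  expect_true(all(nd@records$dice[!is.na(nd@records$dice)] >= 0 &
                  nd@records$dice[!is.na(nd@records$dice)] <= 1))
  expect_false(any(nd@permutationMap == col(nd@permutationMap)))

  # a duplicated schedule violates the uniqueness guard
  subjects[[2]]$schedules <- subjects[[1]]$schedules
  expect_error(buildNull(subjects, 1, seed = 11), "unique")
})

test_that("null distributions reject permutations with fixed points", {
  rec <- data.frame(subject = "s1", network = "visual", temporalPcc = 0.9)
  expect_error(new("NullDistribution", records = rec,
                   permutationMap = matrix(c(1L, 2L), 1), nRounds = 1L,
                   seed = 1L),
               "derangement")
})
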