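test_that("identical rows give a zero statistic and p = 1", {
  res <- chiSquareTest(rbind(c(10, 20, 5), c(10, 20, 5)))
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p.value, 1, tolerance = 1e-12)
  expect_identical(res$df, 2L)
})

test_that("the printed MRI vs arthroscopy grade table shows no association", {
  gt <- readGradeTable(system.file("extdata", "grade_table.csv",
                                   package = "kneefusion"))
  expect_identical(unname(rowSums(counts(gt))), c(60, 60))
  res <- chiSquareTest(counts(gt))
  ref <- naiveChisq(counts(gt))                 # independent formula oracle
  expect_equal(res$statistic, ref$statistic, tolerance = 1e-10)
  expect_equal(res$statistic, 2.44, tolerance = 0.005)
  expect_identical(res$df, 3L)
  expect_equal(res$p.value, ref$p.value, tolerance = 1e-10)
  expect_gt(res$p.value, 0.05)
  expect_equal(res$p.value, 0.49, tolerance = 0.01)
})

test_that("chi-square matches the textbook formula on random tables", {
  set.seed(30)
  for (rep in 1:5) {
    m <- matrix(rpois(6, 20) + 1, 2, 3)
    res <- chiSquareTest(m); ref <- naiveChisq(m)
    expect_equal(res$statistic, ref$statistic, tolerance = 1e-10)
    expect_equal(res$p.value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("chi-square is symmetric under row swap and column permutation", {
  m <- rbind(c(12, 7, 21, 4), c(9, 15, 11, 8))
  base <- chiSquareTest(m)$statistic
  expect_equal(chiSquareTest(m[2:1, ])$statistic, base, tolerance = 1e-12)
  expect_equal(chiSquareTest(m[, c(3, 1, 4, 2)])$statistic, base,
               tolerance = 1e-12)
})

test_that("a zero expected count is rejected naming the cell", {
  expect_error(chiSquareTest(rbind(c(0, 5), c(0, 7))), "cell")
})

test_that("Yates correction is available but off by default", {
  m <- rbind(c(8, 12), c(15, 5))
  expect_equal(chiSquareTest(m)$statistic,
               unname(suppressWarnings(chisq.test(m, correct = FALSE))$statistic),
               tolerance = 1e-12)
  expect_lt(chiSquareTest(m, correct = TRUE)$statistic,
            chiSquareTest(m)$statistic)
})

test_that("diagnostic stats binarize grades with grade 0 as the negative class", {
  allPos <- diagnosticStats(rep("III", 4), rep("I", 4))
  expect_equal(allPos$sensitivity, 1)
  expect_equal(allPos$accuracy, 1)
  expect_true(is.na(allPos$specificity))
  disagree <- diagnosticStats(c("I", "0"), c("0", "I"))
  expect_equal(disagree$sensitivity, 0)
  expect_equal(disagree$specificity, 0)
  expect_error(diagnosticStats(c("IV"), c("0")), "invalid grade")
})

test_that("diagnostic stats equal loop-computed counts on synthetic pairs", {
  set.seed(31)
  grades <- c("0", "I", "II", "III")
  index <- sample(grades, 60, replace = TRUE)
  ref <- sample(grades, 60, replace = TRUE)
  got <- diagnosticStats(index, ref)
  cmRef <- naiveConfusion(as.integer(index != "0"), as.integer(ref != "0"))
  expect_equal(got$sensitivity, cmRef["TP"] / (cmRef["TP"] + cmRef["FN"]),
               ignore_attr = TRUE)
  expect_equal(got$specificity, cmRef["TN"] / (cmRef["TN"] + cmRef["FP"]),
               ignore_attr = TRUE)
  expect_equal(got$accuracy, (cmRef["TP"] + cmRef["TN"]) / 60, ignore_attr = TRUE)
})

test_that("positive rates reproduce the printed concomitant-injury proportions", {
  cc <- readConcomitantCounts(system.file("extdata", "concomitant_counts.csv",
                                          package = "kneefusion"))
  men <- cc[cc$category == "meniscus_tear", ]
  resMen <- positiveRates(men$acute_pos, men$acute_n, men$chronic_pos, men$chronic_n)
  expect_equal(resMen$acuteRate, 30 / 43, tolerance = 1e-12)
  expect_equal(100 * resMen$acuteRate, 69.77, tolerance = 0.01)
  bone <- cc[cc$category == "bone_contusion", ]
  resBone <- positiveRates(bone$acute_pos, bone$acute_n, bone$chronic_pos, bone$chronic_n)
  expect_equal(100 * resBone$chronicRate, 17.65, tolerance = 0.01)
  # equal proportions give p = 1
  expect_equal(positiveRates(5, 10, 10, 20)$p.value, 1, tolerance = 1e-12)
})

test_that("grade tables validate the equal-total invariant", {
  expect_error(gradeTable(rbind(c(1, 2, 3, 4), c(1, 2, 3, 5))), "row sums")
  expect_error(gradeTable(rbind(c(-1, 2, 3, 4), c(1, 2, 3, 2))), "nonnegative")
})
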