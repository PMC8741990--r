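test_that("the packaged cohort matches the published composition", {
  rec <- loadCohort()
  expect_identical(nrow(rec), 32L)
  expect_identical(as.integer(table(rec$histology)[c("ADN", "SQC", "LCC")]),
                   c(15L, 16L, 1L))
  expect_identical(sum(rec$volume_cm3 < 40), 28L)
  expect_true(all(rec$dose_mg > 0 & rec$dose_mg <= 40))
  expect_true(all(rec$n_injections %in% c(2, 4, 5)))
})

test_that("printed predictions reproduce the published accuracies", {
  cc <- concordance(loadCohort(), "printed")
  expect_identical(round(cc$overall), 72)            # 23 of 32
  expect_identical(unname(cc$by_histology["ADN"]), 80)       # 12 of 15
  expect_identical(unname(cc$by_histology["SQC"]), 62.5)     # 10 of 16
  expect_identical(unname(cc$by_histology["LCC"]), 100)
})

test_that("printed confusion tallies and percentages match the published table", {
  conf <- confusionSummary(loadCohort(), "printed")
  expect_identical(confusionCounts(conf),
                   c(tp = 20L, tn = 3L, fn = 4L, fp = 5L))
  expect_equal(round(confusionPct(conf), 1),
               c(tp = 62.5, tn = 9.4, fn = 12.5, fp = 15.6))
  expect_equal(accuracy(conf), 100 * 23 / 32, tolerance = 1e-12)
})

test_that("clinical response rates and volume statistics re-tabulate exactly", {
  rec <- loadCohort()
  by <- split(rec$outcome, rec$histology)
  expect_equal(100 * mean(by$ADN), 80)
  expect_equal(100 * mean(by$SQC), 68.75)            # printed truncated: 68.7
  expect_equal(trunc(1000 * mean(by$SQC)) / 10, 68.7)
  expect_equal(100 * mean(by$LCC), 100)
  # the outcome column sums to 24 responders (the text reports 25)
  expect_identical(sum(rec$outcome), 24L)
  # the 13 adenocarcinomas other than the two giant false negatives
  adn <- rec[rec$histology == "ADN", ]
  rest <- adn$volume_cm3[!adn$patient_id %in% c("ADN-1", "ADN-15")]
  expect_identical(length(rest), 13L)
  expect_equal(round(mean(rest), 1), 14.1)
  expect_equal(round(sd(rest), 1), 19.2)
})

test_that("confusion is order invariant and exact agreement zeroes FP/FN", {
  rec <- loadCohort()
  perm <- rec[rev(seq_len(nrow(rec))), ]
  expect_identical(confusionCounts(confusionSummary(perm)),
                   confusionCounts(confusionSummary(rec)))
  agree <- rec
  agree$prediction_printed <- agree$outcome
  conf <- confusionSummary(agree)
  expect_identical(conf@fp, 0L)
  expect_identical(conf@fn, 0L)
})

test_that("schema violations are reported with row and column", {
  bad <- loadCohort()
  bad$dose_mg[3] <- 55
  path <- tempfile(fileext = ".csv")
  write.csv(bad, path, row.names = FALSE)
  expect_error(loadCohort(path), "row 3, column 'dose_mg'")
  bad2 <- loadCohort()[, -2]
  write.csv(bad2, path, row.names = FALSE)
  expect_error(loadCohort(path), "header")
  unlink(path)
})

test_that("exact rank test enumerates the two-sided null", {
  # the two giant adenocarcinomas against the remaining thirteen
  rec <- loadCohort()
  adn <- rec$volume_cm3[rec$histology == "ADN"]
  big <- adn[adn > 100]
  expect_equal(exactRankTest(big, setdiff(adn, big)), 2 / 105,
               tolerance = 1e-12)
  expect_equal(round(2 / 105, 3), 0.019)
  # tiny enumerations, worked out by hand
  expect_equal(exactRankTest(1, 2), 1)
  expect_equal(exactRankTest(c(1, 2), c(3, 4)), 2 / 6, tolerance = 1e-12)
  # independent oracle: the exact Wilcoxon distribution
  set.seed(17)
  a <- rnorm(4); b <- rnorm(6) + 0.5
  expect_equal(exactRankTest(a, b),
               wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-12)
  expect_error(exactRankTest(c(1, 2), c(2, 3)), "ties")
  expect_error(exactRankTest(rnorm(13), rnorm(13)), "25")
})

test_that("cohort replay annotates saturating and vanishing-dose records correctly", {
  rec <- loadCohort()
  sub <- rec[rec$patient_id %in% c("ADN-2", "ADN-11", "SQC-10"), ]
  out <- regeneratePredictions(sub, n_replicates = 10, seed = 1)
  expect_identical(out$prediction_model, c(1L, 1L, 1L))
  expect_true(all(out$v_response_model > 99))
  tiny <- sub
  tiny$dose_mg <- 0.001
  out2 <- regeneratePredictions(tiny, n_replicates = 10, seed = 1)
  expect_identical(out2$prediction_model, c(0L, 0L, 0L))
  # determinism of the full pipeline given the master seed
  expect_identical(regeneratePredictions(sub, n_replicates = 5, seed = 2),
                   regeneratePredictions(sub, n_replicates = 5, seed = 2))
})

test_that("an identity perturbation reproduces the baseline tally exactly", {
  rec <- loadCohort()[c(2, 3, 4, 11, 12, 13, 17, 25, 28, 30, 32), ]  # small tumors
  tab <- sensitivityAnalysis(rec, factors = 1, n_replicates = 5, seed = 1)
  base <- tab[tab$parameter == "baseline", c("tp", "tn", "fn", "fp")]
  for (p in c("D", "k_i", "k_f", "mu")) {
    row <- tab[tab$parameter == p, c("tp", "tn", "fn", "fp")]
    expect_identical(unname(unlist(row)), unname(unlist(base)))
  }
})

test_that("lowering the median IC50 tenfold shifts predictions toward positives", {
  rec <- loadCohort()
  tab <- sensitivityAnalysis(rec, factors = 0.1, n_replicates = 10, seed = 1)
  base <- tab[tab$parameter == "baseline", ]
  mu01 <- tab[tab$parameter == "mu", ]
  expect_lt(mu01$fn, base$fn)
  expect_gte(mu01$tp + mu01$fp, base$tp + base$fp)
})
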