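test_that("AIC arithmetic and weights behave as published tables require", {
  expect_equal(aicScore(0, 0), 0)
  expect_equal(aicScore(-100, 5), 210)

  delta <- c(0, 2)
  w <- akaikeWeights(delta)
  expect_equal(sum(w), 1)
  expect_equal(akaikeWeights(delta + 137.2), w)  # constant-shift invariance
  expect_equal(w[2] / w[1], exp(-1))
})

test_that("rank tables satisfy the weight/ML invariants and tie-breaks", {
  tab <- aicTableFromValues(c(10, 12.25, 10), model = c("a", "b", "c"),
                            K = c(5L, 4L, 3L))
  tb <- as.data.frame(tab)
  expect_equal(tb$model[1], "c")          # AIC tie broken by smaller K
  expect_equal(tb$deltaAIC[1], 0)
  expect_equal(sum(tb$w), 1, tolerance = 1e-12)
  expect_equal(tb$ML, exp(-tb$deltaAIC / 2))

  single <- aicTableFromValues(432.1, model = "only")
  expect_equal(as.data.frame(single)$w, 1)
  expect_equal(as.data.frame(single)$ML, 1)
})

test_that("rankModels refuses fits on differently shaped data", {
  f1 <- handmadeFit(0.5, 0.5, tinyHistory())
  f2 <- handmadeFit(0.5, 0.5, detectionHistory(matrix(0L, 2, 2)))
  expect_error(rankModels(list(f1, f2)), "identically shaped")
  one <- rankModels(list(f1))
  expect_equal(as.data.frame(one)$w, 1)
})

test_that("model averaging combines estimates and unconditional SEs correctly", {
  # hand formula on two equally weighted models
  w <- c(0.5, 0.5); est <- c(0.6, 0.8); se <- c(0.1, 0.1)
  avg <- sum(w * est)
  expect_equal(avg, 0.7)
  use <- sum(w * sqrt(se^2 + (est - avg)^2))
  expect_equal(use, sqrt(0.02), tolerance = 1e-12)

  # via fitted objects: single model returns its own estimate and se
  sim <- simulateDataset(simConfig(nSites = 100, nSegments = 8, seed = 51))
  fit <- fitOccu(sim$y, sim$covs, occuSpec(), nStarts = 2, seed = 1)
  ma <- modelAverage(list(fit), "psi")
  pr <- predictPsi(fit)
  expect_equal(ma$estimate, mean(pr$psi), tolerance = 1e-12)
  expect_equal(ma$se, ma$components$se[1], tolerance = 1e-12)
  expect_true(ma$estimate >= min(ma$components$estimate) - 1e-12 &&
              ma$estimate <= max(ma$components$estimate) + 1e-12)

  map <- modelAverage(list(fit), "p")
  rp <- realParameters(fit)
  expect_equal(map$estimate, rp$estimate[rp$parameter == "p"])
})

test_that("averaging with near-degenerate weights returns the top model", {
  sim <- simulateDataset(simConfig(nSites = 150, nSegments = 8,
                                   correlated = FALSE, seed = 52))
  f1 <- fitOccu(sim$y, sim$covs, occuSpec(correlated = FALSE),
                nStarts = 2, seed = 1)
  f2 <- f1
  f2@aic <- f1@aic + 60  # weight ~ exp(-30), numerically 0
  f2@loglik <- f1@loglik - 30
  tab <- rankModels(list(f1, f2))
  ma <- modelAverage(tab, "psi")
  expect_equal(ma$estimate, mean(predictPsi(f1)$psi), tolerance = 1e-10)
})

test_that("stepwise additive search keeps only AIC-improving covariates", {
  # one informative covariate (Term), one pure noise column
  sim <- simulateDataset(simConfig(
    nSites = 300, nSegments = 10,
    betaPsi = c(`(Intercept)` = 0, Term = 1.5),
    alphaP = qlogis(0.35),
    continuousCovs = "EVI", segmentProbs = c(termite = 0.3),
    seed = 61))
  path <- stepwiseAdditive(sim$y, sim$covs, character(0),
                           psiPool = c("Term", "EVI"), nStarts = 2, seed = 2)
  models <- vapply(path, function(f)
    paste(sort(f@spec@psiCovariates), collapse = "+"), character(1))
  expect_true("" %in% models)           # null fitted
  expect_true("Term" %in% models)       # univariates fitted
  expect_true("EVI" %in% models)
  best <- rankModels(path)
  expect_match(as.data.frame(best)$model[1], "Term")

  # single-covariate pool: path is null + univariate
  path1 <- stepwiseAdditive(sim$y, sim$covs, character(0), psiPool = "Term",
                            nStarts = 2, seed = 3)
  expect_equal(length(path1), 2L)
})

test_that("two-step selection finds a strong occupancy driver and returns both tables", {
  sim <- simulateDataset(simConfig(
    nSites = 300, nSegments = 10,
    betaPsi = c(`(Intercept)` = 0, Term = 1.5),
    alphaP = c(`(Intercept)` = qlogis(0.3), Term = 0.7),
    continuousCovs = "EVI", segmentProbs = c(termite = 0.3),
    seed = 62))
  sel <- twoStepSelection(sim$y, sim$covs, psiPool = c("Term", "EVI"),
                          nStarts = 2, seed = 4)
  expect_s4_class(sel$detectionTable, "OccuAICTable")
  expect_s4_class(sel$occupancyTable, "OccuAICTable")
  # the informative covariate lands in the top occupancy model
  expect_match(as.data.frame(sel$occupancyTable)$model[1], "psi\\(.*Term")
  # step-1 models all keep the global occupancy structure
  det_models <- as.data.frame(sel$detectionTable)$model
  expect_true(all(grepl("psi\\(EVI\\+Term|psi\\(Term\\+EVI", det_models)))
})

test_that("a one-candidate pool yields single-row tables with weight 1", {
  sim <- simulateDataset(simConfig(nSites = 120, nSegments = 8,
                                   continuousCovs = "EVI",
                                   segmentProbs = c(termite = 0.3),
                                   seed = 63))
  sel <- twoStepSelection(sim$y, sim$covs, psiPool = "EVI",
                          pCandidates = list(character(0)),
                          nStarts = 2, seed = 5, secondBestP = FALSE)
  expect_equal(as.data.frame(sel$detectionTable)$w, 1)
})

test_that("with noise-only covariates the null occupancy model stays on top", {
  sim <- simulateDataset(simConfig(nSites = 300, nSegments = 10,
                                   continuousCovs = c("EVI", "Tcov"),
                                   segmentProbs = c(termite = 0.3),
                                   seed = 64))
  path <- stepwiseAdditive(sim$y, sim$covs, character(0),
                           psiPool = c("EVI", "Tcov"), nStarts = 2, seed = 6)
  tb <- as.data.frame(rankModels(path))
  null_delta <- tb$deltaAIC[grepl("psi(.)", tb$model, fixed = TRUE)]
  expect_lt(null_delta, 2)
  # and no multivariate model was retained on the path
  expect_false(any(grepl("psi(EVI+Tcov)", tb$model, fixed = TRUE) |
                   grepl("psi(Tcov+EVI)", tb$model, fixed = TRUE)))
})
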