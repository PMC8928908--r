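test_that("MLE beats a fine grid for the intercept-only standard model", {
  sim <- simulateDataset(simConfig(nSites = 80, nSegments = 6,
                                   correlated = FALSE,
                                   alphaP = qlogis(0.4), seed = 11))
  fit <- fitOccu(sim$y, sim$covs, occuSpec(correlated = FALSE),
                 nStarts = 3, seed = 1)
  obj <- function(par) negLogLikelihood(par, sim$y, sim$covs,
                                        occuSpec(correlated = FALSE))
  grid <- seq(0.01, 0.99, by = 0.001)
  best_grid <- Inf
  for (psi in seq(0.05, 0.99, by = 0.01)) {
    vals <- vapply(grid, function(p) obj(c(qlogis(psi), qlogis(p))),
                   numeric(1))
    best_grid <- min(best_grid, min(vals))
  }
  expect_lte(-fit@loglik, best_grid + 1e-6)
  expect_true(fit@converged)
  expect_equal(fit@aic, -2 * fit@loglik + 2 * fit@K)
})

test_that("intercept-only parameters are recovered from large simulations", {
  sim <- simulateDataset(simConfig(nSites = 2000, nSegments = 20,
                                   correlated = FALSE,
                                   betaPsi = qlogis(0.7),
                                   alphaP = qlogis(0.25), seed = 21))
  fit <- fitOccu(sim$y, sim$covs, occuSpec(correlated = FALSE),
                 nStarts = 2, seed = 2)
  rp <- realParameters(fit)
  psi_hat <- rp$estimate[rp$parameter == "psi"]
  # 3 Monte-Carlo SEs of a binomial proportion at n = 2000
  expect_lt(abs(psi_hat - 0.7), 3 * sqrt(0.7 * 0.3 / 2000) + 0.01)
  expect_lt(abs(rp$estimate[rp$parameter == "p"] - 0.25), 0.03)
})

test_that("datasets with no detections push occupancy to the boundary", {
  y <- detectionHistory(matrix(0L, 30, 5))
  covs <- new("SiteCovariates",
              data = data.frame(row.names = siteIDs(y)),
              scaled = FALSE, scaleParams = list())
  fit <- fitOccu(y, covs, occuSpec(correlated = FALSE), nStarts = 2, seed = 3)
  lp <- linearPredictors(fit@spec, coef(fit), covs)
  expect_true(lp$psi[1] < 0.05 || lp$p[1] < 0.05)
  expect_true(length(fit@boundaryFlags) > 0)
})

test_that("estimates are invariant to site order and refits are reproducible", {
  sim <- simulateDataset(simConfig(nSites = 120, nSegments = 10, seed = 31))
  spec <- occuSpec()
  fit1 <- fitOccu(sim$y, sim$covs, spec, nStarts = 2, seed = 5)
  fit1b <- fitOccu(sim$y, sim$covs, spec, nStarts = 2, seed = 5)
  expect_equal(fit1@loglik, fit1b@loglik, tolerance = 1e-6)
  expect_identical(coef(fit1), coef(fit1b))

  perm <- sample(nSites(sim$y))
  yp <- detectionHistory(detections(sim$y)[perm, ],
                         siteIDs = siteIDs(sim$y)[perm])
  cvp <- sim$covs
  cvp@data <- cvp@data[perm, , drop = FALSE]
  fit2 <- fitOccu(yp, cvp, spec, nStarts = 2, seed = 5)
  expect_lt(max(abs(coef(fit1) - coef(fit2))), 1e-5)
})

test_that("delta-method SEs match the closed form and Monte-Carlo draws", {
  # logistic derivative at 0: se = 0.25 * sqrt(var)
  y <- tinyHistory()
  fit <- handmadeFit(0.5, 0.5, y)
  fit@vcov <- diag(c(0.01, 0.04))
  dimnames(fit@vcov) <- list(names(coef(fit)), names(coef(fit)))
  rp <- realParameters(fit)
  expect_equal(rp$estimate[rp$parameter == "p"], 0.5)
  expect_equal(rp$se[rp$parameter == "p"], 0.25 * 0.2, tolerance = 1e-6)
  expect_equal(rp$se[rp$parameter == "psi"], 0.25 * 0.1, tolerance = 1e-6)

  # zero variance -> zero se
  fit@vcov <- matrix(0, 2, 2, dimnames = dimnames(fit@vcov))
  expect_equal(realParameters(fit)$se, c(0, 0))

  # against simulation from the sampling distribution of the link parameter
  fit@coefficients[] <- c(0.4, -0.9)
  fit@vcov <- diag(c(0.09, 0.04))
  dimnames(fit@vcov) <- list(names(coef(fit)), names(coef(fit)))
  rp <- realParameters(fit)
  set.seed(77)
  draws_p <- plogis(rnorm(1e5, -0.9, 0.2))
  expect_lt(abs(rp$se[rp$parameter == "p"] - sd(draws_p)) / sd(draws_p), 0.05)
})

test_that("per-site psi predictions respect the link ordering and the mean profile", {
  sim <- simulateDataset(simConfig(
    nSites = 150, nSegments = 10,
    betaPsi = c(`(Intercept)` = 0.5, Term = 1), seed = 41))
  fit <- fitOccu(sim$y, sim$covs, occuSpec(psi = "Term"), nStarts = 2, seed = 6)
  pred <- predictPsi(fit)
  eta_order <- order(covValues(sim$covs)$Term * coef(fit)["psi_Term"])
  expect_true(all(diff(pred$psi[eta_order]) >= -1e-12))

  at_mean <- predictPsi(fit, applyScale(
    siteCovariates(as.data.frame(as.list(scaleParams(sim$covs)$center))),
    scaleParams(sim$covs)))
  rp <- realParameters(fit)
  expect_equal(at_mean$psi, rp$estimate[rp$parameter == "psi"],
               tolerance = 1e-10)
  expect_equal(at_mean$se, rp$se[rp$parameter == "psi"], tolerance = 1e-6)

  # intercept-only model: identical psi for all sites
  fit0 <- fitOccu(sim$y, sim$covs, occuSpec(correlated = FALSE),
                  nStarts = 2, seed = 6)
  expect_equal(length(unique(predictPsi(fit0)$psi)), 1L)
})

test_that("non-converged fits refuse real-parameter derivation unless forced", {
  fit <- handmadeFit(0.5, 0.5, tinyHistory())
  fit@converged <- FALSE
  expect_error(realParameters(fit), "did not converge")
  expect_silent(realParameters(fit, force = TRUE))
})
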