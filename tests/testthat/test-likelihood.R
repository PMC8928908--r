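test_that("model notation and parameter counts follow the covariate structure", {
  g6 <- paste0("x", 1:6)
  expect_equal(countParameters(occuSpec(psi = g6, p = c("x1", "x2", "x3"))), 14L)
  expect_equal(countParameters(occuSpec(psi = "x1", p = c("x1", "x2", "x3"))), 9L)
  expect_equal(countParameters(occuSpec(correlated = FALSE)), 2L)
  expect_equal(countParameters(occuSpec(piMode = "stationary")), 4L)
  expect_equal(
    modelNotation(occuSpec(psi = "Term", p = c("Term", "EVI", "TRI"))),
    "psi(Term),th0(),th1(),p(Term+EVI+TRI),th0pi()")
})

test_that("linear predictors apply the logit link per site", {
  covs <- scaleCovariates(siteCovariates(data.frame(x = c(1, 2, 3))))
  lp0 <- linearPredictors(occuSpec(correlated = FALSE), c(0, 0), covs)
  expect_equal(lp0$psi, rep(0.5, 3))
  lp1 <- linearPredictors(occuSpec(psi = "x", correlated = FALSE),
                          c(0, 1, 0), covs)
  expect_equal(lp1$psi, plogis(covValues(covs)$x))
  expect_equal(plogis(1), 1 / (1 + exp(-1)))
  expect_error(linearPredictors(occuSpec(psi = "nope", correlated = FALSE),
                                c(0, 0, 0), covs), "unknown covariate")
})

test_that("stationary pi is the chain equilibrium", {
  covs <- scaleCovariates(siteCovariates(data.frame(x = c(1, 2, 3))))
  spec <- occuSpec(piMode = "stationary")
  lp <- linearPredictors(spec, c(0, 0, qlogis(0.2), qlogis(0.8)), covs)
  expect_equal(lp$pi, 0.2 / (1 + 0.2 - 0.8))  # = 0.5
})

test_that("standard site likelihood matches hand-computed cases", {
  expect_equal(siteLikelihoodStandard(1, 0.5, 0.5), 0.25)
  expect_equal(siteLikelihoodStandard(0, 0.5, 0.5), 0.75)
  expect_equal(siteLikelihoodStandard(c(0, 1, 0), 0.7, 0.3), 0.1029)
  # missing contributes factor 1
  expect_equal(siteLikelihoodStandard(c(NA, 1), 0.5, 0.5), 0.25)
  expect_error(siteLikelihoodStandard(1, 1.2, 0.5), "probabilities")
})

test_that("correlated site likelihood matches enumeration over latent paths", {
  expect_equal(siteLikelihoodCorrelated(1, 0.69, 0.3, 0.7, 0.5, 0.25),
               0.69 * 0.5 * 0.25)
  # 4-path hand enumeration: 0.48 + 0.048 + 0.032 + 0.0512 = 0.6112
  expect_equal(siteLikelihoodCorrelated(c(0, 0), 0.5, 0.2, 0.8, 0.4, 0.6),
               0.5 * 0.6112 + 0.5)
  # y = 1 where p = 0 is impossible, not an error
  expect_equal(siteLikelihoodCorrelated(1, 0.5, 0.3, 0.7, 0.5, 0), 0)
  # all-missing history carries no information
  expect_equal(siteLikelihoodBruteforce(c(NA, NA, NA), 0.3, 0.2, 0.9, 0.4, 0.7), 1)
  expect_error(siteLikelihoodBruteforce(rep(0, 17), 0.5, 0.5, 0.5, 0.5, 0.5),
               "16")
})

test_that("forward recursion equals brute force for random draws, K <= 12", {
  set.seed(101)
  for (i in 1:300) {
    K <- sample(1:12, 1)
    h <- randomHistory(K)
    pr <- randomChainParams()
    fwd <- siteLikelihoodCorrelated(h, pr$psi, pr$theta0, pr$theta1, pr$pi, pr$p)
    bf <- siteLikelihoodBruteforce(h, pr$psi, pr$theta0, pr$theta1, pr$pi, pr$p)
    expect_lt(abs(fwd - bf), 1e-10)
  }
})

test_that("history probabilities sum to one over all 2^K outcomes", {
  set.seed(202)
  for (K in c(3, 6, 10)) {
    H <- allHistories(K)
    pr <- randomChainParams()
    tot_c <- sum(apply(H, 1, siteLikelihoodCorrelated, psi = pr$psi,
                       theta0 = pr$theta0, theta1 = pr$theta1, pi = pr$pi,
                       p = pr$p))
    tot_s <- sum(apply(H, 1, siteLikelihoodStandard, psi = pr$psi, p = pr$p))
    expect_lt(abs(tot_c - 1), 1e-9)
    expect_lt(abs(tot_s - 1), 1e-9)
  }
})

test_that("correlated model collapses to the standard model in known limits", {
  set.seed(303)
  for (i in 1:25) {
    K <- sample(1:10, 1)
    h <- randomHistory(K)
    pr <- randomChainParams()
    # theta0 = theta1 = pi = 1: sign always locally present
    expect_equal(
      siteLikelihoodCorrelated(h, pr$psi, 1, 1, 1, pr$p),
      siteLikelihoodStandard(h, pr$psi, pr$p))
    # theta0 = theta1 = pi = theta: iid availability, p' = theta * p
    th <- runif(1, 0.1, 0.9)
    expect_equal(
      siteLikelihoodCorrelated(h, pr$psi, th, th, th, pr$p),
      siteLikelihoodStandard(h, pr$psi, th * pr$p),
      tolerance = 1e-12)
  }
})

test_that("no-detection probability is at least 1 - psi; detected histories increase with psi", {
  set.seed(404)
  for (i in 1:25) {
    K <- sample(2:10, 1)
    pr <- randomChainParams()
    lik0 <- siteLikelihoodCorrelated(rep(0, K), pr$psi, pr$theta0, pr$theta1,
                                     pr$pi, pr$p)
    expect_gte(lik0, 1 - pr$psi - 1e-12)
    h <- randomHistory(K, missProb = 0)
    h[sample(K, 1)] <- 1
    psis <- sort(runif(4))
    liks <- vapply(psis, function(ps)
      siteLikelihoodCorrelated(h, ps, pr$theta0, pr$theta1, pr$pi, pr$p),
      numeric(1))
    expect_true(all(diff(liks) >= -1e-14))
  }
})

test_that("total NLL is additive and agrees with the enumeration oracle", {
  spec <- occuSpec()
  set.seed(505)
  covs <- function(n) new("SiteCovariates",
                          data = data.frame(row.names = sprintf("s%d", 1:n)),
                          scaled = FALSE, scaleParams = list())
  ym <- matrix(sample(c(0L, 0L, 0L, 1L, NA), 8 * 6, replace = TRUE), 8, 6)
  ym[1, ] <- 0L  # ensure at least one clean row
  y <- detectionHistory(ym)
  params <- rnorm(5)
  nll <- negLogLikelihood(params, y, covs(8), spec)
  sp <- linearPredictors(spec, params, covs(8), nSeg = 6)
  oracle <- -sum(vapply(1:8, function(i)
    log(siteLikelihoodBruteforce(ym[i, ], sp$psi[i], sp$theta0, sp$theta1,
                                 sp$pi, sp$p[i])), numeric(1)))
  expect_lt(abs(nll - oracle), 1e-10)

  y1 <- detectionHistory(ym[1:3, , drop = FALSE])
  y2 <- detectionHistory(ym[4:8, , drop = FALSE])
  expect_equal(negLogLikelihood(params, y1, covs(3), spec) +
               negLogLikelihood(params, y2, covs(5), spec), nll)

  # single site, intercept-only standard model at psi = p = 0.5
  ystd <- detectionHistory(matrix(1L, 1, 1))
  expect_equal(negLogLikelihood(c(0, 0), ystd, covs(1),
                                occuSpec(correlated = FALSE)), -log(0.25))
})

test_that("long all-detection transects do not underflow", {
  h <- rep(1L, 20)
  v <- siteLikelihoodCorrelated(h, 0.9, 0.1, 0.95, 0.5, 0.1)
  expect_gt(v, 0)
  expect_true(is.finite(log(v)))
})

test_that("model specifications round-trip through their YAML form", {
  path <- withr::local_tempfile(fileext = ".yml")
  s1 <- occuSpec(psi = "Term", p = c("Term", "EVI", "TRI"))
  writeOccuSpec(s1, path)
  s2 <- readOccuSpec(path)
  expect_equal(modelNotation(s2), modelNotation(s1))
  expect_equal(countParameters(s2), countParameters(s1))

  s3 <- occuSpec(correlated = FALSE)
  writeOccuSpec(s3, path)
  expect_false(readOccuSpec(path)@correlated)

  s4 <- occuSpec(piMode = "fixed", piValue = 0.4)
  writeOccuSpec(s4, path)
  expect_equal(readOccuSpec(path)@piValue, 0.4)
})
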