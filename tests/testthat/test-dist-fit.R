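# Distribution fitting, AIC model selection, z test.

test_that("normal MLE is closed form and exact on shifted data", {
  set.seed(1)
  x <- rnorm(200, 10, 2)
  fit <- fitDistribution(x, "normal")
  expect_equal(fit@mu, mean(x))
  expect_equal(fit@sigma, sqrt(mean((x - mean(x))^2)))
  shifted <- fitDistribution(x + 100, "normal")
  expect_equal(shifted@mu, mean(x) + 100)
  expect_equal(shifted@sigma, fit@sigma, tolerance = 1e-12)
})

test_that("lognormal MLE recovers parameters from large seeded samples", {
  set.seed(2)
  x <- rlnorm(10000, meanlog = 7, sdlog = 0.1)
  fit <- fitDistribution(x, "lognormal")
  expect_lt(abs(fit@mu - 7), 0.01)
  expect_lt(abs(fit@sigma - 0.1) / 0.1, 0.05)
  expect_error(fitDistribution(c(x[1:10], 0), "lognormal"),
               "non-positive")
})

test_that("truncated-normal fitting matches the plain normal when bounds are wide", {
  set.seed(3)
  x <- rnorm(500, 50, 5)
  plain <- fitDistribution(x, "normal")
  wide <- fitDistribution(x, "truncnorm", lower = -1e12, upper = 1e12)
  expect_lt(abs(wide@mu - plain@mu), 1e-6)
  expect_lt(abs(wide@sigma - plain@sigma), 1e-6)
  expect_lt(abs(wide@logLik - plain@logLik), 1e-6)
  # genuinely truncated data pull the location beyond the bound-censored mean
  set.seed(4)
  y <- rnorm(4000, 2, 4); y <- y[y >= 0 & y <= 20]
  tfit <- fitDistribution(y, "truncnorm", lower = 0, upper = 20)
  expect_lt(tfit@mu, mean(y))
  expect_gt(tfit@sigma, sqrt(mean((y - mean(y))^2)))
})

test_that("truncnorm and lognormal densities are proper and closed-form checks hold", {
  tfit <- new("FittedDistribution", relationship = "", family = "truncnorm",
              mu = 10, sigma = 30, lower = 0, upper = 100, n = 10L,
              logLik = 0)
  z <- integrate(function(x) densityICS(tfit, x), 0, 100,
                 rel.tol = 1e-10)$value
  expect_lt(abs(z - 1), 1e-6)
  expect_equal(densityICS(tfit, -5), 0)
  expect_equal(densityICS(tfit, 105), 0)
  lfit <- new("FittedDistribution", relationship = "", family = "lognormal",
              mu = 3, sigma = 0.4, lower = 0, upper = Inf, n = 10L,
              logLik = 0)
  # density at the median x = e^mu equals 1 / (e^mu sigma sqrt(2 pi))
  expect_equal(densityICS(lfit, exp(3)),
               1 / (exp(3) * 0.4 * sqrt(2 * pi)), tolerance = 1e-12)
  expect_equal(densityICS(lfit, 0), 0)
})

test_that("fitted pdfs agree with seeded Monte-Carlo histograms", {
  set.seed(8)
  lfit <- new("FittedDistribution", relationship = "", family = "lognormal",
              mu = 6, sigma = 0.3, lower = 0, upper = Inf, n = 10L,
              logLik = 0)
  draws <- randomICS(lfit, 1e6)
  grid <- quantile(draws, c(0.2, 0.4, 0.6, 0.8))
  for (x0 in grid) {
    w <- x0 * 0.02
    est <- mean(draws >= x0 - w & draws < x0 + w) / (2 * w)
    expect_lt(abs(est - densityICS(lfit, x0)) / densityICS(lfit, x0),
              0.02)
  }
})

test_that("AIC is 2k - 2 logLik with k = 2 and matches density summation", {
  f0 <- new("FittedDistribution", relationship = "", family = "normal",
            mu = 0, sigma = 1, lower = -Inf, upper = Inf, n = 5L,
            logLik = 0)
  expect_equal(AIC(f0), 4.0)
  set.seed(9)
  x <- rlnorm(500, 5, 0.2)
  fit <- fitDistribution(x, "lognormal")
  expect_equal(AIC(fit),
               4 - 2 * sum(dlnorm(x, fit@mu, fit@sigma, log = TRUE)),
               tolerance = 1e-10)
  f2 <- fitDistribution(x, "normal")
  expect_equal(AIC(fit) - AIC(f2), -2 * (fit@logLik - f2@logLik),
               tolerance = 1e-10)
})

test_that("AIC model selection identifies the generating family", {
  rels <- c("C-1", "C-2", "C-3", "C-4", "C-5", "UN")
  mus <- c(8.0, 7.6, 7.0, 6.4, 6.0, 5.2)
  hitsLog <- 0L; hitsNorm <- 0L
  nRep <- 20L
  for (r in seq_len(nRep)) {
    set.seed(1000 + r)
    vLog <- setNames(lapply(mus, function(m) rlnorm(249, m, 0.25)), rels)
    selLog <- selectModel(vLog, "C", upper = 2e4)
    hitsLog <- hitsLog + (selLog@chosen == "lognormal")
    vNorm <- setNames(lapply(mus, function(m)
      rnorm(249, 400 * m, 400)), rels)
    selNorm <- selectModel(vNorm, "C", upper = 1e7)
    hitsNorm <- hitsNorm + (selNorm@chosen %in% c("normal", "truncnorm"))
  }
  expect_gte(hitsLog, ceiling(0.95 * nRep))
  expect_gte(hitsNorm, ceiling(0.95 * nRep))
})

test_that("model selection validates its inputs and applies the zero policy", {
  rels <- c("C-1", "C-2", "C-3", "C-4", "C-5", "UN")
  set.seed(11)
  v <- setNames(lapply(rels, function(r) rlnorm(100, 6, 0.3)), rels)
  expect_error(selectModel(v[-1L], "C", upper = 3662.5), "C-1")
  # a few zeros in UN are excluded with a message
  v$UN[1:3] <- 0
  expect_message(sel <- selectModel(v, "C", upper = 3662.5), "excluded 3")
  expect_equal(sel@fits$lognormal$UN@n, 97L)
  # too many zeros error out
  v$UN[1:20] <- 0
  expect_error(suppressMessages(selectModel(v, "C", upper = 3662.5)),
               "not applicable")
})

test_that("the lineal group fits L-2, L-3 and UN only", {
  set.seed(12)
  v <- list("L-2" = rlnorm(100, 7.5, 0.1), "L-3" = rlnorm(100, 6.8, 0.2),
            "UN" = rlnorm(100, 4, 0.5))
  sel <- selectModel(v, "L", upper = 3662.5)
  expect_equal(sort(names(chosenFits(sel))), c("L-2", "L-3", "UN"))
})

test_that("the z test is calibrated under the null and detects gross shifts", {
  fit <- new("FittedDistribution", relationship = "", family = "lognormal",
             mu = 7, sigma = 0.2, lower = 0, upper = Inf, n = 100L,
             logLik = 0)
  set.seed(13)
  pvals <- vapply(1:500, function(i) {
    obs <- rlnorm(10, 7, 0.2)
    zTestICS(obs, fit)$p.value
  }, numeric(1))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  # single observation at the fitted median: z = 0, p = 1
  res <- zTestICS(exp(7), fit)
  expect_equal(res$z, 0)
  expect_equal(res$p.value, 1)
  # +10 sigma shift is detected
  res2 <- zTestICS(rlnorm(10, 7 + 10 * 0.2, 0.2), fit)
  expect_lt(res2$p.value, 1e-6)
})

test_that("fitted model sets round-trip through JSON", {
  set.seed(14)
  fits <- list(
    "C-1" = fitDistribution(rlnorm(50, 8, 0.1), "lognormal",
                            relationship = "C-1"),
    "UN" = fitDistribution(rnorm(50, 300, 40), "truncnorm", lower = 0,
                           upper = 3662.5, relationship = "UN"))
  f <- withr::local_tempfile(fileext = ".json")
  writeModelsJSON(fits, f, group = "C")
  back <- readModelsJSON(f)
  expect_equal(names(back), c("C-1", "UN"))
  expect_equal(back[["C-1"]]@mu, fits[["C-1"]]@mu)
  expect_equal(back[["UN"]]@sigma, fits[["UN"]]@sigma)
  expect_equal(back[["UN"]]@upper, 3662.5)
  expect_equal(back[["C-1"]]@upper, Inf)
})
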