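# Likelihood ratios, posteriors, Hummel predicates, predicate geometry.

lognormFit <- function(mu, sigma, rel = "") {
  new("FittedDistribution", relationship = rel, family = "lognormal",
      mu = mu, sigma = sigma, lower = 0, upper = Inf, n = 10L, logLik = 0)
}

test_that("likelihood ratios satisfy identity, reciprocity and closed forms", {
  h1 <- lognormFit(7, 0.2); h2 <- lognormFit(5, 0.5)
  expect_equal(likelihoodRatio(1000, h1, h1)$lr, 1)
  a <- likelihoodRatio(800, h1, h2); b <- likelihoodRatio(800, h2, h1)
  expect_equal(a$lr * b$lr, 1, tolerance = 1e-12)
  expect_equal(a$log10Lr, -b$log10Lr, tolerance = 1e-12)
  # closed-form density ratio at a chosen point
  x <- 900
  want <- dlnorm(x, 7, 0.2) / dlnorm(x, 5, 0.5)
  expect_equal(likelihoodRatio(x, h1, h2)$lr, want, tolerance = 1e-10)
  # underflowed denominator -> +Inf with flag; both zero -> error
  far <- lognormFit(1, 0.01)
  r <- likelihoodRatio(3000, h1, far)
  expect_true(is.infinite(r$lr) && r$infinite)
  expect_error(likelihoodRatio(0, h1, h2), "undefined")
})

test_that("posteriors normalize, reduce to density ratios under flat priors, and match brute force", {
  h <- list("A" = lognormFit(7, 0.2), "B" = lognormFit(6, 0.3),
            "UN" = lognormFit(4, 0.5))
  hs <- hypothesisSet(h)
  res <- posteriorProbs(700, hs)
  expect_equal(sum(posteriors(res)), 1, tolerance = 1e-12)
  # Eq(2) with flat priors == Eq(3) pure density ratio
  dens <- vapply(h, function(f) densityICS(f, 700), numeric(1))
  expect_equal(unname(posteriors(res)), unname(dens / sum(dens)),
               tolerance = 1e-12)
  # arbitrary priors vs direct unnormalized product
  pri <- c(A = 0.5, B = 0.2, UN = 0.3)
  res2 <- posteriorProbs(700, hypothesisSet(h, priors = pri))
  expect_equal(unname(posteriors(res2)),
               unname(dens * pri / sum(dens * pri)), tolerance = 1e-12)
  # two equal-density hypotheses split 50/50
  eq <- hypothesisSet(list(X = lognormFit(6, 0.3),
                           Y = lognormFit(6, 0.3)))
  expect_equal(unname(posteriors(posteriorProbs(500, eq))), c(0.5, 0.5))
})

test_that("posteriors are invariant to scaling all densities and match LR/(LR+1)", {
  h1 <- lognormFit(7, 0.2); h2 <- lognormFit(5, 0.6)
  hs <- hypothesisSet(list(R = h1, UN = h2))
  for (x in c(200, 700, 1500)) {
    p <- posteriors(posteriorProbs(x, hs))[["R"]]
    lr <- likelihoodRatio(x, h1, h2)$lr
    expect_equal(p, lr / (lr + 1), tolerance = 1e-9)
  }
  # scaling invariance: posteriors depend only on density ratios, checked
  # across a wide range where absolute densities differ by many orders
  hsBig <- hypothesisSet(list(R = lognormFit(7 + log(1e50), 0.2),
                              UN = lognormFit(5 + log(1e50), 0.6)))
  for (x in c(200, 700, 1500))
    expect_equal(posteriors(posteriorProbs(x * 1e50, hsBig))[["R"]],
                 posteriors(posteriorProbs(x, hs))[["R"]],
                 tolerance = 1e-9)
})

test_that("log-space arithmetic survives astronomically small densities", {
  # ICS deep in one tail: naive density ratios underflow, log space works
  hs <- hypothesisSet(list(R = lognormFit(8.2, 0.05),
                           UN = lognormFit(5, 0.3)))
  res <- posteriorProbs(3600, hs)
  expect_equal(sum(posteriors(res)), 1, tolerance = 1e-12)
  expect_gt(res@log10LrVsUN[["R"]], 20)
  expect_error(posteriorProbs(0, hs), "zero")
})

test_that("Hummel predicates partition [0, 1]", {
  expect_equal(hummelPredicate(c(0.998, 0.999, 1)),
               rep("practically proven", 3))
  expect_equal(hummelPredicate(c(0.99, 0.9979)), rep("highly likely", 2))
  expect_equal(hummelPredicate(c(0.95, 0.9899)), rep("very likely", 2))
  expect_equal(hummelPredicate(c(0.90, 0.9499)), rep("likely", 2))
  expect_equal(hummelPredicate(c(0, 0.5, 0.8999)),
               rep("undetermined", 3))
  # every probability lands in exactly one band
  set.seed(21)
  p <- runif(200)
  expect_true(all(nzchar(hummelPredicate(p))))
})

test_that("the parent-child pre-check separates L-1 from everything else", {
  coh <- smallCohort()
  g <- cohortGenotypes(coh)
  l1 <- relationshipPairs(coh, "L-1")[1:4, ]
  for (i in seq_len(nrow(l1)))
    expect_true(l1Precheck(ibsStates(g, l1$sampleA[i], l1$sampleB[i])))
  sib <- relationshipPairs(coh, "C-1")[1:4, ]
  for (i in seq_len(nrow(sib)))
    expect_false(l1Precheck(ibsStates(g, sib$sampleA[i], sib$sampleB[i])))
  # parent-child survives a 0.05% genotype error rate at default tolerance
  noisy <- injectGenotypeErrors(g, errorRate = 5e-4, seed = 71L)
  hits <- vapply(seq_len(nrow(l1)), function(i)
    l1Precheck(ibsStates(noisy, l1$sampleA[i], l1$sampleB[i])),
    logical(1))
  expect_true(all(hits))
  expect_error(l1Precheck(new("IbsTrack", state = integer(),
                              locusIndex = integer(), chrom = character(),
                              samples = c("a", "b"))), "empty")
})

test_that("predicate ranges cover the bulk of a well-separated target and match pointwise recomputation", {
  hs <- hypothesisSet(list(R = lognormFit(7.5, 0.1, "R"),
                           UN = lognormFit(4, 0.3, "UN")))
  rng <- predicateRanges(hs, "R", icsMax = 3662.5, gridStep = 1)
  expect_true(all(rng$upper > rng$lower))
  expect_equal(rng$lower[1L], 0)
  expect_equal(rng$upper[nrow(rng)], 3662.5)
  proven <- rng[rng$predicate == "practically proven", ]
  # the target's central 95% mass lies inside its proven region
  qs <- qlnorm(c(0.025, 0.975), 7.5, 0.1)
  expect_true(any(proven$lower <= qs[1L] & proven$upper >= qs[2L]))
  # midpoints of each interval reproduce the band
  mids <- (rng$lower + rng$upper) / 2
  post <- vapply(mids, function(x)
    posteriors(posteriorProbs(x, hs))[["R"]], numeric(1))
  expect_equal(hummelPredicate(post), rng$predicate)
})

test_that("a degenerate near-single hypothesis set is practically proven everywhere", {
  # posterior of the dominant hypothesis ~ 1 across the domain when the
  # competitor is pushed far away
  hs <- hypothesisSet(list(R = lognormFit(6, 1),
                           FAR = lognormFit(-40, 0.01)))
  rng <- predicateRanges(hs, "R", icsMax = 1000, gridStep = 1)
  expect_equal(unique(rng$predicate), "practically proven")
})

test_that("predicate masses are monotone in threshold and match Monte Carlo", {
  hs <- hypothesisSet(list(R = lognormFit(7.2, 0.15, "R"),
                           S = lognormFit(6.6, 0.2, "S"),
                           UN = lognormFit(4.5, 0.4, "UN")))
  icsMax <- 3662.5
  for (target in c("R", "S", "UN")) {
    masses <- vapply(c(0.998, 0.99, 0.95, 0.90), function(thr)
      predicateMass(hs, target, thr, icsMax = icsMax), numeric(1))
    expect_true(all(diff(masses) >= -1e-9))
    # Monte-Carlo oracle: fraction of draws whose posterior clears 0.90
    set.seed(31)
    draws <- randomICS(hs@fits[[target]], 1e5)
    draws <- draws[draws > 0 & draws <= icsMax]
    dens <- vapply(hs@fits, function(f) densityICS(f, draws),
                   numeric(length(draws)))
    post <- dens[, target] / rowSums(dens)
    mc <- mean(post >= 0.90)
    expect_lt(abs(masses[4L] - mc), 0.005)
  }
})

test_that("classifyPair routes lineal pairs through the pre-check and returns verdicts", {
  coh <- smallCohort()
  g <- cohortGenotypes(coh)
  icsMax <- totalMapLength(geneticMap(coh))
  # calibrate crude lognormal fits from the cohort itself
  sw <- icsSweep(coh, thGrid = c(3))
  fitsL <- lapply(c("L-2", "L-3", "UN"), function(r)
    fitDistribution(pmax(sweepValues(sw, r)[, 1L], 1), "lognormal",
                    relationship = r))
  names(fitsL) <- c("L-2", "L-3", "UN")
  hsL <- hypothesisSet(fitsL, group = "L")
  l1 <- relationshipPairs(coh, "L-1")[1, ]
  res <- classifyPair(g, l1$sampleA, l1$sampleB, hsL, th = 3, group = "L")
  expect_equal(res@bestHypothesis, "L-1")
  expect_equal(res@predicate, "practically proven")
  expect_equal(icsValue(res@ics), icsMax)
  l2 <- relationshipPairs(coh, "L-2")[1, ]
  res2 <- classifyPair(g, l2$sampleA, l2$sampleB, hsL, th = 3,
                       group = "L")
  expect_true(res2@bestHypothesis %in% names(fitsL))
  expect_equal(sum(posteriors(res2)), 1, tolerance = 1e-9)
})
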