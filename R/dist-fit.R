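# Per-relationship ICS distribution fitting.
#
# Three candidate families, each with a location mu and scale sigma:
# normal, normal truncated to [0, total map length], and log-normal.
# Normal and log-normal MLEs are closed-form; the truncated normal is
# maximized numerically from the untruncated solution. Families are
# compared by AIC = 2k - 2 log(ML) with k = 2 per relationship, summed
# over the relationships of a group (C or L) since every relationship has
# its own mu and sigma.

.dtrunc <- function(x, mu, sigma, lower, upper, log = FALSE) {
  z <- stats::pnorm(upper, mu, sigma) - stats::pnorm(lower, mu, sigma)
  ld <- stats::dnorm(x, mu, sigma, log = TRUE) - log(z)
  ld[x < lower | x > upper] <- -Inf
  if (log) ld else exp(ld)
}

#' Fit an ICS distribution by maximum likelihood
#'
#' Normal: closed form (`mu` = sample mean, `sigma` = MLE standard
#' deviation). Log-normal: closed form on log values (all values must be
#' positive). Truncated normal on `[lower, upper]`: numeric likelihood
#' maximization (BFGS on `(mu, log sigma)`) initialized at the untruncated
#' MLE.
#'
#' @param values numeric ICS values (n >= 2; >= 10 recommended for stable
#'   scale estimates).
#' @param family `"normal"`, `"truncnorm"` or `"lognormal"`.
#' @param lower,upper truncation bounds (truncnorm; `upper` is typically
#'   [totalMapLength()]).
#' @param relationship label stored with the fit.
#' @return a [FittedDistribution-class].
#' @export
fitDistribution <- function(values,
                            family = c("normal", "truncnorm", "lognormal"),
                            lower = 0, upper = Inf, relationship = "") {
  family <- match.arg(family)
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) stop("at least 2 values are required")
  if (anyNA(values)) stop("values must not contain NA")
  if (family == "lognormal") {
    bad <- sum(values <= 0)
    if (bad > 0L)
      stop(bad, " non-positive value(s): log-normal support is (0, Inf)")
    lx <- log(values)
    mu <- mean(lx); sigma <- sqrt(mean((lx - mu)^2))
    if (sigma <= 0) stop("degenerate sample: zero variance on log scale")
    ll <- sum(stats::dlnorm(values, mu, sigma, log = TRUE))
    lo <- 0; up <- Inf
  } else if (family == "normal") {
    mu <- mean(values); sigma <- sqrt(mean((values - mu)^2))
    if (sigma <= 0) stop("degenerate sample: zero variance")
    ll <- sum(stats::dnorm(values, mu, sigma, log = TRUE))
    lo <- -Inf; up <- Inf
  } else {
    if (!is.finite(lower) || !is.finite(upper) || lower >= upper)
      stop("truncnorm requires finite lower < upper")
    if (any(values < lower | values > upper))
      stop("values outside the truncation bounds")
    mu0 <- mean(values); s0 <- sqrt(mean((values - mu0)^2))
    if (s0 <= 0) stop("degenerate sample: zero variance")
    negll <- function(p)
      -sum(.dtrunc(values, p[1L], exp(p[2L]), lower, upper, log = TRUE))
    opt <- stats::optim(c(mu0, log(s0)), negll, method = "BFGS",
                        control = list(reltol = 1e-10, maxit = 2000L))
    if (opt$convergence != 0L)
      stop("truncated-normal optimizer failed to converge (code ",
           opt$convergence, "): ", opt$message %||% "")
    mu <- opt$par[1L]; sigma <- exp(opt$par[2L]); ll <- -opt$value
    lo <- lower; up <- upper
  }
  new("FittedDistribution", relationship = relationship, family = family,
      mu = mu, sigma = sigma, lower = lo, upper = up, n = n, logLik = ll)
}

#' Probability density of a fitted ICS distribution
#'
#' `f(ICS | H)`: the density of an ICS value under the hypothesis whose
#' distribution was fitted. The truncated normal is renormalized over its
#' bounds; the log-normal density is 0 at `x = 0`.
#'
#' @param fit a [FittedDistribution-class].
#' @param x ICS value(s), `x >= 0`.
#' @param log return log densities.
#' @return numeric densities.
#' @export
densityICS <- function(fit, x, log = FALSE) {
  switch(fit@family,
    normal = stats::dnorm(x, fit@mu, fit@sigma, log = log),
    lognormal = stats::dlnorm(x, fit@mu, fit@sigma, log = log),
    truncnorm = .dtrunc(x, fit@mu, fit@sigma, fit@lower, fit@upper,
                        log = log))
}

#' Random draws from a fitted ICS distribution
#' @param fit a [FittedDistribution-class].
#' @param n number of draws.
#' @return numeric vector.
#' @export
randomICS <- function(fit, n) {
  switch(fit@family,
    normal = stats::rnorm(n, fit@mu, fit@sigma),
    lognormal = stats::rlnorm(n, fit@mu, fit@sigma),
    truncnorm = {
      # inverse-CDF sampling within the bounds
      pl <- stats::pnorm(fit@lower, fit@mu, fit@sigma)
      pu <- stats::pnorm(fit@upper, fit@mu, fit@sigma)
      stats::qnorm(stats::runif(n, pl, pu), fit@mu, fit@sigma)
    })
}

#' @describeIn fitDistribution AIC of a fit: `2k - 2 logLik` with `k = 2`
#'   (location and scale).
#' @param object a [FittedDistribution-class].
#' @param ... ignored.
#' @param k unused; the parameter count is fixed at 2.
#' @exportS3Method stats::AIC
AIC.FittedDistribution <- function(object, ..., k = 2) {
  2 * 2 - 2 * object@logLik
}

#' @exportS3Method stats::logLik
logLik.FittedDistribution <- function(object, ...) {
  structure(object@logLik, df = 2L, class = "logLik")
}

setMethod("show", "FittedDistribution", function(object) {
  cat(sprintf(
    "FittedDistribution [%s] %s: mu = %.4f, sigma = %.4f (n = %d, logLik = %.2f)\n",
    object@relationship, object@family, object@mu, object@sigma, object@n,
    object@logLik))
})

#' Fit all three families per relationship and select by group AIC
#'
#' Every relationship of a group is fitted with its own location and scale
#' under each candidate family; the group AIC of a family is the sum of
#' its per-relationship AICs, and the family with the lowest group AIC is
#' chosen. Numerical ties (|dAIC| < 1e-6, which occur between the normal
#' and a truncated normal whose data sit far from the bounds) are resolved
#' in the order log-normal, truncated normal, normal.
#'
#' For the collateral group the relationships are C-1..C-5 plus UN; for
#' the lineal group L-2, L-3 plus UN (parent-child pairs are completely
#' separated from every other relationship and are handled by
#' [l1Precheck()], not by a fitted density). ICS values of exactly 0 are
#' excluded from log-normal fitting with a message; if more than 5% of a
#' relationship's values are 0 the fit errors out.
#'
#' @param valuesByRelationship named list of numeric ICS vectors.
#' @param group `"C"` or `"L"`.
#' @param upper truncation upper bound, typically [totalMapLength()].
#' @param lower truncation lower bound (default 0).
#' @return a [ModelSelection-class].
#' @export
selectModel <- function(valuesByRelationship, group = c("C", "L"),
                        upper, lower = 0) {
  group <- match.arg(group)
  want <- switch(group, C = c("C-1", "C-2", "C-3", "C-4", "C-5", "UN"),
                 L = c("L-2", "L-3", "UN"))
  missing <- setdiff(want, names(valuesByRelationship))
  if (length(missing))
    stop("missing relationship class(es): ", paste(missing, collapse = ", "))
  fams <- c("lognormal", "truncnorm", "normal")  # tie-break preference order
  fits <- lapply(fams, function(fam) {
    out <- lapply(want, function(rel) {
      v <- valuesByRelationship[[rel]]
      if (fam == "lognormal") {
        nz <- sum(v == 0)
        if (nz > 0.05 * length(v))
          stop("relationship ", rel, ": ", nz, " of ", length(v),
               " ICS values are 0; log-normal fitting is not applicable")
        if (nz > 0L) {
          message("relationship ", rel, ": excluded ", nz,
                  " zero ICS value(s) from log-normal fitting")
          v <- v[v > 0]
        }
      }
      fitDistribution(v, fam, lower = lower, upper = upper,
                      relationship = rel)
    })
    names(out) <- want
    out
  })
  names(fits) <- fams
  aics <- vapply(fits, function(fl)
    sum(vapply(fl, AIC.FittedDistribution, numeric(1))), numeric(1))
  best <- aics - min(aics) < 1e-6
  chosen <- fams[which(best)[1L]]  # fams are in tie-break order
  new("ModelSelection", group = group, aic = aics, chosen = chosen,
      fits = fits)
}

#' Fits of the chosen (or a given) family in a ModelSelection
#' @param x a [ModelSelection-class].
#' @param family optional family name (default the chosen one).
#' @return named list of [FittedDistribution-class].
#' @export
chosenFits <- function(x, family = x@chosen) x@fits[[family]]

setMethod("show", "ModelSelection", function(object) {
  cat(sprintf("ModelSelection (%s relatives): chosen %s\n", object@group,
              object@chosen))
  for (f in names(object@aic))
    cat(sprintf("  AIC[%s] = %.3f\n", f, object@aic[f]))
})

#' z test of observed ICS values against a fitted distribution
#'
#' The fitted distribution is the null: on its natural scale (log scale
#' for the log-normal) the sample mean of `observed` is compared to `mu`
#' with known sigma, `z = (mean - mu) / (sigma / sqrt(n))`, two-sided.
#'
#' @param observed numeric ICS values.
#' @param fit a [FittedDistribution-class].
#' @return list with `z`, `p.value`, `n`.
#' @export
zTestICS <- function(observed, fit) {
  n <- length(observed)
  if (n == 0L) stop("observed must be nonempty")
  x <- if (fit@family == "lognormal") {
    if (any(observed <= 0))
      stop("non-positive observation under a log-normal fit")
    log(observed)
  } else observed
  z <- (mean(x) - fit@mu) / (fit@sigma / sqrt(n))
  list(z = z, p.value = 2 * stats::pnorm(-abs(z)), n = n)
}

#' Serialize fitted models to JSON
#'
#' The JSON file is the contract between calibration and inference:
#' an array of objects `{group, relationship, family, mu, sigma, lower,
#' upper, n}`.
#'
#' @param fits named list of [FittedDistribution-class].
#' @param path output path.
#' @param group group label stored with each record.
#' @return `path`, invisibly.
#' @export
writeModelsJSON <- function(fits, path, group = "") {
  recs <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    c(list(group = group, relationship = nm, family = f@family, mu = f@mu,
           sigma = f@sigma),
      if (is.finite(f@lower)) list(lower = f@lower),
      if (is.finite(f@upper)) list(upper = f@upper),
      list(n = f@n, logLik = f@logLik))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read fitted models from JSON
#' @param path JSON path written by [writeModelsJSON()].
#' @return named list of [FittedDistribution-class].
#' @export
readModelsJSON <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(recs, function(r)
    new("FittedDistribution", relationship = r$relationship,
        family = r$family, mu = as.numeric(r$mu),
        sigma = as.numeric(r$sigma),
        lower = as.numeric(r$lower %||% -Inf),
        upper = as.numeric(r$upper %||% Inf),
        n = as.integer(r$n %||% 0L),
        logLik = as.numeric(r$logLik %||% NA_real_)))
  names(out) <- vapply(recs, `[[`, "", "relationship")
  out
}
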