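#' Beta-binomial probability mass function
#'
#' Probability of observing `m` positive nodes among `e` examined when
#' each patient's per-node involvement probability is drawn from a
#' Beta(alpha, beta) and nodes are conditionally independent:
#' `C(e, m) * Be(alpha + m, beta + e - m) / Be(alpha, beta)`.
#' Computed in log space (`lchoose` + `lbeta`) so large `e` stays stable.
#' The beta mixing captures between-patient heterogeneity in nodal
#' disease burden (overdispersion relative to a plain binomial).
#'
#' `e = 0` is allowed only with `m = 0` and returns probability 1.
#'
#' @param m Integer vector, positive nodes observed, `0 <= m <= e`.
#' @param e Integer vector, nodes examined.
#' @param alpha,beta Positive shape parameters.
#' @param log If `TRUE`, return log probabilities.
#' @return Numeric vector of (log) probabilities; for fixed `e` the
#'   probabilities over `m = 0..e` sum to 1.
#' @examples
#' dbetabinom(0, 1, 1, 1)        # uniform: 1/2
#' sum(dbetabinom(0:10, 10, 2, 3))  # 1
#' @export
dbetabinom <- function(m, e, alpha, beta, log = FALSE) {
  if (any(alpha <= 0) || any(beta <= 0)) {
    stop("shape parameters must be positive")
  }
  n <- max(length(m), length(e))
  m <- rep_len(as.numeric(m), n)
  e <- rep_len(as.numeric(e), n)
  if (any(m < 0) || any(m > e)) stop("require 0 <= m <= e")
  lp <- lchoose(e, m) + lbeta(alpha + m, beta + e - m) - lbeta(alpha, beta)
  lp[e == 0 & m == 0] <- 0
  if (log) lp else exp(lp)
}

#' Log-likelihood of positive-node counts
#'
#' Sum of beta-binomial log probabilities over `(m, e)` pairs. The
#' fitting set contains node-positive patients only (`m >= 1`); pairs
#' with `m = e` are excluded upstream by [exclude_all_positive()].
#' Identical pairs are aggregated internally so cohorts with many
#' patients at the same `(m, e)` cost one pmf evaluation.
#'
#' @param m,e Integer vectors of equal length, `1 <= m <= e`.
#' @param alpha,beta Positive shapes.
#' @param conditioning `"none"` (default): plain sum of log pmf terms.
#'   `"observed"`: each term is conditioned on the pair being observable
#'   in the fitting set, i.e. on `1 <= m <= e - 1` — the patient was
#'   staged node positive (`m >= 1`) and survived the all-positive
#'   exclusion (`m < e`) — dividing each pmf by
#'   `1 - pmf(0) - pmf(e)`. The conditioned form is the correct
#'   likelihood for data sampled the way the fitting set is assembled;
#'   maximizing the unconditioned form on such data overstates the mean
#'   involved-node fraction and understates the false-negative
#'   probability.
#' @return A finite log-likelihood; if a term underflows, a large
#'   negative sentinel is returned instead of `-Inf` so optimisers can
#'   still compare parameter values.
#' @export
betabinom_loglik <- function(m, e, alpha, beta,
                             conditioning = c("none", "observed")) {
  conditioning <- match.arg(conditioning)
  if (length(m) == 0L) stop("empty observation set")
  stopifnot(length(m) == length(e))
  if (any(m < 1) || any(m > e)) stop("fitting pairs require 1 <= m <= e")
  agg <- aggregate_pairs(m, e)
  lp <- dbetabinom(agg$m, agg$e, alpha, beta, log = TRUE)
  if (conditioning == "observed") {
    if (any(agg$m >= agg$e)) {
      stop("conditioning = \"observed\" requires m < e (all-positive ",
           "pairs are outside the observable window)")
    }
    p0 <- exp(lbeta(alpha, beta + agg$e) - lbeta(alpha, beta))
    pe <- exp(lbeta(alpha + agg$e, beta) - lbeta(alpha, beta))
    lp <- lp - log(pmax(1 - p0 - pe, 1e-300))
  }
  ll <- sum(agg$w * lp)
  if (!is.finite(ll)) ll <- -1e10
  ll
}

# collapse repeated (m, e) pairs into unique rows with weights
aggregate_pairs <- function(m, e) {
  key <- m * 100000 + e
  tab <- tapply(rep(1L, length(key)), key, sum)
  k <- as.numeric(names(tab))
  list(m = k %/% 100000, e = k %% 100000, w = as.numeric(tab))
}

#' Drop patients with every examined node positive
#'
#' Patients whose examined nodes are all positive (`m = e`) are removed
#' before likelihood fitting: for them more examined nodes could only
#' have raised the positive count, and their false-negative probability
#' is identically zero, so they carry no information about the shape
#' parameters' tail. They remain counted in the true-positive tallies
#' used by the false-negative count estimate.
#'
#' @param m,e Integer vectors of equal length.
#' @return A list with `m`, `e` (the kept pairs) and `n_excluded`.
#' @export
exclude_all_positive <- function(m, e) {
  stopifnot(length(m) == length(e))
  keep <- m < e
  list(m = m[keep], e = e[keep], n_excluded = sum(!keep))
}

#' Maximum-likelihood fit of the beta-binomial shapes
#'
#' Estimates `(alpha, beta)` from the positive-node counts of
#' node-positive patients in one T stage. Optimisation runs in
#' unconstrained `(log alpha, log beta)` space (L-BFGS-B bounded to
#' `[1e-4, 1e4]` per shape to keep underdispersed data from diverging),
#' started from a method-of-moments estimate on the `m/e` fractions and
#' falling back to `(1, 1)` when moments degenerate.
#'
#' The default objective conditions each patient's contribution on being
#' observable in the fitting set (`1 <= m <= e - 1`; see
#' [betabinom_loglik()]): the fitting set is assembled from patients
#' staged node positive, with all-positive patients excluded, and
#' ignoring that selection inflates the estimated involved-node fraction
#' and deflates the false-negative probabilities the downstream
#' correction depends on. `conditioning = "none"` reproduces the plain
#' unconditioned fit for comparison.
#'
#' @param m,e Integer vectors: positive and examined node counts of pN+
#'   patients (`1 <= m <= e`). `m = e` pairs are excluded internally and
#'   counted.
#' @param t_stage Optional stage label stored in the result.
#' @param conditioning Likelihood conditioning, `"observed"` (default)
#'   or `"none"`; see [betabinom_loglik()].
#' @return An object of class `nss_fit`: list with `alpha`, `beta`,
#'   `log_likelihood`, `converged`, `n_used`, `n_excluded_all_positive`,
#'   `conditioning`, `t_stage`.
#' @export
fit_betabinom <- function(m, e, t_stage = NA_integer_,
                          conditioning = c("observed", "none")) {
  conditioning <- match.arg(conditioning)
  stopifnot(length(m) == length(e))
  if (any(m < 1) || any(m > e)) stop("fitting pairs require 1 <= m <= e")
  kept <- exclude_all_positive(m, e)
  if (length(kept$m) < 2L) {
    stop("too few usable pairs after excluding all-positive patients; ",
         "pool strata or collect more pN+ patients")
  }
  m <- kept$m; e <- kept$e
  agg <- aggregate_pairs(m, e)

  # method-of-moments start on the observed fractions
  p <- m / e
  mu <- mean(p)
  s2 <- stats::var(p)
  start <- c(1, 1)
  if (is.finite(s2) && s2 > 0 && mu > 0 && mu < 1) {
    nu <- mu * (1 - mu) / s2 - 1
    if (is.finite(nu) && nu > 0) {
      start <- pmin(pmax(c(mu * nu, (1 - mu) * nu), 0.01), 100)
    }
  }

  negll <- function(logpar) {
    a <- exp(logpar[1]); b <- exp(logpar[2])
    lp <- lchoose(agg$e, agg$m) + lbeta(a + agg$m, b + agg$e - agg$m) -
      lbeta(a, b)
    if (conditioning == "observed") {
      p0 <- exp(lbeta(a, b + agg$e) - lbeta(a, b))
      pe <- exp(lbeta(a + agg$e, b) - lbeta(a, b))
      lp <- lp - log(pmax(1 - p0 - pe, 1e-300))
    }
    ll <- sum(agg$w * lp)
    if (!is.finite(ll)) 1e10 else -ll
  }
  opt <- stats::optim(log(start), negll, method = "L-BFGS-B",
                      lower = log(1e-4), upper = log(1e4),
                      control = list(factr = 1e2, maxit = 500))
  structure(list(
    alpha = exp(opt$par[1]),
    beta = exp(opt$par[2]),
    log_likelihood = -opt$value,
    converged = opt$convergence == 0L,
    n_used = length(m),
    n_excluded_all_positive = kept$n_excluded,
    conditioning = conditioning,
    t_stage = t_stage
  ), class = "nss_fit")
}

#' Fit the beta-binomial model in every T stage of a cohort
#'
#' Applies [fit_betabinom()] to the node-positive patients of each
#' stratum present in the cohort.
#'
#' @param cohort An `nss_cohort`.
#' @return A named list (`"1"`, `"2"`, ...) of `nss_fit` objects, one per
#'   T stage present.
#' @export
fit_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "nss_cohort"))
  stages <- sort(unique(cohort$t_stage))
  fits <- lapply(stages, function(t) {
    rows <- cohort[cohort$t_stage == t & cohort$nodes_positive >= 1L, ]
    fit_betabinom(rows$nodes_positive, rows$nodes_examined, t_stage = t)
  })
  names(fits) <- as.character(stages)
  fits
}

#' @export
print.nss_fit <- function(x, ...) {
  cat(sprintf(
    "Beta-binomial fit%s: alpha=%.4f beta=%.4f (mean fraction %.3f)\n",
    if (is.na(x$t_stage)) "" else paste0(" [T", x$t_stage, "]"),
    x$alpha, x$beta, x$alpha / (x$alpha + x$beta)))
  cat(sprintf("  logLik %.3f, converged %s, n=%d used, %d all-positive excluded\n",
              x$log_likelihood, x$converged, x$n_used,
              x$n_excluded_all_positive))
  invisible(x)
}
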