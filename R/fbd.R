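#' Piecewise-constant birth-death-sampling parameters
#'
#' Parameters of the fossilized birth-death (FBD) skyline: per-interval
#' birth (lambda), death (mu) and sampling (psi) rates, the
#' extant-sampling probability rho (default 0: all samples predate the
#' present), and the interval boundaries. Rates are per ka because ages
#' are in ka. Rates and boundaries are given from the oldest interval to
#' the youngest; boundaries are strictly decreasing ages, and the oldest
#' interval extends to the origin.
#'
#' @param lambda,mu,psi numeric vectors of per-interval rates (>= 0),
#'   length = `length(boundaries) + 1`, oldest interval first.
#' @param boundaries strictly decreasing interval boundary ages (ka);
#'   `numeric(0)` for a constant-rate model.
#' @param rho probability of sampling a lineage at the present, in
#'   `[0, 1]`; default 0.
#' @return Object of class `fbd_params`.
#' @export
fbd_params <- function(lambda, mu, psi, boundaries = numeric(0), rho = 0) {
  k <- length(boundaries) + 1L
  stopifnot(length(lambda) == k, length(mu) == k, length(psi) == k,
            rho >= 0, rho <= 1)
  if (any(c(lambda, mu, psi) < 0)) stop("rates must be >= 0")
  if (length(boundaries) > 1L && any(diff(boundaries) >= 0))
    stop("boundaries must be strictly decreasing (oldest first)")
  structure(list(lambda = as.numeric(lambda), mu = as.numeric(mu),
                 psi = as.numeric(psi),
                 boundaries = as.numeric(boundaries), rho = as.numeric(rho)),
            class = "fbd_params")
}

#' Net diversification rate
#'
#' The rate at which the tree grows: `d = lambda - mu`, in
#' `(-Inf, Inf)`.
#'
#' @param lambda,mu birth and death rates (vectorized).
#' @return `lambda - mu`.
#' @export
diversification_rate <- function(lambda, mu) lambda - mu

#' Turnover rate
#'
#' The rate at which lineages are replaced: `t = mu / lambda`, in
#' `(0, Inf)` for positive rates.
#'
#' @param lambda birth rate(s), strictly positive.
#' @param mu death rate(s).
#' @return `mu / lambda`.
#' @export
turnover_rate <- function(lambda, mu) {
  if (any(lambda == 0)) stop("turnover undefined at lambda = 0")
  mu / lambda
}

## Precompute per-interval constants for p0 and the branch propagator q.
## Intervals are handled youngest-first internally: edges
## 0 = e0 < e1 < ... < e_{K-1} < Inf, interval l covers [e_{l-1}, e_l).
## p0(t): probability that a lineage alive at age t leaves no sampled
## descendants. q(t): branch propagator with q(0) = 1,
## d log q / dt = 2 lambda p0(t) - (lambda + mu + psi).
fbd_tables <- function(params) {
  K <- length(params$lambda)
  ## reverse to youngest-first
  lam <- rev(params$lambda); mu <- rev(params$mu); psi <- rev(params$psi)
  edges <- rev(params$boundaries)              # ascending, length K - 1
  A <- B <- pbase <- logqbase <- numeric(K)
  p <- 1 - params$rho
  lq <- 0
  for (l in seq_len(K)) {
    pbase[l] <- p; logqbase[l] <- lq
    if (lam[l] > 0) {
      A[l] <- sqrt((lam[l] - mu[l] - psi[l])^2 + 4 * lam[l] * psi[l])
      B[l] <- ((1 - 2 * p) * lam[l] + mu[l] + psi[l]) / A[l]
    } else {
      A[l] <- mu[l] + psi[l]
      B[l] <- NA_real_
    }
    if (l < K) {
      dl <- edges[l] - if (l > 1L) edges[l - 1L] else 0
      p <- fbd_p0_rel(dl, lam[l], mu[l], psi[l], A[l], B[l], p)
      lq <- lq + fbd_logq_rel(dl, lam[l], mu[l], psi[l], A[l], B[l])
    }
  }
  list(K = K, lam = lam, mu = mu, psi = psi, edges = edges,
       A = A, B = B, pbase = pbase, logqbase = logqbase)
}

## p0 within one interval, delta above the interval's young edge
fbd_p0_rel <- function(delta, lam, mu, psi, A, B, pinit) {
  if (lam > 0) {
    eA <- exp(A * delta)
    (lam + mu + psi - A * (eA * (1 + B) - (1 - B)) / (eA * (1 + B) + (1 - B))) /
      (2 * lam)
  } else if (mu + psi > 0) {
    m <- mu / (mu + psi)
    m + (pinit - m) * exp(-(mu + psi) * delta)
  } else pinit
}

## log q within one interval relative to its young edge (stable form)
fbd_logq_rel <- function(delta, lam, mu, psi, A, B) {
  if (lam > 0) {
    -A * delta + log(4) - 2 * log((1 + B) + (1 - B) * exp(-A * delta))
  } else {
    -(mu + psi) * delta
  }
}

fbd_interval_of <- function(tab, t) findInterval(t, tab$edges) + 1L

fbd_p0 <- function(tab, t) {
  l <- fbd_interval_of(tab, t)
  delta <- t - c(0, tab$edges)[l]
  lam <- tab$lam[l]; mu <- tab$mu[l]; psi <- tab$psi[l]
  A <- tab$A[l]; B <- tab$B[l]; pinit <- tab$pbase[l]
  out <- numeric(length(t))
  pos <- lam > 0
  if (any(pos)) {
    eA <- exp(A[pos] * delta[pos])
    out[pos] <- (lam[pos] + mu[pos] + psi[pos] -
                   A[pos] * (eA * (1 + B[pos]) - (1 - B[pos])) /
                   (eA * (1 + B[pos]) + (1 - B[pos]))) / (2 * lam[pos])
  }
  if (any(!pos)) {
    i <- !pos
    out[i] <- vapply(which(i), function(j)
      fbd_p0_rel(delta[j], lam[j], mu[j], psi[j], A[j], B[j], pinit[j]), 0)
  }
  out
}

fbd_logq <- function(tab, t) {
  l <- fbd_interval_of(tab, t)
  delta <- t - c(0, tab$edges)[l]
  lam <- tab$lam[l]; mu <- tab$mu[l]; psi <- tab$psi[l]
  A <- tab$A[l]; B <- tab$B[l]
  out <- numeric(length(t))
  pos <- lam > 0
  if (any(pos))
    out[pos] <- -A[pos] * delta[pos] + log(4) -
      2 * log((1 + B[pos]) + (1 - B[pos]) * exp(-A[pos] * delta[pos]))
  if (any(!pos))
    out[!pos] <- -(mu[!pos] + psi[!pos]) * delta[!pos]
  tab$logqbase[l] + out
}

fbd_rate_at <- function(tab, what, t)
  tab[[what]][fbd_interval_of(tab, t)]

#' Log density of a sampled tree under the FBD skyline
#'
#' Probability density of an observed sampled-ancestor tree under the
#' fossilized birth-death process with piecewise-constant birth, death
#' and sampling rates, conditioned on the origin time and (by default)
#' on observing at least one sample. Bifurcation events contribute a
#' birth-rate factor, terminal samples a sampling-rate factor times the
#' probability that their continuing lineage is never sampled again, and
#' sampled ancestors a bare sampling-rate factor; every branch carries
#' the no-observed-event propagator between its endpoint ages.
#'
#' @param tree an [sa_tree] (ages in the same units as the rates'
#'   inverse, i.e. ka).
#' @param params an [fbd_params].
#' @param condition `"origin_survival"` (default: condition on the
#'   origin and on at least one sample) or `"origin"` (origin only).
#' @return Log density (`-Inf` for impossible configurations, e.g. a
#'   sample in an interval with zero sampling rate).
#' @export
fbd_log_density <- function(tree, params,
                            condition = c("origin_survival", "origin")) {
  condition <- match.arg(condition)
  stopifnot(inherits(tree, "sa_tree"), inherits(params, "fbd_params"))
  if (tree$origin_age < max(tree$age)) stop("tree is older than its origin")
  samp_ages <- tree$age[tree$is_sample]
  if (params$rho == 0 && any(samp_ages <= 0))
    stop("sample at age <= 0 requires rho > 0")
  tab <- fbd_tables(params)
  bif <- bifurcation_nodes(tree)
  tips <- tip_nodes(tree)
  sas <- sa_nodes(tree)
  lam_b <- fbd_rate_at(tab, "lam", tree$age[bif])
  psi_t <- fbd_rate_at(tab, "psi", tree$age[tips])
  psi_s <- fbd_rate_at(tab, "psi", tree$age[sas])
  if (any(lam_b == 0) || any(psi_t == 0) || any(psi_s == 0)) return(-Inf)
  p0_t <- fbd_p0(tab, tree$age[tips])
  lf <- fbd_logq(tab, tree$origin_age) +
    sum(log(lam_b) + fbd_logq(tab, tree$age[bif])) +
    sum(log(psi_t) + log(p0_t) - fbd_logq(tab, tree$age[tips])) +
    sum(log(psi_s))
  if (condition == "origin_survival") {
    p0_origin <- fbd_p0(tab, tree$origin_age)
    lf <- lf - log1p(-p0_origin)
  }
  lf
}
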