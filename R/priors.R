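#' Prior specification
#'
#' Named prior choices for every block of the model, with the defaults
#' used throughout the analysis: Exp(rate 10, mean 0.1) on each
#' per-interval birth, death and sampling rate; an improper U(0, Inf)
#' on the origin time (zero log-density contribution on its support);
#' N(0, sd 2) on each trait root value; LogNormal(location 1, scale 0.3,
#' log space) on each per-trait variance rate; U(-1, 1) on the shared
#' trait correlation; for the uncorrelated lognormal clock an Exp(10)
#' prior on the mean branch rate and a Gamma(shape 0.54, scale 0.38,
#' mean ~0.2) prior on the log-space spread; for the two-category clock
#' an Exp(5, mean 0.2) prior on each category rate and a uniform prior
#' on branch assignments; uniform tip-age priors within each sample's
#' calibrated one-sigma interval.
#'
#' @param rate_prior_rate exponential rate for lambda/mu/psi priors.
#' @param root_mean,root_sd normal prior on root values.
#' @param sigma2_location,sigma2_scale lognormal prior on variance
#'   rates.
#' @param sigma2_log_space if TRUE (default) location/scale are in log
#'   space; if FALSE the location is the real-space mean.
#' @param clock_mean_rate exponential rate for the ULNC mean branch
#'   rate.
#' @param clock_sd_shape,clock_sd_scale gamma prior on the ULNC
#'   log-space spread.
#' @param ncat_rate exponential rate for the two-category clock's
#'   category rates.
#' @return A `prior_spec` list.
#' @export
prior_spec <- function(rate_prior_rate = 10,
                       root_mean = 0, root_sd = 2,
                       sigma2_location = 1, sigma2_scale = 0.3,
                       sigma2_log_space = TRUE,
                       clock_mean_rate = 10,
                       clock_sd_shape = 0.54, clock_sd_scale = 0.38,
                       ncat_rate = 5) {
  structure(list(rate_prior_rate = rate_prior_rate,
                 root_mean = root_mean, root_sd = root_sd,
                 sigma2_location = sigma2_location,
                 sigma2_scale = sigma2_scale,
                 sigma2_log_space = sigma2_log_space,
                 clock_mean_rate = clock_mean_rate,
                 clock_sd_shape = clock_sd_shape,
                 clock_sd_scale = clock_sd_scale,
                 ncat_rate = ncat_rate),
            class = "prior_spec")
}

dlnorm_spec <- function(x, spec) {
  if (spec$sigma2_log_space) {
    stats::dlnorm(x, meanlog = spec$sigma2_location, sdlog = spec$sigma2_scale,
                  log = TRUE)
  } else {
    ## location given as the real-space mean
    ml <- log(spec$sigma2_location) - spec$sigma2_scale^2 / 2
    stats::dlnorm(x, meanlog = ml, sdlog = spec$sigma2_scale, log = TRUE)
  }
}

#' Relaxed clock states
#'
#' Two relaxed clocks are supported. `ULNC`: every branch rate is an
#' independent draw from a lognormal whose real-space mean M and
#' log-space spread S are estimated. `nCat2`: two estimated rate values
#' and a per-branch category assignment. A strict clock (single shared
#' rate) is available for simulation and fixed-clock runs. The rate is
#' shared across traits.
#'
#' @param model `"ulnc"`, `"ncat2"` or `"strict"`.
#' @param n_branches number of branches (= number of tree nodes; the
#'   origin-to-root stem counts as a branch).
#' @param M,S ULNC mean branch rate (real space) and log-space spread.
#' @param rates explicit per-branch rates (ULNC) — drawn from the
#'   lognormal if missing.
#' @param r1,r2 nCat2 category rate values.
#' @param categories integer vector of per-branch assignments in {1, 2}.
#' @param rate strict-clock rate.
#' @param seed seed for drawing missing ULNC rates / categories.
#' @return Object of class `clock_state` with a `rates` accessor field.
#' @export
clock_state <- function(model = c("ulnc", "ncat2", "strict"), n_branches,
                        M = 0.1, S = 0.2, rates = NULL,
                        r1 = 0.2, r2 = 0.2, categories = NULL,
                        rate = 1, seed = 1) {
  model <- match.arg(model)
  cl <- switch(model,
    ulnc = {
      if (is.null(rates))
        rates <- with_seed(seed, stats::rlnorm(n_branches, log(M) - S^2 / 2, S))
      list(model = "ulnc", M = M, S = S, rates = as.numeric(rates))
    },
    ncat2 = {
      if (is.null(categories))
        categories <- with_seed(seed, sample(1:2, n_branches, replace = TRUE))
      list(model = "ncat2", r1 = r1, r2 = r2, categories = as.integer(categories))
    },
    strict = list(model = "strict", rate = rate))
  structure(cl, class = "clock_state")
}

#' Per-branch rates of a clock state
#'
#' @param clock a [clock_state].
#' @param n_branches branch count (needed for the strict clock).
#' @return Numeric vector of branch rates.
#' @export
clock_rates <- function(clock, n_branches = NULL) {
  switch(clock$model,
         ulnc = clock$rates,
         ncat2 = c(clock$r1, clock$r2)[clock$categories],
         strict = rep(clock$rate, n_branches))
}

#' Log prior density of a clock state
#'
#' ULNC: lognormal log densities of all branch rates given (M, S), plus
#' the Exp hyperprior on M and the Gamma hyperprior on S. nCat2: Exp
#' prior on each category rate value plus log(1/2) per branch
#' assignment. Off-support states return `-Inf`.
#'
#' @param clock a [clock_state].
#' @param spec a [prior_spec].
#' @return Log density.
#' @export
clock_log_prior <- function(clock, spec = prior_spec()) {
  if (clock$model == "ulnc") {
    if (clock$M <= 0 || clock$S <= 0 || any(clock$rates <= 0)) return(-Inf)
    sum(stats::dlnorm(clock$rates, log(clock$M) - clock$S^2 / 2, clock$S,
                      log = TRUE)) +
      stats::dexp(clock$M, spec$clock_mean_rate, log = TRUE) +
      stats::dgamma(clock$S, shape = spec$clock_sd_shape,
                    scale = spec$clock_sd_scale, log = TRUE)
  } else if (clock$model == "ncat2") {
    if (clock$r1 <= 0 || clock$r2 <= 0) return(-Inf)
    stats::dexp(clock$r1, spec$ncat_rate, log = TRUE) +
      stats::dexp(clock$r2, spec$ncat_rate, log = TRUE) +
      length(clock$categories) * log(0.5)
  } else {
    0
  }
}

#' Joint log prior of a full model state
#'
#' Sums the log prior densities of every block: Exp priors on each
#' per-interval birth/death/sampling rate, the (improper, flat) origin
#' prior, normal priors on root values, lognormal priors on variance
#' rates, the uniform correlation prior with the positive-definiteness
#' constraint, the clock prior, and uniform tip-age priors within each
#' sample's calibrated interval. Parameters off their support give
#' `-Inf`.
#'
#' @param state a model state as used by [run_mcmc()]: a list with
#'   `tree`, `lambda`, `mu`, `psi`, `root`, `sigma2`, `corr`, `clock`.
#' @param spec a [prior_spec].
#' @param age_bounds optional data.frame (`taxon_id`, `age_min`,
#'   `age_max`, model time) giving each sample's uniform age prior;
#'   omit for fixed tip ages.
#' @return Log prior density.
#' @export
evaluate_priors <- function(state, spec = prior_spec(), age_bounds = NULL) {
  r <- spec$rate_prior_rate
  rates <- c(state$lambda, state$mu, state$psi)
  if (any(rates < 0)) return(-Inf)
  lp <- sum(stats::dexp(rates, r, log = TRUE))
  ## origin: U(0, Inf), flat on its support
  if (state$tree$origin_age <= 0 ||
      state$tree$origin_age < max(state$tree$age)) return(-Inf)
  lp <- lp + sum(stats::dnorm(state$root, spec$root_mean, spec$root_sd,
                              log = TRUE))
  if (any(state$sigma2 <= 0)) return(-Inf)
  lp <- lp + sum(dlnorm_spec(state$sigma2, spec))
  k <- length(state$sigma2)
  if (state$corr <= -1 || state$corr >= 1) return(-Inf)
  if (k > 1L && state$corr <= -1 / (k - 1)) return(-Inf)  # non-PD Sigma
  lp <- lp + stats::dunif(state$corr, -1, 1, log = TRUE)
  lp <- lp + clock_log_prior(state$clock, spec)
  if (!is.null(age_bounds)) {
    samp <- which(state$tree$is_sample)
    idx <- match(state$tree$label[samp], age_bounds$taxon_id)
    if (anyNA(idx)) stop("age bounds missing for some samples")
    a <- state$tree$age[samp]
    lo <- age_bounds$age_min[idx]; hi <- age_bounds$age_max[idx]
    if (any(a < lo - 1e-12 | a > hi + 1e-12)) return(-Inf)
    w <- hi - lo
    lp <- lp + sum(-log(w[w > 0]))
  }
  lp
}
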