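test_that("sa_tree validates its structural invariants", {
  expect_error(sa_tree(c(NA, 1), c(1, 2), c(TRUE, TRUE), c("A", "B"), 3),
               "parent ages")
  expect_error(sa_tree(c(NA, 1), c(2, 1), c(TRUE, TRUE), c("A", "B"), 1.5),
               "origin_age")
  expect_error(sa_tree(c(NA, 1, 1, 1), c(3, 1, 1.2, 0.5), rep(TRUE, 4),
                       letters[1:4], 4), "at most two")
  ## unsampled degree-1 node forbidden
  expect_error(sa_tree(c(NA, 1), c(2, 1), c(FALSE, TRUE), c(NA, "B"), 3),
               "bifurcations")
  tr <- quartet_tree()
  expect_equal(length(fbdshape:::tip_nodes(tr)), 4)
  expect_equal(length(fbdshape:::sa_nodes(tr)), 0)
  ch <- chain_tree()
  expect_equal(fbdshape:::sa_nodes(ch), 1L)
})

test_that("newick round trip preserves sampled-ancestor trees", {
  for (tr in list(chain_tree(), quartet_tree(),
                  random_sa_tree(5, min_samples = 4, max_samples = 10))) {
    txt <- write_sa_newick(tr)
    back <- read_sa_newick(txt, origin_age = tr$origin_age)
    expect_equal(sort(fbdshape:::sample_labels(back)),
                 sort(fbdshape:::sample_labels(tr)))
    expect_equal(length(fbdshape:::sa_nodes(back)),
                 length(fbdshape:::sa_nodes(tr)))
    ## ages preserved (match by label)
    s1 <- which(tr$is_sample); s2 <- which(back$is_sample)
    m <- match(tr$label[s1], back$label[s2])
    expect_equal(back$age[s2][m], tr$age[s1], tolerance = 1e-6)
    expect_equal(fbd_log_density(back, fbd_params(0.5, 0.2, 0.4)),
                 fbd_log_density(tr, fbd_params(0.5, 0.2, 0.4)),
                 tolerance = 1e-6)
  }
})

## independent closed-form oracle for the constant-rate process, coded
## in the classical (c1, c2) algebra
oracle_p0 <- function(t, l, m, s) {
  c1 <- sqrt((l - m - s)^2 + 4 * l * s)
  c2 <- -(l - m - s) / c1
  e <- exp(-c1 * t)
  (l + m + s + c1 * (e * (1 - c2) - (1 + c2)) / (e * (1 - c2) + (1 + c2))) /
    (2 * l)
}
oracle_q <- function(t, l, m, s) {
  c1 <- sqrt((l - m - s)^2 + 4 * l * s)
  c2 <- -(l - m - s) / c1
  e <- exp(-c1 * t)
  4 * e / (e * (1 - c2) + (1 + c2))^2
}

test_that("constant-rate FBD density matches the hand-coded closed form", {
  l <- 0.5; m <- 0.2; s <- 0.4
  ## two-sample chain: sampled ancestor at x over a tip at y
  x <- 2; y <- 1; x0 <- 3
  tr <- chain_tree(x, y, x0)
  expected <- log(oracle_q(x0, l, m, s)) + log(s) +
    log(s * oracle_p0(y, l, m, s) / oracle_q(y, l, m, s)) -
    log(1 - oracle_p0(x0, l, m, s))
  expect_equal(fbd_log_density(tr, fbd_params(l, m, s)), expected,
               tolerance = 1e-10)
  ## quartet with three bifurcations: full event-factor assembly
  tr2 <- quartet_tree()
  bifs <- c(2.0, 1.6, 3.0)
  tips <- c(1.0, 0.2, 0.8, 0.4)
  expected2 <- log(oracle_q(3.6, l, m, s)) +
    sum(log(l * oracle_q(bifs, l, m, s))) +
    sum(log(s * oracle_p0(tips, l, m, s) / oracle_q(tips, l, m, s))) -
    log(1 - oracle_p0(3.6, l, m, s))
  expect_equal(fbd_log_density(tr2, fbd_params(l, m, s)), expected2,
               tolerance = 1e-10)
})

test_that("piecewise p0 and the branch propagator match ODE integration", {
  p <- fbd_params(c(0.7, 0.3), c(0.2, 0.4), c(0.5, 0.25), boundaries = 2.0)
  tab <- fbdshape:::fbd_tables(p)
  rate_at <- function(t) {
    i <- findInterval(t, 2.0) + 1L
    c(rev(p$lambda)[i], rev(p$mu)[i], rev(p$psi)[i])
  }
  deriv <- function(t, y, parms) {
    r <- rate_at(t)
    list(c(r[2] - (r[1] + r[2] + r[3]) * y[1] + r[1] * y[1]^2,
           2 * r[1] * y[1] - (r[1] + r[2] + r[3])))
  }
  times <- c(0, 0.8, 1.5, 2.0, 2.7, 3.5)
  out <- deSolve::ode(c(1, 0), times, deriv, NULL, method = "ode45",
                      atol = 1e-12, rtol = 1e-12)
  for (i in 2:nrow(out)) {
    expect_equal(fbdshape:::fbd_p0(tab, out[i, 1]), unname(out[i, 2]),
                 tolerance = 1e-8)
    expect_equal(fbdshape:::fbd_logq(tab, out[i, 1]), unname(out[i, 3]),
                 tolerance = 1e-8)
  }
})

test_that("a skyline with equal rates reduces to the constant-rate density", {
  trees <- list(chain_tree(), quartet_tree(),
                random_sa_tree(9, min_samples = 4, max_samples = 12))
  pc <- fbd_params(0.45, 0.15, 0.35)
  ps <- fbd_params(rep(0.45, 4), rep(0.15, 4), rep(0.35, 4),
                   boundaries = c(2.4, 1.5, 0.6))
  for (tr in trees)
    expect_equal(fbd_log_density(tr, ps), fbd_log_density(tr, pc),
                 tolerance = 1e-10)
})

test_that("impossible configurations are -Inf, invalid inputs error", {
  tr <- quartet_tree()
  ## no sampling anywhere but fossil samples present
  expect_equal(fbd_log_density(tr, fbd_params(0.5, 0.2, 0)), -Inf)
  ## sampling zero only in an interval holding samples
  ps <- fbd_params(c(0.5, 0.5), c(0.2, 0.2), c(0.4, 0), boundaries = 0.3)
  expect_equal(fbd_log_density(tr, ps), -Inf)
  ## tree older than stated origin
  bad <- tr; bad$origin_age <- 1.0
  expect_error(fbd_log_density(structure(bad, class = "sa_tree"),
                               fbd_params(0.5, 0.2, 0.4)), "older")
  ## sample at the present with rho = 0
  tr0 <- sa_tree(c(NA, 1L), c(1, 0), c(TRUE, TRUE), c("A", "B"), 2)
  expect_error(fbd_log_density(tr0, fbd_params(0.5, 0.2, 0.4)), "rho")
})

test_that("FBD density is invariant to child order and node relabelling", {
  tr <- quartet_tree()
  p <- fbd_params(c(0.6, 0.3), c(0.25, 0.1), c(0.5, 0.3), boundaries = 1.2)
  ref <- fbd_log_density(tr, p)
  ## permute node storage order
  perm <- c(7L, 5L, 6L, 1L, 2L, 3L, 4L)
  inv <- order(perm)
  tr2 <- sa_tree(parent = ifelse(is.na(tr$parent[perm]), NA_integer_,
                                 inv[tr$parent[perm]]),
                 age = tr$age[perm], is_sample = tr$is_sample[perm],
                 label = tr$label[perm], origin_age = tr$origin_age)
  expect_equal(fbd_log_density(tr2, p), ref, tolerance = 1e-12)
})

test_that("diversification and turnover follow their formulas", {
  expect_equal(diversification_rate(0.2, 0.05), 0.15)
  expect_equal(diversification_rate(0.3, 0.3), 0)
  expect_equal(diversification_rate(0.1, 0.4),
               -diversification_rate(0.4, 0.1))
  expect_equal(turnover_rate(0.2, 0.05), 0.25)
  expect_equal(turnover_rate(0.2, 0), 0)
  ## scale invariance
  expect_equal(turnover_rate(3 * 0.2, 3 * 0.05), turnover_rate(0.2, 0.05))
  expect_error(turnover_rate(0, 0.1), "lambda")
})

test_that("Brownian pruning equals the dense Kronecker oracle on random trees", {
  set.seed(99)
  worst <- 0
  for (case in 1:100) {
    tr <- random_sa_tree(case, min_samples = 3, max_samples = 8)
    k <- sample(1:3, 1)
    corr <- runif(1, -0.3, 0.8)
    if (k > 1) corr <- max(corr, -1 / (k - 1) + 0.05)
    bm <- bm_params(rnorm(k), runif(k, 0.3, 2), if (k > 1) corr else 0)
    rates <- rlnorm(length(tr$parent), log(0.5), 0.4)
    tm <- simulate_bm_traits(tr, bm, rates, seed = case)
    a <- bm_log_likelihood(tr, tm, bm, rates)
    b <- bm_log_likelihood_dense(tr, tm, bm, rates)
    worst <- max(worst, abs(a - b))
  }
  expect_lt(worst, 1e-8)
})

test_that("with zero correlation the likelihood factorizes across traits", {
  tr <- random_sa_tree(3, min_samples = 4, max_samples = 8)
  bm <- bm_params(c(0.1, -0.5, 1), c(0.8, 1.2, 0.5), 0)
  rates <- rep(0.7, length(tr$parent))
  tm <- simulate_bm_traits(tr, bm, rates, seed = 31)
  joint <- bm_log_likelihood(tr, tm, bm, rates)
  parts <- vapply(1:3, function(j) {
    bm1 <- bm_params(bm$root[j], bm$sigma2[j], 0)
    tm1 <- trait_matrix(tm$values[, j, drop = FALSE], taxa = tm$taxa)
    bm_log_likelihood(tr, tm1, bm1, rates)
  }, 0)
  expect_equal(joint, sum(parts), tolerance = 1e-10)
})

test_that("single-sample Brownian density is the analytic normal", {
  ## one tip at age y below the origin: variance = sigma2 * rate * path
  tr <- sa_tree(c(NA, 1L), c(1.5, 0.5), c(TRUE, TRUE), c("A", "B"), 3)
  bm <- bm_params(0.3, 0.9, 0)
  tm <- trait_matrix(matrix(c(0.8, -0.2), 2, 1,
                            dimnames = list(c("A", "B"), "PC1")),
                     taxa = c("A", "B"))
  rate <- 0.6
  ll <- bm_log_likelihood(tr, tm, bm, rep(rate, 2))
  ## chain: A observed at depth (3 - 1.5), B at further (1.5 - 0.5)
  v1 <- 0.9 * rate * (3 - 1.5)
  v2 <- 0.9 * rate * (1.5 - 0.5)
  expected <- dnorm(0.8, 0.3, sqrt(v1), log = TRUE) +
    dnorm(-0.2, 0.8, sqrt(v2), log = TRUE)
  expect_equal(ll, expected, tolerance = 1e-12)
})

test_that("degenerate trait models are rejected", {
  expect_error(bm_params(c(0, 0, 0), c(1, 1, 1), -0.9), "positive definite")
  tr <- chain_tree()
  bm <- bm_params(0, 1, 0)
  tm <- trait_matrix(matrix(0.5, 1, 1, dimnames = list("A", NULL)),
                     taxa = "A")
  expect_error(bm_log_likelihood(tr, tm, bm), "missing trait rows")
})

test_that("zero variance rates pin every sample at the root values", {
  tr <- random_sa_tree(12, min_samples = 4, max_samples = 8)
  bm <- bm_params(c(1.5, -2), c(1e-12, 1e-12), 0)
  tm <- simulate_bm_traits(tr, bm, 1, seed = 4)
  expect_equal(unname(tm$values),
               matrix(rep(c(1.5, -2), each = nrow(tm$values)),
                      ncol = 2), tolerance = 1e-4)
})

test_that("simulated Brownian increments have the stated moments", {
  ## star-like check on a chain: tip variance over replicates ~ sigma2*tau
  reps <- 400
  x <- vapply(1:reps, function(i) {
    tm <- simulate_bm_traits(chain_tree(2, 1, 3), bm_params(0, 1.3, 0),
                             rates = 1, seed = i)
    tm$values[tm$taxa == "B", 1]
  }, 0)
  ## B sits 2 time units below the origin
  expect_equal(var(x), 1.3 * 2, tolerance = 0.25)
  ## cross-trait correlation of increments
  y <- t(vapply(1:reps, function(i) {
    tm <- simulate_bm_traits(chain_tree(2, 1, 3), bm_params(c(0, 0),
                             c(1, 1), 0.9), rates = 1, seed = 5000 + i)
    tm$values[tm$taxa == "B", ]
  }, c(0, 0)))
  expect_equal(cor(y)[1, 2], 0.9, tolerance = 0.05)
})

test_that("prior evaluation covers every block and its support", {
  tr <- quartet_tree()
  st <- list(tree = tr, lambda = rep(0.1, 2), mu = rep(0.05, 2),
             psi = rep(0.2, 2), root = c(0.5, -0.5),
             sigma2 = c(2, 3), corr = 0.2,
             clock = clock_state("strict", rate = 0.5))
  sp <- prior_spec()
  lp <- evaluate_priors(st, sp)
  manual <- sum(dexp(c(st$lambda, st$mu, st$psi), 10, log = TRUE)) +
    sum(dnorm(st$root, 0, 2, log = TRUE)) +
    sum(dlnorm(st$sigma2, 1, 0.3, log = TRUE)) +
    dunif(0.2, -1, 1, log = TRUE)
  expect_equal(lp, manual, tolerance = 1e-12)
  ## off-support states are -Inf, not errors
  bad <- st; bad$corr <- 1.5
  expect_equal(evaluate_priors(bad, sp), -Inf)
  bad <- st; bad$sigma2[1] <- -1
  expect_equal(evaluate_priors(bad, sp), -Inf)
  bad <- st; bad$lambda[1] <- -0.1
  expect_equal(evaluate_priors(bad, sp), -Inf)
  ## tip-age bounds: inside contributes -log(width), outside -Inf
  ab <- data.frame(taxon_id = c("A", "B", "C", "D"),
                   age_min = c(0.9, 0.1, 0.7, 0.3),
                   age_max = c(1.1, 0.3, 0.9, 0.5))
  expect_equal(evaluate_priors(st, sp, ab), manual + 4 * -log(0.2),
               tolerance = 1e-12)
  ab$age_max[1] <- 0.95  # now tip A (age 1.0) is outside
  expect_equal(evaluate_priors(st, sp, ab), -Inf)
})

test_that("the Exp(10) rate prior has mean 0.1", {
  ## parametrized by rate: mean is 1/rate
  g <- seq(0, 10, by = 1e-3)
  expect_equal(sum(g * dexp(g, 10)) * 1e-3, 0.1, tolerance = 1e-3)
})

test_that("clock priors match their analytic forms", {
  cl <- clock_state("ulnc", 6, M = 0.15, S = 0.3,
                    rates = c(0.1, 0.2, 0.15, 0.12, 0.3, 0.09))
  sp <- prior_spec()
  manual <- sum(dlnorm(cl$rates, log(0.15) - 0.3^2 / 2, 0.3, log = TRUE)) +
    dexp(0.15, 10, log = TRUE) +
    dgamma(0.3, shape = 0.54, scale = 0.38, log = TRUE)
  expect_equal(clock_log_prior(cl, sp), manual, tolerance = 1e-12)
  ## nCat2: Exp(5) on the rate values plus log(1/2) per branch
  c2 <- clock_state("ncat2", 7, r1 = 0.1, r2 = 0.4,
                    categories = c(1, 2, 1, 1, 2, 2, 1))
  expect_equal(clock_log_prior(c2, sp),
               dexp(0.1, 5, log = TRUE) + dexp(0.4, 5, log = TRUE) +
                 7 * log(0.5), tolerance = 1e-12)
  ## ULNC concentrates at its mean as S -> 0
  cl2 <- clock_state("ulnc", 3, M = 0.2, S = 1e-5,
                     rates = rep(0.2, 3))
  expect_gt(clock_log_prior(cl2, sp), clock_log_prior(cl, sp))
  ## off support
  cl$rates[1] <- -1
  expect_equal(clock_log_prior(cl, sp), -Inf)
})
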