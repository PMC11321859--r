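test_that("ESS behaves like a spectral estimator should", {
  set.seed(5)
  x <- rnorm(10000)
  e <- ess(x)
  expect_gt(e, 9000); expect_lte(e, 10000)
  ## AR(1): ESS ~ n (1 - phi) / (1 + phi)
  phi <- 0.9
  y <- as.numeric(stats::arima.sim(list(ar = phi), 20000))
  expect_equal(ess(y), 20000 * (1 - phi) / (1 + phi), tolerance = 0.35)
  ## clamped at n; degenerate flagged
  expect_lte(ess(rnorm(50)), 50)
  cst <- ess(rep(3.2, 100))
  expect_equal(as.numeric(cst), 100)
  expect_true(attr(cst, "degenerate"))
  expect_error(ess(1:5), "at least 10")
})

test_that("combine_logs removes burn-in and concatenates", {
  mk <- function(vals) {
    structure(list(table = data.frame(generation = seq_along(vals),
                                      posterior = vals, likelihood = 0,
                                      prior = vals),
                   trees = as.list(seq_along(vals)),
                   config = mcmc_config(seed = 1)),
              class = "posterior_trace")
  }
  a <- mk(rnorm(1000)); b <- mk(rnorm(1000))
  comb <- combine_logs(list(a, b), 0.20)
  expect_equal(nrow(comb$table), 1600)
  expect_length(comb$trees, 1600)
  ## single chain: just truncation
  expect_equal(nrow(combine_logs(list(a), 0.2)$table), 800)
  ## combined mean is the mean of the post-burn-in chains
  expect_equal(mean(comb$table$posterior),
               mean(c(a$table$posterior[201:1000],
                      b$table$posterior[201:1000])), tolerance = 1e-12)
  b2 <- b; colnames(b2$table)[2] <- "other"
  expect_error(combine_logs(list(a, b2)), "schema")
})

test_that("convergence_report applies the ESS threshold to the core columns", {
  mk <- function(n) {
    structure(list(table = data.frame(generation = 1:n,
                                      posterior = rnorm(n),
                                      likelihood = rnorm(n),
                                      prior = rnorm(n)),
                   trees = vector("list", n),
                   config = mcmc_config(seed = 1)),
              class = "posterior_trace")
  }
  good <- convergence_report(mk(5000))
  expect_true(attr(good, "pass"))
  bad <- convergence_report(mk(50))
  expect_false(attr(bad, "pass"))
  expect_true(all(c("chain", "column", "ess") %in% colnames(good)))
  ## reproducible from the same trace
  expect_identical(convergence_report(mk(500))$ess,
                   convergence_report(mk(500))$ess)
})

test_that("runs are reproducible and internally consistent", {
  res <- make_study_scenario(16, seed = 3)
  cfg <- mcmc_config(n_generations = 1200, sample_every = 10, seed = 21)
  t1 <- run_mcmc(res$traits, res$samples, present_bp = res$present_bp,
                 config = cfg)
  t2 <- run_mcmc(res$traits, res$samples, present_bp = res$present_bp,
                 config = cfg)
  expect_identical(t1$table, t2$table)
  ## posterior = likelihood + prior on the log scale, every row
  expect_lt(max(abs(t1$table$posterior - t1$table$likelihood -
                      t1$table$prior)), 1e-8)
  ## rows equally spaced in generations
  expect_equal(unique(diff(t1$table$generation)), 10)
  ## sampled trees stay valid and within their age bounds
  for (tr in t1$table$origin) expect_gt(tr, 0)
  lastree <- t1$trees[[length(t1$trees)]]
  expect_silent(fbdshape:::validate_sa_tree(lastree))
  b <- res$samples
  samp <- which(lastree$is_sample)
  j <- match(lastree$label[samp], b$taxon_id)
  expect_true(all(lastree$age[samp] + res$present_bp >= b$age_min[j] - 1e-6))
  expect_true(all(lastree$age[samp] + res$present_bp <= b$age_max[j] + 1e-6))
})

test_that("under the prior the trait likelihood is off and untouched", {
  res <- make_study_scenario(16, seed = 3)
  cfg <- mcmc_config(n_generations = 1500, sample_every = 10, seed = 8,
                     under_prior = TRUE)
  tr <- run_mcmc(res$traits, res$samples, present_bp = res$present_bp,
                 config = cfg)
  expect_true(all(tr$table$likelihood == 0))
  expect_equal(tr$table$posterior, tr$table$prior)
})

test_that("tree-free prior-only sampling reproduces the analytic priors", {
  res <- make_study_scenario(16, seed = 3)
  cfg <- mcmc_config(n_generations = 60000, sample_every = 30, seed = 17,
                     tree_free = TRUE, under_prior = TRUE)
  tr <- run_mcmc(res$traits, res$samples, present_bp = res$present_bp,
                 config = cfg)
  tab <- tr$table[-seq_len(400), ]
  k <- ncol(res$traits$values)
  checks <- list(
    lambda_1 = 0.1, mu_2 = 0.1, psi_4 = 0.1, clock_M = 0.1,
    sigma2_1 = exp(1 + 0.3^2 / 2),
    corr = (1 - 1 / (k - 1)) / 2,        # U(-1,1) truncated to PD states
    root_1 = 0,
    clock_S = 0.54 * 0.38)
  for (cn in names(checks)) {
    x <- tab[[cn]]
    z <- (mean(x) - checks[[cn]]) / (sd(x) / sqrt(ess(x)))
    expect_lt(abs(z), 5)
  }
  ## distributional agreement on a thinned subsample
  thin <- tab$psi_2[seq(1, nrow(tab), by = 25)]
  ks <- suppressWarnings(stats::ks.test(thin, stats::pexp, 10))
  expect_gt(ks$p.value, 0.01)
})

test_that("fixed-tree rate posteriors match a grid-integration oracle", {
  sc <- sim_scenario(0.6, 0.2, 0.7, origin_age = 3, seed = 21)
  tr0 <- simulate_fbd_tree(sc, min_samples = 5)
  labs <- fbdshape:::sample_labels(tr0)
  samp <- which(tr0$is_sample)
  tm <- trait_matrix(matrix(0, length(labs), 1), taxa = labs)
  ds <- dated_samples(labs, labs, tr0$age[samp], tr0$age[samp],
                      tr0$age[samp])
  cfg <- mcmc_config(n_generations = 120000, sample_every = 40, seed = 4,
                     under_prior = TRUE, fixed_topology = TRUE,
                     fixed_tip_ages = TRUE,
                     move_weights = c(node_age = 0, origin_slide = 0))
  trc <- run_mcmc(tm, ds, boundaries_bp = numeric(0), present_bp = 0,
                  config = cfg)
  trX <- trc$trees[[1]]
  gl <- seq(0.01, 4, length.out = 42)
  gm <- seq(0.005, 2, length.out = 30)
  gp <- seq(0.01, 2.5, length.out = 36)
  arr <- array(0, c(42, 30, 36))
  for (i in seq_along(gl)) for (j in seq_along(gm)) for (h in seq_along(gp))
    arr[i, j, h] <- fbd_log_density(trX, fbd_params(gl[i], gm[j], gp[h])) +
      dexp(gl[i], 10, log = TRUE) + dexp(gm[j], 10, log = TRUE) +
      dexp(gp[h], 10, log = TRUE)
  w <- exp(arr - max(arr)); w <- w / sum(w)
  oracle <- c(sum(apply(w, 1, sum) * gl), sum(apply(w, 2, sum) * gm),
              sum(apply(w, 3, sum) * gp))
  tab <- trc$table[-seq_len(500), ]
  for (i in 1:3) {
    x <- tab[[c("lambda_1", "mu_1", "psi_1")[i]]]
    z <- (mean(x) - oracle[i]) / (sd(x) / sqrt(ess(x)))
    expect_lt(abs(z), 5)
  }
})

test_that("trace and tree logs survive their file round trips", {
  res <- make_study_scenario(16, seed = 3)
  cfg <- mcmc_config(n_generations = 600, sample_every = 20, seed = 2)
  tr <- run_mcmc(res$traits, res$samples, present_bp = res$present_bp,
                 config = cfg)
  p1 <- withr::local_tempfile(fileext = ".log")
  write_trace(tr, p1)
  back <- read_trace(p1)
  expect_equal(back$posterior, tr$table$posterior, tolerance = 1e-10)
  p2 <- withr::local_tempfile(fileext = ".trees")
  write_tree_log(tr$trees[1:5], p2)
  trees <- read_tree_log(p2)
  expect_length(trees, 5)
  expect_setequal(fbdshape:::sample_labels(trees[[1]]),
                  fbdshape:::sample_labels(tr$trees[[1]]))
})

test_that("alternative clock models run through the sampler", {
  res <- make_study_scenario(16, seed = 3)
  for (cm in c("ncat2", "strict")) {
    cfg <- mcmc_config(n_generations = 800, sample_every = 20, seed = 3)
    tr <- run_mcmc(res$traits, res$samples, present_bp = res$present_bp,
                   clock_model = cm, config = cfg)
    expect_lt(max(abs(tr$table$posterior - tr$table$likelihood -
                        tr$table$prior)), 1e-8)
    if (cm == "ncat2") {
      expect_true(all(c("clock_r1", "clock_r2") %in% colnames(tr$table)))
      expect_true(all(tr$table$clock_r1 > 0 & tr$table$clock_r2 > 0))
    } else {
      expect_true("clock_rate" %in% colnames(tr$table))
    }
  }
})
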