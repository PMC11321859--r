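test_that("scenario construction validates its invariants", {
  expect_error(sim_scenario(-0.1, 0.1, 0.1, origin_age = 4), ">= 0")
  expect_error(sim_scenario(c(0.1, 0.2), c(0.1, 0.1), c(0.1, 0.1),
                            interval_boundaries = 5, origin_age = 4),
               "origin_age")
  sc <- sim_scenario(0.3, 0.1, 0.2, origin_age = 4)
  expect_s3_class(sc, "sim_scenario")
})

test_that("no sampling anywhere means no tree", {
  sc <- sim_scenario(0.3, 0.1, 0, origin_age = 4)
  expect_error(simulate_fbd_tree(sc), "no samples possible")
})

test_that("without branching or death, samples form a chain of ancestors", {
  sc <- sim_scenario(0, 0, 0.8, origin_age = 6, seed = 2)
  tr <- simulate_fbd_tree(sc, min_samples = 3)
  n_samp <- sum(tr$is_sample)
  ## all samples except the most recent are sampled ancestors
  expect_equal(length(fbdshape:::sa_nodes(tr)), n_samp - 1L)
  expect_equal(length(fbdshape:::tip_nodes(tr)), 1L)
  ## strictly ordered ages down the chain
  expect_true(all(diff(tr$age[fbdshape:::postorder(tr)]) > 0))
})

test_that("rejection failure is reported with the scenario", {
  sc <- sim_scenario(0, 0, 0.0001, origin_age = 0.5, seed = 3)
  expect_error(simulate_fbd_tree(sc, min_samples = 5, max_attempts = 20),
               "20 attempts")
})

test_that("sample counts match an independent event-count oracle", {
  l <- 0.4; m <- 0.1; s <- 0.3; origin <- 15
  n <- 150
  sc0 <- sim_scenario(l, m, s, origin_age = origin, seed = 1)
  counts <- vapply(seq_len(n), function(i) {
    sc <- sc0; sc$seed <- i
    sum(simulate_fbd_tree(sc)$is_sample)
  }, 0)
  set.seed(404)
  oracle <- vapply(seq_len(n), function(i)
    oracle_sample_count(l, m, s, origin), 0)
  ## means agree within combined Monte-Carlo error (3.5 sigma)
  se <- sqrt(var(counts) / n + var(oracle) / n)
  expect_lt(abs(mean(counts) - mean(oracle)), 3.5 * se)
})

test_that("the generator is a fixed function of the seed", {
  a <- make_study_scenario(16, seed = 11)
  b <- make_study_scenario(16, seed = 11)
  expect_identical(a, b)
  c <- make_study_scenario(16, seed = 12)
  expect_false(identical(a$tree, c$tree))
})

test_that("the study window and stratification contracts hold", {
  res <- make_study_scenario(16, seed = 3)
  expect_equal(as.integer(table(res$samples$bin)), rep(4L, 4))
  expect_equal(nrow(res$samples), 16)
  ## every emitted age within the 15-11 ka window
  expect_true(all(res$samples$median_age >= 11 &
                  res$samples$median_age <= 15))
  true_bp <- res$tree$age[which(res$tree$is_sample)] + res$present_bp
  expect_true(all(true_bp >= 11 & true_bp <= 15))
  ## one trait row per sample, matching labels
  expect_setequal(res$traits$taxa, res$samples$taxon_id)
  expect_equal(nrow(res$traits$values), 16)
  ## per-locale date tables exist and are non-empty
  expect_setequal(names(res$c14_tables), res$samples$locale_id |>
                    sub(pattern = "^L_", replacement = ""))
  expect_true(all(vapply(res$c14_tables, nrow, 1L) >= 1L))
})

test_that("radiocarbon simulation has the stated error structure", {
  g <- seq(10, 16, by = 0.01)
  ideal <- cal_curve(g, g, rep(0, length(g)))
  ## no lab error, no curve error: dates equal the curve mean exactly
  d <- simulate_radiocarbon(13.2, ideal, lab_error = 0, n_dates = 5, seed = 1)
  expect_equal(d$c14_age, rep(13.2, 5))
  expect_equal(nrow(simulate_radiocarbon(13, ideal, 0.05, 0, seed = 1)), 0)
  expect_error(simulate_radiocarbon(9, ideal, 0.05, 1, seed = 1), "outside")
  ## empirical sd ~ sqrt(lab^2 + curve^2)
  wig <- make_synthetic_calcurve(10, 16, wiggle_amplitude = 0.05, seed = 2,
                                 curve_error = 0.03)
  d2 <- simulate_radiocarbon(13.2, wig, lab_error = 0.04, n_dates = 1000,
                             seed = 9)
  expect_equal(sd(d2$c14_age), sqrt(0.04^2 + 0.03^2), tolerance = 0.08)
})

test_that("the synthetic calibration curve behaves like a calibration curve", {
  flat <- make_synthetic_calcurve(10, 16, wiggle_amplitude = 0, seed = 1)
  expect_equal(flat$c14_mean, flat$grid, tolerance = 1e-12)
  expect_equal(diff(flat$grid)[1], 0.005, tolerance = 1e-12)
  expect_equal(range(flat$grid), c(10, 16))
  ## self-consistency: simulate at 13.0 ka, calibrate, recover the age
  cv <- make_synthetic_calcurve(10, 16, wiggle_amplitude = 0.08, seed = 5)
  dd <- simulate_radiocarbon(13.0, cv, lab_error = 0.06, n_dates = 3, seed = 6)
  dens <- spd(lapply(seq_len(3), function(j)
    calibrate(dd$c14_age[j], dd$error[j], cv)))
  med <- median_age(dens)
  sig <- sqrt(0.06^2 + mean(cv$c14_error)^2) / sqrt(3)
  expect_lt(abs(med - 13.0), max(2 * sig, 0.15))
})

test_that("round trip simulate -> calibrate -> median recovers true ages", {
  cv <- make_synthetic_calcurve(10.5, 16, wiggle_amplitude = 0.08, seed = 13)
  set.seed(77)
  ok <- 0L
  n <- 200
  for (i in seq_len(n)) {
    age <- runif(1, 11.2, 15.2)
    d <- simulate_radiocarbon(age, cv, lab_error = 0.06, n_dates = 1,
                              seed = 7000 + i)
    dens <- calibrate(d$c14_age, d$error, cv)
    ## the calibrated density's own one-sigma half-width is the
    ## relevant uncertainty: curve wiggles locally inflate or shrink
    ## the calendar-age error relative to the 14C-space error
    sr <- sigma_range(dens)
    tol <- max(sr[2] - sr[1], 2 * sqrt(0.06^2 + mean(cv$c14_error)^2))
    if (abs(median_age(dens) - age) <= tol) ok <- ok + 1L
  }
  expect_gte(ok / n, 0.9)
})

test_that("Brownian trait columns are exchangeable when exchangeably parameterized", {
  tr <- random_sa_tree(8, min_samples = 5, max_samples = 10)
  reps <- 200
  v <- t(vapply(seq_len(reps), function(i) {
    tm <- simulate_bm_traits(tr, bm_params(c(0, 0), c(1, 1), 0), 1,
                             seed = 900 + i)
    apply(tm$values, 2, var)
  }, c(0, 0)))
  ## permutation check: the two per-trait variance distributions agree
  expect_lt(abs(mean(v[, 1]) - mean(v[, 2])),
            3.5 * sd(v[, 1] - v[, 2]) / sqrt(reps))
  ## and their pooled increments are uncorrelated
  x <- t(vapply(seq_len(reps), function(i) {
    tm <- simulate_bm_traits(chain_tree(), bm_params(c(0, 0), c(1, 1), 0), 1,
                             seed = 300 + i)
    tm$values[tm$taxa == "B", ]
  }, c(0, 0)))
  expect_lt(abs(cor(x)[1, 2]), 0.2)
})

test_that("traits map to outlines and back through the PCA basis", {
  ## basis built from synthetic coefficient variation
  set.seed(21)
  efas <- lapply(1:25, function(i) {
    H <- fbdshape:::synthetic_shape_template()
    H[2:6, ] <- H[2:6, ] + rnorm(20, sd = 0.05)
    structure(list(specimen_id = paste0("s", i), harmonics = H,
                   a0 = 0, c0 = 0), class = "efa")
  })
  fit <- fit_pca(efa_table(efas))
  B <- fit$basis
  ## zero scores give the mean shape
  o0 <- traits_to_outline(rep(0, 3), B, n_points = 96)
  ref <- efa_inverse(fbdshape:::unflatten_coeffs(B$mean), 96)
  expect_equal(o0$points, ref$points, tolerance = 1e-10)
  ## round trip recovers the scores
  row <- c(0.06, -0.03, 0.02)
  o <- traits_to_outline(row, B, n_points = 128)
  cf <- efa_transform(o, length(B$mean) / 4, parameterization = "uniform")
  back <- pca_project(B, as.vector(t(cf$harmonics)))
  expect_equal(unname(back[1, 1:3]), row, tolerance = 1e-6)
  expect_lt(max(abs(back[1, -(1:3)])), 1e-6)
  ## dimension and point-count contracts
  expect_error(traits_to_outline(rep(0, 99), B), "exceed")
  expect_error(traits_to_outline(c(1, 0, 0, 0.5), n_points = 4), ">= 8")
  ## without a basis, values are leading harmonic coefficients: a pure
  ## ellipse row reconstructs an ellipse of matching eccentricity
  oe <- traits_to_outline(c(2, 0, 0, 1), n_points = 64)
  expect_equal(max(oe$points[, 1]), 2, tolerance = 1e-9)
  expect_equal(max(oe$points[, 2]), 1, tolerance = 1e-3)
})

test_that("study outlines respond to their generating traits", {
  res <- make_study_scenario(16, seed = 3)
  expect_length(res$outlines, 16)
  ## outlines differ across samples but share the template scale
  p1 <- res$outlines[[1]]$points
  p2 <- res$outlines[[2]]$points
  expect_gt(max(abs(p1 - p2)), 1e-4)
  expect_lt(max(abs(p1)), 3)
})

test_that("pruning a sampled tree to a sample subset preserves structure", {
  tr <- random_sa_tree(15, min_samples = 6, max_samples = 12)
  labs <- fbdshape:::sample_labels(tr)
  keep <- labs[seq_len(4)]
  sub <- prune_sa_tree(tr, keep)
  expect_setequal(fbdshape:::sample_labels(sub), keep)
  ## ages of kept samples preserved
  for (lb in keep) {
    expect_equal(sub$age[which(sub$label == lb)],
                 tr$age[which(tr$label == lb)])
  }
  expect_equal(sub$origin_age, tr$origin_age)
  expect_error(prune_sa_tree(tr, labs[1]), "at least 2")
})
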