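#' Simulation scenario
#'
#' Bundles everything needed to generate one synthetic study:
#' piecewise-constant birth/death/sampling rates (per ka, oldest
#' interval first), interval boundaries (strictly decreasing ages),
#' origin age, extant-sampling probability rho (default 0: sampling
#' stops before the present), the trait model and clock used to evolve
#' characters, and the seed.
#'
#' @param birth_rates,death_rates,sampling_rates per-interval rates
#'   (>= 0), oldest first.
#' @param interval_boundaries strictly decreasing boundary ages (ka).
#' @param origin_age origin of the process (> oldest boundary).
#' @param rho extant sampling probability, default 0.
#' @param n_traits number of continuous traits.
#' @param bm_sigma2 per-trait variance rates.
#' @param bm_corr shared trait correlation in (-1, 1).
#' @param clock_rate strict clock rate used when simulating traits.
#' @param seed integer seed.
#' @return Object of class `sim_scenario`.
#' @export
sim_scenario <- function(birth_rates, death_rates, sampling_rates,
                         interval_boundaries = numeric(0),
                         origin_age, rho = 0,
                         n_traits = 1L, bm_sigma2 = rep(1, n_traits),
                         bm_corr = 0, clock_rate = 1, seed = 1L) {
  params <- fbd_params(birth_rates, death_rates, sampling_rates,
                       interval_boundaries, rho)
  if (length(interval_boundaries) && origin_age <= max(interval_boundaries))
    stop("origin_age must exceed the oldest interval boundary")
  structure(list(params = params, origin_age = as.numeric(origin_age),
                 n_traits = as.integer(n_traits),
                 bm_sigma2 = as.numeric(bm_sigma2), bm_corr = bm_corr,
                 clock_rate = clock_rate, seed = as.integer(seed)),
            class = "sim_scenario")
}

## One forward pass of the event-by-event birth-death-sampling
## simulation. Returns the full event tree (deaths and extant tips
## included) or NULL if no event budget is left.
simulate_fbd_forward <- function(params, origin_age, max_events = 200000L) {
  tab <- fbd_tables(params)
  edges <- tab$edges                       # ascending internal boundaries
  parent <- integer(0); age <- numeric(0); type <- character(0)
  new_node <- function(p, a, ty) {
    parent[length(parent) + 1L] <<- p
    age[length(age) + 1L] <<- a
    type[length(type) + 1L] <<- ty
    length(parent)
  }
  ## lineages: data of last node id (NA for the founder before any event)
  active <- list(NA_integer_)
  t <- origin_age
  n_events <- 0L
  while (length(active) && t > 0) {
    ## interval covering ages just BELOW t (we move toward the present)
    l <- sum(edges < t) + 1L
    lam <- tab$lam[l]; mu <- tab$mu[l]; psi <- tab$psi[l]
    tot <- length(active) * (lam + mu + psi)
    lower <- if (l > 1L) edges[l - 1L] else 0
    tnext <- if (tot > 0) t - stats::rexp(1L, tot) else -Inf
    if (tnext <= lower) { t <- lower; next }   # cross into the next interval
    t <- tnext
    n_events <- n_events + 1L
    if (n_events > max_events) return(NULL)
    i <- sample.int(length(active), 1L)
    u <- stats::runif(1L) * (lam + mu + psi)
    if (u < lam) {
      nd <- new_node(active[[i]], t, "birth")
      active[[i]] <- nd
      active[[length(active) + 1L]] <- nd
    } else if (u < lam + mu) {
      new_node(active[[i]], t, "death")
      active[[i]] <- NULL
    } else {
      nd <- new_node(active[[i]], t, "sample")
      active[[i]] <- nd
    }
  }
  ## survivors to the present
  for (i in seq_along(active)) {
    ty <- if (params$rho > 0 && stats::runif(1L) < params$rho) "sample" else "extant"
    new_node(active[[i]], 0, ty)
  }
  list(parent = parent, age = age, type = type)
}

## Reduce a full event tree to the sampled tree: keep sample nodes and
## every ancestor of a sample; suppress unsampled degree-1 nodes.
## `keep_labels` optionally restricts which samples are kept.
prune_event_tree <- function(ev, origin_age, keep = NULL, labels = NULL) {
  n <- length(ev$parent)
  is_samp <- ev$type == "sample"
  if (!is.null(keep)) is_samp <- is_samp & keep
  if (!any(is_samp)) return(NULL)
  has_samp <- is_samp
  ## propagate toward the root (children before parents: ages increase
  ## rootward and are strictly ordered along lineages)
  for (i in order(ev$age)) if (has_samp[i] && !is.na(ev$parent[i]))
    has_samp[ev$parent[i]] <- TRUE
  ## every ancestor of a kept node is kept, so parents need no re-linking
  kept <- which(has_samp)
  parent <- match(ev$parent[kept], kept)
  age <- ev$age[kept]; samp <- is_samp[kept]
  nk <- length(kept)
  ## suppress unsampled pass-through nodes (births whose other side was
  ## pruned); suppression cannot create new pass-through nodes
  nc <- tabulate(parent[!is.na(parent)], nbins = nk)
  droppable <- !samp & nc == 1L
  final <- which(!droppable)
  newpar <- vapply(final, function(i) {
    p <- parent[i]
    while (!is.na(p) && droppable[p]) p <- parent[p]
    if (is.na(p)) NA_integer_ else p
  }, 1L)
  remap <- match(newpar, final)
  lab <- rep(NA_character_, length(final))
  sfin <- samp[final]
  lab[sfin] <- if (is.null(labels)) paste0("s", seq_len(sum(sfin)))
               else labels[kept[final]][sfin]
  sa_tree(remap, age[final], sfin, lab, origin_age)
}

#' Simulate a sampled tree under the FBD skyline
#'
#' Forward event-by-event simulation from the origin: each lineage
#' branches, dies and is sampled at the piecewise-constant per-ka rates;
#' the full realization is then pruned to the sampled tree (samples and
#' their connecting lineages only), with samples that have sampled
#' descendants becoming degree-2 sampled ancestors. Realizations with
#' fewer than `min_samples` samples are rejected and redrawn, up to a
#' capped number of attempts.
#'
#' @param scenario a [sim_scenario].
#' @param min_samples minimum samples required (default 2).
#' @param max_attempts rejection cap (default 10000).
#' @return An [sa_tree]; sample labels are `s1, s2, ...` in node order.
#' @export
simulate_fbd_tree <- function(scenario, min_samples = 2L, max_attempts = 10000L) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (all(scenario$params$psi == 0) && scenario$params$rho == 0)
    stop("no samples possible: psi = 0 everywhere and rho = 0")
  with_seed(scenario$seed, {
    for (a in seq_len(max_attempts)) {
      ev <- simulate_fbd_forward(scenario$params, scenario$origin_age)
      if (is.null(ev)) next
      if (sum(ev$type == "sample") < min_samples) next
      return(prune_event_tree(ev, scenario$origin_age))
    }
    stop(sprintf(
      "no realization with >= %d samples in %d attempts (origin %.3g, psi %s)",
      min_samples, max_attempts, scenario$origin_age,
      paste(signif(scenario$params$psi, 3), collapse = "/")))
  })
}

#' Synthetic radiocarbon calibration curve
#'
#' A stand-in calibration curve for fully synthetic studies: the
#' radiocarbon age tracks the calendar age plus smooth low-frequency
#' sinusoidal wiggles, with positive per-point curve errors, on a
#' regular 5-year grid. With zero wiggle amplitude the curve is the
#' identity.
#'
#' @param min_ka,max_ka calendar-age span (ka).
#' @param wiggle_amplitude amplitude of the wiggles (ka); 0 for the
#'   identity curve.
#' @param seed integer seed (randomizes the wiggle phases).
#' @param curve_error per-point curve error (ka).
#' @return A [cal_curve].
#' @export
make_synthetic_calcurve <- function(min_ka, max_ka, wiggle_amplitude = 0.08,
                                    seed = 1L, curve_error = 0.025) {
  stopifnot(min_ka < max_ka)
  grid <- seq(min_ka, max_ka, by = 0.005)
  with_seed(seed, {
    ph <- stats::runif(3L, 0, 2 * pi)
    wig <- wiggle_amplitude * (sin(2 * pi * grid / 1.3 + ph[1L]) +
                               0.6 * sin(2 * pi * grid / 0.45 + ph[2L]) +
                               0.3 * sin(2 * pi * grid / 0.17 + ph[3L]))
    err <- curve_error * (1 + 0.2 * sin(2 * pi * grid / 0.9 + ph[1L]))
    cal_curve(grid, grid + wig, err)
  })
}

#' Simulate laboratory radiocarbon dates for a known age
#'
#' Each date is drawn as
#' `Normal(curve mean at the true age, sqrt(lab_error^2 + curve_error^2))`,
#' emulating repeated laboratory measurements from one layer.
#'
#' @param true_age_ka true calendar age (ka), within the curve span.
#' @param curve a [cal_curve].
#' @param lab_error reported laboratory error (ka).
#' @param n_dates number of dates (0 gives an empty table).
#' @param seed integer seed.
#' @return data.frame with columns `c14_age`, `error` (the reported lab
#'   error).
#' @export
simulate_radiocarbon <- function(true_age_ka, curve, lab_error, n_dates, seed) {
  stopifnot(inherits(curve, "cal_curve"))
  if (true_age_ka < min(curve$grid) || true_age_ka > max(curve$grid))
    stop(sprintf("true age %.3f ka outside curve span [%.3f, %.3f]",
                 true_age_ka, min(curve$grid), max(curve$grid)))
  if (n_dates == 0L)
    return(data.frame(c14_age = numeric(0), error = numeric(0)))
  at <- curve_at(curve, true_age_ka)
  with_seed(seed, {
    sd <- sqrt(lab_error^2 + at$error^2)
    data.frame(c14_age = stats::rnorm(n_dates, at$mean, sd),
               error = rep(lab_error, n_dates))
  })
}

#' Outline from a trait row
#'
#' Maps continuous trait values back to elliptic Fourier coefficients —
#' through a PCA basis when one is given, or treating the values
#' directly as leading harmonic coefficients — and evaluates the inverse
#' Fourier series.
#'
#' @param trait_row numeric vector of trait values.
#' @param basis optional `pca_basis` on flattened coefficients; the
#'   trait dimension must not exceed the basis dimension.
#' @param n_points outline points (>= 8).
#' @param specimen_id name for the outline.
#' @return An [outline].
#' @export
traits_to_outline <- function(trait_row, basis = NULL, n_points = 120L,
                              specimen_id = "synthetic") {
  if (!is.null(basis)) {
    flat <- pca_backproject(basis, trait_row)
  } else {
    flat <- c(trait_row, rep(0, (4L - length(trait_row) %% 4L) %% 4L))
  }
  efa_inverse(unflatten_coeffs(flat), n_points = n_points,
              specimen_id = specimen_id)
}

## Fixed coefficient template for synthetic projectile-point-like
## outlines: an elongated first harmonic with mild higher-harmonic
## structure (pointed tip, hint of a tang).
synthetic_shape_template <- function(n_harmonics = 8L) {
  H <- matrix(0, n_harmonics, 4L,
              dimnames = list(paste0("h", seq_len(n_harmonics)),
                              c("a", "b", "c", "d")))
  H[1L, ] <- c(1.00, 0.00, 0.00, 0.42)
  H[2L, ] <- c(0.00, 0.03, 0.02, 0.00)
  H[3L, ] <- c(-0.10, 0.00, 0.00, 0.05)
  H[4L, ] <- c(0.00, 0.01, 0.01, 0.00)
  H[5L, ] <- c(0.03, 0.00, 0.00, 0.02)
  H
}

## Trait values perturb higher-harmonic coefficients of the template.
scenario_outline <- function(trait_row, gain = 0.04, n_points = 120L,
                             specimen_id = "synthetic") {
  H <- synthetic_shape_template()
  flat <- as.vector(t(H))
  k <- length(trait_row)
  slots <- 4L + seq_len(k)       # skip the first-harmonic block
  if (max(slots) > length(flat)) stop("too many traits for the template")
  flat[slots] <- flat[slots] + gain * trait_row
  efa_inverse(unflatten_coeffs(flat), n_points = n_points,
              specimen_id = specimen_id)
}

#' Prune a sampled tree to a subset of its samples
#'
#' Keeps the named samples and their connecting lineages; dropped
#' samples on retained lineages become ordinary (unlabelled) points and
#' are suppressed; unsampled pass-through nodes are removed. The origin
#' is unchanged.
#'
#' @param tree an [sa_tree].
#' @param keep_labels sample labels to keep (>= 2).
#' @return An [sa_tree] on the kept samples.
#' @export
prune_sa_tree <- function(tree, keep_labels) {
  stopifnot(inherits(tree, "sa_tree"))
  keep <- tree$is_sample & tree$label %in% keep_labels
  if (sum(keep) < 2L) stop("need at least 2 kept samples")
  ev <- list(parent = tree$parent, age = tree$age,
             type = ifelse(tree$is_sample, "sample", "birth"))
  prune_event_tree(ev, tree$origin_age, keep = keep, labels = tree$label)
}

#' Default study scenario
#'
#' The frozen conditions of the synthetic study emulating a Late
#' Glacial sampling window: sampling present at 11 ka BP, origin at
#' 15 ka BP (4 ka of process time), four climate intervals bounded at
#' 14.6 / 12.9 / 11.7 ka BP, a high early birth rate seeding the
#' radiation from a single founder, and sampling intensity scaled with
#' the number of locales a study collates. Trait variance rates decay
#' like a principal-component eigenvalue spectrum.
#'
#' @param n_taxa target number of dated samples (16, 32, 60 or 87).
#' @param seed integer seed.
#' @param n_traits number of traits simulated (default 9).
#' @return A [sim_scenario] with attribute fields used by
#'   [make_study_scenario()].
#' @export
study_scenario <- function(n_taxa = 32L, seed = 1L, n_traits = 9L) {
  psi_scale <- max(1, n_taxa / 32)
  sig <- c(3, 1.2, 0.6, 0.35, 0.2, 0.12, 0.08, 0.05, 0.03,
           0.02, 0.012, 0.008)[seq_len(n_traits)]
  sc <- sim_scenario(
    birth_rates    = c(3.0, 1.2, 0.8, 0.5),
    death_rates    = c(0.1, 0.3, 0.4, 0.6),
    sampling_rates = c(1.5, 0.5, 0.5, 0.55) * psi_scale,
    interval_boundaries = c(3.6, 1.9, 0.7),   # 14.6/12.9/11.7 ka BP
    origin_age = 4.0,                          # 15 ka BP
    n_traits = n_traits, bm_sigma2 = sig, bm_corr = 0.3,
    clock_rate = 0.5, seed = seed)
  sc$present_bp <- 11
  sc$n_taxa <- as.integer(n_taxa)
  sc
}

#' Generate a full synthetic study
#'
#' Simulates one complete synthetic dataset with the statistical
#' structure the inference assumes: an FBD tree over the 15-11 ka BP
#' sampling window (model time measured before a sampling present of
#' 11 ka BP), Brownian traits at the samples, synthetic outlines built
#' from the traits, and per-locale radiocarbon dates against a shared
#' synthetic calibration curve, calibrated and summed into median ages
#' and one-sigma intervals. Sample counts per climate bin are filled as
#' evenly as each realization allows: realizations are redrawn toward
#' the even target up to an attempt budget, after which bins keep what
#' they have and younger bins back-fill the total.
#'
#' @param n_taxa 16, 32, 60 or 87 dated samples.
#' @param seed integer seed; the whole study is a fixed function of it.
#' @param n_traits traits to simulate (default 9).
#' @param even_fill_attempts attempt budget for the even per-bin fill.
#' @return A list of class `sim_result`: `tree` (truth, model time),
#'   `traits`, `outlines`, `samples` (a [dated_samples] table, ka BP),
#'   `c14_tables` (per-locale date tables), `curve`, `scenario`,
#'   `present_bp`.
#' @export
make_study_scenario <- function(n_taxa = 32L, seed = 1L, n_traits = 9L,
                                even_fill_attempts = 500L) {
  n_taxa <- as.integer(n_taxa)
  sc <- study_scenario(n_taxa, seed, n_traits)
  present <- sc$present_bp
  per_bin <- rep(n_taxa %/% 4L, 4L)
  extra <- n_taxa %% 4L
  if (extra) per_bin[seq_len(extra) + (4L - extra)] <- per_bin[seq_len(extra) + (4L - extra)] + 1L
  boundaries_bp <- c(14.6, 12.9, 11.7)
  best <- NULL; best_score <- -Inf
  with_seed(derive_seed(seed, 1L), {
    for (a in seq_len(even_fill_attempts)) {
      ev <- simulate_fbd_forward(sc$params, sc$origin_age)
      if (is.null(ev)) next
      sidx <- which(ev$type == "sample")
      if (length(sidx) < n_taxa) next
      bins <- assign_bin(ev$age[sidx] + present, boundaries_bp)
      cnt <- table(bins)
      score <- sum(pmin(as.integer(cnt), per_bin))
      if (score > best_score) { best <- list(ev = ev, sidx = sidx, bins = bins)
                                best_score <- score }
      if (score >= n_taxa) break
    }
  })
  if (is.null(best))
    stop(sprintf("could not realize %d samples in %d attempts", n_taxa,
                 even_fill_attempts))
  ev <- best$ev; sidx <- best$sidx; bins <- best$bins
  ## stratified pick: per-bin targets, then back-fill from younger bins
  avail <- as.integer(table(bins))
  take <- pmin(per_bin, avail)
  deficit <- n_taxa - sum(take)
  for (b in 4:1) {            # youngest bins back-fill first
    if (deficit <= 0L) break
    room <- avail[b] - take[b]
    add <- min(room, deficit)
    take[b] <- take[b] + add; deficit <- deficit - add
  }
  if (deficit > 0L) stop("internal: fill bookkeeping failed")
  keep <- logical(length(ev$parent))
  with_seed(derive_seed(seed, 2L), {
    for (b in seq_len(4L)) {
      inb <- sidx[as.integer(bins) == b]
      keep[inb[sample.int(length(inb))[seq_len(take[b])]]] <- TRUE
    }
  })
  tree <- prune_event_tree(ev, sc$origin_age, keep = keep)
  ## relabel samples young-to-old for readable ids
  samp_nodes <- which(tree$is_sample)
  tree$label[samp_nodes] <- sprintf("t%02d", rank(tree$age[samp_nodes],
                                                  ties.method = "first"))
  bm <- bm_params(root = rep(0, sc$n_traits), sigma2 = sc$bm_sigma2,
                  corr = sc$bm_corr)
  traits <- simulate_bm_traits(tree, bm, rates = sc$clock_rate,
                               seed = derive_seed(seed, 3L))
  outlines <- lapply(seq_along(traits$taxa), function(i)
    scenario_outline(traits$values[i, ], specimen_id = traits$taxa[i]))
  curve <- make_synthetic_calcurve(10.5, 16, wiggle_amplitude = 0.08,
                                   seed = derive_seed(seed, 4L))
  true_bp <- tree$age[samp_nodes] + present
  labs <- tree$label[samp_nodes]
  c14_tables <- list()
  med <- lo <- hi <- numeric(length(labs))
  with_seed(derive_seed(seed, 5L), {
    for (i in seq_along(labs)) {
      nd <- 1L + stats::rpois(1L, 1.2)
      tab <- simulate_radiocarbon(true_bp[i], curve, lab_error = 0.06,
                                  n_dates = nd,
                                  seed = derive_seed(seed, 100L + i))
      c14_tables[[labs[i]]] <- tab
      dens <- spd(lapply(seq_len(nrow(tab)), function(j)
        calibrate(tab$c14_age[j], tab$error[j], curve)))
      med[i] <- median_age(dens)
      sr <- sigma_range(dens)
      lo[i] <- sr[1L]; hi[i] <- sr[2L]
    }
  })
  ## the uniform tip-age prior must contain the median starting age
  lo <- pmin(lo, med); hi <- pmax(hi, med)
  samples <- dated_samples(taxon_id = labs, locale_id = paste0("L_", labs),
                           median_age = med, age_min = lo, age_max = hi,
                           bin = assign_bin(round(med, 3), boundaries_bp))
  structure(list(tree = tree, traits = traits, outlines = outlines,
                 samples = samples, c14_tables = c14_tables, curve = curve,
                 scenario = sc, present_bp = present),
            class = "sim_result")
}
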