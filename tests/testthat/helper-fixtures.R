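## Shared fixtures, built in code.

## dense ellipse outline sampled uniformly in the curve parameter
ellipse_outline <- function(a = 2, b = 1, n = 200, id = "ellipse") {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  outline(cbind(a * cos(th), b * sin(th)), id)
}

## smooth blobby closed shape with a few harmonics
blob_outline <- function(n = 240, id = "blob", seed = 1) {
  set.seed(seed)
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- 1 + 0.25 * sin(2 * th + 0.4) + 0.12 * cos(3 * th) + 0.05 * sin(5 * th)
  outline(cbind(r * cos(th), r * sin(th)), id)
}

## fixed two-sample chain tree: sampled ancestor above a terminal tip
chain_tree <- function(age_old = 2, age_young = 1, origin = 3) {
  sa_tree(parent = c(NA, 1L), age = c(age_old, age_young),
          is_sample = c(TRUE, TRUE), label = c("A", "B"),
          origin_age = origin)
}

## fixed four-tip bifurcating tree with serial tip ages
quartet_tree <- function() {
  ## ((A:1,B:2):1,(C:1.5,D:0.5):2.5); with ages
  sa_tree(parent = c(5L, 5L, 6L, 6L, 7L, 7L, NA),
          age = c(1.0, 0.2, 0.8, 0.4, 2.0, 1.6, 3.0),
          is_sample = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
          label = c("A", "B", "C", "D", NA, NA, NA),
          origin_age = 3.6)
}

## random sampled-ancestor tree via the forward simulator
random_sa_tree <- function(seed, lambda = 0.6, mu = 0.2, psi = 0.8,
                           origin = 3, min_samples = 3, max_samples = 8) {
  for (off in 0:200) {
    sc <- sim_scenario(lambda, mu, psi, origin_age = origin,
                       seed = seed + 1000L * off)
    tr <- simulate_fbd_tree(sc, min_samples = min_samples)
    if (sum(tr$is_sample) <= max_samples) return(tr)
  }
  stop("no tree of requested size found")
}

## independent event-count oracle: Gillespie population simulation that
## only counts psi-sampling events (no tree construction)
oracle_sample_count <- function(lambda, mu, psi, origin, min_samples = 2) {
  repeat {
    n <- 1L
    t <- origin
    k <- 0L
    while (n > 0L && t > 0) {
      tot <- n * (lambda + mu + psi)
      t <- t - stats::rexp(1L, tot)
      if (t <= 0) break
      u <- stats::runif(1L) * (lambda + mu + psi)
      if (u < lambda) n <- n + 1L
      else if (u < lambda + mu) n <- n - 1L
      else k <- k + 1L
    }
    if (k >= min_samples) return(k)
  }
}

## brute-force HPD: exhaustive search over contiguous sorted windows
oracle_hpd <- function(x, level = 0.95) {
  x <- sort(x)
  n <- length(x)
  m <- ceiling(level * n)
  best <- c(-Inf, Inf)
  for (i in seq_len(n - m + 1L)) {
    if (x[i + m - 1L] - x[i] < best[2L] - best[1L])
      best <- c(x[i], x[i + m - 1L])
  }
  best
}

## brute-force clade tally over a tree sample
oracle_clade_probs <- function(trees) {
  all_ids <- unlist(lapply(trees, function(tr) unique(fbdshape:::clade_ids(tr))))
  tab <- table(all_ids)
  sort(as.numeric(tab) / length(trees), decreasing = TRUE)
}
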