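#' Multivariate Brownian-motion parameters
#'
#' The trait model: a k-variate Brownian random walk with per-trait
#' variance rates sigma2 and a single shared among-character correlation
#' r, giving the trait covariance rate matrix
#' `Sigma[i,j] = r * sqrt(sigma2_i * sigma2_j)` (diagonal `sigma2`).
#' The walk starts at the process origin with the root values. Sigma
#' must be positive definite, which for an equicorrelation matrix
#' requires `r > -1 / (k - 1)`.
#'
#' @param root numeric vector of root (ancestral) values, one per trait.
#' @param sigma2 positive per-trait variance rates (per ka).
#' @param corr shared correlation in (-1, 1); default 0.
#' @return Object of class `bm_params` (with the assembled `Sigma`).
#' @export
bm_params <- function(root, sigma2, corr = 0) {
  k <- length(root)
  stopifnot(length(sigma2) == k, all(sigma2 > 0), corr > -1, corr < 1)
  R <- matrix(corr, k, k); diag(R) <- 1
  s <- sqrt(sigma2)
  Sigma <- R * tcrossprod(s)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev))
    stop("trait covariance matrix is not positive definite (corr too negative?)")
  structure(list(root = as.numeric(root), sigma2 = as.numeric(sigma2),
                 corr = corr, Sigma = Sigma, k = k),
            class = "bm_params")
}

## per-branch variance multipliers: duration x clock rate, indexed by
## node; the root entry is the origin-to-root stem.
branch_variances <- function(tree, rates) {
  n <- length(tree$parent)
  stopifnot(length(rates) == n, all(rates > 0))
  v <- numeric(n)
  nr <- which(!is.na(tree$parent))
  v[nr] <- (tree$age[tree$parent[nr]] - tree$age[nr]) * rates[nr]
  r <- root_node(tree)
  v[r] <- (tree$origin_age - tree$age[r]) * rates[r]
  v
}

#' Simulate Brownian traits along a sampled tree
#'
#' The walk starts at the origin with `bm$root` and adds an independent
#' multivariate normal increment with covariance
#' `(branch duration x branch clock rate) * Sigma` along every branch
#' (the origin-to-root stem included). Trait rows are returned for every
#' sample (terminal tips and sampled ancestors).
#'
#' @param tree an [sa_tree].
#' @param bm a [bm_params].
#' @param rates per-branch clock rates indexed by node (the root entry
#'   scales the stem); a scalar is recycled.
#' @param seed integer seed.
#' @return A [trait_matrix] with one row per sample, in `which(is_sample)`
#'   order.
#' @export
simulate_bm_traits <- function(tree, bm, rates = 1, seed) {
  stopifnot(inherits(tree, "sa_tree"), inherits(bm, "bm_params"))
  n <- length(tree$parent)
  if (length(rates) == 1L) rates <- rep(rates, n)
  v <- branch_variances(tree, rates)
  U <- chol(bm$Sigma)
  with_seed(seed, {
    vals <- matrix(NA_real_, n, bm$k)
    ord <- rev(postorder(tree))          # parents before children
    for (nd in ord) {
      p <- tree$parent[nd]
      base <- if (is.na(p)) bm$root else vals[p, ]
      z <- stats::rnorm(bm$k)
      vals[nd, ] <- base + sqrt(v[nd]) * as.vector(z %*% U)
    }
    samp <- which(tree$is_sample)
    tm <- vals[samp, , drop = FALSE]
    rownames(tm) <- tree$label[samp]
    trait_matrix(tm, taxa = tree$label[samp])
  })
}

#' Brownian-motion log likelihood by pruning
#'
#' Joint multivariate normal density of the sample trait values under
#' the Brownian model, computed by a post-order pruning pass. The trait
#' dimension is first whitened through the Cholesky factor of Sigma, so
#' each transformed trait is an independent unit-rate Brownian motion on
#' the variance-scaled tree; sampled ancestors enter as exact internal
#' observations. Equal to the dense multivariate normal density with
#' mean `root` per trait and covariance `C (x) Sigma`, where C holds the
#' variance-scaled shared path lengths from the origin.
#'
#' @param tree an [sa_tree].
#' @param traits a [trait_matrix] (or matrix with sample labels as row
#'   names) holding one row per sample.
#' @param bm a [bm_params].
#' @param rates per-branch clock rates indexed by node (scalar
#'   recycled).
#' @return Log likelihood.
#' @export
bm_log_likelihood <- function(tree, traits, bm, rates = 1) {
  stopifnot(inherits(tree, "sa_tree"), inherits(bm, "bm_params"))
  Y <- if (inherits(traits, "trait_matrix")) traits$values else as.matrix(traits)
  n <- length(tree$parent)
  if (length(rates) == 1L) rates <- rep(rates, n)
  v <- branch_variances(tree, rates)
  samp <- which(tree$is_sample)
  idx <- match(tree$label[samp], rownames(Y))
  if (anyNA(idx)) stop("missing trait rows for: ",
                       paste(tree$label[samp][is.na(idx)], collapse = ", "))
  if (ncol(Y) != bm$k) stop("trait dimension does not match bm parameters")
  U <- chol(bm$Sigma)
  Ui <- backsolve(U, diag(bm$k))
  Ys <- Y[idx, , drop = FALSE] %*% Ui        # whitened traits, sample order
  roots <- as.vector(bm$root %*% Ui)
  ns <- length(samp)
  ## log |Sigma|^{-ns/2} Jacobian of the whitening
  ll <- -ns * sum(log(diag(U)))
  obs <- rep(NA_integer_, n); obs[samp] <- seq_len(ns)
  m <- matrix(0, n, bm$k)     # partial means
  pv <- numeric(n)            # partial variances (shared across traits)
  ch <- children_list(tree)
  for (nd in postorder(tree)) {
    kids <- ch[[nd]]
    if (length(kids) == 0L) {
      m[nd, ] <- Ys[obs[nd], ]; pv[nd] <- 0
    } else if (length(kids) == 1L) {
      ## sampled ancestor: exact observation on the lineage
      Vc <- pv[kids] + v[kids]
      x <- Ys[obs[nd], ]
      ll <- ll + sum(stats::dnorm(m[kids, ] - x, 0, sqrt(Vc), log = TRUE))
      m[nd, ] <- x; pv[nd] <- 0
    } else {
      V1 <- pv[kids[1L]] + v[kids[1L]]
      V2 <- pv[kids[2L]] + v[kids[2L]]
      ll <- ll + sum(stats::dnorm(m[kids[1L], ] - m[kids[2L], ], 0,
                                  sqrt(V1 + V2), log = TRUE))
      m[nd, ] <- (m[kids[1L], ] * V2 + m[kids[2L], ] * V1) / (V1 + V2)
      pv[nd] <- V1 * V2 / (V1 + V2)
    }
  }
  r <- root_node(tree)
  Vr <- pv[r] + v[r]
  ll + sum(stats::dnorm(m[r, ] - roots, 0, sqrt(Vr), log = TRUE))
}

#' Dense reference Brownian-motion likelihood
#'
#' Independent reference computation of [bm_log_likelihood()]: builds
#' the variance-scaled shared-path matrix C over samples explicitly,
#' forms the full `C (x) Sigma` covariance by Kronecker product and
#' evaluates one dense multivariate normal density. Quadratic memory in
#' samples x traits; intended for small trees and cross-checks.
#'
#' @inheritParams bm_log_likelihood
#' @return Log likelihood.
#' @export
bm_log_likelihood_dense <- function(tree, traits, bm, rates = 1) {
  stopifnot(inherits(tree, "sa_tree"), inherits(bm, "bm_params"))
  Y <- if (inherits(traits, "trait_matrix")) traits$values else as.matrix(traits)
  n <- length(tree$parent)
  if (length(rates) == 1L) rates <- rep(rates, n)
  v <- branch_variances(tree, rates)
  ## variance-scaled depth from the origin
  D <- numeric(n)
  for (nd in rev(postorder(tree))) {
    p <- tree$parent[nd]
    D[nd] <- v[nd] + if (is.na(p)) 0 else D[p]
  }
  anc <- lapply(seq_len(n), function(nd) {
    path <- nd
    while (!is.na(tree$parent[path[1L]])) path <- c(tree$parent[path[1L]], path)
    path
  })
  samp <- which(tree$is_sample)
  idx <- match(tree$label[samp], rownames(Y))
  if (anyNA(idx)) stop("missing trait rows")
  ns <- length(samp)
  C <- matrix(0, ns, ns)
  for (i in seq_len(ns)) for (j in seq_len(i)) {
    common <- intersect(anc[[samp[i]]], anc[[samp[j]]])
    mrca <- common[which.max(D[common])]
    C[i, j] <- C[j, i] <- D[mrca]
  }
  V <- kronecker(C, bm$Sigma)
  y <- as.vector(t(Y[idx, , drop = FALSE]))          # sample-major blocks
  mu <- rep(bm$root, times = ns)
  Uv <- chol(V)
  z <- backsolve(Uv, y - mu, transpose = TRUE)
  -0.5 * length(y) * log(2 * pi) - sum(log(diag(Uv))) - 0.5 * sum(z^2)
}
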