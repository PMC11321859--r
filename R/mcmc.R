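#' MCMC configuration
#'
#' @param n_generations total Metropolis-Hastings proposals.
#' @param sample_every thinning interval for the trace and tree log.
#' @param seed integer seed; the whole run is a fixed function of it.
#' @param under_prior if TRUE the trait likelihood is switched off
#'   (constant 0), so rate posteriors reflect only the tree model and
#'   the sampling times.
#' @param burnin_fraction leading fraction discarded by
#'   [combine_logs()] and summaries (default 0.20).
#' @param ess_threshold convergence threshold on prior/posterior/
#'   likelihood effective sample sizes (default 200).
#' @param move_weights named numeric vector overriding default move
#'   weights.
#' @param fixed_topology if TRUE, topology-changing moves (exchange,
#'   subtree regraft, sampled-ancestor toggle) are disabled.
#' @param fixed_tip_ages if TRUE tip ages stay at their starting
#'   values.
#' @param tree_free if TRUE the tree model density is also switched
#'   off and the tree held fixed, so every parameter is sampled from
#'   its analytic prior — a validity harness for the sampler.
#' @param tuning named list of proposal scales.
#' @return Object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_generations = 20000L, sample_every = 20L, seed = 1L,
                        under_prior = FALSE, burnin_fraction = 0.20,
                        ess_threshold = 200, move_weights = NULL,
                        fixed_topology = FALSE, fixed_tip_ages = FALSE,
                        tree_free = FALSE, tuning = list()) {
  stopifnot(n_generations > 0, burnin_fraction >= 0, burnin_fraction < 1)
  tun <- utils::modifyList(list(rate_scale = 0.7, sigma2_scale = 0.5,
                                corr_slide = 0.25, root_slide = 1.2,
                                clock_scale = 0.6, origin_slide = 0.4,
                                age_slide = 0.3), tuning)
  structure(list(n_generations = as.integer(n_generations),
                 sample_every = as.integer(sample_every),
                 seed = as.integer(seed), under_prior = under_prior,
                 burnin_fraction = burnin_fraction,
                 ess_threshold = ess_threshold,
                 move_weights = move_weights,
                 fixed_topology = if (tree_free) TRUE else fixed_topology,
                 fixed_tip_ages = if (tree_free) TRUE else fixed_tip_ages,
                 tree_free = tree_free,
                 tuning = tun),
            class = "mcmc_config")
}

## ---- internal tree edits (pure functions on sa_tree lists) ----------

## uniform age window for a node given its neighbours; returns c(lo, hi)
age_window <- function(tr, nd) {
  kids <- children_of(tr, nd)
  lo <- if (length(kids)) max(tr$age[kids]) else 0
  p <- tr$parent[nd]
  hi <- if (is.na(p)) tr$origin_age else tr$age[p]
  c(lo, hi)
}

## convert terminal sample `i` into a sampled ancestor on its sibling
## lineage; removes the parent bifurcation. Returns NULL if invalid.
toggle_tip_to_sa <- function(tr, i) {
  p <- tr$parent[i]
  if (is.na(p) || tr$is_sample[p]) return(NULL)
  kids <- children_of(tr, p)
  s <- setdiff(kids, i)
  if (length(s) != 1L) return(NULL)
  if (tr$age[i] <= tr$age[s]) return(NULL)      # must sit above the sibling top
  g <- tr$parent[p]
  tr$parent[i] <- g                              # i takes p's place
  tr$parent[s] <- i
  keep <- setdiff(seq_along(tr$parent), p)
  remap <- match(tr$parent[keep], keep)
  list(tree = sa_tree(remap, tr$age[keep], tr$is_sample[keep], tr$label[keep],
                      tr$origin_age),
       removed = p, kept = keep)
}

## convert sampled ancestor `z` into a terminal sample: a new
## bifurcation of age `u` takes its place on the lineage
toggle_sa_to_tip <- function(tr, z, u) {
  c0 <- children_of(tr, z)
  if (length(c0) != 1L) return(NULL)
  g <- tr$parent[z]
  hi <- if (is.na(g)) tr$origin_age else tr$age[g]
  if (u <= tr$age[z] || u >= hi) return(NULL)
  n <- length(tr$parent)
  tr$parent <- c(tr$parent, if (is.na(g)) NA_integer_ else g)
  tr$age <- c(tr$age, u)
  tr$is_sample <- c(tr$is_sample, FALSE)
  tr$label <- c(tr$label, NA_character_)
  p <- n + 1L
  tr$parent[z] <- p
  tr$parent[c0] <- p
  list(tree = sa_tree(tr$parent, tr$age, tr$is_sample, tr$label,
                      tr$origin_age),
       added = p)
}

## tips whose conversion to a sampled ancestor is geometrically valid
convertible_tips <- function(tr) {
  tips <- tip_nodes(tr)
  ok <- vapply(tips, function(i) {
    p <- tr$parent[i]
    if (is.na(p) || tr$is_sample[p]) return(FALSE)
    s <- setdiff(children_of(tr, p), i)
    length(s) == 1L && tr$age[i] > tr$age[s]
  }, TRUE)
  tips[ok]
}

## ---- the sampler -----------------------------------------------------

#' Metropolis-Hastings sampler for the joint phylodynamic model
#'
#' Samples trees, tip ages, the origin, piecewise-constant
#' birth/death/sampling rates, Brownian trait parameters and relaxed
#' clock parameters from the posterior
#' `FBD skyline density x Brownian trait likelihood x priors`
#' (or the priors-plus-tree-model alone when run under the prior). The
#' move set covers scale moves on all positive parameters, slides on
#' tip ages within their calibrated intervals, node-age and origin
#' slides, narrow exchange, subtree regrafting and a reversible-jump
#' toggle between terminal samples and sampled ancestors.
#'
#' @param traits a [trait_matrix] (one row per taxon).
#' @param samples a [dated_samples] table; `age_min`/`age_max` give the
#'   uniform tip-age prior (equal values fix the age).
#' @param boundaries_bp skyline interval boundaries in ka BP (oldest
#'   first); default the Greenland event stratigraphy
#'   `c(14.6, 12.9, 11.7)`.
#' @param present_bp age (ka BP) of the sampling present; tip ages are
#'   modelled as time before this epoch. Default 0.
#' @param clock_model `"ulnc"`, `"ncat2"` or `"strict"`.
#' @param prior a [prior_spec].
#' @param config an [mcmc_config].
#' @return A `posterior_trace`: list with `table` (one row per
#'   retained generation: posterior, likelihood, prior, all scalar
#'   parameters), `trees` (sampled [sa_tree]s), `acceptance` (per-move
#'   acceptance rates), `config`, `boundaries_bp`, `present_bp`.
#' @export
run_mcmc <- function(traits, samples, boundaries_bp = c(14.6, 12.9, 11.7),
                     present_bp = 0, clock_model = c("ulnc", "ncat2", "strict"),
                     prior = prior_spec(), config = mcmc_config()) {
  clock_model <- match.arg(clock_model)
  stopifnot(inherits(traits, "trait_matrix"), nrow(samples) >= 2L)
  if (!setequal(traits$taxa, samples$taxon_id))
    stop("taxa differ between traits and dated samples")
  k <- ncol(traits$values)
  K <- length(boundaries_bp) + 1L
  boundaries <- boundaries_bp - present_bp   # model time
  age_bounds <- data.frame(taxon_id = samples$taxon_id,
                           age_min = pmax(samples$age_min - present_bp, 1e-4),
                           age_max = pmax(samples$age_max - present_bp, 2e-4))
  age_bounds$age_min <- pmin(age_bounds$age_min, age_bounds$age_max)
  with_seed(config$seed, {
    state <- init_state(traits, age_bounds, boundaries, k, K, clock_model,
                        prior, config)
    data <- list(traits = traits, age_bounds = age_bounds,
                 boundaries = boundaries, under_prior = config$under_prior,
                 tree_free = config$tree_free)
    curr <- eval_blocks(state, data, prior, c("fbd", "bm", "prior"), list())
    if (!is.finite(total_log_post(curr)))
      stop("no finite-density starting state could be constructed")
    moves <- build_moves(state, config)
    mnames <- names(moves$fun)
    acc <- prop <- stats::setNames(numeric(length(mnames)), mnames)
    n_out <- config$n_generations %/% config$sample_every
    tab <- vector("list", n_out)
    trees <- vector("list", n_out)
    brates <- vector("list", n_out)
    oi <- 0L
    for (g in seq_len(config$n_generations)) {
      mi <- sample.int(length(mnames), 1L, prob = moves$w)
      mv <- moves$fun[[mi]](state, data, config$tuning)
      prop[mi] <- prop[mi] + 1
      if (!is.null(mv)) {
        cand <- eval_blocks(mv$state, data, prior, mv$blocks, curr)
        lr <- total_log_post(cand) - total_log_post(curr) + mv$log_hastings
        if (is.finite(lr) && (lr >= 0 || log(stats::runif(1L)) < lr)) {
          state <- mv$state; curr <- cand
          acc[mi] <- acc[mi] + 1
        }
      }
      if (g %% config$sample_every == 0L) {
        oi <- oi + 1L
        tab[[oi]] <- trace_row(g, state, curr, k, K)
        trees[[oi]] <- state$tree
        brates[[oi]] <- clock_rates(state$clock, length(state$tree$parent))
      }
    }
    table <- do.call(rbind, tab)
    structure(list(table = as.data.frame(table), trees = trees,
                   branch_rates = brates,
                   acceptance = ifelse(prop > 0, acc / prop, NA_real_),
                   config = config, boundaries_bp = boundaries_bp,
                   present_bp = present_bp, clock_model = clock_model),
              class = "posterior_trace")
  })
}

#' @export
print.posterior_trace <- function(x, ...) {
  cat(sprintf("<posterior_trace> %d rows x %d columns, %d trees\n",
              nrow(x$table), ncol(x$table), length(x$trees)))
  invisible(x)
}

total_log_post <- function(curr) curr$fbd + curr$bm + curr$prior

eval_blocks <- function(state, data, prior, blocks, curr) {
  out <- curr
  if ("prior" %in% blocks)
    out$prior <- evaluate_priors(state, prior, data$age_bounds)
  if (!is.finite(out$prior)) { out$fbd <- out$fbd %||% -Inf; out$bm <- 0; return(out) }
  if ("fbd" %in% blocks) {
    out$fbd <- if (isTRUE(data$tree_free)) 0 else {
      params <- fbd_params(state$lambda, state$mu, state$psi, data$boundaries)
      fbd_log_density(state$tree, params)
    }
  }
  if ("bm" %in% blocks) {
    out$bm <- if (data$under_prior) 0 else {
      bm <- tryCatch(bm_params(state$root, state$sigma2, state$corr),
                     error = function(e) NULL)
      if (is.null(bm)) -Inf
      else bm_log_likelihood(state$tree, data$traits, bm,
                             clock_rates(state$clock, length(state$tree$parent)))
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## starting state: tip ages at their interval midpoints, a compact
## age-sequential starting tree, rates at prior means
init_state <- function(traits, age_bounds, boundaries, k, K, clock_model,
                       prior, config) {
  ages <- (age_bounds$age_min + age_bounds$age_max) / 2
  labs <- age_bounds$taxon_id
  ord <- order(ages)                       # youngest first
  n <- length(ages)
  parent <- rep(NA_integer_, 2L * n - 1L)
  age <- numeric(2L * n - 1L)
  is_samp <- c(rep(TRUE, n), rep(FALSE, n - 1L))
  label <- c(labs[ord], rep(NA_character_, n - 1L))
  age[seq_len(n)] <- ages[ord]
  ## sequential joins: lineage tops merged oldest-last, small increments
  tops <- seq_len(n)                       # node ids, ages ascending
  nid <- n
  while (length(tops) > 1L) {
    o <- order(age[tops])
    a <- tops[o[1L]]; b <- tops[o[2L]]
    nid <- nid + 1L
    age[nid] <- max(age[c(a, b)]) + stats::rexp(1L, 5) + 1e-3
    parent[c(a, b)] <- nid
    tops <- c(setdiff(tops, c(a, b)), nid)
  }
  origin <- age[nid] + 0.5
  tree <- sa_tree(parent, age, is_samp, label, origin)
  clock <- switch(clock_model,
    ulnc = clock_state("ulnc", length(parent), M = 0.1, S = 0.2,
                       rates = rep(0.1, length(parent))),
    ncat2 = clock_state("ncat2", length(parent), r1 = 0.2, r2 = 0.2,
                        categories = rep(1:2, length.out = length(parent))),
    strict = clock_state("strict", rate = 0.1))
  list(tree = tree,
       lambda = rep(1 / prior$rate_prior_rate, K),
       mu = rep(1 / prior$rate_prior_rate, K),
       psi = rep(1 / prior$rate_prior_rate, K),
       root = unname(colMeans(traits$values)),
       sigma2 = rep(exp(prior$sigma2_location), k),
       corr = 0,
       clock = clock)
}

trace_row <- function(g, state, curr, k, K) {
  cl <- state$clock
  clcols <- switch(cl$model,
    ulnc = c(clock_M = cl$M, clock_S = cl$S,
             clock_rate_median = stats::median(cl$rates),
             clock_rate_var = stats::var(cl$rates)),
    ncat2 = {
      r <- clock_rates(cl)
      c(clock_r1 = cl$r1, clock_r2 = cl$r2,
        clock_rate_median = stats::median(r), clock_rate_var = stats::var(r))
    },
    strict = c(clock_rate = cl$rate))
  c(generation = g,
    posterior = total_log_post(curr), likelihood = curr$bm,
    prior = curr$fbd + curr$prior,
    stats::setNames(state$lambda, paste0("lambda_", seq_len(K))),
    stats::setNames(state$mu, paste0("mu_", seq_len(K))),
    stats::setNames(state$psi, paste0("psi_", seq_len(K))),
    origin = state$tree$origin_age,
    root_age = state$tree$age[root_node(state$tree)],
    n_sampled_ancestors = length(sa_nodes(state$tree)),
    stats::setNames(state$sigma2, paste0("sigma2_", seq_len(k))),
    corr = state$corr,
    stats::setNames(state$root, paste0("root_", seq_len(k))),
    clcols)
}

## ---- proposal kernels ------------------------------------------------

scale_propose <- function(x, delta) {
  m <- exp(stats::runif(1L, -delta, delta))
  list(value = x * m, log_hastings = log(m))
}

build_moves <- function(state, config) {
  k <- length(state$sigma2); K <- length(state$lambda)
  fixed_ages <- config$fixed_tip_ages
  fun <- list(
    rate_scale = function(s, d, tun) {
      block <- sample(c("lambda", "mu", "psi"), 1L)
      i <- sample.int(K, 1L)
      pr <- scale_propose(s[[block]][i], tun$rate_scale)
      s[[block]][i] <- pr$value
      list(state = s, log_hastings = pr$log_hastings, blocks = c("fbd", "prior"))
    },
    sigma2_scale = function(s, d, tun) {
      i <- sample.int(k, 1L)
      pr <- scale_propose(s$sigma2[i], tun$sigma2_scale)
      s$sigma2[i] <- pr$value
      list(state = s, log_hastings = pr$log_hastings, blocks = c("bm", "prior"))
    },
    corr_slide = function(s, d, tun) {
      s$corr <- s$corr + stats::runif(1L, -tun$corr_slide, tun$corr_slide)
      list(state = s, log_hastings = 0, blocks = c("bm", "prior"))
    },
    root_slide = function(s, d, tun) {
      i <- sample.int(k, 1L)
      s$root[i] <- s$root[i] + stats::rnorm(1L, 0, tun$root_slide)
      list(state = s, log_hastings = 0, blocks = c("bm", "prior"))
    },
    clock_hyper = function(s, d, tun) {
      cl <- s$clock
      if (cl$model == "ulnc") {
        if (stats::runif(1L) < 0.5) {
          pr <- scale_propose(cl$M, tun$clock_scale); cl$M <- pr$value
        } else {
          pr <- scale_propose(cl$S, tun$clock_scale); cl$S <- pr$value
        }
      } else if (cl$model == "ncat2") {
        if (stats::runif(1L) < 0.5) {
          pr <- scale_propose(cl$r1, tun$clock_scale); cl$r1 <- pr$value
        } else {
          pr <- scale_propose(cl$r2, tun$clock_scale); cl$r2 <- pr$value
        }
      } else {
        pr <- scale_propose(cl$rate, tun$clock_scale); cl$rate <- pr$value
      }
      s$clock <- cl
      list(state = s, log_hastings = pr$log_hastings, blocks = c("bm", "prior"))
    },
    clock_branch = function(s, d, tun) {
      cl <- s$clock
      if (cl$model == "ulnc") {
        i <- sample.int(length(cl$rates), 1L)
        if (stats::runif(1L) < 0.5) {
          pr <- scale_propose(cl$rates[i], tun$clock_scale)
          cl$rates[i] <- pr$value
          lh <- pr$log_hastings
        } else {
          ## independence redraw from the branch-rate prior: the prior
          ## ratio cancels the proposal, leaving the likelihood ratio
          ml <- log(cl$M) - cl$S^2 / 2
          new <- stats::rlnorm(1L, ml, cl$S)
          lh <- stats::dlnorm(cl$rates[i], ml, cl$S, log = TRUE) -
            stats::dlnorm(new, ml, cl$S, log = TRUE)
          cl$rates[i] <- new
        }
        s$clock <- cl
        list(state = s, log_hastings = lh, blocks = c("bm", "prior"))
      } else if (cl$model == "ncat2") {
        i <- sample.int(length(cl$categories), 1L)
        cl$categories[i] <- 3L - cl$categories[i]
        s$clock <- cl
        list(state = s, log_hastings = 0, blocks = c("bm", "prior"))
      } else NULL
    },
    clock_spread_all = function(s, d, tun) {
      ## scale the ULNC log-space spread and every branch rate's
      ## log-deviation from the mean together (deterministic
      ## reparameterized scale move with its Jacobian)
      cl <- s$clock
      if (cl$model != "ulnc") return(NULL)
      m <- exp(stats::runif(1L, -tun$clock_scale, tun$clock_scale))
      ml_old <- log(cl$M) - cl$S^2 / 2
      Snew <- cl$S * m
      ml_new <- log(cl$M) - Snew^2 / 2
      z <- (log(cl$rates) - ml_old) / cl$S
      rnew <- exp(ml_new + Snew * z)
      lj <- log(m) + sum(log(m) + log(rnew) - log(cl$rates))
      cl$S <- Snew; cl$rates <- rnew
      s$clock <- cl
      list(state = s, log_hastings = lj, blocks = c("bm", "prior"))
    },
    clock_scale_all = function(s, d, tun) {
      ## scale the ULNC mean and every branch rate together: walks the
      ## hierarchy out of its funnel
      cl <- s$clock
      if (cl$model != "ulnc") return(NULL)
      m <- exp(stats::runif(1L, -tun$clock_scale, tun$clock_scale))
      cl$M <- cl$M * m
      cl$rates <- cl$rates * m
      s$clock <- cl
      list(state = s, log_hastings = (length(cl$rates) + 1) * log(m),
           blocks = c("bm", "prior"))
    },
    tip_age = function(s, d, tun) {
      if (fixed_ages) return(NULL)
      tr <- s$tree
      samp <- which(tr$is_sample)
      nd <- samp[sample.int(length(samp), 1L)]
      b <- d$age_bounds
      j <- match(tr$label[nd], b$taxon_id)
      win <- age_window(tr, nd)
      lo <- max(b$age_min[j], win[1L]); hi <- min(b$age_max[j], win[2L])
      if (hi <= lo) return(NULL)
      tr$age[nd] <- stats::runif(1L, lo, hi)
      s$tree <- tr
      list(state = s, log_hastings = 0, blocks = c("fbd", "bm", "prior"))
    },
    node_age = if (config$tree_free) NULL else function(s, d, tun) {
      tr <- s$tree
      bif <- bifurcation_nodes(tr)
      if (!length(bif)) return(NULL)
      nd <- bif[sample.int(length(bif), 1L)]
      win <- age_window(tr, nd)
      if (win[2L] <= win[1L]) return(NULL)
      tr$age[nd] <- stats::runif(1L, win[1L], win[2L])
      s$tree <- tr
      list(state = s, log_hastings = 0, blocks = c("fbd", "bm", "prior"))
    },
    origin_slide = if (config$tree_free) NULL else function(s, d, tun) {
      tr <- s$tree
      o <- tr$origin_age + stats::runif(1L, -tun$origin_slide, tun$origin_slide)
      if (o <= tr$age[root_node(tr)]) return(NULL)
      tr$origin_age <- o
      s$tree <- tr
      list(state = s, log_hastings = 0, blocks = c("fbd", "bm", "prior"))
    },
    narrow_exchange = if (config$fixed_topology) NULL else function(s, d, tun) {
      mv <- propose_narrow_exchange(s$tree)
      if (is.null(mv)) return(NULL)
      s$tree <- mv$tree
      list(state = s, log_hastings = mv$log_hastings,
           blocks = c("fbd", "bm", "prior"))
    },
    subtree_regraft = if (config$fixed_topology) NULL else function(s, d, tun) {
      mv <- propose_spr(s$tree)
      if (is.null(mv)) return(NULL)
      s$tree <- mv$tree
      list(state = s, log_hastings = mv$log_hastings,
           blocks = c("fbd", "bm", "prior"))
    },
    sa_toggle = if (config$fixed_topology) NULL else function(s, d, tun) {
      mv <- propose_sa_toggle(s$tree, s$clock)
      if (is.null(mv)) return(NULL)
      s$tree <- mv$tree
      s$clock <- mv$clock
      list(state = s, log_hastings = mv$log_hastings,
           blocks = c("fbd", "bm", "prior"))
    })
  fun <- fun[!vapply(fun, is.null, TRUE)]
  w <- c(rate_scale = 4, sigma2_scale = 1.5, corr_slide = 0.5,
         root_slide = 1, clock_hyper = 1.5, clock_branch = 2,
         clock_scale_all = 1, clock_spread_all = 1,
         tip_age = 2, node_age = 3, origin_slide = 1.5,
         narrow_exchange = 2, subtree_regraft = 2, sa_toggle = 2)
  w <- w[names(fun)]
  if (!is.null(config$move_weights)) {
    ov <- config$move_weights
    w[names(ov)[names(ov) %in% names(w)]] <- ov[names(ov) %in% names(w)]
  }
  list(fun = fun, w = w)
}
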