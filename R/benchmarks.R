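#' Parameter-recovery experiment on synthetic studies
#'
#' Simulates replicate synthetic studies with [make_study_scenario()],
#' runs the joint inference on each, and records whether the 95%
#' highest-posterior-density interval of every per-interval birth,
#' death and sampling rate covers the simulating value. Problem sizes
#' default to desk scale; the replicate seed stream is a fixed function
#' of `seed`.
#'
#' @param n_replicates number of simulated studies.
#' @param n_taxa taxa per study (default 32).
#' @param n_generations,sample_every chain settings per replicate.
#' @param seed base seed.
#' @param level HPD level (default 0.95).
#' @param clock_model clock used in inference (default ULNC).
#' @return List with `table` (one row per replicate x parameter:
#'   `replicate`, `parameter`, `truth`, `hpd_lo`, `hpd_hi`, `covered`)
#'   and `coverage` (pooled fraction covered).
#' @export
recovery_experiment <- function(n_replicates = 8L, n_taxa = 32L,
                                n_generations = 18000L, sample_every = 25L,
                                seed = 1L, level = 0.95,
                                clock_model = "ulnc") {
  rows <- list()
  for (r in seq_len(n_replicates)) {
    res <- make_study_scenario(n_taxa, seed = derive_seed(seed, 31L + r))
    cfg <- mcmc_config(n_generations = n_generations,
                       sample_every = sample_every,
                       seed = derive_seed(seed, 97L + r))
    tr <- run_mcmc(res$traits, res$samples, present_bp = res$present_bp,
                   clock_model = clock_model, config = cfg)
    burn <- floor(cfg$burnin_fraction * nrow(tr$table))
    tab <- tr$table[seq.int(burn + 1L, nrow(tr$table)), , drop = FALSE]
    p <- res$scenario$params
    truth <- c(stats::setNames(p$lambda, paste0("lambda_", 1:4)),
               stats::setNames(p$mu, paste0("mu_", 1:4)),
               stats::setNames(p$psi, paste0("psi_", 1:4)))
    for (nm in names(truth)) {
      h <- hpd_interval(tab[[nm]], level)
      rows[[length(rows) + 1L]] <-
        data.frame(replicate = r, parameter = nm, truth = truth[[nm]],
                   hpd_lo = h[1L], hpd_hi = h[2L],
                   covered = truth[[nm]] >= h[1L] && truth[[nm]] <= h[2L])
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  list(table = table, coverage = mean(table$covered))
}

#' Under-the-prior contrast of the sampling-rate posterior
#'
#' Runs the skyline inference on one synthetic study with the trait
#' likelihood disabled, so any information about the rates comes from
#' the sampling times alone, and contrasts the posterior of the
#' sampling rate in a well-sampled interval with its Exp prior.
#'
#' @param n_taxa taxa in the synthetic study.
#' @param n_generations,sample_every chain settings.
#' @param seed integer seed.
#' @param interval which skyline interval's psi to contrast (default 3,
#'   a densely sampled bin).
#' @param prior_rate the Exp prior rate (default 10).
#' @return List with `ks_statistic` (Kolmogorov distance between the
#'   posterior sample and the prior), `posterior_median`,
#'   `prior_median`, and the `trace`.
#' @export
under_prior_contrast <- function(n_taxa = 32L, n_generations = 30000L,
                                 sample_every = 25L, seed = 1L,
                                 interval = 3L, prior_rate = 10) {
  res <- make_study_scenario(n_taxa, seed = derive_seed(seed, 7L))
  cfg <- mcmc_config(n_generations = n_generations,
                     sample_every = sample_every,
                     seed = derive_seed(seed, 11L), under_prior = TRUE)
  tr <- run_mcmc(res$traits, res$samples, present_bp = res$present_bp,
                 config = cfg)
  burn <- floor(cfg$burnin_fraction * nrow(tr$table))
  x <- tr$table[[paste0("psi_", interval)]][-seq_len(burn)]
  ks <- suppressWarnings(stats::ks.test(x, stats::pexp, prior_rate))
  list(ks_statistic = unname(ks$statistic),
       posterior_median = stats::median(x),
       prior_median = stats::qexp(0.5, prior_rate),
       trace = tr)
}

#' Clock-rate trend across trait counts
#'
#' Runs the inference on one synthetic study with nested prefixes of
#' the trait axes and records the posterior median clock rate per
#' trait count — the taxa-trait benchmarking axis along which adding
#' lower-variance traits dilutes the shared clock.
#'
#' @param trait_counts increasing trait prefix sizes (>= 4 values for a
#'   trend test).
#' @param n_taxa taxa in the synthetic study.
#' @param n_generations,sample_every chain settings per cell.
#' @param seed integer seed.
#' @return data.frame with `n_traits`, `median_clock_rate`,
#'   `clock_rate_var`, plus attributes `spearman` (rank correlation of
#'   median clock rate with trait count), `kendall_tau` and
#'   `trend_p` (one-sided Kendall test of a decreasing trend).
#' @export
clock_trait_trend <- function(trait_counts = c(2L, 3L, 4L, 6L, 8L, 9L),
                              n_taxa = 32L, n_generations = 20000L,
                              sample_every = 25L, seed = 1L) {
  res <- make_study_scenario(n_taxa, seed = derive_seed(seed, 13L))
  rows <- list()
  for (i in seq_along(trait_counts)) {
    np <- trait_counts[i]
    tm <- trait_matrix(res$traits$values[, seq_len(np), drop = FALSE],
                       taxa = res$traits$taxa)
    cfg <- mcmc_config(n_generations = n_generations,
                       sample_every = sample_every,
                       seed = derive_seed(seed, 17L + i))
    tr <- run_mcmc(tm, res$samples, present_bp = res$present_bp,
                   config = cfg)
    burn <- floor(cfg$burnin_fraction * nrow(tr$table))
    tab <- tr$table[-seq_len(burn), , drop = FALSE]
    rows[[i]] <- data.frame(n_traits = np,
                            median_clock_rate = stats::median(tab$clock_rate_median),
                            clock_rate_var = stats::median(tab$clock_rate_var))
  }
  out <- do.call(rbind, rows)
  attr(out, "spearman") <- stats::cor(out$n_traits, out$median_clock_rate,
                                      method = "spearman")
  kt <- suppressWarnings(
    stats::cor.test(out$n_traits, out$median_clock_rate,
                    method = "kendall", alternative = "less"))
  attr(out, "kendall_tau") <- unname(kt$estimate)
  attr(out, "trend_p") <- kt$p.value
  out
}
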