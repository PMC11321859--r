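#' Shortest highest-posterior-density interval
#'
#' The shortest contiguous interval containing `ceiling(level * n)` of
#' the sorted samples.
#'
#' @param samples numeric vector, length >= 10 (constant vectors give a
#'   zero-width interval).
#' @param level probability mass, default 0.95.
#' @return `c(lo, hi)`.
#' @export
hpd_interval <- function(samples, level = 0.95) {
  x <- sort(as.numeric(samples))
  n <- length(x)
  if (n < 10L) stop("need at least 10 samples")
  m <- ceiling(level * n)
  if (m >= n) return(c(x[1L], x[n]))
  widths <- x[seq.int(m, n)] - x[seq.int(1L, n - m + 1L)]
  i <- which.min(widths)
  c(x[i], x[i + m - 1L])
}

## canonical string id for the sample set under a node (clade);
## sampled ancestors count as members of their attachment clade
clade_ids <- function(tr) {
  n <- length(tr$parent)
  sets <- vector("list", n)
  ch <- children_list(tr)
  for (nd in postorder(tr)) {
    kids <- ch[[nd]]
    s <- unlist(sets[kids], use.names = FALSE)
    if (tr$is_sample[nd]) s <- c(s, tr$label[nd])
    sets[[nd]] <- sort(s)
  }
  vapply(sets, paste, "", collapse = "|")
}

#' Posterior clade probabilities
#'
#' Frequency of each clade (taxon set under a node, sampled ancestors
#' included in their attachment clade) across a posterior tree sample.
#'
#' @param trees non-empty list of [sa_tree]s over one taxon set.
#' @return Named numeric vector of probabilities (names are
#'   `|`-joined sorted taxon labels).
#' @export
clade_probabilities <- function(trees) {
  stopifnot(length(trees) >= 1L)
  taxa <- sort(sample_labels(trees[[1L]]))
  counts <- new.env(hash = TRUE)
  for (tr in trees) {
    if (!identical(sort(sample_labels(tr)), taxa))
      stop("trees have inconsistent taxon sets")
    for (cl in unique(clade_ids(tr))) {
      cur <- counts[[cl]]
      counts[[cl]] <- if (is.null(cur)) 1L else cur + 1L
    }
  }
  out <- unlist(as.list(counts))
  sort(out / length(trees), decreasing = TRUE)
}

#' Maximum clade credibility tree
#'
#' Selects the sampled tree maximizing the sum of log clade
#' probabilities (the product of clade supports); no consensus tree is
#' constructed. By default node heights are kept as they are in the
#' selected target tree; alternatively each clade age can be replaced
#' by the median age of matching clades across the sample. The tree is
#' annotated per node with the clade posterior probability, the 95% HPD
#' of matching-clade ages, and the median branch length of matching
#' clades.
#'
#' @param trees non-empty list of [sa_tree]s.
#' @param keep_target_heights keep the target tree's own node ages
#'   (default TRUE); otherwise use median matching-clade ages.
#' @param rates optional list of per-branch rate vectors (indexed by
#'   node, parallel to `trees`) used to annotate median branch rates.
#' @return List of class `mcc_tree`: `tree`, `log_clade_credibility`,
#'   `annotations` (data.frame per node: clade, pp, age, age_hpd_lo,
#'   age_hpd_hi, median_branch_length, median_branch_rate).
#' @export
mcc_tree <- function(trees, keep_target_heights = TRUE, rates = NULL) {
  pp <- clade_probabilities(trees)
  score <- function(tr) sum(log(pp[clade_ids(tr)]))
  scores <- vapply(trees, score, 0)
  best <- which.max(scores)
  target <- trees[[best]]
  ids <- clade_ids(target)
  ## collect matching-clade ages and branch lengths across the sample
  age_pool <- lapply(ids, function(i) numeric(0))
  names(age_pool) <- ids
  len_pool <- age_pool
  rate_pool <- age_pool
  for (ti in seq_along(trees)) {
    tr <- trees[[ti]]
    cid <- clade_ids(tr)
    bl <- branch_durations(tr)
    for (nd in seq_along(cid)) {
      cl <- cid[nd]
      if (!is.null(age_pool[[cl]])) {
        age_pool[[cl]] <- c(age_pool[[cl]], tr$age[nd])
        if (!is.na(bl[nd])) len_pool[[cl]] <- c(len_pool[[cl]], bl[nd])
        if (!is.null(rates))
          rate_pool[[cl]] <- c(rate_pool[[cl]], rates[[ti]][nd])
      }
    }
  }
  ann <- data.frame(
    node = seq_along(ids), clade = ids, pp = as.numeric(pp[ids]),
    age = target$age,
    age_hpd_lo = vapply(ids, function(i)
      if (length(age_pool[[i]]) >= 10L) hpd_interval(age_pool[[i]])[1L]
      else min(age_pool[[i]]), 0),
    age_hpd_hi = vapply(ids, function(i)
      if (length(age_pool[[i]]) >= 10L) hpd_interval(age_pool[[i]])[2L]
      else max(age_pool[[i]]), 0),
    median_branch_length = vapply(ids, function(i) {
      v <- len_pool[[i]]
      if (length(v)) stats::median(v) else NA_real_ }, 0),
    median_branch_rate = vapply(ids, function(i) {
      v <- rate_pool[[i]]
      if (length(v)) stats::median(v) else NA_real_ }, 0),
    row.names = NULL)
  tree <- target
  if (!keep_target_heights) {
    med <- vapply(ids, function(i) stats::median(age_pool[[i]]), 0)
    ## only adopt median heights when they respect the ordering
    ok <- tryCatch({
      t2 <- target; t2$age <- unname(med)
      validate_sa_tree(t2); t2
    }, error = function(e) NULL)
    if (!is.null(ok)) { tree <- ok; ann$age <- unname(med) }
  }
  structure(list(tree = tree, log_clade_credibility = scores[best],
                 annotations = ann, target_index = best),
            class = "mcc_tree")
}

#' @export
print.mcc_tree <- function(x, ...) {
  cat(sprintf("<mcc_tree> log clade credibility %.3f, %d nodes\n",
              x$log_clade_credibility, nrow(x$annotations)))
  invisible(x)
}

#' Skyline rate summary
#'
#' Per-interval median and 95% HPD of the birth, death and sampling
#' rates plus the diversification (`d = lambda - mu`) and turnover
#' (`t = mu / lambda`) rates, the latter two recomputed row-wise from
#' the trace before summarizing.
#'
#' @param trace a `posterior_trace` (or its `table`).
#' @param bin_labels interval labels, oldest first.
#' @param burnin_fraction leading fraction discarded (0 if the trace is
#'   already combined/burned in).
#' @return data.frame with columns `bin`, `rate`, `median`, `hpd_lo`,
#'   `hpd_hi`.
#' @export
skyline_summary <- function(trace,
                            bin_labels = c("GS-2", "GI-1", "GS-1", "Holocene"),
                            burnin_fraction = 0) {
  tab <- if (inherits(trace, "posterior_trace")) trace$table else trace
  K <- length(bin_labels)
  need <- c(paste0("lambda_", 1:K), paste0("mu_", 1:K), paste0("psi_", 1:K))
  if (!all(need %in% colnames(tab)))
    stop("trace lacks per-interval rate columns: ",
         paste(setdiff(need, colnames(tab)), collapse = ", "))
  if (burnin_fraction > 0) {
    n <- nrow(tab)
    tab <- tab[seq.int(floor(burnin_fraction * n) + 1L, n), , drop = FALSE]
  }
  rows <- list()
  for (i in seq_len(K)) {
    lam <- tab[[paste0("lambda_", i)]]
    mu <- tab[[paste0("mu_", i)]]
    psi <- tab[[paste0("psi_", i)]]
    vals <- list(lambda = lam, mu = mu, psi = psi,
                 d = diversification_rate(lam, mu),
                 t = mu / pmax(lam, .Machine$double.xmin))
    for (rn in names(vals)) {
      h <- hpd_interval(vals[[rn]])
      rows[[length(rows) + 1L]] <-
        data.frame(bin = bin_labels[i], rate = rn,
                   median = stats::median(vals[[rn]]),
                   hpd_lo = h[1L], hpd_hi = h[2L])
    }
  }
  out <- do.call(rbind, rows)
  out$bin <- factor(out$bin, levels = bin_labels)
  out
}

#' Node and branch metrics of an MCC tree
#'
#' Long-format table of the four metric families used to benchmark
#' taxa-trait combinations: posterior clade probabilities of internal
#' clades, lengths of the 95% HPD ranges of node ages, median branch
#' lengths, and median branch rates; with per-family median and mean
#' summary rows appended.
#'
#' @param mcc an `mcc_tree`.
#' @return data.frame with columns `metric`, `node`, `value`, `summary`
#'   (`"value"`, `"median"` or `"mean"`).
#' @export
tree_metrics <- function(mcc) {
  stopifnot(inherits(mcc, "mcc_tree"))
  ann <- mcc$annotations
  tr <- mcc$tree
  internal <- which(!tr$is_sample | vapply(seq_along(tr$parent), function(nd)
    length(children_of(tr, nd)) > 0L, TRUE))
  branches <- which(!is.na(tr$parent))
  fam <- list(
    pp = data.frame(metric = "pp", node = internal,
                    value = ann$pp[internal]),
    age_hpd_width = data.frame(metric = "age_hpd_width", node = internal,
                               value = (ann$age_hpd_hi - ann$age_hpd_lo)[internal]),
    branch_length = data.frame(metric = "branch_length", node = branches,
                               value = ann$median_branch_length[branches]),
    branch_rate = data.frame(metric = "branch_rate", node = branches,
                             value = ann$median_branch_rate[branches]))
  out <- do.call(rbind, fam)
  out$summary <- "value"
  for (m in names(fam)) {
    v <- fam[[m]]$value
    v <- v[is.finite(v)]
    if (!length(v)) next
    out <- rbind(out,
                 data.frame(metric = m, node = NA_integer_,
                            value = stats::median(v), summary = "median"),
                 data.frame(metric = m, node = NA_integer_,
                            value = mean(v), summary = "mean"))
  }
  rownames(out) <- NULL
  out
}

#' Taxa-by-trait benchmarking grid
#'
#' Runs the inference over a grid of taxon counts and trait counts
#' (trait subsets are nested prefixes of the PC axes) and records for
#' each cell the posterior median clock rate, the clock-rate variance,
#' and the MCC tree metric summaries. Cells use a shared base seed plus
#' a cell offset; per-cell failures are recorded and the grid
#' continues.
#'
#' @param traits full [trait_matrix] (taxa x all PC axes).
#' @param samples full [dated_samples] table.
#' @param taxa_counts integer vector of taxa subset sizes (stratified
#'   subsampling by climate bin).
#' @param trait_counts integer vector of trait prefix sizes.
#' @param base_config an [mcmc_config]; each cell derives its seed from
#'   it.
#' @param ... further arguments passed to [run_mcmc()] (e.g.
#'   `present_bp`, `boundaries_bp`, `clock_model`).
#' @return data.frame with one row per cell: `n_taxa`, `n_traits`,
#'   `seed`, `median_clock_rate`, `clock_rate_var`, `mean_pp`,
#'   `median_age_hpd_width`, `median_branch_length`, `error`
#'   (NA on success).
#' @export
run_grid <- function(traits, samples, taxa_counts, trait_counts,
                     base_config = mcmc_config(), ...) {
  rows <- list()
  cell <- 0L
  for (nt in taxa_counts) for (np in trait_counts) {
    cell <- cell + 1L
    seed <- derive_seed(base_config$seed, cell)
    row <- data.frame(n_taxa = nt, n_traits = np, seed = seed,
                      median_clock_rate = NA_real_, clock_rate_var = NA_real_,
                      mean_pp = NA_real_, median_age_hpd_width = NA_real_,
                      median_branch_length = NA_real_, error = NA_character_)
    res <- tryCatch({
      per_bin <- max(1L, nt %/% length(unique(samples$bin)))
      sub <- stratified_subsample(samples, per_bin, seed)
      if (nrow(sub) > nt) sub <- sub[seq_len(nt), , drop = FALSE]
      keep <- sub$taxon_id
      tm <- trait_matrix(traits$values[match(keep, traits$taxa),
                                       seq_len(np), drop = FALSE],
                         taxa = keep)
      cfg <- base_config; cfg$seed <- seed
      tr <- run_mcmc(tm, sub, config = cfg, ...)
      burn <- floor(cfg$burnin_fraction * nrow(tr$table))
      tab <- tr$table[seq.int(burn + 1L, nrow(tr$table)), , drop = FALSE]
      row$median_clock_rate <- stats::median(tab$clock_rate_median)
      row$clock_rate_var <- stats::median(tab$clock_rate_var)
      keep_rows <- seq.int(burn + 1L, length(tr$trees))
      mcc <- mcc_tree(tr$trees[keep_rows], rates = tr$branch_rates[keep_rows])
      tm2 <- tree_metrics(mcc)
      row$mean_pp <- tm2$value[tm2$metric == "pp" & tm2$summary == "mean"]
      row$median_age_hpd_width <-
        tm2$value[tm2$metric == "age_hpd_width" & tm2$summary == "median"]
      row$median_branch_length <-
        tm2$value[tm2$metric == "branch_length" & tm2$summary == "median"]
      row
    }, error = function(e) { row$error <- conditionMessage(e); row })
    rows[[cell]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
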