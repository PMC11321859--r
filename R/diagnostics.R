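#' Effective sample size of an autocorrelated series
#'
#' Autocorrelation-based ESS using the spectral-density-at-zero
#' estimator: an autoregressive model is fitted by AIC and the ESS is
#' `n * var(x) / s(0)` where `s(0)` is the fitted spectral density at
#' frequency zero. Constant (degenerate) series report their length
#' with a `degenerate` attribute.
#'
#' @param series numeric vector, length >= 10.
#' @return ESS (clamped to `length(series)`).
#' @export
ess <- function(series) {
  x <- as.numeric(series)
  n <- length(x)
  if (n < 10L) stop("need at least 10 samples for an ESS")
  v <- stats::var(x)
  if (!is.finite(v) || v < .Machine$double.eps * max(1, mean(x)^2)) {
    out <- n
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  fit <- tryCatch(stats::ar(x, aic = TRUE, order.max = min(50L, n %/% 4L)),
                  error = function(e) NULL)
  if (is.null(fit) || !length(fit$ar)) {
    s0 <- v
  } else {
    s0 <- fit$var.pred / (1 - sum(fit$ar))^2
  }
  min(n, n * v / s0)
}

#' Combine posterior traces with burn-in removal
#'
#' Removes the leading `burnin_fraction` of every chain and
#' concatenates the remaining rows (and tree logs).
#'
#' @param traces list of `posterior_trace` objects with identical
#'   column schemas.
#' @param burnin_fraction leading fraction to discard, default 0.20.
#' @return A combined `posterior_trace`.
#' @export
combine_logs <- function(traces, burnin_fraction = 0.20) {
  stopifnot(length(traces) >= 1L,
            all(vapply(traces, inherits, TRUE, "posterior_trace")))
  cols <- lapply(traces, function(tr) colnames(tr$table))
  if (!all(vapply(cols, identical, TRUE, cols[[1L]])))
    stop("traces differ in column schema")
  cut <- function(tr) {
    n <- nrow(tr$table)
    keep <- seq.int(floor(burnin_fraction * n) + 1L, n)
    list(table = tr$table[keep, , drop = FALSE], trees = tr$trees[keep],
         branch_rates = tr$branch_rates[keep])
  }
  parts <- lapply(traces, cut)
  out <- traces[[1L]]
  out$table <- do.call(rbind, lapply(parts, `[[`, "table"))
  rownames(out$table) <- NULL
  out$trees <- do.call(c, lapply(parts, `[[`, "trees"))
  out$branch_rates <- do.call(c, lapply(parts, `[[`, "branch_rates"))
  out
}

#' Convergence report on trace columns
#'
#' ESS per numeric column for each trace (chains assessed separately),
#' with a pass flag requiring prior, posterior and likelihood ESS all
#' at or above the threshold.
#'
#' @param traces a `posterior_trace` or list of them.
#' @param threshold ESS threshold, default 200.
#' @return data.frame with columns `chain`, `column`, `ess`, plus an
#'   attribute `pass` (logical).
#' @export
convergence_report <- function(traces, threshold = 200) {
  if (inherits(traces, "posterior_trace")) traces <- list(traces)
  rows <- list()
  pass <- TRUE
  for (ci in seq_along(traces)) {
    tab <- traces[[ci]]$table
    for (col in setdiff(colnames(tab), "generation")) {
      e <- ess(tab[[col]])
      rows[[length(rows) + 1L]] <- data.frame(chain = ci, column = col,
                                              ess = as.numeric(e))
      if (col %in% c("prior", "posterior", "likelihood")) {
        degen <- isTRUE(attr(e, "degenerate"))
        if (!degen && e < threshold) pass <- FALSE
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "pass") <- pass
  out
}

#' Write a posterior trace as a tab-separated log
#'
#' BEAST-style column log: `#` comment header with provenance (seed,
#' generations, model), then one tab-separated row per sample.
#'
#' @param trace a `posterior_trace`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fbdshape trace | seed %d | generations %d | clock %s",
                     trace$config$seed, trace$config$n_generations,
                     trace$clock_model), con)
  utils::write.table(trace$table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a trace log written by [write_trace()]
#'
#' @param path file path.
#' @return data.frame of trace rows (tree log not included).
#' @export
read_trace <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
}

#' Write sampled trees as a NEXUS tree log
#'
#' @param trees list of [sa_tree]s.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tree_log <- function(trees, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#NEXUS", con)
  writeLines("begin trees;", con)
  for (i in seq_along(trees))
    writeLines(sprintf("  tree STATE_%d = %s", i, write_sa_newick(trees[[i]])),
               con)
  writeLines("end;", con)
  invisible(path)
}

#' Read a NEXUS tree log written by [write_tree_log()]
#'
#' @param path file path.
#' @return List of [sa_tree]s.
#' @export
read_tree_log <- function(path) {
  lines <- readLines(path)
  tl <- grep("^\\s*tree\\s", lines, value = TRUE)
  lapply(tl, function(l) read_sa_newick(sub("^[^=]*=\\s*", "", l)))
}
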