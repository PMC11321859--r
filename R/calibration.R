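#' Radiocarbon calibration curve
#'
#' A calibration curve maps calendar age to conventional radiocarbon age
#' with a per-point curve error, on a strictly increasing calendar-age
#' grid (linear interpolation between grid points). All ages are in ka.
#'
#' @param grid strictly increasing calendar ages (ka BP).
#' @param c14_mean radiocarbon age (ka) at each grid point.
#' @param c14_error positive curve error (ka) at each grid point.
#' @return Object of class `cal_curve`.
#' @export
cal_curve <- function(grid, c14_mean, c14_error) {
  grid <- as.numeric(grid); c14_mean <- as.numeric(c14_mean)
  c14_error <- as.numeric(c14_error)
  n <- length(grid)
  stopifnot(n >= 2L, length(c14_mean) == n, length(c14_error) == n)
  if (any(diff(grid) <= 0)) stop("calibration grid must be strictly increasing")
  ## zero errors are tolerated for idealized test curves; calibration
  ## itself requires a positive combined error
  if (any(c14_error < 0)) stop("curve errors must be non-negative")
  structure(list(grid = grid, c14_mean = c14_mean, c14_error = c14_error),
            class = "cal_curve")
}

#' @export
print.cal_curve <- function(x, ...) {
  cat(sprintf("<cal_curve> %d points on [%.3f, %.3f] ka\n",
              length(x$grid), min(x$grid), max(x$grid)))
  invisible(x)
}

curve_at <- function(curve, age) {
  list(mean = stats::approx(curve$grid, curve$c14_mean, xout = age, rule = 2)$y,
       error = stats::approx(curve$grid, curve$c14_error, xout = age, rule = 2)$y)
}

#' Calibrated-age density
#'
#' @param grid calendar ages (ka).
#' @param density non-negative values integrating to 1 over the grid
#'   (trapezoid rule).
#' @return Object of class `cal_density`.
#' @export
cal_density <- function(grid, density) {
  grid <- as.numeric(grid); density <- as.numeric(density)
  stopifnot(length(grid) == length(density), all(density >= 0))
  mass <- trapz(grid, density)
  if (!is.finite(mass) || mass <= 0) stop("density has no mass on the grid")
  structure(list(grid = grid, density = density / mass), class = "cal_density")
}

trapz <- function(x, y) sum(diff(x) * (y[-length(y)] + y[-1L]) / 2)

#' Calibrate a radiocarbon date
#'
#' The posterior density of the calendar age theta is proportional to
#' `Normal(c14_age; mu(theta), sqrt(c14_err^2 + sigma(theta)^2))` where
#' mu and sigma are the curve mean and error, evaluated on the curve's
#' native grid and normalized by the trapezoid rule.
#'
#' @param c14_age conventional radiocarbon age (ka).
#' @param c14_err laboratory error (ka), > 0.
#' @param curve a [cal_curve].
#' @return A [cal_density] over the curve grid.
#' @export
calibrate <- function(c14_age, c14_err, curve) {
  stopifnot(inherits(curve, "cal_curve"), c14_err > 0)
  sd <- sqrt(c14_err^2 + curve$c14_error^2)
  dens <- stats::dnorm(c14_age, mean = curve$c14_mean, sd = sd)
  if (trapz(curve$grid, dens) <= 0)
    stop("date has zero mass on the calibration grid")
  cal_density(curve$grid, dens)
}

#' Summed probability distribution of calibrated dates
#'
#' Pointwise sum of member densities on a shared grid, renormalized to
#' integrate to one.
#'
#' @param densities non-empty list of [cal_density] on the same grid.
#' @return A [cal_density].
#' @export
spd <- function(densities) {
  if (!length(densities)) stop("spd of an empty list")
  stopifnot(all(vapply(densities, inherits, TRUE, "cal_density")))
  g <- densities[[1L]]$grid
  for (d in densities)
    if (length(d$grid) != length(g) || any(d$grid != g))
      stop("spd members must share one grid")
  cal_density(g, Reduce(`+`, lapply(densities, `[[`, "density")))
}

#' Median of a calibrated density
#'
#' Calendar age at which the cumulative mass (trapezoid rule) first
#' reaches one half, linearly interpolated between grid points.
#'
#' @param d a [cal_density].
#' @return Median age (ka).
#' @export
median_age <- function(d) {
  stopifnot(inherits(d, "cal_density"))
  g <- d$grid; f <- d$density
  cum <- c(0, cumsum(diff(g) * (f[-length(f)] + f[-1L]) / 2))
  cum <- cum / cum[length(cum)]
  i <- which(cum >= 0.5)[1L]
  if (i == 1L) return(g[1L])
  g[i - 1L] + (0.5 - cum[i - 1L]) / (cum[i] - cum[i - 1L]) * (g[i] - g[i - 1L])
}

#' Highest-density age range
#'
#' Smallest set of highest-density grid regions containing `level` of the
#' probability mass; the envelope (min, max) of that set's support is
#' returned. A central (equal-tail) interval is available as an
#' alternative convention.
#'
#' @param d a [cal_density].
#' @param level probability mass to cover; the default 0.6827 is the
#'   conventional one-sigma region.
#' @param type "hpd" (highest-density region, default) or "central"
#'   (equal-tail quantile interval).
#' @return Numeric vector `c(min, max)` in ka.
#' @export
sigma_range <- function(d, level = 0.6827, type = c("hpd", "central")) {
  stopifnot(inherits(d, "cal_density"), level > 0, level < 1)
  type <- match.arg(type)
  g <- d$grid; f <- d$density
  n <- length(g)
  ## per-point mass: each point carries half of its adjacent segment masses
  dg <- diff(g)
  w <- numeric(n)
  seg <- dg * (f[-n] + f[-1L]) / 2
  w[-n] <- w[-n] + seg / 2
  w[-1L] <- w[-1L] + seg / 2
  w <- w / sum(w)
  if (type == "hpd") {
    ord <- order(f, decreasing = TRUE)
    cum <- cumsum(w[ord])
    k <- which(cum >= level)[1L]
    keep <- sort(ord[seq_len(k)])
    range(g[keep])
  } else {
    cum <- cumsum(w)
    lo <- g[which(cum >= (1 - level) / 2)[1L]]
    hi <- g[which(cum >= 1 - (1 - level) / 2)[1L]]
    c(lo, hi)
  }
}

#' Scale an age from years to ka
#'
#' Ages in years BP are divided by 1000 and rounded half-even to three
#' decimals, the resolution used throughout the analysis.
#'
#' @param age_bp age in years BP, >= 0 (vectorized).
#' @return Age in ka BP rounded to 3 decimals.
#' @export
scale_age <- function(age_bp) {
  if (any(age_bp < 0)) stop("ages must be non-negative")
  round(age_bp / 1000, 3L)
}

#' Assign an age to a climate interval
#'
#' The Greenland event stratigraphy bins used throughout: GS-2 for ages
#' at or above the oldest boundary, then GI-1, GS-1 and Holocene.
#' Boundaries are closed on the older side: an age equal to a boundary
#' belongs to the younger bin.
#'
#' @param age age(s) in ka BP.
#' @param boundaries strictly decreasing bin boundaries in ka BP;
#'   default `c(14.6, 12.9, 11.7)`.
#' @param labels bin labels from oldest to youngest.
#' @return Factor of bin labels.
#' @export
assign_bin <- function(age, boundaries = c(14.6, 12.9, 11.7),
                       labels = c("GS-2", "GI-1", "GS-1", "Holocene")) {
  boundaries <- as.numeric(boundaries)
  if (any(diff(boundaries) >= 0)) stop("boundaries must be strictly decreasing")
  if (length(labels) != length(boundaries) + 1L)
    stop("need one more label than boundaries")
  idx <- vapply(age, function(a) sum(a < boundaries) + 1L, 1L)
  factor(labels[idx], levels = labels)
}

#' Dated sample records
#'
#' @param taxon_id,locale_id identifiers.
#' @param median_age,age_min,age_max ages in ka BP satisfying
#'   `age_min <= median_age <= age_max`.
#' @param bin optional climate bin label; computed from the median age
#'   when missing.
#' @return A data.frame of class `dated_samples` with one row per taxon.
#' @export
dated_samples <- function(taxon_id, locale_id, median_age, age_min, age_max,
                          bin = NULL) {
  median_age <- round(median_age, 3L); age_min <- round(age_min, 3L)
  age_max <- round(age_max, 3L)
  if (any(age_min > median_age | median_age > age_max))
    stop("need age_min <= median_age <= age_max")
  if (is.null(bin)) bin <- assign_bin(median_age)
  out <- data.frame(taxon_id = as.character(taxon_id),
                    locale_id = as.character(locale_id),
                    median_age = median_age, age_min = age_min,
                    age_max = age_max, bin = bin,
                    stringsAsFactors = FALSE)
  class(out) <- c("dated_samples", "data.frame")
  out
}

#' Draw one specimen per locale
#'
#' The sampling protocol that makes site/layer abundance data compatible
#' with a Poisson sampling process along lineages: exactly one uniformly
#' chosen specimen per unique locale.
#'
#' @param records data.frame with at least a `locale_id` column.
#' @param seed integer seed (the draw is a fixed function of it).
#' @return Subset of `records`, one row per locale, ordered by locale.
#' @export
sample_one_per_locale <- function(records, seed) {
  if (!nrow(records)) stop("no records to sample from")
  stopifnot("locale_id" %in% names(records))
  with_seed(seed, {
    locales <- sort(unique(records$locale_id))
    rows <- vapply(locales, function(l) {
      idx <- which(records$locale_id == l)
      if (length(idx) == 1L) idx else sample(idx, 1L)
    }, 1L)
    records[rows, , drop = FALSE]
  })
}

#' Stratified subsample by climate bin
#'
#' Up to `per_bin` samples uniformly chosen per climate bin. Bins with
#' fewer samples return everything they have (with a warning for empty
#' bins). With a fixed seed, the kept sets are nested as `per_bin`
#' grows: each bin's rows are put in a random order once and the first
#' `per_bin` taken.
#'
#' @param samples a [dated_samples] table (or data.frame with a `bin`
#'   column).
#' @param per_bin maximum samples kept per bin, >= 1.
#' @param seed integer seed.
#' @return Subset of `samples`.
#' @export
stratified_subsample <- function(samples, per_bin, seed) {
  stopifnot(per_bin >= 1L, "bin" %in% names(samples))
  bins <- if (is.factor(samples$bin)) levels(samples$bin) else unique(samples$bin)
  with_seed(seed, {
    keep <- integer(0)
    for (b in bins) {
      idx <- which(samples$bin == b)
      if (!length(idx)) { warning(sprintf("bin %s has no samples", b)); next }
      ord <- idx[sample.int(length(idx))]
      keep <- c(keep, ord[seq_len(min(per_bin, length(ord)))])
    }
    samples[sort(keep), , drop = FALSE]
  })
}
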