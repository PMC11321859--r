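#' Closed outline objects
#'
#' An `outline` is an ordered sequence of 2D points describing the closed
#' contour of one specimen. The polygon is implicitly closed: the first
#' point is treated as following the last. Outlines must have at least 8
#' points and no consecutive duplicate points.
#'
#' @param points numeric matrix with two columns (x, y).
#' @param specimen_id character scalar naming the specimen.
#' @return An object of class `outline`: a list with `specimen_id` and
#'   `points`.
#' @export
outline <- function(points, specimen_id = "specimen") {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("outline points must have two columns (x, y)")
  storage.mode(points) <- "double"
  if (nrow(points) < 8L) stop("an outline needs at least 8 points")
  if (any(!is.finite(points))) stop("outline coordinates must be finite")
  ## closed polygon: drop an explicit duplicate closing point
  n <- nrow(points)
  if (isTRUE(all.equal(points[1L, ], points[n, ], tolerance = 1e-12,
                       check.attributes = FALSE))) {
    points <- points[-n, , drop = FALSE]
    n <- n - 1L
  }
  if (n < 8L) stop("an outline needs at least 8 distinct points")
  nxt <- c(2:n, 1L)
  seg <- sqrt(rowSums((points[nxt, , drop = FALSE] - points)^2))
  if (any(seg == 0)) stop("outline has consecutive duplicate points")
  structure(list(specimen_id = as.character(specimen_id), points = points),
            class = "outline")
}

#' @export
print.outline <- function(x, ...) {
  cat("<outline> ", x$specimen_id, ": ", nrow(x$points), " points\n", sep = "")
  invisible(x)
}

outline_centroid <- function(o) colMeans(o$points)

## centroid size: root mean squared distance of points to the centroid
outline_centroid_size <- function(o) {
  ctr <- outline_centroid(o)
  sqrt(mean(rowSums(sweep(o$points, 2, ctr)^2)))
}

#' Normalize an outline
#'
#' Centres the outline on its centroid, scales it to unit centroid size
#' (root mean squared point distance to the centroid), rotates it by a
#' supplied per-specimen angle, and rotates the point indexing so that a
#' designated homologous point comes first. Orientation is an input, not
#' inferred: reorientation of specimens to a standard direction is a
#' manual curation step upstream of this function.
#'
#' @param raw an [outline].
#' @param orientation_angle rotation applied to the outline, in radians
#'   (counter-clockwise). Default 0.
#' @param start_index index of the point that is homologous across
#'   specimens; the point order is rotated so this point becomes the
#'   first. Default 1 (leave the start as given).
#' @return A normalized [outline]: centroid at the origin, centroid size
#'   one.
#' @export
normalize_outline <- function(raw, orientation_angle = 0, start_index = 1L) {
  stopifnot(inherits(raw, "outline"))
  p <- raw$points
  n <- nrow(p)
  start_index <- as.integer(start_index)
  if (start_index < 1L || start_index > n) stop("start_index out of range")
  p <- sweep(p, 2, colMeans(p))
  size <- sqrt(mean(rowSums(p^2)))
  if (size < 1e-300) stop("degenerate outline: zero centroid size")
  p <- p / size
  if (orientation_angle != 0) {
    ca <- cos(orientation_angle); sa <- sin(orientation_angle)
    p <- p %*% matrix(c(ca, -sa, sa, ca), 2, 2)   # counter-clockwise
  }
  if (start_index != 1L) p <- p[c(start_index:n, seq_len(start_index - 1L)), , drop = FALSE]
  outline(p, raw$specimen_id)
}

#' Elliptic Fourier coefficients of a closed outline
#'
#' Decomposes a closed polygon into per-harmonic coefficients
#' (a_n, b_n, c_n, d_n) using arc-length parameterization of the contour
#' (the classical formulation for chain-coded/polygonal outlines). No
#' size or rotation normalization is applied here; normalization belongs
#' to [normalize_outline()].
#'
#' @param outline an [outline].
#' @param n_harmonics number of harmonics H (>= 1, at most
#'   `floor(n_points / 2)`).
#' @param parameterization `"arc"` (default): the classical chord /
#'   arc-length parameterization of the closed polygon; `"uniform"`:
#'   one parameter unit per vertex, which makes the transform an exact
#'   inverse of [efa_inverse()] evaluated at equally spaced parameter
#'   values (the arc-length convention re-parameterizes the contour, so
#'   its inverse-forward round trip is exact only for constant-speed
#'   contours).
#' @return An object of class `efa`: list with `specimen_id`, `harmonics`
#'   (H x 4 matrix, columns a, b, c, d), and the constant terms `a0`, `c0`.
#' @export
efa_transform <- function(outline, n_harmonics,
                          parameterization = c("arc", "uniform")) {
  stopifnot(inherits(outline, "outline"))
  parameterization <- match.arg(parameterization)
  p <- outline$points
  n <- nrow(p)
  n_harmonics <- as.integer(n_harmonics)
  hmax <- n %/% 2L
  if (n_harmonics < 1L) stop("n_harmonics must be >= 1")
  if (n_harmonics > hmax)
    stop(sprintf("n_harmonics too large for %d points; maximum is %d", n, hmax))
  if (parameterization == "uniform") {
    ## discrete Fourier coefficients of the vertices at equally spaced
    ## parameter values: the exact inverse of efa_inverse()
    t <- (seq_len(n) - 1L) / n
    h <- seq_len(n_harmonics)
    ph <- 2 * pi * outer(h, t)
    C <- cos(ph); S <- sin(ph)
    harmonics <- cbind(a = 2 * as.vector(C %*% p[, 1L]) / n,
                       b = 2 * as.vector(S %*% p[, 1L]) / n,
                       c = 2 * as.vector(C %*% p[, 2L]) / n,
                       d = 2 * as.vector(S %*% p[, 2L]) / n)
    rownames(harmonics) <- paste0("h", h)
    return(structure(list(specimen_id = outline$specimen_id,
                          harmonics = harmonics,
                          a0 = mean(p[, 1L]), c0 = mean(p[, 2L])),
                     class = "efa"))
  }
  nxt <- c(2:n, 1L)
  dx <- p[nxt, 1L] - p[, 1L]
  dy <- p[nxt, 2L] - p[, 2L]
  dt <- sqrt(dx^2 + dy^2)
  t1 <- cumsum(dt)            # arc length at the END of each segment
  t0 <- c(0, t1[-n])          # arc length at the start of each segment
  T <- t1[n]
  h <- seq_len(n_harmonics)
  w <- 2 * pi * outer(h, 1, `*`)[, 1] / T     # angular frequency per harmonic
  ## phases at segment endpoints, harmonics x segments
  c1 <- cos(outer(w, t1)); c0 <- cos(outer(w, t0))
  s1 <- sin(outer(w, t1)); s0 <- sin(outer(w, t0))
  fx <- dx / dt; fy <- dy / dt
  k <- T / (2 * pi^2 * h^2)
  a <- k * as.vector((c1 - c0) %*% fx)
  b <- k * as.vector((s1 - s0) %*% fx)
  cc <- k * as.vector((c1 - c0) %*% fy)
  d <- k * as.vector((s1 - s0) %*% fy)
  ## constant (DC) terms of the arc-length parameterized contour
  xi <- cumsum(dx) - dx / dt * t1
  a0 <- sum(dx / (2 * dt) * (t1^2 - t0^2) + xi * dt) / T + p[1L, 1L]
  zeta <- cumsum(dy) - dy / dt * t1
  c0c <- sum(dy / (2 * dt) * (t1^2 - t0^2) + zeta * dt) / T + p[1L, 2L]
  harmonics <- cbind(a = a, b = b, c = cc, d = d)
  rownames(harmonics) <- paste0("h", h)
  structure(list(specimen_id = outline$specimen_id, harmonics = harmonics,
                 a0 = a0, c0 = c0c),
            class = "efa")
}

#' @export
print.efa <- function(x, ...) {
  cat("<efa> ", x$specimen_id, ": ", nrow(x$harmonics), " harmonics\n", sep = "")
  invisible(x)
}

#' Evaluate the inverse elliptic Fourier series
#'
#' Reconstructs a closed outline from elliptic Fourier coefficients by
#' evaluating the truncated Fourier series at `n_points` equally spaced
#' positions of the arc-length parameter.
#'
#' @param coeffs an `efa` object or a plain H x 4 matrix (columns
#'   a, b, c, d).
#' @param n_points number of points to evaluate (>= 8).
#' @param specimen_id name for the reconstructed outline.
#' @param centre logical; drop the constant terms so the outline is
#'   centred (default TRUE when `coeffs` is a bare matrix, otherwise use
#'   the stored constants).
#' @return An [outline].
#' @export
efa_inverse <- function(coeffs, n_points = 120L, specimen_id = NULL,
                        centre = NULL) {
  if (inherits(coeffs, "efa")) {
    H <- coeffs$harmonics
    a0 <- coeffs$a0; c0 <- coeffs$c0
    if (is.null(specimen_id)) specimen_id <- coeffs$specimen_id
    if (is.null(centre)) centre <- FALSE
  } else {
    H <- as.matrix(coeffs)
    a0 <- 0; c0 <- 0
    if (is.null(specimen_id)) specimen_id <- "reconstruction"
    if (is.null(centre)) centre <- TRUE
  }
  if (ncol(H) != 4L) stop("coefficient matrix must have 4 columns (a, b, c, d)")
  n_points <- as.integer(n_points)
  if (n_points < 8L) stop("n_points must be >= 8")
  if (centre) { a0 <- 0; c0 <- 0 }
  t <- seq(0, 1, length.out = n_points + 1L)[-(n_points + 1L)]
  h <- seq_len(nrow(H))
  ph <- 2 * pi * outer(t, h)           # n_points x H phases
  x <- a0 + cos(ph) %*% H[, 1L] + sin(ph) %*% H[, 2L]
  y <- c0 + cos(ph) %*% H[, 3L] + sin(ph) %*% H[, 4L]
  outline(cbind(x, y), specimen_id)
}

#' Cumulative harmonic power fractions
#'
#' The power of harmonic n is (a_n^2 + b_n^2 + c_n^2 + d_n^2) / 2;
#' returned as cumulative fractions of the total power across all
#' supplied harmonics.
#'
#' @param coeffs an `efa` object or H x 4 coefficient matrix.
#' @return Numeric vector of length H, non-decreasing, ending at 1.
#' @export
harmonic_power <- function(coeffs) {
  H <- if (inherits(coeffs, "efa")) coeffs$harmonics else as.matrix(coeffs)
  pw <- rowSums(H^2) / 2
  tot <- sum(pw)
  if (tot == 0) stop("all-zero coefficients: harmonic power undefined")
  cumsum(pw) / tot
}

#' Choose the number of harmonics reaching a power threshold
#'
#' Computes elliptic Fourier coefficients at a generous maximum number of
#' harmonics and returns the smallest H whose cumulative harmonic power
#' reaches the threshold.
#'
#' @param outline an [outline].
#' @param threshold fraction of total harmonic power in (0, 1), e.g.
#'   0.999.
#' @param h_max maximum number of harmonics to consider; defaults to the
#'   admissible maximum `floor(n_points / 2)`.
#' @param ... passed to [efa_transform()].
#' @return Integer number of harmonics.
#' @export
choose_harmonics <- function(outline, threshold = 0.999, h_max = NULL, ...) {
  stopifnot(inherits(outline, "outline"))
  if (!(threshold > 0 && threshold < 1)) stop("threshold must be in (0, 1)")
  if (is.null(h_max)) h_max <- nrow(outline$points) %/% 2L
  cf <- efa_transform(outline, h_max, ...)
  cum <- harmonic_power(cf)
  idx <- which(cum >= threshold)
  if (!length(idx))
    stop(sprintf("threshold %.6g not reachable with %d harmonics", threshold, h_max))
  unname(idx[1L])
}
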