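#' Flatten elliptic Fourier coefficients into a table
#'
#' Stacks per-specimen `efa` objects into a specimens x (4 * H) matrix
#' with column order a1, b1, c1, d1, a2, ... All specimens must share the
#' same number of harmonics.
#'
#' @param efas list of `efa` objects.
#' @return Numeric matrix with specimen ids as row names.
#' @export
efa_table <- function(efas) {
  stopifnot(length(efas) >= 1L, all(vapply(efas, inherits, TRUE, "efa")))
  hh <- vapply(efas, function(e) nrow(e$harmonics), 1L)
  if (length(unique(hh)) != 1L) stop("specimens differ in harmonic count")
  m <- t(vapply(efas, function(e) as.vector(t(e$harmonics)), numeric(4L * hh[1L])))
  rownames(m) <- vapply(efas, `[[`, "", "specimen_id")
  colnames(m) <- paste0(rep(c("a", "b", "c", "d"), hh[1L]),
                        rep(seq_len(hh[1L]), each = 4L))
  m
}

unflatten_coeffs <- function(v) {
  if (length(v) %% 4L != 0L) stop("flattened coefficient length must be a multiple of 4")
  matrix(v, ncol = 4L, byrow = TRUE, dimnames = list(NULL, c("a", "b", "c", "d")))
}

#' Principal component analysis of flattened coefficients
#'
#' Centred (but not variance-scaled) PCA via the eigendecomposition of
#' the covariance of the coefficient table. Returns the basis (mean,
#' orthonormal loadings, eigenvalues) and the scores as a trait matrix.
#'
#' @param coeff_table specimens x p matrix of flattened coefficients
#'   (see [efa_table()]).
#' @return List with components `basis` (class `pca_basis`: `mean`,
#'   `loadings`, `eigenvalues`) and `traits` (class `trait_matrix`:
#'   `taxa`, `values`, `explained`).
#' @export
fit_pca <- function(coeff_table) {
  x <- as.matrix(coeff_table)
  if (nrow(x) < 2L) stop("PCA needs at least 2 specimens")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  ## drop numerically null axes (centred PCA has rank <= n - 1)
  keep <- ev > max(ev) * 1e-12
  basis <- structure(list(mean = pc$center,
                          loadings = pc$rotation[, keep, drop = FALSE],
                          eigenvalues = ev[keep]),
                     class = "pca_basis")
  traits <- trait_matrix(pc$x[, keep, drop = FALSE],
                         taxa = rownames(x),
                         eigenvalues = ev[keep])
  list(basis = basis, traits = traits)
}

#' Trait matrix of PC scores
#'
#' @param values taxa x k numeric matrix of scores.
#' @param taxa character vector of taxon ids (defaults to row names).
#' @param eigenvalues optional per-axis variances used to compute the
#'   cumulative explained-variance fractions.
#' @return Object of class `trait_matrix`: `taxa`, `values`, `explained`.
#' @export
trait_matrix <- function(values, taxa = rownames(values), eigenvalues = NULL) {
  values <- as.matrix(values)
  if (is.null(taxa)) taxa <- paste0("t", seq_len(nrow(values)))
  rownames(values) <- taxa
  if (is.null(colnames(values))) colnames(values) <- paste0("PC", seq_len(ncol(values)))
  explained <- if (is.null(eigenvalues)) NULL else cumsum(eigenvalues) / sum(eigenvalues)
  structure(list(taxa = as.character(taxa), values = values, explained = explained),
            class = "trait_matrix")
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat("<trait_matrix> ", length(x$taxa), " taxa x ", ncol(x$values),
      " traits\n", sep = "")
  invisible(x)
}

#' Project flattened coefficients onto a PCA basis
#'
#' @param basis a `pca_basis`.
#' @param coeff_rows matrix (or vector) of flattened coefficients.
#' @return Matrix of scores (rows match input rows).
#' @export
pca_project <- function(basis, coeff_rows) {
  stopifnot(inherits(basis, "pca_basis"))
  x <- if (is.null(dim(coeff_rows))) matrix(coeff_rows, nrow = 1L) else as.matrix(coeff_rows)
  sweep(x, 2, basis$mean) %*% basis$loadings
}

## scores (possibly fewer than full rank) -> flattened coefficient vector
pca_backproject <- function(basis, scores) {
  scores <- as.numeric(scores)
  k <- length(scores)
  if (k > ncol(basis$loadings)) stop("trait dimension exceeds basis dimension")
  basis$mean + as.vector(basis$loadings[, seq_len(k), drop = FALSE] %*% scores)
}

#' Synthetic shape along a principal component axis
#'
#' Reconstructs the outline at `mean + multiple * sqrt(eigenvalue) *
#' loading` for one PC axis — the standard visualization of the shape
#' variation a component captures.
#'
#' @param basis a `pca_basis` fitted on flattened elliptic Fourier
#'   coefficients.
#' @param axis integer axis index.
#' @param multiple number of standard deviations along the axis (0 gives
#'   the mean shape).
#' @param n_points points in the reconstructed outline.
#' @return An [outline].
#' @export
shape_along_axis <- function(basis, axis, multiple = 0, n_points = 120L) {
  stopifnot(inherits(basis, "pca_basis"))
  axis <- as.integer(axis)
  if (axis < 1L || axis > ncol(basis$loadings)) stop("axis out of basis range")
  v <- basis$mean + multiple * sqrt(basis$eigenvalues[axis]) * basis$loadings[, axis]
  efa_inverse(unflatten_coeffs(v), n_points = n_points,
              specimen_id = sprintf("PC%d_%+.1fsd", axis, multiple), centre = FALSE)
}
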