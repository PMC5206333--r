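## principal coordinate analysis of a distance matrix

#' Principal Coordinate Analysis
#'
#' Gower double-centering of `-0.5 * D^2` followed by eigendecomposition.
#' Coordinates are eigenvectors scaled by the square root of their (positive)
#' eigenvalues; inertia percentages are relative to the sum of positive
#' eigenvalues. Negative eigenvalues are reported (their absolute sum in
#' `negativeEigenvalueMass`), not corrected; `correction = "lingoes"` adds
#' the smallest constant to squared distances that makes the configuration
#' Euclidean. Axis signs are fixed by making the largest-magnitude loading
#' on each axis positive.
#'
#' @param d symmetric labelled distance matrix with zero diagonal
#' @param correction `"none"` (default) or `"lingoes"`
#' @return object of class `PcoaResult`: list with `coordinates`
#'   (entities x axes), `eigenvalues`, `inertiaPct`,
#'   `negativeEigenvalueMass`
#' @export
pcoa <- function(d, correction = c("none", "lingoes")) {
  correction <- match.arg(correction)
  if (max(abs(d - t(d))) > 1e-8) stop("input matrix is not symmetric")
  n <- nrow(d)
  A <- -0.5 * d^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  if (correction == "lingoes") {
    negmin <- min(e$values)
    if (negmin < -1e-10) {
      c1 <- -negmin
      d2 <- d^2 + 2 * c1
      diag(d2) <- 0
      B <- J %*% (-0.5 * d2) %*% J
      B <- (B + t(B)) / 2
      e <- eigen(B, symmetric = TRUE)
    }
  }
  ev <- e$values
  pos <- which(ev > max(ev) * 1e-12 & ev > 0)
  coords <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(ev[pos]), length(pos))
  # reproducible axis orientation
  for (k in seq_len(ncol(coords))) {
    if (coords[which.max(abs(coords[, k])), k] < 0) coords[, k] <- -coords[, k]
  }
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  structure(list(
    coordinates = coords,
    eigenvalues = ev,
    inertiaPct = 100 * ev[pos] / sum(ev[pos]),
    negativeEigenvalueMass = sum(abs(ev[ev < 0]))
  ), class = "PcoaResult")
}

#' @export
print.PcoaResult <- function(x, ...) {
  cat("PCoA:", nrow(x$coordinates), "entities,",
      ncol(x$coordinates), "positive axes\n")
  cat("inertia % (first axes):",
      paste(sprintf("%.2f", head(x$inertiaPct, 4)), collapse = ", "), "\n")
  cat("negative-eigenvalue mass:",
      sprintf("%.4g", x$negativeEigenvalueMass), "\n")
  invisible(x)
}
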