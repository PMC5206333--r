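## isolation by distance: Mantel tests, beta regression, model ladders

offDiag <- function(m) m[lower.tri(m)]

mantelR <- function(a, b) cor(offDiag(a), offDiag(b))

permuteMat <- function(m, idx) m[idx, idx]

#' Mantel tests (standard, stratified, partial)
#'
#' Pearson correlation over off-diagonal pairs, with permutation p-values:
#' the standard scheme permutes entity labels of matrix `b`; the stratified
#' scheme restricts permutations to label swaps within strata (a
#' whole-stratum permutation mode is available); the partial scheme
#' correlates the residuals of `a` and `b` after regressing each on the
#' covariate matrix, and permutes the residual labels. The p-value is
#' one-tailed: `(1 + #(r_perm >= r_obs)) / (1 + permutations)`. For
#' `exact = TRUE` (standard scheme, small n) all `n!` label permutations are
#' enumerated instead.
#'
#' @param a,b symmetric labelled distance matrices with matching labels
#' @param scheme `"standard"`, `"stratified"` or `"partial"`
#' @param nPerm permutations (>= 99 recommended)
#' @param strata factor over labels (stratified scheme)
#' @param covariate symmetric matrix (partial scheme)
#' @param wholeStratum permute whole strata rather than within strata
#' @param exact enumerate all permutations (standard scheme, n <= 8)
#' @return object of class `MantelResult`: list with `r`, `p`, `nPerm`,
#'   `scheme`
#' @export
mantelTest <- function(a, b, scheme = c("standard", "stratified", "partial"),
                       nPerm = 999L, strata = NULL, covariate = NULL,
                       wholeStratum = FALSE, exact = FALSE) {
  scheme <- match.arg(scheme)
  stopifnot(identical(rownames(a), rownames(b)))
  n <- nrow(a)
  if (sd(offDiag(a)) == 0 || sd(offDiag(b)) == 0)
    stop("constant distance matrix: Mantel r undefined")
  if (scheme == "stratified" && is.null(strata))
    stop("stratified scheme requires strata")
  if (scheme == "partial" && is.null(covariate))
    stop("partial scheme requires a covariate matrix")

  if (scheme == "partial") {
    cv <- offDiag(covariate)
    ra <- matrix(0, n, n); rb <- matrix(0, n, n)
    ra[lower.tri(ra)] <- stats::resid(lm(offDiag(a) ~ cv))
    rb[lower.tri(rb)] <- stats::resid(lm(offDiag(b) ~ cv))
    ra <- ra + t(ra); rb <- rb + t(rb)
    a <- ra; b <- rb
  }
  robs <- mantelR(a, b)

  permIdx <- function() {
    if (scheme == "stratified") {
      if (wholeStratum) {
        # permute stratum identities among strata of equal size
        idx <- seq_len(n)
        sizes <- table(strata)
        for (sz in unique(sizes)) {
          grp <- names(sizes)[sizes == sz]
          perm <- sample(grp)
          for (gi in seq_along(grp))
            idx[strata == grp[gi]] <- which(strata == perm[gi])
        }
        idx
      } else {
        idx <- seq_len(n)
        for (s in unique(strata)) {
          w <- which(strata == s)
          idx[w] <- w[sample(length(w))]
        }
        idx
      }
    } else sample(n)
  }

  if (exact && scheme == "standard") {
    if (n > 8) stop("exact enumeration limited to n <= 8")
    allp <- permutationsOf(n)
    rperm <- apply(allp, 1L, function(idx) mantelR(a, permuteMat(b, idx)))
    p <- mean(rperm >= robs - 1e-12)
    nPerm <- nrow(allp)
  } else {
    rperm <- replicate(nPerm, mantelR(a, permuteMat(b, permIdx())))
    p <- (1 + sum(rperm >= robs - 1e-12)) / (1 + nPerm)
  }
  structure(list(r = robs, p = p, nPerm = nPerm, scheme = scheme),
            class = "MantelResult")
}

#' @export
print.MantelResult <- function(x, ...) {
  cat(sprintf("Mantel (%s): r = %.3f, p = %.4g (%d permutations)\n",
              x$scheme, x$r, x$p, x$nPerm))
  invisible(x)
}

#' Hierarchical-island vs stepping-stone Mantel protocol
#'
#' Runs the four tests that discriminate a hierarchical island model (HIM)
#' from a stepping-stone model (SSM): (1) standard genetic ~ geographic;
#' (2) genetic ~ geographic stratified by cluster; (3) genetic ~ geographic
#' partialling out cluster membership; (4) genetic ~ cluster membership
#' partialling out geography. Interpretation tags: a significant (1) alone
#' does not discriminate; a non-significant (2) supports HIM; a significant
#' (3) with relatively high r supports SSM; a significant (4) supports HIM.
#'
#' @param genetic,geographic symmetric population distance matrices
#' @param clusters named vector population -> cluster
#' @param nPerm permutations per test (default 4999)
#' @param alpha significance level for the tags (0.05)
#' @return data.frame with one row per test: matrices, adjustment, `r`,
#'   `p`, `supports`
#' @export
himSsmProtocol <- function(genetic, geographic, clusters, nPerm = 4999L,
                           alpha = 0.05) {
  strata <- factor(clusters[rownames(genetic)])
  ci <- clusterIndicatorMatrix(clusters[rownames(genetic)])
  degenerate <- nlevels(strata) < 2
  t1 <- mantelTest(genetic, geographic, "standard", nPerm)
  t2 <- if (!degenerate && any(table(strata) > 1))
    mantelTest(genetic, geographic, "stratified", nPerm, strata = strata)
  else t1  # single cluster degenerates to the standard scheme
  t3 <- if (degenerate) t1 else
    mantelTest(genetic, geographic, "partial", nPerm, covariate = ci)
  t4 <- if (degenerate) list(r = NA_real_, p = NA_real_) else
    mantelTest(genetic, ci, "partial", nPerm, covariate = geographic)
  tag <- function(tt, rule) rule(tt)
  data.frame(
    matrixA = "genetic",
    matrixB = c("geographic", "geographic", "geographic", "clusters"),
    adjustment = c("none", "stratified by clusters",
                   "partial: clusters as covariate",
                   "partial: geography as covariate"),
    r = c(t1$r, t2$r, t3$r, t4$r),
    p = c(t1$p, t2$p, t3$p, t4$p),
    supports = c(
      if (t1$p <= alpha) "no discrimination" else "neither",
      if (t2$p > alpha) "HIM" else "not HIM",
      if (t3$p <= alpha) "SSM" else "not SSM",
      if (is.na(t4$p)) "undefined" else if (t4$p <= alpha) "HIM" else "not HIM"),
    stringsAsFactors = FALSE)
}

## ---- beta regression --------------------------------------------------

betaLogLik <- function(par, y, X) {
  k <- ncol(X)
  beta <- par[seq_len(k)]
  phi <- exp(par[k + 1L])
  mu <- plogis(drop(X %*% beta))
  mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
  sum(lgamma(phi) - lgamma(mu * phi) - lgamma((1 - mu) * phi) +
        (mu * phi - 1) * log(y) + ((1 - mu) * phi - 1) * log(1 - y))
}

#' Beta regression with logit mean link
#'
#' Maximum-likelihood fit of a beta model with constant precision:
#' `y ~ Beta(mu * phi, (1 - mu) * phi)`, `logit(mu) = X beta`. Starting
#' values are OLS on the link-transformed response with a method-of-moments
#' precision; optimisation is quasi-Newton with restarts. The pseudo-R2 is
#' the squared Pearson correlation between the link-transformed response
#' and the linear predictor (Ferrari & Cribari-Neto).
#'
#' @param y response strictly inside (0, 1)
#' @param X model matrix or data.frame of covariates (an intercept is
#'   added)
#' @return object of class `IbdModelFit`: list with `coefficients` (table
#'   with estimates and standard errors), `phi`, `logLik`, `aic`,
#'   `pseudoR2`, `converged`, `transform`
#' @export
fitBetaRegression <- function(y, X = NULL) {
  if (any(y <= 0 | y >= 1)) stop("response must lie strictly inside (0,1)")
  Xm <- if (is.null(X)) matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  else cbind("(Intercept)" = 1, as.matrix(X))
  if (length(y) <= ncol(Xm) + 1L) stop("too few observations for the model")
  eta0 <- qlogis(y)
  b0 <- coef(lm(eta0 ~ Xm - 1))
  mu0 <- plogis(drop(Xm %*% b0))
  v <- var(y - mu0)
  phi0 <- max(mean(mu0 * (1 - mu0)) / max(v, 1e-8) - 1, 1)
  start <- c(b0, log(phi0))
  fit <- NULL
  for (sc in c(1, 0.5, 2)) {
    cand <- try(optim(start * sc, betaLogLik, y = y, X = Xm,
                      control = list(fnscale = -1, maxit = 2000,
                                     reltol = 1e-12),
                      method = "BFGS", hessian = TRUE), silent = TRUE)
    if (!inherits(cand, "try-error") && cand$convergence == 0) { fit <- cand; break }
  }
  if (is.null(fit)) stop("beta regression failed to converge after restarts")
  # Newton polish: drive the gradient to numerical zero
  f <- function(p) betaLogLik(p, y, Xm)
  for (step in 1:5) {
    g <- numericGradient(f, fit$par)
    if (sqrt(sum(g^2)) < 1e-7) break
    H <- numericHessian(f, fit$par)
    delta <- try(solve(H, g), silent = TRUE)
    if (inherits(delta, "try-error")) break
    cand <- fit$par - delta
    if (is.finite(f(cand)) && f(cand) >= fit$value) {
      fit$par <- cand; fit$value <- f(cand); fit$hessian <- H
    } else break
  }
  k <- ncol(Xm)
  est <- fit$par[seq_len(k)]
  se <- rep(NA_real_, k + 1L)
  covm <- try(solve(-fit$hessian), silent = TRUE)
  if (!inherits(covm, "try-error") && all(diag(covm) > 0))
    se <- sqrt(diag(covm))
  eta <- drop(Xm %*% est)
  ll <- fit$value
  npar <- k + 1L
  structure(list(
    coefficients = data.frame(term = colnames(Xm), estimate = est,
                              se = se[seq_len(k)], row.names = NULL),
    phi = exp(fit$par[k + 1L]), phiSe = se[k + 1L],
    logLik = ll, aic = -2 * ll + 2 * npar, npar = npar,
    pseudoR2 = if (sd(eta) == 0) 0 else cor(qlogis(y), eta)^2,
    converged = TRUE, n = length(y),
    gradientNorm = sqrt(sum(numericGradient(function(p)
      betaLogLik(p, y, Xm), fit$par)^2))
  ), class = "IbdModelFit")
}

numericGradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, 0)
}

numericHessian <- function(f, x, h = 1e-5) {
  k <- length(x)
  H <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in i:k) {
    if (i == j) {
      xp <- x; xm <- x
      xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
      H[i, i] <- (f(xp) - 2 * f(x) + f(xm)) / h^2
    } else {
      xpp <- x; xpp[i] <- xpp[i] + h; xpp[j] <- xpp[j] + h
      xpm <- x; xpm[i] <- xpm[i] + h; xpm[j] <- xpm[j] - h
      xmp <- x; xmp[i] <- xmp[i] - h; xmp[j] <- xmp[j] + h
      xmm <- x; xmm[i] <- xmm[i] - h; xmm[j] <- xmm[j] - h
      H[i, j] <- H[j, i] <- (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h^2)
    }
  }
  H
}

#' @export
print.IbdModelFit <- function(x, ...) {
  cat(sprintf("beta regression: n = %d, logLik = %.2f, AIC = %.2f, pseudo-R2 = %.3f\n",
              x$n, x$logLik, x$aic, x$pseudoR2))
  print(transform(x$coefficients, estimate = signif(estimate, 4),
                  se = signif(se, 3)))
  invisible(x)
}

#' Map distances into (0, 1)
#'
#' Min-max rescaling followed by the Smithson-Verkuilen compression
#' `(y (n - 1) + 0.5)/n`, so the response is strictly inside the unit
#' interval. The record of the transformation is attached so a ladder of
#' models shares it.
#' @param d numeric vector of distances
#' @export
squeezeUnit <- function(d) {
  n <- length(d)
  y <- (d - min(d)) / (max(d) - min(d))
  y <- (y * (n - 1) + 0.5) / n
  attr(y, "transform") <- list(min = min(d), max = max(d), n = n,
                               method = "minmax + Smithson-Verkuilen")
  y
}

#' Ladder of beta-regression IBD models with barrier covariates
#'
#' The response is the vector of off-diagonal genetic distances mapped into
#' (0,1) by [squeezeUnit()] (shared across the ladder). The first model uses
#' geographic distance alone; subsequent models add barrier covariates one
#' order at a time. For `barrierDef = "structure-clusters"` the covariates
#' are cluster-boundary indicators (the pair straddles cluster c's
#' boundary), added cluster by cluster; for `"barrier-order"` they derive
#' from a `BarrierSet`, the k-th indicator marking pairs newly separated by
#' barrier k. With `cumulative = TRUE` (default) step k carries a single
#' indicator "separated at order <= k"; otherwise the k per-order
#' indicators enter separately.
#'
#' @param nei symmetric population genetic-distance matrix
#' @param geo symmetric geographic-distance matrix (same labels)
#' @param barrierDef `"structure-clusters"` or `"barrier-order"`
#' @param components named cluster vector, or a `BarrierSet`
#' @param cumulative single cumulative indicator per step (default)
#' @return object of class `ModelLadder`: list with `fits`, `aic`,
#'   `pseudoR2`, `best` (index), `barrierDef`
#' @export
buildModelLadder <- function(nei, geo,
                             barrierDef = c("structure-clusters", "barrier-order"),
                             components, cumulative = TRUE) {
  barrierDef <- match.arg(barrierDef)
  stopifnot(identical(rownames(nei), rownames(geo)))
  y <- squeezeUnit(offDiag(nei))
  gkm <- offDiag(geo) / 1000  # kilometres keep coefficients O(1)
  pops <- rownames(nei)
  pairIdx <- which(lower.tri(nei), arr.ind = TRUE)
  indicators <- list()
  if (barrierDef == "structure-clusters") {
    cl <- components[pops]
    for (cc in unique(cl)) {
      indicators[[as.character(cc)]] <-
        (cl[pairIdx[, 1]] == cc) != (cl[pairIdx[, 2]] == cc)
    }
  } else {
    bs <- components
    prev <- rep(FALSE, nrow(pairIdx))
    for (k in seq_along(bs$barriers)) {
      comp <- barrierComponents(bs, k)
      sep <- comp[pops[pairIdx[, 1]]] != comp[pops[pairIdx[, 2]]]
      indicators[[paste0("barrier", k)]] <- sep & !prev
      prev <- prev | sep
    }
  }
  indicators <- Filter(function(v) any(v) && !all(v), indicators)
  Xs <- list(data.frame(geoKm = gkm))
  fits <- list(fitBetaRegression(y, Xs[[1]]))
  labels <- "distance-only"
  for (k in seq_along(indicators)) {
    Xk <- data.frame(geoKm = gkm)
    if (cumulative) {
      cum <- Reduce(`|`, indicators[seq_len(k)])
      if (all(cum) || !any(cum)) { next }
      Xk$separated <- as.numeric(cum)
    } else {
      for (nm in names(indicators)[seq_len(k)])
        Xk[[nm]] <- as.numeric(indicators[[nm]])
    }
    fit <- try(fitBetaRegression(y, Xk), silent = TRUE)
    if (inherits(fit, "try-error")) next
    fits[[length(fits) + 1L]] <- fit
    Xs[[length(Xs) + 1L]] <- Xk
    labels <- c(labels, paste0("barriers 1-", k))
  }
  aic <- vapply(fits, `[[`, 0, "aic")
  best <- which.min(aic)
  structure(list(fits = fits, labels = labels, aic = aic,
                 pseudoR2 = vapply(fits, `[[`, 0, "pseudoR2"),
                 best = best, bestX = Xs[[best]], barrierDef = barrierDef,
                 transform = attr(y, "transform")),
            class = "ModelLadder")
}

#' @export
print.ModelLadder <- function(x, ...) {
  cat("Model ladder (", x$barrierDef, ")\n")
  for (i in seq_along(x$fits))
    cat(sprintf("  %-16s AIC = %8.2f  pseudo-R2 = %.3f%s\n", x$labels[i],
                x$aic[i], x$pseudoR2[i], if (i == x$best) "  <- best" else ""))
  invisible(x)
}
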