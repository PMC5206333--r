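## hierarchical AMOVA on the dominant matrix, pairwise FST, Slatkin Nm

# squared Euclidean distances between binary rows with pairwise deletion,
# rescaled by totalBands / sharedBands
dominantSquaredDistances <- function(v) {
  ok <- !is.na(v)
  x0 <- v; x0[!ok] <- 0
  ok <- ok * 1
  cross <- x0 %*% t(x0)
  sq <- (x0^2) %*% t(ok)
  shared <- ok %*% t(ok)
  d2 <- sq + t(sq) - 2 * cross
  B <- ncol(v)
  d2 <- ifelse(shared > 0, d2 * B / shared, NA)
  diag(d2) <- 0
  d2
}

ssWithinGroups <- function(d2, grouping) {
  # sum over groups of (1/n_g) * sum_{i<j in g} d2
  s <- 0
  for (g in unique(grouping)) {
    idx <- which(grouping == g)
    if (length(idx) < 2) next
    s <- s + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
  }
  s
}

amovaComponents <- function(d2, populations, clusters) {
  N <- nrow(d2)
  popsOf <- as.character(populations)
  grpOf <- as.character(clusters[popsOf])
  P <- length(unique(popsOf))
  G <- length(unique(grpOf))
  ssTotal <- sum(d2[upper.tri(d2)]) / N
  ssWP <- ssWithinGroups(d2, popsOf)
  ssWG <- ssWithinGroups(d2, grpOf)
  ssAP <- ssWG - ssWP
  ssAG <- ssTotal - ssWG
  dfAG <- G - 1; dfAP <- P - G; dfWP <- N - P
  np <- table(popsOf); ng <- table(grpOf)
  grpOfPop <- vapply(names(np), function(p) grpOf[match(p, popsOf)], "")
  sumNp2ByG <- sum(vapply(names(ng), function(g) {
    sum(np[grpOfPop == g]^2) / ng[[g]]
  }, 0))
  n1 <- (N - sumNp2ByG) / dfAP
  n2 <- (sumNp2ByG - sum(np^2) / N) / dfAG
  n3 <- (N - sum(ng^2) / N) / dfAG
  sc <- ssWP / dfWP
  sb <- (ssAP / dfAP - sc) / n1
  sa <- (ssAG / dfAG - sc - n2 * sb) / n3
  list(df = c(AG = dfAG, AP = dfAP, WP = dfWP),
       ss = c(AG = ssAG, AP = ssAP, WP = ssWP, total = ssTotal),
       sigma = c(AG = sa, AP = sb, WP = sc))
}

phiFromSigma <- function(sigma) {
  tot <- sum(sigma)
  c(phiCT = sigma[["AG"]] / tot,
    phiSC = sigma[["AP"]] / (sigma[["AP"]] + sigma[["WP"]]),
    phiST = (sigma[["AG"]] + sigma[["AP"]]) / tot)
}

#' Three-level AMOVA on a dominant matrix
#'
#' Partitions molecular variance among clusters, among populations within
#' clusters, and within populations, from squared Euclidean distances
#' between binary band vectors (missing bands pairwise-deleted with
#' rescaling). Variance components are solved from the expected mean squares
#' with unbalanced-design coefficients; Phi statistics follow. Percentages
#' use components truncated at zero; the raw signed components are also
#' reported. P-values come from three permutation schemes: individuals
#' among all populations (Phi_ST), individuals among populations within
#' clusters (Phi_SC), and whole populations among clusters (Phi_CT).
#'
#' @param dm a [DominantMatrix-class] object
#' @param clusters named vector population -> cluster label
#' @param nPerm permutations per scheme (default 999); 0 skips the tests
#' @return object of class `AmovaResult`: list with `table` (df, SS,
#'   variance components, percentages), `phi`, `pValues`, `nPerm`
#' @export
amova <- function(dm, clusters, nPerm = 999L) {
  populations <- dm@population
  if (!all(levels(populations) %in% names(clusters)))
    stop("every population needs a cluster assignment")
  if (length(unique(clusters[levels(populations)])) < 2)
    stop("need >= 2 clusters")
  single <- names(table(clusters[levels(populations)]))[
    table(clusters[levels(populations)]) == 1]
  flagged <- if (length(single))
    paste("cluster(s) with a single population (Phi_SC partially confounded):",
          paste(single, collapse = ", ")) else NULL
  d2 <- dominantSquaredDistances(dm@values)
  comp <- amovaComponents(d2, populations, clusters)
  phi <- phiFromSigma(comp$sigma)
  sigTrunc <- pmax(comp$sigma, 0)
  pct <- 100 * sigTrunc / sum(sigTrunc)
  tab <- data.frame(
    source = c("Among clusters", "Among populations within clusters",
               "Within populations", "Total"),
    df = c(comp$df, sum(comp$df)),
    SS = c(comp$ss[c("AG", "AP", "WP")], comp$ss[["total"]]),
    sigma = c(comp$sigma, sum(comp$sigma)),
    pct = c(pct, 100), row.names = NULL)

  pv <- c(phiCT = NA_real_, phiSC = NA_real_, phiST = NA_real_)
  if (nPerm > 0L) {
    popChr <- as.character(populations)
    grpChr <- as.character(clusters[popChr])
    n <- length(popChr)
    statST <- statSC <- statCT <- numeric(nPerm)
    for (b in seq_len(nPerm)) {
      # (1) individuals among all populations
      p1 <- sample(popChr)
      statST[b] <- phiFromSigma(amovaComponents(d2, p1, clusters)$sigma)[["phiST"]]
      # (2) individuals among populations within clusters
      p2 <- popChr
      for (g in unique(grpChr)) {
        idx <- which(grpChr == g)
        p2[idx] <- popChr[idx][sample(length(idx))]
      }
      statSC[b] <- phiFromSigma(amovaComponents(d2, p2, clusters)$sigma)[["phiSC"]]
      # (3) whole populations among clusters
      pops <- names(clusters)
      cl3 <- setNames(sample(as.character(clusters)), pops)
      statCT[b] <- phiFromSigma(amovaComponents(d2, popChr, cl3)$sigma)[["phiCT"]]
    }
    pv <- c(phiCT = (1 + sum(statCT >= phi[["phiCT"]])) / (1 + nPerm),
            phiSC = (1 + sum(statSC >= phi[["phiSC"]])) / (1 + nPerm),
            phiST = (1 + sum(statST >= phi[["phiST"]])) / (1 + nPerm))
  }
  structure(list(table = tab, phi = phi, pValues = pv, nPerm = nPerm,
                 flagged = flagged), class = "AmovaResult")
}

#' @export
print.AmovaResult <- function(x, ...) {
  cat("AMOVA (", x$nPerm, "permutations )\n")
  print(transform(x$table, SS = round(SS, 2), sigma = round(sigma, 3),
                  pct = round(pct, 2)))
  cat(sprintf("Phi_CT = %.3f  Phi_SC = %.3f  Phi_ST = %.3f\n",
              x$phi[["phiCT"]], x$phi[["phiSC"]], x$phi[["phiST"]]))
  if (!is.null(x$flagged)) cat("note:", x$flagged, "\n")
  invisible(x)
}

twoLevelPhiST <- function(d2, populations) {
  popChr <- as.character(populations)
  N <- nrow(d2)
  P <- length(unique(popChr))
  ssTotal <- sum(d2[upper.tri(d2)]) / N
  ssWP <- ssWithinGroups(d2, popChr)
  ssAP <- ssTotal - ssWP
  dfAP <- P - 1; dfWP <- N - P
  np <- table(popChr)
  nprime <- (N - sum(np^2) / N) / dfAP
  sc <- ssWP / dfWP
  sa <- (ssAP / dfAP - sc) / nprime
  sa / (sa + sc)
}

#' Pairwise and global FST from two-level AMOVA
#'
#' For each population pair a two-level AMOVA (among/within populations)
#' yields Phi_ST, used as FST (negative estimates truncated at 0); the
#' global FST comes from the all-population two-level AMOVA. Slatkin
#' gene-flow estimates fill the lower triangle of the `nm` matrix.
#'
#' @param dm a [DominantMatrix-class] object
#' @param nPerm permutations for pairwise p-values (0 = none, default)
#' @param nmForm passed to [slatkinNm()]
#' @return object of class `PairwiseFstResult`: list with `fst` (symmetric
#'   matrix), `nm`, `pValues`, `globalFst`
#' @export
pairwiseFst <- function(dm, nPerm = 0L, nmForm = "diploid") {
  pops <- levels(dm@population)
  if (length(pops) < 2) stop("need >= 2 populations")
  small <- pops[table(dm@population)[pops] < 2]
  if (length(small))
    warning("population(s) of 1 individual skipped in pairs: ",
            paste(small, collapse = ", "))
  d2full <- dominantSquaredDistances(dm@values)
  fst <- matrix(NA_real_, length(pops), length(pops),
                dimnames = list(pops, pops))
  diag(fst) <- 0
  pv <- fst
  for (i in seq_along(pops)) for (j in seq_along(pops)) {
    if (j <= i) next
    if (pops[i] %in% small || pops[j] %in% small) next
    idx <- which(dm@population %in% c(pops[i], pops[j]))
    d2 <- d2full[idx, idx]
    popv <- as.character(dm@population[idx])
    obs <- twoLevelPhiST(d2, popv)
    fst[i, j] <- fst[j, i] <- max(0, obs)
    if (nPerm > 0L) {
      perm <- replicate(nPerm, twoLevelPhiST(d2, sample(popv)))
      pv[i, j] <- pv[j, i] <- (1 + sum(perm >= obs)) / (1 + nPerm)
    }
  }
  globalFst <- max(0, twoLevelPhiST(d2full, dm@population))
  nm <- slatkinNm(fst, form = nmForm)
  nm[upper.tri(nm, diag = TRUE)] <- NA
  structure(list(fst = fst, nm = nm, pValues = pv, globalFst = globalFst,
                 nPerm = nPerm), class = "PairwiseFstResult")
}

#' Slatkin gene-flow estimate from FST
#'
#' Default diploid form `Nm = (1/FST - 1)/4`; the haploid form
#' `(1/FST - 1)/2` is available. `FST = 0` gives the cap (infinite gene
#' flow); `FST = 1` gives 0.
#'
#' @param fst numeric (scalar/matrix) in `[0, 1]`
#' @param form `"diploid"` (default) or `"haploid"`
#' @param cap value reported for FST = 0 (default 1000)
#' @export
slatkinNm <- function(fst, form = c("diploid", "haploid"), cap = 1000) {
  form <- match.arg(form)
  div <- if (form == "diploid") 4 else 2
  out <- ifelse(fst <= 0, cap, (1 / fst - 1) / div)
  out
}
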