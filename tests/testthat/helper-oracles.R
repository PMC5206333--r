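# independent oracles and small fixture builders, coded without reference to
# the package internals they check

# build an SsrGenotypes object from a list of per-individual locus lists
makeGenotypes <- function(cells, population, motif = 3L, lociNames = NULL) {
  # cells: list of individuals, each a list of integer allele-size vectors
  nL <- length(cells[[1]])
  if (is.null(lociNames)) lociNames <- paste0("L", seq_len(nL))
  g <- matrix(list(), length(cells), nL,
              dimnames = list(names(cells), lociNames))
  for (i in seq_along(cells)) for (j in seq_len(nL))
    g[[i, j]] <- as.integer(cells[[i]][[j]])
  loci <- data.frame(name = lociNames, motifLength = rep_len(motif, nL))
  SsrGenotypes(g, loci, population)
}

# ---- Bruvo brute force -------------------------------------------------

# all completions of a distinct-allele set to 4 copies (multisets)
oracleCompletions <- function(a) {
  if (length(a) == 4L) return(list(sort(a)))
  grids <- expand.grid(rep(list(a), 4L - length(a)))
  out <- unique(lapply(seq_len(nrow(grids)),
                       function(r) sort(c(a, as.numeric(grids[r, ])))))
  # keep one representative per multiset of the *composition* space:
  # compositions correspond to multisets of extra copies, so unique() is right
  out
}

oracleBruvoLocus <- function(g1, g2, motif) {
  if (!length(g1) || !length(g2)) return(NA_real_)
  anchor <- min(c(g1, g2))
  r1 <- round((g1 - anchor) / motif)
  r2 <- round((g2 - anchor) / motif)
  perms <- permsOracle(4L)
  score <- function(a, b) {
    min(apply(perms, 1L, function(p) mean(1 - 2^(-abs(a - b[p])))))
  }
  c1 <- oracleCompletions(r1)
  c2 <- oracleCompletions(r2)
  mean(outer(seq_along(c1), seq_along(c2),
             Vectorize(function(i, j) score(c1[[i]], c2[[j]]))))
}

permsOracle <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- permsOracle(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

oracleBruvoMatrix <- function(x) {
  g <- x@genotypes
  n <- nrow(g)
  D <- matrix(0, n, n, dimnames = list(rownames(g), rownames(g)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    ds <- vapply(seq_len(ncol(g)), function(l)
      oracleBruvoLocus(g[[i, l]], g[[j, l]], x@loci$motifLength[l]), 0)
    D[i, j] <- D[j, i] <- mean(ds, na.rm = TRUE)
  }
  D
}

# ---- AMOVA direct summation -------------------------------------------

# three-level AMOVA from centroid deviations (complete binary data only);
# independent of the pairwise-distance formulation used by the package
oracleAmova <- function(v, populations, clusters) {
  populations <- as.character(populations)
  groups <- as.character(clusters[populations])
  N <- nrow(v)
  grand <- colMeans(v)
  ssTotal <- sum(sweep(v, 2, grand)^2)
  ssWP <- 0
  for (p in unique(populations)) {
    rows <- v[populations == p, , drop = FALSE]
    ssWP <- ssWP + sum(sweep(rows, 2, colMeans(rows))^2)
  }
  ssWG <- 0
  for (g in unique(groups)) {
    rows <- v[groups == g, , drop = FALSE]
    ssWG <- ssWG + sum(sweep(rows, 2, colMeans(rows))^2)
  }
  ssAP <- ssWG - ssWP
  ssAG <- ssTotal - ssWG
  P <- length(unique(populations)); G <- length(unique(groups))
  dfAG <- G - 1; dfAP <- P - G; dfWP <- N - P
  np <- table(populations); ng <- table(groups)
  grpOfPop <- vapply(names(np),
                     function(p) groups[match(p, populations)], "")
  A <- sum(vapply(names(ng), function(g) sum(np[grpOfPop == g]^2) / ng[[g]], 0))
  n1 <- (N - A) / dfAP
  n2 <- (A - sum(np^2) / N) / dfAG
  n3 <- (N - sum(ng^2) / N) / dfAG
  sc <- ssWP / dfWP
  sb <- (ssAP / dfAP - sc) / n1
  sa <- (ssAG / dfAG - sc - n2 * sb) / n3
  list(df = c(dfAG, dfAP, dfWP), ss = c(ssAG, ssAP, ssWP),
       sigma = c(sa, sb, sc))
}

# two-level AMOVA oracle (among/within populations) from centroid deviations
oracleTwoLevelPhi <- function(v, populations) {
  populations <- as.character(populations)
  N <- nrow(v); P <- length(unique(populations))
  grand <- colMeans(v)
  ssTotal <- sum(sweep(v, 2, grand)^2)
  ssWP <- 0
  for (p in unique(populations)) {
    rows <- v[populations == p, , drop = FALSE]
    ssWP <- ssWP + sum(sweep(rows, 2, colMeans(rows))^2)
  }
  ssAP <- ssTotal - ssWP
  np <- table(populations)
  nprime <- (N - sum(np^2) / N) / (P - 1)
  sc <- ssWP / (N - P)
  sa <- (ssAP / (P - 1) - sc) / nprime
  sa / (sa + sc)
}

# random binary dominant fixture with population/cluster structure
randomDominant <- function(nPerPop, nBands = 12L, nClusters = 2L,
                           shift = 0.3) {
  nPop <- length(nPerPop)
  cl <- rep_len(paste0("g", seq_len(nClusters)), nPop)
  pops <- paste0("p", seq_len(nPop))
  base <- matrix(runif(nBands), nClusters, nBands)
  v <- NULL; popv <- NULL
  for (k in seq_len(nPop)) {
    pr <- pmin(pmax(base[match(cl[k], paste0("g", seq_len(nClusters))), ] +
                      runif(nBands, -shift, shift), 0.05), 0.95)
    rows <- matrix(rbinom(nPerPop[k] * nBands, 1, rep(pr, each = nPerPop[k])),
                   nPerPop[k], nBands)
    v <- rbind(v, rows); popv <- c(popv, rep(pops[k], nPerPop[k]))
  }
  # guarantee every band present somewhere
  for (b in seq_len(ncol(v))) if (all(v[, b] == 0)) v[sample(nrow(v), 1), b] <- 1L
  rownames(v) <- sprintf("i%02d", seq_len(nrow(v)))
  colnames(v) <- sprintf("L%d.%d", rep(1:3, length.out = nBands), seq_len(nBands))
  info <- data.frame(locus = sub("\\..*", "", colnames(v)),
                     size = seq_len(nBands))
  list(dm = DominantMatrix(v, info, popv),
       clusters = setNames(cl, pops))
}

# ---- Delaunay O(n^4) empty-circumcircle checker -----------------------

oracleDelaunayEdges <- function(x, y) {
  n <- length(x)
  inCircle <- function(ax, ay, bx, by, cx, cy, px, py) {
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) return(TRUE)
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    r2 <- (ax - ux)^2 + (ay - uy)^2
    ((px - ux)^2 + (py - uy)^2) < r2 * (1 - 1e-12)
  }
  edges <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    found <- FALSE
    for (k in seq_len(n)) {
      if (k == i || k == j) next
      empty <- TRUE
      for (p in seq_len(n)) {
        if (p %in% c(i, j, k)) next
        if (inCircle(x[i], y[i], x[j], y[j], x[k], y[k], x[p], y[p])) {
          empty <- FALSE; break
        }
      }
      if (empty) { found <- TRUE; break }
    }
    if (found) edges <- rbind(edges, c(i, j))
  }
  edges
}
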