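## per-population and total diversity statistics for tetraploid genotypes

#' Allele frequencies per population and locus
#'
#' Each usable cell contributes 4 gene copies. Under `"equal-split"` a
#' dosage-ambiguous cell with k distinct alleles gives each of them weight
#' 4/k; under `"known-only"` ambiguous cells are excluded. Missing cells
#' contribute nothing. Population-locus combinations with zero usable cells
#' get an empty frequency map and are flagged in `attr(,"empty")`.
#'
#' @param x an [SsrGenotypes-class] object
#' @param dosagePolicy `"equal-split"` or `"known-only"`
#' @return object of class `AlleleFreqTable`: list with `counts[[pop]][[locus]]`
#'   (named weight vectors summing to the gene copies used), `copies`
#'   (population x locus matrix of gene-copy counts) and `policy`.
#' @export
alleleFrequencies <- function(x, dosagePolicy = c("equal-split", "known-only")) {
  dosagePolicy <- match.arg(dosagePolicy)
  g <- x@genotypes
  pops <- levels(x@population)
  locs <- colnames(g)
  copies <- matrix(0, length(pops), length(locs), dimnames = list(pops, locs))
  counts <- setNames(vector("list", length(pops)), pops)
  empty <- character(0)
  for (p in pops) {
    rows <- which(x@population == p)
    counts[[p]] <- setNames(vector("list", length(locs)), locs)
    for (j in seq_along(locs)) {
      acc <- numeric(0)
      for (i in rows) {
        a <- g[[i, j]]
        if (!length(a)) next
        if (length(a) < 4L && dosagePolicy == "known-only") next
        w <- if (length(a) == 4L) table(a) else
          setNames(rep(4 / length(a), length(a)), a)
        for (nm in names(w))
          acc[nm] <- (if (nm %in% names(acc)) acc[nm] else 0) + as.numeric(w[nm])
        copies[p, j] <- copies[p, j] + 4
      }
      counts[[p]][[j]] <- acc[order(as.numeric(names(acc)))]
      if (copies[p, j] == 0) empty <- c(empty, paste(p, locs[j], sep = ":"))
    }
  }
  out <- structure(list(counts = counts, copies = copies, policy = dosagePolicy,
                        populations = pops, loci = locs),
                   class = "AlleleFreqTable")
  attr(out, "empty") <- empty
  out
}

freqVector <- function(ft, pop, locus) {
  cnt <- ft$counts[[pop]][[locus]]
  if (!length(cnt)) return(numeric(0))
  cnt / sum(cnt)
}

#' Nei unbiased gene diversity
#'
#' He = (n/(n-1)) (1 - sum p^2), with n the number of gene copies used at
#' the population-locus combination; the multilocus value is the unweighted
#' mean over loci with at least 2 copies. Combinations with fewer than 2
#' copies are undefined (`NA`).
#'
#' @param ft an `AlleleFreqTable` from [alleleFrequencies()]
#' @return list with `perLocus` (population x locus matrix) and
#'   `perPopulation` (multilocus means)
#' @export
geneDiversity <- function(ft) {
  he <- ft$copies * NA_real_
  for (p in ft$populations) for (l in ft$loci) {
    n <- ft$copies[p, l]
    if (n >= 2) {
      pvec <- freqVector(ft, p, l)
      he[p, l] <- n / (n - 1) * (1 - sum(pvec^2))
    }
  }
  list(perLocus = he, perPopulation = rowMeans(he, na.rm = TRUE))
}

#' Rarefied allelic richness
#'
#' Expected number of alleles in a subsample of `g` gene copies:
#' `sum_a (1 - choose(N - N_a, g)/choose(N, g))`, evaluated with
#' `lchoose` so that fractional equal-split counts are handled (the binomial
#' coefficient is continued through the gamma function). `g` defaults to the
#' smallest gene-copy count over populations and loci (for complete data,
#' 4 x smallest population size).
#'
#' @param ft an `AlleleFreqTable`
#' @param g rarefaction gene-copy count (>= 2)
#' @return list with `perLocus`, `perPopulation`, and `g`
#' @export
allelicRichness <- function(ft, g = NULL) {
  if (is.null(g)) g <- min(ft$copies[ft$copies > 0])
  if (g < 2) stop("rarefaction copy count g must be >= 2")
  if (g > min(ft$copies[ft$copies > 0]))
    stop("g exceeds the smallest gene-copy count (", min(ft$copies[ft$copies > 0]), ")")
  ar <- ft$copies * NA_real_
  for (p in ft$populations) for (l in ft$loci) {
    N <- ft$copies[p, l]
    if (N < g) next
    cnt <- ft$counts[[p]][[l]]
    terms <- vapply(cnt, function(na) {
      if (N - na < g) 1 else 1 - exp(lchoose(N - na, g) - lchoose(N, g))
    }, 0)
    ar[p, l] <- sum(terms)
  }
  list(perLocus = ar, perPopulation = rowMeans(ar, na.rm = TRUE), g = g)
}

#' Observed allele counts
#'
#' Multilocus mean number of distinct alleles per population, plus the
#' pooled count over all populations per locus.
#' @param ft an `AlleleFreqTable`
#' @export
alleleCounts <- function(ft) {
  na <- ft$copies * NA_real_
  for (p in ft$populations) for (l in ft$loci)
    na[p, l] <- length(ft$counts[[p]][[l]])
  pooled <- vapply(ft$loci, function(l) {
    length(unique(unlist(lapply(ft$populations,
                                function(p) names(ft$counts[[p]][[l]])))))
  }, 0)
  list(perLocus = na, perPopulation = rowMeans(na, na.rm = TRUE),
       pooledPerLocus = pooled, totalAlleles = sum(pooled))
}

#' Total gene diversity (HT)
#'
#' Per locus, HT is computed from the unweighted mean of population allele
#' frequencies with the small-sample correction
#' `HT = 1 - sum(xbar^2) + HS/(c~ * npop)`, where HS is the mean unbiased
#' within-population diversity and `c~` the harmonic mean gene-copy count;
#' the multilocus HT is the mean over loci.
#'
#' @param ft an `AlleleFreqTable`
#' @return list with `perLocus` and `multilocus`
#' @export
totalGeneDiversity <- function(ft) {
  if (length(ft$populations) < 2) stop("HT requires >= 2 populations")
  he <- geneDiversity(ft)$perLocus
  ht <- setNames(rep(NA_real_, length(ft$loci)), ft$loci)
  for (l in ft$loci) {
    use <- ft$populations[ft$copies[, l] >= 2]
    if (length(use) < 2) next
    alleles <- sort(unique(unlist(lapply(use, function(p)
      as.numeric(names(ft$counts[[p]][[l]]))))))
    pm <- sapply(use, function(p) {
      v <- freqVector(ft, p, l)
      out <- setNames(rep(0, length(alleles)), alleles)
      out[names(v)] <- v
      out
    })
    xbar <- rowMeans(as.matrix(pm))
    hs <- mean(he[use, l])
    ctilde <- 1 / mean(1 / ft$copies[use, l])
    ht[l] <- 1 - sum(xbar^2) + hs / (ctilde * length(use))
  }
  list(perLocus = ht, multilocus = mean(ht, na.rm = TRUE))
}

#' Private alleles
#'
#' An allele is private when it occurs in exactly one population. By default
#' Pa(pop) = 100 x (private alleles of pop) / (total distinct alleles over
#' all populations and loci), so the per-population percentages sum to the
#' total. The alternative denominator (`"own"`) divides by the population's
#' own allele count instead.
#'
#' @param ft an `AlleleFreqTable`
#' @param denominator `"global"` (default) or `"own"`
#' @return list with `perPopulation` (percent), `total`, and `counts`
#' @export
privateAlleles <- function(ft, denominator = c("global", "own")) {
  denominator <- match.arg(denominator)
  if (length(ft$populations) < 2) stop("private alleles require >= 2 populations")
  priv <- setNames(rep(0, length(ft$populations)), ft$populations)
  own <- priv
  totalAlleles <- 0
  for (l in ft$loci) {
    pres <- lapply(ft$populations, function(p) names(ft$counts[[p]][[l]]))
    names(pres) <- ft$populations
    all <- unique(unlist(pres))
    totalAlleles <- totalAlleles + length(all)
    inPops <- sapply(all, function(a)
      sum(vapply(pres, function(v) a %in% v, TRUE)))
    for (p in ft$populations) {
      own[p] <- own[p] + length(pres[[p]])
      priv[p] <- priv[p] + sum(inPops[pres[[p]]] == 1)
    }
  }
  pct <- if (denominator == "global") 100 * priv / totalAlleles else
    100 * priv / pmax(own, 1)
  list(perPopulation = pct,
       total = if (denominator == "global") sum(pct) else NA_real_,
       counts = priv, totalAlleles = totalAlleles)
}

## ---- inbreeding -------------------------------------------------------

# exact mean within-individual identity over all dosage completions,
# indexed by the number of distinct alleles (pairs of identical copies /
# the 6 within-individual copy pairs)
QIND_AMBIG <- c(`1` = 1, `2` = 4 / 9, `3` = 1 / 6, `4` = 0)

qIndCell <- function(a) {
  if (!length(a)) return(NA_real_)
  if (length(a) == 4L) {
    m <- table(a)
    sum(m * (m - 1)) / 12
  } else QIND_AMBIG[[as.character(length(a))]]
}

# equal-split weight matrix (rows = individuals of one population at one
# locus, columns = alleles); NULL if no usable cells
weightMatrix <- function(cells, alleles) {
  w <- matrix(0, length(cells), length(alleles),
              dimnames = list(NULL, alleles))
  for (i in seq_along(cells)) {
    a <- cells[[i]]
    if (!length(a)) { w[i, ] <- NA; next }
    if (length(a) == 4L) {
      tb <- table(a)
      w[i, names(tb)] <- as.numeric(tb)
    } else w[i, as.character(a)] <- 4 / length(a)
  }
  w
}

qPopFromWeights <- function(w) {
  ok <- !is.na(w[, 1L])
  w <- w[ok, , drop = FALSE]
  n <- nrow(w)
  if (n < 2) return(NA_real_)
  C <- colSums(w)
  (sum(C^2) - sum(w^2)) / (16 * n * (n - 1))
}

#' Individual and multilocus inbreeding coefficients
#'
#' Fi compares the mean identity-in-state of the 6 within-individual gene
#' copy pairs (Q_ind; averaged exactly over all dosage completions for
#' ambiguous cells) with the mean identity over between-individual copy
#' pairs in the same population (Q_pop):
#' `Fi = (Q_ind - Q_pop) / (1 - Q_pop)`, combined over loci as the ratio of
#' summed numerators to summed denominators. FIS is the same ratio over all
#' individuals and loci. Monomorphic population-locus combinations
#' (denominator 0) are skipped. Significance is assessed by permuting gene
#' copies among individuals within populations (ambiguous cells resolved to
#' one sampled dosage completion first), two-sided.
#'
#' @param x an [SsrGenotypes-class] object
#' @param nPerm number of permutations (default 999); 0 skips the test
#' @return list with `fiIndividual`, `fiPopulation`, `fiPopulationP`,
#'   `fis`, `fisP`, `nPerm`
#' @export
inbreedingCoefficients <- function(x, nPerm = 999L) {
  g <- x@genotypes
  pops <- levels(x@population)
  nI <- nrow(g)
  num <- matrix(NA_real_, nI, ncol(g))
  den <- matrix(NA_real_, nI, ncol(g))
  for (p in pops) {
    rows <- which(x@population == p)
    for (j in seq_len(ncol(g))) {
      cells <- g[rows, j]
      alleles <- as.character(sort(unique(unlist(cells))))
      if (length(alleles) < 2) next  # monomorphic or empty: skipped
      w <- weightMatrix(cells, alleles)
      qp <- qPopFromWeights(w)
      if (is.na(qp) || qp >= 1) next
      for (k in seq_along(rows)) {
        qi <- qIndCell(cells[[k]])
        if (is.na(qi)) next
        num[rows[k], j] <- qi - qp
        den[rows[k], j] <- 1 - qp
      }
    }
  }
  fiInd <- rowSums(num, na.rm = TRUE) / rowSums(den, na.rm = TRUE)
  fiInd[rowSums(!is.na(den)) == 0] <- NA
  names(fiInd) <- rownames(g)
  fiPop <- vapply(pops, function(p) {
    rows <- x@population == p
    sum(num[rows, ], na.rm = TRUE) / sum(den[rows, ], na.rm = TRUE)
  }, 0)
  fis <- sum(num, na.rm = TRUE) / sum(den, na.rm = TRUE)

  fisP <- NA_real_
  fiPopP <- setNames(rep(NA_real_, length(pops)), pops)
  if (nPerm > 0L) {
    resolved <- resolveDosage(g)
    obs <- fisFromResolved(resolved, x@population)
    perm <- replicate(nPerm, {
      fisFromResolved(permuteCopies(resolved, x@population), x@population)
    })
    fisP <- (1 + sum(abs(perm["fis", ]) >= abs(obs["fis"]))) / (1 + nPerm)
    for (p in pops) {
      fiPopP[p] <- (1 + sum(abs(perm[p, ]) >= abs(obs[p]))) / (1 + nPerm)
    }
  }
  list(fiIndividual = fiInd, fiPopulation = fiPop, fiPopulationP = fiPopP,
       fis = fis, fisP = fisP, nPerm = nPerm)
}

# sample one dosage completion for each ambiguous cell (uniform over
# compositions of the remaining copies among the distinct alleles)
resolveDosage <- function(g) {
  res <- g
  for (idx in seq_along(g)) {
    a <- g[[idx]]
    if (length(a) %in% c(1L, 2L, 3L)) res[[idx]] <- sampleCompletion(a)
  }
  res
}

completionsOf <- function(a) {
  k <- length(a)
  extra <- 4L - k
  if (extra == 0L) return(list(sort(a)))
  comps <- compositions(extra, k)
  lapply(seq_len(nrow(comps)), function(r) sort(rep(a, times = 1L + comps[r, ])))
}

compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, 1L, 1L))
  out <- NULL
  for (i in 0:n) {
    rest <- compositions(n - i, k - 1L)
    out <- rbind(out, cbind(i, rest))
  }
  unname(out)
}

sampleCompletion <- function(a) {
  cs <- completionsOf(a)
  cs[[sample.int(length(cs), 1L)]]
}

fisFromResolved <- function(g, population) {
  pops <- levels(population)
  numT <- 0; denT <- 0
  popNum <- setNames(rep(0, length(pops)), pops)
  popDen <- popNum
  for (p in pops) {
    rows <- which(population == p)
    for (j in seq_len(ncol(g))) {
      cells <- g[rows, j]
      alleles <- as.character(sort(unique(unlist(cells))))
      if (length(alleles) < 2) next
      w <- weightMatrix(cells, alleles)
      qp <- qPopFromWeights(w)
      if (is.na(qp) || qp >= 1) next
      for (k in seq_along(rows)) {
        qi <- qIndCell(cells[[k]])
        if (is.na(qi)) next
        popNum[p] <- popNum[p] + (qi - qp)
        popDen[p] <- popDen[p] + (1 - qp)
      }
    }
  }
  fis <- sum(popNum) / sum(popDen)
  c(fis = fis, setNames(popNum / popDen, pops))
}

# shuffle resolved gene copies among individuals within each population
permuteCopies <- function(g, population) {
  out <- g
  for (p in levels(population)) {
    rows <- which(population == p)
    for (j in seq_len(ncol(g))) {
      cells <- g[rows, j]
      use <- which(vapply(cells, length, 0L) == 4L)
      if (length(use) < 2) next
      pool <- sample(unlist(cells[use]))
      for (k in seq_along(use))
        out[[rows[use[k]], j]] <- sort(pool[(4L * k - 3L):(4L * k)])
    }
  }
  out
}

#' Per-population diversity summary table
#'
#' Assembles the per-population report: sample size N, multilocus mean
#' allele count NA, rarefied allelic richness AR, unbiased gene diversity
#' He, mean individual inbreeding coefficient Fi with its permutation
#' p-value, and the private-allele percentage Pa; plus totals (pooled NA,
#' AR at the same rarefaction depth, total diversity HT, multilocus FIS with
#' p-value, summed Pa).
#'
#' @param x an [SsrGenotypes-class] object
#' @param g rarefaction copy count (default: smallest gene-copy count)
#' @param nPerm permutations for the inbreeding tests
#' @param dosagePolicy passed to [alleleFrequencies()]
#' @return list with `table` (data.frame, one row per population) and
#'   `totals` (named list)
#' @export
diversitySummary <- function(x, g = NULL, nPerm = 999L,
                             dosagePolicy = "equal-split") {
  ft <- alleleFrequencies(x, dosagePolicy)
  na <- alleleCounts(ft)
  ar <- allelicRichness(ft, g)
  he <- geneDiversity(ft)
  ht <- totalGeneDiversity(ft)
  pa <- privateAlleles(ft)
  inb <- inbreedingCoefficients(x, nPerm = nPerm)
  pops <- ft$populations
  tab <- data.frame(
    population = pops,
    N = as.integer(table(x@population)[pops]),
    NA_ = na$perPopulation[pops],
    AR = ar$perPopulation[pops],
    He = he$perPopulation[pops],
    Fi = inb$fiPopulation[pops],
    Fi_p = inb$fiPopulationP[pops],
    Pa = pa$perPopulation[pops],
    row.names = NULL, check.names = FALSE
  )
  totals <- list(
    N = nInd(x),
    NA_total = mean(na$pooledPerLocus),
    totalAlleles = na$totalAlleles,
    HT = ht$multilocus,
    FIS = inb$fis, FIS_p = inb$fisP,
    Pa_total = pa$total,
    rarefaction_g = ar$g, nPerm = nPerm
  )
  list(table = tab, totals = totals)
}
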