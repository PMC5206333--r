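## Bayesian admixture clustering of the dominant matrix, Evanno delta-K,
## greedy alignment of replicate runs

#' MCMC settings for admixture runs
#'
#' Desk-scale defaults (20000 repetitions, 5000 burn-in, 3 replicates per K)
#' keep a full K-scan tractable on one CPU; the full-scale settings used in
#' classic STRUCTURE analyses (500000/50000, 10 replicates, K 1--10) can be
#' requested explicitly.
#'
#' @param reps total MCMC iterations
#' @param burnin iterations discarded (must be < reps)
#' @param replicates independent runs per K
#' @param kRange inclusive range of K values
#' @param thin record the likelihood trace every `thin` iterations
#' @param seed integer seed
#' @export
mcmcSettings <- function(reps = 20000L, burnin = 5000L, replicates = 3L,
                         kRange = 1:7, thin = 10L, seed = 1L) {
  stopifnot(burnin < reps, replicates >= 1L, min(kRange) >= 1L)
  list(reps = as.integer(reps), burnin = as.integer(burnin),
       replicates = as.integer(replicates), kRange = as.integer(kRange),
       thin = as.integer(thin), seed = as.integer(seed))
}

#' Run the admixture Gibbs sampler for one K
#'
#' Bands are modelled as haploid biallelic loci. The sampler alternates:
#' per-(individual, band) cluster-of-origin indicators; cluster band
#' frequencies under the correlated-frequencies F-model (conjugate Beta
#' update around ancestral frequencies); Metropolis updates of the ancestral
#' frequencies and per-cluster drift parameters F_k (uniform priors); and
#' Dirichlet(alpha) admixture proportions with a Metropolis step on the
#' shared alpha (uniform(0,10) prior). The reported Q matrix is the
#' posterior mean over post-burn-in iterations.
#'
#' Initialisation runs `nInits` short independent pilot chains
#' (`initIters` sweeps each) and continues the best by log-likelihood:
#' the conjugate updates converge fast, so chains headed for poorly merged
#' local modes are cheap to detect and discard.
#'
#' @param dm a [DominantMatrix-class] object
#' @param K number of clusters (1 <= K <= number of individuals)
#' @param reps,burnin,thin MCMC controls
#' @param nInits,initIters pilot-chain initialisation controls
#' @param seed optional seed (`set.seed` is called when non-NULL)
#' @return object of class `AdmixtureRun`: list with `q` (individuals x K,
#'   rows summing to 1), `lnP` (thinned trace), `meanLnP`, `K`, `alpha`,
#'   `F`, `seed`
#' @export
runAdmixture <- function(dm, K, reps = 20000L, burnin = 5000L, thin = 10L,
                         nInits = 5L, initIters = 1000L, seed = NULL) {
  v <- dm@values
  if (any(rowSums(!is.na(v)) == 0L)) stop("individual with all bands missing")
  if (K > nrow(v)) stop("K exceeds the number of individuals")
  if (!is.null(seed)) set.seed(seed)
  res <- structure_gibbs_cpp(v, as.integer(K), as.integer(reps),
                             as.integer(burnin), as.integer(thin),
                             as.integer(nInits), as.integer(initIters))
  q <- res$q
  dimnames(q) <- list(rownames(v), paste0("cluster", seq_len(K)))
  # model likelihood estimated as mean - var/2 of the post-burn-in trace
  # (the deviance-based estimator STRUCTURE reports; over-parameterised K
  # inflates the trace variance and is penalised accordingly)
  post <- res$lnP[seq.int(floor(burnin / thin) + 1L, length(res$lnP))]
  meanLnP <- mean(post) - var(post) / 2
  structure(list(q = q, lnP = res$lnP, meanLnP = meanLnP, K = K,
                 alpha = res$alpha, F = res$F, seed = seed,
                 settings = list(reps = reps, burnin = burnin, thin = thin)),
            class = "AdmixtureRun")
}

#' @export
print.AdmixtureRun <- function(x, ...) {
  cat("AdmixtureRun: K =", x$K, " mean lnP =", sprintf("%.1f", x$meanLnP), "\n")
  invisible(x)
}

#' Scan K values with replicate runs
#'
#' @param dm a [DominantMatrix-class] object
#' @param settings from [mcmcSettings()]
#' @return list with `runs` (list of lists of `AdmixtureRun` per K) and
#'   `lnPTable` (data.frame K, replicate, meanLnP)
#' @export
admixtureScan <- function(dm, settings = mcmcSettings()) {
  runs <- list()
  tab <- NULL
  for (K in settings$kRange) {
    runs[[as.character(K)]] <- lapply(seq_len(settings$replicates), function(r) {
      runAdmixture(dm, K, reps = settings$reps, burnin = settings$burnin,
                   thin = settings$thin,
                   seed = settings$seed + 1000L * K + r)
    })
    tab <- rbind(tab, data.frame(
      K = K, replicate = seq_len(settings$replicates),
      meanLnP = vapply(runs[[as.character(K)]], `[[`, 0, "meanLnP")))
  }
  list(runs = runs, lnPTable = tab)
}

#' Evanno delta-K table
#'
#' `deltaK(K) = |L(K+1) - 2 L(K) + L(K-1)| / sd(L(K))`, defined for interior
#' K only; the best K is the interior argmax. K values whose replicate sd is
#' zero get `NA` and are flagged.
#'
#' @param lnPTable data.frame with columns `K`, `meanLnP` (one row per
#'   replicate), e.g. from [admixtureScan()]
#' @return data.frame with columns `K`, `meanLnP`, `sdLnP`, `Lprime`,
#'   `Lsecond`, `deltaK`, and attribute `bestK`
#' @export
evanno <- function(lnPTable) {
  agg <- aggregate(meanLnP ~ K, lnPTable, function(v) c(mean(v), sd(v)))
  K <- agg$K
  if (length(K) < 3) stop("need >= 3 consecutive K values")
  mu <- agg$meanLnP[, 1]
  sdv <- agg$meanLnP[, 2]
  n <- length(K)
  lp <- c(NA, diff(mu))
  ls <- c(NA, abs(diff(mu, differences = 2)), NA)
  dk <- ls / sdv
  dk[sdv == 0] <- NA
  out <- data.frame(K = K, meanLnP = mu, sdLnP = sdv, Lprime = lp,
                    Lsecond = ls, deltaK = dk)
  interior <- 2:(n - 1)
  best <- if (all(is.na(dk[interior]))) NA_integer_ else
    K[interior][which.max(dk[interior])]
  attr(out, "bestK") <- best
  out
}

permutationsOf <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutationsOf(k - 1L)
  out <- NULL
  for (i in seq_len(k)) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  unname(out)
}

#' Align replicate admixture runs (greedy)
#'
#' Resolves label switching across replicate runs of the same K: run 1 is
#' the reference; each subsequent run receives the column permutation
#' minimising the squared Frobenius distance to the running mean
#' (exhaustive over K! permutations for K <= 8, greedy column matching
#' otherwise). Returns the averaged aligned Q matrix and a pairwise
#' similarity score (1 for identical runs up to permutation).
#'
#' @param runs list of `AdmixtureRun` objects sharing K and individuals
#' @return list with `q` (consensus), `aligned` (list of aligned Q
#'   matrices), `permutations`, `similarity`
#' @export
alignRuns <- function(runs) {
  qs <- lapply(runs, function(r) if (inherits(r, "AdmixtureRun")) r$q else r)
  K <- ncol(qs[[1]])
  if (!all(vapply(qs, ncol, 0L) == K) ||
      !all(vapply(qs, nrow, 0L) == nrow(qs[[1]])))
    stop("runs must share K and individual order")
  perms <- list(seq_len(K))
  aligned <- list(qs[[1]])
  runmean <- qs[[1]]
  if (length(qs) > 1) {
    allperm <- if (K <= 8L) permutationsOf(K) else NULL
    for (r in 2:length(qs)) {
      q <- qs[[r]]
      if (!is.null(allperm)) {
        costs <- apply(allperm, 1L, function(pp) sum((q[, pp] - runmean)^2))
        best <- allperm[which.min(costs), ]
      } else {
        # greedy column matching by maximal correlation
        best <- integer(K)
        avail <- seq_len(K)
        for (k in seq_len(K)) {
          sims <- vapply(avail, function(a) -sum((q[, a] - runmean[, k])^2), 0)
          best[k] <- avail[which.max(sims)]
          avail <- setdiff(avail, best[k])
        }
      }
      perms[[r]] <- best
      aligned[[r]] <- q[, best, drop = FALSE]
      colnames(aligned[[r]]) <- colnames(runmean)
      runmean <- Reduce(`+`, aligned) / length(aligned)
    }
  }
  consensus <- Reduce(`+`, aligned) / length(aligned)
  sim <- 1
  if (length(aligned) > 1) {
    pairsim <- combn(length(aligned), 2L, function(ij) {
      1 - sum((aligned[[ij[1]]] - aligned[[ij[2]]])^2) / (2 * nrow(consensus))
    })
    sim <- mean(pairsim)
  }
  list(q = consensus, aligned = aligned, permutations = perms,
       similarity = sim)
}
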