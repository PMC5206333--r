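## Bruvo, Nei (dominant) and geographic distance matrices

#' Bruvo distance between two tetraploid genotypes at one locus
#'
#' Per-allele distance `1 - 2^-|x|` with `x` the repeat-count difference;
#' the genotype distance is the minimum over all bijective assignments of
#' the four copies (exhaustive over the 24 permutations). Dosage-ambiguous
#' genotypes are expanded to all completions to 4 copies and the mean over
#' completion pairs is returned. Returns `NA` when either genotype is
#' missing.
#'
#' @param g1,g2 integer vectors of allele sizes (bp), length 0--4
#' @param motifLength bp per repeat unit
#' @return distance in `[0, 1]`
#' @export
bruvoPair <- function(g1, g2, motifLength) {
  if (!length(g1) || !length(g2)) return(NA_real_)
  anchor <- min(c(g1, g2))
  r1 <- sizesToRepeats(g1, motifLength, anchor)
  r2 <- sizesToRepeats(g2, motifLength, anchor)
  bruvo_locus_cpp(r1, r2)
}

#' Multilocus Bruvo distance matrix
#'
#' The multilocus distance is the mean of per-locus Bruvo distances over
#' loci scored in both individuals. Pairs sharing no scored locus are an
#' error unless `allowMissing = TRUE` (then `NA`).
#'
#' @param x an [SsrGenotypes-class] object (loci must carry motif lengths)
#' @param allowMissing keep pairs with zero shared loci as `NA`
#' @return a symmetric labelled matrix with `kind = "bruvo"`
#' @export
bruvoMatrix <- function(x, allowMissing = FALSE) {
  if (nInd(x) < 2) stop("need >= 2 individuals")
  g <- x@genotypes
  n <- nrow(g); L <- ncol(g)
  cells <- vector("list", n * L)
  for (j in seq_len(L)) {
    sizes <- unlist(g[, j])
    anchor <- if (length(sizes)) min(sizes) else 0L
    motif <- x@loci$motifLength[j]
    for (i in seq_len(n)) {
      a <- g[[i, j]]
      cells[[(j - 1L) * n + i]] <-
        if (length(a)) sizesToRepeats(a, motif, anchor) else integer(0)
    }
  }
  res <- bruvo_matrix_cpp(cells, n, L)
  d <- res$d
  dimnames(d) <- list(rownames(g), rownames(g))
  if (any(is.na(d[upper.tri(d)]))) {
    if (!allowMissing) stop("some individual pairs share no scored locus")
  }
  distMatrix(d, "bruvo")
}

#' Nei genetic distance between populations from a dominant matrix
#'
#' Each band is treated as a biallelic locus with presence frequency `p`
#' per population. Nei's standard distance is
#' `D = -ln(J12 / sqrt(J1 J2))` with the J terms averaged over bands
#' (`J12 = mean(p1 p2 + (1-p1)(1-p2))` etc.). `variant = "unbiased"`
#' replaces the within-population J terms by their small-sample unbiased
#' estimates `(n J - 1)/(n - 1)`. A zero `J12` (completely disjoint
#' profiles) gives a capped distance with a warning.
#'
#' @param dm a [DominantMatrix-class] object
#' @param variant `"standard"` (Nei 1972, default) or `"unbiased"` (1978)
#' @param cap ceiling for infinite distances (default 10)
#' @return a symmetric labelled matrix with `kind = "nei"`; capped cells
#'   are flagged in `attr(,"capped")`
#' @export
neiDistance <- function(dm, variant = c("standard", "unbiased"), cap = 10) {
  variant <- match.arg(variant)
  pops <- levels(dm@population)
  if (length(pops) < 2) stop("need >= 2 populations")
  v <- dm@values
  p <- t(vapply(pops, function(pp)
    colMeans(v[dm@population == pp, , drop = FALSE] == 1L, na.rm = TRUE),
    numeric(ncol(v))))
  nind <- as.integer(table(dm@population)[pops])
  D <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  capped <- NULL
  jWithin <- function(i) {
    j <- p[i, ]^2 + (1 - p[i, ])^2
    if (variant == "unbiased") j <- (nind[i] * j - 1) / (nind[i] - 1)
    mean(j, na.rm = TRUE)
  }
  for (i in seq_along(pops)) for (j in seq_along(pops)) {
    if (j <= i) next
    j12 <- mean(p[i, ] * p[j, ] + (1 - p[i, ]) * (1 - p[j, ]), na.rm = TRUE)
    if (j12 <= 0) {
      D[i, j] <- D[j, i] <- cap
      capped <- rbind(capped, c(pops[i], pops[j]))
    } else {
      d <- -log(j12 / sqrt(jWithin(i) * jWithin(j)))
      D[i, j] <- D[j, i] <- min(d, cap)
      if (d > cap) capped <- rbind(capped, c(pops[i], pops[j]))
    }
  }
  if (!is.null(capped))
    warning(nrow(capped), " population pair(s) at the distance cap ", cap)
  out <- distMatrix(D, "nei")
  attr(out, "capped") <- capped
  out
}

#' Great-circle distance matrix between populations
#'
#' Haversine distances in metres on a sphere of radius 6371000 m.
#'
#' @param coords data.frame with columns `population`, `lat`, `lon`
#'   (decimal degrees)
#' @return a symmetric labelled matrix with `kind = "geographic"`
#' @export
geographicMatrix <- function(coords) {
  if (any(is.na(coords$lat)) || any(is.na(coords$lon)))
    stop("missing coordinates for: ",
         paste(coords$population[is.na(coords$lat) | is.na(coords$lon)],
               collapse = ", "))
  n <- nrow(coords)
  D <- matrix(0, n, n, dimnames = list(coords$population, coords$population))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    D[i, j] <- D[j, i] <- geosphere::distHaversine(
      c(coords$lon[i], coords$lat[i]), c(coords$lon[j], coords$lat[j]),
      r = 6371000)
  }
  distMatrix(D, "geographic")
}

#' Cluster-membership indicator matrix
#'
#' Binary population-by-population matrix: 1 iff the two populations belong
#' to different genetic clusters.
#'
#' @param clusters named vector (population -> cluster label)
#' @return a symmetric labelled matrix with `kind = "cluster-indicator"`
#' @export
clusterIndicatorMatrix <- function(clusters) {
  m <- outer(clusters, clusters, FUN = `!=`) * 1
  dimnames(m) <- list(names(clusters), names(clusters))
  distMatrix(m, "cluster-indicator")
}

#' Export a distance matrix as lower-triangle PHYLIP text
#' @param d symmetric labelled matrix
#' @param path output path
#' @export
writePhylipLower <- function(d, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(nrow(d)), con)
  for (i in seq_len(nrow(d)))
    writeLines(paste(c(rownames(d)[i],
                       formatC(d[i, seq_len(i - 1)], format = "g")),
                     collapse = "  "), con)
  invisible(path)
}
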