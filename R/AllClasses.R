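#' @import methods
#' @importFrom stats aggregate coef cor dbeta lm na.omit optim plogis qlogis
#'   quantile rbeta rbinom rgamma rmultinom runif sd setNames var
#' @importFrom utils read.csv write.csv head combn
#' @useDynLib polypopgen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

PLOIDY <- 4L

#' Tetraploid microsatellite genotypes
#'
#' `SsrGenotypes` holds a rectangular individuals-by-loci table of tetraploid
#' microsatellite genotypes. Each cell is an integer vector of allele sizes
#' (bp): length 4 means the allele dosage is fully known (copies counted with
#' multiplicity), length 1--3 means only the distinct allele set is known
#' (dosage-ambiguous), and length 0 marks a missing genotype. Every
#' individual belongs to exactly one population; population coordinates
#' (decimal degrees) are an optional sidecar.
#'
#' @slot genotypes a matrix of mode `list` (individuals x loci); each element
#'   an integer vector of 0--4 allele sizes in bp.
#' @slot loci a `data.frame` with columns `name`, `motifLength` (bp per
#'   repeat unit), `sizeMin`, `sizeMax`.
#' @slot population factor of length `nrow(genotypes)` assigning each
#'   individual to a population.
#' @slot coords `NULL`, or a `data.frame` with columns `population`, `lat`,
#'   `lon` (decimal degrees).
#' @slot metadata free-form list (filter reports, provenance).
#'
#' @seealso [readGenotypes()], [toDominant()], [simulateHierarchical()]
#' @export
setClass("SsrGenotypes",
  representation(
    genotypes = "matrix",
    loci = "data.frame",
    population = "factor",
    coords = "ANY",
    metadata = "list"
  )
)

validSsrGenotypes <- function(object) {
  msg <- character(0)
  g <- object@genotypes
  if (!is.matrix(g) || mode(g) != "list")
    return("genotypes must be a matrix of mode 'list'")
  if (is.null(rownames(g)) || is.null(colnames(g)))
    msg <- c(msg, "genotypes must have individual row names and locus column names")
  if (anyDuplicated(rownames(g)))
    msg <- c(msg, "duplicate individual labels")
  need <- c("name", "motifLength", "sizeMin", "sizeMax")
  if (!all(need %in% names(object@loci)))
    return(paste("loci table must have columns:", paste(need, collapse = ", ")))
  if (!identical(as.character(object@loci$name), colnames(g)))
    msg <- c(msg, "loci table names must match genotype column names in order")
  if (any(!is.na(object@loci$motifLength) & object@loci$motifLength < 1))
    msg <- c(msg, "motifLength must be >= 1")
  if (any(object@loci$sizeMin > object@loci$sizeMax, na.rm = TRUE))
    msg <- c(msg, "locus sizeMin must be <= sizeMax")
  if (length(object@population) != nrow(g))
    msg <- c(msg, "population must have one entry per individual")
  if (any(is.na(object@population)))
    msg <- c(msg, "every individual must be assigned to a population")
  lens <- vapply(g, length, 0L)
  if (any(lens > PLOIDY))
    msg <- c(msg, "a genotype cannot carry more than 4 allele copies")
  bad <- character(0)
  for (j in seq_len(ncol(g))) {
    lo <- object@loci$sizeMin[j]; hi <- object@loci$sizeMax[j]
    if (is.na(lo) || is.na(hi)) next
    for (i in seq_len(nrow(g))) {
      a <- g[[i, j]]
      if (length(a) && (any(a < lo) || any(a > hi)))
        bad <- c(bad, sprintf("%s@%s", rownames(g)[i], colnames(g)[j]))
    }
  }
  if (length(bad))
    msg <- c(msg, paste("allele size outside locus size range for:",
                        paste(head(bad, 5L), collapse = ", "),
                        if (length(bad) > 5L) sprintf("(+%d more)", length(bad) - 5L) else ""))
  if (!is.null(object@coords)) {
    if (!all(c("population", "lat", "lon") %in% names(object@coords)))
      msg <- c(msg, "coords must have columns population, lat, lon")
  }
  if (length(msg)) msg else TRUE
}
setValidity("SsrGenotypes", validSsrGenotypes)

#' Construct an SsrGenotypes object
#'
#' @param genotypes list-matrix of allele-size vectors (see class docs), with
#'   individual row names and locus column names.
#' @param loci data.frame with `name`, `motifLength`, `sizeMin`, `sizeMax`;
#'   if `sizeMin`/`sizeMax` are missing they are inferred from the data.
#' @param population factor or character of per-individual population labels.
#' @param coords optional data.frame (`population`, `lat`, `lon`).
#' @param metadata optional list.
#' @return a validated [SsrGenotypes-class] object.
#' @export
SsrGenotypes <- function(genotypes, loci, population, coords = NULL,
                         metadata = list()) {
  if (is.null(loci$sizeMin) || is.null(loci$sizeMax)) {
    rng <- lapply(seq_len(ncol(genotypes)), function(j) {
      a <- unlist(genotypes[, j])
      if (!length(a)) c(NA_real_, NA_real_) else range(a)
    })
    if (is.null(loci$sizeMin)) loci$sizeMin <- vapply(rng, `[`, 0, 1L)
    if (is.null(loci$sizeMax)) loci$sizeMax <- vapply(rng, `[`, 0, 2L)
  }
  if (is.null(loci$motifLength)) loci$motifLength <- NA_integer_
  new("SsrGenotypes",
      genotypes = genotypes,
      loci = as.data.frame(loci, stringsAsFactors = FALSE),
      population = droplevels(as.factor(population)),
      coords = coords, metadata = metadata)
}

#' Dominant (band presence/absence) matrix
#'
#' Binary recoding of co-dominant SSR genotypes: one band per
#' (locus, allele size) pair observed anywhere in the data set; a cell is 1
#' if the individual's distinct allele set contains that size, 0 otherwise,
#' and `NA` where the genotype at the band's locus is missing.
#'
#' @slot values integer matrix (individuals x bands) with entries 0/1/NA.
#' @slot bandInfo data.frame with columns `locus` and `size` describing each
#'   band (column order: loci in input order, sizes ascending within locus).
#' @slot population factor of per-individual population labels.
#' @export
setClass("DominantMatrix",
  representation(values = "matrix", bandInfo = "data.frame",
                 population = "factor")
)

setValidity("DominantMatrix", function(object) {
  v <- object@values
  msg <- character(0)
  if (!all(v %in% c(0L, 1L, NA)))
    msg <- c(msg, "values must be 0, 1 or NA")
  if (nrow(object@bandInfo) != ncol(v))
    msg <- c(msg, "bandInfo must describe every band column")
  if (length(object@population) != nrow(v))
    msg <- c(msg, "population must have one entry per individual")
  if (ncol(v) && any(colSums(v == 1L, na.rm = TRUE) == 0L))
    msg <- c(msg, "every band must be present in at least one individual")
  if (length(msg)) msg else TRUE
})

#' @describeIn DominantMatrix-class constructor.
#' @param values,bandInfo,population see slots.
#' @export
DominantMatrix <- function(values, bandInfo, population) {
  storage.mode(values) <- "integer"
  new("DominantMatrix", values = values,
      bandInfo = as.data.frame(bandInfo, stringsAsFactors = FALSE),
      population = droplevels(as.factor(population)))
}

## labelled symmetric distance matrix with a "kind" tag ------------------

#' Tag a symmetric labelled matrix as a distance matrix
#'
#' Distance matrices in polypopgen are plain symmetric base matrices with
#' dimnames and a `kind` attribute (`"bruvo"`, `"nei"`, `"geographic"`,
#' `"cluster-indicator"`).
#'
#' @param m symmetric numeric matrix with matching dimnames.
#' @param kind character tag.
#' @return the matrix with its `kind` attribute set.
#' @export
distMatrix <- function(m, kind) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (is.null(rownames(m))) stop("distance matrix must be labelled")
  if (max(abs(m - t(m)), na.rm = TRUE) > 1e-8) stop("matrix is not symmetric")
  attr(m, "kind") <- kind
  m
}

#' @rdname distMatrix
#' @export
distKind <- function(m) attr(m, "kind")
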