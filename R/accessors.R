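## generics + accessors for the data containers

#' @rdname SsrGenotypes-class
#' @param object,x an `SsrGenotypes` or `DominantMatrix` object
#' @export
setGeneric("individuals", function(x) standardGeneric("individuals"))
#' @rdname SsrGenotypes-class
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))
#' @rdname SsrGenotypes-class
#' @export
setGeneric("lociInfo", function(x) standardGeneric("lociInfo"))
#' @rdname SsrGenotypes-class
#' @export
setGeneric("coordinates", function(x) standardGeneric("coordinates"))
#' @rdname SsrGenotypes-class
#' @export
setGeneric("nInd", function(x) standardGeneric("nInd"))
#' @rdname SsrGenotypes-class
#' @export
setGeneric("nLoc", function(x) standardGeneric("nLoc"))
#' @rdname DominantMatrix-class
#' @export
setGeneric("bandInfo", function(x) standardGeneric("bandInfo"))
#' @rdname DominantMatrix-class
#' @export
setGeneric("bandValues", function(x) standardGeneric("bandValues"))

#' @rdname SsrGenotypes-class
#' @export
setMethod("individuals", "SsrGenotypes", function(x) rownames(x@genotypes))
#' @rdname SsrGenotypes-class
#' @export
setMethod("populations", "SsrGenotypes", function(x) x@population)
#' @rdname SsrGenotypes-class
#' @export
setMethod("lociInfo", "SsrGenotypes", function(x) x@loci)
#' @rdname SsrGenotypes-class
#' @export
setMethod("coordinates", "SsrGenotypes", function(x) x@coords)
#' @rdname SsrGenotypes-class
#' @export
setMethod("nInd", "SsrGenotypes", function(x) nrow(x@genotypes))
#' @rdname SsrGenotypes-class
#' @export
setMethod("nLoc", "SsrGenotypes", function(x) ncol(x@genotypes))

#' @rdname DominantMatrix-class
#' @export
setMethod("individuals", "DominantMatrix", function(x) rownames(x@values))
#' @rdname DominantMatrix-class
#' @export
setMethod("populations", "DominantMatrix", function(x) x@population)
#' @rdname DominantMatrix-class
#' @export
setMethod("bandInfo", "DominantMatrix", function(x) x@bandInfo)
#' @rdname DominantMatrix-class
#' @export
setMethod("bandValues", "DominantMatrix", function(x) x@values)
#' @rdname DominantMatrix-class
#' @export
setMethod("nInd", "DominantMatrix", function(x) nrow(x@values))

#' Genotype accessor
#'
#' Returns the allele-size vector for one individual at one locus
#' (integer(0) if missing).
#'
#' @param x an [SsrGenotypes-class] object
#' @param individual,locus row/column label or index
#' @export
genotypeAt <- function(x, individual, locus) x@genotypes[[individual, locus]]

#' Is a genotype dosage-known?
#'
#' A tetraploid genotype is dosage-known when all four allele copies are
#' recorded with multiplicity (cell length 4); cells with 1--3 distinct
#' alleles are dosage-ambiguous.
#' @param g integer vector of allele sizes
#' @export
dosageKnown <- function(g) length(g) == 4L

setMethod("show", "SsrGenotypes", function(object) {
  cat("SsrGenotypes:", nInd(object), "individuals x", nLoc(object),
      "loci (ploidy 4)\n")
  tab <- table(object@population)
  cat("populations (", length(tab), "): ",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n", sep = "")
  lens <- vapply(object@genotypes, length, 0L)
  cat(sprintf("cells: %.1f%% dosage-known, %.1f%% ambiguous, %.1f%% missing\n",
              100 * mean(lens == 4L), 100 * mean(lens %in% 1:3),
              100 * mean(lens == 0L)))
  if (!is.null(object@coords)) cat("coordinates: present\n")
})

setMethod("show", "DominantMatrix", function(object) {
  cat("DominantMatrix:", nrow(object@values), "individuals x",
      ncol(object@values), "bands\n")
  cat("loci:", length(unique(object@bandInfo$locus)),
      " missing cells:", sum(is.na(object@values)), "\n")
})
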