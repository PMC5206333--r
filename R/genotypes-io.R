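## readers/writers and derived encodings for tetraploid SSR genotypes

parseAlleleCell <- function(x) {
  # "150/153/153/156" or "150" or "" -> integer vector; NULL on parse failure
  x <- trimws(x)
  if (is.na(x) || x == "" || toupper(x) %in% c("NA", "-9")) return(integer(0))
  parts <- strsplit(x, "[/;|]")[[1]]
  parts <- parts[nzchar(trimws(parts))]
  vals <- suppressWarnings(as.numeric(parts))
  if (any(is.na(vals))) return(NULL)
  sort(as.integer(round(vals)))
}

#' Read tetraploid SSR genotypes from a tabular file
#'
#' Two dialects are supported. `"wide"`: one row per individual with columns
#' `individual`, `population`, then one column per locus holding the allele
#' sizes separated by `/` (1--4 values; 4 values mean the dosage is known,
#' fewer give the distinct set only). `"long"`: columns `individual`,
#' `population`, `locus`, `allele`, one row per allele copy (repeat a size to
#' declare multiplicity). Unparseable allele entries become missing genotypes
#' with a warning giving the count; duplicate individual labels (wide) are a
#' hard error; allele sizes outside a declared locus size range fail
#' validation with the offenders listed.
#'
#' @param path CSV file path.
#' @param format `"wide"` or `"long"`.
#' @param loci optional data.frame (`name`, `motifLength`, `sizeMin`,
#'   `sizeMax`). When absent, size ranges are inferred from the data and the
#'   motif length is left `NA` (Bruvo distances then require it to be set).
#' @param coordsPath optional CSV sidecar with columns
#'   `population`, `lat`, `lon`.
#' @return an [SsrGenotypes-class] object.
#' @export
readGenotypes <- function(path, format = c("wide", "long"), loci = NULL,
                          coordsPath = NULL) {
  format <- match.arg(format)
  raw <- read.csv(path, check.names = FALSE, colClasses = "character")
  nbad <- 0L
  if (format == "wide") {
    if (anyDuplicated(raw$individual))
      stop("duplicate individual label(s): ",
           paste(unique(raw$individual[duplicated(raw$individual)]), collapse = ", "))
    locNames <- setdiff(names(raw), c("individual", "population"))
    g <- matrix(list(), nrow(raw), length(locNames),
                dimnames = list(raw$individual, locNames))
    for (j in seq_along(locNames)) {
      for (i in seq_len(nrow(raw))) {
        cell <- parseAlleleCell(raw[[locNames[j]]][i])
        if (is.null(cell)) { nbad <- nbad + 1L; cell <- integer(0) }
        g[[i, j]] <- cell
      }
    }
    pop <- raw$population
  } else {
    raw$allele_num <- suppressWarnings(as.numeric(raw$allele))
    nbad <- sum(is.na(raw$allele_num) & !is.na(raw$allele) &
                  raw$allele != "" & toupper(raw$allele) != "NA")
    raw <- raw[!is.na(raw$allele_num), , drop = FALSE]
    inds <- unique(raw$individual)
    locNames <- unique(raw$locus)
    g <- matrix(list(), length(inds), length(locNames),
                dimnames = list(inds, locNames))
    for (i in seq_along(inds)) for (j in seq_along(locNames)) g[[i, j]] <- integer(0)
    for (r in seq_len(nrow(raw))) {
      i <- raw$individual[r]; j <- raw$locus[r]
      g[[i, j]] <- sort(c(g[[i, j]], as.integer(round(raw$allele_num[r]))))
    }
    pop <- raw$population[match(inds, raw$individual)]
  }
  if (nbad > 0L)
    warning(nbad, " unparseable allele entrie(s) treated as missing")
  if (is.null(loci))
    loci <- data.frame(name = colnames(g), stringsAsFactors = FALSE)
  else
    loci <- loci[match(colnames(g), loci$name), , drop = FALSE]
  coords <- if (!is.null(coordsPath)) read.csv(coordsPath) else NULL
  SsrGenotypes(g, loci, pop, coords = coords)
}

#' Write genotypes to a wide CSV
#'
#' Inverse of [readGenotypes()] with `format = "wide"`.
#' @param x an [SsrGenotypes-class] object
#' @param path output CSV path
#' @export
writeGenotypes <- function(x, path) {
  g <- x@genotypes
  out <- data.frame(individual = rownames(g),
                    population = as.character(x@population),
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (j in seq_len(ncol(g)))
    out[[colnames(g)[j]]] <- vapply(g[, j], function(a) paste(a, collapse = "/"), "")
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Recode co-dominant genotypes to a dominant band matrix
#'
#' One band per (locus, allele size) pair observed anywhere; band order is
#' locus order then ascending allele size. Presence (1) means the allele is
#' in the individual's distinct set; a missing genotype masks all of that
#' locus' bands as `NA` for that individual.
#'
#' @param x an [SsrGenotypes-class] object
#' @return a [DominantMatrix-class] object
#' @export
toDominant <- function(x) {
  g <- x@genotypes
  bands <- do.call(rbind, lapply(seq_len(ncol(g)), function(j) {
    sizes <- sort(unique(unlist(g[, j])))
    if (!length(sizes)) return(NULL)
    data.frame(locus = colnames(g)[j], size = sizes, stringsAsFactors = FALSE)
  }))
  v <- matrix(NA_integer_, nrow(g), nrow(bands),
              dimnames = list(rownames(g),
                              paste(bands$locus, bands$size, sep = ".")))
  for (b in seq_len(nrow(bands))) {
    j <- match(bands$locus[b], colnames(g))
    v[, b] <- vapply(g[, j], function(a) {
      if (!length(a)) NA_integer_ else as.integer(bands$size[b] %in% a)
    }, 0L)
  }
  DominantMatrix(v, bands, x@population)
}

#' Drop populations below a minimum sample size
#'
#' Removes every population with fewer than `minN` individuals; the removal
#' report is stored in `metadata$removedPopulations` of the returned object.
#' Genotypes of retained individuals are untouched.
#'
#' @param x an [SsrGenotypes-class] object
#' @param minN minimum number of individuals per retained population
#'   (default 6).
#' @export
filterSmallPopulations <- function(x, minN = 6L) {
  stopifnot(minN >= 1L)
  tab <- table(x@population)
  drop <- names(tab)[tab < minN]
  if (length(drop) == length(tab))
    stop("all populations have fewer than ", minN, " individuals")
  keep <- !(as.character(x@population) %in% drop)
  out <- SsrGenotypes(x@genotypes[keep, , drop = FALSE], x@loci,
                      droplevels(x@population[keep]),
                      coords = if (is.null(x@coords)) NULL else
                        x@coords[!(x@coords$population %in% drop), , drop = FALSE],
                      metadata = x@metadata)
  out@metadata$removedPopulations <-
    data.frame(population = drop, n = as.integer(tab[drop]))
  out
}

#' Export a dominant matrix in STRUCTURE raw-data format
#'
#' One row per individual: label, integer population index, then one
#' 0/1 column per band; missing cells are written as -9. A header line gives
#' the band names. [readStructureFile()] round-trips the format.
#'
#' @param dm a [DominantMatrix-class] object
#' @param path output path
#' @export
writeStructureFile <- function(dm, path) {
  v <- dm@values
  v[is.na(v)] <- -9L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(dm@values), collapse = " "), con)
  popIdx <- as.integer(dm@population)
  for (i in seq_len(nrow(v)))
    writeLines(paste(c(rownames(v)[i], popIdx[i], v[i, ]), collapse = " "), con)
  invisible(path)
}

#' @rdname writeStructureFile
#' @param populationLevels optional character vector mapping the integer
#'   population column back to labels (defaults to `"pop<k>"`).
#' @export
readStructureFile <- function(path, populationLevels = NULL) {
  lines <- readLines(path)
  bands <- strsplit(lines[1L], " ")[[1]]
  rows <- strsplit(lines[-1L], " ")
  v <- t(vapply(rows, function(r) as.integer(r[-(1:2)]), integer(length(bands))))
  v[v == -9L] <- NA_integer_
  rownames(v) <- vapply(rows, `[`, "", 1L)
  colnames(v) <- bands
  popIdx <- vapply(rows, function(r) as.integer(r[2L]), 0L)
  pop <- if (is.null(populationLevels)) paste0("pop", popIdx) else
    populationLevels[popIdx]
  info <- data.frame(
    locus = sub("\\.[0-9]+$", "", bands),
    size = as.integer(sub("^.*\\.", "", bands)), stringsAsFactors = FALSE)
  DominantMatrix(v, info, pop)
}

#' Convert allele sizes to repeat counts
#'
#' Repeat counts are anchored at the locus' minimum observed size:
#' `(size - minSize)/motifLength`, rounded to the nearest integer. A warning
#' reports alleles whose residual exceeds 0.2 repeat units (off-lattice
#' sizes). Only differences in repeat counts matter for Bruvo distances.
#'
#' @param sizes integer allele sizes at one locus
#' @param motifLength bp per repeat unit
#' @param anchor size corresponding to repeat count 0 (locus minimum)
#' @export
sizesToRepeats <- function(sizes, motifLength, anchor) {
  if (is.na(motifLength)) stop("motifLength is NA; set it in the loci table")
  x <- (sizes - anchor) / motifLength
  r <- round(x)
  if (any(abs(x - r) > 0.2))
    warning(sum(abs(x - r) > 0.2),
            " allele size(s) off the repeat lattice by > 0.2 units")
  as.integer(r)
}
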