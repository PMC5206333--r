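## end-to-end orchestration

#' Run the full analysis pipeline
#'
#' Executes import (if `x` is a file path), small-population filtering,
#' diversity statistics, Bruvo distances, PCoA, the admixture K-scan with
#' Evanno delta-K and replicate alignment, AMOVA / pairwise FST, Monmonier
#' barriers, the Mantel HIM/SSM protocol and the two beta-regression model
#' ladders. Stages needing coordinates (barriers, IBD) are skipped with a
#' notice when no coordinates are present. Every stochastic stage derives
#' its seed from `seed`. Tables are written as CSV into `outDir` (when not
#' `NULL`) together with a JSON run summary.
#'
#' @param x an [SsrGenotypes-class] object, or a wide-format genotype CSV
#'   path
#' @param outDir output directory (`NULL` = no files written)
#' @param minN minimum population size retained (default 6)
#' @param mcmc settings from [mcmcSettings()]
#' @param nPerm permutations for AMOVA / inbreeding / Mantel tests
#' @param maxBarriers maximum Monmonier barriers (default 9)
#' @param seed master seed
#' @param clusters optional named population -> cluster vector; when absent
#'   clusters come from the admixture consensus at the Evanno best K
#' @return a list of stage results (class `PipelineResult`)
#' @export
runPipeline <- function(x, outDir = NULL, minN = 6L,
                        mcmc = mcmcSettings(), nPerm = 999L,
                        maxBarriers = 9L, seed = 1L, clusters = NULL) {
  if (is.character(x)) x <- readGenotypes(x)
  res <- list(seed = seed, settings = list(minN = minN, nPerm = nPerm,
                                           maxBarriers = maxBarriers,
                                           mcmc = mcmc))
  out <- function(name, obj) {
    res[[name]] <<- obj
    obj
  }
  writeCsv <- function(df, name) {
    if (!is.null(outDir)) {
      dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
      write.csv(df, file.path(outDir, name), row.names = FALSE)
    }
  }

  writePng <- function(name, expr) {
    if (!is.null(outDir)) {
      dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
      grDevices::png(file.path(outDir, name), width = 900, height = 600)
      on.exit(grDevices::dev.off(), add = TRUE, after = FALSE)
      force(expr)
    }
    invisible(NULL)
  }

  filtered <- out("genotypes", filterSmallPopulations(x, minN))
  set.seed(seed)
  div <- out("diversity", diversitySummary(filtered, nPerm = nPerm))
  writeCsv(div$table, "diversity.csv")

  dom <- out("dominant", toDominant(filtered))
  bruvo <- out("bruvo", bruvoMatrix(filtered))
  ord <- out("pcoa", pcoa(bruvo))
  writeCsv(data.frame(individual = rownames(ord$coordinates),
                      population = as.character(populations(filtered)),
                      ord$coordinates[, seq_len(min(4, ncol(ord$coordinates)))]),
           "pcoa.csv")
  writePng("pcoa.png", plotPcoa(ord, populations(filtered)))

  mcmc$seed <- seed
  scan <- out("admixture", admixtureScan(dom, mcmc))
  ev <- out("evanno", evanno(scan$lnPTable))
  bestK <- attr(ev, "bestK")
  writeCsv(ev, "evanno.csv")
  cons <- out("consensusQ", alignRuns(scan$runs[[as.character(bestK)]]))
  writeCsv(data.frame(individual = rownames(cons$q), cons$q), "qmatrix.csv")
  writePng("admixture.png", plotAdmixture(cons$q, populations(filtered)))

  if (is.null(clusters)) {
    # population-level majority cluster from the consensus Q
    popMeans <- rowsum(cons$q, group = as.character(populations(filtered)))
    clusters <- setNames(colnames(popMeans)[max.col(popMeans)],
                         rownames(popMeans))
  }
  res$clusters <- clusters

  set.seed(seed + 1L)
  am <- out("amova", amova(dom, clusters, nPerm = nPerm))
  writeCsv(am$table, "amova.csv")
  set.seed(seed + 2L)
  pw <- out("pairwiseFst", pairwiseFst(dom))
  res$globalFst <- pw$globalFst

  nei <- out("nei", neiDistance(dom))
  co <- coordinates(filtered)
  if (is.null(co)) {
    message("no coordinates: barrier and IBD stages skipped")
  } else {
    co <- co[match(levels(populations(filtered)), co$population), ]
    geo <- out("geographic", geographicMatrix(co))
    geo <- geo[rownames(nei), rownames(nei)]
    net <- out("network", delaunayNetwork(co))
    bs <- out("barriers", monmonierBarriers(net, nei, maxBarriers))
    writePng("barriers.png", plotBarriers(bs))
    set.seed(seed + 3L)
    him <- out("himSsm", himSsmProtocol(nei, geo, clusters,
                                        nPerm = max(nPerm, 999L)))
    writeCsv(him, "mantel.csv")
    lad1 <- out("ladderClusters",
                buildModelLadder(nei, geo, "structure-clusters", clusters))
    lad2 <- out("ladderBarriers",
                buildModelLadder(nei, geo, "barrier-order", bs))
    writeCsv(data.frame(ladder = "structure-clusters", step = lad1$labels,
                        aic = lad1$aic, pseudoR2 = lad1$pseudoR2),
             "ladder_clusters.csv")
    writePng("ibd.png", plotIbd(nei, geo, lad1))
  }
  if (!is.null(outDir)) {
    summary <- list(
      nIndividuals = nInd(filtered),
      nPopulations = nlevels(populations(filtered)),
      totalAlleles = div$totals$totalAlleles,
      HT = div$totals$HT, FIS = div$totals$FIS,
      globalFst = res$globalFst, bestK = bestK,
      pcoaInertia = head(ord$inertiaPct, 2),
      seed = seed)
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  class(res) <- "PipelineResult"
  res
}

#' @export
print.PipelineResult <- function(x, ...) {
  cat("polypopgen pipeline result\n")
  cat("  individuals:", nInd(x$genotypes),
      " populations:", nlevels(populations(x$genotypes)), "\n")
  cat("  HT =", round(x$diversity$totals$HT, 3),
      " FIS =", round(x$diversity$totals$FIS, 3),
      " global FST =", round(x$globalFst, 3), "\n")
  if (!is.null(x$evanno)) cat("  best K =", attr(x$evanno, "bestK"), "\n")
  invisible(x)
}
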