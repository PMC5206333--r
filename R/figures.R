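## report figures (base graphics)

#' PCoA scatter of the first two axes
#'
#' One symbol/colour per population group, as in classic SSR ordination
#' figures.
#'
#' @param ord a `PcoaResult`
#' @param groups factor of per-entity group labels (e.g. populations)
#' @param main plot title
#' @export
plotPcoa <- function(ord, groups, main = "Principal Coordinate Analysis") {
  groups <- as.factor(groups)
  xy <- ord$coordinates[, 1:2, drop = FALSE]
  cols <- grDevices::hcl.colors(nlevels(groups), "Dark 3")
  graphics::plot(xy, col = cols[groups], pch = (seq_len(nlevels(groups)) %% 18)[groups],
                 xlab = sprintf("Axis 1 (%.2f%%)", ord$inertiaPct[1]),
                 ylab = sprintf("Axis 2 (%.2f%%)", ord$inertiaPct[2]),
                 main = main)
  graphics::legend("topright", legend = levels(groups), col = cols,
                   pch = seq_len(nlevels(groups)) %% 18, cex = 0.7, bty = "n")
  invisible(NULL)
}

#' Stacked-bar plot of admixture proportions
#'
#' Each vertical bar is one individual; individuals are ordered by
#' population, with population separators.
#'
#' @param q individuals x K matrix of admixture proportions (rows sum to 1)
#' @param populations factor of per-individual population labels
#' @param main plot title
#' @export
plotAdmixture <- function(q, populations, main = "Admixture proportions") {
  populations <- as.factor(populations)
  ord <- order(populations)
  qo <- t(q[ord, , drop = FALSE])
  cols <- grDevices::hcl.colors(nrow(qo), "Dark 3")
  graphics::barplot(qo, col = cols, border = NA, space = 0, axes = FALSE,
                    names.arg = rep("", ncol(qo)), main = main)
  breaks <- cumsum(table(populations[ord]))
  graphics::abline(v = breaks[-length(breaks)], col = "white", lwd = 2)
  mids <- breaks - diff(c(0, breaks)) / 2
  graphics::mtext(names(breaks), side = 1, at = mids, cex = 0.7, line = 0.3)
  invisible(NULL)
}

#' Genetic-versus-geographic distance scatter with model predictions
#'
#' Off-diagonal pairs of the two matrices, the distance-only fit (dashed)
#' and, when given, the best barrier-augmented model's predictions.
#'
#' @param nei,geo symmetric population distance matrices (same labels)
#' @param ladder optional `ModelLadder`; its first and best fits are drawn
#' @param main plot title
#' @export
plotIbd <- function(nei, geo, ladder = NULL,
                    main = "Isolation by distance") {
  x <- geo[lower.tri(geo)] / 1000
  y <- nei[lower.tri(nei)]
  graphics::plot(x, y, pch = 19, col = "grey30",
                 xlab = "geographic distance (km)",
                 ylab = "genetic distance (Nei)", main = main)
  if (!is.null(ladder)) {
    tr <- ladder$transform
    toY <- function(z) (z * tr$n - 0.5) / (tr$n - 1) * (tr$max - tr$min) + tr$min
    predOf <- function(fit, X) {
      est <- fit$coefficients$estimate
      plogis(drop(cbind(1, as.matrix(X)) %*% est))
    }
    o <- order(x)
    f1 <- ladder$fits[[1]]
    graphics::lines(x[o], toY(predOf(f1, data.frame(geoKm = x)))[o],
                    lty = 2, lwd = 2)
    if (ladder$best > 1 && !is.null(ladder$bestX)) {
      fb <- ladder$fits[[ladder$best]]
      graphics::points(x, toY(predOf(fb, ladder$bestX)), col = "red3")
      graphics::legend("bottomright",
                       legend = c("distance only", "best barrier model"),
                       lty = c(2, NA), pch = c(NA, 1),
                       col = c("black", "red3"), bty = "n")
    }
  }
  invisible(NULL)
}

#' Map of populations, Delaunay network and Monmonier barriers
#'
#' Populations on the projected plane, Delaunay edges in grey, and each
#' barrier's crossed edges over-plotted with its rank label.
#'
#' @param bs a `BarrierSet`
#' @param main plot title
#' @export
plotBarriers <- function(bs, main = "Monmonier barriers") {
  net <- bs$network
  pts <- net$points
  graphics::plot(pts$x / 1000, pts$y / 1000, pch = 19,
                 xlab = "x (km)", ylab = "y (km)", main = main)
  graphics::text(pts$x / 1000, pts$y / 1000, pts$population, pos = 3,
                 cex = 0.7)
  for (e in seq_len(nrow(net$edges))) {
    i <- net$edges$i[e]; j <- net$edges$j[e]
    graphics::segments(pts$x[i] / 1000, pts$y[i] / 1000,
                       pts$x[j] / 1000, pts$y[j] / 1000, col = "grey80")
  }
  cols <- grDevices::hcl.colors(max(length(bs$barriers), 2L), "Zissou 1")
  for (b in seq_along(bs$barriers)) {
    bb <- bs$barriers[[b]]
    for (r in seq_len(nrow(bb))) {
      i <- match(bb$pop1[r], pts$population)
      j <- match(bb$pop2[r], pts$population)
      # draw the crossing as the perpendicular midpoint tick of the edge
      mx <- (pts$x[i] + pts$x[j]) / 2000; my <- (pts$y[i] + pts$y[j]) / 2000
      dx <- (pts$y[j] - pts$y[i]); dy <- -(pts$x[j] - pts$x[i])
      nrm <- sqrt(dx^2 + dy^2)
      sc <- 10 / max(nrm / 1000, 1e-9)
      graphics::segments(mx - dx / 1000 * sc, my - dy / 1000 * sc,
                         mx + dx / 1000 * sc, my + dy / 1000 * sc,
                         col = cols[b], lwd = 3)
    }
    first <- bs$barriers[[b]][1, ]
    i <- match(first$pop1, pts$population); j <- match(first$pop2, pts$population)
    graphics::text((pts$x[i] + pts$x[j]) / 2000, (pts$y[i] + pts$y[j]) / 2000,
                   bs$labels[b], font = 2, col = cols[b], pos = 2)
  }
  invisible(NULL)
}
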