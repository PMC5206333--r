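## Delaunay network of populations and Monmonier barrier detection

# equirectangular local projection (metres) centred on the point centroid;
# adequate for triangulation topology at archipelago scale
projectEquirectangular <- function(coords, R = 6371000) {
  lat0 <- mean(coords$lat) * pi / 180
  x <- R * cos(lat0) * (coords$lon - mean(coords$lon)) * pi / 180
  y <- R * (coords$lat - mean(coords$lat)) * pi / 180
  data.frame(population = coords$population, x = x, y = y,
             stringsAsFactors = FALSE)
}

circumcircle <- function(ax, ay, bx, by, cx, cy) {
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-12) return(NULL)
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  list(x = ux, y = uy, r2 = (ax - ux)^2 + (ay - uy)^2)
}

# Bowyer-Watson incremental Delaunay triangulation
delaunayTriangles <- function(x, y) {
  n <- length(x)
  span <- max(max(x) - min(x), max(y) - min(y), 1)
  cx <- mean(range(x)); cy <- mean(range(y))
  sx <- c(cx - 20 * span, cx + 20 * span, cx)
  sy <- c(cy - 10 * span, cy - 10 * span, cy + 20 * span)
  px <- c(x, sx); py <- c(y, sy)
  tris <- list(c(n + 1L, n + 2L, n + 3L))
  for (i in seq_len(n)) {
    bad <- logical(length(tris))
    for (t in seq_along(tris)) {
      v <- tris[[t]]
      cc <- circumcircle(px[v[1]], py[v[1]], px[v[2]], py[v[2]],
                         px[v[3]], py[v[3]])
      if (is.null(cc)) { bad[t] <- TRUE; next }
      bad[t] <- ((px[i] - cc$x)^2 + (py[i] - cc$y)^2) < cc$r2 * (1 + 1e-12)
    }
    # polygon boundary = edges of bad triangles not shared by two bad ones
    edges <- NULL
    for (t in which(bad)) {
      v <- tris[[t]]
      edges <- rbind(edges, t(apply(cbind(v, v[c(2, 3, 1)]), 1L, sort)))
    }
    tris <- tris[!bad]
    if (!is.null(edges)) {
      key <- paste(edges[, 1], edges[, 2])
      keep <- edges[key %in% names(which(table(key) == 1L)), , drop = FALSE]
      for (r in seq_len(nrow(keep)))
        tris[[length(tris) + 1L]] <- c(keep[r, 1], keep[r, 2], i)
    }
  }
  tris <- Filter(function(v) all(v <= n), tris)
  if (!length(tris)) return(NULL)
  do.call(rbind, lapply(tris, sort))
}

#' Delaunay network with Voronoi adjacency
#'
#' Triangulates the populations on an equirectangular local projection
#' (Bowyer-Watson). Each Delaunay edge is paired with its dual Voronoi edge
#' via the one or two adjacent triangles (circumcenters); edges with a
#' single adjacent triangle form the outer boundary. Collinear
#' configurations get a deterministic micro-jitter (documented fallback).
#'
#' @param coords data.frame with `population`, `lat`, `lon`
#' @return object of class `DelaunayNetwork`: list with `points`
#'   (projected), `edges` (data.frame `i`, `j`, `pop1`, `pop2`, `boundary`),
#'   `triangles`, `circumcenters`, `edgeTriangles`
#' @export
delaunayNetwork <- function(coords) {
  if (nrow(coords) < 3) stop("need >= 3 populations")
  pts <- projectEquirectangular(coords)
  tri <- delaunayTriangles(pts$x, pts$y)
  if (is.null(tri)) {
    # collinear: deterministic jitter proportional to the configuration
    # span, escalated until the in-circle tests become numerically stable
    span <- max(max(pts$x) - min(pts$x), max(pts$y) - min(pts$y), 1)
    base <- sin(12.9898 * seq_len(nrow(pts)))
    for (amp in c(1e-3, 1e-2, 5e-2)) {
      cand <- pts
      cand$x <- pts$x + amp * span * base
      cand$y <- pts$y + amp * span * rev(base)
      tri <- delaunayTriangles(cand$x, cand$y)
      if (!is.null(tri)) { pts <- cand; break }
    }
    if (is.null(tri)) stop("degenerate configuration: triangulation failed")
  }
  edgeKey <- function(i, j) paste(pmin(i, j), pmax(i, j))
  em <- unique(rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(1, 3)]))
  em <- em[order(em[, 1], em[, 2]), , drop = FALSE]
  keys <- edgeKey(em[, 1], em[, 2])
  edgeTriangles <- setNames(vector("list", length(keys)), keys)
  cc <- matrix(NA_real_, nrow(tri), 2)
  for (t in seq_len(nrow(tri))) {
    v <- tri[t, ]
    c0 <- circumcircle(pts$x[v[1]], pts$y[v[1]], pts$x[v[2]], pts$y[v[2]],
                       pts$x[v[3]], pts$y[v[3]])
    cc[t, ] <- c(c0$x, c0$y)
    for (pair in list(v[c(1, 2)], v[c(2, 3)], v[c(1, 3)])) {
      k <- edgeKey(pair[1], pair[2])
      edgeTriangles[[k]] <- c(edgeTriangles[[k]], t)
    }
  }
  edges <- data.frame(
    i = em[, 1], j = em[, 2],
    pop1 = pts$population[em[, 1]], pop2 = pts$population[em[, 2]],
    boundary = vapply(keys, function(k) length(edgeTriangles[[k]]) == 1L, TRUE),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(points = pts, edges = edges, triangles = tri,
                 circumcenters = cc, edgeTriangles = edgeTriangles),
            class = "DelaunayNetwork")
}

#' @export
print.DelaunayNetwork <- function(x, ...) {
  cat("DelaunayNetwork:", nrow(x$points), "points,", nrow(x$edges),
      "edges,", nrow(x$triangles), "triangles\n")
  invisible(x)
}

#' Monmonier maximum-difference barriers
#'
#' Each barrier starts at the uncrossed Delaunay edge with the largest
#' genetic distance and grows across the Voronoi diagram: from each side of
#' the starting edge it repeatedly crosses the adjacent uncrossed Delaunay
#' edge with the largest distance, until it reaches the network boundary or
#' closes a loop. Crossed edges are removed from candidacy for later
#' barriers, so barrier edge sets are disjoint. Ties are broken by
#' lexicographic population-pair order, making the procedure deterministic;
#' the output is invariant to uniform scaling of the distance matrix.
#'
#' @param net a `DelaunayNetwork` from [delaunayNetwork()]
#' @param d symmetric population distance matrix (e.g. [neiDistance()])
#' @param maxBarriers maximum number of barriers (default 9)
#' @return object of class `BarrierSet`: list with `barriers` (each a
#'   data.frame `pop1`, `pop2`, `distance` of crossed edges, in crossing
#'   order), `labels` (letters by relevance order), `network`
#' @export
monmonierBarriers <- function(net, d, maxBarriers = 9L) {
  stopifnot(maxBarriers >= 1L)
  edges <- net$edges
  ne <- nrow(edges)
  dist <- vapply(seq_len(ne), function(e) d[edges$pop1[e], edges$pop2[e]], 0)
  if (any(is.na(dist))) stop("distance undefined for some Delaunay edge")
  # lexicographic tie-break order
  lex <- order(pmin(edges$pop1, edges$pop2), pmax(edges$pop1, edges$pop2))
  lexRank <- integer(ne); lexRank[lex] <- seq_len(ne)
  adj <- lapply(seq_len(ne), function(e) {
    k <- paste(edges$i[e], edges$j[e])
    tr <- net$edgeTriangles[[k]]
    if (length(tr) == 1L) c(tr, 0L) else tr  # 0 = outer node
  })
  triEdges <- lapply(seq_len(nrow(net$triangles)), function(t) {
    which(vapply(adj, function(a) t %in% a, TRUE))
  })
  crossed <- logical(ne)
  pickMax <- function(cand) {
    if (!length(cand)) return(NA_integer_)
    best <- cand[dist[cand] >= max(dist[cand]) - 1e-15]
    best[which.min(lexRank[best])]
  }
  walk <- function(startNode, visited, barrier) {
    node <- startNode
    repeat {
      if (node == 0L || node %in% visited$nodes) break
      visited$nodes <- c(visited$nodes, node)
      cand <- setdiff(triEdges[[node]], which(crossed))
      e <- pickMax(cand)
      if (is.na(e)) break
      crossed[e] <<- TRUE
      barrier <- c(barrier, e)
      node <- setdiff(adj[[e]], node)[1]
    }
    list(visited = visited, barrier = barrier)
  }
  barriers <- list()
  for (b in seq_len(maxBarriers)) {
    e0 <- pickMax(which(!crossed))
    if (is.na(e0)) break
    crossed[e0] <- TRUE
    visited <- list(nodes = integer(0))
    res1 <- walk(adj[[e0]][1], visited, integer(0))
    res2 <- walk(adj[[e0]][2], res1$visited, integer(0))
    eidx <- c(rev(res1$barrier), e0, res2$barrier)
    barriers[[b]] <- data.frame(
      pop1 = edges$pop1[eidx], pop2 = edges$pop2[eidx],
      distance = dist[eidx], row.names = NULL)
  }
  structure(list(barriers = barriers,
                 labels = letters[seq_along(barriers)], network = net),
            class = "BarrierSet")
}

#' @export
print.BarrierSet <- function(x, ...) {
  cat("BarrierSet:", length(x$barriers), "barrier(s)\n")
  for (b in seq_along(x$barriers)) {
    bb <- x$barriers[[b]]
    cat(sprintf("  %s: %s\n", x$labels[b],
                paste(sprintf("%s-%s", bb$pop1, bb$pop2), collapse = ", ")))
  }
  invisible(x)
}

#' Population separation induced by the first k barriers
#'
#' Removes the Delaunay edges crossed by barriers `1..upTo` and returns the
#' connected-component label of every population; pairs in different
#' components are "separated by" those barriers.
#'
#' @param bs a `BarrierSet`
#' @param upTo number of leading barriers to apply
#' @return named integer vector of component labels
#' @export
barrierComponents <- function(bs, upTo) {
  net <- bs$network
  edges <- net$edges
  cut <- unique(do.call(rbind, lapply(bs$barriers[seq_len(upTo)],
                                      function(b) b[, c("pop1", "pop2")])))
  keep <- !(paste(edges$pop1, edges$pop2) %in% paste(cut$pop1, cut$pop2) |
              paste(edges$pop2, edges$pop1) %in% paste(cut$pop1, cut$pop2))
  pops <- net$points$population
  comp <- setNames(seq_along(pops), pops)
  repeat {
    changed <- FALSE
    for (e in which(keep)) {
      a <- edges$pop1[e]; b <- edges$pop2[e]
      if (comp[a] != comp[b]) {
        newc <- min(comp[a], comp[b])
        comp[comp == comp[a] | comp == comp[b]] <- newc
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))[] -> idx
  setNames(idx, pops)
}
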