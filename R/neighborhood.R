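# Spatial neighborhood analysis. Each cell is a node; Delaunay
# triangulation (dual to the Voronoi tessellation) connects neighboring
# nodes, the nearest neighbor is the edge-neighbor at minimal Euclidean
# distance (the Delaunay graph provably contains the nearest-neighbor
# graph), and neighborhood enrichment compares observed neighbor-type
# counts against label permutations on fixed positions.

# Sutherland-Hodgman clip of a polygon against a convex clip polygon
# (counter-clockwise). Used for Voronoi tiles (convex subjects).
clip_convex <- function(subject, clip) {
  cx <- clip[, 1]; cy <- clip[, 2]
  if (sum(cx * c(cy[-1], cy[1]) - c(cx[-1], cx[1]) * cy) < 0) {
    clip <- clip[rev(seq_len(nrow(clip))), , drop = FALSE]
  }
  out <- subject
  n <- nrow(clip)
  for (i in seq_len(n)) {
    if (nrow(out) == 0) break
    a <- clip[i, ]; b <- clip[if (i == n) 1 else i + 1, ]
    inside <- function(p) (b[1] - a[1]) * (p[2] - a[2]) -
      (b[2] - a[2]) * (p[1] - a[1]) >= 0
    isect <- function(p, q) {
      dc <- c(a[1] - b[1], a[2] - b[2]); dp <- c(p[1] - q[1], p[2] - q[2])
      n1 <- a[1] * b[2] - a[2] * b[1]; n2 <- p[1] * q[2] - p[2] * q[1]
      n3 <- 1 / (dc[1] * dp[2] - dc[2] * dp[1])
      c((n1 * dp[1] - n2 * dc[1]) * n3, (n1 * dp[2] - n2 * dc[2]) * n3)
    }
    inp <- out
    out <- matrix(numeric(0), 0, 2)
    m <- nrow(inp)
    for (j in seq_len(m)) {
      p <- inp[j, ]; q <- inp[if (j == m) 1 else j + 1, ]
      if (inside(q)) {
        if (!inside(p)) out <- rbind(out, isect(p, q))
        out <- rbind(out, q)
      } else if (inside(p)) {
        out <- rbind(out, isect(p, q))
      }
    }
  }
  out
}

#' Build the spatial neighbor graph of a cell map
#'
#' Computes the Delaunay triangulation of the cell centroids (via
#' [deldir::deldir()]), the symmetric edge set, and per node the nearest
#' neighbor among its edge-neighbors with its Euclidean distance. With
#' fewer than 3 points, or all points collinear, triangulation is flagged
#' unavailable and nearest neighbors come from a direct search. Optionally
#' returns the Voronoi tile polygon per node, clipped to the convex hull of
#' `clip` (tiles at the window boundary are truncated).
#'
#' @param called an `iss_called` data frame (or any data frame with
#'   `cell_id`, `x`, `y`). Duplicate coordinates are an error.
#' @param clip optional polygon used to clip Voronoi tiles.
#' @param compute_voronoi also return clipped Voronoi tiles.
#' @return An `iss_graph`: `cell_id`, `x`, `y`, `edges` (2-column index
#'   matrix, i < j), `nn` (data frame: cell_id, nn_cell_id, nn_index,
#'   distance), `delaunay` flag, optional `voronoi` list of polygons.
#' @export
build_graph <- function(called, clip = NULL, compute_voronoi = FALSE) {
  x <- called$x; y <- called$y
  n <- length(x)
  assert_that(n >= 1, "no cells")
  assert_that(!anyDuplicated(cbind(x, y)),
              "duplicate cell coordinates are not supported")
  ids <- as.character(called$cell_id %||% seq_len(n))

  collinear <- function() {
    if (n < 3) return(TRUE)
    dx <- x - x[1]; dy <- y - y[1]
    cr <- dx[2] * dy - dy[2] * dx
    all(abs(cr) < 1e-9 * max(1, max(abs(dx)), max(abs(dy)))^2)
  }

  if (n < 3 || collinear()) {
    nn_index <- integer(n); nn_dist <- numeric(n)
    if (n == 1) {
      nn_index <- NA_integer_; nn_dist <- NA_real_
    } else {
      kn <- FNN::get.knn(cbind(x, y), k = 1)
      nn_index <- kn$nn.index[, 1]; nn_dist <- kn$nn.dist[, 1]
    }
    g <- list(cell_id = ids, x = x, y = y,
              edges = matrix(integer(0), 0, 2),
              nn = data.frame(cell_id = ids,
                              nn_cell_id = ids[nn_index],
                              nn_index = nn_index, distance = nn_dist,
                              stringsAsFactors = FALSE),
              delaunay = FALSE, voronoi = NULL)
    warning("fewer than 3 non-collinear points: triangulation unavailable, ",
            "nearest neighbors from direct search")
    return(structure(g, class = "iss_graph"))
  }

  rw <- c(min(x), max(x), min(y), max(y))
  if (!is.null(clip)) {
    rw <- c(min(rw[1], min(clip[, 1])), max(rw[2], max(clip[, 1])),
            min(rw[3], min(clip[, 2])), max(rw[4], max(clip[, 2])))
  }
  dd <- deldir::deldir(x, y, rw = rw, suppressMsge = TRUE)
  edges <- cbind(pmin(dd$delsgs$ind1, dd$delsgs$ind2),
                 pmax(dd$delsgs$ind1, dd$delsgs$ind2))
  edges <- unique(edges)

  both <- rbind(edges, edges[, 2:1, drop = FALSE])
  ed <- sqrt((x[both[, 1]] - x[both[, 2]])^2 +
               (y[both[, 1]] - y[both[, 2]])^2)
  o <- order(both[, 1], ed, both[, 2])
  first <- !duplicated(both[o, 1])
  nn_index <- integer(n); nn_dist <- numeric(n)
  nn_index[both[o, 1][first]] <- both[o, 2][first]
  nn_dist[both[o, 1][first]] <- ed[o][first]

  voronoi <- NULL
  if (compute_voronoi) {
    tl <- deldir::tile.list(dd)
    voronoi <- lapply(tl, function(t) {
      poly <- cbind(t$x, t$y)
      if (!is.null(clip)) {
        hull <- clip[chull(clip[, 1], clip[, 2]), , drop = FALSE]
        poly <- clip_convex(poly, hull)
      }
      colnames(poly) <- c("x", "y")
      poly
    })
    names(voronoi) <- ids[vapply(tl, function(t) t$ptNum, integer(1))]
  }

  structure(list(cell_id = ids, x = x, y = y, edges = edges,
                 nn = data.frame(cell_id = ids, nn_cell_id = ids[nn_index],
                                 nn_index = nn_index, distance = nn_dist,
                                 stringsAsFactors = FALSE),
                 delaunay = TRUE, voronoi = voronoi),
            class = "iss_graph")
}

#' @export
print.iss_graph <- function(x, ...) {
  cat(sprintf("Neighbor graph: %d nodes, %d Delaunay edges%s\n",
              length(x$cell_id), nrow(x$edges),
              if (x$delaunay) "" else " (triangulation unavailable)"))
  invisible(x)
}

graph_labels <- function(graph, labels) {
  if (!is.null(names(labels))) labels <- labels[graph$cell_id]
  assert_that(length(labels) == length(graph$cell_id) && !anyNA(labels),
              "every node needs a label")
  as.character(labels)
}

#' Nearest-neighbor type composition
#'
#' Entry (a, b) is the percentage of cells of type a whose nearest neighbor
#' is of type b; each row of the matrix sums to 100. Types with no cells
#' give `NA` rows, flagged in attribute `undefined`.
#'
#' @param graph an `iss_graph`.
#' @param labels type label per node (named by cell_id or positional).
#' @param types type universe; defaults to sorted observed labels.
#' @return types x types matrix of percentages.
#' @export
nn_composition <- function(graph, labels, types = NULL) {
  lab <- graph_labels(graph, labels)
  types <- types %||% sort(unique(lab))
  tab <- table(factor(lab, levels = types),
               factor(lab[graph$nn$nn_index], levels = types))
  tot <- rowSums(tab)
  out <- 100 * sweep(unclass(tab), 1, pmax(tot, 1), "/")
  out[tot == 0, ] <- NA_real_
  dimnames(out) <- list(type = types, nn_type = types)
  undef <- types[tot == 0]
  if (length(undef))
    warning("types with no cells: ", paste(undef, collapse = ", "))
  attr(out, "undefined") <- undef
  out
}

#' Mean distance to the most prevalent nearest-neighbor type
#'
#' For each type a, identifies the most frequent nearest-neighbor type b*
#' (ties broken by type order, flagged) and returns the mean Euclidean
#' nearest-neighbor distance over cells of type a whose nearest neighbor is
#' of type b*.
#'
#' @inheritParams nn_composition
#' @return data frame: `type`, `nn_type`, `mean_distance` (um), `n_pairs`,
#'   `tie` flag.
#' @export
nn_mean_distance <- function(graph, labels, types = NULL) {
  lab <- graph_labels(graph, labels)
  comp <- suppressWarnings(nn_composition(graph, labels, types))
  types <- rownames(comp)
  out <- lapply(types, function(a) {
    row <- comp[a, ]
    if (all(is.na(row))) return(NULL)
    bstar <- types[which.max(row)]
    tie <- sum(row == max(row, na.rm = TRUE), na.rm = TRUE) > 1
    idx <- lab == a & lab[graph$nn$nn_index] == bstar
    data.frame(type = a, nn_type = bstar,
               mean_distance = mean(graph$nn$distance[idx]),
               n_pairs = sum(idx), tie = tie, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Permutation-based neighborhood enrichment test
#'
#' Compares the observed neighbor-type statistic against a null built by
#' permuting the type labels uniformly at random over the fixed positions
#' (the graph and label multiset are preserved exactly). The default
#' statistic counts, per ordered type pair (a, b), the cells of type a
#' whose nearest neighbor has type b; `statistic = "edge_count"` instead
#' counts Delaunay edges joining types a and b (a symmetric statistic).
#' Reports the permutation z-score and the add-one-corrected empirical
#' p-value `p = (1 + #permutations with statistic >= observed) /
#' (1 + n_permutations)` for one-sided enrichment (two-sided doubles the
#' smaller tail). Where the null is degenerate (sd = 0) the z-score is
#' `NA` and the p-value still comes from tie counting.
#'
#' @inheritParams nn_composition
#' @param n_permutations number of label permutations (>= 100).
#' @param seed integer seed for the permutation stream.
#' @param statistic `"nn_count"` (default) or `"edge_count"`.
#' @param alternative `"greater"` (enrichment, default) or `"two.sided"`.
#' @return An `iss_enrichment`: matrices `observed`, `null_mean`,
#'   `null_sd`, `z`, `p` over type pairs, a long-format `pairs` data
#'   frame, and the test parameters.
#' @export
enrichment_test <- function(graph, labels, n_permutations = 1000, seed = 1,
                            statistic = c("nn_count", "edge_count"),
                            alternative = c("greater", "two.sided"),
                            types = NULL) {
  statistic <- match.arg(statistic)
  alternative <- match.arg(alternative)
  assert_that(n_permutations >= 100, "use at least 100 permutations")
  lab <- graph_labels(graph, labels)
  types <- types %||% sort(unique(lab))
  K <- length(types)
  li <- match(lab, types)

  if (statistic == "nn_count") {
    nni <- graph$nn$nn_index
    stat_fn <- function(l) {
      m <- tabulate((l - 1L) * K + l[nni], K * K)
      matrix(m, K, K, byrow = TRUE)
    }
  } else {
    assert_that(graph$delaunay, "edge_count requires a triangulation")
    e1 <- graph$edges[, 1]; e2 <- graph$edges[, 2]
    stat_fn <- function(l) {
      a <- pmin(l[e1], l[e2]); b <- pmax(l[e1], l[e2])
      m <- matrix(tabulate((a - 1L) * K + b, K * K), K, K, byrow = TRUE)
      m + t(m) - diag(diag(m))
    }
  }

  obs <- stat_fn(li)
  B <- n_permutations
  s1 <- matrix(0, K, K); s2 <- matrix(0, K, K)
  ge <- matrix(0L, K, K); le <- matrix(0L, K, K)
  withr::with_seed(seed, {
    for (b in seq_len(B)) {
      s <- stat_fn(sample(li))
      s1 <- s1 + s
      s2 <- s2 + s * s
      ge <- ge + (s >= obs)
      le <- le + (s <= obs)
    }
  })
  mu <- s1 / B
  sdv <- sqrt(pmax((s2 - B * mu^2) / (B - 1), 0))
  z <- (obs - mu) / sdv
  z[sdv == 0] <- NA_real_
  p_g <- (1 + ge) / (1 + B)
  p_l <- (1 + le) / (1 + B)
  p <- if (alternative == "greater") p_g else pmin(2 * pmin(p_g, p_l), 1)
  dn <- list(type = types, nn_type = types)
  dimnames(obs) <- dimnames(mu) <- dimnames(sdv) <- dimnames(z) <-
    dimnames(p) <- dn

  pairs <- data.frame(type_a = rep(types, each = K),
                      type_b = rep(types, K),
                      observed = as.vector(t(obs)),
                      null_mean = as.vector(t(mu)),
                      null_sd = as.vector(t(sdv)),
                      z = as.vector(t(z)), p = as.vector(t(p)),
                      stringsAsFactors = FALSE)
  structure(list(observed = obs, null_mean = mu, null_sd = sdv, z = z,
                 p = p, pairs = pairs, statistic = statistic,
                 alternative = alternative, n_permutations = B,
                 seed = seed, types = types),
            class = "iss_enrichment")
}

#' @export
print.iss_enrichment <- function(x, ...) {
  sig <- sum(x$p <= 0.05, na.rm = TRUE)
  cat(sprintf(
    "Neighborhood enrichment (%s, %d permutations): %d/%d pairs p <= 0.05\n",
    x$statistic, x$n_permutations, sig, length(x$p)))
  invisible(x)
}
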