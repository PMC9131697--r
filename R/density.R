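# Kernel-density tissue maps and cortical depth profiles. 2-D maps use an
# isotropic Gaussian kernel evaluated on a regular grid and masked to the
# section polygon; unnormalized layers integrate to the cell count. Depth
# profiles project cells onto the pial-to-white-matter axis and smooth in
# one dimension with boundary reflection so mass is conserved on [0, 1].

#' Gaussian kernel density map of one cell population
#'
#' Evaluates the kernel density of the given points on a regular grid over
#' the polygon's bounding box and masks nodes outside the polygon (`NA`).
#' Values are in cells per um^2 and the unmasked layer integrates to the
#' number of cells (up to kernel mass lying outside the polygon).
#'
#' @param x,y cell coordinates in um (may be empty: returns an all-zero,
#'   flagged layer).
#' @param polygon two-column boundary polygon.
#' @param bandwidth Gaussian kernel standard deviation in um (> 0).
#' @param spacing grid spacing in um.
#' @return An `iss_kde`: list with grid vectors `x`, `y`, value matrix `z`
#'   (`z[i, j]` at `(x[i], y[j])`, as [graphics::image()] expects),
#'   `bandwidth`, `spacing` and the cell count `n`.
#' @export
kde_map <- function(x, y, polygon, bandwidth = 100, spacing = 20) {
  assert_that(bandwidth > 0, "bandwidth must be positive")
  assert_that(spacing > 0, "spacing must be positive")
  bx <- range(polygon[, 1]); by <- range(polygon[, 2])
  gx <- seq(bx[1], bx[2], by = spacing)
  gy <- seq(by[1], by[2], by = spacing)
  flagged <- length(x) == 0
  if (flagged) {
    z <- matrix(0, length(gx), length(gy))
  } else {
    A <- outer(gx, x, function(g, c) dnorm(g - c, sd = bandwidth))
    B <- outer(gy, y, function(g, c) dnorm(g - c, sd = bandwidth))
    z <- A %*% t(B)
  }
  grid <- expand.grid(gx = gx, gy = gy)
  inside <- point_in_polygon(grid$gx, grid$gy, polygon)
  z[!inside] <- NA_real_
  structure(list(x = gx, y = gy, z = z, bandwidth = bandwidth,
                 spacing = spacing, n = length(x), flagged = flagged),
            class = "iss_kde")
}

#' Kernel density maps for every type of a called cell map
#'
#' @param called an `iss_called` data frame.
#' @param polygon section boundary polygon (e.g. one layout region).
#' @param types types to map; defaults to the panel order.
#' @inheritParams kde_map
#' @return named list of `iss_kde` layers.
#' @export
kde_maps <- function(called, polygon, types = NULL, bandwidth = 100,
                     spacing = 20) {
  types <- types %||% attr(called, "type_ids") %||%
    sort(unique(called$called_type))
  setNames(lapply(types, function(ty) {
    idx <- called$called_type == ty
    kde_map(called$x[idx], called$y[idx], polygon, bandwidth, spacing)
  }), types)
}

kde_integral <- function(layer) {
  sum(layer$z, na.rm = TRUE) * layer$spacing^2
}

#' Normalize density layers to the section maximum
#'
#' Divides every layer by the single maximum over all types and grid nodes,
#' so the global maximum is exactly 1 and layers are comparable within the
#' section. This is the per-section normalization of brain maps; for the
#' spinal-cord display the same operation is applied separately to the GM
#' and WM layer sets (call once per compartment).
#'
#' @param layers a named list of `iss_kde` layers (or a single layer).
#' @return the layers rescaled; attribute `max_density` holds the divisor.
#' @export
normalize_section <- function(layers) {
  single <- inherits(layers, "iss_kde")
  if (single) layers <- list(layers)
  m <- max(vapply(layers, function(l) max(l$z, 0, na.rm = TRUE), numeric(1)))
  assert_that(is.finite(m) && m > 0, "all layers are zero: cannot normalize")
  out <- lapply(layers, function(l) { l$z <- l$z / m; l })
  attr(out, "max_density") <- m
  if (single) out[[1]] else out
}

#' Cortical depth profile of called cells
#'
#' Projects each cell onto the region's depth axis (0 = pial surface, 1 =
#' white-matter boundary) by scalar projection, then smooths the per-type
#' depth samples with a 1-D Gaussian kernel using boundary reflection at 0
#' and 1, so each type's profile integrates to its cell count. Per-layer
#' occupancy is the exact integral of the smoothed profile between
#' consecutive layer breaks (closed form via the Gaussian CDF). Cells
#' projecting outside [0, 1] are clipped, with a warning if they exceed 5%.
#'
#' @param called an `iss_called` data frame.
#' @param depth_axis list with `from` (pial point) and `to` (white-matter
#'   point), as stored in a layout's `depth_axis`.
#' @param layer_breaks increasing fractional depths in (0, 1) delimiting
#'   layers; 4 breaks give the cortical layers I, II/III, IV, V, VI.
#' @param bandwidth kernel standard deviation as a fraction of the cortical
#'   depth.
#' @param n_grid number of grid points on [0, 1].
#' @param types types to profile; defaults to the panel order.
#' @return An `iss_depth_profile`: `depth` grid, `profile` (grid x types,
#'   smoothed occurrence), `occupancy` (types x layers), `counts`,
#'   `layer_breaks`, `bandwidth`, `n_clipped`.
#' @export
depth_profile <- function(called, depth_axis, layer_breaks = NULL,
                          bandwidth = 0.05, n_grid = 201, types = NULL) {
  assert_that(!is.null(depth_axis), "depth_axis is required")
  assert_that(bandwidth > 0, "bandwidth must be positive")
  if (!is.null(layer_breaks))
    assert_that(all(diff(layer_breaks) > 0) && all(layer_breaks > 0) &&
                  all(layer_breaks < 1),
                "layer_breaks must be strictly increasing within (0, 1)")
  types <- types %||% attr(called, "type_ids") %||%
    sort(unique(called$called_type))
  a <- as.numeric(depth_axis$from); b <- as.numeric(depth_axis$to)
  ab <- b - a
  t_raw <- ((called$x - a[1]) * ab[1] + (called$y - a[2]) * ab[2]) /
    sum(ab^2)
  n_clip <- sum(t_raw < 0 | t_raw > 1)
  if (n_clip > 0.05 * length(t_raw))
    warning(sprintf("%d of %d cells project outside the depth axis",
                    n_clip, length(t_raw)))
  t_d <- pmin(pmax(t_raw, 0), 1)

  tg <- seq(0, 1, length.out = n_grid)
  refl_density <- function(d, grid) {
    if (length(d) == 0) return(rep(0, length(grid)))
    f <- function(centers) rowSums(outer(grid, centers, function(g, c)
      dnorm(g - c, sd = bandwidth)))
    f(d) + f(-d) + f(2 - d)
  }
  refl_mass <- function(d, lo, hi) {
    if (length(d) == 0) return(0)
    m <- function(centers) sum(pnorm((hi - centers) / bandwidth) -
                                 pnorm((lo - centers) / bandwidth))
    m(d) + m(-d) + m(2 - d)
  }

  brk <- c(0, layer_breaks, 1)
  layer_names <- if (length(brk) == 6) c("I", "II/III", "IV", "V", "VI")
                 else sprintf("L%d", seq_len(length(brk) - 1))
  prof <- matrix(0, n_grid, length(types), dimnames = list(NULL, types))
  occ <- matrix(0, length(types), length(brk) - 1,
                dimnames = list(types, layer_names))
  counts <- setNames(integer(length(types)), types)
  for (ty in types) {
    d <- t_d[called$called_type == ty]
    counts[ty] <- length(d)
    prof[, ty] <- refl_density(d, tg)
    for (j in seq_len(length(brk) - 1))
      occ[ty, j] <- refl_mass(d, brk[j], brk[j + 1])
  }
  structure(list(depth = tg, profile = prof, occupancy = occ,
                 counts = counts, layer_breaks = layer_breaks,
                 bandwidth = bandwidth, n_clipped = n_clip),
            class = "iss_depth_profile")
}

#' Average depth profiles over sections
#'
#' @param profiles list of `iss_depth_profile` objects on identical grids.
#' @param normalize divide each section's profile matrix by its own maximum
#'   before averaging (per-section normalization); default uses raw
#'   smoothed occurrences.
#' @return list with `depth`, `mean` and `sem` (grid x types), `n`.
#' @export
aggregate_profiles <- function(profiles, normalize = FALSE) {
  assert_that(length(profiles) >= 1, "need at least one profile")
  mats <- lapply(profiles, function(p) {
    m <- p$profile
    if (normalize) m <- m / max(m)
    m
  })
  arr <- simplify2array(mats)
  list(depth = profiles[[1]]$depth,
       mean = apply(arr, c(1, 2), mean),
       sem = apply(arr, c(1, 2), sd) / sqrt(length(mats)),
       n = length(mats))
}

#' Per-area normalized occurrences
#'
#' Assigns cells to named area polygons (first containing polygon wins) and
#' reports per area the count and the percentage of that area's called
#' cells per type, so occurrences are comparable across areas of different
#' size and cellularity. Empty areas are flagged with `NA` occurrences.
#'
#' @param called an `iss_called` data frame.
#' @param areas named list of disjoint polygons (e.g. `layout$areas` with
#'   S1, M1, M2, Cg1, Cg2).
#' @param types type universe; defaults to the panel order.
#' @return data frame: `area`, `type`, `count`, `occurrence` (%).
#' @export
area_occurrence <- function(called, areas, types = NULL) {
  types <- types %||% attr(called, "type_ids") %||%
    sort(unique(called$called_type))
  lay <- structure(list(regions = areas), class = "iss_layout")
  aa <- assign_region(called$x, called$y, lay)
  out <- list()
  for (ar in names(areas)) {
    idx <- aa == ar
    cnt <- table(factor(called$called_type[idx], levels = types))
    tot <- sum(cnt)
    if (tot == 0) warning(sprintf("area '%s' contains no cells", ar))
    out[[ar]] <- data.frame(area = ar, type = types,
                            count = as.integer(cnt),
                            occurrence = if (tot > 0)
                              100 * as.numeric(cnt) / tot else NA_real_,
                            stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}
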