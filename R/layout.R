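# Region annotations: named simple polygons (micrometre coordinates) with a
# GM/WM compartment label, an optional pial-to-white-matter depth axis and
# fractional layer breaks for cortical regions, and optional cortical-area
# polygons. Regions are ordered; a point lying in several polygons belongs to
# the first listed (this is how an inner GM polygon can sit inside an outer
# WM boundary without polygon holes).

#' Area of a simple polygon (shoelace formula)
#'
#' @param poly two-column matrix of vertices (um); result in um^2.
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

point_in_polygon <- function(px, py, poly) {
  sp::point.in.polygon(px, py, poly[, 1], poly[, 2]) > 0
}

polygon_contains <- function(outer, inner) {
  all(point_in_polygon(inner[, 1], inner[, 2], outer))
}

# Simplicity check: no two non-adjacent edges intersect.
polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  p <- rbind(poly, poly[1, ])
  seg_int <- function(a1, a2, b1, b2) {
    d1 <- (b2[1] - b1[1]) * (a1[2] - b1[2]) - (b2[2] - b1[2]) * (a1[1] - b1[1])
    d2 <- (b2[1] - b1[1]) * (a2[2] - b1[2]) - (b2[2] - b1[2]) * (a2[1] - b1[1])
    d3 <- (a2[1] - a1[1]) * (b1[2] - a1[2]) - (a2[2] - a1[2]) * (b1[1] - a1[1])
    d4 <- (a2[1] - a1[1]) * (b2[2] - a1[2]) - (a2[2] - a1[2]) * (b2[1] - a1[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # adjacent through closure
      if (seg_int(p[i, ], p[i + 1, ], p[j, ], p[j + 1, ])) return(FALSE)
    }
  }
  TRUE
}

rect_poly <- function(x0, y0, x1, y1) {
  cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}

#' Build a synthetic tissue-section annotation
#'
#' Two layouts are provided. `"brain_coronal"` emulates a hemisected coronal
#' section: a cortical band `CTX` (gray matter) with a pial-to-white-matter
#' depth axis and fractional breaks delimiting layers I, II/III, IV, V and
#' VI, above a corpus-callosum band `CC` (white matter); the cortex is also
#' subdivided laterally-to-medially into the area polygons S1, M1, M2, Cg1
#' and Cg2. `"spinal_cord"` emulates a cord cross-section: a gray-matter
#' butterfly polygon listed before the outer white-matter boundary, so points
#' inside the butterfly are GM and the WM area is the outer area minus the
#' contained GM area.
#'
#' @param kind `"brain_coronal"` or `"spinal_cord"`.
#' @param scale characteristic size in micrometres (cortical depth for the
#'   brain layout; cord radius for the spinal layout). Must be positive.
#' @return An `iss_layout` object: named, ordered list of polygons with
#'   compartments, per-region areas in mm^2, optional `depth_axis`,
#'   `layer_breaks` and `areas`.
#' @examples
#' lay <- make_layout("brain_coronal", scale = 1000)
#' names(lay$regions)
#' @export
make_layout <- function(kind = c("brain_coronal", "spinal_cord"),
                        scale = 1000) {
  kind <- match.arg(kind)
  assert_that(is.numeric(scale) && scale > 0, "scale must be positive")
  if (kind == "brain_coronal") {
    w <- 2.5 * scale
    regions <- list(
      CTX = rect_poly(0, 0.35 * scale, w, 1.35 * scale),
      CC  = rect_poly(0, 0.10 * scale, w, 0.35 * scale))
    compartment <- c(CTX = "GM", CC = "WM")
    depth_axis <- list(CTX = list(from = c(w / 2, 1.35 * scale),
                                  to   = c(w / 2, 0.35 * scale)))
    layer_breaks <- list(CTX = c(0.10, 0.35, 0.50, 0.75))
    wfrac <- c(S1 = 0.30, M1 = 0.25, M2 = 0.20, Cg1 = 0.15, Cg2 = 0.10)
    xb <- cumsum(c(0, wfrac)) * w
    areas <- lapply(seq_along(wfrac), function(i)
      rect_poly(xb[i], 0.35 * scale, xb[i + 1], 1.35 * scale))
    names(areas) <- names(wfrac)
  } else {
    th <- seq(0, 2 * pi, length.out = 73)[-73]
    outer <- cbind(x = scale * cos(th), y = 0.7 * scale * sin(th))
    gm <- cbind(
      x = scale * c(-0.15, -0.50, -0.55, -0.20, -0.55, -0.50, -0.15,
                     0.15,  0.50,  0.55,  0.20,  0.55,  0.50,  0.15),
      y = scale * c( 0.55,  0.45,  0.20,  0.10, -0.05, -0.35, -0.45,
                    -0.45, -0.35, -0.05,  0.10,  0.20,  0.45,  0.55))
    regions <- list(GM = gm, WM = outer)
    compartment <- c(GM = "GM", WM = "WM")
    depth_axis <- NULL
    layer_breaks <- NULL
    areas <- NULL
  }

  # Effective area per region subtracts earlier-listed polygons it contains.
  raw <- vapply(regions, polygon_area, numeric(1))
  eff <- raw
  nm <- names(regions)
  for (i in seq_along(regions)) {
    if (i == 1) next
    for (j in seq_len(i - 1)) {
      if (polygon_contains(regions[[i]], regions[[j]]))
        eff[i] <- eff[i] - raw[j]
    }
  }
  structure(list(regions = regions, compartment = compartment,
                 depth_axis = depth_axis, layer_breaks = layer_breaks,
                 areas = areas, area_mm2 = eff / 1e6),
            class = "iss_layout")
}

#' @export
print.iss_layout <- function(x, ...) {
  cat(sprintf("Tissue layout: %d regions (%s)\n", length(x$regions),
              paste(sprintf("%s[%s, %.2f mm2]", names(x$regions),
                            x$compartment[names(x$regions)],
                            x$area_mm2[names(x$regions)]), collapse = ", ")))
  if (!is.null(x$areas))
    cat("Cortical areas:", paste(names(x$areas), collapse = ", "), "\n")
  invisible(x)
}

layout_bbox <- function(layout) {
  xs <- unlist(lapply(layout$regions, function(p) p[, 1]))
  ys <- unlist(lapply(layout$regions, function(p) p[, 2]))
  c(xmin = min(xs), xmax = max(xs), ymin = min(ys), ymax = max(ys))
}

#' Assign points to annotated regions
#'
#' Each point is assigned to the first region in the layout's listed order
#' whose polygon contains it (boundary points included); points in no region
#' are `"unassigned"`. The listed-order rule makes assignment deterministic
#' for overlapping annotations (e.g. a GM polygon inside a WM boundary).
#'
#' @param x,y point coordinates in micrometres.
#' @param layout an `iss_layout`.
#' @return Character vector of region names.
#' @export
assign_region <- function(x, y, layout) {
  out <- rep("unassigned", length(x))
  for (nm in names(layout$regions)) {
    idx <- out == "unassigned"
    if (!any(idx)) break
    inside <- point_in_polygon(x[idx], y[idx], layout$regions[[nm]])
    out[idx][inside] <- nm
  }
  out
}

#' Write / read a layout as GeoJSON
#'
#' Regions (and cortical areas) are stored as a FeatureCollection of Polygon
#' features with properties `name`, `role` ("region" or "area"),
#' `compartment`, and, where present, `layer_breaks` and `depth_axis`.
#' Feature order encodes the region precedence.
#'
#' @param layout an `iss_layout`.
#' @param path file path.
#' @export
write_layout_geojson <- function(layout, path) {
  feat <- function(name, poly, role, props = list()) {
    ring <- rbind(poly, poly[1, , drop = FALSE])
    coords <- lapply(seq_len(nrow(ring)), function(i) as.numeric(ring[i, ]))
    list(type = "Feature",
         properties = c(list(name = name, role = role), props),
         geometry = list(type = "Polygon", coordinates = list(coords)))
  }
  feats <- lapply(names(layout$regions), function(nm) {
    props <- list(compartment = unname(layout$compartment[[nm]]))
    if (!is.null(layout$layer_breaks[[nm]]))
      props$layer_breaks <- layout$layer_breaks[[nm]]
    if (!is.null(layout$depth_axis[[nm]]))
      props$depth_axis <- list(as.numeric(layout$depth_axis[[nm]]$from),
                               as.numeric(layout$depth_axis[[nm]]$to))
    feat(nm, layout$regions[[nm]], "region", props)
  })
  if (!is.null(layout$areas))
    feats <- c(feats, lapply(names(layout$areas), function(nm)
      feat(nm, layout$areas[[nm]], "area")))
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_layout_geojson
#' @export
read_layout_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  assert_that(identical(gj$type, "FeatureCollection"),
              "not a GeoJSON FeatureCollection")
  regions <- list(); compartment <- character(0)
  depth_axis <- list(); layer_breaks <- list(); areas <- list()
  for (f in gj$features) {
    nm <- f$properties$name
    ring <- f$geometry$coordinates[[1]]
    poly <- do.call(rbind, lapply(ring, as.numeric))
    if (nrow(poly) > 1 && all(poly[1, ] == poly[nrow(poly), ]))
      poly <- poly[-nrow(poly), , drop = FALSE]
    colnames(poly) <- c("x", "y")
    if (identical(f$properties$role, "area")) {
      areas[[nm]] <- poly
    } else {
      regions[[nm]] <- poly
      compartment[nm] <- f$properties$compartment %||% NA_character_
      if (!is.null(f$properties$layer_breaks))
        layer_breaks[[nm]] <- as.numeric(unlist(f$properties$layer_breaks))
      if (!is.null(f$properties$depth_axis))
        depth_axis[[nm]] <- list(
          from = as.numeric(unlist(f$properties$depth_axis[[1]])),
          to   = as.numeric(unlist(f$properties$depth_axis[[2]])))
    }
  }
  raw <- vapply(regions, polygon_area, numeric(1))
  eff <- raw
  for (i in seq_along(regions)) {
    if (i == 1) next
    for (j in seq_len(i - 1)) {
      if (polygon_contains(regions[[i]], regions[[j]]))
        eff[i] <- eff[i] - raw[j]
    }
  }
  structure(list(regions = regions, compartment = compartment,
                 depth_axis = if (length(depth_axis)) depth_axis else NULL,
                 layer_breaks = if (length(layer_breaks)) layer_breaks else NULL,
                 areas = if (length(areas)) areas else NULL,
                 area_mm2 = eff / 1e6),
            class = "iss_layout")
}
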