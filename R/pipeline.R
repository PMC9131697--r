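# End-to-end orchestration: simulate (or load) -> type -> abundance ->
# density -> neighbors, with a JSON run manifest. One global seed is split
# deterministically into per-stage seeds so stages can be rerun alone.

default_config <- function() {
  list(preset = "p60", scale = 1000, seed = 1,
       spots = NULL, cells = NULL, profiles = NULL, layout = NULL,
       pan_marker = "Plp1",
       radius = 15, min_pan_count = 1, min_probability = NULL,
       kde_bandwidth = 100, kde_spacing = 20, depth_bandwidth = 0.05,
       n_permutations = 1000,
       write_density_grids = FALSE, write_png = FALSE,
       outdir = NULL)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load from the configured input files), typing,
#' abundance, density/depth profiles, and neighborhood analysis per region,
#' writing all tabular outputs and a JSON manifest (configuration echo,
#' package version, per-stage row counts and timings) to `outdir`. Given
#' the same configuration and seed the CSV outputs are bit-identical.
#'
#' @param config list overriding the defaults: either a simulation `preset`
#'   (`"p10"`/`"p20"`/`"p60"` with `scale`) or the four input paths
#'   `spots`, `cells`, `profiles`, `layout`; module parameters `radius`,
#'   `min_pan_count`, `min_probability`, `kde_bandwidth`, `kde_spacing`,
#'   `depth_bandwidth`, `n_permutations`; `seed`; `outdir` (required).
#'   `write_density_grids`/`write_png` opt into raster outputs.
#' @return invisibly, a list with every stage's in-memory result and the
#'   manifest.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- modifyList(default_config(), config)
  assert_that(!is.null(cfg$outdir), "config$outdir is required")
  assert_that(is.numeric(cfg$seed), "config$seed must be set")
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  tic <- function() proc.time()[["elapsed"]]
  res <- list()

  run_stage <- function(name, fn) {
    t0 <- tic()
    out <- tryCatch(fn(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    stages[[name]] <<- list(seconds = round(tic() - t0, 3),
                            rows = out$rows %||% NA)
    out$value
  }

  from_files <- !is.null(cfg$spots)
  if (from_files) {
    assert_that(!is.null(cfg$cells) && !is.null(cfg$profiles) &&
                  !is.null(cfg$layout),
                "config needs spots, cells, profiles and layout paths")
    for (f in c("spots", "cells", "profiles", "layout"))
      assert_that(file.exists(cfg[[f]]),
                  sprintf("config$%s: file not found: %s", f, cfg[[f]]))
  }

  sim <- run_stage("inputs", function() {
    if (from_files) {
      v <- list(profiles = read_profiles(cfg$profiles, cfg$pan_marker),
                layout = read_layout_geojson(cfg$layout),
                spots = read_spots(cfg$spots),
                cells = read_cells(cfg$cells))
    } else {
      pre <- simulate_preset(cfg$preset, scale = cfg$scale, seed = cfg$seed)
      v <- list(profiles = pre$profiles, layout = pre$layout,
                spots = pre$tissue$spots, cells = pre$tissue$cells,
                tissue = pre$tissue)
      write_spots(v$spots, file.path(cfg$outdir, "spots.csv"))
      write_cells(v$cells, file.path(cfg$outdir, "cells.csv"))
      write_profiles(v$profiles, file.path(cfg$outdir, "profiles.csv"))
      write_layout_geojson(v$layout, file.path(cfg$outdir, "regions.geojson"))
    }
    list(value = v, rows = nrow(v$spots))
  })
  res$inputs <- sim

  typing <- run_stage("typing", function() {
    ty <- run_typing(sim$spots, sim$cells, sim$profiles,
                     max_radius = cfg$radius)
    write_counts_matrix(ty$counts,
                        file.path(cfg$outdir, "cell_by_gene.csv"))
    write_counts_matrix(ty$posterior,
                        file.path(cfg$outdir, "cell_probabilities.csv"))
    list(value = ty, rows = nrow(ty$counts))
  })
  res$typing <- typing

  called <- run_stage("calling", function() {
    cc <- call_cells(typing, sim$cells, min_pan_count = cfg$min_pan_count,
                     min_probability = cfg$min_probability,
                     pan_marker = cfg$pan_marker)
    write_called_cells(cc, file.path(cfg$outdir, "called_cells.csv"))
    list(value = cc, rows = nrow(cc))
  })
  res$called <- called

  res$abundance <- run_stage("abundance", function() {
    ab <- abundance_table(called, sim$layout, sample = "run",
                          types = sim$profiles$type_ids)
    write.csv(ab, file.path(cfg$outdir, "abundance.csv"),
              row.names = FALSE)
    list(value = ab, rows = nrow(ab))
  })

  res$density <- run_stage("density", function() {
    out <- list()
    gm_regions <- names(sim$layout$regions)[
      sim$layout$compartment[names(sim$layout$regions)] == "GM"]
    for (r in names(sim$layout$regions)) {
      inreg <- assign_region(called$x, called$y, sim$layout) == r
      sub <- called[inreg, , drop = FALSE]
      attr(sub, "type_ids") <- sim$profiles$type_ids
      if (nrow(sub) == 0) next
      maps <- kde_maps(sub, sim$layout$regions[[r]],
                       bandwidth = cfg$kde_bandwidth,
                       spacing = cfg$kde_spacing)
      nz <- any(vapply(maps, function(l) max(l$z, 0, na.rm = TRUE),
                       numeric(1)) > 0)
      if (nz) maps <- normalize_section(maps)
      out[[r]] <- maps
      if (cfg$write_density_grids) {
        for (ty in names(maps))
          write.csv(maps[[ty]]$z,
                    file.path(cfg$outdir,
                              sprintf("density_%s_%s.csv", r, ty)),
                    row.names = FALSE)
      }
      if (cfg$write_png) plot_density_maps(
        maps, file.path(cfg$outdir, sprintf("density_%s.png", r)))
    }
    dp <- NULL
    for (r in gm_regions) {
      if (is.null(sim$layout$depth_axis[[r]])) next
      inreg <- assign_region(called$x, called$y, sim$layout) == r
      sub <- called[inreg, , drop = FALSE]
      attr(sub, "type_ids") <- sim$profiles$type_ids
      if (nrow(sub) == 0) next
      dp <- depth_profile(sub, sim$layout$depth_axis[[r]],
                          sim$layout$layer_breaks[[r]],
                          bandwidth = cfg$depth_bandwidth)
      write.csv(data.frame(depth = dp$depth, dp$profile,
                           check.names = FALSE),
                file.path(cfg$outdir, sprintf("depth_profile_%s.csv", r)),
                row.names = FALSE)
      write.csv(data.frame(type = rownames(dp$occupancy), dp$occupancy,
                           check.names = FALSE),
                file.path(cfg$outdir, sprintf("depth_occupancy_%s.csv", r)),
                row.names = FALSE)
    }
    ao <- NULL
    if (!is.null(sim$layout$areas)) {
      ao <- area_occurrence(called, sim$layout$areas,
                            types = sim$profiles$type_ids)
      write.csv(ao, file.path(cfg$outdir, "area_occurrence.csv"),
                row.names = FALSE)
    }
    list(value = list(maps = out, depth = dp, areas = ao),
         rows = length(out))
  })

  res$neighbors <- run_stage("neighbors", function() {
    out <- list()
    regs <- assign_region(called$x, called$y, sim$layout)
    for (r in names(sim$layout$regions)) {
      sub <- called[regs == r, , drop = FALSE]
      if (nrow(sub) < 10) next
      g <- build_graph(sub, clip = sim$layout$regions[[r]])
      labs <- setNames(sub$called_type, sub$cell_id)
      comp <- suppressWarnings(
        nn_composition(g, labs, types = sim$profiles$type_ids))
      nnd <- nn_mean_distance(g, labs, types = sim$profiles$type_ids)
      enr <- enrichment_test(g, labs, n_permutations = cfg$n_permutations,
                             seed = derive_seed(cfg$seed, "neighbors"),
                             types = sim$profiles$type_ids)
      write.csv(data.frame(type = rownames(comp), comp, check.names = FALSE),
                file.path(cfg$outdir, sprintf("nn_composition_%s.csv", r)),
                row.names = FALSE)
      write.csv(nnd, file.path(cfg$outdir,
                               sprintf("nn_distances_%s.csv", r)),
                row.names = FALSE)
      write.csv(enr$pairs, file.path(cfg$outdir,
                                     sprintf("enrichment_%s.csv", r)),
                row.names = FALSE)
      out[[r]] <- list(graph = g, composition = comp, distances = nnd,
                       enrichment = enr)
    }
    list(value = out, rows = length(out))
  })

  manifest <- list(config = cfg[!vapply(cfg, is.null, logical(1))],
                   package = "issmap",
                   version = as.character(packageVersion("issmap")),
                   stages = stages)
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}

#' Validate pipeline inputs
#'
#' Schema and consistency checks over any subset of the four inputs
#' (in-memory objects or file paths): required columns and finite
#' coordinates for spots and cells, panel agreement between spots and
#' profiles, profile invariants, polygon simplicity/area and layer-break
#' monotonicity for the layout. Returns a machine-readable issue table; a
#' clean input set gives zero rows.
#'
#' @param spots,cells,profiles,layout objects or file paths (any may be
#'   `NULL`).
#' @return data frame with columns `component`, `issue`, `detail`.
#' @export
validate_inputs <- function(spots = NULL, cells = NULL, profiles = NULL,
                            layout = NULL) {
  issues <- list()
  add <- function(component, issue, detail = "")
    issues[[length(issues) + 1]] <<- data.frame(
      component = component, issue = issue, detail = as.character(detail),
      stringsAsFactors = FALSE)
  load_safe <- function(x, reader, component) {
    if (is.character(x)) {
      tryCatch(reader(x), error = function(e) {
        add(component, "parse_error", conditionMessage(e)); NULL
      })
    } else x
  }
  profiles <- load_safe(profiles, read_profiles, "profiles")
  layout <- load_safe(layout, read_layout_geojson, "layout")
  spots <- load_safe(spots, read_spots, "spots")
  cells <- load_safe(cells, read_cells, "cells")

  if (!is.null(profiles)) {
    tryCatch(validate_profiles(profiles),
             error = function(e) add("profiles", "invalid",
                                     conditionMessage(e)))
  }
  if (!is.null(spots)) {
    miss <- setdiff(c("spot_id", "gene", "x", "y"), colnames(spots))
    if (length(miss)) add("spots", "missing_columns",
                          paste(miss, collapse = ","))
    else {
      if (!all(is.finite(spots$x)) || !all(is.finite(spots$y)))
        add("spots", "non_finite_coordinates",
            sum(!is.finite(spots$x) | !is.finite(spots$y)))
      if (!is.null(profiles)) {
        unknown <- setdiff(unique(spots$gene), profiles$gene_ids)
        if (length(unknown))
          add("spots", "gene_not_in_panel",
              sprintf("%d genes, %d spots", length(unknown),
                      sum(spots$gene %in% unknown)))
      }
    }
  }
  if (!is.null(cells)) {
    miss <- setdiff(c("cell_id", "x", "y"), colnames(cells))
    if (length(miss)) add("cells", "missing_columns",
                          paste(miss, collapse = ","))
    else {
      if (anyDuplicated(cells$cell_id))
        add("cells", "duplicate_cell_ids",
            sum(duplicated(cells$cell_id)))
      if (!is.null(cells$area) && any(cells$area <= 0, na.rm = TRUE))
        add("cells", "non_positive_area", sum(cells$area <= 0, na.rm = TRUE))
    }
  }
  if (!is.null(layout)) {
    for (nm in names(layout$regions)) {
      poly <- layout$regions[[nm]]
      if (polygon_area(poly) <= 0)
        add("layout", "zero_area_polygon", nm)
      if (!polygon_is_simple(poly))
        add("layout", "invalid_geometry", nm)
    }
    for (nm in names(layout$layer_breaks %||% list())) {
      lb <- layout$layer_breaks[[nm]]
      if (any(diff(lb) <= 0) || any(lb <= 0) || any(lb >= 1))
        add("layout", "invalid_layer_breaks", nm)
    }
  }
  if (length(issues) == 0)
    return(data.frame(component = character(0), issue = character(0),
                      detail = character(0), stringsAsFactors = FALSE))
  do.call(rbind, issues)
}
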