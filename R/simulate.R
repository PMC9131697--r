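# Synthetic ISS tissue generator. Cells are placed by a homogeneous Poisson
# point process per region, typed from region-specific abundance fractions,
# given per-gene Poisson (optionally negative-binomial) transcript counts
# proportional to the type's reference profile, and each transcript becomes
# a spot scattered isotropically around the cell centroid. Uniform background
# spots with uniform gene identity emulate decoding noise.

sample_points_in_region <- function(n, region, layout, max_tries = 2000) {
  if (n == 0) return(cbind(x = numeric(0), y = numeric(0)))
  poly <- layout$regions[[region]]
  bx <- range(poly[, 1]); by <- range(poly[, 2])
  xs <- numeric(0); ys <- numeric(0); tries <- 0
  while (length(xs) < n && tries < max_tries) {
    m <- max(2L * (n - length(xs)), 32L)
    px <- runif(m, bx[1], bx[2]); py <- runif(m, by[1], by[2])
    ok <- assign_region(px, py, layout) == region
    xs <- c(xs, px[ok]); ys <- c(ys, py[ok])
    tries <- tries + 1
  }
  assert_that(length(xs) >= n,
              sprintf("could not sample points inside region '%s'", region))
  cbind(x = xs[seq_len(n)], y = ys[seq_len(n)])
}

default_sim_params <- function() {
  list(density = c(GM = 200, WM = 650),  # cells per mm^2, by compartment
       mean_transcripts = 15,            # target transcripts per cell
       spot_sigma = 3,                   # spot scatter around centroid (um)
       background = 0.05,                # background spots, fraction of true
       background_per_mm2 = NULL,        # alternative absolute rate
       area_meanlog = log(80),           # cell area: log-normal, median 80 um^2
       area_sdlog = 0.35,
       dispersion = NULL)                # NB size parameter; NULL = Poisson
}

#' Simulate a ground-truth ISS tissue
#'
#' Generates segmented cells and decoded transcript spots for a given layout,
#' reference panel and per-region type-abundance specification. See the
#' package vignette for the generative model. Fully reproducible from `seed`.
#'
#' @param profiles an `iss_profiles` object.
#' @param layout an `iss_layout`; `abundance_spec` must cover all its regions.
#' @param abundance_spec named list: region -> named numeric vector of type
#'   fractions summing to 1 (names from `profiles$type_ids`).
#' @param params list overriding the generator defaults: `density` (cells per
#'   mm^2; scalar, named by region, or named by compartment GM/WM),
#'   `mean_transcripts`, `spot_sigma` (um), `background` (fraction of true
#'   spots) or `background_per_mm2`, `area_meanlog`/`area_sdlog`, and
#'   `dispersion` (negative-binomial size; `NULL` for Poisson counts).
#' @param seed integer seed.
#' @return An `iss_tissue`: list with `cells` (cell_id, x, y, area,
#'   true_type, region), `spots` (spot_id, gene, x, y, source), plus the
#'   abundance spec, parameters and layout used.
#' @export
simulate_tissue <- function(profiles, layout, abundance_spec,
                            params = list(), seed = 1) {
  validate_profiles(profiles)
  p <- modifyList(default_sim_params(), params)
  regions <- names(layout$regions)
  assert_that(all(regions %in% names(abundance_spec)),
              "abundance_spec must cover every region in the layout")
  for (r in regions) {
    fr <- abundance_spec[[r]]
    assert_that(all(names(fr) %in% profiles$type_ids),
                sprintf("unknown type in abundance_spec for '%s'", r))
    assert_that(all(fr >= 0) && abs(sum(fr) - 1) <= 1e-9,
                sprintf("abundance fractions for '%s' must sum to 1", r))
  }

  dens <- function(r) {
    d <- p$density
    v <- if (length(d) == 1 && is.null(names(d))) d
         else if (r %in% names(d)) d[[r]]
         else d[[layout$compartment[[r]]]]
    assert_that(is.numeric(v) && v > 0,
                sprintf("no positive density for region '%s'", r))
    v
  }

  gene_ids <- profiles$gene_ids
  G <- length(gene_ids)
  # per-type transcript identity distribution
  probs <- sweep(profiles$mean_expr, 2, colSums(profiles$mean_expr), "/")

  withr::with_seed(seed, {
    cells <- do.call(rbind, lapply(regions, function(r) {
      n <- rpois(1, dens(r) * layout$area_mm2[[r]])
      if (n == 0) return(NULL)
      xy <- sample_points_in_region(n, r, layout)
      data.frame(x = xy[, 1], y = xy[, 2],
                 area = rlnorm(n, p$area_meanlog, p$area_sdlog),
                 true_type = sample(names(abundance_spec[[r]]), n,
                                    replace = TRUE,
                                    prob = abundance_spec[[r]]),
                 region = r)
    }))
    assert_that(!is.null(cells) && nrow(cells) > 0,
                "simulation produced no cells; increase density or area")
    cells <- data.frame(cell_id = sprintf("cell_%05d", seq_len(nrow(cells))),
                        cells, stringsAsFactors = FALSE)

    lam <- probs[, cells$true_type, drop = FALSE] * p$mean_transcripts # G x n
    cnt <- if (is.null(p$dispersion)) {
      matrix(rpois(length(lam), lam), nrow = G)
    } else {
      matrix(rnbinom(length(lam), mu = lam, size = p$dispersion), nrow = G)
    }
    nz <- which(cnt > 0, arr.ind = TRUE)
    reps <- cnt[nz]
    gene <- rep(gene_ids[nz[, 1]], reps)
    src <- rep(cells$cell_id[nz[, 2]], reps)
    cx <- rep(cells$x[nz[, 2]], reps)
    cy <- rep(cells$y[nz[, 2]], reps)
    n_true <- length(gene)
    sx <- cx + rnorm(n_true, 0, p$spot_sigma)
    sy <- cy + rnorm(n_true, 0, p$spot_sigma)

    bb <- layout_bbox(layout)
    n_bg <- if (!is.null(p$background_per_mm2)) {
      rpois(1, p$background_per_mm2 *
              (bb["xmax"] - bb["xmin"]) * (bb["ymax"] - bb["ymin"]) / 1e6)
    } else {
      rpois(1, p$background * n_true)
    }
    if (n_bg > 0) {
      gene <- c(gene, sample(gene_ids, n_bg, replace = TRUE))
      sx <- c(sx, runif(n_bg, bb["xmin"], bb["xmax"]))
      sy <- c(sy, runif(n_bg, bb["ymin"], bb["ymax"]))
      src <- c(src, rep("background", n_bg))
    }
    spots <- data.frame(spot_id = sprintf("spot_%07d", seq_along(gene)),
                        gene = gene, x = sx, y = sy, source = src,
                        stringsAsFactors = FALSE)

    structure(list(cells = cells, spots = spots,
                   abundance_spec = abundance_spec,
                   params = c(p, list(seed = seed)), layout = layout),
              class = "iss_tissue")
  })
}

#' @export
print.iss_tissue <- function(x, ...) {
  cat(sprintf("Synthetic ISS tissue: %d cells, %d spots (%d background)\n",
              nrow(x$cells), nrow(x$spots),
              sum(x$spots$source == "background")))
  invisible(x)
}

#' Randomly permute ground-truth cell labels
#'
#' Returns a copy of the tissue in which `true_type` labels are permuted
#' uniformly at random across cells while every position is kept - the null
#' configuration used by the permutation-based neighborhood test.
#'
#' @param tissue an `iss_tissue`.
#' @param seed integer seed.
#' @export
shuffle_labels <- function(tissue, seed = 1) {
  assert_that(nrow(tissue$cells) > 0, "tissue has no cells")
  tissue$cells$true_type <- withr::with_seed(seed,
    sample(tissue$cells$true_type))
  tissue
}

# Study-condition presets. Mean transcripts per cell and per-region cell
# densities follow the reported P10/P20/P60 measurements; type-abundance
# fractions are qualitative renderings of the reported compositions (early
# lineage stages dominant at P10, mature MOL5/6 dominant at P60).
preset_table <- function() {
  ab <- function(...) {
    v <- c(...)
    names(v) <- c("OPC", "COP", "NFOL1", "NFOL2", "MFOL1", "MFOL2",
                  paste0("MOL", 1:6), "VLMC")
    stopifnot(abs(sum(v) - 1) < 1e-9)
    v
  }
  list(
    p10 = list(mean_transcripts = 13.4, density = c(CTX = 207, CC = 648),
      abundance = list(
        CTX = ab(.22, .09, .12, .05, .12, .12, .05, .03, .03, .03, .08, .03, .03),
        CC  = ab(.20, .13, .16, .05, .09, .09, .07, .04, .03, .02, .06, .03, .03))),
    p20 = list(mean_transcripts = 14.6, density = c(CTX = 194, CC = 750),
      abundance = list(
        CTX = ab(.16, .06, .08, .05, .10, .09, .05, .04, .04, .04, .18, .06, .05),
        CC  = ab(.15, .09, .10, .04, .08, .07, .05, .05, .05, .03, .17, .05, .07))),
    p60 = list(mean_transcripts = 17.4, density = c(CTX = 170, CC = 609),
      abundance = list(
        CTX = ab(.12, .03, .02, .02, .03, .02, .02, .08, .06, .05, .30, .20, .05),
        CC  = ab(.10, .04, .03, .02, .06, .03, .01, .12, .05, .04, .32, .13, .05))))
}

#' Simulate a preset developmental stage
#'
#' Convenience wrapper bundling the default 124-gene panel, a coronal brain
#' layout (CTX + CC) and stage-specific generator conditions: mean
#' transcripts per cell 13.4 (p10), 14.6 (p20) or 17.4 (p60) and cell
#' densities of 207/648, 194/750 and 170/609 cells per mm^2 in CTX/CC
#' respectively, with stage-appropriate lineage compositions.
#'
#' @param preset `"p10"`, `"p20"` or `"p60"`.
#' @param scale layout scale in micrometres (cortical depth).
#' @param seed integer seed; per-stage seeds are derived from it.
#' @param params overrides merged over the preset generator parameters.
#' @return list with `profiles`, `layout`, `tissue` and the preset name.
#' @export
simulate_preset <- function(preset = c("p60", "p20", "p10"), scale = 1000,
                            seed = 1, params = list()) {
  preset <- match.arg(preset)
  ps <- preset_table()[[preset]]
  profiles <- make_reference_profiles(seed = derive_seed(seed, "profiles"))
  layout <- make_layout("brain_coronal", scale = scale)
  pr <- modifyList(list(mean_transcripts = ps$mean_transcripts,
                        density = ps$density), params)
  tissue <- simulate_tissue(profiles, layout, ps$abundance, params = pr,
                            seed = derive_seed(seed, "simulate"))
  list(profiles = profiles, layout = layout, tissue = tissue, preset = preset)
}
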