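#' Build synthetic reference expression profiles
#'
#' Constructs a genes-by-types matrix of mean expression per cell emulating a
#' targeted marker panel for a lineage of related cell populations: each type
#' gets `markers_per_type` dedicated elevated genes, `n_shared_genes` genes
#' are elevated in two to four types (lineage-shared markers), and one
#' pan-lineage marker (default `"Plp1"`) is elevated in every type. All other
#' entries sit at `off_level`. Marker magnitudes are jittered log-normally so
#' types are not exchangeable; the construction is fully reproducible from
#' `seed`.
#'
#' With the defaults (13 types, 9 markers each, 6 shared genes) the panel has
#' `13 * 9 + 6 + 1 = 124` genes, the size used for oligodendrocyte-lineage
#' mapping, and the default type names are the canonical lineage populations
#' OPC, COP, NFOL1/2, MFOL1/2, MOL1-6 and VLMC.
#'
#' @param n_types number of cell types (>= 2).
#' @param markers_per_type dedicated elevated genes per type (>= 1).
#' @param n_shared_genes genes elevated in >= 2 types (>= 0).
#' @param marker_level mean count of an elevated gene (per cell, arbitrary
#'   expression units); must exceed `off_level`.
#' @param off_level baseline mean of non-marker genes (>= 0).
#' @param seed integer seed.
#' @param type_ids optional character vector of type names.
#' @param pan_marker name of the pan-lineage marker gene.
#' @return An object of class `iss_profiles`: list with `gene_ids`,
#'   `type_ids`, `mean_expr` (genes x types matrix) and `pan_marker`.
#' @examples
#' pr <- make_reference_profiles(3, markers_per_type = 2, n_shared_genes = 1,
#'                               seed = 1)
#' dim(pr$mean_expr)
#' @export
make_reference_profiles <- function(n_types = 13, markers_per_type = 9,
                                    n_shared_genes = 6, marker_level = 3,
                                    off_level = 0.05, seed = 1,
                                    type_ids = NULL, pan_marker = "Plp1") {
  assert_that(n_types >= 2, "n_types must be >= 2")
  assert_that(markers_per_type >= 1, "markers_per_type must be >= 1")
  assert_that(n_shared_genes >= 0, "n_shared_genes must be >= 0")
  assert_that(marker_level > 0, "marker_level must be positive")
  assert_that(off_level >= 0, "off_level must be non-negative")
  assert_that(marker_level > off_level, "marker_level must exceed off_level")

  if (is.null(type_ids)) {
    type_ids <- if (n_types == 13) {
      c("OPC", "COP", "NFOL1", "NFOL2", "MFOL1", "MFOL2",
        paste0("MOL", 1:6), "VLMC")
    } else {
      sprintf("T%02d", seq_len(n_types))
    }
  }
  assert_that(length(type_ids) == n_types && !anyDuplicated(type_ids),
              "type_ids must be unique and of length n_types")

  marker_genes <- unlist(lapply(type_ids, function(t)
    sprintf("%s.mk%d", t, seq_len(markers_per_type))))
  shared_genes <- if (n_shared_genes > 0)
    sprintf("Shared%02d", seq_len(n_shared_genes)) else character(0)
  gene_ids <- c(pan_marker, marker_genes, shared_genes)
  assert_that(!anyDuplicated(gene_ids), "gene ids must be unique")

  m <- withr::with_seed(seed, {
    M <- matrix(off_level, nrow = length(gene_ids), ncol = n_types,
                dimnames = list(gene_ids, type_ids))
    # pan marker distinctly high across the whole lineage (the Plp1 role)
    M[pan_marker, ] <- 2 * marker_level * exp(rnorm(n_types, 0, 0.15))
    for (k in seq_len(n_types)) {
      rows <- sprintf("%s.mk%d", type_ids[k], seq_len(markers_per_type))
      M[rows, k] <- marker_level * exp(rnorm(markers_per_type, 0, 0.2))
    }
    for (g in shared_genes) {
      nt <- sample(2:min(4, n_types), 1)
      ks <- sample(n_types, nt)
      M[g, ks] <- 0.7 * marker_level * exp(rnorm(nt, 0, 0.2))
    }
    M
  })

  out <- structure(list(gene_ids = gene_ids, type_ids = type_ids,
                        mean_expr = m, pan_marker = pan_marker),
                   class = "iss_profiles")
  validate_profiles(out)
  out
}

validate_profiles <- function(x) {
  assert_that(inherits(x, "iss_profiles"), "not an iss_profiles object")
  assert_that(all(x$mean_expr >= 0), "mean_expr entries must be >= 0")
  assert_that(!anyDuplicated(x$gene_ids), "gene_ids must be unique")
  assert_that(!anyDuplicated(x$type_ids), "type_ids must be unique")
  assert_that(x$pan_marker %in% x$gene_ids, "pan_marker must be in gene_ids")
  assert_that(all(x$mean_expr[x$pan_marker, ] > 0),
              "pan_marker must have positive mean in every type")
  assert_that(all(apply(x$mean_expr, 2, function(v) any(v > 0))),
              "every type needs at least one positive-mean gene")
  invisible(x)
}

#' @export
print.iss_profiles <- function(x, ...) {
  cat(sprintf("Reference profiles: %d genes x %d types (pan marker: %s)\n",
              length(x$gene_ids), length(x$type_ids), x$pan_marker))
  invisible(x)
}

#' Write / read reference profiles as CSV
#'
#' The matrix is stored with one row per gene; the first column holds the
#' gene symbol and the remaining columns the per-type mean expression.
#'
#' @param profiles an `iss_profiles` object.
#' @param path file path.
#' @export
write_profiles <- function(profiles, path) {
  df <- data.frame(gene = profiles$gene_ids, profiles$mean_expr,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @param pan_marker pan-lineage marker gene (must be present in the file).
#' @export
read_profiles <- function(path, pan_marker = "Plp1") {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  out <- structure(list(gene_ids = df[[1]], type_ids = colnames(m),
                        mean_expr = m, pan_marker = pan_marker),
                   class = "iss_profiles")
  validate_profiles(out)
  out
}
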