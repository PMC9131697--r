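# Probabilistic cell typing. Spots are assigned hard to the nearest
# segmented-cell centroid within a radius; each cell's gene-count vector is
# then scored against the reference profiles with an independent-Poisson
# likelihood and a per-cell exposure equal to its total assigned count,
# giving a posterior probability vector over types (the per-cell "pie
# chart"). This is a deterministic, closed-form simplification of the joint
# pciSeq model; see the vignette.

#' Assign transcript spots to segmented cells
#'
#' Each spot is assigned to the nearest cell centroid (Euclidean distance)
#' if that distance is at most `max_radius`, otherwise it is labelled
#' background. Nearest centroids are found with a k-d tree
#' ([FNN::get.knnx()]).
#'
#' @param spots data frame with columns `spot_id`, `gene`, `x`, `y` (um).
#' @param cells data frame with columns `cell_id`, `x`, `y` (um).
#' @param max_radius maximum spot-to-centroid distance in um (> 0).
#' @param gene_ids gene universe for the count matrix columns; defaults to
#'   the sorted genes present in `spots`. Pass the panel's
#'   `profiles$gene_ids` so the matrix aligns with the reference profiles.
#' @return list with `assignment` (spot_id, cell_id or `NA` for background,
#'   distance) and `counts` (cells x genes integer matrix).
#' @export
assign_spots_to_cells <- function(spots, cells, max_radius = 15,
                                  gene_ids = NULL) {
  assert_that(max_radius > 0, "max_radius must be positive")
  gene_ids <- gene_ids %||% sort(unique(spots$gene))
  if (is.null(cells) || nrow(cells) == 0) {
    warning("empty cell table: all spots labelled background")
    return(list(
      assignment = data.frame(spot_id = spots$spot_id,
                              cell_id = NA_character_,
                              distance = NA_real_),
      counts = matrix(0L, 0, length(gene_ids),
                      dimnames = list(NULL, gene_ids))))
  }
  kn <- FNN::get.knnx(as.matrix(cells[, c("x", "y")]),
                      as.matrix(spots[, c("x", "y")]), k = 1)
  idx <- kn$nn.index[, 1]
  d <- kn$nn.dist[, 1]
  bg <- d > max_radius
  assignment <- data.frame(spot_id = spots$spot_id,
                           cell_id = ifelse(bg, NA_character_,
                                            cells$cell_id[idx]),
                           distance = d, stringsAsFactors = FALSE)
  counts <- table(factor(cells$cell_id[idx[!bg]], levels = cells$cell_id),
                  factor(spots$gene[!bg], levels = gene_ids))
  counts <- matrix(as.integer(counts), nrow = nrow(cells),
                   dimnames = list(cells$cell_id, gene_ids))
  list(assignment = assignment, counts = counts)
}

#' Posterior cell-type probabilities from gene counts
#'
#' For cell c with counts n_cg and total N_c, the likelihood of type k is an
#' independent Poisson per gene with mean `N_c * q_gk`, where `q_gk` is the
#' reference profile of type k, pseudocounted and normalized to sum to one
#' over genes. The posterior over types is computed in log space and each
#' row is normalized to 1; cells with no counts get the prior exactly.
#' Because profiles are normalized per type, the per-cell exposure
#' contributes equally to every type and cancels - only the transcript
#' identity mix discriminates.
#'
#' @param counts cells x genes matrix; columns must match the panel.
#' @param profiles an `iss_profiles` object.
#' @param prior probability vector over types (default uniform).
#' @param pseudocount added to every profile entry before normalization
#'   (> 0) so zero-profile genes have finite log-likelihood.
#' @return cells x types matrix of posterior probabilities, rows summing
#'   to 1.
#' @export
compute_type_posteriors <- function(counts, profiles, prior = NULL,
                                    pseudocount = 1e-3) {
  validate_profiles(profiles)
  assert_that(pseudocount > 0, "pseudocount must be positive")
  assert_that(!is.null(colnames(counts)) &&
                setequal(colnames(counts), profiles$gene_ids),
              "count matrix genes do not match the reference panel")
  counts <- counts[, profiles$gene_ids, drop = FALSE]
  K <- length(profiles$type_ids)
  prior <- prior %||% rep(1 / K, K)
  assert_that(length(prior) == K && all(prior > 0) &&
                abs(sum(prior) - 1) <= 1e-9,
              "prior must be a positive probability vector over types")

  q <- profiles$mean_expr + pseudocount
  q <- sweep(q, 2, colSums(q), "/")
  loglik <- counts %*% log(q)                      # cells x types
  lp <- sweep(loglik, 2, log(prior), "+")
  post <- exp(lp - apply(lp, 1, max))
  post <- post / rowSums(post)
  zero <- rowSums(counts) == 0
  if (any(zero)) post[zero, ] <- matrix(prior, sum(zero), K, byrow = TRUE)
  colnames(post) <- profiles$type_ids
  rownames(post) <- rownames(counts)
  post
}

#' Run spot assignment and typing in one step
#'
#' @inheritParams assign_spots_to_cells
#' @inheritParams compute_type_posteriors
#' @return An `iss_typing` object: `counts`, `posterior`, `assignment`,
#'   plus the panel's type order and pan marker.
#' @export
run_typing <- function(spots, cells, profiles, max_radius = 15,
                       prior = NULL, pseudocount = 1e-3) {
  asg <- assign_spots_to_cells(spots, cells, max_radius,
                               gene_ids = profiles$gene_ids)
  post <- compute_type_posteriors(asg$counts, profiles, prior, pseudocount)
  structure(list(counts = asg$counts, posterior = post,
                 assignment = asg$assignment,
                 type_ids = profiles$type_ids,
                 pan_marker = profiles$pan_marker),
            class = "iss_typing")
}

#' @export
print.iss_typing <- function(x, ...) {
  cat(sprintf("Typing result: %d cells x %d genes, %d types, %d/%d spots assigned\n",
              nrow(x$counts), ncol(x$counts), length(x$type_ids),
              sum(!is.na(x$assignment$cell_id)), nrow(x$assignment)))
  invisible(x)
}

#' Winner-takes-all cell calling with pan-marker gating
#'
#' Retains cells whose assigned pan-marker transcript count is at least
#' `min_pan_count` (the expressed-pan-marker gate), calls each retained cell
#' as the type with maximal posterior probability (ties broken by panel
#' order), and records that maximum. By default no probability cut is
#' applied; low-certainty cells are retained and reported, and
#' `min_probability` can optionally drop them.
#'
#' @param typing an `iss_typing` object.
#' @param cells the cell table used for typing (for coordinates/area/region).
#' @param min_pan_count minimum pan-marker transcripts (default 1).
#' @param min_probability optional minimum winning probability.
#' @param pan_marker pan-lineage gene (default from `typing`).
#' @return An `iss_called` data frame: `cell_id`, `x`, `y`, `area`,
#'   `region` (if present in `cells`), `called_type`, `max_probability`,
#'   `pan_count`. The panel's type order is kept in attribute `type_ids`.
#' @export
call_cells <- function(typing, cells, min_pan_count = 1,
                       min_probability = NULL, pan_marker = NULL) {
  pan_marker <- pan_marker %||% typing$pan_marker
  assert_that(pan_marker %in% colnames(typing$counts),
              "pan_marker not in the panel")
  pan <- typing$counts[, pan_marker]
  win <- max.col(typing$posterior, ties.method = "first")
  maxp <- typing$posterior[cbind(seq_len(nrow(typing$posterior)), win)]
  df <- data.frame(cell_id = rownames(typing$counts),
                   called_type = typing$type_ids[win],
                   max_probability = maxp,
                   pan_count = as.integer(pan),
                   stringsAsFactors = FALSE)
  keep <- df$pan_count >= min_pan_count
  if (!is.null(min_probability)) keep <- keep & df$max_probability >= min_probability
  df <- df[keep, , drop = FALSE]
  extra <- intersect(c("x", "y", "area", "region", "true_type"),
                     colnames(cells))
  df <- merge(df, cells[, c("cell_id", extra)], by = "cell_id", sort = FALSE)
  df <- df[order(df$cell_id), ]
  rownames(df) <- NULL
  structure(df, type_ids = typing$type_ids, class = c("iss_called",
                                                      class(df)))
}

#' Mean pie charts per called type
#'
#' Summarizes how each called population shares probability mass with the
#' others. The default reading averages the full posterior vectors over the
#' cells called as each type (rows sum to 1); `method = "top2"` instead
#' tabulates the runner-up type among those cells, the co-occurrence reading
#' of "how often a population is called with another".
#'
#' @param typing an `iss_typing` object.
#' @param called an `iss_called` data frame.
#' @param method `"mean_posterior"` (default) or `"top2"`.
#' @return types x types matrix; rows for called types with no cells are
#'   `NA` and listed in attribute `undefined`.
#' @export
mean_pie_charts <- function(typing, called,
                            method = c("mean_posterior", "top2")) {
  method <- match.arg(method)
  assert_that(nrow(called) > 0, "no called cells")
  types <- typing$type_ids
  post <- typing$posterior[called$cell_id, , drop = FALSE]
  out <- matrix(NA_real_, length(types), length(types),
                dimnames = list(called = types, type = types))
  if (method == "mean_posterior") {
    for (k in types) {
      idx <- called$called_type == k
      if (any(idx)) out[k, ] <- colMeans(post[idx, , drop = FALSE])
    }
  } else {
    p2 <- post
    win <- max.col(p2, ties.method = "first")
    p2[cbind(seq_len(nrow(p2)), win)] <- -Inf
    second <- types[max.col(p2, ties.method = "first")]
    for (k in types) {
      idx <- called$called_type == k
      if (any(idx))
        out[k, ] <- as.numeric(table(factor(second[idx], levels = types))) /
          sum(idx)
    }
  }
  undef <- types[rowSums(!is.na(out)) == 0]
  if (length(undef))
    warning("called types with no cells: ", paste(undef, collapse = ", "))
  attr(out, "undefined") <- undef
  out
}

#' Mean confusion matrix of the non-winning probability mass
#'
#' For each cell, the posterior restricted to the non-winning types is
#' renormalized to sum to 1; rows are the means of these vectors over cells
#' called as each type, so the matrix shows where residual probability mass
#' goes. The diagonal is zero. Cells with an exact one-hot posterior carry
#' no residual mass and are excluded; a row where all cells are one-hot is
#' `NA` and flagged.
#'
#' @inheritParams mean_pie_charts
#' @return types x types matrix with zero diagonal; undefined rows in
#'   attribute `undefined`.
#' @export
confusion_matrix <- function(typing, called) {
  assert_that(nrow(called) > 0, "no called cells")
  types <- typing$type_ids
  post <- typing$posterior[called$cell_id, , drop = FALSE]
  win <- match(called$called_type, types)
  p2 <- post
  p2[cbind(seq_len(nrow(p2)), win)] <- 0
  s <- rowSums(p2)
  contrib <- s > 0
  out <- matrix(NA_real_, length(types), length(types),
                dimnames = list(called = types, type = types))
  for (k in types) {
    idx <- called$called_type == k & contrib
    if (any(idx))
      out[k, ] <- colMeans(p2[idx, , drop = FALSE] / s[idx])
  }
  undef <- types[rowSums(!is.na(out)) == 0]
  if (length(undef))
    warning("confusion rows undefined (one-hot or absent): ",
            paste(undef, collapse = ", "))
  attr(out, "undefined") <- undef
  out
}
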