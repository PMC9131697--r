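# Shared fixtures, built in code at test time.

# Small three-type panel with unique markers and one shared gene.
tiny_profiles <- function(off_level = 0.05, n_shared = 1, seed = 42) {
  make_reference_profiles(n_types = 3, markers_per_type = 2,
                          n_shared_genes = n_shared, marker_level = 3,
                          off_level = off_level, seed = seed)
}

# Single square region of the given side (um), usable as GM or WM.
square_layout <- function(side = 1000, compartment = "WM",
                          name = "R1") {
  poly <- cbind(x = c(0, side, side, 0), y = c(0, 0, side, side))
  structure(list(regions = setNames(list(poly), name),
                 compartment = setNames(compartment, name),
                 depth_axis = NULL, layer_breaks = NULL, areas = NULL,
                 area_mm2 = setNames(side^2 / 1e6, name)),
            class = "iss_layout")
}

# Minimal typing object from an explicit posterior/count matrix.
fake_typing <- function(posterior, counts = NULL, pan_marker = "Plp1") {
  if (is.null(counts)) {
    counts <- matrix(1L, nrow(posterior), 1,
                     dimnames = list(rownames(posterior), pan_marker))
  }
  structure(list(counts = counts, posterior = posterior,
                 assignment = NULL, type_ids = colnames(posterior),
                 pan_marker = pan_marker), class = "iss_typing")
}

fake_called <- function(cell_id, called_type, type_ids,
                        x = NULL, y = NULL) {
  n <- length(cell_id)
  df <- data.frame(cell_id = cell_id, called_type = called_type,
                   x = x %||% rep(0, n), y = y %||% rep(0, n),
                   stringsAsFactors = FALSE)
  structure(df, type_ids = type_ids, class = c("iss_called", class(df)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force all-pairs nearest neighbor (independent oracle).
nn_oracle <- function(x, y) {
  D <- as.matrix(stats::dist(cbind(x, y)))
  diag(D) <- Inf
  idx <- apply(D, 1, which.min)
  list(index = unname(idx), distance = D[cbind(seq_along(idx), idx)])
}

# Direct per-type Poisson log-likelihood enumeration (independent oracle;
# keeps the factorial terms the implementation drops).
posterior_oracle <- function(counts_row, profiles, prior, pseudocount) {
  K <- length(profiles$type_ids)
  N <- sum(counts_row)
  ll <- vapply(seq_len(K), function(k) {
    q <- profiles$mean_expr[, k] + pseudocount
    q <- q / sum(q)
    sum(stats::dpois(counts_row, N * q, log = TRUE))
  }, numeric(1))
  w <- log(prior) + ll
  p <- exp(w - max(w))
  p / sum(p)
}
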