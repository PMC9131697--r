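# Abundance statistics of the called cell map: counts and densities per
# annotated region, relative occurrences per pan-marker-positive cells, the
# rate-of-change ratio between conditions, and ANOVA + Tukey group
# comparisons across tissue sections.

#' Count called cells per region and type
#'
#' Cells are assigned to regions by point-in-polygon containment of their
#' centroid (listed-order precedence); cells outside every polygon are
#' counted under `"unassigned"` rather than dropped.
#'
#' @param called an `iss_called` data frame (or any data frame with `x`,
#'   `y`, `called_type`).
#' @param layout an `iss_layout`.
#' @param types type universe for the output grid; defaults to the panel
#'   order carried by `called`, else the sorted observed types.
#' @return data frame with columns `region`, `type`, `count`, complete over
#'   the region x type grid.
#' @export
count_by_region <- function(called, layout, types = NULL) {
  types <- types %||% attr(called, "type_ids") %||%
    sort(unique(called$called_type))
  reg <- assign_region(called$x, called$y, layout)
  levs <- c(names(layout$regions), "unassigned")
  tab <- table(factor(reg, levels = levs),
               factor(called$called_type, levels = types))
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("region", "type", "count")
  out$count <- as.integer(out$count)
  out
}

#' Cells per square millimetre
#'
#' @param count cell counts.
#' @param area_mm2 region areas in mm^2 (recycled); must be positive.
#' @export
cell_density <- function(count, area_mm2) {
  assert_that(all(area_mm2 > 0), "region areas must be positive")
  count / area_mm2
}

#' Relative abundance as percent of total
#'
#' `100 * counts / sum(counts)`; used per (sample, region) so values are
#' percentages of the pan-marker-positive cells of that tissue. A zero
#' total yields `NA` with a warning.
#'
#' @param counts non-negative counts for one (sample, region).
#' @export
relative_abundance <- function(counts) {
  tot <- sum(counts)
  if (tot <= 0) {
    warning("zero total count: relative abundance undefined")
    return(rep(NA_real_, length(counts)))
  }
  100 * counts / tot
}

#' Full abundance table for one section
#'
#' Combines [count_by_region()], [cell_density()] and
#' [relative_abundance()]: per (region, type) the count, density in cells
#' per mm^2, and percentage of that region's called (pan-marker-positive)
#' cells. The `"unassigned"` bucket has no area and gets `NA` density.
#'
#' @inheritParams count_by_region
#' @param sample sample / section identifier stored in the first column.
#' @export
abundance_table <- function(called, layout, sample = "s1", types = NULL) {
  cnt <- count_by_region(called, layout, types)
  areas <- c(layout$area_mm2, unassigned = NA_real_)
  cnt$density <- ifelse(is.na(areas[cnt$region]), NA_real_,
                        cnt$count / areas[cnt$region])
  cnt$fraction <- NA_real_
  for (r in unique(cnt$region)) {
    idx <- cnt$region == r
    if (sum(cnt$count[idx]) > 0)
      cnt$fraction[idx] <- relative_abundance(cnt$count[idx])
  }
  data.frame(sample = sample, cnt, stringsAsFactors = FALSE)
}

#' Rate-of-change ratio between two conditions
#'
#' For a cell type measured in two conditions with `x` the larger and `y`
#' the smaller value, the percent increase toward the larger condition is
#' `100 - 100 / (x / y)`. The worked example: x = 30, y = 10 gives 66.66%,
#' i.e. the increase of 20 is 66.66% of x. The caller orients the pair;
#' `x < y` is an error, and `y <= 0` (type absent in one condition) yields
#' `NA` with a warning rather than a spurious 100%.
#'
#' @param x value in the larger condition (vectorized).
#' @param y value in the smaller condition.
#' @return percent increase in `[0, 100)`; 0 iff `x == y`.
#' @examples
#' change_ratio(30, 10)  # 66.66...
#' @export
change_ratio <- function(x, y) {
  assert_that(length(x) == length(y) || length(x) == 1 || length(y) == 1,
              "x and y lengths must be compatible")
  bad <- !is.na(x) & !is.na(y) & x < y
  assert_that(!any(bad), "x must be the larger condition (x >= y)")
  out <- 100 - 100 / (x / y)
  undef <- !is.na(y) & y <= 0
  if (any(undef)) {
    warning("change ratio undefined where the smaller condition is <= 0")
    out[undef] <- NA_real_
  }
  out
}

#' Significance stars
#'
#' `*`, `**`, `***`, `****` at p < 0.05, 0.01, 0.001, 0.0001; `"ns"`
#' otherwise, `""` for `NA`.
#' @param p p-values.
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), "",
    ifelse(p < 1e-4, "****",
      ifelse(p < 1e-3, "***",
        ifelse(p < 0.01, "**",
          ifelse(p < 0.05, "*", "ns")))))
}

#' Per-type group comparisons (one-way ANOVA + Tukey HSD)
#'
#' For every type, fits a one-way ANOVA of `value` across `group` over
#' samples and reports each pairwise contrast with the unadjusted pooled-SD
#' t-test p-value and the Tukey-adjusted p-value, plus significance stars on
#' the adjusted value. Contrasts involving a group with fewer than two
#' samples are flagged `not_testable`; zero residual variance is flagged
#' `degenerate` with `NA` p-values.
#'
#' @param df long data frame with at least columns `type`, `group`, `value`
#'   (one row per sample x type).
#' @param value,group,type_col column names.
#' @return data frame: `type`, `contrast`, `diff` (difference of group
#'   means), `p_raw`, `p_adj`, `stars`, `note`.
#' @export
compare_groups <- function(df, value = "value", group = "group",
                           type_col = "type") {
  out <- list()
  for (ty in unique(df[[type_col]])) {
    d <- df[df[[type_col]] == ty, ]
    g <- factor(d[[group]])
    v <- d[[value]]
    ok <- !is.na(v)
    g <- droplevels(g[ok]); v <- v[ok]
    ns <- table(g)
    combs <- if (nlevels(g) >= 2) combn(levels(g), 2) else
      matrix(character(0), 2, 0)
    if (ncol(combs) == 0) next
    small <- names(ns)[ns < 2]
    res <- data.frame(type = ty,
                      contrast = paste(combs[2, ], combs[1, ], sep = "-"),
                      diff = NA_real_, p_raw = NA_real_, p_adj = NA_real_,
                      stars = "", note = "", stringsAsFactors = FALSE)
    testable <- !(combs[1, ] %in% small | combs[2, ] %in% small)
    res$note[!testable] <- "not_testable"
    if (any(testable) && nlevels(g) >= 2) {
      means <- tapply(v, g, mean)
      res$diff <- means[combs[2, ]] - means[combs[1, ]]
      if (isTRUE(all.equal(stats::var(v), 0)) || length(v) <= nlevels(g)) {
        res$note[testable] <- "degenerate"
      } else {
        fit <- aov(v ~ g)
        if (summary(fit)[[1]]["Residuals", "Mean Sq"] <= 0) {
          res$note[testable] <- "degenerate"
        } else {
          tk <- TukeyHSD(fit)$g
          key <- paste(combs[2, ], combs[1, ], sep = "-")
          keyr <- paste(combs[1, ], combs[2, ], sep = "-")
          rn <- rownames(tk)
          padj <- tk[, "p adj"][match(key, rn)]
          padj[is.na(padj)] <- tk[, "p adj"][match(keyr, rn)][is.na(padj)]
          res$p_adj <- padj
          pt <- suppressWarnings(
            pairwise.t.test(v, g, p.adjust.method = "none"))$p.value
          praw <- mapply(function(a, b) {
            p1 <- if (b %in% rownames(pt) && a %in% colnames(pt))
              pt[b, a] else NA
            if (is.na(p1) && a %in% rownames(pt) && b %in% colnames(pt))
              p1 <- pt[a, b]
            p1
          }, combs[1, ], combs[2, ])
          res$p_raw <- as.numeric(praw)
          res$p_adj[!testable] <- NA
          res$p_raw[!testable] <- NA
          res$stars <- significance_stars(res$p_adj)
        }
      }
    }
    out[[length(out) + 1]] <- res
  }
  do.call(rbind, out)
}

#' Condition-change table (ratios + Tukey p-values)
#'
#' Per type, compares a value (relative occurrence or density) between two
#' conditions over samples: reports which condition is larger (direction),
#' the oriented [change_ratio()] of the condition means, and raw /
#' Tukey-adjusted p-values from [compare_groups()].
#'
#' @param df long data frame with columns `type`, `condition`, `sample`,
#'   and the value column.
#' @param x,y the two condition labels to compare.
#' @param value value column name.
#' @return data frame: `type`, `direction`, `mean_x`, `mean_y`, `ratio`,
#'   `p_raw`, `p_adj`, `stars`, `note`.
#' @export
condition_changes <- function(df, x, y, value = "fraction") {
  d <- df[df$condition %in% c(x, y), ]
  cg <- compare_groups(data.frame(type = d$type, group = d$condition,
                                  value = d[[value]]))
  out <- lapply(unique(d$type), function(ty) {
    di <- d[d$type == ty, ]
    mx <- mean(di[[value]][di$condition == x], na.rm = TRUE)
    my <- mean(di[[value]][di$condition == y], na.rm = TRUE)
    hi <- if (mx >= my) x else y
    a <- max(mx, my); b <- min(mx, my)
    ratio <- if (b > 0) 100 - 100 / (a / b) else NA_real_
    row <- cg[cg$type == ty, ][1, ]
    data.frame(type = ty, direction = hi, mean_x = mx, mean_y = my,
               ratio = ratio, p_raw = row$p_raw, p_adj = row$p_adj,
               stars = row$stars, note = row$note, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
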