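# Plain-CSV readers/writers for the pipeline's tabular interfaces.
# On-disk column names carry units (x_um, y_um, area_um2); in memory the
# package uses x, y, area.

#' Read and write pipeline tables
#'
#' Spot tables are stored as `spot_id,gene,x_um,y_um`; cell tables as
#' `cell_id,x_um,y_um,area_um2,region,true_type` (the last two optional);
#' called-cell tables as
#' `cell_id,x_um,y_um,region,called_type,max_probability,pan_count`.
#'
#' @param x the table to write.
#' @param path file path.
#' @name iss_io
NULL

#' @rdname iss_io
#' @export
write_spots <- function(x, path) {
  write.csv(data.frame(spot_id = x$spot_id, gene = x$gene,
                       x_um = x$x, y_um = x$y),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname iss_io
#' @export
read_spots <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  data.frame(spot_id = df$spot_id, gene = df$gene, x = df$x_um, y = df$y_um,
             stringsAsFactors = FALSE)
}

#' @rdname iss_io
#' @export
write_cells <- function(x, path) {
  out <- data.frame(cell_id = x$cell_id, x_um = x$x, y_um = x$y,
                    area_um2 = x$area)
  if (!is.null(x$region)) out$region <- x$region
  if (!is.null(x$true_type)) out$true_type <- x$true_type
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname iss_io
#' @export
read_cells <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  out <- data.frame(cell_id = df$cell_id, x = df$x_um, y = df$y_um,
                    area = df$area_um2, stringsAsFactors = FALSE)
  if (!is.null(df$region)) out$region <- df$region
  if (!is.null(df$true_type)) out$true_type <- df$true_type
  out
}

#' @rdname iss_io
#' @export
write_called_cells <- function(x, path) {
  out <- data.frame(cell_id = x$cell_id, x_um = x$x, y_um = x$y,
                    region = x$region %||% NA_character_,
                    called_type = x$called_type,
                    max_probability = x$max_probability,
                    pan_count = x$pan_count)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname iss_io
#' @param type_ids panel type order to attach to the called table.
#' @export
read_called_cells <- function(path, type_ids = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  out <- data.frame(cell_id = df$cell_id, x = df$x_um, y = df$y_um,
                    region = df$region, called_type = df$called_type,
                    max_probability = df$max_probability,
                    pan_count = df$pan_count, stringsAsFactors = FALSE)
  structure(out, type_ids = type_ids, class = c("iss_called", class(out)))
}

#' @rdname iss_io
#' @export
write_counts_matrix <- function(x, path) {
  write.csv(data.frame(cell_id = rownames(x), x, check.names = FALSE),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname iss_io
#' @export
read_counts_matrix <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
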