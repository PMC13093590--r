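#' Read occurrence points from CSV
#'
#' Reads a table of georeferenced occurrence records. Coordinates must be in
#' the same projected CRS (meters) as the rest of the analysis. If the file
#' has no id column, ids are assigned from row order.
#'
#' @param path path to a CSV file.
#' @param x_col,y_col names of the coordinate columns.
#' @param id_col optional name of an id column; ids must be unique.
#' @return A tibble with columns `id`, `x`, `y`, plus any remaining columns
#'   from the file.
#' @export
read_points_csv <- function(path, x_col = "x", y_col = "y", id_col = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0) {
    return(tibble::tibble(id = integer(), x = numeric(), y = numeric()))
  }
  for (col in c(x_col, y_col)) {
    if (!col %in% names(df)) {
      stop("column '", col, "' not found in ", path, call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad) > 0) {
      stop("non-numeric coordinate in column '", col, "' at row ", bad[1],
           call. = FALSE)
    }
    if (anyNA(v)) {
      stop("missing coordinate in column '", col, "' at row ",
           which(is.na(v))[1], call. = FALSE)
    }
    df[[col]] <- v
  }
  id <- if (!is.null(id_col)) {
    if (!id_col %in% names(df)) {
      stop("column '", id_col, "' not found in ", path, call. = FALSE)
    }
    if (anyDuplicated(df[[id_col]])) stop("ids are not unique", call. = FALSE)
    df[[id_col]]
  } else {
    seq_len(nrow(df))
  }
  extra <- setdiff(names(df), c(x_col, y_col, id_col))
  dplyr::bind_cols(
    tibble::tibble(id = id, x = df[[x_col]], y = df[[y_col]]),
    df[extra]
  )
}
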