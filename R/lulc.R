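#' Default NLCD consolidation table
#'
#' Maps the 15 NLCD classes of a rural northeastern landscape onto five
#' consolidated categories: open water; developed (open space plus low,
#' medium and high intensity); forest (deciduous, evergreen, mixed); grassland
#' (pasture/hay, cultivated crops, herbaceous, shrub/scrub, and barren land);
#' and wetland (woody plus emergent herbaceous). Consolidated classes are
#' coded 1-5 in that order.
#'
#' @return A tibble with columns `code` (NLCD), `class` (name) and
#'   `class_code` (1-5).
#' @export
nlcd_consolidation <- function() {
  tibble::tibble(
    code = c(11L, 21L, 22L, 23L, 24L, 31L, 41L, 42L, 43L, 52L, 71L, 81L,
             82L, 90L, 95L),
    class = c("open_water", "developed", "developed", "developed", "developed",
              "grassland", "forest", "forest", "forest", "grassland",
              "grassland", "grassland", "grassland", "wetland", "wetland")
  ) |>
    dplyr::mutate(class_code = match(
      .data$class,
      c("open_water", "developed", "forest", "grassland", "wetland")))
}

#' Consolidated class names in code order
#' @export
consolidated_classes <- function() {
  c("open_water", "developed", "forest", "grassland", "wetland")
}

#' Default landscape resistance table
#'
#' Integer resistance-to-movement values per NLCD class for a semiaquatic
#' wetland specialist, derived from landscape-genetic connectivity modelling
#' of the study species. Low values (open water 1, forest 6) indicate
#' preferred movement habitat; high values (developed 117, emergent wetlands
#' 466) resist movement. The NODATA code maps to `NA` (impassable).
#'
#' @return A tibble with columns `code` (NLCD) and `resistance`.
#' @export
default_resistance_table <- function() {
  tibble::tibble(
    code = c(0L, 11L, 21L, 22L, 23L, 24L, 31L, 41L, 42L, 43L, 52L, 71L,
             81L, 82L, 90L, 95L),
    resistance = c(NA, 1, 117, 117, 117, 117, 113, 6, 6, 6, 6, 30,
                   113, 2, 30, 466)
  )
}

#' NLCD wetland class codes (woody + emergent herbaceous)
#' @export
wetland_codes <- function() c(90L, 95L)

#' Consolidate an NLCD raster into five classes
#'
#' Per-cell lookup through a consolidation table; nodata cells are preserved.
#' Any raster code absent from the table is an error (a silent drop would
#' corrupt buffer compositions).
#'
#' @param raster a categorical [raster_grid()] of NLCD codes.
#' @param table a consolidation table as from [nlcd_consolidation()].
#' @return A [raster_grid()] of class codes 1-5.
#' @export
consolidate <- function(raster, table = nlcd_consolidation()) {
  stopifnot(inherits(raster, "raster_grid"))
  v <- raster$values
  present <- unique(v[!is.na(v)])
  unknown <- setdiff(present, table$code)
  if (length(unknown) > 0) {
    stop("raster codes not covered by consolidation table: ",
         paste(sort(unknown), collapse = ", "), call. = FALSE)
  }
  out <- raster
  idx <- match(v, table$code)
  out$values <- matrix(table$class_code[idx], nrow = nrow(v))
  out
}

#' Reclassify an NLCD raster into a resistance surface
#'
#' Per-cell lookup of integer resistance values. Codes mapped to `NA`
#' resistance (and nodata cells) become impassable cells.
#'
#' @param raster a categorical [raster_grid()] of NLCD codes.
#' @param table a resistance table with columns `code`, `resistance`
#'   (default [default_resistance_table()]).
#' @return A [raster_grid()] of resistance values.
#' @export
reclassify_resistance <- function(raster, table = default_resistance_table()) {
  stopifnot(inherits(raster, "raster_grid"))
  v <- raster$values
  present <- unique(v[!is.na(v)])
  unknown <- setdiff(present, table$code)
  if (length(unknown) > 0) {
    stop("raster codes not covered by resistance table: ",
         paste(sort(unknown), collapse = ", "), call. = FALSE)
  }
  out <- raster
  out$values <- matrix(table$resistance[match(v, table$code)], nrow = nrow(v))
  out
}
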