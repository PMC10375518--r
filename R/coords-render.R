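#' Pixel geometry of a rendered time-series image
#'
#' Every series is rendered on an identical canvas (1,000 x 666 px at
#' 96 dpi) with a fixed plot area, so that a single affine map converts
#' between dates and x-pixels for all images of a series batch. The plot
#' area defaults to 952 px wide: with the 7 px minimum-distance cutoff this
#' gives exactly 136 cutoff-width intervals per image, the quantity used as
#' the per-image true-negative budget by the evaluation stage.
#'
#' @param date_min,date_max First and last timepoint plotted.
#' @param image_width_px,image_height_px Canvas size in pixels.
#' @param plot_left,plot_right,plot_top,plot_bottom Pixel bounds of the
#'   plot area (x grows rightward, y downward from the top edge).
#' @param granularity Bin width of the series (`"day"`, `"week"`,
#'   `"month"`); used when converting a pixel back to the nearest
#'   timepoint-interval start.
#' @return An object of class `plot_coordinates`.
#' @export
plot_coordinates <- function(date_min, date_max,
                             image_width_px = 1000L,
                             image_height_px = 666L,
                             plot_left = 24, plot_right = 976,
                             plot_top = 20, plot_bottom = 626,
                             granularity = "day") {
  date_min <- as.Date(date_min)
  date_max <- as.Date(date_max)
  stopifnot(!is.na(date_min), !is.na(date_max), date_max >= date_min,
            plot_left >= 0, plot_right <= image_width_px,
            plot_right > plot_left,
            plot_top >= 0, plot_bottom <= image_height_px,
            plot_bottom > plot_top)
  structure(
    list(date_min = date_min, date_max = date_max,
         image_width_px = as.integer(image_width_px),
         image_height_px = as.integer(image_height_px),
         plot_left = plot_left, plot_right = plot_right,
         plot_top = plot_top, plot_bottom = plot_bottom,
         granularity = granularity),
    class = "plot_coordinates")
}

#' @export
print.plot_coordinates <- function(x, ...) {
  cat("<plot_coordinates> ", x$image_width_px, "x", x$image_height_px,
      " px; plot x ", x$plot_left, "..", x$plot_right, "; ",
      format(x$date_min), " .. ", format(x$date_max), "\n", sep = "")
  invisible(x)
}

#' Convert dates to x-pixels and back
#'
#' The map is affine and strictly increasing: `date_min` falls on the left
#' edge of the plot area and `date_max` on the right edge. `px_to_date()`
#' inverts it; with `round = TRUE` (the default) the result is snapped to
#' the start of the nearest timepoint interval at the coordinates'
#' granularity, so a consensus label always indexes a real timepoint.
#'
#' @param date Date vector within `[date_min, date_max]`.
#' @param coords A [plot_coordinates()] object.
#' @return `date_to_px()`: fractional x-pixels; `px_to_date()`: dates.
#' @export
date_to_px <- function(date, coords) {
  date <- as.Date(date)
  if (any(date < coords$date_min | date > coords$date_max, na.rm = TRUE)) {
    stop("date outside [date_min, date_max] of the plot", call. = FALSE)
  }
  span <- as.numeric(coords$date_max - coords$date_min)
  if (span == 0) {
    return(rep((coords$plot_left + coords$plot_right) / 2, length(date)))
  }
  frac <- as.numeric(date - coords$date_min) / span
  coords$plot_left + frac * (coords$plot_right - coords$plot_left)
}

#' @rdname date_to_px
#' @param x_px Fractional x-pixel positions inside the plot area.
#' @param round Snap to the nearest interval start (see Details).
#' @export
px_to_date <- function(x_px, coords, round = TRUE) {
  span <- as.numeric(coords$date_max - coords$date_min)
  frac <- (x_px - coords$plot_left) / (coords$plot_right - coords$plot_left)
  exact <- as.numeric(coords$date_min) + frac * span
  if (!round) {
    # fractional date, useful for round-trip checks
    return(structure(exact, class = "Date"))
  }
  lower <- bin_timepoints(as.Date(floor(exact), origin = "1970-01-01"),
                          coords$granularity)
  step <- switch(coords$granularity, day = 1, week = 7, month = 31)
  upper <- bin_timepoints(lower + step, coords$granularity)
  nearer_lower <- (exact - as.numeric(lower)) <= (as.numeric(upper) - exact)
  as.Date(ifelse(nearer_lower, as.numeric(lower), as.numeric(upper)),
          origin = "1970-01-01")
}

# Scale class of an aggregation function: frequency-like counts get a
# y-axis starting at 0 and ending no earlier than 10; percentages are
# always drawn 0-100; value-like functions use the data range.
function_scale <- function(fun) {
  counts <- c("n", "missing_n", "nonconformant_n", "midnight_n",
              "distinct", "subcat_n", "sum")
  percs <- c("missing_perc", "nonconformant_perc", "midnight_perc",
             "subcat_perc", "nonzero_perc")
  if (fun %in% counts) "count" else if (fun %in% percs) "percentage"
  else "value"
}

#' y-axis limits for a series under the fixed plotting rules
#'
#' Count-valued functions are plotted from 0 to at least 10; percentages
#' from 0 to 100; other functions span the data range. A subcategory count
#' series shares the y-scale of the whole-field count series via
#' `y_max_override`.
#'
#' @param values Numeric series values (may contain NA).
#' @param fun Aggregation-function label.
#' @param y_max_override Optional upper limit (e.g. the field-level count
#'   maximum, for `subcat_n`).
#' @return Length-2 numeric `c(ymin, ymax)`.
#' @export
y_limits_for <- function(values, fun, y_max_override = NULL) {
  sc <- function_scale(fun)
  vmax <- suppressWarnings(max(values, na.rm = TRUE))
  if (!is.finite(vmax)) vmax <- 0
  if (sc == "percentage") return(c(0, 100))
  if (sc == "count") {
    top <- max(10, vmax, y_max_override %||% 0)
    return(c(0, top))
  }
  vmin <- suppressWarnings(min(values, na.rm = TRUE))
  if (!is.finite(vmin)) vmin <- 0
  if (vmin == vmax) vmax <- vmin + 1
  c(vmin, vmax)
}

#' Render one time series to a fixed-geometry PNG
#'
#' Draws the series as a scatter of points on the standard 1,000 x 666 px
#' canvas at 96 dpi, with the y-axis rules of [y_limits_for()] and NA
#' values shown as gaps (absent points). No metadata is drawn inside the
#' plot area. The pixel geometry of the result is exactly the
#' [plot_coordinates()] passed in, so annotations made on the image can be
#' converted back to dates.
#'
#' @param timepoints Date vector (the gap-free series index).
#' @param values Numeric values, NA allowed.
#' @param fun Aggregation-function label (drives the y-scale rules).
#' @param path Output PNG path.
#' @param coords Optional [plot_coordinates()]; defaults to the standard
#'   geometry for the series' date range.
#' @param y_max_override See [y_limits_for()].
#' @return The [plot_coordinates()] used, invisibly.
#' @export
render_series <- function(timepoints, values, fun, path,
                          coords = NULL, y_max_override = NULL) {
  stopifnot(length(timepoints) == length(values), length(timepoints) > 0)
  timepoints <- as.Date(timepoints)
  if (is.null(coords)) {
    coords <- plot_coordinates(min(timepoints), max(timepoints))
  }
  ylim <- y_limits_for(values, fun, y_max_override)
  dpi <- 96
  grDevices::png(path, width = coords$image_width_px,
                 height = coords$image_height_px, res = dpi,
                 type = "cairo")
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mai = c(coords$image_height_px - coords$plot_bottom,
                        coords$plot_left,
                        coords$plot_top,
                        coords$image_width_px - coords$plot_right) / dpi,
                xaxs = "i", yaxs = "i")
  graphics::plot.new()
  graphics::plot.window(xlim = as.numeric(c(coords$date_min,
                                            coords$date_max)),
                        ylim = ylim)
  graphics::box()
  ok <- !is.na(values)
  graphics::points(as.numeric(timepoints)[ok], values[ok],
                   pch = 16, cex = 0.4, col = "#1f4e79")
  invisible(coords)
}

#' Write/read a coordinates manifest CSV
#'
#' The manifest records, per image id, every parameter needed to convert an
#' annotation pixel back to a date bit-identically: canvas size, plot-area
#' bounds, date range and granularity.
#'
#' @param manifest Tibble with columns `image_id` plus the
#'   [plot_coordinates()] fields, or a named list of `plot_coordinates`.
#' @param path CSV path.
#' @return `path` invisibly; the reader returns a named list of
#'   `plot_coordinates` keyed by image id.
#' @export
write_coords_manifest <- function(manifest, path) {
  if (is.list(manifest) && !is.data.frame(manifest)) {
    manifest <- dplyr::bind_rows(lapply(names(manifest), function(id) {
      co <- manifest[[id]]
      tibble::tibble(image_id = id,
                     date_min = co$date_min, date_max = co$date_max,
                     image_width_px = co$image_width_px,
                     image_height_px = co$image_height_px,
                     plot_left = co$plot_left, plot_right = co$plot_right,
                     plot_top = co$plot_top, plot_bottom = co$plot_bottom,
                     granularity = co$granularity)
    }))
  }
  readr::write_csv(manifest, path, na = "")
  invisible(path)
}

#' @rdname write_coords_manifest
#' @export
read_coords_manifest <- function(path) {
  df <- readr::read_csv(path, na = "", show_col_types = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    plot_coordinates(df$date_min[i], df$date_max[i],
                     df$image_width_px[i], df$image_height_px[i],
                     df$plot_left[i], df$plot_right[i],
                     df$plot_top[i], df$plot_bottom[i],
                     df$granularity[i])
  })
  names(out) <- df$image_id
  out
}
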