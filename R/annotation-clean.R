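#' Cleaning rules for raw annotation lines
#'
#' @param min_distance_cutoff_px Pixel distance below which two lines by
#'   the same person are treated as the same change point (default 7).
#' @param max_people_per_image Retirement cap: only the first
#'   `max_people_per_image` distinct people (by earliest attempt) count per
#'   image (default 41).
#' @return An object of class `cleaning_config`.
#' @export
cleaning_config <- function(min_distance_cutoff_px = 7,
                            max_people_per_image = 41L) {
  stopifnot(min_distance_cutoff_px > 0, max_people_per_image >= 1)
  structure(list(min_distance_cutoff_px = min_distance_cutoff_px,
                 max_people_per_image = as.integer(max_people_per_image)),
            class = "cleaning_config")
}

#' Keep only each person's first classification, capped per image
#'
#' The serving platform may show the same image to a person more than once
#' and may collect more classifications than the retirement threshold. For
#' each (image, person), only lines from the earliest classification are
#' kept (ties broken by classification id); then only the first
#' `max_people_per_image` distinct people per image, ordered by their
#' earliest attempt time, are retained.
#'
#' @param lines Annotation-line tibble with columns `image_id`,
#'   `person_id`, `classification_id`, `attempt_time`, `x_px`, `colour`.
#' @param config A [cleaning_config()].
#' @return Filtered tibble of lines.
#' @export
keep_first_attempts <- function(lines, config = cleaning_config()) {
  if (nrow(lines) == 0) return(lines)
  first_cls <- lines |>
    dplyr::group_by(.data$image_id, .data$person_id) |>
    dplyr::slice_min(dplyr::pick("attempt_time", "classification_id"),
                     n = 1, with_ties = TRUE) |>
    dplyr::ungroup()
  # lines of the winning classification only (slice_min keeps ties on the
  # composite key, i.e. all lines of that one classification)
  kept_people <- first_cls |>
    dplyr::distinct(.data$image_id, .data$person_id, .data$attempt_time,
                    .data$classification_id) |>
    dplyr::group_by(.data$image_id) |>
    dplyr::arrange(.data$attempt_time, .data$classification_id,
                   .by_group = TRUE) |>
    dplyr::slice_head(n = config$max_people_per_image) |>
    dplyr::ungroup() |>
    dplyr::select("image_id", "person_id")
  dplyr::semi_join(first_cls, kept_people,
                   by = c("image_id", "person_id"))
}

#' Merge near-coincident lines drawn by the same person
#'
#' Within each (image, person), lines closer together than the minimum
#' distance cutoff are taken to mark the same change point and are merged
#' into a single line at the unweighted mean of all contributing
#' positions. Merging is transitive (connected components of the
#' strictly-closer-than-cutoff graph), so chains collapse to one line.
#' If any contributing line is green (certain), the merged line is green;
#' lines exactly the cutoff apart remain distinct.
#'
#' @inheritParams keep_first_attempts
#' @return Tibble of lines with merged positions; column `n_merged` gives
#'   the number of raw lines contributing to each output line.
#' @export
merge_same_person <- function(lines, config = cleaning_config()) {
  if (nrow(lines) == 0) {
    return(dplyr::mutate(lines, n_merged = integer()))
  }
  cutoff <- config$min_distance_cutoff_px
  lines |>
    dplyr::group_by(.data$image_id, .data$person_id) |>
    dplyr::group_modify(function(df, key) {
      comp <- chain_components(df$x_px, cutoff)
      df |>
        dplyr::mutate(.comp = comp) |>
        dplyr::group_by(.data$.comp) |>
        dplyr::summarise(
          classification_id = min(.data$classification_id),
          attempt_time = min(.data$attempt_time),
          x_px = mean(.data$x_px),
          colour = if (any(.data$colour == "green")) "green" else "yellow",
          n_merged = dplyr::n(), .groups = "drop") |>
        dplyr::select(-".comp")
    }) |>
    dplyr::ungroup()
}

# Connected components of the "strictly closer than cutoff" graph on a 1-D
# point set: after sorting, components are maximal runs of consecutive
# points with gap < cutoff.
chain_components <- function(x, cutoff) {
  ord <- order(x)
  gaps <- diff(x[ord])
  comp_sorted <- cumsum(c(1L, as.integer(gaps >= cutoff)))
  comp <- integer(length(x))
  comp[ord] <- comp_sorted
  comp
}

#' Apply the full cleaning sequence
#'
#' [keep_first_attempts()] followed by [merge_same_person()], with a log of
#' line counts at each step.
#'
#' @inheritParams keep_first_attempts
#' @param quiet Suppress the per-step message.
#' @return Cleaned line tibble with attribute `cleaning_log` (named counts:
#'   `raw`, `after_first_attempts`, `after_merging`).
#' @export
clean_annotations <- function(lines, config = cleaning_config(),
                              quiet = FALSE) {
  n_raw <- nrow(lines)
  first <- keep_first_attempts(lines, config)
  merged <- merge_same_person(first, config)
  log <- c(raw = n_raw, after_first_attempts = nrow(first),
           after_merging = nrow(merged))
  if (!quiet) {
    message("annotation cleaning: ", n_raw, " lines in, ",
            nrow(first), " after first-attempt filter, ",
            nrow(merged), " after same-person merging")
  }
  attr(merged, "cleaning_log") <- log
  merged
}

#' Read a Zooniverse-style classification export
#'
#' One row per classification; the drawn lines live in a JSON `annotations`
#' payload (a list of tasks, each with a `value` array of drawn marks
#' carrying an `x` position and a `tool` index, tool 0 = green / certain,
#' tool 1 = yellow / uncertain). Extra columns and extra JSON keys are
#' tolerated; classifications with no drawn lines contribute no rows.
#'
#' @param path Export CSV with at least `classification_id`, `user_name`
#'   (or `user_id`), `created_at`, `subject_ids` and `annotations` columns.
#' @return Annotation-line tibble (`image_id`, `person_id`,
#'   `classification_id`, `attempt_time`, `x_px`, `colour`).
#' @export
read_zooniverse_export <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  need <- c("classification_id", "created_at", "subject_ids", "annotations")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("export is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  person <- df$user_name %||% df$user_id
  if (is.null(person)) stop("export needs user_name or user_id",
                            call. = FALSE)
  rows <- lapply(seq_len(nrow(df)), function(i) {
    ann <- jsonlite::fromJSON(df$annotations[i], simplifyVector = FALSE)
    marks <- list()
    for (task in ann) {
      vals <- task$value
      if (is.list(vals)) {
        marks <- c(marks, Filter(function(m) !is.null(m$x), vals))
      }
    }
    if (length(marks) == 0) return(NULL)
    tibble::tibble(
      image_id = df$subject_ids[i],
      person_id = person[i],
      classification_id = as.integer(df$classification_id[i]),
      attempt_time = parse_datetime_vec(df$created_at[i]),
      x_px = vapply(marks, function(m) as.numeric(m$x), numeric(1)),
      colour = vapply(marks, function(m) {
        if (identical(as.integer(m$tool %||% 0L), 1L)) "yellow" else "green"
      }, character(1))
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) empty_annotations() else out
}

#' Read/write the plain per-line annotation CSV dialect
#'
#' One row per drawn line with ISO-8601 attempt timestamps; the natural
#' interchange format between pipeline stages.
#'
#' @param path CSV path.
#' @return The reader returns an annotation-line tibble; the writer returns
#'   `path` invisibly.
#' @export
read_annotation_csv <- function(path) {
  readr::read_csv(path, na = "", show_col_types = FALSE,
                  col_types = readr::cols(
                    image_id = "c", person_id = "c",
                    classification_id = "i",
                    attempt_time = readr::col_datetime(),
                    x_px = "d", colour = "c"))
}

#' @rdname read_annotation_csv
#' @param lines Annotation-line tibble.
#' @export
write_annotation_csv <- function(lines, path) {
  out <- lines
  out$attempt_time <- format(out$attempt_time, "%Y-%m-%d %H:%M:%S",
                             tz = "UTC")
  readr::write_csv(out, path, na = "")
  invisible(path)
}
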