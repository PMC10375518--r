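#' Describe one field of a record extract
#'
#' A field specification carries the field's name, its semantic type (which
#' determines the set of aggregation functions applied to it), and optional
#' generator settings used by [generate_extract()].
#'
#' @param name Field name (string).
#' @param field_type One of `"Timepoint"`, `"Numeric"`, `"Categorical"`,
#'   `"Datetime"`, `"UniqueIdentifier"`, `"Freetext"`.
#' @param has_time_element Logical; whether values carry a time-of-day
#'   component. Only meaningful for Timepoint and Datetime fields, where it
#'   enables the `midnight_n`/`midnight_perc` series.
#' @param subcategories Optional character vector of category values for a
#'   Categorical field (used by the generator; observed values are used
#'   during aggregation).
#' @param mean,sd Baseline normal distribution for a Numeric field
#'   (generator only). Change-point magnitudes are expressed in units of
#'   this baseline `sd`.
#' @param missing_rate Probability a generated value is missing.
#' @return An object of class `field_spec`.
#' @export
field_spec <- function(name, field_type,
                       has_time_element = FALSE,
                       subcategories = NULL,
                       mean = 50, sd = 10,
                       missing_rate = 0.05) {
  field_types <- c("Timepoint", "Numeric", "Categorical", "Datetime",
                   "UniqueIdentifier", "Freetext")
  if (!field_type %in% field_types) {
    stop("Unknown field_type '", field_type, "'; must be one of: ",
         paste(field_types, collapse = ", "), call. = FALSE)
  }
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            missing_rate >= 0, missing_rate <= 1, sd >= 0)
  structure(
    list(name = name, field_type = field_type,
         has_time_element = isTRUE(has_time_element),
         subcategories = subcategories,
         mean = mean, sd = sd, missing_rate = missing_rate),
    class = "field_spec"
  )
}

#' @export
print.field_spec <- function(x, ...) {
  cat("<field_spec> ", x$name, " [", x$field_type, "]\n", sep = "")
  invisible(x)
}

#' Define a ground-truth change point for the synthetic generator
#'
#' The five kinds mirror the ways a time series can change abruptly:
#' a shift in level, a break in trend, a change in (vertical) variability,
#' a run of absent data points, or an isolated outlier.
#'
#' @param position Date at which the change occurs.
#' @param kind One of `"level"`, `"trend"`, `"variability"`, `"presence"`,
#'   `"outlier"`.
#' @param magnitude Dimensionless effect size, in units of the target
#'   field's baseline standard deviation (for `"variability"`, the factor by
#'   which the SD is multiplied from `position` onward).
#' @param field Name of the Numeric field the change applies to, or `NA` for
#'   extract-level changes (`"presence"` with `field = NA` removes whole
#'   records). Defaults to `NA`.
#' @param gap_days For `"presence"`: number of consecutive empty days
#'   starting at `position`.
#' @param series_id Optional identifier linking the truth to an image/series.
#' @return An object of class `change_point_truth`.
#' @export
change_point_truth <- function(position, kind, magnitude = 5,
                               field = NA_character_, gap_days = 7L,
                               series_id = NA_character_) {
  kinds <- c("level", "trend", "variability", "presence", "outlier")
  if (!kind %in% kinds) {
    stop("Unknown change-point kind '", kind, "'; must be one of: ",
         paste(kinds, collapse = ", "), call. = FALSE)
  }
  position <- as.Date(position)
  stopifnot(!is.na(position), is.numeric(magnitude), gap_days >= 1)
  structure(
    list(position = position, kind = kind, magnitude = magnitude,
         field = field, gap_days = as.integer(gap_days),
         series_id = series_id),
    class = "change_point_truth"
  )
}

#' Parameters of the simulated volunteer population
#'
#' Volunteers are modelled as independent and identically distributed: each
#' one inspects the image, detects each true change point independently with
#' probability `detect_prob`, draws the line with Gaussian pixel jitter, is
#' uncertain (yellow line) with probability `uncertain_prob`, and adds a
#' Poisson number of spurious lines placed uniformly across the plot area.
#' With probability `repeat_prob` the platform serves the volunteer the same
#' image again and an independent second classification is recorded, which
#' downstream first-attempt filtering must discard.
#'
#' @param n_volunteers Number of distinct volunteers classifying each image.
#' @param detect_prob Per-change-point, per-volunteer detection probability.
#' @param jitter_sd Standard deviation (pixels) of line-placement jitter.
#' @param uncertain_prob Probability a drawn line is yellow (uncertain).
#' @param noise_rate Expected number of spurious lines per volunteer per
#'   image.
#' @param repeat_prob Probability of a repeat classification by the same
#'   volunteer.
#' @return An object of class `volunteer_model`.
#' @export
volunteer_model <- function(n_volunteers = 41L, detect_prob = 0.8,
                            jitter_sd = 2, uncertain_prob = 0.1,
                            noise_rate = 0.3, repeat_prob = 0.05) {
  probs <- c(detect_prob, uncertain_prob, repeat_prob)
  stopifnot(all(probs >= 0 & probs <= 1), jitter_sd >= 0, noise_rate >= 0,
            n_volunteers >= 0)
  structure(
    list(n_volunteers = as.integer(n_volunteers), detect_prob = detect_prob,
         jitter_sd = jitter_sd, uncertain_prob = uncertain_prob,
         noise_rate = noise_rate, repeat_prob = repeat_prob),
    class = "volunteer_model"
  )
}

#' Generate a typed record extract with injected change points
#'
#' Simulates a record table in the shape of an EHR extract: one timepoint
#' field plus any number of typed data fields, with `n_per_day` records per
#' day across `date_span`. Each [change_point_truth()] perturbs generation
#' from its position onward: `level` adds `magnitude * sd` to the target
#' field's mean, `trend` adds a linear drift of `magnitude * sd` per 30
#' days, `variability` multiplies the SD by `magnitude`, `presence` empties
#' `gap_days` consecutive days (whole records when `field` is `NA`, else
#' just the target field), and `outlier` shifts a single day by
#' `magnitude * sd`.
#'
#' @param fields List of [field_spec()] objects; exactly one must have
#'   `field_type == "Timepoint"`.
#' @param date_span Length-2 Date vector, first and last day inclusive.
#' @param truths List of [change_point_truth()] objects (may be empty).
#' @param seed Integer RNG seed; identical seeds give identical extracts.
#' @param n_per_day Records generated per day.
#' @param extract_id Identifier stored on the result.
#' @return A tibble of records with attributes `fields`, `extract_id`,
#'   `timepoint_field` and `truths`; class `record_table`.
#' @export
generate_extract <- function(fields, date_span, truths = list(), seed = 1L,
                             n_per_day = 50L, extract_id = "synthetic") {
  types <- vapply(fields, function(f) f$field_type, character(1))
  tp_idx <- which(types == "Timepoint")
  if (length(tp_idx) != 1L) {
    stop("`fields` must contain exactly one Timepoint field", call. = FALSE)
  }
  date_span <- as.Date(date_span)
  stopifnot(length(date_span) == 2L, !anyNA(date_span),
            date_span[2] >= date_span[1])
  if (inherits(truths, "change_point_truth")) truths <- list(truths)
  for (tr in truths) {
    if (tr$position < date_span[1] || tr$position > date_span[2]) {
      stop("change-point position ", format(tr$position),
           " lies outside the date span", call. = FALSE)
    }
  }

  days <- seq(date_span[1], date_span[2], by = "day")
  tp_field <- fields[[tp_idx]]
  data_fields <- fields[-tp_idx]

  out <- withr::with_seed(as.integer(seed), {
    # which days are emptied entirely by record-level presence gaps
    drop_day <- rep(FALSE, length(days))
    for (tr in truths) {
      if (tr$kind == "presence" && is.na(tr$field)) {
        gap <- days >= tr$position & days < tr$position + tr$gap_days
        drop_day <- drop_day | gap
      }
    }
    keep_days <- days[!drop_day]
    n_rec <- length(keep_days) * n_per_day
    day_of <- rep(keep_days, each = n_per_day)

    tod <- if (tp_field$has_time_element) {
      stats::runif(n_rec, 0, 86399)
    } else {
      rep(0, n_rec)
    }
    rec <- tibble::tibble(
      !!tp_field$name := as.POSIXct(day_of, tz = "UTC") + tod
    )

    for (f in data_fields) {
      rec[[f$name]] <- generate_field_values(f, day_of, truths)
    }
    rec
  })

  structure(out,
            class = c("record_table", class(out)),
            fields = fields,
            extract_id = extract_id,
            timepoint_field = tp_field$name,
            truths = truths)
}

# Per-field value generation; `day_of` is the record's day, used to apply
# change-point effects positioned in time.
generate_field_values <- function(f, day_of, truths) {
  n <- length(day_of)
  vals <- switch(
    f$field_type,
    Numeric = {
      mu <- rep(f$mean, n)
      sigma <- rep(f$sd, n)
      for (tr in truths) {
        if (!is.na(tr$field) && tr$field != f$name) next
        after <- day_of >= tr$position
        if (tr$kind == "level") {
          mu[after] <- mu[after] + tr$magnitude * f$sd
        } else if (tr$kind == "trend") {
          mu[after] <- mu[after] +
            tr$magnitude * f$sd *
            as.numeric(day_of[after] - tr$position) / 30
        } else if (tr$kind == "variability") {
          sigma[after] <- sigma[after] * tr$magnitude
        } else if (tr$kind == "outlier") {
          on_day <- day_of == tr$position
          mu[on_day] <- mu[on_day] + tr$magnitude * f$sd
        }
      }
      formatC(stats::rnorm(n, mu, sigma), format = "f", digits = 4)
    },
    Categorical = {
      cats <- f$subcategories %||% c("A", "B", "C")
      sample(cats, n, replace = TRUE)
    },
    Datetime = {
      d <- as.POSIXct(day_of, tz = "UTC") -
        stats::runif(n, 0, 30 * 86400)
      format(d, "%Y-%m-%d %H:%M:%S")
    },
    UniqueIdentifier = sprintf("ID%08d", sample.int(.Machine$integer.max, n)),
    Freetext = replicate(n, paste(sample(letters, 8, TRUE), collapse = "")),
    stop("Unknown field_type '", f$field_type, "'", call. = FALSE)
  )
  if (f$missing_rate > 0) {
    vals[stats::runif(n) < f$missing_rate] <- NA_character_
  }
  # field-level presence gaps blank the field, leaving the record in place
  for (tr in truths) {
    if (tr$kind == "presence" && !is.na(tr$field) && tr$field == f$name) {
      gap <- day_of >= tr$position & day_of < tr$position + tr$gap_days
      vals[gap] <- NA_character_
    }
  }
  vals
}

#' Simulate volunteer annotation lines for one image
#'
#' Applies a [volunteer_model()] to a set of true change points rendered at
#' known pixel positions: each volunteer detects each truth independently,
#' drawing a vertical line at the truth's pixel plus Gaussian jitter
#' (clamped to the plot area), coloured yellow with `uncertain_prob` and
#' green otherwise; spurious lines arrive as a Poisson count per volunteer,
#' placed uniformly across the plot area. Repeat classifications (second,
#' independent attempts by the same volunteer) are emitted with
#' `repeat_prob` so first-attempt filtering can be exercised.
#'
#' @param truth_px Numeric vector of true change-point x-pixels (inside the
#'   plot area).
#' @param coords A [plot_coordinates()] object.
#' @param model A [volunteer_model()].
#' @param image_id Image identifier stamped on every line.
#' @param seed Integer RNG seed.
#' @return A tibble of annotation lines: `image_id`, `person_id`,
#'   `classification_id`, `attempt_time`, `x_px`, `colour`.
#' @export
simulate_annotations <- function(truth_px, coords, model,
                                 image_id = "img-1", seed = 1L) {
  stopifnot(inherits(model, "volunteer_model"))
  if (length(truth_px) > 0) {
    if (any(truth_px < coords$plot_left | truth_px > coords$plot_right)) {
      stop("truth positions must lie inside the plot area", call. = FALSE)
    }
  }
  if (model$n_volunteers == 0L) return(empty_annotations())

  withr::with_seed(as.integer(seed), {
    t0 <- as.POSIXct("2022-01-01 00:00:00", tz = "UTC")
    cls_id <- 0L
    rows <- vector("list", model$n_volunteers * 2L)
    k <- 0L
    for (v in seq_len(model$n_volunteers)) {
      person <- sprintf("vol-%04d", v)
      n_attempts <- 1L + stats::rbinom(1L, 1L, model$repeat_prob)
      for (a in seq_len(n_attempts)) {
        cls_id <- cls_id + 1L
        attempt_time <- t0 + (v * 60) + (a - 1L) * 86400 +
          stats::runif(1, 0, 30)
        xs <- numeric(0)
        if (length(truth_px) > 0) {
          hit <- stats::runif(length(truth_px)) < model$detect_prob
          xs <- truth_px[hit] +
            stats::rnorm(sum(hit), 0, model$jitter_sd)
        }
        n_noise <- stats::rpois(1L, model$noise_rate)
        xs <- c(xs, stats::runif(n_noise, coords$plot_left,
                                 coords$plot_right))
        if (length(xs) == 0) next
        xs <- pmin(pmax(xs, coords$plot_left), coords$plot_right)
        colour <- ifelse(stats::runif(length(xs)) < model$uncertain_prob,
                         "yellow", "green")
        k <- k + 1L
        rows[[k]] <- tibble::tibble(
          image_id = image_id, person_id = person,
          classification_id = cls_id, attempt_time = attempt_time,
          x_px = xs, colour = colour
        )
      }
    }
    if (k == 0L) empty_annotations() else dplyr::bind_rows(rows[seq_len(k)])
  })
}

empty_annotations <- function() {
  tibble::tibble(image_id = character(), person_id = character(),
                 classification_id = integer(),
                 attempt_time = as.POSIXct(character(), tz = "UTC"),
                 x_px = numeric(), colour = character())
}

#' Write ground-truth change points to CSV (ISO-8601 dates)
#' @param truths List of [change_point_truth()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_truths_csv <- function(truths, path) {
  df <- dplyr::bind_rows(lapply(truths, function(tr) {
    tibble::tibble(series_id = tr$series_id,
                   position = format(tr$position, "%Y-%m-%d"),
                   kind = tr$kind, magnitude = tr$magnitude,
                   field = tr$field, gap_days = tr$gap_days)
  }))
  readr::write_csv(df, path, na = "")
  invisible(path)
}

#' Read ground-truth change points from CSV
#' @param path CSV produced by [write_truths_csv()].
#' @return List of [change_point_truth()] objects.
#' @export
read_truths_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    change_point_truth(position = df$position[i], kind = df$kind[i],
                       magnitude = df$magnitude[i],
                       field = if (is.na(df$field[i])) NA_character_
                               else df$field[i],
                       gap_days = df$gap_days[i],
                       series_id = df$series_id[i])
  })
}
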