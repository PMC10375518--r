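#' Prepare a record extract for aggregation
#'
#' Drops rows whose timepoint value is missing or unparseable (such records
#' cannot be assigned to any temporal bin), removes exact duplicate rows
#' keeping one copy, and retains per-day counts of removed duplicates as
#' the source for the extract-level duplicate-record series (`sum`,
#' `nonzero_perc`).
#'
#' @param records A `record_table` (tibble with `fields`, `extract_id` and
#'   `timepoint_field` attributes), e.g. from [generate_extract()] or
#'   [read_extract_csv()].
#' @return A list with elements `records` (cleaned table, with a parsed
#'   `.timepoint` POSIXct column added), `duplicate_counts` (tibble `day`,
#'   `removed`, `total_rows`: removed duplicates and pre-dedup row counts
#'   per day) and `n_excluded` (rows dropped for invalid timepoints).
#' @export
prepare_extract <- function(records) {
  tp_field <- attr(records, "timepoint_field")
  stopifnot(!is.null(tp_field))
  fields <- attr(records, "fields")
  extract_id <- attr(records, "extract_id")

  tp <- parse_datetime_vec(records[[tp_field]])
  n_excluded <- sum(is.na(tp))
  keep <- !is.na(tp)
  if (!any(keep)) {
    stop("no records with a valid timepoint value remain; empty extract",
         call. = FALSE)
  }
  rec <- records[keep, , drop = FALSE]
  tp <- tp[keep]
  rec$.timepoint <- tp
  rec$.day <- as.Date(tp, tz = "UTC")

  dup <- duplicated(rec[setdiff(names(rec), ".day")])
  pre <- dplyr::count(tibble::tibble(day = rec$.day), .data$day,
                      name = "total_rows")
  removed <- dplyr::count(tibble::tibble(day = rec$.day[dup]), .data$day,
                          name = "removed")
  dup_counts <- dplyr::left_join(pre, removed, by = "day")
  dup_counts$removed[is.na(dup_counts$removed)] <- 0L

  rec <- rec[!dup, , drop = FALSE]
  attr(rec, "fields") <- fields
  attr(rec, "extract_id") <- extract_id
  attr(rec, "timepoint_field") <- tp_field
  class(rec) <- c("record_table", class(tibble::tibble()))

  list(records = rec, duplicate_counts = dup_counts,
       n_excluded = n_excluded)
}

# Lenient datetime parser: accepts POSIXct/Date directly, else tries
# "yyyy-mm-dd HH:MM:SS" then "yyyy-mm-dd"; anything else is NA (invalid).
parse_datetime_vec <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  if (inherits(x, "Date")) return(as.POSIXct(x, tz = "UTC"))
  x <- as.character(x)
  out <- as.POSIXct(rep(NA_real_, length(x)), tz = "UTC", origin = "1970-01-01")
  ok <- !is.na(x) & nzchar(x)
  parsed <- suppressWarnings(
    lubridate::parse_date_time(x[ok], orders = c("Ymd HMS", "Ymd HM", "Ymd"),
                               tz = "UTC", quiet = TRUE))
  out[ok] <- parsed
  out
}

#' Assign dates to regular temporal bins
#'
#' Bins are days (midnight to midnight), weeks (Monday to Sunday) or
#' calendar months; each date maps to exactly one bin, identified by its
#' start date.
#'
#' @param dates Date or POSIXct vector.
#' @param granularity `"day"`, `"week"` or `"month"`.
#' @return Date vector of bin start dates, same length as `dates`.
#' @export
bin_timepoints <- function(dates, granularity = c("day", "week", "month")) {
  granularity <- match.arg(granularity)
  d <- if (inherits(dates, "POSIXct")) as.Date(dates, tz = "UTC")
       else as.Date(dates)
  switch(granularity,
    day   = d,
    week  = lubridate::floor_date(d, "week", week_start = 1),
    month = lubridate::floor_date(d, "month"))
}

# Gap-free index of bin starts covering [min_day, max_day].
bin_index <- function(min_day, max_day, granularity) {
  start <- bin_timepoints(min_day, granularity)
  end <- bin_timepoints(max_day, granularity)
  seq(start, end, by = granularity)
}

# Function labels applicable per field type (extract-level pseudo-fields
# ALL_DATA and DUPLICATES included).
functions_for_type <- function(field_type) {
  switch(field_type,
    Timepoint = c("n", "midnight_n", "midnight_perc"),
    Numeric = c("missing_n", "missing_perc", "nonconformant_n",
                "nonconformant_perc", "n", "min", "max", "mean", "median"),
    Categorical = c("missing_n", "missing_perc", "n", "distinct",
                    "subcat_n", "subcat_perc"),
    Datetime = c("missing_n", "missing_perc", "nonconformant_n",
                 "nonconformant_perc", "n", "min", "max",
                 "midnight_n", "midnight_perc"),
    UniqueIdentifier = c("missing_n", "missing_perc", "n", "minlength",
                         "maxlength", "meanlength"),
    Freetext = c("missing_n", "missing_perc", "n"),
    ALL_DATA = c("missing_n", "missing_perc", "nonconformant_n",
                 "nonconformant_perc", "n"),
    DUPLICATES = c("sum", "nonzero_perc"),
    stop("Unknown field_type '", field_type, "'", call. = FALSE))
}

is_missing_value <- function(x) is.na(x) | (is.character(x) & !nzchar(x))

# Conformance checks return a logical per *present* value.
numeric_conformant <- function(x) !is.na(suppressWarnings(as.numeric(x)))
datetime_conformant <- function(x) !is.na(parse_datetime_vec(x))

#' Aggregate one field into its data-quality time series
#'
#' Applies every aggregation function applicable to the field's type, per
#' temporal bin, producing one series per function (and one per observed
#' subcategory for `subcat_n`/`subcat_perc`). Bins with no records get 0
#' for `n` and `NA` for every other function. Nonconformance means a
#' nonnumeric value in a Numeric field or a nondate value in a Datetime
#' field. `midnight_*` series are emitted only when the field has a time
#' element; `subcat_*` series only when the field has fewer than
#' `subcat_limit` distinct observed values.
#'
#' @param records Cleaned record table from [prepare_extract()] (must carry
#'   the `.day` helper column).
#' @param field A [field_spec()] for a column of `records`.
#' @param granularity `"day"`, `"week"` or `"month"`.
#' @param subcat_limit Maximum number of distinct values for which
#'   per-subcategory series are produced (default 20).
#' @return Long tibble: `field`, `fun`, `subcategory`, `granularity`,
#'   `timepoint`, `value`.
#' @export
aggregate_field <- function(records, field, granularity = "day",
                            subcat_limit = 20L) {
  stopifnot(inherits(field, "field_spec"))
  funs <- functions_for_type(field$field_type)
  if (!field$has_time_element) {
    funs <- setdiff(funs, c("midnight_n", "midnight_perc"))
  }
  values <- records[[field$name]]
  if (field$field_type == "Timepoint") values <- records$.timepoint
  bins <- bin_timepoints(records$.day, granularity)
  index <- bin_index(min(records$.day), max(records$.day), granularity)

  subcats <- NULL
  if (field$field_type == "Categorical") {
    obs <- unique(values[!is_missing_value(values)])
    if (length(obs) < subcat_limit) subcats <- sort(obs)
    else funs <- setdiff(funs, c("subcat_n", "subcat_perc"))
  }

  per_bin <- split(values, factor(as.character(bins),
                                  levels = as.character(index)))
  rows <- lapply(funs, function(fun) {
    if (fun %in% c("subcat_n", "subcat_perc")) {
      dplyr::bind_rows(lapply(subcats, function(sc) {
        v <- vapply(per_bin, aggregate_one, numeric(1),
                    fun = fun, field = field, subcat = sc)
        series_tibble(field$name, fun, sc, granularity, index, v)
      }))
    } else {
      v <- vapply(per_bin, aggregate_one, numeric(1),
                  fun = fun, field = field, subcat = NULL)
      series_tibble(field$name, fun, NA_character_, granularity, index, v)
    }
  })
  dplyr::bind_rows(rows)
}

series_tibble <- function(field, fun, subcategory, granularity, index, v) {
  tibble::tibble(field = field, fun = fun, subcategory = subcategory,
                 granularity = granularity, timepoint = index,
                 value = unname(v))
}

# One bin, one function -> one numeric value (NA where undefined).
aggregate_one <- function(x, fun, field, subcat = NULL) {
  n_total <- length(x)
  if (n_total == 0L) {
    return(if (fun == "n") 0 else NA_real_)
  }
  miss <- is_missing_value(x)
  present <- x[!miss]
  n <- length(present)
  switch(fun,
    n = n,
    missing_n = sum(miss),
    missing_perc = 100 * sum(miss) / n_total,
    nonconformant_n = ,
    nonconformant_perc = {
      conf <- if (field$field_type == "Numeric") numeric_conformant(present)
              else datetime_conformant(present)
      nc <- sum(!conf)
      if (fun == "nonconformant_n") nc
      else if (n > 0) 100 * nc / n else NA_real_
    },
    min = ,
    max = ,
    mean = ,
    median = {
      num <- conformant_numeric_values(present, field)
      if (length(num) == 0) NA_real_
      else switch(fun, min = min(num), max = max(num),
                  mean = mean(num), median = stats::median(num))
    },
    midnight_n = ,
    midnight_perc = {
      tp <- if (inherits(x, "POSIXct")) x else parse_datetime_vec(present)
      tp <- tp[!is.na(tp)]
      mid <- sum(as.numeric(tp) %% 86400 == 0)
      if (fun == "midnight_n") mid
      else if (length(tp) > 0) 100 * mid / length(tp) else NA_real_
    },
    minlength = if (n > 0) min(nchar(present)) else NA_real_,
    maxlength = if (n > 0) max(nchar(present)) else NA_real_,
    meanlength = if (n > 0) mean(nchar(present)) else NA_real_,
    distinct = length(unique(present)),
    subcat_n = sum(present == subcat),
    subcat_perc = if (n > 0) 100 * sum(present == subcat) / n else NA_real_,
    stop("Unknown aggregation function '", fun, "'", call. = FALSE))
}

# Numeric value extraction: Numeric fields parse to double; Datetime
# fields are expressed as days since 1970-01-01 so min/max remain numeric.
conformant_numeric_values <- function(present, field) {
  if (field$field_type == "Numeric") {
    v <- suppressWarnings(as.numeric(present))
    v[!is.na(v)]
  } else {
    d <- parse_datetime_vec(present)
    as.numeric(d[!is.na(d)]) / 86400
  }
}

#' Build the full set of data-quality time series for an extract
#'
#' Runs [prepare_extract()] then [aggregate_field()] for every data field
#' at every requested granularity, and adds the extract-level `ALL_DATA`
#' series (cells pooled over all non-timepoint fields) and the `DUPLICATES`
#' series (`sum` of removed duplicate records, `nonzero_perc` percentage of
#' rows that were duplicates).
#'
#' @param records A `record_table`.
#' @param granularities Character vector within `c("day","week","month")`.
#' @param subcat_limit Passed to [aggregate_field()].
#' @return Long tibble with columns `extract`, `field`, `fun`,
#'   `subcategory`, `granularity`, `timepoint`, `value`.
#' @export
aggregate_extract <- function(records,
                              granularities = c("day", "week", "month"),
                              subcat_limit = 20L) {
  stopifnot(all(granularities %in% c("day", "week", "month")))
  prep <- prepare_extract(records)
  rec <- prep$records
  fields <- attr(rec, "fields")
  extract_id <- attr(rec, "extract_id") %||% "extract"

  out <- lapply(granularities, function(g) {
    per_field <- dplyr::bind_rows(lapply(fields, function(f) {
      aggregate_field(rec, f, g, subcat_limit)
    }))
    dplyr::bind_rows(per_field,
                     aggregate_all_data(rec, fields, g),
                     aggregate_duplicates(prep$duplicate_counts, rec, g))
  })
  dplyr::bind_rows(out) |>
    dplyr::mutate(extract = extract_id, .before = 1)
}

# ALL_DATA: pool every non-timepoint cell; nonconformance assessed over
# Numeric and Datetime fields only.
aggregate_all_data <- function(rec, fields, granularity) {
  data_fields <- Filter(function(f) f$field_type != "Timepoint", fields)
  index <- bin_index(min(rec$.day), max(rec$.day), granularity)
  bins <- bin_timepoints(rec$.day, granularity)
  fbin <- factor(as.character(bins), levels = as.character(index))

  miss_n <- pres_n <- nonconf_n <- rec_n <- rep(0, length(index))
  for (f in data_fields) {
    x <- rec[[f$name]]
    miss <- is_missing_value(x)
    miss_n <- miss_n + tapply_sum(miss, fbin)
    pres_n <- pres_n + tapply_sum(!miss, fbin)
    if (f$field_type %in% c("Numeric", "Datetime")) {
      conf_fun <- if (f$field_type == "Numeric") numeric_conformant
                  else datetime_conformant
      nc <- !miss & !conf_fun(x)
      nonconf_n <- nonconf_n + tapply_sum(nc, fbin)
    }
  }
  rec_n <- tapply_sum(rep(TRUE, nrow(rec)), fbin)
  empty <- rec_n == 0
  cell_n <- miss_n + pres_n

  mk <- function(fun, v) {
    series_tibble("ALL_DATA", fun, NA_character_, granularity, index, v)
  }
  dplyr::bind_rows(
    mk("missing_n", ifelse(empty, NA_real_, miss_n)),
    mk("missing_perc",
       ifelse(empty | cell_n == 0, NA_real_, 100 * miss_n / cell_n)),
    mk("nonconformant_n", ifelse(empty, NA_real_, nonconf_n)),
    mk("nonconformant_perc",
       ifelse(empty | pres_n == 0, NA_real_, 100 * nonconf_n / pres_n)),
    mk("n", ifelse(empty, 0, pres_n))
  )
}

tapply_sum <- function(x, fbin) {
  v <- tapply(x, fbin, sum)
  v[is.na(v)] <- 0
  as.numeric(v)
}

aggregate_duplicates <- function(dup_counts, rec, granularity) {
  index <- bin_index(min(rec$.day), max(rec$.day), granularity)
  bins <- bin_timepoints(dup_counts$day, granularity)
  fbin <- factor(as.character(bins), levels = as.character(index))
  removed <- tapply_sum(dup_counts$removed, fbin)
  total <- tapply_sum(dup_counts$total_rows, fbin)
  dplyr::bind_rows(
    series_tibble("DUPLICATES", "sum", NA_character_, granularity, index,
                  ifelse(total == 0, NA_real_, removed)),
    series_tibble("DUPLICATES", "nonzero_perc", NA_character_, granularity,
                  index,
                  ifelse(total == 0, NA_real_, 100 * removed / total))
  )
}

#' Write/read the long series table as CSV (NA encoded as empty)
#' @param series Tibble from [aggregate_extract()].
#' @param path File path.
#' @return `path` invisibly; for the reader, the parsed tibble.
#' @export
write_series_csv <- function(series, path) {
  readr::write_csv(series, path, na = "")
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  readr::read_csv(path, na = "", show_col_types = FALSE,
                  col_types = readr::cols(
                    extract = "c", field = "c", fun = "c",
                    subcategory = "c", granularity = "c",
                    timepoint = readr::col_date(), value = "d"))
}

#' Read a record extract from CSV with a field-specification YAML
#'
#' The YAML lists one entry per field: `name`, `type`, and optionally
#' `has_time_element`. All values are read as character; typing is applied
#' during aggregation.
#'
#' @param csv_path Record CSV.
#' @param fields_yaml Path to the field-spec YAML.
#' @param extract_id Identifier for the extract.
#' @return A `record_table` tibble.
#' @export
read_extract_csv <- function(csv_path, fields_yaml, extract_id = NULL) {
  spec <- yaml::read_yaml(fields_yaml)
  fields <- lapply(spec$fields, function(f) {
    field_spec(f$name, f$type,
               has_time_element = isTRUE(f$has_time_element))
  })
  types <- vapply(fields, function(f) f$field_type, character(1))
  tp <- which(types == "Timepoint")
  if (length(tp) != 1L) {
    stop("field spec must contain exactly one Timepoint field",
         call. = FALSE)
  }
  rec <- readr::read_csv(csv_path, na = "", show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  structure(rec, class = c("record_table", class(rec)),
            fields = fields,
            extract_id = extract_id %||% spec$extract_id %||% "extract",
            timepoint_field = fields[[tp]]$name)
}

#' Write a record extract to CSV
#' @param records A `record_table`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_extract_csv <- function(records, path) {
  out <- tibble::as_tibble(records)
  out <- out[setdiff(names(out), c(".timepoint", ".day"))]
  tp <- attr(records, "timepoint_field")
  if (inherits(out[[tp]], "POSIXct")) {
    out[[tp]] <- format(out[[tp]], "%Y-%m-%d %H:%M:%S", tz = "UTC")
  }
  readr::write_csv(out, path, na = "")
  invisible(path)
}
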