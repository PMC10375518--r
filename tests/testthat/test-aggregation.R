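make_record_table <- function(df, fields, tp_field) {
  structure(tibble::as_tibble(df),
            class = c("record_table", class(tibble::tibble())),
            fields = fields, extract_id = "fix",
            timepoint_field = tp_field)
}

fix_fields <- list(
  field_spec("when", "Timepoint", has_time_element = TRUE),
  field_spec("num", "Numeric"),
  field_spec("cat", "Categorical"))

test_that("prepare_extract removes duplicates and invalid timepoints", {
  df <- tibble::tibble(
    when = c(rep("2021-01-04 10:00:00", 3), "2021-01-05 09:00:00",
             "not a date", NA),
    num = c("1", "1", "1", "2", "3", "4"),
    cat = c("A", "A", "A", "B", "A", "B"))
  rec <- make_record_table(df, fix_fields, "when")
  prep <- prepare_extract(rec)
  expect_identical(nrow(prep$records), 2L)       # 3 dups -> 1, plus 1
  expect_identical(prep$n_excluded, 2L)
  d4 <- prep$duplicate_counts[prep$duplicate_counts$day ==
                                as.Date("2021-01-04"), ]
  expect_identical(d4$removed, 2L)
  expect_identical(d4$total_rows, 3L)
})

test_that("an all-invalid extract raises an empty-extract error", {
  df <- tibble::tibble(when = c(NA, "nope"), num = c("1", "2"),
                       cat = c("A", "B"))
  rec <- make_record_table(df, fix_fields, "when")
  expect_error(prepare_extract(rec), "empty extract")
})

test_that("duplicate-free extracts give an identically zero sum series", {
  df <- tibble::tibble(
    when = sprintf("2021-01-%02d 08:00:00", 4:10),
    num = as.character(1:7), cat = rep("A", 7))
  agg <- aggregate_extract(make_record_table(df, fix_fields, "when"), "day")
  s <- dplyr::filter(agg, field == "DUPLICATES", fun == "sum")
  expect_identical(s$value, rep(0, 7))
})

test_that("temporal bins follow day/week/month boundary rules", {
  # Sunday 2019-06-30 belongs to the week starting Monday 2019-06-24
  expect_identical(bin_timepoints(as.Date("2019-06-30"), "week"),
                   as.Date("2019-06-24"))
  expect_identical(bin_timepoints(as.Date("2019-06-30"), "month"),
                   as.Date("2019-06-01"))
  # same calendar day, different times -> same day bin
  t1 <- as.POSIXct("2020-03-05 00:10:00", tz = "UTC")
  t2 <- as.POSIXct("2020-03-05 23:50:00", tz = "UTC")
  expect_identical(bin_timepoints(t1, "day"), bin_timepoints(t2, "day"))
})

test_that("numeric aggregation matches direct arithmetic", {
  df <- tibble::tibble(
    when = rep("2021-01-04 08:00:00", 3),
    num = c("1.0", NA, "3.0"), cat = c("A", "B", "A"))
  agg <- aggregate_extract(make_record_table(df, fix_fields, "when"), "day")
  val <- function(f, fn) {
    dplyr::filter(agg, field == f, fun == fn)$value
  }
  expect_identical(val("num", "missing_n"), 1)
  expect_equal(val("num", "missing_perc"), 100 / 3)
  expect_identical(val("num", "n"), 2)
  expect_identical(val("num", "min"), 1)
  expect_identical(val("num", "max"), 3)
  expect_identical(val("num", "mean"), 2)
  expect_identical(val("num", "median"), 2)
})

test_that("nonconformant values are counted, not averaged", {
  df <- tibble::tibble(
    when = rep("2021-01-04 08:00:00", 3),
    num = c("1.0", "abc", "3.0"), cat = c("A", "B", "A"))
  agg <- aggregate_extract(make_record_table(df, fix_fields, "when"), "day")
  val <- function(fn) dplyr::filter(agg, field == "num", fun == fn)$value
  expect_identical(val("nonconformant_n"), 1)
  expect_equal(val("nonconformant_perc"), 100 / 3)
  expect_identical(val("mean"), 2)   # "abc" excluded from the mean
  expect_identical(val("n"), 3)      # but still a present value
})

test_that("subcategory series appear only below the distinct-value limit", {
  df <- tibble::tibble(
    when = rep("2021-01-04 08:00:00", 42),
    num = as.character(1:42),
    cat = c(rep(sprintf("c%02d", 1:21), 2)))
  agg <- aggregate_extract(make_record_table(df, fix_fields, "when"), "day")
  expect_identical(nrow(dplyr::filter(agg, fun == "subcat_n")), 0L)
  expect_identical(dplyr::filter(agg, field == "cat",
                                 fun == "distinct")$value, 21)
  # a raised limit re-enables them (one series per subcategory)
  agg25 <- aggregate_extract(make_record_table(df, fix_fields, "when"),
                             "day", subcat_limit = 25)
  expect_identical(nrow(dplyr::filter(agg25, fun == "subcat_n")), 21L)
})

test_that("empty intervals give n = 0 and NA for other functions", {
  df <- tibble::tibble(
    when = c("2021-01-04 08:00:00", "2021-01-06 08:00:00"),
    num = c("5", "7"), cat = c("A", "B"))
  agg <- aggregate_extract(make_record_table(df, fix_fields, "when"), "day")
  gap_day <- as.Date("2021-01-05")
  gap <- dplyr::filter(agg, timepoint == gap_day)
  expect_identical(dplyr::filter(gap, fun == "n")$value, rep(0, 4))
  expect_true(all(is.na(dplyr::filter(gap, fun != "n")$value)))
})

test_that("midnight counts require a time element", {
  df <- tibble::tibble(
    when = c("2021-01-04 00:00:00", "2021-01-04 08:00:00"),
    num = c("1", "2"), cat = c("A", "B"))
  agg <- aggregate_extract(make_record_table(df, fix_fields, "when"), "day")
  expect_identical(dplyr::filter(agg, field == "when",
                                 fun == "midnight_n")$value, 1)
  expect_identical(dplyr::filter(agg, field == "when",
                                 fun == "midnight_perc")$value, 50)
  no_time <- list(field_spec("when", "Timepoint"),
                  fix_fields[[2]], fix_fields[[3]])
  agg2 <- aggregate_extract(make_record_table(df, no_time, "when"), "day")
  expect_identical(nrow(dplyr::filter(agg2, fun == "midnight_n")), 0L)
})

test_that("conservation and closure invariants hold on a generated extract", {
  ext <- small_extract(seed = 17)
  prep <- prepare_extract(ext)
  n_day <- table(prep$records$.day)
  agg <- aggregate_extract(ext, c("day", "week"))

  wide_day <- agg |>
    dplyr::filter(granularity == "day", field == "num") |>
    tidyr::pivot_wider(id_cols = "timepoint", names_from = "fun",
                       values_from = "value")
  total <- as.numeric(n_day[as.character(wide_day$timepoint)])
  total[is.na(total)] <- 0
  nonempty <- total > 0
  # missing_n + n = records in the interval
  expect_equal(wide_day$missing_n[nonempty] + wide_day$n[nonempty],
               total[nonempty])
  # missing_perc from its own counts
  expect_equal(wide_day$missing_perc[nonempty],
               100 * wide_day$missing_n[nonempty] / total[nonempty])

  # subcategory closure: sum over subcategories of subcat_n equals n
  sub <- agg |>
    dplyr::filter(granularity == "day", field == "cat",
                  fun == "subcat_n") |>
    dplyr::group_by(timepoint) |>
    dplyr::summarise(total_sub = sum(value), .groups = "drop")
  cat_n <- dplyr::filter(agg, granularity == "day", field == "cat",
                         fun == "n")
  joined <- dplyr::inner_join(sub, cat_n, by = "timepoint") |>
    dplyr::filter(value > 0)
  expect_equal(joined$total_sub, joined$value)
  sub_perc <- agg |>
    dplyr::filter(granularity == "day", field == "cat",
                  fun == "subcat_perc") |>
    dplyr::group_by(timepoint) |>
    dplyr::summarise(s = sum(value), .groups = "drop") |>
    dplyr::filter(!is.na(s))
  expect_equal(sub_perc$s, rep(100, nrow(sub_perc)))

  # weekly n equals the sum of its daily n values
  daily_n <- dplyr::filter(agg, granularity == "day", field == "num",
                           fun == "n")
  weekly_n <- dplyr::filter(agg, granularity == "week", field == "num",
                            fun == "n")
  rolled <- daily_n |>
    dplyr::mutate(week = bin_timepoints(timepoint, "week")) |>
    dplyr::group_by(week) |>
    dplyr::summarise(n = sum(value), .groups = "drop")
  expect_equal(weekly_n$value,
               rolled$n[match(weekly_n$timepoint, rolled$week)])

  # every series index is gap-free over the full record span
  spans <- agg |>
    dplyr::group_by(field, fun, subcategory, granularity) |>
    dplyr::summarise(ok = identical(
      as.numeric(timepoint),
      as.numeric(bin_index(min(prep$records$.day),
                           max(prep$records$.day),
                           granularity[1]))), .groups = "drop")
  expect_true(all(spans$ok))

  # percentages stay within [0, 100]
  percs <- dplyr::filter(agg, grepl("perc", fun), !is.na(value))
  expect_true(all(percs$value >= 0 & percs$value <= 100))
})

test_that("the series table and record extract round-trip through CSV", {
  ext <- small_extract(seed = 23, n_per_day = 5,
                       span = c("2021-01-01", "2021-01-20"))
  agg <- aggregate_extract(ext, "day")
  path <- withr::local_tempfile(fileext = ".csv")
  write_series_csv(agg, path)
  back <- read_series_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(agg))

  rec_path <- withr::local_tempfile(fileext = ".csv")
  yml_path <- withr::local_tempfile(fileext = ".yml")
  write_extract_csv(ext, rec_path)
  yaml::write_yaml(list(extract_id = "test-extract", fields = list(
    list(name = "evt_date", type = "Timepoint", has_time_element = TRUE),
    list(name = "num", type = "Numeric"),
    list(name = "cat", type = "Categorical"),
    list(name = "uid", type = "UniqueIdentifier"))), yml_path)
  rec2 <- read_extract_csv(rec_path, yml_path)
  agg2 <- aggregate_extract(rec2, "day")
  expect_equal(as.data.frame(agg2), as.data.frame(agg))
})
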