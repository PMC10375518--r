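#' Pipeline configuration
#'
#' Reads (or builds) the configuration shared by all stages: output
#' directory, seeds, granularities, geometry, cleaning cutoff, consensus
#' parameters, volunteer model and synthetic-scenario settings.
#'
#' @param path Optional YAML file; values found there override the
#'   defaults below.
#' @param ... Named overrides applied on top of the file.
#' @return An object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(path = NULL, ...) {
  cfg <- list(
    out_dir = "pipeline-out",
    seed = 1L,
    granularities = "day",
    n_per_day = 40L,
    n_days = 120L,
    start_date = "2015-01-01",
    n_images = 6L,
    truths_per_image = 2L,
    subcat_limit = 20L,
    cutoff_px = 7,
    intervals_per_image = 136L,
    render = FALSE,
    volunteer = list(n_volunteers = 41L, detect_prob = 0.8, jitter_sd = 2,
                     uncertain_prob = 0.1, noise_rate = 0.3,
                     repeat_prob = 0.05),
    consensus = list(include_yellow = FALSE, min_pts = 5L, eps_px = 3)
  )
  if (!is.null(path)) {
    cfg <- utils::modifyList(cfg, yaml::read_yaml(path))
  }
  cfg <- utils::modifyList(cfg, list(...))
  structure(cfg, class = "pipeline_config")
}

pipeline_stages <- c("simulate", "aggregate", "render", "clean",
                     "consensus", "evaluate")

#' Run the pipeline end to end on a synthetic scenario
#'
#' Executes the requested stages in order: `simulate` (generate an extract
#' and ground-truth change points, simulate volunteer and expert
#' annotation lines), `aggregate` (build the data-quality series),
#' `render` (optionally draw the per-image PNGs), `clean` (first-attempt
#' filter and same-person merging), `consensus` (density-clustered
#' labels), `evaluate` (score against the simulated expert lines). Each
#' stage writes its CSV/JSON artefacts into `config$out_dir` and the run
#' finishes with a manifest recording the config, seed, stage list and an
#' MD5 hash per artefact. Re-running with an identical config reproduces
#' identical CSV outputs byte for byte.
#'
#' The stages must form a prefix of the full chain; later stages read the
#' artefacts written by earlier ones, so a stage whose input artefact is
#' absent stops with an error naming the stage to run first.
#'
#' @param config A [pipeline_config()].
#' @param stages Character vector, a prefix of
#'   `c("simulate","aggregate","render","clean","consensus","evaluate")`.
#' @return Invisibly, the manifest (a named list), also written as
#'   `manifest.json` in the output directory.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = pipeline_stages) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  idx <- sort(match(stages, pipeline_stages))
  if (!identical(idx, seq_len(length(idx)))) {
    stop("stages must form a contiguous prefix of the chain: ",
         paste(pipeline_stages, collapse = " -> "), call. = FALSE)
  }
  stages <- pipeline_stages[idx]
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)
  require_artefact <- function(f, producer) {
    if (!file.exists(p(f))) {
      stop("missing artefact '", f, "': run the '", producer,
           "' stage first", call. = FALSE)
    }
  }
  artefacts <- character(0)
  note <- function(f) artefacts <<- union(artefacts, f)

  if ("simulate" %in% stages) {
    sim <- simulate_scenario(config)
    write_extract_csv(sim$extract, p("records.csv")); note("records.csv")
    write_truths_csv(sim$truths, p("truths.csv")); note("truths.csv")
    write_annotation_csv(sim$volunteer_lines, p("annotations_raw.csv"))
    note("annotations_raw.csv")
    write_annotation_csv(sim$expert_lines, p("expert_lines.csv"))
    note("expert_lines.csv")
    write_coords_manifest(sim$coords, p("coords_manifest.csv"))
    note("coords_manifest.csv")
  }

  if ("aggregate" %in% stages) {
    require_artefact("records.csv", "simulate")
    fields_yaml <- p("fields.yml")
    if (!file.exists(fields_yaml)) {
      stop("missing artefact 'fields.yml': run the 'simulate' stage first",
           call. = FALSE)
    }
    rec <- read_extract_csv(p("records.csv"), fields_yaml)
    series <- aggregate_extract(rec, config$granularities,
                                config$subcat_limit)
    write_series_csv(series, p("series.csv")); note("series.csv")
  }

  if ("render" %in% stages && isTRUE(config$render)) {
    require_artefact("series.csv", "aggregate")
    series <- read_series_csv(p("series.csv"))
    img_dir <- p("images")
    dir.create(img_dir, showWarnings = FALSE)
    keys <- dplyr::distinct(series, .data$field, .data$fun,
                            .data$subcategory, .data$granularity)
    for (i in seq_len(nrow(keys))) {
      s <- dplyr::semi_join(series, keys[i, ],
                            by = c("field", "fun", "subcategory",
                                   "granularity"))
      fname <- sprintf("%s_%s_%s.png", keys$field[i], keys$fun[i],
                       keys$granularity[i])
      render_series(s$timepoint, s$value, keys$fun[i],
                    file.path(img_dir, fname))
    }
  }

  if ("clean" %in% stages) {
    require_artefact("annotations_raw.csv", "simulate")
    raw <- read_annotation_csv(p("annotations_raw.csv"))
    cfg <- cleaning_config(config$cutoff_px)
    cleaned <- clean_annotations(raw, cfg, quiet = TRUE)
    write_annotation_csv(
      dplyr::select(cleaned, -"n_merged"), p("annotations_clean.csv"))
    note("annotations_clean.csv")
    log <- attr(cleaned, "cleaning_log")
    jsonlite::write_json(as.list(log), p("cleaning_log.json"),
                         auto_unbox = TRUE)
    note("cleaning_log.json")
  }

  if ("consensus" %in% stages) {
    require_artefact("annotations_clean.csv", "clean")
    require_artefact("coords_manifest.csv", "simulate")
    cleaned <- read_annotation_csv(p("annotations_clean.csv"))
    coords <- read_coords_manifest(p("coords_manifest.csv"))
    params <- consensus_params(config$consensus$include_yellow,
                               config$consensus$min_pts,
                               config$consensus$eps_px)
    labels <- consensus_labels(cleaned, params, coords)
    write_labels_csv(labels, p("consensus_labels.csv"))
    note("consensus_labels.csv")
  }

  if ("evaluate" %in% stages) {
    require_artefact("consensus_labels.csv", "consensus")
    require_artefact("expert_lines.csv", "simulate")
    labels <- read_labels_csv(p("consensus_labels.csv"))
    expert_raw <- read_annotation_csv(p("expert_lines.csv"))
    # expert lines get the same same-person merging, for consistency
    expert <- merge_same_person(expert_raw,
                                cleaning_config(config$cutoff_px))
    all_ids <- names(read_coords_manifest(p("coords_manifest.csv")))
    counts <- match_labels(labels, expert, config$cutoff_px,
                           config$intervals_per_image, image_ids = all_ids)
    m <- classifier_metrics(counts)
    jsonlite::write_json(metric_set_to_list(m), p("metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    note("metrics.json")
  }

  manifest <- list(
    stages = stages,
    seed = config$seed,
    config = unclass(config),
    artefacts = lapply(stats::setNames(artefacts, artefacts), function(f) {
      list(path = f, md5 = unname(tools::md5sum(p(f))))
    })
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}

metric_set_to_list <- function(m) {
  list(sensitivity = m$sensitivity, specificity = m$specificity,
       ppv = m$ppv, npv = m$npv, mcc = m$mcc,
       counts = unclass(m$counts))
}

# Build the synthetic scenario for a pipeline run: one Numeric-field
# extract whose daily mean series is "imaged", with truths spread over
# n_images independent images, volunteer lines from the configured model,
# and a deterministic expert who marks every truth exactly.
simulate_scenario <- function(config) {
  start <- as.Date(config$start_date)
  span <- c(start, start + config$n_days - 1L)
  fields <- list(
    field_spec("record_date", "Timepoint", has_time_element = TRUE),
    field_spec("value", "Numeric", missing_rate = 0.02)
  )
  truths <- list()
  kinds <- c("level", "trend", "variability", "presence", "outlier")
  vm <- do.call(volunteer_model, config$volunteer)

  coords_list <- list()
  vol_rows <- list()
  exp_rows <- list()
  base_seed <- as.integer(config$seed)
  for (i in seq_len(config$n_images)) {
    img <- sprintf("img-%03d", i)
    co <- plot_coordinates(span[1], span[2])
    coords_list[[img]] <- co
    # truths at deterministic, well-separated dates within the span
    tr_dates <- start + round(seq(0.2, 0.8,
                                  length.out = config$truths_per_image) *
                                (config$n_days - 1))
    tr <- lapply(seq_along(tr_dates), function(j) {
      change_point_truth(tr_dates[j],
                         kinds[(i + j - 1) %% length(kinds) + 1],
                         magnitude = 6, field = "value",
                         series_id = img)
    })
    truths <- c(truths, tr)
    tr_px <- date_to_px(tr_dates, co)
    vol_rows[[i]] <- simulate_annotations(tr_px, co, vm, image_id = img,
                                          seed = base_seed + i)
    exp_rows[[i]] <- tibble::tibble(
      image_id = img, person_id = "expert",
      classification_id = i, attempt_time =
        as.POSIXct("2022-06-01", tz = "UTC"),
      x_px = tr_px, colour = "green")
  }

  extract <- generate_extract(fields, span, truths = list(),
                              seed = base_seed,
                              n_per_day = config$n_per_day,
                              extract_id = "synthetic")
  # persist the field spec so the aggregate stage can re-read the extract
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(
    list(extract_id = "synthetic",
         fields = list(
           list(name = "record_date", type = "Timepoint",
                has_time_element = TRUE),
           list(name = "value", type = "Numeric"))),
    file.path(config$out_dir, "fields.yml"))

  list(extract = extract, truths = truths,
       volunteer_lines = dplyr::bind_rows(vol_rows),
       expert_lines = dplyr::bind_rows(exp_rows),
       coords = coords_list)
}
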