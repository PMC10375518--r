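#' Confusion counts for the interval-based binary-classifier approximation
#'
#' @param tp,tn,fp,fn Non-negative counts.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts> TP=", x$tp, " TN=", x$tn, " FP=", x$fp,
      " FN=", x$fn, "\n", sep = "")
  invisible(x)
}

#' Score consensus labels against expert lines
#'
#' Approximates a binary classifier per image: an expert line with at
#' least one consensus label closer than `cutoff_px` is a true positive
#' (however many labels sit near it — no double counting of false
#' positives); an expert line with none is a false negative; a label with
#' no expert line closer than `cutoff_px` is a false positive (one label
#' near two expert lines therefore yields two true positives and no false
#' negative). True negatives are estimated per image as
#' `intervals_per_image` — the number of cutoff-width slots across the
#' plot, i.e. the maximum number of distinguishable change points — minus
#' TP + FP + FN for that image, then summed over images.
#'
#' @param labels Consensus-label tibble (`image_id`, `x_px`).
#' @param expert Expert-line tibble (`image_id`, `x_px`); both certain and
#'   uncertain expert lines belong here.
#' @param cutoff_px Minimum distance cutoff (default 7).
#' @param intervals_per_image True-negative budget per image (default
#'   `floor(952 / 7) = 136`).
#' @param image_ids Optional character vector of images to score (so
#'   images with no labels and no expert lines still contribute TN);
#'   defaults to the union of images present in `labels` and `expert`.
#' @return A `confusion_counts` object with attribute `per_image` (tibble
#'   of per-image counts).
#' @export
match_labels <- function(labels, expert, cutoff_px = 7,
                         intervals_per_image = 136L, image_ids = NULL) {
  ids <- image_ids %||% union(unique(labels$image_id),
                              unique(expert$image_id))
  per_image <- lapply(ids, function(id) {
    lx <- labels$x_px[labels$image_id == id]
    ex <- expert$x_px[expert$image_id == id]
    if (length(ex) == 0) {
      tp <- 0L; fn <- 0L; fp <- length(lx)
    } else if (length(lx) == 0) {
      tp <- 0L; fn <- length(ex); fp <- 0L
    } else {
      d <- abs(outer(ex, lx, "-"))
      tp <- sum(apply(d, 1, min) < cutoff_px)
      fn <- length(ex) - tp
      fp <- sum(apply(d, 2, min) >= cutoff_px)
    }
    tn <- intervals_per_image - (tp + fp + fn)
    if (tn < 0) {
      stop("negative per-image TN on image '", id,
           "': intervals_per_image too small", call. = FALSE)
    }
    tibble::tibble(image_id = id, tp = tp, fp = fp, fn = fn, tn = tn)
  })
  per_image <- dplyr::bind_rows(per_image)
  out <- confusion_counts(sum(per_image$tp), sum(per_image$tn),
                          sum(per_image$fp), sum(per_image$fn))
  attr(out, "per_image") <- per_image
  out
}

#' Wilson score interval for a binomial proportion
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level (default 0.95).
#' @return Length-2 numeric `c(lower, upper)`; `c(NA, NA)` when `n == 0`.
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  centre <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  denom <- 1 + z^2 / n
  c((centre - half) / denom, (centre + half) / denom)
}

#' Classifier metrics with confidence intervals
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), positive predictive
#' value TP/(TP+FP), negative predictive value TN/(TN+FN), each with a
#' Wilson score 95% CI, plus the Matthews correlation coefficient
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}{
#'   \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}.}
#' A metric whose denominator is zero is `NA`; MCC is defined as 0 when
#' any of the four marginal sums is zero.
#'
#' @param counts A [confusion_counts()].
#' @param conf Confidence level for the CIs.
#' @return An object of class `metric_set`: a list with `sensitivity`,
#'   `specificity`, `ppv`, `npv` (each `list(point, lower, upper)`) and
#'   `mcc`.
#' @export
classifier_metrics <- function(counts, conf = 0.95) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  prop <- function(k, n) {
    if (n == 0) return(list(point = NA_real_, lower = NA_real_,
                            upper = NA_real_))
    ci <- wilson_ci(k, n, conf)
    list(point = k / n, lower = ci[1], upper = ci[2])
  }
  marginals <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  mcc <- if (any(marginals == 0)) 0 else {
    (tp * tn - fp * fn) / sqrt(prod(marginals))
  }
  structure(list(sensitivity = prop(tp, tp + fn),
                 specificity = prop(tn, tn + fp),
                 ppv = prop(tp, tp + fp),
                 npv = prop(tn, tn + fn),
                 mcc = mcc,
                 counts = counts),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  fmt <- function(m, name) {
    if (is.na(m$point)) return(cat(name, ": NA\n", sep = ""))
    cat(sprintf("%s: %.1f%% (95%% CI, %.1f%%-%.1f%%)\n", name,
                100 * m$point, 100 * m$lower, 100 * m$upper))
  }
  fmt(x$sensitivity, "sensitivity")
  fmt(x$specificity, "specificity")
  fmt(x$ppv, "PPV")
  fmt(x$npv, "NPV")
  cat(sprintf("MCC: %.3f\n", x$mcc))
  invisible(x)
}

#' Estimated true-negative total from the interval budget
#'
#' `n_images * intervals_per_image - (tp + fp + fn)`: the interval-based
#' estimate of true negatives pooled over a set of images.
#'
#' @param n_images Number of images scored.
#' @param tp,fp,fn Pooled counts over those images.
#' @param intervals_per_image Cutoff-width intervals per image.
#' @return The TN total (numeric).
#' @export
estimate_tn <- function(n_images, tp, fp, fn, intervals_per_image = 136L) {
  n_images * intervals_per_image - (tp + fp + fn)
}

#' Stratified tuning/test split of images
#'
#' Within each extract, a fraction `tuning_fraction` of images (rounded to
#' nearest) is assigned to the tuning set at random; the rest form the
#' test set. The split is disjoint, exhaustive, and reproducible for a
#' given seed.
#'
#' @param images Tibble with columns `image_id` and `extract`.
#' @param tuning_fraction Fraction assigned to tuning (default 0.7).
#' @param seed Integer RNG seed.
#' @return List with character vectors `tuning` and `test`.
#' @export
split_images <- function(images, tuning_fraction = 0.7, seed = 1L) {
  stopifnot(all(c("image_id", "extract") %in% names(images)),
            tuning_fraction > 0, tuning_fraction < 1)
  withr::with_seed(as.integer(seed), {
    tuning <- character(0)
    for (ex in unique(images$extract)) {
      ids <- images$image_id[images$extract == ex]
      if (length(ids) < 2) {
        warning("extract '", ex, "' has fewer than 2 images; ",
                "assigning all to the tuning set", call. = FALSE)
        tuning <- c(tuning, ids)
        next
      }
      n_tune <- round(tuning_fraction * length(ids))
      tuning <- c(tuning, sample(ids, n_tune))
    }
    list(tuning = tuning,
         test = setdiff(images$image_id, tuning))
  })
}

#' The parameter grid searched during tuning
#'
#' Include/exclude yellow lines crossed with `min_pts` 2..20 and integer
#' `eps_px` 1..7 — 266 combinations.
#'
#' @param min_pts_range,eps_range Integer ranges.
#' @return Tibble with columns `include_yellow`, `min_pts`, `eps_px`.
#' @export
consensus_grid <- function(min_pts_range = 2:20, eps_range = 1:7) {
  tidyr::expand_grid(include_yellow = c(FALSE, TRUE),
                     min_pts = as.integer(min_pts_range),
                     eps_px = as.numeric(eps_range))
}

#' Grid-search consensus parameters by Matthews correlation coefficient
#'
#' For every parameter combination, consensus labels are produced on the
#' tuning images, scored against the expert lines with counts pooled
#' across images, and summarised by MCC. The result is ranked by MCC
#' descending with deterministic tie-breaks: smaller `min_pts`, then
#' smaller `eps_px`, then exclude-yellow first.
#'
#' @param lines Cleaned annotation lines.
#' @param expert Expert-line tibble (`image_id`, `x_px`).
#' @param tuning_ids Character vector of image ids to tune on.
#' @param cutoff_px Matching cutoff (default 7).
#' @param intervals_per_image Per-image TN budget (default 136).
#' @param grid Parameter grid (default [consensus_grid()]).
#' @return Tibble: grid columns plus `tp`, `tn`, `fp`, `fn`, `mcc`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, sorted best-first.
#' @export
tune_grid <- function(lines, expert, tuning_ids, cutoff_px = 7,
                      intervals_per_image = 136L,
                      grid = consensus_grid()) {
  lines <- dplyr::filter(lines, .data$image_id %in% tuning_ids)
  expert <- dplyr::filter(expert, .data$image_id %in% tuning_ids)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    params <- consensus_params(grid$include_yellow[i], grid$min_pts[i],
                               grid$eps_px[i])
    labels <- consensus_labels(lines, params)
    counts <- match_labels(labels, expert, cutoff_px,
                           intervals_per_image, image_ids = tuning_ids)
    m <- classifier_metrics(counts)
    tibble::tibble(include_yellow = params$include_yellow,
                   min_pts = params$min_pts, eps_px = params$eps_px,
                   tp = counts$tp, tn = counts$tn, fp = counts$fp,
                   fn = counts$fn, mcc = m$mcc,
                   sensitivity = m$sensitivity$point,
                   specificity = m$specificity$point,
                   ppv = m$ppv$point, npv = m$npv$point)
  })
  dplyr::bind_rows(res) |>
    dplyr::arrange(dplyr::desc(.data$mcc), .data$min_pts, .data$eps_px,
                   .data$include_yellow)
}

#' Distribution of minimum same-person line distances
#'
#' For each (image, person) with at least two drawn lines, the minimum
#' pairwise distance between those lines; the distribution supports the
#' choice of the minimum distance cutoff. Histogram bins are integer-width,
#' closed on the left and open on the right (a minimum distance equal to an
#' integer falls in the bar to its right).
#'
#' @param lines Raw (pre-merge, first-attempt) annotation lines.
#' @param max_px Upper display bound of the histogram (default 10).
#' @return List with `distances` (tibble `image_id`, `person_id`,
#'   `min_distance`) and `histogram` (tibble `bin_left`, `bin_right`,
#'   `count`, where the last bin collects everything >= `max_px`).
#' @export
min_distance_distribution <- function(lines, max_px = 10) {
  distances <- lines |>
    dplyr::group_by(.data$image_id, .data$person_id) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::summarise(min_distance = min(diff(sort(.data$x_px))),
                     .groups = "drop")
  bins <- tibble::tibble(bin_left = 0:(max_px - 1),
                         bin_right = 1:max_px)
  counts <- vapply(seq_len(nrow(bins)), function(i) {
    sum(distances$min_distance >= bins$bin_left[i] &
          distances$min_distance < bins$bin_right[i])
  }, numeric(1))
  overflow <- sum(distances$min_distance >= max_px)
  histogram <- dplyr::bind_rows(
    dplyr::mutate(bins, count = counts),
    tibble::tibble(bin_left = max_px, bin_right = Inf, count = overflow))
  list(distances = distances, histogram = histogram)
}
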