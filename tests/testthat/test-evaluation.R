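test_that("matching enforces both double-counting rules", {
  # several labels near one expert line: 1 TP, 0 FP
  c1 <- match_labels(tibble::tibble(image_id = "a", x_px = c(100, 104)),
                     tibble::tibble(image_id = "a", x_px = 100))
  expect_identical(c(c1$tp, c1$fp, c1$fn), c(1L, 0L, 0L))
  # one label near two expert lines: 2 TP, 0 FN
  c2 <- match_labels(tibble::tibble(image_id = "a", x_px = 100),
                     tibble::tibble(image_id = "a", x_px = c(97, 104)))
  expect_identical(c(c2$tp, c2$fp, c2$fn), c(2L, 0L, 0L))
  # an empty image is all true negatives
  c3 <- match_labels(tibble::tibble(image_id = character(),
                                    x_px = numeric()),
                     tibble::tibble(image_id = character(),
                                    x_px = numeric()),
                     image_ids = "empty")
  expect_identical(c(c3$tp, c3$fp, c3$fn, c3$tn), c(0L, 0L, 0L, 136L))
  # too small an interval budget is a configuration error
  expect_error(
    match_labels(tibble::tibble(image_id = "a", x_px = seq(1, 900, 50)),
                 tibble::tibble(image_id = "a", x_px = numeric()),
                 intervals_per_image = 10),
    "intervals_per_image too small")
})

test_that("matching agrees with the exhaustive proximity oracle", {
  set.seed(601)
  for (i in 1:300) {
    lab <- runif(sample(0:20, 1), 0, 952)
    exp_ <- runif(sample(0:20, 1), 0, 952)
    got <- match_labels(tibble::tibble(image_id = "a", x_px = lab),
                        tibble::tibble(image_id = "a", x_px = exp_),
                        image_ids = "a")
    want <- match_brute(lab, exp_, 7, 136)
    expect_identical(c(got$tp, got$fp, got$fn, got$tn),
                     as.integer(unname(want)), info = paste("case", i))
    # TP + FN always partitions the expert lines
    expect_identical(got$tp + got$fn, length(exp_))
    expect_lte(got$fp, length(lab))
  }
})

test_that("metrics reproduce the worked example and its special cases", {
  m <- classifier_metrics(confusion_counts(492, 38194, 90, 120))
  expect_equal(round(100 * m$sensitivity$point, 1), 80.4)
  expect_equal(round(100 * m$specificity$point, 1), 99.8)
  expect_equal(round(100 * m$ppv$point, 1), 84.5)
  expect_equal(round(100 * m$npv$point, 1), 99.7)
  expect_equal(round(m$mcc, 3), 0.822)

  perfect <- classifier_metrics(confusion_counts(10, 10, 0, 0))
  expect_identical(perfect$sensitivity$point, 1)
  expect_identical(perfect$specificity$point, 1)
  expect_identical(perfect$ppv$point, 1)
  expect_identical(perfect$npv$point, 1)
  expect_identical(perfect$mcc, 1)

  # swapping TP<->FP and TN<->FN negates the MCC
  a <- classifier_metrics(confusion_counts(30, 200, 12, 7))$mcc
  b <- classifier_metrics(confusion_counts(12, 7, 30, 200))$mcc
  expect_equal(a, -b)

  # zero marginal sums: MCC defined as 0, undefined rates are NA
  degenerate <- classifier_metrics(confusion_counts(0, 50, 0, 0))
  expect_identical(degenerate$mcc, 0)
  expect_true(is.na(degenerate$sensitivity$point))
  expect_true(is.na(degenerate$ppv$point))
})

test_that("Wilson intervals match the closed form and the printed CI", {
  wilson_oracle <- function(k, n, z = 1.96) {
    p <- k / n
    c((p + z^2 / (2 * n) - z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
        (1 + z^2 / n),
      (p + z^2 / (2 * n) + z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
        (1 + z^2 / n))
  }
  for (case in list(c(492, 612), c(38194, 38284), c(3, 10), c(0, 25))) {
    expect_equal(wilson_ci(case[1], case[2]),
                 wilson_oracle(case[1], case[2]), tolerance = 1e-4)
  }
  expect_equal(round(100 * wilson_ci(492, 612), 1), c(77.1, 83.3))
  expect_identical(wilson_ci(0, 0), c(NA_real_, NA_real_))
})

test_that("the interval-based TN estimate matches the pooled formula", {
  expect_identical(estimate_tn(286, 492, 90, 120), 38194)
  expect_identical(estimate_tn(1, 0, 0, 0), 136)
})

test_that("the stratified split is exact, disjoint and reproducible", {
  imgs <- tibble::tibble(
    image_id = sprintf("img-%03d", 1:10),
    extract = rep("e1", 10))
  s <- split_images(imgs, 0.7, seed = 5)
  expect_identical(length(s$tuning), 7L)
  expect_identical(length(s$test), 3L)
  expect_identical(sort(c(s$tuning, s$test)), sort(imgs$image_id))
  expect_identical(split_images(imgs, 0.7, seed = 5), s)
  expect_false(identical(split_images(imgs, 0.7, seed = 6)$tuning,
                         s$tuning))
  tiny <- tibble::tibble(image_id = "only", extract = "e1")
  expect_warning(s2 <- split_images(tiny), "fewer than 2 images")
  expect_identical(s2$tuning, "only")
})

test_that("the tuning grid is complete and its ranking deterministic", {
  g <- consensus_grid()
  expect_identical(nrow(g), 266L)
  expect_identical(nrow(dplyr::distinct(g)), 266L)
  expect_setequal(unique(g$min_pts), 2:20)
  expect_setequal(unique(g$eps_px), as.numeric(1:7))

  # noiseless lines: every admissible grid point scores MCC 1
  co <- plot_coordinates("2020-01-01", "2020-12-31")
  vm <- volunteer_model(n_volunteers = 41, detect_prob = 1, jitter_sd = 0,
                        uncertain_prob = 0, noise_rate = 0,
                        repeat_prob = 0)
  truth_px <- list("i1" = c(150, 400), "i2" = c(250, 700, 900))
  lines <- dplyr::bind_rows(lapply(names(truth_px), function(id) {
    simulate_annotations(truth_px[[id]], co, vm, image_id = id, seed = 3)
  }))
  expert <- dplyr::bind_rows(lapply(names(truth_px), function(id) {
    tibble::tibble(image_id = id, x_px = truth_px[[id]])
  }))
  small_grid <- consensus_grid(min_pts_range = c(2, 5, 20),
                               eps_range = c(1, 3, 7))
  ranked <- tune_grid(lines, expert, names(truth_px), grid = small_grid)
  expect_true(all(ranked$mcc == 1))
  # ranking order under ties: min_pts, then eps, then exclude-yellow
  expect_identical(ranked$min_pts[1:2], c(2L, 2L))
  expect_identical(ranked$eps_px[1], 1)
  expect_false(ranked$include_yellow[1])
  # order of processing does not change the ranking
  shuffled <- lines[sample(nrow(lines)), ]
  ranked2 <- tune_grid(shuffled, expert, names(truth_px),
                       grid = small_grid)
  expect_equal(as.data.frame(ranked2), as.data.frame(ranked))
})

test_that("minimum same-person distances bin left-closed right-open", {
  lines <- dplyr::bind_rows(
    make_lines(c(100, 103, 220), person = "p1"),
    make_lines(500, person = "p2"),
    make_lines(c(40, 47), person = "p3"))
  mdd <- min_distance_distribution(lines)
  expect_identical(nrow(mdd$distances), 2L)   # p2 contributes nothing
  expect_identical(
    mdd$distances$min_distance[mdd$distances$person_id == "p1"], 3)
  # a minimum distance of exactly 3 falls in bin [3, 4)
  bin3 <- mdd$histogram[mdd$histogram$bin_left == 3, ]
  expect_identical(bin3$count, 1)
  bin7 <- mdd$histogram[mdd$histogram$bin_left == 7, ]
  expect_identical(bin7$count, 1)
  expect_identical(sum(mdd$histogram$count), 2)
})
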