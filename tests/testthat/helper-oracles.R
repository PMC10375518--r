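# Independent reference implementations used as oracles. Deliberately
# quadratic / brute-force and structured differently from the package code.

# Density clustering by explicit pairwise-distance BFS over core points.
dbscan_brute <- function(x, min_pts, eps) {
  n <- length(x)
  if (n == 0) return(integer(0))
  d <- abs(outer(x, x, "-"))
  core <- rowSums(d <= eps) >= min_pts
  cl <- integer(n)
  visited <- rep(FALSE, n)
  cid <- 0L
  for (i in order(x)) {
    if (!core[i] || visited[i]) next
    cid <- cid + 1L
    queue <- i
    while (length(queue) > 0) {
      j <- queue[1]
      queue <- queue[-1]
      if (visited[j]) next
      visited[j] <- TRUE
      cl[j] <- cid
      queue <- c(queue, which(core & d[j, ] <= eps & !visited))
    }
  }
  for (i in which(!core)) {
    cands <- which(core & d[i, ] <= eps)
    if (length(cands) > 0) {
      dmin <- min(d[i, cands])
      cl[i] <- min(cl[cands[d[i, cands] == dmin]])
    }
  }
  cl
}

# Exhaustive pairwise proximity matcher (strict < cutoff).
match_brute <- function(label_px, expert_px, cutoff, intervals) {
  tp <- sum(vapply(expert_px,
                   function(e) any(abs(label_px - e) < cutoff),
                   logical(1)))
  fn <- length(expert_px) - tp
  fp <- sum(vapply(label_px,
                   function(l) !any(abs(expert_px - l) < cutoff),
                   logical(1)))
  c(tp = tp, fp = fp, fn = fn, tn = intervals - (tp + fp + fn))
}

# Minimal annotation-line tibble builder.
make_lines <- function(x_px, person = "p1", image = "img-1",
                       colour = "green", cls = NULL, time = NULL) {
  n <- length(x_px)
  tibble::tibble(
    image_id = rep_len(image, n),
    person_id = rep_len(person, n),
    classification_id = cls %||% rep(1L, n),
    attempt_time = time %||% rep(as.POSIXct("2022-01-01", tz = "UTC"), n),
    x_px = x_px,
    colour = rep_len(colour, n))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Two-field synthetic extract used across aggregation tests.
small_extract <- function(truths = list(), seed = 11, n_per_day = 15,
                          span = c("2021-01-01", "2021-03-15")) {
  fields <- list(
    field_spec("evt_date", "Timepoint", has_time_element = TRUE),
    field_spec("num", "Numeric", missing_rate = 0.1),
    field_spec("cat", "Categorical", subcategories = c("A", "B", "C"),
               missing_rate = 0.1),
    field_spec("uid", "UniqueIdentifier", missing_rate = 0))
  generate_extract(fields, span, truths, seed = seed,
                   n_per_day = n_per_day, extract_id = "test-extract")
}
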