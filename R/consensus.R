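#' Parameters of the consensus-label clustering
#'
#' @param include_yellow Include uncertain (yellow) lines in clustering.
#' @param min_pts Minimum number of lines needed to create a cluster
#'   (the point itself counts).
#' @param eps_px Epsilon-neighbourhood: the maximum distance, in pixels,
#'   between two lines in a cluster.
#' @return An object of class `consensus_params`. The defaults are the
#'   tuned values used for final label creation: exclude yellow lines,
#'   `min_pts = 5`, `eps_px = 3`.
#' @export
consensus_params <- function(include_yellow = FALSE, min_pts = 5L,
                             eps_px = 3) {
  stopifnot(min_pts >= 2, eps_px > 0)
  structure(list(include_yellow = isTRUE(include_yellow),
                 min_pts = as.integer(min_pts), eps_px = eps_px),
            class = "consensus_params")
}

#' One-dimensional density-based clustering with noise
#'
#' DBSCAN specialised to points on a line. A position is a *core* point if
#' at least `min_pts` positions (itself included) lie within `eps_px` of
#' it; clusters are the connected components of core points under the
#' within-`eps_px` relation, plus *border* points (non-core positions
#' within `eps_px` of a core point). Everything else is noise. A border
#' point reachable from several clusters joins the cluster of its nearest
#' core point, ties going to the lower cluster id. Distances compare
#' inclusively (`<= eps_px`): eps is the maximum distance between two
#' lines in a cluster.
#'
#' @param positions Numeric vector of x-pixel positions (finite).
#' @param min_pts Minimum points to form a cluster (>= 2).
#' @param eps_px Neighbourhood radius in pixels (> 0).
#' @return Integer vector, same length as `positions`: cluster id (1, 2,
#'   ... in order of increasing position) or 0 for noise.
#' @export
dbscan_1d <- function(positions, min_pts = 5L, eps_px = 3) {
  stopifnot(all(is.finite(positions)), min_pts >= 2, eps_px > 0)
  n <- length(positions)
  if (n == 0) return(integer(0))
  ord <- order(positions)
  x <- positions[ord]

  # neighbour counts via two-pointer sweep over the sorted positions
  lo <- findInterval(x - eps_px, x, left.open = TRUE) + 1L
  hi <- findInterval(x + eps_px, x)
  n_nbr <- hi - lo + 1L
  core <- n_nbr >= min_pts

  cl_sorted <- integer(n)
  cid <- 0L
  core_idx <- which(core)
  if (length(core_idx) > 0) {
    # consecutive core points chain into one cluster when within eps
    gap_new <- c(TRUE, diff(x[core_idx]) > eps_px)
    cl_core <- cumsum(gap_new)
    cid <- max(cl_core)
    cl_sorted[core_idx] <- cl_core

    # border points: non-core within eps of a core point; nearest core
    # wins, ties to the lower cluster id (the left neighbour, since
    # cluster ids increase with position)
    border_idx <- which(!core)
    if (length(border_idx) > 0) {
      xc <- x[core_idx]
      pos <- findInterval(x[border_idx], xc)
      left <- pmax(pos, 1L)
      right <- pmin(pos + 1L, length(xc))
      d_left <- ifelse(pos >= 1L, x[border_idx] - xc[left], Inf)
      d_right <- ifelse(pos < length(xc), xc[right] - x[border_idx], Inf)
      nearest <- ifelse(d_left <= d_right, left, right)
      d_min <- pmin(d_left, d_right)
      ok <- d_min <= eps_px
      cl_sorted[border_idx[ok]] <- cl_core[nearest[ok]]
    }
  }
  out <- integer(n)
  out[ord] <- cl_sorted
  out
}

#' Derive consensus change-point labels from cleaned annotation lines
#'
#' Per image: yellow (uncertain) lines are dropped first unless
#' `include_yellow` is set; [dbscan_1d()] is run on the remaining x-pixel
#' positions; lines labelled noise are ignored; each cluster yields one
#' consensus label at the unweighted mean of its member positions. Labels
#' are converted back to dates through the image's [plot_coordinates()]
#' when a coordinates manifest is supplied. An image may yield zero labels.
#'
#' @param lines Cleaned annotation-line tibble (see [clean_annotations()]).
#' @param params A [consensus_params()].
#' @param coords Optional: a single [plot_coordinates()] applied to every
#'   image, or a named list keyed by image id (as returned by
#'   [read_coords_manifest()]). When omitted, `date` is `NA`.
#' @return Tibble of consensus labels: `image_id`, `x_px`,
#'   `n_contributors`, `date`.
#' @export
consensus_labels <- function(lines, params = consensus_params(),
                             coords = NULL) {
  stopifnot(inherits(params, "consensus_params"))
  empty <- tibble::tibble(image_id = character(), x_px = numeric(),
                          n_contributors = integer(),
                          date = as.Date(character()))
  if (nrow(lines) == 0) return(empty)
  use <- if (params$include_yellow) lines
         else dplyr::filter(lines, .data$colour == "green")
  if (nrow(use) == 0) return(empty)

  labs <- use |>
    dplyr::group_by(.data$image_id) |>
    dplyr::group_modify(function(df, key) {
      cl <- dbscan_1d(df$x_px, params$min_pts, params$eps_px)
      keep <- cl > 0
      if (!any(keep)) {
        return(tibble::tibble(x_px = numeric(), n_contributors = integer()))
      }
      tibble::tibble(x_px = df$x_px[keep], cluster = cl[keep]) |>
        dplyr::group_by(.data$cluster) |>
        dplyr::summarise(x_px = mean(.data$x_px),
                         n_contributors = dplyr::n(), .groups = "drop") |>
        dplyr::select("x_px", "n_contributors")
    }) |>
    dplyr::ungroup()
  if (nrow(labs) == 0) return(empty)

  labs$date <- as.Date(NA)
  if (!is.null(coords)) {
    if (inherits(coords, "plot_coordinates")) {
      labs$date <- px_to_date(labs$x_px, coords)
    } else {
      ids <- unique(labs$image_id)
      unknown <- setdiff(ids, names(coords))
      if (length(unknown) > 0) {
        stop("image id(s) missing from coordinates manifest: ",
             paste(unknown, collapse = ", "), call. = FALSE)
      }
      for (id in ids) {
        sel <- labs$image_id == id
        labs$date[sel] <- px_to_date(labs$x_px[sel], coords[[id]])
      }
    }
  }
  dplyr::arrange(labs, .data$image_id, .data$x_px)
}

#' Write/read consensus labels as CSV
#' @param labels Tibble from [consensus_labels()].
#' @param path CSV path.
#' @return `path` invisibly; reader returns the parsed tibble.
#' @export
write_labels_csv <- function(labels, path) {
  readr::write_csv(labels, path, na = "")
  invisible(path)
}

#' @rdname write_labels_csv
#' @export
read_labels_csv <- function(path) {
  readr::read_csv(path, na = "", show_col_types = FALSE,
                  col_types = readr::cols(
                    image_id = "c", x_px = "d", n_contributors = "i",
                    date = readr::col_date()))
}
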