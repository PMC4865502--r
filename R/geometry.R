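#' Screen geometry for the 'What was where?' task
#'
#' Bundles the spatial constants of the delayed-reproduction task, all in
#' degrees of visual angle: the visible screen extent, the margin items must
#' keep from the screen edges, the exclusion zone around the screen centre,
#' the minimum pairwise separation between items in a memory array, and the
#' radius used to classify a report as a swap (misbinding) error. Defaults
#' follow the published task: a 62 x 35 degree display, items at least 3.9
#' degrees from the edges and 6.5 degrees from the centre, never within 9
#' degrees of each other, and a 4.5 degree swap radius.
#'
#' The coordinate convention is Cartesian degrees of visual angle with the
#' origin at screen centre, x rightward and y upward. The published display
#' was 1920 x 1080 pixels; [deg_to_px()] and [px_to_deg()] give the linear
#' map between the two frames.
#'
#' @param width_deg,height_deg Screen extent (degrees of visual angle).
#' @param edge_margin_deg Minimum distance from an item centre to the nearest
#'   screen edge.
#' @param centre_exclusion_deg Minimum distance from an item centre to the
#'   screen centre.
#' @param min_separation_deg Minimum pairwise distance between item centres
#'   within a memory array.
#' @param swap_radius_deg Maximum distance from a non-target at which a
#'   report counts as a swap error. Must satisfy
#'   `2 * swap_radius_deg <= min_separation_deg` so a report can never be
#'   attributed to two different items.
#'
#' @return An object of class `screen_geometry` (a validated named list).
#' @examples
#' geom <- screen_geometry()
#' geom$min_separation_deg
#' @export
screen_geometry <- function(width_deg = 62,
                            height_deg = 35,
                            edge_margin_deg = 3.9,
                            centre_exclusion_deg = 6.5,
                            min_separation_deg = 9,
                            swap_radius_deg = 4.5) {
  geom <- list(
    width_deg = width_deg,
    height_deg = height_deg,
    edge_margin_deg = edge_margin_deg,
    centre_exclusion_deg = centre_exclusion_deg,
    min_separation_deg = min_separation_deg,
    swap_radius_deg = swap_radius_deg
  )
  bad <- names(geom)[!vapply(geom, function(v) is.numeric(v) && length(v) == 1 && is.finite(v) && v > 0, logical(1))]
  if (length(bad)) {
    abort(paste0("screen_geometry fields must be single positive numbers: ", paste(bad, collapse = ", ")))
  }
  if (width_deg <= 2 * edge_margin_deg + 2 * centre_exclusion_deg) {
    abort("infeasible geometry: width_deg must exceed 2*edge_margin_deg + 2*centre_exclusion_deg")
  }
  if (height_deg <= 2 * edge_margin_deg) {
    abort("infeasible geometry: height_deg must exceed 2*edge_margin_deg")
  }
  if (2 * swap_radius_deg > min_separation_deg) {
    abort(paste0(
      "swap attribution uniqueness violated: 2*swap_radius_deg (",
      2 * swap_radius_deg, ") must not exceed min_separation_deg (",
      min_separation_deg, ")"
    ))
  }
  structure(geom, class = "screen_geometry")
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat("<screen_geometry> (degrees of visual angle)\n")
  for (nm in names(x)) cat(sprintf("  %-22s %.2f\n", nm, x[[nm]]))
  invisible(x)
}

#' Convert between degrees of visual angle and screen pixels
#'
#' Fixed linear map from the published correspondence of a 1920 x 1080 pixel
#' matrix to approximately 62 x 35 degrees of visual angle. Degree
#' coordinates are centred (origin at screen centre, y upward); pixel
#' coordinates follow the usual display convention (origin at the top-left
#' corner, y downward).
#'
#' @param x_deg,y_deg,x_px,y_px Coordinate vectors.
#' @param geometry A [screen_geometry()].
#' @param screen_px Pixel matrix dimensions, width then height.
#' @return A tibble with the converted coordinate pair.
#' @export
deg_to_px <- function(x_deg, y_deg, geometry = screen_geometry(), screen_px = c(1920, 1080)) {
  sx <- screen_px[1] / geometry$width_deg
  sy <- screen_px[2] / geometry$height_deg
  tibble::tibble(
    x_px = (x_deg + geometry$width_deg / 2) * sx,
    y_px = (geometry$height_deg / 2 - y_deg) * sy
  )
}

#' @rdname deg_to_px
#' @export
px_to_deg <- function(x_px, y_px, geometry = screen_geometry(), screen_px = c(1920, 1080)) {
  sx <- geometry$width_deg / screen_px[1]
  sy <- geometry$height_deg / screen_px[2]
  tibble::tibble(
    x_deg = x_px * sx - geometry$width_deg / 2,
    y_deg = geometry$height_deg / 2 - y_px * sy
  )
}

# half-extents of the rectangle available to item centres
.margin_rect <- function(geometry) {
  c(
    x = geometry$width_deg / 2 - geometry$edge_margin_deg,
    y = geometry$height_deg / 2 - geometry$edge_margin_deg
  )
}

# m uniform proposals inside the edge-margin rectangle (m x 2 matrix)
.propose_points <- function(m, geometry) {
  hx <- .margin_rect(geometry)
  cbind(runif(m, -hx["x"], hx["x"]), runif(m, -hx["y"], hx["y"]))
}

# Draw one feasible point per row, respecting edge margin, centre exclusion
# and min separation from every point in `existing` (a list of m x 2
# matrices, one per already-placed item). Vectorised rejection sampling.
.sample_next_point <- function(m, geometry, existing = list(), max_attempts = 10000) {
  out <- matrix(NA_real_, m, 2)
  todo <- rep(TRUE, m)
  attempts <- 0L
  while (any(todo)) {
    k <- sum(todo)
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      abort(paste0(
        "location sampling budget exhausted after ", max_attempts,
        " rounds (constraints: edge_margin/centre_exclusion/min_separation); ",
        k, " point(s) unplaced"
      ))
    }
    prop <- .propose_points(k, geometry)
    ok <- sqrt(prop[, 1]^2 + prop[, 2]^2) >= geometry$centre_exclusion_deg
    for (ex in existing) {
      exk <- ex[todo, , drop = FALSE]
      d2 <- (prop[, 1] - exk[, 1])^2 + (prop[, 2] - exk[, 2])^2
      ok <- ok & d2 > geometry$min_separation_deg^2
    }
    idx <- which(todo)[ok]
    out[idx, ] <- prop[ok, , drop = FALSE]
    todo[idx] <- FALSE
  }
  out
}

# n_arrays independent memory arrays of n_items points each.
# Returns tibble(array_id, item_slot, x_deg, y_deg).
.sample_arrays <- function(n_arrays, n_items, geometry, fixed = NULL, max_attempts = 10000) {
  existing <- list()
  if (!is.null(fixed)) {
    for (j in seq_len(ncol(fixed) / 2)) {
      existing[[j]] <- fixed[, c(2 * j - 1, 2 * j), drop = FALSE]
    }
  }
  pts <- vector("list", n_items)
  for (k in seq_len(n_items)) {
    pts[[k]] <- .sample_next_point(n_arrays, geometry, existing, max_attempts)
    existing[[length(existing) + 1L]] <- pts[[k]]
  }
  tibble::tibble(
    array_id = rep(seq_len(n_arrays), times = n_items),
    item_slot = rep(seq_len(n_items), each = n_arrays),
    x_deg = unlist(lapply(pts, function(p) p[, 1])),
    y_deg = unlist(lapply(pts, function(p) p[, 2]))
  ) |>
    dplyr::arrange(.data$array_id, .data$item_slot)
}

#' Sample item locations for one memory array
#'
#' Places `n` item centres by rejection sampling under the task's spatial
#' constraints: at least `edge_margin_deg` from every screen edge, at least
#' `centre_exclusion_deg` from the screen centre, and pairwise distances
#' greater than `min_separation_deg`. Optionally conditions on already-fixed
#' locations (used by the chance-correction null, which redraws non-target
#' positions given the realized target position).
#'
#' @param n Number of new locations to draw.
#' @param geometry A [screen_geometry()].
#' @param fixed Optional data frame or matrix of existing locations
#'   (columns `x_deg`, `y_deg`) that the new points must also respect.
#' @param max_attempts Rejection-sampling budget (proposal rounds per point).
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with columns `x_deg`, `y_deg` (`n` rows).
#' @examples
#' sample_locations(3, screen_geometry(), seed = 1)
#' @export
sample_locations <- function(n, geometry = screen_geometry(), fixed = NULL,
                             max_attempts = 10000, seed = NULL) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 1)
  if (!inherits(geometry, "screen_geometry")) abort("`geometry` must be a screen_geometry()")
  fixed_mat <- NULL
  if (!is.null(fixed)) {
    fixed <- as.data.frame(fixed)
    if (!is.null(names(fixed)) && all(c("x_deg", "y_deg") %in% names(fixed))) {
      fixed <- fixed[, c("x_deg", "y_deg")]
    }
    fm <- as.matrix(fixed)
    # one row per fixed point -> replicate across the single array as columns
    fixed_mat <- matrix(t(fm), nrow = 1)
  }
  draw <- function() {
    res <- .sample_arrays(1L, as.integer(n), geometry, fixed = fixed_mat, max_attempts = max_attempts)
    tibble::tibble(x_deg = res$x_deg, y_deg = res$y_deg)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
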