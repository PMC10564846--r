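#' Annotate trajectory points with nearest-grid-cell field values
#'
#' Each point along a backward trajectory is associated with the nearest
#' values of gridded model fields (e.g. boundary-layer height, 10-m wind,
#' land mask). Nearest is Euclidean in latitude/longitude degrees; exact
#' ties resolve to the lowest cell index.
#'
#' @param points Tibble with `lat`, `lon` columns (other columns kept).
#' @param grid Tibble with `lat`, `lon` and one or more field columns.
#' @return `points` with the grid's field columns appended.
#' @export
nearest_grid_annotation <- function(points, grid) {
  assert_columns(points, c("lat", "lon"), "trajectory points")
  assert_columns(grid, c("lat", "lon"), "field grid")
  fields <- setdiff(names(grid), c("lat", "lon"))
  if (length(fields) == 0) abort("Grid has no field columns.")
  out_of <- points$lat < min(grid$lat) - 1e-9 | points$lat > max(grid$lat) + 1e-9 |
    points$lon < min(grid$lon) - 1e-9 | points$lon > max(grid$lon) + 1e-9
  if (any(out_of)) abort("Trajectory point outside grid bounds.")
  idx <- purrr::map_int(seq_len(nrow(points)), function(i) {
    d2 <- (grid$lat - points$lat[i])^2 + (grid$lon - points$lon[i])^2
    which.min(d2)  # lowest index on ties
  })
  dplyr::bind_cols(points, grid[idx, fields, drop = FALSE])
}

#' Classify trajectory points as over-sea and loading
#'
#' The sea flag is the negation of the land mask. Loading conditions (the
#' uptake of generic marine particles into the air mass) hold where the
#' point is within the mixing layer (altitude at or below boundary-layer
#' height) and the surface wind strictly exceeds the wind threshold
#' (default 3 m s^-1). Optionally, loading can additionally require the
#' point to be over sea. Points missing boundary-layer height or wind are
#' flagged unevaluable and excluded from fraction denominators.
#'
#' @param points Tibble with `altitude`, `blh`, `wind`, `land` columns.
#' @param loading_wind Wind threshold, exceeded strictly (default 3).
#' @param loading_requires_sea Require `!land` for loading (default `FALSE`,
#'   the two stated criteria only).
#' @return `points` with logical columns `sea`, `loading`, `evaluable`.
#' @export
classify_points <- function(points, loading_wind = 3,
                            loading_requires_sea = FALSE) {
  assert_columns(points, c("altitude", "blh", "wind", "land"), "trajectory points")
  evaluable <- !is.na(points$blh) & !is.na(points$wind)
  sea <- !points$land
  loading <- evaluable & points$altitude <= points$blh &
    points$wind > loading_wind
  if (loading_requires_sea) loading <- loading & sea
  points %>% mutate(sea = sea, loading = loading, evaluable = evaluable)
}

#' Per-event sea-time and loading fractions
#'
#' For each trajectory, the fractions of evaluable points flagged over-sea
#' and loading within the first `window_hours` hours before arrival; the
#' event summary is the unweighted mean over its trajectories. The default
#' window is the first four days (96 hourly points) of a 5-day trajectory.
#'
#' @param points Classified trajectory points (see [classify_points()]) with
#'   `trajectory_id`, `event`, and `hours_before` columns.
#' @param window_hours Scoring window (default 96).
#' @return A list: `$trajectories` (per-trajectory tibble `event`,
#'   `trajectory_id`, `n_points`, `sea_fraction`, `loading_fraction`) and
#'   `$events` (per-event means, with `sea_percent` / `loading_percent`).
#' @export
event_summary <- function(points, window_hours = 96) {
  assert_columns(points, c("trajectory_id", "event", "hours_before",
                           "sea", "loading", "evaluable"),
                 "classified trajectory points")
  win <- points %>% filter(.data$hours_before <= window_hours, .data$evaluable)
  if (nrow(win) == 0) abort("Empty scoring window.")
  tj <- win %>%
    group_by(.data$event, .data$trajectory_id) %>%
    summarise(n_points = dplyr::n(),
              sea_fraction = mean(.data$sea),
              loading_fraction = mean(.data$loading),
              .groups = "drop")
  ev <- tj %>%
    group_by(.data$event) %>%
    summarise(n_trajectories = dplyr::n(),
              sea_fraction = mean(.data$sea_fraction),
              loading_fraction = mean(.data$loading_fraction),
              .groups = "drop") %>%
    mutate(sea_percent = 100 * .data$sea_fraction,
           loading_percent = 100 * .data$loading_fraction)
  list(trajectories = tj, events = ev)
}

#' Read a trajectory point table
#'
#' CSV with one row per hourly point: `trajectory_id`, `event`,
#' `hours_before` (1..120 along the backward path), `lat`, `lon`,
#' `altitude` (m), `blh` (boundary-layer height, m), `wind` (surface wind,
#' m s^-1), `land` (0/1 or logical).
#'
#' @param path Path to the CSV.
#' @return A tibble of trajectory points.
#' @export
read_trajectories <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  assert_columns(raw, c("trajectory_id", "event", "hours_before", "altitude",
                        "blh", "wind", "land"), "trajectory table")
  raw %>% mutate(land = as.logical(.data$land))
}
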