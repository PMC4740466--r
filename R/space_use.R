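#' Hourly centre-of-activity positions
#'
#' Short-interval position estimates: within each local clock hour the
#' animal's position is estimated as the mean receiver position weighted by
#' the number of detections at each receiver, computed on the projected
#' (UTM) plane and back-projected to geographic coordinates. Each estimate
#' therefore lies inside the convex hull of the contributing receivers.
#'
#' @param joined detections with `tag_id`, `timestamp`, `latitude`,
#'   `longitude` (receiver positions).
#' @param tz_offset_hours local-time offset for hour bins (default UTC+10).
#' @param zone UTM zone used for the weighted mean (default 55 south).
#' @return Tibble with one row per tag and hour bin: `tag_id`, `hour_bin`
#'   (POSIXct, start of local clock hour expressed in UTC), `easting`,
#'   `northing`, `longitude`, `latitude`, `n_detections`; sorted by tag
#'   and time.
#' @export
center_of_activity <- function(joined, tz_offset_hours = 10, zone = 55) {
  if (nrow(joined) == 0) {
    return(tibble::tibble(tag_id = character(),
                          hour_bin = as.POSIXct(character(), tz = "UTC"),
                          easting = numeric(), northing = numeric(),
                          longitude = numeric(), latitude = numeric(),
                          n_detections = integer()))
  }
  utm <- project_to_utm(joined$longitude, joined$latitude, zone = zone)
  det <- joined
  det$easting <- utm$easting
  det$northing <- utm$northing
  # clock-aligned local hours, stored as the UTC instant the bin starts
  local <- as.numeric(det$timestamp) + tz_offset_hours * 3600
  det$hour_bin <- as.POSIXct(floor(local / 3600) * 3600 -
                               tz_offset_hours * 3600,
                             origin = "1970-01-01", tz = "UTC")
  coa <- det |>
    dplyr::group_by(.data$tag_id, .data$hour_bin) |>
    dplyr::summarise(easting = mean(.data$easting),
                     northing = mean(.data$northing),
                     n_detections = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$tag_id, .data$hour_bin)
  geo <- utm_to_lonlat(coa$easting, coa$northing, zone = zone)
  coa$longitude <- geo$longitude
  coa$latitude <- geo$latitude
  coa[c("tag_id", "hour_bin", "easting", "northing", "longitude", "latitude",
        "n_detections")]
}

#' Minimum linear dispersal between consecutive positions
#'
#' Straight-line distance and elapsed time between each pair of consecutive
#' centre-of-activity positions of one animal — a lower bound on distance
#' travelled. Distances are planar on the UTM plane by default; set
#' `geodesic = TRUE` for great-circle distances (uses the geosphere
#' package), relevant only for spans far outside one UTM zone.
#'
#' @param coa centre-of-activity tibble from [center_of_activity()].
#' @param geodesic use WGS84 geodesic instead of planar distance.
#' @return Tibble with one row per consecutive pair: `tag_id`, `from_bin`,
#'   `to_bin`, `distance_km`, `elapsed_h`.
#' @export
dispersal_steps <- function(coa, geodesic = FALSE) {
  coa <- dplyr::arrange(coa, .data$tag_id, .data$hour_bin)
  out <- coa |>
    dplyr::group_by(.data$tag_id) |>
    dplyr::mutate(from_bin = dplyr::lag(.data$hour_bin),
                  d_e = .data$easting - dplyr::lag(.data$easting),
                  d_n = .data$northing - dplyr::lag(.data$northing),
                  lon0 = dplyr::lag(.data$longitude),
                  lat0 = dplyr::lag(.data$latitude)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$from_bin))
  if (nrow(out) == 0) {
    return(tibble::tibble(tag_id = character(),
                          from_bin = as.POSIXct(character(), tz = "UTC"),
                          to_bin = as.POSIXct(character(), tz = "UTC"),
                          distance_km = numeric(), elapsed_h = numeric()))
  }
  dist_m <- if (geodesic) {
    if (!requireNamespace("geosphere", quietly = TRUE)) {
      abort("geodesic distances need the geosphere package")
    }
    geosphere::distGeo(cbind(out$lon0, out$lat0),
                       cbind(out$longitude, out$latitude))
  } else {
    sqrt(out$d_e^2 + out$d_n^2)
  }
  tibble::tibble(tag_id = out$tag_id, from_bin = out$from_bin,
                 to_bin = out$hour_bin, distance_km = dist_m / 1000,
                 elapsed_h = as.numeric(out$hour_bin - out$from_bin,
                                        units = "hours"))
}

#' Roaming index
#'
#' Proportion of monitored sites (reefs) at which an animal was detected;
#' a site counts as visited on any single detection there (no
#' two-detections rule — visit counting is deliberately more permissive
#' than day-level presence).
#'
#' @param sites_visited integer count of distinct sites with detections.
#' @param sites_monitored integer count of monitored sites, `>= 1`.
#' @return `sites_visited / sites_monitored`, vectorised.
#' @export
#' @examples
#' roaming_index(11, 17) # 0.647
roaming_index <- function(sites_visited, sites_monitored) {
  if (any(sites_monitored < 1)) abort("sites_monitored must be >= 1")
  if (any(sites_visited < 0 | sites_visited > sites_monitored)) {
    abort("sites_visited must lie in [0, sites_monitored]")
  }
  sites_visited / sites_monitored
}

#' Distinct sites visited per animal within one array
#'
#' @param joined detections with `tag_id`, `array_id`, `site_id`.
#' @param array_id array to restrict to.
#' @return Tibble: `tag_id`, `sites_visited`.
#' @export
sites_visited <- function(joined, array_id) {
  joined[joined$array_id == array_id, , drop = FALSE] |>
    dplyr::group_by(.data$tag_id) |>
    dplyr::summarise(sites_visited = dplyr::n_distinct(.data$site_id),
                     .groups = "drop")
}

#' Site-to-site movement matrix
#'
#' Directed transition counts between sites (or arrays): for each animal,
#' consecutive detections at different units contribute a transition from
#' the earlier to the later unit. In `"individuals"` mode (the default) the
#' matrix counts distinct animals per ordered pair over the whole period —
#' the connectivity measure used for circular connectivity plots; in
#' `"moves"` mode it counts raw transitions, appropriate for move-frequency
#' summaries.
#'
#' @param joined detections with `tag_id`, `timestamp`, `site_id`,
#'   `array_id` (and `sex` when stratifying).
#' @param level `"site"` or `"array"`.
#' @param mode `"individuals"` or `"moves"`.
#' @param units optional character vector fixing the matrix dimensions
#'   (e.g. all monitored reefs, so never-visited reefs appear as zero
#'   rows); defaults to the units observed.
#' @param stratify_by_sex return a list of matrices split by `sex`.
#' @return A `movement_matrix` object: an integer matrix with `from` rows
#'   and `to` columns and attributes `level` and `mode` (self-transitions
#'   are never counted: a run of detections at one unit is collapsed
#'   first). With `stratify_by_sex = TRUE`, a named list of such objects.
#' @export
movement_matrix <- function(joined, level = c("site", "array"),
                            mode = c("individuals", "moves"), units = NULL,
                            stratify_by_sex = FALSE) {
  level <- match.arg(level)
  mode <- match.arg(mode)
  if (stratify_by_sex) {
    if (!"sex" %in% names(joined)) abort("stratify_by_sex needs a sex column")
    return(lapply(split(joined, joined$sex), movement_matrix,
                  level = level, mode = mode, units = units))
  }
  unit_col <- if (level == "site") "site_id" else "array_id"
  det <- dplyr::arrange(joined, .data$tag_id, .data$timestamp)
  steps <- det |>
    dplyr::group_by(.data$tag_id) |>
    dplyr::reframe({
      u <- rle(.data[[unit_col]])$values  # collapse runs at the same unit
      if (length(u) < 2) {
        tibble::tibble(from = character(), to = character())
      } else {
        tibble::tibble(from = u[-length(u)], to = u[-1])
      }
    })
  all_units <- sort(unique(c(units, steps$from, steps$to,
                             joined[[unit_col]])))
  m <- matrix(0L, length(all_units), length(all_units),
              dimnames = list(from = all_units, to = all_units))
  if (nrow(steps) > 0) {
    counted <- if (mode == "individuals") {
      dplyr::distinct(steps, .data$tag_id, .data$from, .data$to)
    } else {
      steps
    }
    tab <- table(factor(counted$from, all_units), factor(counted$to, all_units))
    m <- m + unclass(tab)
    dimnames(m) <- list(from = all_units, to = all_units)
  }
  structure(m, level = level, mode = mode, class = c("movement_matrix",
                                                     class(m)))
}

#' @export
print.movement_matrix <- function(x, ...) {
  cat(sprintf("movement matrix (%s level, %s mode): %d units, %d %s\n",
              attr(x, "level"), attr(x, "mode"), nrow(x), sum(x),
              if (attr(x, "mode") == "individuals") "individual links"
              else "moves"))
  print(unclass(x), ...)
  invisible(x)
}

#' Long-format export of a movement matrix
#'
#' @param m `movement_matrix` object (or list of them from sex
#'   stratification).
#' @param keep_zero keep zero-count pairs (default FALSE).
#' @return Tibble: `from`, `to`, `count`, `stratum`; directly consumable
#'   by circular-plot tooling.
#' @export
movement_matrix_long <- function(m, keep_zero = FALSE) {
  if (is.list(m) && !is.matrix(m)) {
    return(dplyr::bind_rows(purrr::imap(m, function(mm, s) {
      out <- movement_matrix_long(mm, keep_zero)
      out$stratum <- s
      out
    })))
  }
  out <- tibble::as_tibble(as.data.frame.table(unclass(m),
                                               stringsAsFactors = FALSE))
  names(out) <- c("from", "to", "count")
  out$stratum <- "all"
  if (!keep_zero) out <- out[out$count > 0, , drop = FALSE]
  out
}

#' Move frequencies within and between shelf positions
#'
#' Aggregates a movement matrix into a 2x2 percentage table over inner and
#' outer midshelf reefs: inner->inner, inner->outer, outer->inner,
#' outer->outer, summing to 100\% of all moves in the matrix.
#'
#' @param m `movement_matrix` object (typically `"moves"` mode).
#' @param shelf_labels named character vector mapping every site in the
#'   matrix to `"inner"` or `"outer"`.
#' @return A 2x2 numeric matrix of percentages with attribute `n_moves`.
#' @export
shelf_position_frequencies <- function(m, shelf_labels) {
  sites <- rownames(m)
  missing_lab <- setdiff(sites, names(shelf_labels))
  if (length(missing_lab) > 0) {
    abort(sprintf("unlabelled site(s): %s", paste(missing_lab, collapse = ", ")))
  }
  if (!all(shelf_labels %in% c("inner", "outer"))) {
    abort("shelf labels must be 'inner' or 'outer'")
  }
  total <- sum(m)
  if (total == 0) abort("no moves in matrix")
  lab <- shelf_labels[sites]
  counts <- matrix(0, 2, 2, dimnames = list(from = c("inner", "outer"),
                                            to = c("inner", "outer")))
  for (a in c("inner", "outer")) for (b in c("inner", "outer")) {
    counts[a, b] <- sum(m[lab == a, lab == b, drop = FALSE])
  }
  out <- 100 * counts / total
  attr(out, "n_moves") <- total
  out
}

#' Acoustic coverage of a reef
#'
#' Fraction of a reef's area inside the nominal detection range of its
#' receivers: the summed detection-range disc areas divided by the reef
#' area, capped at 1. No overlap correction is applied, so tightly packed
#' receivers can saturate the estimate — it is a potential-coverage bound,
#' not a measured one.
#'
#' @param reef_area_km2 positive reef area in square kilometres.
#' @param radii_m positive detection radii, one per receiver, in metres.
#' @return A one-row tibble: `reef_area_km2`, `n_receivers`,
#'   `coverage_fraction` in (0, 1\].
#' @export
#' @examples
#' acoustic_coverage(19.635, c(250, 250)) # 0.02
acoustic_coverage <- function(reef_area_km2, radii_m) {
  assert_scalar_number(reef_area_km2, "reef_area_km2")
  if (reef_area_km2 <= 0) abort("reef area must be positive")
  if (length(radii_m) == 0 || any(radii_m <= 0)) {
    abort("detection radii must be positive")
  }
  disc_km2 <- pi * (radii_m / 1000)^2
  tibble::tibble(reef_area_km2 = reef_area_km2,
                 n_receivers = length(radii_m),
                 coverage_fraction = min(1, sum(disc_km2) / reef_area_km2))
}
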