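check_min_samples <- function(traj, n, what) {
  if (nrow(traj) < n) {
    stop_insufficient(sprintf("%s needs at least %d samples, got %d.",
                              what, n, nrow(traj)))
  }
}

#' Mean speed of the COP
#'
#' Total path length (sum of successive Euclidean displacements) divided by
#' elapsed time, in mm/s. Low values in quiet stance indicate good postural
#' control.
#'
#' @param traj a COP trajectory (`time_s`, `ml_mm`, `ap_mm`).
#' @return mean speed in mm/s.
#' @examples
#' traj <- tibble::tibble(time_s = c(0, 2), ml_mm = c(0, 10), ap_mm = 0)
#' mean_speed(traj) # 10 mm in 2 s -> 5 mm/s
#' @export
mean_speed <- function(traj) {
  traj <- as_cop_trajectory(traj)
  check_min_samples(traj, 2, "mean_speed")
  path <- sum(sqrt(diff(traj$ml_mm)^2 + diff(traj$ap_mm)^2))
  path / (traj$time_s[nrow(traj)] - traj$time_s[1])
}

#' RMS position of the COP
#'
#' Root-mean-square radial distance of the COP from the trajectory's own
#' mean point, in mm.
#'
#' @inheritParams mean_speed
#' @return RMS radial distance in mm.
#' @export
rms_position <- function(traj) {
  traj <- as_cop_trajectory(traj)
  check_min_samples(traj, 2, "rms_position")
  dx <- traj$ml_mm - mean(traj$ml_mm)
  dy <- traj$ap_mm - mean(traj$ap_mm)
  sqrt(mean(dx^2 + dy^2))
}

#' Sway area
#'
#' Surface covered by the COP trajectory, in cm^2. The default is the 95%
#' prediction ellipse, `pi * chi2_2(0.95) * sqrt(det(Sigma))` with `Sigma`
#' the 2 x 2 sample covariance of (ML, AP) — the standard posturographic
#' area measure. `"convex_hull"` returns the area of the convex hull of the
#' samples instead.
#'
#' @inheritParams mean_speed
#' @param method `"ellipse95"` (default) or `"convex_hull"`.
#' @return area in cm^2 (positions are mm, so mm^2 / 100).
#' @examples
#' sq <- tibble::tibble(time_s = 0:3, ml_mm = c(0, 1, 1, 0), ap_mm = c(0, 0, 1, 1))
#' sway_area(sq, method = "convex_hull") # unit square: 0.01 cm^2
#' @export
sway_area <- function(traj, method = c("ellipse95", "convex_hull")) {
  method <- match.arg(method)
  traj <- as_cop_trajectory(traj)
  check_min_samples(traj, 3, "sway_area")
  xy <- cbind(traj$ml_mm, traj$ap_mm)
  if (method == "ellipse95") {
    det_s <- det(cov(xy))
    # collinear samples give a singular covariance: a flat cloud has area 0
    area_mm2 <- pi * qchisq(0.95, df = 2) * sqrt(max(det_s, 0))
  } else {
    hull <- grDevices::chull(xy)
    if (length(hull) < 3) {
      stop_degenerate("convex hull needs at least 3 non-collinear samples.")
    }
    h <- xy[hull, , drop = FALSE]
    i2 <- c(2:nrow(h), 1)
    area_mm2 <- abs(sum(h[, 1] * h[i2, 2] - h[i2, 1] * h[, 2])) / 2
    if (area_mm2 == 0) {
      stop_degenerate("convex hull is degenerate (collinear samples).")
    }
  }
  area_mm2 / 100
}

#' Directional displacement range
#'
#' Max minus min of one COP coordinate, in mm.
#'
#' @inheritParams mean_speed
#' @param axis `"AP"` (anteroposterior) or `"ML"` (mediolateral).
#' @return range in mm.
#' @export
directional_range <- function(traj, axis = c("AP", "ML")) {
  axis <- match.arg(axis)
  traj <- as_cop_trajectory(traj)
  check_min_samples(traj, 2, "directional_range")
  v <- if (axis == "AP") traj$ap_mm else traj$ml_mm
  max(v) - min(v)
}

#' COP limits along the octagon radii
#'
#' Maximum displacement reached along each of the 8 octagon directions,
#' measured from the trajectory's start point (assumed quiet stance at the
#' centre): for direction `d`, the maximum over samples of the scalar
#' projection of `cop - start` onto `d`, floored at 0.
#'
#' @inheritParams mean_speed
#' @param geom a [los_geometry()].
#' @return tibble with columns `direction`, `limit_mm`.
#' @export
cop_limits <- function(traj, geom = los_geometry()) {
  traj <- as_cop_trajectory(traj)
  check_min_samples(traj, 1, "cop_limits")
  rel <- cbind(traj$ml_mm - traj$ml_mm[1], traj$ap_mm - traj$ap_mm[1])
  proj <- rel %*% rbind(geom$ux, geom$uy)
  tibble(
    direction = geom$direction,
    limit_mm = pmax(apply(proj, 2, max), 0)
  )
}

#' Per-direction success score of a LOS trial
#'
#' Quantifies how well-managed the COP excursion was in each direction. The
#' default scorer is a path-efficiency ratio: during the phase in which
#' direction `d` was the target, `100 * (2 * peak on-axis excursion) /
#' (path length travelled)`, clamped to \[0, 100\]. A perfectly straight
#' out-and-back excursion scores 100; a meandering path with twice the
#' straight out-and-back length scores 50; no movement scores 0. The scorer
#' is pluggable: supply any `function(phase, ux, uy)` receiving the phase's
#' samples (a tibble) and the unit direction, returning a percentage.
#'
#' @inheritParams mean_speed
#' @param geom a [los_geometry()].
#' @param scorer scoring function; `NULL` uses the path-efficiency default.
#' @return tibble with columns `direction`, `success_pct`.
#' @export
success_scores <- function(traj, geom = los_geometry(), scorer = NULL) {
  traj <- as_cop_trajectory(traj)
  if (!"target_dir" %in% names(traj)) {
    stop_config("success_scores needs a `target_dir` per-sample annotation.")
  }
  if (is.null(scorer)) scorer <- success_path_efficiency
  scores <- purrr::pmap_dbl(geom, function(direction, ux, uy, target_mm) {
    phase <- traj[traj$target_dir == direction, , drop = FALSE]
    if (nrow(phase) < 2) {
      stop_config(sprintf("no samples annotated for direction '%s'.", direction))
    }
    scorer(phase, ux, uy)
  })
  tibble(direction = geom$direction,
         success_pct = pmin(pmax(scores, 0), 100))
}

# default scorer: effective out-and-back on-axis displacement over distance
# travelled during the phase
success_path_efficiency <- function(phase, ux, uy) {
  path <- sum(sqrt(diff(phase$ml_mm)^2 + diff(phase$ap_mm)^2))
  if (path == 0) return(0)
  onaxis <- (phase$ml_mm - phase$ml_mm[1]) * ux + (phase$ap_mm - phase$ap_mm[1]) * uy
  100 * 2 * max(max(onaxis), 0) / path
}

static_variable_units <- function() {
  tibble(
    variable = c("COP mean speed", "RMS", "Area", "AP disp.", "ML disp."),
    units = c("mm/s", "mm", "cm^2", "mm", "mm")
  )
}

#' Extract the balance variable panel for one task execution
#'
#' Static tasks (RSEO, RSEC, SSEO, SSEC) yield five variables: COP mean
#' speed \[mm/s\], RMS \[mm\], Area \[cm^2\], AP disp. \[mm\], ML disp.
#' \[mm\]. The LOS task yields those five plus the eight per-direction COP
#' limits (`Lim.COP.<direction>` \[mm\]) and eight success scores
#' (`Success.<direction>` \[%\]), 21 variables in total.
#'
#' @inheritParams mean_speed
#' @param task one of `"RSEO"`, `"RSEC"`, `"SSEO"`, `"SSEC"`, `"LOS"`.
#' @param geom a [los_geometry()]; required when `task = "LOS"`.
#' @param scorer optional success scorer passed to [success_scores()].
#' @return tibble with columns `task`, `variable`, `units`, `value`.
#' @export
extract_variables <- function(traj, task = c("RSEO", "RSEC", "SSEO", "SSEC", "LOS"),
                              geom = NULL, scorer = NULL) {
  task <- match.arg(task)
  traj <- as_cop_trajectory(traj)
  static <- static_variable_units()
  static$value <- c(
    mean_speed(traj),
    rms_position(traj),
    sway_area(traj),
    directional_range(traj, "AP"),
    directional_range(traj, "ML")
  )
  out <- static
  if (task == "LOS") {
    if (is.null(geom)) stop_config("LOS extraction requires a `geom` octagon geometry.")
    lims <- cop_limits(traj, geom)
    succ <- success_scores(traj, geom, scorer = scorer)
    out <- dplyr::bind_rows(
      static,
      tibble(variable = paste0("Lim.COP.", lims$direction),
             units = "mm", value = lims$limit_mm),
      tibble(variable = paste0("Success.", succ$direction),
             units = "%", value = succ$success_pct)
    )
  }
  dplyr::bind_cols(tibble(task = task), out)
}
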