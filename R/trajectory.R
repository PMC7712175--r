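#' Compute the centre of pressure from four load cells
#'
#' The platform measures vertical force at four cells of known position; the
#' COP at each sample is the force-weighted centroid of the cell positions:
#' `cop = sum(f_i * p_i) / sum(f_i)`.
#'
#' @param forces data frame with columns `time_s`, `f1`, `f2`, `f3`, `f4`
#'   (forces in N, all >= 0).
#' @param cell_xy 4 x 2 numeric matrix of cell positions, columns (ML, AP)
#'   in mm.
#' @return a `cop_trajectory` tibble (`time_s`, `ml_mm`, `ap_mm`).
#' @examples
#' cells <- rbind(c(-100, 100), c(100, 100), c(100, -100), c(-100, -100))
#' forces <- tibble::tibble(time_s = 0:1, f1 = 1, f2 = 1, f3 = 1, f4 = 1)
#' compute_cop(forces, cells) # equal load -> COP at the centre
#' @export
compute_cop <- function(forces, cell_xy) {
  fcols <- c("f1", "f2", "f3", "f4")
  if (!all(c("time_s", fcols) %in% names(forces))) {
    stop_invalid_spec("`forces` must have columns time_s, f1..f4.")
  }
  cell_xy <- as.matrix(cell_xy)
  if (!all(dim(cell_xy) == c(4, 2))) {
    stop_invalid_spec("`cell_xy` must be a 4 x 2 matrix of (ML, AP) positions.")
  }
  if (nrow(unique(cell_xy)) != 4) {
    stop_invalid_spec("the four cell positions must be distinct.")
  }
  fmat <- as.matrix(forces[fcols])
  if (any(fmat < 0)) stop_invalid_spec("cell forces must be >= 0.")
  total <- rowSums(fmat)
  bad <- which(total <= 0)
  if (length(bad) > 0) {
    stop_degenerate(sprintf(
      "zero total force at sample index %d: COP undefined.", bad[1]))
  }
  cop <- (fmat %*% cell_xy) / total
  dt <- diff(forces$time_s)
  fs <- if (length(dt) > 0 && all(dt > 0)) 1 / stats::median(dt) else NA_real_
  new_cop_trajectory(forces$time_s, cop[, 1], cop[, 2], fs)
}

as_cop_trajectory <- function(x) {
  if (!all(c("time_s", "ml_mm", "ap_mm") %in% names(x))) {
    stop_invalid_spec("a COP trajectory needs columns time_s, ml_mm, ap_mm.")
  }
  if (is.unsorted(x$time_s, strictly = TRUE)) {
    stop_invalid_spec("`time_s` must be strictly increasing.")
  }
  if (!all(is.finite(x$ml_mm)) || !all(is.finite(x$ap_mm))) {
    stop_invalid_spec("COP coordinates must be finite.")
  }
  x
}

traj_fs <- function(traj) {
  fs <- attr(traj, "fs_hz")
  if (!is.null(fs) && is.finite(fs)) return(fs)
  1 / stats::median(diff(traj$time_s))
}

#' Low-pass filter a COP trajectory
#'
#' Zero-phase (forward-backward) second-order Butterworth filter applied to
#' both coordinates. Raw metrics are computed without filtering by default;
#' this is offered for noisy recordings.
#'
#' @param traj a COP trajectory (`time_s`, `ml_mm`, `ap_mm`).
#' @param cutoff_hz cutoff frequency in Hz, below the Nyquist rate.
#' @return the filtered trajectory.
#' @export
lowpass_cop <- function(traj, cutoff_hz = 10) {
  traj <- as_cop_trajectory(traj)
  fs <- traj_fs(traj)
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2) {
    stop_invalid_spec("`cutoff_hz` must lie in (0, fs/2).")
  }
  bf <- signal::butter(2, cutoff_hz / (fs / 2), type = "low")
  traj$ml_mm <- as.numeric(signal::filtfilt(bf, traj$ml_mm))
  traj$ap_mm <- as.numeric(signal::filtfilt(bf, traj$ap_mm))
  traj
}

#' @rdname trajectory_io
#' @export
write_cop_trajectory <- function(traj, path) {
  readr::write_csv(as_tibble(traj), path)
  invisible(path)
}

#' Read and write COP trajectories as delimited text
#'
#' Trajectories are stored as CSV with columns `time_s`, `ml_mm`, `ap_mm`
#' and, for limits-of-stability trials, `target_dir`.
#'
#' @param traj a COP trajectory tibble.
#' @param path file path.
#' @return `read_cop_trajectory()` returns a `cop_trajectory` tibble;
#'   `write_cop_trajectory()` returns `path` invisibly.
#' @name trajectory_io
#' @export
read_cop_trajectory <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  x <- as_cop_trajectory(x)
  new_cop_trajectory(x$time_s, x$ml_mm, x$ap_mm,
                     fs_hz = 1 / stats::median(diff(x$time_s)),
                     target_dir = x[["target_dir"]])
}

#' Plot a COP trajectory
#'
#' @param object a `cop_trajectory`.
#' @param ... unused.
#' @return a ggplot: the sway path in the (ML, AP) plane, coloured by target
#'   direction when present.
#' @method autoplot cop_trajectory
#' @export
autoplot.cop_trajectory <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$ml_mm, y = .data$ap_mm))
  if ("target_dir" %in% names(object)) {
    p <- p + ggplot2::geom_path(ggplot2::aes(colour = .data$target_dir))
  } else {
    p <- p + ggplot2::geom_path(colour = "grey30")
  }
  p + ggplot2::coord_equal() +
    ggplot2::labs(x = "ML [mm]", y = "AP [mm]", colour = "Direction") +
    ggplot2::theme_minimal()
}
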