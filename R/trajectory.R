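#' Construct a trajectory set
#'
#' Six signed lateral-deflection time series at a fixed sampling interval:
#' the minimal distance of each vertical mass pair to the glottal midline,
#' rows ordered as [trajectory_row_labels()] (left rows signed negative by
#' convention).
#'
#' @param values 6 x n numeric matrix of deflections in mm
#' @param dt sampling interval in ms
#' @return an object of class `trajectory_set`
#' @export
trajectory_set <- function(values, dt = 0.25) {
  values <- as.matrix(values)
  if (nrow(values) != 6L) abort("a trajectory set has exactly 6 rows")
  if (ncol(values) < 1L) abort("a trajectory set needs at least one time step")
  if (any(!is.finite(values))) abort("trajectory values must be finite")
  stopifnot(is.numeric(dt), dt > 0)
  rownames(values) <- trajectory_row_labels()
  structure(list(values = values, dt = dt), class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("<trajectory_set> 6 x %d deflections (mm), dt = %g ms (%.1f ms)\n",
              ncol(x$values), x$dt, ncol(x$values) * x$dt))
  rng <- range(x$values)
  cat(sprintf("  range [%.4f, %.4f] mm\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
as_tibble.trajectory_set <- function(x, ...) {
  n <- ncol(x$values)
  out <- tibble(t_ms = (seq_len(n)) * x$dt)
  for (r in trajectory_row_labels()) out[[r]] <- x$values[r, ]
  out
}

#' Tidy a trajectory set into long format
#'
#' @param x a [trajectory_set()]
#' @param ... unused
#' @return tibble with columns `t_ms`, `side`, `section`, `deflection_mm`
#' @export
tidy.trajectory_set <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), -"t_ms",
                      names_to = c("side", "section"), names_sep = "_",
                      values_to = "deflection_mm")
}

#' Plot a trajectory set
#'
#' @param object a [trajectory_set()]
#' @param ... unused
#' @return a ggplot object: deflection against time, one panel per section,
#'   colour per side
#' @export
autoplot.trajectory_set <- function(object, ...) {
  df <- tidy.trajectory_set(object)
  df$section <- factor(df$section, levels = SECTIONS,
                       labels = c("posterior", "medial", "anterior"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_ms, y = .data$deflection_mm,
                                   colour = .data$side)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~section, ncol = 1) +
    ggplot2::labs(x = "time [ms]", y = "lateral deflection [mm]",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Simulate one six-mass model instance
#'
#' Integrates the lateral six-mass system with classical RK4 from the standard
#' initial condition (lower masses deflected outward by
#' `initial_lower_deflection`, upper masses at rest, zero velocities) and
#' returns the mass-pair edge trajectories.
#'
#' @param q a [scaling_vector()]
#' @param rest a [rest_positions()] grid (mm)
#' @param cfg a [phys_config()]
#' @param keep_history keep the full 12-mass state history (for diagnostics)
#' @return a list of class `sim_result`: `traj` (a [trajectory_set()] in mm;
#'   `NULL` if the integration went non-finite at step 1), `ok` (logical),
#'   `bad_step` (first non-finite step index or `NA`), and when requested
#'   `x_hist`/`v_hist` (12 x n matrices, SI units)
#' @export
simulate_sixmass <- function(q = scaling_vector(),
                             rest = rest_positions(numeric(6)),
                             cfg = phys_config(),
                             keep_history = FALSE) {
  q <- scaling_vector(q)
  if (!inherits(rest, "rest_positions")) rest <- rest_positions(rest)
  validate_phys_config(cfg)
  res <- .simulate_cpp(as.numeric(q), as.numeric(rest) * MM, config_si(cfg),
                       cfg$n_steps, keep_history)
  traj <- NULL
  if (res$ok) {
    traj <- trajectory_set(res$traj / MM, dt = cfg$dt)
  } else if (!is.na(res$bad_step) && res$bad_step > 1L) {
    traj <- trajectory_set(res$traj[, seq_len(res$bad_step - 1L), drop = FALSE] / MM,
                           dt = cfg$dt)
  }
  structure(list(traj = traj, ok = res$ok, bad_step = res$bad_step,
                 x_hist = res$x_hist, v_hist = res$v_hist,
                 q = q, rest = rest),
            class = "sim_result")
}

#' Extract trajectories from a state history
#'
#' For each side and longitudinal section the trajectory is the signed lateral
#' position of the vertical-pair member closest to the glottal midline
#' (tie: the lower mass). Overlap states may cross zero; the raw signed value
#' is recorded.
#'
#' @param x_hist 12 x n state-history matrix in SI metres (layout of
#'   `simulate_sixmass(keep_history = TRUE)$x_hist`)
#' @param cfg a [phys_config()] (supplies `dt`)
#' @return a [trajectory_set()] in mm
#' @export
extract_trajectories <- function(x_hist, cfg = phys_config()) {
  stopifnot(is.matrix(x_hist), nrow(x_hist) == 12L, ncol(x_hist) >= 1L)
  n <- ncol(x_hist)
  out <- matrix(0, 6L, n)
  for (s in 1:2) for (j in 1:3) {
    ib <- (s - 1) * 6 + (j - 1) * 2 + 1   # bottom
    it <- ib + 1                          # top
    xb <- x_hist[ib, ]; xu <- x_hist[it, ]
    out[(s - 1) * 3 + j, ] <- ifelse(abs(xu) < abs(xb), xu, xb)
  }
  trajectory_set(out / MM, dt = cfg$dt)
}

#' Oscillation filter
#'
#' A simulated sample counts as oscillating when its trajectory standard
#' deviation statistic reaches `threshold`. Following the model's classical
#' CGS convention the statistic is computed on trajectories expressed in cm
#' (the default threshold of `1e-3` therefore corresponds to a 10 um standard
#' deviation), per trajectory over the post-transient window, then aggregated
#' over the six rows (mean by default). Values exactly at the threshold pass.
#'
#' @param traj a [trajectory_set()] (mm), or `NULL` (an unstable simulation),
#'   which never oscillates
#' @param threshold unitless threshold on the std statistic (default `1e-3`)
#' @param transient_ms initial window excluded from the statistic (ms)
#' @param aggregate `"mean"` (default) or `"min"` over the six rows
#' @param unit length unit the statistic is computed in
#' @return logical flag
#' @export
is_oscillating <- function(traj, threshold = 1e-3, transient_ms = 75,
                           aggregate = c("mean", "min"),
                           unit = c("cm", "mm", "m")) {
  aggregate <- match.arg(aggregate)
  unit <- match.arg(unit)
  if (is.null(traj)) return(FALSE)
  stopifnot(inherits(traj, "trajectory_set"))
  oscillation_statistic(traj, transient_ms, aggregate, unit) >= threshold
}

# the scalar std statistic behind the oscillation filter
oscillation_statistic <- function(traj, transient_ms = 75,
                                  aggregate = c("mean", "min"),
                                  unit = c("cm", "mm", "m")) {
  aggregate <- match.arg(aggregate)
  unit <- match.arg(unit)
  fac <- switch(unit, cm = MM / CM, mm = 1, m = MM)
  v <- traj$values * fac
  start <- min(ncol(v), floor(transient_ms / traj$dt) + 1L)
  v <- v[, start:ncol(v), drop = FALSE]
  if (ncol(v) < 2L) return(0)
  stds <- apply(v, 1L, stats::sd)
  if (aggregate == "mean") mean(stds) else min(stds)
}

#' Read / write trajectory CSV files
#'
#' Plain CSV with header `t_ms,left_P,left_M,left_A,right_P,right_M,right_A`,
#' deflections in mm, left columns signed negative. The sampling interval is
#' inferred from the `t_ms` column. A violated sign convention produces a
#' warning, not an error, and the data are preserved.
#'
#' @param path file path
#' @param traj a [trajectory_set()]
#' @param digits significant digits written
#' @return `read_trajectories()` returns a [trajectory_set()];
#'   `write_trajectories()` returns `path` invisibly.
#' @export
read_trajectories <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("t_ms", trajectory_row_labels())
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("trajectory file is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (nrow(df) < 2L) abort("trajectory file needs at least 2 rows")
  for (cn in need) {
    if (!is.numeric(df[[cn]])) {
      abort(sprintf("non-numeric values in column '%s'", cn))
    }
  }
  dts <- diff(df$t_ms)
  if (any(dts <= 0) || (max(dts) - min(dts)) > 1e-6 * mean(dts)) {
    abort("t_ms column must be strictly increasing and equispaced")
  }
  vals <- t(as.matrix(df[, trajectory_row_labels()]))
  if (any(vals[1:3, ] > 0) || any(vals[4:6, ] < 0)) {
    warn("trajectory sign convention violated (left should be <= 0, right >= 0); data preserved")
  }
  trajectory_set(vals, dt = mean(dts))
}

#' @rdname read_trajectories
#' @export
write_trajectories <- function(traj, path, digits = 8) {
  stopifnot(inherits(traj, "trajectory_set"))
  df <- as.data.frame(as_tibble.trajectory_set(traj))
  df[] <- lapply(df, function(col) signif(col, digits))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
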