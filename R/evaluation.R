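#' Fundamental frequency estimate with overtone suppression
#'
#' Estimates f0 as the arg-max over frequencies above 50 Hz of the
#' reciprocally scaled Fourier magnitude `|X(f)| / f` of the mean-removed
#' signal (the 1/f weighting suppresses overtones). Resolution is one
#' spectral bin, `fs / n`.
#'
#' @param x numeric time series (one trajectory row)
#' @param fs sampling rate in Hz (4 kHz at the default 0.25 ms step)
#' @param f_min lower cutoff in Hz (frequencies at or below are ignored)
#' @param weighting `"1/f"` (default) or `"1/f2"`
#' @return estimated f0 in Hz, or `NA` with a warning for a constant signal
#' @export
estimate_f0 <- function(x, fs = 4000, f_min = 50,
                        weighting = c("1/f", "1/f2")) {
  weighting <- match.arg(weighting)
  x <- as.numeric(x)
  n <- length(x)
  if (n < 4L || stats::sd(x) == 0) {
    warn("f0 undefined for a constant signal")
    return(NA_real_)
  }
  x <- x - mean(x)
  spec <- Mod(fft(x))[seq_len(n %/% 2L)]
  freqs <- (seq_len(n %/% 2L) - 1L) * fs / n
  keep <- freqs > f_min
  if (!any(keep)) {
    warn("no spectral bins above the cutoff")
    return(NA_real_)
  }
  w <- if (weighting == "1/f") spec[keep] / freqs[keep] else spec[keep] / freqs[keep]^2
  freqs[keep][which.max(w)]
}

#' Trajectory amplitude
#'
#' The maximum of the positively-oriented trajectory: right rows are used as
#' recorded, left rows (signed negative) are sign-flipped first.
#'
#' @param x numeric trajectory (mm)
#' @param side `"right"` (identity orientation) or `"left"` (flip sign)
#' @return amplitude in mm
#' @export
amplitude <- function(x, side = c("right", "left")) {
  side <- match.arg(side)
  x <- as.numeric(x)
  stopifnot(length(x) >= 1L)
  if (side == "left") x <- -x
  max(x)
}

#' Per-trajectory observables
#'
#' Fundamental frequency and amplitude of each of the six trajectories,
#' estimated on the post-transient window.
#'
#' @param traj a [trajectory_set()]
#' @param transient_ms initial window excluded from the estimates (ms)
#' @return tibble with columns `row`, `side`, `section`, `f0` (Hz),
#'   `amplitude` (mm)
#' @export
trajectory_observables <- function(traj, transient_ms = 75) {
  stopifnot(inherits(traj, "trajectory_set"))
  fs <- 1000 / traj$dt
  start <- min(ncol(traj$values), floor(transient_ms / traj$dt) + 1L)
  v <- traj$values[, start:ncol(traj$values), drop = FALSE]
  tibble(
    row = trajectory_row_labels(),
    side = rep(SIDES, each = 3L),
    section = rep(SECTIONS, 2L),
    f0 = vapply(1:6, function(i) suppressWarnings(estimate_f0(v[i, ], fs)), numeric(1)),
    amplitude = vapply(1:6, function(i) amplitude(v[i, ], side = rep(SIDES, each = 3L)[i]),
                       numeric(1))
  )
}

#' Statistical-guess baseline for every parameter
#'
#' The optimal constant guess for an i.i.d. log-uniform component is the
#' distribution median; its expected absolute error (about 0.994 at the
#' default bounds) is identical for all 14 components.
#'
#' @param bounds a [loguniform_bounds()]
#' @return tibble with columns `parameter`, `optimal_guess`, `mae_bound`
#' @export
guess_baseline_table <- function(bounds = loguniform_bounds()) {
  u <- sqrt(bounds$q_min * bounds$q_max)
  tibble(parameter = scaling_names(),
         optimal_guess = u,
         mae_bound = optimal_guess_mae(u, bounds))
}

#' Evaluate a surrogate in observable space
#'
#' Predicts scaling vectors for every record of a test set, re-simulates the
#' six-mass model at the predictions (rest positions taken as the time-wise
#' means of the observed trajectories), and compares observed against
#' re-simulated trajectories via fundamental frequency and amplitude, and
#' the subglottal pressure factor against its truth (also in Pa, through the
#' default 800 Pa). Re-simulation instabilities are excluded from the
#' averages with a logged count.
#'
#' @param model a trained `sixmass_surrogate`, or a function mapping a
#'   [trajectory_set()] to a 14-long scaling vector (an oracle, for
#'   validation)
#' @param testset a `labeled_dataset`
#' @param cfg a [phys_config()]
#' @param transient_ms transient cut for the observable estimates (ms)
#' @param rest_source where the re-simulation's rest positions come from:
#'   `"trajectory_means"` (the time-wise means of the observed trajectories,
#'   the only estimate available for recordings; default) or `"labels"` (the
#'   stored generating rest positions, available for synthetic data and used
#'   by the pipeline's oracle checks)
#' @return an object of class `prediction_report`: list with `summary` (a
#'   tibble of MAE/MAPE/median-AE per observable), `per_sample` (tibble),
#'   `p_s_correlation`, `n_evaluated`, `n_unstable`
#' @export
evaluate_surrogate <- function(model, testset, cfg = phys_config(),
                               transient_ms = 75,
                               rest_source = c("trajectory_means", "labels")) {
  rest_source <- match.arg(rest_source)
  stopifnot(inherits(testset, "labeled_dataset"))
  n <- length(testset$records)
  if (n == 0L) abort("empty test set")

  qhat <- if (inherits(model, "sixmass_surrogate")) {
    as.matrix(predict(model, testset))
  } else if (is.function(model)) {
    t(vapply(testset$records, function(r) as.numeric(model(r$traj)), numeric(14)))
  } else {
    abort("model must be a sixmass_surrogate or a predictor function")
  }
  colnames(qhat) <- scaling_names()

  rows <- vector("list", n)
  n_unstable <- 0L
  for (i in seq_len(n)) {
    rec <- testset$records[[i]]
    obs <- trajectory_observables(rec$traj, transient_ms)
    rest <- if (rest_source == "labels") {
      rest_positions(rec$rest)
    } else {
      # time-wise trajectory means, clamped to the sign convention
      rest_raw <- rowMeans(rec$traj$values)
      rest_positions(c(pmin(rest_raw[1:3], 0), pmax(rest_raw[4:6], 0)))
    }
    sim <- simulate_sixmass(scaling_vector(qhat[i, ]), rest, cfg)
    if (!sim$ok) {
      n_unstable <- n_unstable + 1L
      next
    }
    prd <- trajectory_observables(sim$traj, transient_ms)
    rows[[i]] <- tibble(
      sample = i,
      p_s_true = rec$q[["p_s"]],
      p_s_pred = qhat[i, "p_s"],
      f0_true = mean(obs$f0, na.rm = TRUE),
      f0_pred = mean(prd$f0, na.rm = TRUE),
      amp_true = mean(obs$amplitude),
      amp_pred = mean(prd$amplitude)
    )
  }
  per_sample <- dplyr::bind_rows(rows)
  if (nrow(per_sample) == 0L) abort("every re-simulation was unstable")

  mk <- function(true, pred, name, unit) {
    ae <- abs(pred - true)
    tibble(observable = name, unit = unit,
           mae = mean(ae), medae = median(ae),
           mape = mean(ae / pmax(abs(true), 1e-12)))
  }
  summary <- dplyr::bind_rows(
    mk(per_sample$p_s_true, per_sample$p_s_pred, "p_s_scale", ""),
    mk(per_sample$p_s_true * cfg$p_s, per_sample$p_s_pred * cfg$p_s, "p_s", "Pa"),
    mk(per_sample$f0_true, per_sample$f0_pred, "f0", "Hz"),
    mk(per_sample$amp_true, per_sample$amp_pred, "amplitude", "mm")
  )
  structure(list(summary = summary, per_sample = per_sample,
                 p_s_correlation = suppressWarnings(
                   stats::cor(per_sample$p_s_true, per_sample$p_s_pred)),
                 n_evaluated = nrow(per_sample),
                 n_unstable = n_unstable),
            class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("<prediction_report> %d samples evaluated (%d unstable re-simulations excluded)\n",
              x$n_evaluated, x$n_unstable))
  cat(sprintf("  P_S correlation: %.3f\n", x$p_s_correlation))
  print(as.data.frame(x$summary), digits = 3)
  invisible(x)
}

#' @export
tidy.prediction_report <- function(x, ...) x$summary

#' @export
glance.prediction_report <- function(x, ...) {
  s <- x$summary
  tibble(p_s_mae_pa = s$mae[s$observable == "p_s"],
         f0_mae_hz = s$mae[s$observable == "f0"],
         amplitude_mae_mm = s$mae[s$observable == "amplitude"],
         p_s_correlation = x$p_s_correlation,
         n_evaluated = x$n_evaluated,
         n_unstable = x$n_unstable)
}

#' @export
autoplot.prediction_report <- function(object, ...) {
  df <- object$per_sample
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p_s_true * 800,
                                   y = .data$p_s_pred * 800)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(linetype = "dashed") +
    ggplot2::labs(x = "true P_S [Pa]", y = "predicted P_S [Pa]") +
    ggplot2::theme_minimal()
}
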