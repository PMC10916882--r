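#' Log-uniform sampling bounds
#'
#' Boundaries of the log-uniform law used for every scaling-vector component.
#' The defaults (1/5, 5) are reciprocally inverse, which makes the median 1:
#' scaling by less than a factor is exactly as likely as scaling by more than
#' its reciprocal, so the distribution is symmetric around the model defaults.
#'
#' @param q_min,q_max strictly positive bounds, `q_min < q_max`
#' @return an object of class `loguniform_bounds`
#' @export
loguniform_bounds <- function(q_min = 1 / 5, q_max = 5) {
  stopifnot(is.numeric(q_min), is.numeric(q_max),
            q_min > 0, q_min < q_max, is.finite(q_max))
  structure(list(q_min = q_min, q_max = q_max), class = "loguniform_bounds")
}

#' Draw a scaling vector
#'
#' Each of the 14 components is drawn i.i.d. from the log-uniform density
#' `1 / (q log(q_max/q_min))` on `[q_min, q_max]`, i.e.
#' `exp(Uniform(log q_min, log q_max))`.
#'
#' @param bounds a [loguniform_bounds()]
#' @param n number of vectors to draw
#' @return for `n = 1` a [scaling_vector()]; otherwise an `n x 14` matrix
#'   with one scaling vector per row
#' @export
sample_scaling_vector <- function(bounds = loguniform_bounds(), n = 1L) {
  stopifnot(inherits(bounds, "loguniform_bounds"), n >= 1L)
  draws <- exp(matrix(runif(14L * n, log(bounds$q_min), log(bounds$q_max)),
                      nrow = n))
  colnames(draws) <- scaling_names()
  if (n == 1L) scaling_vector(draws[1L, ]) else draws
}

#' Mean of the log-uniform law
#'
#' Closed form `(q_max - q_min) / log(q_max / q_min)`; approximately 1.49 at
#' the default bounds (while the median is exactly `sqrt(q_min q_max)` = 1).
#'
#' @param bounds a [loguniform_bounds()]
#' @return scalar mean
#' @export
loguniform_mean <- function(bounds = loguniform_bounds()) {
  stopifnot(inherits(bounds, "loguniform_bounds"))
  (bounds$q_max - bounds$q_min) / log(bounds$q_max / bounds$q_min)
}

#' Expected absolute error of a constant guess
#'
#' For a log-uniform variable `q` on `(a, b)`, the mean absolute error of a
#' constant guess `u` in closed form:
#' `E|q - u| = (b + a + u log(u^2/(ab)) - 2u) / log(b/a)`.
#' It is minimised at the distribution median `u = sqrt(ab)`, giving the
#' optimal statistical-guess baseline (about 0.994 at the default bounds).
#'
#' @param u constant guess, within the bounds
#' @param bounds a [loguniform_bounds()]
#' @return scalar expected absolute error
#' @export
optimal_guess_mae <- function(u = 1, bounds = loguniform_bounds()) {
  stopifnot(inherits(bounds, "loguniform_bounds"))
  a <- bounds$q_min; b <- bounds$q_max
  if (!is.numeric(u) || any(u < a) || any(u > b)) {
    abort("the guess u must lie within the sampling bounds")
  }
  (b + a + u * log(u^2 / (a * b)) - 2 * u) / log(b / a)
}

#' Shifted-gamma marginal of a rest position
#'
#' Law of the magnitude of one rest position: `Gamma(alpha, scale = beta) + c`.
#' The shipped defaults for the three longitudinal sections (posterior,
#' medial, anterior) are the fitted values for time-averaged porcine
#' high-speed-video trajectories, in mm.
#'
#' @param alpha shape (> 0)
#' @param beta scale (> 0), in mm
#' @param c shift, in mm
#' @param section optional section label ("P", "M" or "A")
#' @return an object of class `gamma_marginal`
#' @export
gamma_marginal <- function(alpha, beta, c = 0, section = NA_character_) {
  stopifnot(is.numeric(alpha), alpha > 0, is.numeric(beta), beta > 0,
            is.numeric(c), is.finite(c))
  structure(list(alpha = alpha, beta = beta, c = c, section = section),
            class = "gamma_marginal")
}

#' Default rest-position marginals
#'
#' The three shifted-gamma marginals (posterior, medial, anterior) fitted to
#' time-averaged experimental trajectories; skewness is strongest posteriorly
#' and nearly Gaussian anteriorly (large shape).
#'
#' @return named list of three [gamma_marginal()] objects (`P`, `M`, `A`)
#' @export
default_marginals <- function() {
  path <- system.file("extdata", "gamma_marginals.csv", package = "sixmass")
  read_marginals(path)
}

#' Read / write marginal tables
#'
#' CSV with columns `section, alpha, beta, c` (beta is the gamma scale in mm).
#'
#' @param path file path
#' @param marginals named list of [gamma_marginal()]s
#' @return `read_marginals()` returns a named list of [gamma_marginal()]s
#' @export
read_marginals <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("section", "alpha", "beta", "c") %in% names(df)))
  out <- lapply(seq_len(nrow(df)), function(i) {
    gamma_marginal(df$alpha[i], df$beta[i], df$c[i], df$section[i])
  })
  names(out) <- df$section
  out[SECTIONS]
}

#' @rdname read_marginals
#' @export
write_marginals <- function(marginals, path) {
  df <- do.call(rbind, lapply(marginals, function(m) {
    data.frame(section = m$section, alpha = m$alpha, beta = m$beta, c = m$c)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Rest-position dependence structure
#'
#' A normal copula joins the six shifted-gamma marginals: the 6 x 6
#' correlation matrix `rho` (rows/columns ordered as
#' [trajectory_row_labels()]) is blended towards independence as
#' `rho_blend = d I + (1 - d) rho` with `d` in `[0, 1]` (default 0.5, which
#' enlarges sampling diversity).
#'
#' @param rho symmetric positive-semidefinite correlation matrix with unit
#'   diagonal; defaults to [default_rest_correlation()]
#' @param d blend weight towards independence
#' @return an object of class `copula_spec`
#' @export
copula_spec <- function(rho = default_rest_correlation(), d = 0.5) {
  rho <- as.matrix(rho)
  stopifnot(all(dim(rho) == c(6L, 6L)), is.numeric(d), d >= 0, d <= 1)
  if (max(abs(rho - t(rho))) > 1e-8) abort("rho must be symmetric")
  if (max(abs(diag(rho) - 1)) > 1e-8) abort("rho must have unit diagonal")
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) abort("rho must be positive semidefinite")
  blended <- d * diag(6) + (1 - d) * rho
  if (d > 0) {
    evb <- eigen(blended, symmetric = TRUE, only.values = TRUE)$values
    if (min(evb) <= 0) abort("blended correlation must be positive definite")
  }
  dimnames(rho) <- dimnames(blended) <-
    list(trajectory_row_labels(), trajectory_row_labels())
  structure(list(rho = rho, d = d, blended = blended), class = "copula_spec")
}

#' Default rest-position correlation matrix
#'
#' A documented correlation matrix consistent with the experimentally
#' observed structure: same-side medial-to-neighbour correlations within
#' 0.31-0.63, opposite-side anti-correlation strongest posteriorly (-0.8) and
#' weakest anteriorly (-0.2), plus the observed left-anterior anomaly
#' (+0.46 to the opposite posterior, -0.39 to the left posterior). Users can
#' replace it with a matrix estimated from their own trajectory files via
#' [estimate_rest_correlation()].
#'
#' @return 6 x 6 correlation matrix
#' @export
default_rest_correlation <- function() {
  path <- system.file("extdata", "default_rho.csv", package = "sixmass")
  rho <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  dimnames(rho) <- list(trajectory_row_labels(), trajectory_row_labels())
  rho
}

#' Estimate a rest-position correlation matrix from trajectory files
#'
#' Computes the Pearson correlation of the time-wise trajectory means across
#' a set of recordings (one [trajectory_set()] per file).
#'
#' @param paths character vector of trajectory CSV paths (at least 3)
#' @return 6 x 6 correlation matrix
#' @export
estimate_rest_correlation <- function(paths) {
  stopifnot(length(paths) >= 3L)
  means <- t(vapply(paths, function(p) {
    rowMeans(read_trajectories(p)$values)
  }, numeric(6)))
  rho <- stats::cor(means)
  dimnames(rho) <- list(trajectory_row_labels(), trajectory_row_labels())
  rho
}

#' Sample rest-position grids
#'
#' Draws `z ~ N(0, rho_blend)`, maps each component through the standard
#' normal CDF and the inverse CDF of the section's shifted gamma, and applies
#' the side signs (left negative). Marginal laws are exactly the specified
#' gammas; the tiny negative-magnitude tail admitted by a negative shift `c`
#' is clamped to zero so the sign convention always holds.
#'
#' @param marginals named list of three [gamma_marginal()]s (`P`, `M`, `A`)
#' @param copula a [copula_spec()]
#' @param n number of grids
#' @return `n x 6` matrix of signed rest positions (mm), columns
#'   [trajectory_row_labels()]
#' @export
sample_rest_positions <- function(marginals = default_marginals(),
                                  copula = copula_spec(), n = 1L) {
  stopifnot(inherits(copula, "copula_spec"), n >= 1L)
  L <- chol(copula$blended)
  z <- matrix(rnorm(n * 6L), n, 6L) %*% L
  u <- pnorm(z)
  out <- matrix(0, n, 6L)
  side_sign <- c(-1, -1, -1, 1, 1, 1)
  for (col in 1:6) {
    m <- marginals[[SECTIONS[(col - 1L) %% 3L + 1L]]]
    mag <- qgamma(u[, col], shape = m$alpha, scale = m$beta) + m$c
    out[, col] <- side_sign[col] * pmax(mag, 0)
  }
  colnames(out) <- trajectory_row_labels()
  out
}

#' Fit shifted-gamma marginals
#'
#' Maximum-likelihood fit of `Gamma(alpha, scale = beta) + c` to
#' positively-oriented per-position trajectory means, with the shift profile
#' optimised: for each candidate `c` below the sample minimum the gamma part
#' is fitted to `x - c` (via [fitdistrplus::fitdist()]), and `c` is chosen to
#' maximise the profile likelihood. The fitted CDF is checked against the
#' fitting data with a Kolmogorov-Smirnov test at the 1% level.
#'
#' @param samples numeric vector (>= 30 positive-oriented values)
#' @param section optional section label carried into the result
#' @return a [gamma_marginal()] with attributes `logLik` and `ks_p`
#' @export
fit_gamma_marginals <- function(samples, section = NA_character_) {
  samples <- as.numeric(samples)
  if (length(samples) < 30L) abort("need at least 30 samples per position")
  if (stats::sd(samples) == 0) abort("degenerate (constant) samples")

  fit_for_shift <- function(cc) {
    y <- samples - cc
    fit <- tryCatch(
      fitdistrplus::fitdist(y, "gamma", method = "mle",
                            start = moment_start(y), keepdata = FALSE),
      error = function(e) NULL
    )
    if (is.null(fit) || !is.finite(fit$loglik)) return(NULL)
    fit
  }
  moment_start <- function(y) {
    mu <- mean(y); s2 <- stats::var(y)
    list(shape = max(mu^2 / s2, 1e-3), rate = max(mu / s2, 1e-8))
  }

  # profile the shift on (min - 3*sd, min); c must stay below the minimum
  lo <- min(samples) - 3 * stats::sd(samples)
  hi <- min(samples) - 1e-9 * max(1, abs(min(samples)))
  prof <- function(cc) {
    f <- fit_for_shift(cc)
    if (is.null(f)) return(1e10)
    -f$loglik
  }
  opt <- stats::optimize(prof, interval = c(lo, hi))
  cc <- opt$minimum
  fit <- fit_for_shift(cc)
  if (is.null(fit)) abort("shifted-gamma fit failed")
  alpha <- unname(fit$estimate[["shape"]])
  beta <- 1 / unname(fit$estimate[["rate"]])
  ks <- suppressWarnings(
    ks.test(samples, function(xx) pgamma(xx - cc, shape = alpha, scale = beta))
  )
  out <- gamma_marginal(alpha, beta, cc, section)
  attr(out, "logLik") <- fit$loglik
  attr(out, "ks_p") <- ks$p.value
  if (ks$p.value < 0.01) {
    warn(sprintf("shifted-gamma fit rejected at the 1%% level (KS p = %.3g)",
                 ks$p.value))
  }
  out
}

#' Build a labeled synthetic dataset
#'
#' For each requested sample a scaling vector and a rest-position grid are
#' drawn, the six-mass model is simulated, the edge trajectories extracted,
#' and the record kept iff it passes the oscillation filter. Simulation
#' instabilities count as excluded. Everything is reproducible from the seed.
#'
#' @param n_requested number of samples to draw
#' @param bounds a [loguniform_bounds()]
#' @param marginals named list of [gamma_marginal()]s
#' @param copula a [copula_spec()]
#' @param cfg a [phys_config()]
#' @param seed integer RNG seed
#' @param threshold oscillation-filter threshold (see [is_oscillating()])
#' @param progress print a progress line every 1000 samples
#' @return an object of class `labeled_dataset`: list with `records` (each a
#'   list of `traj` ([trajectory_set()]), `q`, `rest`), `seed`, `bounds`,
#'   `survival_fraction`, `n_requested`, `n_excluded`, `n_unstable`
#' @export
build_dataset <- function(n_requested,
                          bounds = loguniform_bounds(),
                          marginals = default_marginals(),
                          copula = copula_spec(),
                          cfg = phys_config(),
                          seed = 1L,
                          threshold = 1e-3,
                          progress = FALSE) {
  stopifnot(n_requested >= 1L)
  set.seed(seed)
  qs <- sample_scaling_vector(bounds, n = n_requested)
  if (n_requested == 1L) qs <- matrix(qs, 1L, 14L, dimnames = list(NULL, scaling_names()))
  rests <- sample_rest_positions(marginals, copula, n = n_requested)
  cfg_si <- config_si(cfg)

  records <- vector("list", n_requested)
  kept <- 0L
  n_unstable <- 0L
  for (i in seq_len(n_requested)) {
    res <- .simulate_cpp(qs[i, ], rests[i, ] * MM, cfg_si, cfg$n_steps, FALSE)
    if (!res$ok) {
      n_unstable <- n_unstable + 1L
      next
    }
    traj <- trajectory_set(res$traj / MM, dt = cfg$dt)
    if (is_oscillating(traj, threshold = threshold)) {
      kept <- kept + 1L
      records[[kept]] <- list(traj = traj, q = qs[i, ], rest = rests[i, ])
    }
    if (progress && i %% 1000L == 0L) {
      message(sprintf("  %d / %d simulated, %d kept", i, n_requested, kept))
    }
  }
  structure(list(
    records = records[seq_len(kept)],
    seed = seed,
    bounds = bounds,
    survival_fraction = kept / n_requested,
    n_requested = as.integer(n_requested),
    n_excluded = as.integer(n_requested - kept),
    n_unstable = n_unstable,
    dt = cfg$dt,
    threshold = threshold
  ), class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d records (of %d requested; survival %.1f%%, %d unstable)\n",
              length(x$records), x$n_requested, 100 * x$survival_fraction,
              x$n_unstable))
  cat(sprintf("  seed %d, bounds [%.3g, %.3g], dt %g ms\n",
              x$seed, x$bounds$q_min, x$bounds$q_max, x$dt))
  invisible(x)
}

#' Glance at a labeled dataset
#'
#' @param x a `labeled_dataset`
#' @param ... unused
#' @return one-row tibble of generation metadata
#' @export
glance.labeled_dataset <- function(x, ...) {
  tibble(n_records = length(x$records), n_requested = x$n_requested,
         n_excluded = x$n_excluded, n_unstable = x$n_unstable,
         survival_fraction = x$survival_fraction, seed = x$seed,
         q_min = x$bounds$q_min, q_max = x$bounds$q_max)
}

#' Save / load a labeled dataset
#'
#' The on-disk container is a single RDS file holding the logical keys
#' `trajectories` (N x 6 x n), `q` (N x 14),
#' `rest_positions` (N x 6) and the generation metadata. A plain-text export
#' of the labels (`q` and rest positions as CSV) is written alongside when
#' `labels_csv` is given.
#'
#' @param dataset a `labeled_dataset`
#' @param path RDS file path
#' @param labels_csv optional CSV path for the label table
#' @return `load_dataset()` returns a `labeled_dataset`
#' @export
save_dataset <- function(dataset, path, labels_csv = NULL) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  n <- length(dataset$records)
  nt <- if (n > 0) ncol(dataset$records[[1]]$traj$values) else 0L
  traj <- array(0, dim = c(n, 6L, nt))
  qm <- matrix(0, n, 14L, dimnames = list(NULL, scaling_names()))
  rm_ <- matrix(0, n, 6L, dimnames = list(NULL, trajectory_row_labels()))
  for (i in seq_len(n)) {
    rec <- dataset$records[[i]]
    traj[i, , ] <- rec$traj$values
    qm[i, ] <- rec$q
    rm_[i, ] <- rec$rest
  }
  obj <- list(trajectories = traj, q = qm, rest_positions = rm_,
              seed = dataset$seed,
              bounds = c(dataset$bounds$q_min, dataset$bounds$q_max),
              dt = dataset$dt, threshold = dataset$threshold,
              survival_fraction = dataset$survival_fraction,
              n_requested = dataset$n_requested,
              n_unstable = dataset$n_unstable)
  saveRDS(obj, path)
  if (!is.null(labels_csv)) {
    utils::write.csv(cbind(as.data.frame(qm), as.data.frame(rm_)),
                     labels_csv, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) {
  obj <- readRDS(path)
  n <- nrow(obj$q)
  records <- lapply(seq_len(n), function(i) {
    list(traj = trajectory_set(obj$trajectories[i, , ], dt = obj$dt),
         q = obj$q[i, ], rest = obj$rest_positions[i, ])
  })
  structure(list(records = records, seed = obj$seed,
                 bounds = loguniform_bounds(obj$bounds[1], obj$bounds[2]),
                 survival_fraction = obj$survival_fraction,
                 n_requested = obj$n_requested,
                 n_excluded = obj$n_requested - n,
                 n_unstable = obj$n_unstable,
                 dt = obj$dt, threshold = obj$threshold),
            class = "labeled_dataset")
}
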