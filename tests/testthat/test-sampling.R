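test_that("log-uniform draws have median 1, mean 1.49 and reciprocal symmetry", {
  set.seed(101)
  draws <- sample_scaling_vector(n = 8000L)
  all_q <- as.numeric(draws)          # 8000 x 14 i.i.d. components
  expect_equal(median(all_q), 1, tolerance = 0.02)
  expect_equal(mean(all_q), loguniform_mean(), tolerance = 0.02)
  # P(q <= 2) == P(q >= 1/2) within 3 Monte-Carlo sigma
  p1 <- mean(all_q <= 2); p2 <- mean(all_q >= 0.5)
  se <- sqrt(p1 * (1 - p1) / length(all_q))
  expect_lt(abs(p1 - p2), 3 * sqrt(2) * se)
  expect_true(all(all_q >= 0.2 - 1e-12 & all_q <= 5 + 1e-12))
})

test_that("log-uniform mean has its closed form", {
  expect_equal(loguniform_mean(loguniform_bounds(0.2, 5)), 4.8 / log(25))
  expect_equal(round(loguniform_mean(), 2), 1.49)
  expect_equal(loguniform_mean(loguniform_bounds(1, exp(1))), exp(1) - 1)
  # degenerate limit -> a
  expect_equal(loguniform_mean(loguniform_bounds(2, 2 * (1 + 1e-9))), 2,
               tolerance = 1e-6)
})

test_that("expected absolute error of a constant guess matches its closed form", {
  # printed value at the median guess
  expect_equal(round(optimal_guess_mae(1), 3), 0.994)
  # minimised at the median sqrt(ab)
  us <- seq(0.25, 4.5, by = 0.05)
  vals <- optimal_guess_mae(us)
  expect_equal(us[which.min(vals)], 1, tolerance = 0.051)
  expect_error(optimal_guess_mae(10), "within the sampling bounds")
  # Monte-Carlo oracle equivalence for random guesses
  set.seed(7)
  q <- exp(runif(2e5, log(0.2), log(5)))
  for (u in c(0.3, 0.7, 1, 2, 4.2)) {
    mc <- mean(abs(q - u))
    se <- sd(abs(q - u)) / sqrt(length(q))
    expect_lt(abs(mc - optimal_guess_mae(u)), 3 * se + 1e-12)
  }
})

test_that("shifted-gamma fitting recovers known parameters", {
  set.seed(55)
  # generator truth: the posterior-row marginal
  truth <- gamma_marginal(5.59, 7.96e-3, -1.66e-4)
  x <- rgamma(576, shape = truth$alpha, scale = truth$beta) + truth$c
  fit <- fit_gamma_marginals(x, section = "P")
  expect_lt(abs(fit$alpha - truth$alpha) / truth$alpha, 0.25)
  expect_gt(attr(fit, "ks_p"), 0.01)
  # shifted exponential special case: alpha ~ 1
  y <- rexp(800, rate = 10) + 0.3
  fit2 <- fit_gamma_marginals(y)
  expect_lt(abs(fit2$alpha - 1), 0.25)
  expect_error(fit_gamma_marginals(rep(1, 100)), "degenerate")
  expect_error(fit_gamma_marginals(1:10), "at least 30")
})

test_that("fitted skewness decreases from posterior to anterior", {
  m <- default_marginals()
  skew <- vapply(m, function(g) 2 / sqrt(g$alpha), numeric(1))
  expect_true(skew[["P"]] > skew[["M"]])
  expect_true(skew[["M"]] > skew[["A"]])
})

test_that("copula sampling preserves the gamma marginals and sign convention", {
  set.seed(17)
  n <- 10000L
  marg <- default_marginals()
  draws <- sample_rest_positions(marg, copula_spec(d = 0.5), n = n)
  expect_true(all(draws[, 1:3] <= 0))
  expect_true(all(draws[, 4:6] >= 0))
  # each column magnitude passes a KS test against its target gamma at 1%
  for (col in 1:6) {
    g <- marg[[c("P", "M", "A")[(col - 1) %% 3 + 1]]]
    p <- suppressWarnings(
      ks.test(abs(draws[, col]),
              function(x) pgamma(x - g$c, shape = g$alpha, scale = g$beta))
    )$p.value
    expect_gt(p, 0.01)
  }
})

test_that("full blend towards independence removes pairwise correlation", {
  set.seed(23)
  n <- 10000L
  draws <- sample_rest_positions(default_marginals(), copula_spec(d = 1), n = n)
  cm <- cor(draws)
  off <- cm[upper.tri(cm)]
  expect_lt(max(abs(off)), 3.3 / sqrt(n))   # ~3 MC sigma for a Pearson r
})

test_that("copula dependence follows the blended correlation at d = 0", {
  set.seed(29)
  n <- 20000L
  cop <- copula_spec(d = 0)
  draws <- sample_rest_positions(default_marginals(), cop, n = n)
  # Spearman rank correlations approximate the normal-copula implication
  sp <- cor(draws, method = "spearman")
  implied <- 6 / pi * asin(cop$blended / 2)
  sign_fix <- outer(c(-1, -1, -1, 1, 1, 1), c(-1, -1, -1, 1, 1, 1))
  expect_lt(max(abs(sp - implied * sign_fix)), 0.05)
})

test_that("copula specification rejects malformed correlation inputs", {
  bad <- diag(6); bad[1, 2] <- 0.5           # asymmetric
  expect_error(copula_spec(bad), "symmetric")
  bad2 <- matrix(0.9, 6, 6); diag(bad2) <- 1
  bad2[1, 2] <- bad2[2, 1] <- -0.9           # indefinite
  expect_error(copula_spec(bad2), "positive semidefinite")
  expect_silent(copula_spec(default_rest_correlation(), d = 0.5))
})

test_that("dataset generation is reproducible and labels round-trip", {
  ds1 <- micro_dataset()
  ds2 <- build_dataset(64L, seed = 421L)
  expect_identical(length(ds1$records), length(ds2$records))
  expect_identical(ds1$records[[1]]$q, ds2$records[[1]]$q)
  expect_identical(ds1$records[[1]]$traj$values, ds2$records[[1]]$traj$values)
  expect_equal(ds1$survival_fraction,
               length(ds1$records) / ds1$n_requested)
  # stored labels re-simulate to the stored trajectories bit-identically
  for (i in c(1L, length(ds1$records))) {
    rec <- ds1$records[[i]]
    res <- simulate_sixmass(scaling_vector(rec$q), rest_positions(rec$rest),
                            phys_config())
    expect_identical(res$traj$values, rec$traj$values)
  }
  # every stored record passed the oscillation filter
  expect_true(all(vapply(ds1$records, function(r) is_oscillating(r$traj),
                         logical(1))))
})

test_that("survival fraction is monotone non-increasing in the threshold", {
  ds <- micro_dataset()
  stats <- vapply(ds$records, function(r) {
    sixmass:::oscillation_statistic(r$traj)
  }, numeric(1))
  thresholds <- c(1e-5, 1e-4, 1e-3, 1e-2, 1e-1)
  surv <- vapply(thresholds, function(th) mean(stats >= th), numeric(1))
  expect_true(all(diff(surv) <= 0))
})

test_that("forcing minimal driving pressure drops the survival fraction", {
  # directional check: with p_s scale pinned to q_min many configurations
  # stop phonating or lose the amplitude the filter requires
  set.seed(77)
  n <- 120L
  qs <- sample_scaling_vector(n = n)
  rests <- sample_rest_positions(n = n)
  cfg <- phys_config()
  keep <- function(qmat) {
    mean(vapply(seq_len(n), function(i) {
      r <- simulate_sixmass(scaling_vector(qmat[i, ]),
                            rest_positions(rests[i, ]), cfg)
      r$ok && is_oscillating(r$traj, unit = "mm", threshold = 0.05)
    }, logical(1)))
  }
  qlow <- qs; qlow[, "p_s"] <- 0.2
  expect_lt(keep(qlow), keep(qs))
})

test_that("datasets save and load with identical content", {
  ds <- micro_dataset()
  path <- withr::local_tempfile(fileext = ".rds")
  csv <- withr::local_tempfile(fileext = ".csv")
  save_dataset(ds, path, labels_csv = csv)
  back <- load_dataset(path)
  expect_equal(length(back$records), length(ds$records))
  expect_equal(back$records[[3]]$q, ds$records[[3]]$q)
  expect_equal(back$records[[3]]$traj$values, ds$records[[3]]$traj$values,
               ignore_attr = TRUE)
  expect_equal(back$survival_fraction, ds$survival_fraction)
  labs <- read.csv(csv)
  expect_equal(nrow(labs), length(ds$records))
  g <- glance(ds)
  expect_equal(g$n_records + g$n_excluded, g$n_requested)
})
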