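# fluctuation-based heat capacity estimation

test_that("variance_cp applies the fluctuation formula with the molar gas constant", {
  # constant series: zero variance, zero heat capacity (needs >= 2 samples)
  expect_equal(variance_cp(rep(5, 100), 300)$value, 0)
  expect_error(variance_cp(3.2, 300), "at least 2")

  # iid Gaussian with variance R*T^2 has Cp = 1 by construction
  set.seed(42)
  n <- 2e4
  h <- rnorm(n, mean = -1000, sd = sqrt(R_GAS * 300^2))
  cp <- variance_cp(h, 300)$value
  expect_lt(abs(cp - 1), 4 * sqrt(2 / (n - 1)))

  # two concatenated constant levels: direct arithmetic oracle
  x <- c(rep(0, 1000), rep(10, 1000))
  v_oracle <- sum((x - mean(x))^2) / (length(x) - 1)
  expect_equal(variance_cp(x, 300)$value, v_oracle / (R_GAS * 300^2),
               tolerance = 1e-12)
  expect_equal(v_oracle, 25.0, tolerance = 1e-2)
})

test_that("variance_cp scales quadratically and ignores energy offsets", {
  set.seed(7)
  h <- rnorm(500, sd = 20)
  base <- variance_cp(h, 310)$value
  expect_equal(variance_cp(3 * h, 310)$value, 9 * base, tolerance = 1e-12)
  expect_equal(variance_cp(h + 1e4, 310)$value, base, tolerance = 1e-9)
})

test_that("cluster-weighted variance removes the between-cluster term", {
  # single cluster collapses to the plain unbiased variance
  set.seed(1)
  x <- rnorm(200)
  expect_equal(cluster_weighted_variance(x, rep(1L, 200))$variance, var(x),
               tolerance = 1e-12)

  # hand-built two-cluster series: per-cluster unbiased variances 4 and 16,
  # equal occupancy -> weighted 10; naive variance of all six points is 38
  x2 <- c(-2, 0, 2, 6, 10, 14)
  lab <- c(1, 1, 1, 2, 2, 2)
  cw <- cluster_weighted_variance(x2, lab)
  expect_equal(cw$variance, 10)
  expect_equal(sort(cw$clusters$variance), c(4, 16))
  expect_equal(cw$clusters$occupancy_pct, c(50, 50))
  expect_equal(var(x2), 38)

  # degenerate cluster is a named error
  expect_error(cluster_weighted_variance(1:5, c(1, 1, 1, 1, 2)),
               "degenerate cluster.*2")
})

test_that("law of total variance holds exactly with the n-denominator convention", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample(50:300, 1)
    k <- sample(2:5, 1)
    lab <- sample.int(k, n, replace = TRUE)
    # regenerate until every cluster has >= 2 members
    while (min(tabulate(lab, k)) < 2) lab <- sample.int(k, n, replace = TRUE)
    x <- rnorm(n, mean = lab * 3, sd = lab)
    cw <- cluster_weighted_variance(x, lab, unbiased = FALSE)
    frac <- tabulate(lab, k) / n
    mus <- tapply(x, lab, mean)
    between <- sum(frac * (mus - sum(frac * mus))^2)
    pop_var <- mean((x - mean(x))^2)
    expect_equal(cw$variance + between, pop_var, tolerance = 1e-12)
  }
})

test_that("cluster-weighted variance tracks the generator's within-state variance", {
  spec <- switching_spec(means = c(0, 30), variances = c(400, 900),
                         dwell_frames = c(300, 100), n_frames = 5e4,
                         temperature_K = 300, seed = 21)
  tr <- gen_switching_energy(spec)
  cw <- cluster_weighted_variance(tr$energy, tr$cluster)
  truth <- attr(tr, "truth")
  expect_lt(abs(cw$variance - truth$within_variance) / truth$within_variance,
            0.05)
  # naive variance is inflated by the between-cluster term
  expect_gt(var(tr$energy), cw$variance + 0.5 * truth$between_variance)
})

test_that("moving-window variance is unbiased and collapses to the plain variance", {
  set.seed(3)
  x <- rnorm(5000, sd = 10)
  # full-length window: exactly the plain sample variance
  expect_equal(moving_window_variance(x, length(x), stride = length(x)),
               var(x), tolerance = 1e-12)
  # unbiasedness for iid data at any window
  n <- 2e4
  y <- rnorm(n, sd = 10)
  for (w in c(10, 100, 1000)) {
    expect_lt(abs(moving_window_variance(y, w) - 100) / 100, 0.05)
  }
  expect_error(moving_window_variance(y, n + 1), "exceeds")
  expect_error(moving_window_variance(y, 1), "at least 2")
  expect_error(moving_window_variance(y, 100, stride = 0), "stride")
})

test_that("short windows exclude slow switching between substates", {
  spec <- switching_spec(means = c(0, 50), variances = c(500, 500),
                         dwell_frames = 1e4, n_frames = 1e5,
                         temperature_K = 300, seed = 13)
  tr <- gen_switching_energy(spec)
  truth <- attr(tr, "truth")
  mw <- moving_window_variance(tr$energy, window = 100)
  expect_lt(abs(mw - truth$within_variance) / truth$within_variance, 0.10)
  # the naive variance is far above: means are 50 apart
  expect_gt(var(tr$energy), 2 * truth$within_variance)
})

test_that("state variances aggregate replicates with across-replicate spread", {
  # identical constant replicates: zero mean and spread
  ens0 <- make_ensemble(replicate(10, rep(3.5, 100), simplify = FALSE))
  sv0 <- state_variance(ens0, method = "plain")
  expect_equal(sv0$mean, 0)
  expect_equal(sv0$sd, 0)

  # replicates built with exact sample variances 250/750 alternating
  vs <- rep(c(250, 750), 5)
  ens <- make_ensemble(lapply(seq_along(vs), function(i) {
    exact_var_series(500, vs[i], seed = i)
  }))
  sv <- state_variance(ens, method = "plain")
  expect_equal(sv$mean, 500, tolerance = 1e-9)
  expect_equal(sv$sd, sd(vs), tolerance = 1e-9)   # = 263.52...
  expect_equal(sv$per_replicate$variance, vs, tolerance = 1e-9)

  # iid Gaussian replicates: mean near truth, spread consistent with
  # chi-square sampling theory (sd of s^2 ~ sigma^2 sqrt(2/(n-1)))
  set.seed(55)
  nf <- 45000
  ens2 <- make_ensemble(replicate(10, rnorm(nf, sd = sqrt(500)),
                                  simplify = FALSE))
  sv2 <- state_variance(ens2, method = "plain")
  expect_lt(abs(sv2$mean - 500) / 500, 0.01)
  theo_sd <- 500 * sqrt(2 / (nf - 1))
  expect_gt(sv2$sd, theo_sd / 3)
  expect_lt(sv2$sd, theo_sd * 3)
})

test_that("burn-in discards initial frames before any estimate", {
  # first 10% of frames carry a huge transient; burn-in must remove it
  e <- c(rep(1e4, 100), exact_var_series(900, 100, seed = 3))
  ens_no <- make_ensemble(list(e), burn_in = 0)
  ens_bi <- state_ensemble(list(make_traj(e)), burn_in_fraction = 0.1)
  expect_gt(state_variance(ens_no, "plain")$mean, 1e5)
  expect_equal(state_variance(ens_bi, "plain")$mean, 100, tolerance = 1e-9)
  expect_error(state_variance(ens_bi, "cluster_weighted"), "labels")
})

test_that("delta_cp differences state variances with quadrature errors", {
  T <- 300
  denom <- R_GAS * T^2
  rs <- state_variance(make_ensemble(lapply(1:5, function(i)
    exact_var_series(400, 2 * denom, seed = i))), "plain")
  ts <- state_variance(make_ensemble(lapply(1:5, function(i)
    exact_var_series(400, 1 * denom, seed = 10 + i)), state = "ts_analogue"),
    "plain")
  est <- delta_cp(rs, ts)
  expect_equal(est$value, -1, tolerance = 1e-9)
  expect_equal(est$sd, sqrt(rs$sd^2 + ts$sd^2) / denom, tolerance = 1e-12)

  # identical ensembles: exactly zero
  expect_equal(delta_cp(rs, rs)$value, 0)

  # antisymmetry: swapping states negates the value, sd unchanged
  swapped <- delta_cp(ts, rs)
  expect_equal(swapped$value, -est$value, tolerance = 1e-12)
  expect_equal(swapped$sd, est$sd, tolerance = 1e-12)

  # temperature mismatch is a hard error
  ts_hot <- state_variance(make_ensemble(list(rnorm(100)),
                                         temperature_K = 320,
                                         state = "ts_analogue"), "plain")
  expect_error(delta_cp(rs, ts_hot), "temperature mismatch")
})

test_that("window scans on substate-free ensembles are flat with a plateau", {
  set.seed(8)
  denom <- R_GAS * 300^2
  rs <- make_ensemble(replicate(6, rnorm(6000, sd = sqrt(2 * denom)),
                                simplify = FALSE), burn_in = 0)
  ts <- make_ensemble(replicate(6, rnorm(6000, sd = sqrt(1.5 * denom)),
                                simplify = FALSE), state = "ts_analogue",
                      burn_in = 0)
  sc <- window_scan(rs, ts, windows_ns = c(5, 10, 15, 20, 25))
  expect_false(is.na(sc$plateau_value))
  plain <- estimate_delta_cp(rs, ts, method = "plain", burn_in = 0)
  expect_lt(abs(sc$plateau_value - plain$value) / abs(plain$value), 0.1)
  # requested windows must fit inside the trajectories
  expect_error(window_scan(rs, ts, windows_ns = c(10, 100)), "exceeds")
  expect_error(window_scan(rs, ts, windows_ns = c(10, 10)), "increasing")
})

test_that("partial estimates use region columns and expose the covariance gap", {
  T <- 320
  spec <- switching_spec(means = 0, variances = 700, ar1_phi = 0.3,
                         n_frames = 4000, temperature_K = T)
  sigma_ind <- diag(c(300, 400))
  dimnames(sigma_ind) <- list(c("core", "lid"), c("core", "lid"))
  mk_ens <- function(sigma, state, seed0) {
    state_ensemble(lapply(1:4, function(i) {
      gen_region_energies(switching_spec(0, sum(sigma), ar1_phi = 0.3,
                                         n_frames = 4000, temperature_K = T),
                          sigma, replicate_id = paste0("r", i),
                          state = state, seed = seed0 + i)
    }), burn_in_fraction = 0)
  }
  rs <- mk_ens(sigma_ind, "reactant", 100)
  ts <- mk_ens(sigma_ind * 0.8, "ts_analogue", 200)

  # region column identical to the total reproduces the total estimate
  one <- diag(1) * 700
  dimnames(one) <- list("all", "all")
  rs1 <- mk_ens(one, "reactant", 300)
  ts1 <- mk_ens(one * 0.8, "ts_analogue", 400)
  tot1 <- estimate_delta_cp(rs1, ts1, method = "plain")
  par1 <- partial_cp(rs1, ts1, region = "all", method = "plain")
  expect_equal(par1$value, tot1$value, tolerance = 1e-9)

  # sample-covariance identity: total - sum(partials) = 2 * dCov / (R T^2)
  # exactly, for any realisation (variance of a sum decomposition)
  total <- estimate_delta_cp(rs, ts, method = "plain")
  p_core <- partial_cp(rs, ts, region = "core", method = "plain")
  p_lid <- partial_cp(rs, ts, region = "lid", method = "plain")
  mean_cov <- function(ens) {
    mean(vapply(ens$trajectories, function(tr) {
      cov(tr$regions$core, tr$regions$lid)
    }, numeric(1)))
  }
  gap_oracle <- 2 * (mean_cov(ts) - mean_cov(rs)) / (R_GAS * T^2)
  expect_equal(total$value - (p_core$value + p_lid$value), gap_oracle,
               tolerance = 1e-10)
  # independent generator: the covariance gap is small relative to the total
  expect_lt(abs(gap_oracle), 0.25 * abs(total$value))
  expect_equal(p_core$region, "core")

  expect_error(partial_cp(rs, ts, region = "nope", method = "plain"),
               "region column 'nope'")
})

test_that("energy histograms resolve replicate structure and bimodality", {
  # constant series occupies a single bin
  ens0 <- make_ensemble(list(rep(7, 50), rep(7, 50)))
  h0 <- energy_histogram(ens0, bins = 20, burn_in = 0)
  expect_equal(sum(h0$pooled > 0), 1)

  # Gaussian generator: moments recovered from the pooled histogram
  set.seed(12)
  ens1 <- make_ensemble(replicate(5, rnorm(5000, mean = -50, sd = 8),
                                  simplify = FALSE))
  h1 <- energy_histogram(ens1, bins = 80, burn_in = 0)
  dx <- diff(h1$breaks[1:2])
  mu_hat <- sum(h1$mids * h1$pooled * dx)
  sd_hat <- sqrt(sum((h1$mids - mu_hat)^2 * h1$pooled * dx))
  expect_lt(abs(mu_hat - (-50)), 0.5)
  expect_lt(abs(sd_hat - 8) / 8, 0.05)

  # well-separated two-cluster generator: bimodal pooled histogram
  spec <- switching_spec(means = c(0, 60), variances = c(25, 25),
                         dwell_frames = 200, n_frames = 2e4,
                         temperature_K = 300, seed = 5)
  ens2 <- state_ensemble(list(gen_switching_energy(spec, seed = 5),
                              gen_switching_energy(spec, seed = 6)))
  h2 <- energy_histogram(ens2, bins = 60)
  d <- h2$pooled
  local_max <- which(diff(sign(diff(d))) == -2) + 1
  peaks <- h2$mids[local_max][d[local_max] > 0.1 * max(d)]
  expect_gte(length(peaks), 2)
  expect_lt(min(peaks), 30)
  expect_gt(max(peaks), 30)
})

test_that("energy tables and manifests round-trip on disk", {
  spec <- switching_spec(means = c(0, 20), variances = c(100, 100),
                         dwell_frames = 50, n_frames = 500,
                         temperature_K = 320, seed = 9)
  ens <- state_ensemble(lapply(1:3, function(i) {
    gen_switching_energy(spec, replicate_id = paste0("rep", i),
                         state = "reactant", seed = 9 + i)
  }))
  dir <- file.path(tempdir(), "ens_roundtrip")
  manifest <- write_state_ensemble(ens, dir)
  back <- read_state_ensemble(manifest)
  expect_equal(length(back$trajectories), 3)
  expect_equal(back$temperature_K, 320)
  for (i in 1:3) {
    expect_equal(back$trajectories[[i]]$energy, ens$trajectories[[i]]$energy,
                 tolerance = 1e-9)
    expect_equal(back$trajectories[[i]]$cluster, ens$trajectories[[i]]$cluster)
  }
  expect_error(read_state_ensemble(file.path(dir, "missing.csv")),
               "not found")
  unlink(dir, recursive = TRUE)
})

test_that("pooled cluster-weighted aggregation pools frames by cluster label", {
  # two replicates sampling the same two clusters with different occupancy
  e1 <- c(exact_var_series(100, 4, m = 0, seed = 1),
          exact_var_series(300, 16, m = 10, seed = 2))
  l1 <- rep(c(1L, 2L), c(100, 300))
  e2 <- c(exact_var_series(300, 4, m = 0, seed = 3),
          exact_var_series(100, 16, m = 10, seed = 4))
  l2 <- rep(c(1L, 2L), c(300, 100))
  ens <- make_ensemble(list(e1, e2))
  ens$trajectories[[1]]$cluster <- l1
  ens$trajectories[[2]]$cluster <- l2
  pooled <- state_variance(ens, "cluster_weighted", pooled = TRUE)
  oracle <- cluster_weighted_variance(c(e1, e2), c(l1, l2))$variance
  expect_equal(pooled$mean, oracle, tolerance = 1e-9)
})
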