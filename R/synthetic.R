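#' Markov-switching energy generator specification
#'
#' Specifies a stationary energy process that switches between
#' conformational clusters according to a first-order Markov chain, with
#' AR(1)-correlated Gaussian emission around the active cluster mean. The
#' stationary variance within cluster c equals `variances[c]`; the lag-1
#' autocorrelation `ar1_phi` mimics the short-time correlation of
#' molecular-dynamics energies.
#'
#' @param means per-cluster means (kJ mol^-1).
#' @param variances per-cluster variances ((kJ mol^-1)^2), strictly positive.
#' @param transition optional per-frame transition matrix (rows sum to 1).
#' @param dwell_frames alternative to `transition`: mean dwell time per
#'   cluster in frames; exits are split evenly over the other clusters.
#' @param ar1_phi lag-1 autocorrelation of the emission, in [0, 1).
#' @param n_frames number of frames.
#' @param time_step_ps frame spacing (ps); default 10.
#' @param temperature_K ensemble temperature (K).
#' @param seed optional RNG seed stored with the spec.
#' @return Object of class `"switching_spec"` carrying a `truth` record:
#'   stationary occupancies, occupancy-weighted within-state variance,
#'   between-cluster variance and their total (law of total variance).
#' @export
switching_spec <- function(means, variances, transition = NULL,
                           dwell_frames = NULL, ar1_phi = 0, n_frames,
                           time_step_ps = 10, temperature_K, seed = NULL) {
  means <- as.numeric(means); variances <- as.numeric(variances)
  k <- length(means)
  stopifnot(length(variances) == k, k >= 1L)
  if (any(variances <= 0)) stop("cluster variances must be strictly positive")
  if (ar1_phi < 0 || ar1_phi >= 1) stop("ar1_phi must be in [0, 1)")
  if (n_frames < 2L) stop("n_frames must be at least 2")
  if (temperature_K <= 0) stop("temperature_K must be positive")
  if (is.null(transition)) {
    if (k == 1L) {
      transition <- matrix(1, 1L, 1L)
    } else {
      if (is.null(dwell_frames)) {
        stop("supply either a transition matrix or dwell_frames")
      }
      dwell_frames <- rep_len(as.numeric(dwell_frames), k)
      if (any(dwell_frames < 1)) stop("dwell times must be at least 1 frame")
      transition <- matrix(0, k, k)
      for (i in seq_len(k)) {
        p_leave <- 1 / dwell_frames[i]
        transition[i, ] <- p_leave / (k - 1L)
        transition[i, i] <- 1 - p_leave
      }
    }
  }
  transition <- as.matrix(transition)
  if (!all(dim(transition) == k)) stop("transition matrix must be k x k")
  if (any(transition < 0) ||
      any(abs(rowSums(transition) - 1) > 1e-8)) {
    stop("transition matrix rows must be non-negative and sum to 1")
  }
  pi_st <- .stationary_distribution(transition)
  within <- sum(pi_st * variances)
  mu_bar <- sum(pi_st * means)
  between <- sum(pi_st * (means - mu_bar)^2)
  structure(list(means = means, variances = variances,
                 transition = transition, ar1_phi = ar1_phi,
                 n_frames = as.integer(n_frames),
                 time_step_ps = time_step_ps,
                 temperature_K = temperature_K, seed = seed,
                 truth = list(occupancy = pi_st,
                              within_variance = within,
                              between_variance = between,
                              total_variance = within + between)),
            class = "switching_spec")
}

.stationary_distribution <- function(P) {
  k <- nrow(P)
  if (k == 1L) return(1)
  # solve pi (I - P + J) = 1 (J the all-ones matrix)
  A <- t(diag(k) - P + matrix(1, k, k))
  pi_st <- tryCatch(solve(A, rep(1, k)), error = function(e) NULL)
  if (is.null(pi_st) || any(pi_st < -1e-10) ||
      abs(sum(pi_st) - 1) > 1e-8) {
    stop("no valid stationary distribution for this transition matrix")
  }
  pmax(pi_st, 0) / sum(pmax(pi_st, 0))
}

# segment-wise simulation of the hidden Markov chain (exact: geometric
# dwell in the current state, then jump by the off-diagonal row)
.sim_markov <- function(P, n, pi_st) {
  k <- nrow(P)
  if (k == 1L) return(rep(1L, n))
  labels <- integer(n)
  s <- sample.int(k, 1L, prob = pi_st)
  i <- 1L
  while (i <= n) {
    p_stay <- P[s, s]
    dwell <- if (p_stay >= 1) n else stats::rgeom(1L, 1 - p_stay) + 1L
    j <- min(n, i + dwell - 1L)
    labels[i:j] <- s
    i <- j + 1L
    if (i <= n) {
      off <- P[s, -s]
      s <- (seq_len(k)[-s])[sample.int(k - 1L, 1L, prob = off)]
    }
  }
  labels
}

# unit-variance AR(1) path of length n with parameter phi
.ar1_unit <- function(n, phi) {
  if (phi == 0) return(stats::rnorm(n))
  innov <- c(stats::rnorm(1L), sqrt(1 - phi^2) * stats::rnorm(n - 1L))
  as.numeric(stats::filter(innov, phi, method = "recursive"))
}

#' Generate a Markov-switching energy trajectory
#'
#' Simulates the hidden cluster sequence from the spec's Markov chain and
#' emits `mean[c] + sd[c] * z_t` where `z` is a unit-variance AR(1) path, so
#' the stationary within-cluster variance equals the spec's cluster
#' variance. True cluster labels are stored on the trajectory; the spec's
#' `truth` record (occupancy-weighted within-state variance, between and
#' total variance) is attached as attribute `"truth"`.
#'
#' @param spec a [switching_spec()].
#' @param replicate_id,state trajectory metadata.
#' @param seed RNG seed; defaults to the spec's.
#' @return An [energy_trajectory()] with cluster labels.
#' @export
gen_switching_energy <- function(spec, replicate_id = "rep1",
                                 state = c("reactant", "ts_analogue"),
                                 seed = spec$seed) {
  stopifnot(inherits(spec, "switching_spec"))
  state <- match.arg(state)
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_frames
  labels <- .sim_markov(spec$transition, n, spec$truth$occupancy)
  z <- .ar1_unit(n, spec$ar1_phi)
  energy <- spec$means[labels] + sqrt(spec$variances[labels]) * z
  tr <- energy_trajectory(time_ps = (seq_len(n) - 1L) * spec$time_step_ps,
                          energy = energy, cluster = labels,
                          replicate_id = replicate_id, state = state,
                          temperature_K = spec$temperature_K)
  attr(tr, "truth") <- spec$truth
  tr
}

#' Generate a noisy MMRT rate profile
#'
#' Draws ln(rate) as the MMRT curve plus iid Gaussian noise. With more than
#' one replicate, the profile holds the per-temperature mean ln(rate) and
#' the replicate standard deviation (usable as fit weights).
#'
#' @param params generator [mmrt_params()].
#' @param temperatures temperature grid (K), within (250, 400).
#' @param noise_sd standard deviation of the ln(rate) noise (>= 0).
#' @param replicates replicate measurements per temperature.
#' @param seed optional RNG seed.
#' @param label profile label.
#' @return A [rate_profile()]; the generator parameters and noise level are
#'   attached as attribute `"truth"`.
#' @export
gen_rate_profile <- function(params, temperatures, noise_sd = 0,
                             replicates = 1, seed = NULL, label = "synthetic") {
  stopifnot(inherits(params, "mmrt_params"))
  temperatures <- as.numeric(temperatures)
  if (any(temperatures <= 250) || any(temperatures >= 400)) {
    stop("temperature grid must lie within (250, 400) K")
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  mu <- mmrt_lnk(params, temperatures)
  draws <- matrix(stats::rnorm(length(mu) * replicates, mean = mu,
                               sd = noise_sd),
                  nrow = length(mu))
  prof <- if (replicates > 1L) {
    rate_profile(temperatures, ln_rate = rowMeans(draws),
                 sd_ln_rate = apply(draws, 1L, stats::sd), label = label)
  } else {
    rate_profile(temperatures, ln_rate = draws[, 1L], label = label)
  }
  attr(prof, "truth") <- list(params = params, noise_sd = noise_sd,
                              replicates = replicates)
  prof
}

#' Generate region-decomposed energies summing to a total
#'
#' Emits per-region energy streams as a stationary multivariate Gaussian
#' AR(1) process with the given inter-region covariance matrix, on top of a
#' Markov-switching cluster mean split across regions. The total column is
#' the exact row sum of the regions, and its within-cluster variance equals
#' `sum(region_sigma)` (all entries), which must match the spec's cluster
#' variances: partial and total estimates downstream then have a known
#' covariance decomposition.
#'
#' @param spec a [switching_spec()]; every cluster variance must equal
#'   `sum(region_sigma)` (the variance of the sum), otherwise the requested
#'   decomposition is inconsistent and an error is raised.
#' @param region_sigma named, symmetric positive semi-definite covariance
#'   matrix of the region streams ((kJ mol^-1)^2).
#' @param region_mean_frac fractions splitting each cluster mean across the
#'   regions (default equal split); must sum to 1.
#' @param replicate_id,state,seed as in [gen_switching_energy()].
#' @return An [energy_trajectory()] whose `regions` columns sum exactly to
#'   the total energy; attribute `"truth"` records `region_sigma` and the
#'   spec truth.
#' @export
gen_region_energies <- function(spec, region_sigma, region_mean_frac = NULL,
                                replicate_id = "rep1",
                                state = c("reactant", "ts_analogue"),
                                seed = spec$seed) {
  stopifnot(inherits(spec, "switching_spec"))
  state <- match.arg(state)
  S <- as.matrix(region_sigma)
  if (is.null(rownames(S)) && is.null(colnames(S))) {
    dimnames(S) <- list(paste0("region", seq_len(nrow(S))),
                        paste0("region", seq_len(nrow(S))))
  }
  if (nrow(S) != ncol(S) || any(abs(S - t(S)) > 1e-8)) {
    stop("region_sigma must be a symmetric square matrix")
  }
  ev <- eigen(S, symmetric = TRUE)
  if (any(ev$values < -1e-8 * max(abs(ev$values)))) {
    stop("region_sigma must be positive semi-definite")
  }
  total_var <- sum(S)
  if (any(abs(spec$variances - total_var) >
          1e-6 * max(total_var, 1))) {
    stop("inconsistent variance decomposition: sum(region_sigma) = ",
         signif(total_var, 6), " but the spec's cluster variances are ",
         paste(signif(spec$variances, 6), collapse = ", "))
  }
  r <- nrow(S)
  frac <- if (is.null(region_mean_frac)) rep(1 / r, r) else
    as.numeric(region_mean_frac)
  if (length(frac) != r || abs(sum(frac) - 1) > 1e-8) {
    stop("region_mean_frac must have one entry per region and sum to 1")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_frames
  labels <- .sim_markov(spec$transition, n, spec$truth$occupancy)
  # matrix square root handles semi-definite covariances
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), r) %*% t(ev$vectors)
  phi <- spec$ar1_phi
  eps <- matrix(stats::rnorm(n * r), n, r)
  Z <- matrix(0, n, r)
  Z[1L, ] <- eps[1L, ] %*% L
  if (n > 1L) {
    scale <- sqrt(1 - phi^2)
    innov <- scale * (eps[-1L, , drop = FALSE] %*% L)
    for (i in 2L:n) Z[i, ] <- phi * Z[i - 1L, ] + innov[i - 1L, ]
  }
  regions <- Z + outer(spec$means[labels], frac)
  colnames(regions) <- rownames(S)
  regions <- as.data.frame(regions)
  tr <- energy_trajectory(time_ps = (seq_len(n) - 1L) * spec$time_step_ps,
                          energy = rowSums(regions), regions = regions,
                          cluster = labels, replicate_id = replicate_id,
                          state = state,
                          temperature_K = spec$temperature_K)
  attr(tr, "truth") <- c(spec$truth, list(region_sigma = S))
  tr
}

#' Generate a toy coordinate trajectory with basin structure
#'
#' Each frame is a reference structure plus the displacement of the active
#' conformational basin plus isotropic Gaussian jitter, then contaminated
#' with a random rigid motion (rotation + translation) so that downstream
#' analyses are forced to superpose. Basin switching follows a symmetric
#' Markov chain with the given mean dwell.
#'
#' @param reference N x 3 matrix of Calpha reference coordinates.
#' @param basin_shifts list of N x 3 displacement matrices, one per basin
#'   (a single zero matrix for one basin).
#' @param jitter_sd per-residue isotropic jitter standard deviation
#'   (angstrom); recycled to N.
#' @param n_frames number of frames.
#' @param dwell_frames mean basin dwell time in frames (ignored for one
#'   basin).
#' @param time_step_ps frame spacing (ps).
#' @param rigid_motion apply a random rigid motion to every frame (default
#'   `TRUE`).
#' @param seed optional RNG seed.
#' @return A [coord_trajectory()] with true basin labels in attribute
#'   `"labels"` and the jitter level in attribute `"truth"`.
#' @export
gen_toy_trajectory <- function(reference, basin_shifts = NULL,
                               jitter_sd = 0.3, n_frames = 100,
                               dwell_frames = 20, time_step_ps = 10,
                               rigid_motion = TRUE, seed = NULL) {
  reference <- as.matrix(reference)
  stopifnot(ncol(reference) == 3L)
  n_atoms <- nrow(reference)
  if (is.null(basin_shifts)) {
    basin_shifts <- list(matrix(0, n_atoms, 3L))
  }
  k <- length(basin_shifts)
  jitter_sd <- rep_len(as.numeric(jitter_sd), n_atoms)
  if (any(jitter_sd < 0)) stop("jitter sds must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  labels <- if (k == 1L) rep(1L, n_frames) else {
    P <- matrix(1 / (dwell_frames * (k - 1L)), k, k)
    diag(P) <- 1 - 1 / dwell_frames
    .sim_markov(P, n_frames, rep(1 / k, k))
  }
  frames <- array(NA_real_, c(n_frames, n_atoms, 3L))
  for (i in seq_len(n_frames)) {
    x <- reference + basin_shifts[[labels[i]]] +
      matrix(stats::rnorm(3L * n_atoms, sd = jitter_sd), n_atoms, 3L)
    if (rigid_motion) {
      x <- x %*% .random_rotation() +
        rep(1, n_atoms) %*% t(stats::runif(3L, -20, 20))
    }
    frames[i, , ] <- x
  }
  tr <- coord_trajectory(frames, time_step_ps = time_step_ps)
  attr(tr, "labels") <- labels
  attr(tr, "truth") <- list(jitter_sd = jitter_sd, n_basins = k)
  tr
}

# uniform random proper rotation via QR of a Gaussian matrix
.random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9L), 3L, 3L))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

#' Synthetic two-state fluctuation experiments
#'
#' Ready-made reactant/transition-state-analogue ensemble pairs mirroring
#' the sampling geometry of the two enzyme systems:
#'
#' * `mall_like_experiment()`: the large-glucosidase scenario at 320 K --
#'   6 conformational clusters, frequent switching (mean dwell 20 ns),
#'   10 replicates of 45 000 frames at 10 ps spacing (450 ns analysed per
#'   run). Both states share the cluster mean layout and kinetics; the
#'   within-state heat capacities are `cp_reactant` and `cp_ts`, so the true
#'   within-state activation heat capacity change is `cp_ts - cp_reactant`
#'   (default -10 kJ mol^-1 K^-1). The intended estimator is the
#'   moving-window protocol / [window_scan()].
#' * `ksi_like_experiment()`: the small-isomerase scenario at 300 K -- two
#'   conformational clusters with unequal occupancy and distinct variances;
#'   the intended estimator is the cluster-weighted protocol.
#'
#' @param n_replicates replicates per state (default 10).
#' @param n_frames frames per replicate (default 45 000).
#' @param temperature_K ensemble temperature (K).
#' @param cp_reactant,cp_ts within-state heat capacities (kJ mol^-1 K^-1)
#'   that fix the generator's within-state variances via
#'   `Var = Cp * R * T^2`.
#' @param n_clusters number of conformational clusters.
#' @param dwell_frames mean cluster dwell (frames).
#' @param ar1_phi lag-1 emission autocorrelation.
#' @param time_step_ps frame spacing (ps).
#' @param seed RNG seed for the whole experiment.
#' @return List with `reactant` and `ts_analogue` [state_ensemble()]s and a
#'   `truth` record (within-state variances and the implied
#'   `delta_cp = cp_ts - cp_reactant`).
#' @export
mall_like_experiment <- function(n_replicates = 10, n_frames = 45000,
                                 temperature_K = 320, cp_reactant = 60,
                                 cp_ts = 50, n_clusters = 6,
                                 dwell_frames = 2000, ar1_phi = 0.8,
                                 time_step_ps = 10, seed = 1) {
  mean_layout <- seq(-1, 1, length.out = n_clusters) * 100
  .two_state_experiment(mean_layout, n_replicates, n_frames, temperature_K,
                        cp_reactant, cp_ts, dwell_frames, ar1_phi,
                        time_step_ps, seed,
                        variance_profile = rep(1, n_clusters))
}

#' @rdname mall_like_experiment
#' @param occupancy target stationary occupancies of the two clusters.
#' @export
ksi_like_experiment <- function(n_replicates = 10, n_frames = 45000,
                                temperature_K = 300, cp_reactant = 35,
                                cp_ts = 35 - 0.86, occupancy = c(0.75, 0.25),
                                ar1_phi = 0.8, time_step_ps = 10, seed = 1) {
  # dwell times proportional to occupancy give the target stationary split
  dwell <- 4000 * occupancy / max(occupancy)
  # distinct per-cluster variances (minor cluster 50% noisier), scaled so the
  # occupancy-weighted within-state variance hits the Cp target exactly
  profile <- c(1, 1.5)
  .two_state_experiment(c(0, 35), n_replicates, n_frames, temperature_K,
                        cp_reactant, cp_ts, dwell, ar1_phi, time_step_ps,
                        seed, variance_profile = profile)
}

.two_state_experiment <- function(mean_layout, n_replicates, n_frames,
                                  temperature_K, cp_reactant, cp_ts,
                                  dwell_frames, ar1_phi, time_step_ps, seed,
                                  variance_profile) {
  k <- length(mean_layout)
  base_spec <- function(cp_state) {
    v_target <- cp_state * .R * temperature_K^2
    sp0 <- switching_spec(mean_layout, rep(1, k),
                          dwell_frames = dwell_frames, ar1_phi = ar1_phi,
                          n_frames = n_frames, time_step_ps = time_step_ps,
                          temperature_K = temperature_K)
    # scale the variance profile so sum(pi * var) == v_target exactly
    w <- sum(sp0$truth$occupancy * variance_profile)
    switching_spec(mean_layout, variance_profile * v_target / w,
                   dwell_frames = dwell_frames, ar1_phi = ar1_phi,
                   n_frames = n_frames, time_step_ps = time_step_ps,
                   temperature_K = temperature_K)
  }
  spec_rs <- base_spec(cp_reactant)
  spec_ts <- base_spec(cp_ts)
  set.seed(seed)
  gen_state <- function(spec, state) {
    state_ensemble(lapply(seq_len(n_replicates), function(i) {
      gen_switching_energy(spec, replicate_id = sprintf("%s_%02d", state, i),
                           state = state, seed = NULL)
    }))
  }
  list(reactant = gen_state(spec_rs, "reactant"),
       ts_analogue = gen_state(spec_ts, "ts_analogue"),
       truth = list(
         temperature_K = temperature_K,
         within_variance_reactant = spec_rs$truth$within_variance,
         within_variance_ts = spec_ts$truth$within_variance,
         delta_cp = (spec_ts$truth$within_variance -
                       spec_rs$truth$within_variance) /
           (.R * temperature_K^2),
         occupancy = spec_rs$truth$occupancy))
}
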