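#' Enthalpy time series for one replicate simulation
#'
#' Holds one replicate's enthalpy trajectory: uniformly spaced times (ps),
#' total energies (kJ mol^-1), optional per-region energy columns and
#' optional conformational-cluster labels aligned to frames. The force-field
#' potential energy of the solute is the usual stand-in for the system
#' enthalpy here.
#'
#' @param time_ps frame times (ps), uniformly spaced.
#' @param energy total energies (kJ mol^-1).
#' @param regions optional data.frame of per-region energy columns
#'   (kJ mol^-1), one row per frame.
#' @param cluster optional integer cluster labels, one per frame.
#' @param replicate_id replicate identifier.
#' @param state `"reactant"` or `"ts_analogue"`.
#' @param temperature_K temperature of the generating ensemble (K).
#' @return Object of class `"energy_trajectory"`.
#' @export
energy_trajectory <- function(time_ps, energy, regions = NULL, cluster = NULL,
                              replicate_id = "rep1",
                              state = c("reactant", "ts_analogue"),
                              temperature_K) {
  state <- match.arg(state)
  time_ps <- as.numeric(time_ps); energy <- as.numeric(energy)
  n <- length(time_ps)
  if (n < 2L) stop("an energy trajectory needs at least 2 frames")
  if (length(energy) != n) stop("time and energy arrays must have equal length")
  if (any(!is.finite(time_ps)) || any(!is.finite(energy))) {
    stop("times and energies must be finite")
  }
  dt <- diff(time_ps)
  if (any(abs(dt - dt[1L]) > 1e-6 * max(abs(dt[1L]), 1))) {
    stop("frame times must be uniformly spaced")
  }
  if (dt[1L] <= 0) stop("frame times must be increasing")
  if (!is.numeric(temperature_K) || length(temperature_K) != 1L ||
      temperature_K <= 0) {
    stop("temperature_K must be a single positive number")
  }
  if (!is.null(cluster)) {
    cluster <- as.integer(cluster)
    if (length(cluster) != n || anyNA(cluster)) {
      stop("cluster labels, when present, must cover every frame")
    }
  }
  if (!is.null(regions)) {
    regions <- as.data.frame(regions)
    if (nrow(regions) != n) stop("region columns must have one row per frame")
    if (!all(vapply(regions, is.numeric, logical(1L)))) {
      stop("region energy columns must be numeric")
    }
  }
  structure(list(time_ps = time_ps, energy = energy, regions = regions,
                 cluster = cluster, replicate_id = as.character(replicate_id),
                 state = state, temperature_K = temperature_K,
                 time_step_ps = dt[1L]),
            class = "energy_trajectory")
}

#' @export
print.energy_trajectory <- function(x, ...) {
  cat(sprintf(
    "Energy trajectory '%s' (%s, %g K): %d frames @ %g ps%s%s\n",
    x$replicate_id, x$state, x$temperature_K, length(x$energy),
    x$time_step_ps,
    if (is.null(x$cluster)) "" else
      sprintf(", %d clusters", length(unique(x$cluster))),
    if (is.null(x$regions)) "" else
      sprintf(", regions: %s", paste(names(x$regions), collapse = ", "))))
  invisible(x)
}

#' Ensemble of replicate trajectories for one state
#'
#' Groups replicate [energy_trajectory()] objects that sample the same state
#' (reactant or transition-state analogue) at the same temperature. A
#' burn-in fraction of initial frames is discarded by all downstream
#' estimators, mirroring the convention of analysing only the equilibrated
#' portion of each run.
#'
#' @param trajectories list of [energy_trajectory()] objects sharing state
#'   and temperature.
#' @param burn_in_fraction fraction of initial frames to discard (default
#'   0.1).
#' @return Object of class `"state_ensemble"`.
#' @export
state_ensemble <- function(trajectories, burn_in_fraction = 0.1) {
  if (!length(trajectories)) stop("an ensemble needs at least one trajectory")
  if (!all(vapply(trajectories, inherits, logical(1L), "energy_trajectory"))) {
    stop("all elements must be energy_trajectory objects")
  }
  temps <- vapply(trajectories, `[[`, numeric(1L), "temperature_K")
  states <- vapply(trajectories, `[[`, character(1L), "state")
  if (length(unique(temps)) != 1L) {
    stop("all trajectories in an ensemble must share one temperature")
  }
  if (length(unique(states)) != 1L) {
    stop("all trajectories in an ensemble must share one state")
  }
  if (burn_in_fraction < 0 || burn_in_fraction >= 1) {
    stop("burn_in_fraction must be in [0, 1)")
  }
  structure(list(trajectories = trajectories,
                 burn_in_fraction = burn_in_fraction,
                 state = states[1L], temperature_K = temps[1L]),
            class = "state_ensemble")
}

#' @export
print.state_ensemble <- function(x, ...) {
  cat(sprintf("State ensemble (%s, %g K): %d replicates, burn-in %.0f%%\n",
              x$state, x$temperature_K, length(x$trajectories),
              100 * x$burn_in_fraction))
  invisible(x)
}

# frames kept after burn-in
.post_burnin <- function(n, fraction) {
  drop <- floor(fraction * n)
  if (drop >= n) stop("insufficient data: no frames remain after burn-in")
  (drop + 1L):n
}

#' Heat capacity from enthalpy fluctuations
#'
#' Applies the equilibrium fluctuation formula `Cp = Var(H) / (R T^2)` with
#' the unbiased sample variance and the molar gas constant
#' (energies in kJ mol^-1, Cp in kJ mol^-1 K^-1).
#'
#' @param energies energy samples (kJ mol^-1), at least 2.
#' @param temperature_K temperature (K).
#' @return A [cp_estimate()] with method `"plain"` (sd `NA`: a single series
#'   carries no replicate spread).
#' @examples
#' set.seed(1)
#' const <- physical_constants()
#' h <- rnorm(1e4, sd = sqrt(const$R * 300^2))  # Cp = 1 by construction
#' variance_cp(h, 300)
#' @export
variance_cp <- function(energies, temperature_K) {
  energies <- as.numeric(energies)
  if (length(energies) < 2L) {
    stop("insufficient data: need at least 2 energy samples")
  }
  if (temperature_K <= 0) stop("temperature must be positive")
  cp_estimate(stats::var(energies) / (.R * temperature_K^2),
              sd = NA_real_, temperature_K = temperature_K,
              method = "plain", n_replicates = 1L)
}

#' Heat capacity (or difference) estimate
#'
#' @param value Cp or delta-Cp value (kJ mol^-1 K^-1).
#' @param sd standard deviation of the estimate (kJ mol^-1 K^-1), `NA` when
#'   no replicate spread is available.
#' @param temperature_K temperature (K).
#' @param method estimation method string, e.g. `"plain"`,
#'   `"cluster_weighted"` or `"moving_window(w=4000,s=400)"`.
#' @param n_replicates number of replicate simulations behind the value.
#' @param region structural region the energies belong to, `"total"` by
#'   default.
#' @return Object of class `"cp_estimate"`.
#' @export
cp_estimate <- function(value, sd = NA_real_, temperature_K, method,
                        n_replicates = NA_integer_, region = "total") {
  if (!is.na(sd) && sd < 0) stop("sd must be non-negative")
  structure(list(value = value, sd = sd, temperature_K = temperature_K,
                 method = method, n_replicates = n_replicates,
                 region = region),
            class = "cp_estimate")
}

#' @export
print.cp_estimate <- function(x, ...) {
  cat(sprintf("Cp estimate [%s, region %s, %g K]: %.4f%s kJ mol^-1 K^-1 (n=%s)\n",
              x$method, x$region, x$temperature_K, x$value,
              if (is.na(x$sd)) "" else sprintf(" +/- %.4f", x$sd),
              x$n_replicates))
  invisible(x)
}

#' Cluster-occupancy-weighted variance
#'
#' Within-substate variance of an energy series: per-cluster variances are
#' averaged with weights equal to the cluster frame fractions,
#' `sum_c f_c Var_c`. Switching between conformational substates inflates
#' the naive total variance by the spread of the cluster means; weighting by
#' occupancy removes that between-cluster term.
#'
#' With `unbiased = TRUE` (default) each per-cluster variance uses the n-1
#' denominator. With `unbiased = FALSE` all terms use the n denominator, in
#' which case the law of total variance holds exactly:
#' plain population variance = weighted within + occupancy-weighted variance
#' of cluster means.
#'
#' @param energies energy samples (kJ mol^-1).
#' @param labels cluster labels aligned to `energies`; every cluster must
#'   hold at least 2 frames.
#' @param unbiased use the n-1 denominator per cluster (default `TRUE`).
#' @return List with `variance` (the weighted within-cluster variance) and
#'   `clusters`, a data.frame with per-cluster `n`, `occupancy_pct`, `mean`
#'   and `variance`.
#' @export
cluster_weighted_variance <- function(energies, labels, unbiased = TRUE) {
  energies <- as.numeric(energies)
  if (length(labels) != length(energies)) {
    stop("cluster labels must align with the energy series")
  }
  f <- factor(labels)
  ns <- tabulate(f)
  small <- levels(f)[ns < 2L]
  if (length(small)) {
    stop("degenerate cluster with fewer than 2 frames: ",
         paste(small, collapse = ", "))
  }
  mus <- tapply(energies, f, mean)
  vars <- tapply(energies, f, stats::var)
  if (!unbiased) vars <- vars * (ns - 1L) / ns
  frac <- ns / length(energies)
  list(variance = sum(frac * vars),
       clusters = data.frame(cluster = levels(f), n = ns,
                             occupancy_pct = 100 * frac,
                             mean = as.numeric(mus),
                             variance = as.numeric(vars),
                             row.names = NULL))
}

#' Moving-window variance
#'
#' Mean of the unbiased variances computed in fixed-length windows slid
#' along the series at multiples of `stride`. Windows shorter than the dwell
#' time of conformational substates suppress the between-substate
#' contribution to the variance without requiring any clustering.
#'
#' @param energies energy samples.
#' @param window window length in frames, `2 <= window <= length(energies)`.
#' @param stride step between window starts in frames (default
#'   `max(1, floor(window / 10))`, i.e. 90% overlap).
#' @return Mean window variance ((kJ mol^-1)^2).
#' @export
moving_window_variance <- function(energies, window,
                                   stride = max(1L, floor(window / 10))) {
  x <- as.numeric(energies)
  n <- length(x)
  window <- as.integer(window); stride <- as.integer(stride)
  if (window < 2L) stop("window must span at least 2 frames")
  if (window > n) stop("window (", window, " frames) exceeds series length (",
                       n, " frames)")
  if (stride < 1L) stop("stride must be at least 1 frame")
  x <- x - mean(x)                      # guards the cumsum arithmetic
  c1 <- c(0, cumsum(x))
  c2 <- c(0, cumsum(x^2))
  starts <- seq.int(1L, n - window + 1L, by = stride)
  s1 <- c1[starts + window] - c1[starts]
  s2 <- c2[starts + window] - c2[starts]
  v <- (s2 - s1^2 / window) / (window - 1L)
  mean(v)
}

#' Per-replicate state variances with aggregation
#'
#' Applies one of the three variance protocols to every replicate of a state
#' ensemble (after burn-in) and aggregates across replicates: the state
#' variance is the mean of the per-replicate values and its uncertainty the
#' standard deviation across replicates.
#'
#' Methods: `"plain"` (full-series variance), `"cluster_weighted"`
#' (occupancy-weighted within-cluster variance; needs cluster labels) and
#' `"moving_window"` (mean windowed variance; needs `window`). For the
#' cluster-weighted protocol `pooled = TRUE` pools frames and labels across
#' replicates before weighting (per-replicate values are still reported and
#' provide the spread).
#'
#' @param ensemble a [state_ensemble()].
#' @param method variance protocol.
#' @param window window length in frames (moving-window protocol).
#' @param stride window stride in frames; default `window / 10`.
#' @param pooled pool frames across replicates (cluster-weighted only).
#' @param region name of a region energy column to analyse instead of the
#'   total energy, or `NULL` for the total.
#' @param burn_in burn-in fraction override; defaults to the ensemble's.
#' @return Object of class `"state_variance"`: `per_replicate` data.frame,
#'   aggregate `mean` and `sd`, and metadata.
#' @export
state_variance <- function(ensemble,
                           method = c("plain", "cluster_weighted",
                                      "moving_window"),
                           window = NULL, stride = NULL, pooled = FALSE,
                           region = NULL, burn_in = NULL) {
  stopifnot(inherits(ensemble, "state_ensemble"))
  method <- match.arg(method)
  if (is.null(burn_in)) burn_in <- ensemble$burn_in_fraction
  if (method == "moving_window" && is.null(window)) {
    stop("the moving-window protocol needs a 'window' (frames)")
  }

  pick_series <- function(tr) {
    e <- if (is.null(region)) tr$energy else {
      if (is.null(tr$regions) || !region %in% names(tr$regions)) {
        stop("region column '", region, "' missing from replicate '",
             tr$replicate_id, "'")
      }
      tr$regions[[region]]
    }
    keep <- .post_burnin(length(e), burn_in)
    list(e = e[keep], cl = if (is.null(tr$cluster)) NULL else tr$cluster[keep],
         id = tr$replicate_id)
  }
  series <- lapply(ensemble$trajectories, pick_series)

  one <- function(s) {
    switch(method,
      plain = stats::var(s$e),
      cluster_weighted = {
        if (is.null(s$cl)) {
          stop("cluster labels required for the cluster-weighted protocol ",
               "(replicate '", s$id, "')")
        }
        cluster_weighted_variance(s$e, s$cl)$variance
      },
      moving_window = {
        if (is.null(stride)) {
          moving_window_variance(s$e, window)
        } else {
          moving_window_variance(s$e, window, stride)
        }
      })
  }
  vals <- vapply(series, one, numeric(1L))
  agg_mean <- mean(vals)
  if (method == "cluster_weighted" && pooled) {
    # pool frames of the same cluster label across replicates
    agg_mean <- cluster_weighted_variance(
      unlist(lapply(series, `[[`, "e")),
      unlist(lapply(series, `[[`, "cl")))$variance
  }
  method_str <- switch(method,
    plain = "plain",
    cluster_weighted = if (pooled) "cluster_weighted(pooled)" else "cluster_weighted",
    moving_window = sprintf("moving_window(w=%d,s=%s)", as.integer(window),
                            if (is.null(stride)) "w/10" else as.integer(stride)))
  structure(list(
    per_replicate = data.frame(
      replicate_id = vapply(series, `[[`, character(1L), "id"),
      variance = vals,
      n_frames = vapply(series, function(s) length(s$e), integer(1L)),
      row.names = NULL),
    mean = agg_mean,
    sd = if (length(vals) > 1L) stats::sd(vals) else 0,
    n_replicates = length(vals),
    temperature_K = ensemble$temperature_K,
    state = ensemble$state,
    method = method_str,
    region = if (is.null(region)) "total" else region
  ), class = "state_variance")
}

#' @export
print.state_variance <- function(x, ...) {
  cat(sprintf(
    "State variance (%s, %s, region %s): %.4g +/- %.4g (kJ mol^-1)^2 over %d replicates\n",
    x$state, x$method, x$region, x$mean, x$sd, x$n_replicates))
  invisible(x)
}

#' Activation heat capacity change between two state ensembles
#'
#' Difference form of the fluctuation formula:
#' `dCp = (Var_TS - Var_RS) / (R T^2)`, with the across-replicate standard
#' deviations of the two state variances combined in quadrature.
#'
#' @param reactant [state_variance()] result for the reactant state.
#' @param ts_analogue [state_variance()] result for the transition-state
#'   analogue.
#' @return A [cp_estimate()] (kJ mol^-1 K^-1).
#' @export
delta_cp <- function(reactant, ts_analogue) {
  stopifnot(inherits(reactant, "state_variance"),
            inherits(ts_analogue, "state_variance"))
  if (abs(reactant$temperature_K - ts_analogue$temperature_K) > 1e-9) {
    stop("temperature mismatch between states: ", reactant$temperature_K,
         " K vs ", ts_analogue$temperature_K, " K")
  }
  if (!identical(reactant$region, ts_analogue$region)) {
    stop("region mismatch between states: '", reactant$region, "' vs '",
         ts_analogue$region, "'")
  }
  T <- reactant$temperature_K
  denom <- .R * T^2
  cp_estimate(
    value = (ts_analogue$mean - reactant$mean) / denom,
    sd = sqrt(reactant$sd^2 + ts_analogue$sd^2) / denom,
    temperature_K = T,
    method = reactant$method,
    n_replicates = min(reactant$n_replicates, ts_analogue$n_replicates),
    region = reactant$region)
}

#' One-call activation heat capacity estimate
#'
#' Convenience wrapper: runs [state_variance()] on both ensembles with the
#' same protocol and takes the difference with [delta_cp()].
#'
#' @inheritParams state_variance
#' @param reactant,ts_analogue [state_ensemble()] objects at the same
#'   temperature.
#' @return A [cp_estimate()].
#' @export
estimate_delta_cp <- function(reactant, ts_analogue,
                              method = c("plain", "cluster_weighted",
                                         "moving_window"),
                              window = NULL, stride = NULL, pooled = FALSE,
                              region = NULL, burn_in = NULL) {
  method <- match.arg(method)
  delta_cp(
    state_variance(reactant, method, window, stride, pooled, region, burn_in),
    state_variance(ts_analogue, method, window, stride, pooled, region, burn_in))
}

#' Window-size convergence scan
#'
#' Recomputes the moving-window activation heat capacity change for a series
#' of window lengths and reports where the scan has converged. Estimates
#' stabilise once windows are long enough to average over local correlation
#' while the between-substate contribution stays controlled; a plateau is
#' declared where three consecutive windows agree pairwise within
#' `plateau_tol` (relative), and extended while the rule keeps holding.
#'
#' @param reactant,ts_analogue [state_ensemble()] objects.
#' @param windows_ns window lengths in ns, strictly increasing (default
#'   5-80 ns).
#' @param stride_frac stride as a fraction of the window (default 0.1).
#' @param plateau_tol relative pairwise tolerance for plateau detection
#'   (default 0.05).
#' @param burn_in burn-in fraction override.
#' @return Object of class `"window_scan"`: `scan` data.frame
#'   (`window_ns`, `delta_cp`, `sd`), `plateau_value` (mean over the plateau
#'   or `NA`), `plateau_range` (first/last window of the plateau or `NULL`).
#' @export
window_scan <- function(reactant, ts_analogue,
                        windows_ns = c(5, 10, 20, 30, 40, 50, 60, 70, 80),
                        stride_frac = 0.1, plateau_tol = 0.05,
                        burn_in = NULL) {
  stopifnot(inherits(reactant, "state_ensemble"),
            inherits(ts_analogue, "state_ensemble"))
  windows_ns <- as.numeric(windows_ns)
  if (is.unsorted(windows_ns, strictly = TRUE)) {
    stop("window lengths must be strictly increasing")
  }
  dt <- reactant$trajectories[[1L]]$time_step_ps
  dts <- vapply(c(reactant$trajectories, ts_analogue$trajectories),
                `[[`, numeric(1L), "time_step_ps")
  if (any(abs(dts - dt) > 1e-9)) {
    stop("all trajectories must share one time step for a window scan")
  }
  ests <- lapply(windows_ns, function(w_ns) {
    w <- as.integer(round(w_ns * 1000 / dt))
    s <- max(1L, as.integer(floor(w * stride_frac)))
    estimate_delta_cp(reactant, ts_analogue, method = "moving_window",
                      window = w, stride = s, burn_in = burn_in)
  })
  vals <- vapply(ests, `[[`, numeric(1L), "value")
  sds <- vapply(ests, `[[`, numeric(1L), "sd")

  reldiff <- function(a, b) abs(a - b) / max(abs(a), abs(b))
  triple_ok <- function(i) {
    v <- vals[i:(i + 2L)]
    max(reldiff(v[1L], v[2L]), reldiff(v[1L], v[3L]), reldiff(v[2L], v[3L])) <
      plateau_tol
  }
  plateau_value <- NA_real_
  plateau_range <- NULL
  m <- length(vals)
  if (m >= 3L) {
    start <- NA_integer_
    for (i in seq_len(m - 2L)) if (triple_ok(i)) { start <- i; break }
    if (!is.na(start)) {
      end <- start + 2L
      while (end < m && triple_ok(end - 1L)) end <- end + 1L
      plateau_value <- mean(vals[start:end])
      plateau_range <- c(windows_ns[start], windows_ns[end])
    }
  }
  structure(list(scan = data.frame(window_ns = windows_ns, delta_cp = vals,
                                   sd = sds),
                 plateau_value = plateau_value,
                 plateau_range = plateau_range,
                 temperature_K = reactant$temperature_K),
            class = "window_scan")
}

#' @export
print.window_scan <- function(x, ...) {
  cat(sprintf("Window scan (%g K), %d windows %g-%g ns\n", x$temperature_K,
              nrow(x$scan), min(x$scan$window_ns), max(x$scan$window_ns)))
  print(x$scan, row.names = FALSE)
  if (is.na(x$plateau_value)) {
    cat("  plateau: none\n")
  } else {
    cat(sprintf("  plateau: %.4f kJ mol^-1 K^-1 over %g-%g ns\n",
                x$plateau_value, x$plateau_range[1L], x$plateau_range[2L]))
  }
  invisible(x)
}

#' Partial activation heat capacity change for a structural region
#'
#' Recomputes the variance difference from a region's energy column only.
#' Inter-region interaction energies are excluded by construction, so
#' partial values over a partition of the structure need not sum to the
#' total: the shortfall is exactly the inter-region covariance term.
#'
#' @inheritParams estimate_delta_cp
#' @param region name of the region energy column; both ensembles must carry
#'   it.
#' @return A [cp_estimate()] labelled with the region.
#' @export
partial_cp <- function(reactant, ts_analogue, region,
                       method = c("plain", "cluster_weighted",
                                  "moving_window"),
                       window = NULL, stride = NULL, burn_in = NULL) {
  method <- match.arg(method)
  for (ens in list(reactant, ts_analogue)) {
    for (tr in ens$trajectories) {
      if (is.null(tr$regions) || !region %in% names(tr$regions)) {
        stop("region column '", region, "' missing from replicate '",
             tr$replicate_id, "' (", ens$state, ")")
      }
    }
  }
  estimate_delta_cp(reactant, ts_analogue, method = method, window = window,
                    stride = stride, region = region, burn_in = burn_in)
}

#' Energy histograms per replicate and pooled
#'
#' Density-normalised histograms of the post-burn-in energies on a common
#' grid; the pooled histogram is the frame-weighted mean of the replicate
#' histograms.
#'
#' @param ensemble a [state_ensemble()].
#' @param bins number of bins over the pooled range (ignored when `breaks`
#'   is given).
#' @param breaks optional explicit break points.
#' @param burn_in burn-in fraction override.
#' @return Object of class `"energy_histogram"`: `breaks`, `mids`,
#'   `replicate` (replicates x bins density matrix) and `pooled` density.
#' @export
energy_histogram <- function(ensemble, bins = 100, breaks = NULL,
                             burn_in = NULL) {
  stopifnot(inherits(ensemble, "state_ensemble"))
  if (is.null(burn_in)) burn_in <- ensemble$burn_in_fraction
  series <- lapply(ensemble$trajectories, function(tr) {
    tr$energy[.post_burnin(length(tr$energy), burn_in)]
  })
  if (is.null(breaks)) {
    rng <- range(unlist(series))
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)  # constant series
    breaks <- seq(rng[1L], rng[2L], length.out = bins + 1L)
  }
  dens <- t(vapply(series, function(e) {
    graphics::hist(e, breaks = breaks, plot = FALSE)$density
  }, numeric(length(breaks) - 1L)))
  rownames(dens) <- vapply(ensemble$trajectories, `[[`, character(1L),
                           "replicate_id")
  wts <- vapply(series, length, integer(1L))
  structure(list(breaks = breaks,
                 mids = (breaks[-1L] + breaks[-length(breaks)]) / 2,
                 replicate = dens,
                 pooled = colSums(dens * wts) / sum(wts)),
            class = "energy_histogram")
}

#' Read an energy table
#'
#' Delimited text (comma or tab, `#` comments), columns `time_ps`,
#' `energy_total`, optional `energy_<region>` columns and an optional
#' `cluster` column.
#'
#' @param path file path.
#' @param replicate_id,state,temperature_K trajectory metadata (usually
#'   supplied by the manifest via [read_state_ensemble()]).
#' @return An [energy_trajectory()].
#' @export
read_energy_table <- function(path, replicate_id = basename(path),
                              state = c("reactant", "ts_analogue"),
                              temperature_K) {
  tab <- .read_delim(path)
  need <- c("time_ps", "energy_total")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("energy table ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "))
  }
  region_cols <- grep("^energy_", names(tab), value = TRUE)
  region_cols <- setdiff(region_cols, "energy_total")
  regions <- if (length(region_cols)) {
    r <- tab[region_cols]
    names(r) <- sub("^energy_", "", names(r))
    r
  } else NULL
  energy_trajectory(tab$time_ps, tab$energy_total, regions = regions,
                    cluster = if ("cluster" %in% names(tab)) tab$cluster else NULL,
                    replicate_id = replicate_id, state = match.arg(state),
                    temperature_K = temperature_K)
}

#' Write an energy table
#'
#' @param traj an [energy_trajectory()].
#' @param path output path (comma separated, header line).
#' @return Invisibly, `path`.
#' @export
write_energy_table <- function(traj, path) {
  stopifnot(inherits(traj, "energy_trajectory"))
  tab <- data.frame(time_ps = traj$time_ps, energy_total = traj$energy)
  if (!is.null(traj$regions)) {
    r <- traj$regions
    names(r) <- paste0("energy_", names(r))
    tab <- cbind(tab, r)
  }
  if (!is.null(traj$cluster)) tab$cluster <- traj$cluster
  utils::write.table(tab, path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a state ensemble from a manifest
#'
#' The manifest is a delimited text file with columns `file`, `state`,
#' `temperature_K` and `replicate_id`; `file` paths are resolved relative to
#' the manifest's directory. All rows must share one state and temperature.
#'
#' @param manifest manifest file path.
#' @param burn_in_fraction burn-in fraction for the ensemble.
#' @return A [state_ensemble()].
#' @export
read_state_ensemble <- function(manifest, burn_in_fraction = 0.1) {
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  tab <- .read_delim(manifest)
  need <- c("file", "state", "temperature_K", "replicate_id")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("manifest ", manifest, " lacks required column(s): ",
         paste(miss, collapse = ", "))
  }
  base <- dirname(manifest)
  trajs <- lapply(seq_len(nrow(tab)), function(i) {
    f <- tab$file[i]
    if (!file.exists(f)) f <- file.path(base, tab$file[i])
    if (!file.exists(f)) stop("energy table not found: ", tab$file[i])
    read_energy_table(f, replicate_id = tab$replicate_id[i],
                      state = tab$state[i],
                      temperature_K = tab$temperature_K[i])
  })
  state_ensemble(trajs, burn_in_fraction = burn_in_fraction)
}

#' Write a state ensemble as energy tables plus a manifest
#'
#' @param ensemble a [state_ensemble()].
#' @param dir output directory (created if needed).
#' @param manifest manifest file name within `dir`.
#' @return Invisibly, the manifest path.
#' @export
write_state_ensemble <- function(ensemble, dir, manifest = "manifest.csv") {
  stopifnot(inherits(ensemble, "state_ensemble"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- vapply(ensemble$trajectories, function(tr) {
    f <- paste0(tr$replicate_id, ".csv")
    write_energy_table(tr, file.path(dir, f))
    f
  }, character(1L))
  tab <- data.frame(
    file = files,
    state = ensemble$state,
    temperature_K = ensemble$temperature_K,
    replicate_id = vapply(ensemble$trajectories, `[[`, character(1L),
                          "replicate_id"))
  path <- file.path(dir, manifest)
  utils::write.table(tab, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an activation heat capacity report
#'
#' JSON plus `key: value` text rendering of a [cp_estimate()] and its
#' supporting per-replicate variances.
#'
#' @param estimate a [cp_estimate()].
#' @param reactant,ts_analogue optional [state_variance()] objects to embed.
#' @param json_path output JSON path; the text report gains extension
#'   `.txt`.
#' @return Invisibly, the report list.
#' @export
write_dcp_report <- function(estimate, json_path, reactant = NULL,
                             ts_analogue = NULL) {
  stopifnot(inherits(estimate, "cp_estimate"))
  sv <- function(x) if (is.null(x)) NULL else
    list(state = x$state, method = x$method, mean = x$mean, sd = x$sd,
         per_replicate = x$per_replicate)
  report <- list(delta_cp = estimate$value, sd = estimate$sd,
                 temperature_K = estimate$temperature_K,
                 method = estimate$method, region = estimate$region,
                 n_replicates = estimate$n_replicates,
                 reactant = sv(reactant), ts_analogue = sv(ts_analogue))
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  writeLines(c(
    sprintf("delta_cp_kJ_mol_K: %.6g", estimate$value),
    sprintf("sd: %.6g", estimate$sd),
    sprintf("temperature_K: %.6g", estimate$temperature_K),
    sprintf("method: %s", estimate$method),
    sprintf("region: %s", estimate$region),
    sprintf("n_replicates: %s", estimate$n_replicates)),
    sub("\\.json$", ".txt", json_path))
  invisible(report)
}
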