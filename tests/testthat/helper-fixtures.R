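# shared fixture builders (everything generated in code; no stored data)

R_GAS <- physical_constants()$R  # kJ mol^-1 K^-1

# constant-variance trajectory: series rescaled so its unbiased sample
# variance is exactly `v` (mean exactly `m`)
exact_var_series <- function(n, v, m = 0, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  x <- (x - mean(x)) / sd(x)
  m + x * sqrt(v)
}

make_traj <- function(energy, temperature_K = 300, replicate_id = "r1",
                      state = "reactant", cluster = NULL, regions = NULL,
                      dt = 10) {
  energy_trajectory(seq_along(energy) * dt - dt, energy, regions = regions,
                    cluster = cluster, replicate_id = replicate_id,
                    state = state, temperature_K = temperature_K)
}

make_ensemble <- function(energies_list, temperature_K = 300,
                          state = "reactant", burn_in = 0, ...) {
  trs <- lapply(seq_along(energies_list), function(i) {
    make_traj(energies_list[[i]], temperature_K = temperature_K,
              replicate_id = sprintf("r%02d", i), state = state, ...)
  })
  state_ensemble(trs, burn_in_fraction = burn_in)
}

# rigid body helpers
random_rotation_matrix <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

apply_rigid <- function(x, rot, trans) {
  x %*% rot + rep(1, nrow(x)) %*% t(trans)
}
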