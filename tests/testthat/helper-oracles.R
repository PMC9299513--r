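# Independent brute-force oracles and small fixture builders used across the
# suite. Oracles deliberately re-derive quantities from first principles and
# never call the implementation paths they check.

# Exhaustive-enumeration Mann-Whitney oracle: U from midranks of the pooled
# sample, two-sided p as the permutation probability of a U at least as far
# from n_a*n_b/2 as observed, over all C(n, n_a) label assignments.
mw_oracle <- function(a, b) {
  n_a <- length(a)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  mu <- n_a * length(b) / 2
  sets <- utils::combn(length(r), n_a)
  u_all <- apply(sets, 2, function(ix) sum(r[ix]) - n_a * (n_a + 1) / 2)
  list(u = u_obs, p = mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9))
}

# Brute-force peak oracle: baseline = mean of final 50% of holding samples,
# peak = signed value of the largest |excursion| among in-window samples.
peak_oracle <- function(s, window_ms = NULL) {
  p <- s$protocol
  dt <- p$sample_interval_ms
  n_hold <- round(p$holding_duration_ms / dt)
  n_step <- round(p$step_duration_ms / dt)
  t_step <- (seq_len(n_step) - 1) * dt
  if (is.null(window_ms)) window_ms <- c(0, max(t_step))
  keep <- which(t_step >= window_ms[1] & t_step <= window_ms[2]) + n_hold
  base_idx <- seq_len(n_hold)
  base_idx <- base_idx[base_idx > n_hold / 2]
  vapply(seq_len(ncol(s$sweeps)), function(j) {
    x <- s$sweeps[keep, j] - mean(s$sweeps[base_idx, j])
    x[which.max(abs(x))]
  }, 0)
}

# Hand-built sweep set: `traces` is a matrix (or vector) of full sweeps laid
# out as n_hold holding samples followed by step samples.
manual_sweep_set <- function(traces, n_hold, dt = 1, holding_mV = -45,
                             potentials = NULL, bath = bath_preset("ames"),
                             ljp_applied = TRUE) {
  traces <- as.matrix(traces)
  n_step <- nrow(traces) - n_hold
  if (is.null(potentials)) potentials <- seq_len(ncol(traces)) * 10 - 55
  prot <- voltage_protocol(holding_mV, min(potentials), max(potentials),
                           if (length(potentials) > 1)
                             diff(potentials)[1] else 10,
                           step_duration_ms = n_step * dt,
                           holding_duration_ms = n_hold * dt,
                           sample_interval_ms = dt)
  sweep_set((seq_len(nrow(traces)) - 1) * dt, traces, potentials, prot, bath,
            cell_id = "manual", ljp_applied = ljp_applied)
}

# Single-channel noiseless cells used throughout.
noiseless_cell <- function(..., leak = 0, seed = 1) {
  cell_spec(channels = list(...), leak_conductance_nS = leak,
            noise_sd_pA = 0, seed = seed)
}

m_cell <- function(noise_sd = 0, seed = 1, gmax = 1.8)
  cell_spec(channels = list(channel_preset("m_current", gmax_nS = gmax)),
            leak_conductance_nS = 0, noise_sd_pA = noise_sd, seed = seed)
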