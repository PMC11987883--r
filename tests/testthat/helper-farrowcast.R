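# Shared fixtures: everything is generated in code at test time.

# A small, fast cohort: 6 sows, 24 h of 5-min points with a 6-h "diurnal"
# cycle and a ramp over the last 6 h. Keeps windowing/splitting/analysis
# tests quick while preserving the full structure of the default generator.
tiny_sim_config <- function(...) {
  args <- list(n_sows = 6, horizon_points = 288L, diurnal_period = 72L,
               ramp_start = 72L)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# A noise-free, jitter-free configuration where every component is known
# in closed form.
clean_sim_config <- function(...) {
  args <- list(noise_sd = 0, bout_sd = 0, final_day_extra_sd = 0,
               baseline_jitter_sd = 0, ramp_start_jitter_sd = 0,
               diurnal_phase = 0, diurnal_phase_sd = 0)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# Tiny model configuration for fast training tests.
tiny_claptnet_config <- function(...) {
  args <- list(seq_len = 12L, cbe_channels = 4L, cbe_kernel_sizes = 3L,
               lstm_hidden = 6L, dropout = 0, epochs = 3L, batch_size = 16L)
  do.call(claptnet_config, utils::modifyList(args, list(...)))
}

# Brute-force textbook scaled-dot-product self-attention (independent
# oracle for the PTW-SA reduction property): explicit double loop over
# query/key positions.
brute_force_attention <- function(H, w_q, w_k, w_v, scale) {
  t <- nrow(H); d <- ncol(H)
  Q <- H %*% w_q; K <- H %*% w_k; V <- H %*% w_v
  O <- matrix(0, t, d)
  W <- matrix(0, t, t)
  for (i in seq_len(t)) {
    scores <- numeric(t)
    for (j in seq_len(t)) scores[j] <- sum(Q[i, ] * K[j, ]) / scale
    e <- exp(scores - max(scores))
    W[i, ] <- e / sum(e)
    for (j in seq_len(t)) O[i, ] <- O[i, ] + W[i, j] * V[j, ]
  }
  list(output = O, weights = W)
}
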