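# Shared helpers: small closed-form oracles and pooled simulation estimators.

# deterministic mass-action integration of irreversible A + B -> C with
# A0 = B0 (copies): At = 1 / (1/A0 + kc * t), kc in per-copy per-second
mass_action_At <- function(A0, kc, t) 1 / (1 / A0 + kc * t)

# maximum-likelihood macroscopic association rate (uM^-1 s^-1) from pooled
# irreversible trajectories: total events over the integrated A_t * B_t
fit_kon_from_runs <- function(frames_list, A0, V_um3) {
  ev <- 0; denom <- 0
  for (fr in frames_list) {
    At <- A0 - fr$n_bonds
    dt <- diff(fr$time_s)
    ev <- ev + fr$n_bonds[length(At)]
    mid <- (At[-1] + At[-length(At)]) / 2
    denom <- denom + sum(mid^2 * dt)
  }
  (ev / denom) * 602.214076 * V_um3
}

# time-average and block-averaged standard error of a (correlated) series
block_mean_se <- function(x, blocks = 10) {
  bl <- split(x, cut(seq_along(x), blocks))
  bm <- vapply(bl, mean, 0)
  c(mean = mean(x), se = stats::sd(bm) / sqrt(blocks))
}

expect_within_3se <- function(value, se, reference, floor_se = 0) {
  expect_lt(abs(value - reference), 3 * max(se, floor_se))
}
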