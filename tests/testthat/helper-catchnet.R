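# Shared builders for the test suite. Everything is generated in code;
# no fixture files.

default_design <- task_design()

# a deterministic (noiseless, lapse-free) observer with one constant weight
noiseless_observer <- function(w, id = "S1", group = "TD") {
  observer(subject_id = id, group = group, weights = w,
           motor_noise_sd = 0, lapse_rate = 0)
}

# homogeneous group spec: every subject follows b * optimal exactly, with
# independent per-condition jitter only
flat_spec <- function(scale = 0.8, jitter = 0.05, noise = 0.03,
                      lapse = 0, lapse_mode = "timeout") {
  group_spec(weight_scale = scale, weight_scale_sd = 0,
             weight_jitter_sd = jitter,
             motor_noise_mean = noise, motor_noise_sd_sd = 0,
             lapse_rate = lapse, lapse_mode = lapse_mode)
}

# simulate a single subject x condition cell: n trials of one condition
# under the linear readout with weight w and motor noise
sim_cell <- function(n, w, prior_sd, likelihood_sd, noise = 0,
                     design = default_design) {
  stim <- sample_trial(rep(prior_sd, n), rep(likelihood_sd, n), design)
  cen <- splash_centroid(stim$splash)
  resp <- w * cen + (1 - w) * design$prior_mean + rnorm(n, 0, noise)
  list(centroid = cen, response = resp, target = stim$target)
}

# independent signed-rank oracle: brute-force enumeration of every sign
# assignment via expand.grid (kept separate from the package's
# convolution-based implementation)
enumerate_signrank <- function(d) {
  d <- d[d != 0]
  m <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d < 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), m)))
  W_all <- signs %*% r
  list(W = W_obs,
       p_le = mean(W_all <= W_obs + 1e-12),
       p_ge = mean(W_all >= W_obs - 1e-12))
}
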