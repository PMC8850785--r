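# Shared fixtures: samples with known ground truth and hand-built protocols.

# Exact-observation sample of n subjects drawn from the expanded log-logistic
# law; measurement noise is omitted so the fit target is the law itself.
make_exact_sample <- function(n, beta0, beta1, alpha, male_fraction = 0.5,
                              seed = 1, location_id = 12,
                              load_type = "pinching", contact_type = "blunt") {
  pop <- sample_population(n, male_fraction, seed = seed)
  y <- draw_threshold(n, beta0, beta1, alpha, gender_code = pop$gender_code,
                      seed = seed + 1)
  sample_from_y(y, pop$gender_code, location_id, load_type, contact_type)
}

# Wrap a vector of exact threshold values as an assembled sample.
sample_from_y <- function(y, gender_code, location_id = 12,
                          load_type = "pinching", contact_type = "blunt") {
  obs <- tibble::tibble(subject_id = sprintf("S%03d", seq_along(y)),
                        gender_code = gender_code,
                        L = y, R = y, censor_type = "exact")
  assemble_sample(average_repeats(impute_midpoint(obs)),
                  location_id, load_type, contact_type)
}

# Minimal protocol list with explicit constants (bypasses default_protocol).
make_protocol <- function(c_H, noise_sd = 0, step = 0.05, start = step,
                          offset = 0, reaction_delay = 0) {
  list(deformation_rate = 1e-3,
       velocity_start = start, velocity_step = step, velocity_max = 1.25,
       pendulum_masses = c(16.5, 6.5), c_H = c_H,
       noise_sd = noise_sd, offset = offset,
       reaction_delay = reaction_delay, sampling_rate = 1e4)
}

# One ground-truth parameter row from the published table.
truth_row <- function(loc, load, contact) {
  tp <- threshold_params()
  tp[tp$location_id == loc & tp$load_type == load &
       tp$contact_type == contact, ]
}
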