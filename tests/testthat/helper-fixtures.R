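# Small in-code fixtures shared across test files.

# long-format response table: one object, explicit normalized texts and
# categories, constant ratings unless given
make_responses <- function(participant_id, object_id, normalized_text,
                           category_label = "cat1",
                           rater1 = 3, rater2 = 3) {
  data.frame(participant_id = participant_id, object_id = object_id,
             raw_text = normalized_text,
             normalized_text = normalized_text,
             category_label = category_label,
             rater1_score = rater1, rater2_score = rater2,
             stringsAsFactors = FALSE)
}

# a clean criterion-4 style recording: 30 blinks + 10 saccade surrogates
# over 180 s with moderate noise
make_reference_recording <- function(seed = 11, noise_sd = 15) {
  set.seed(7)
  bt <- spaced_event_times(30, 180, 0.35)
  st <- spaced_event_times(10, 180, 0.5) + 0.17
  cfg <- eeg_sim_config(blink_times = bt, saccade_times = st,
                        noise_sd = noise_sd, seed = seed)
  c(simulate_eeg(cfg), list(config = cfg))
}

# independent noncentral-F upper tail via the Poisson-mixture-of-betas
# series (does not use pf's ncp argument)
ncf_upper_tail <- function(q, df1, df2, ncp, terms = 400) {
  xx <- df1 * q / (df1 * q + df2)
  j <- 0:terms
  w <- stats::dpois(j, ncp / 2)
  cdf <- sum(w * stats::pbeta(xx, df1 / 2 + j, df2 / 2))
  1 - cdf
}
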