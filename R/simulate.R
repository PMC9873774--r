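# Default frontal montage used throughout: the channels that carry the
# largest blink deflections on a standard 10-10 layout.
FRONTAL_CHANNELS <- c("Fpz", "Fz", "Fp1", "Fp2", "F3", "F4", "FC3", "FC4")

#' Configuration for the EEG-like recording simulator
#'
#' Defines a multichannel resting-state segment into which tent-shaped
#' blink waveforms and step-like saccade surrogates are embedded on top of
#' Gaussian background noise. Amplitudes are in arbitrary signal units
#' (microvolt-scale defaults), times in seconds.
#'
#' @param channel_labels character vector of channel names; channels whose
#'   label starts with "Fp" receive the full blink amplitude, other frontal
#'   channels progressively less (frontal gradient).
#' @param fs sampling rate in Hz (must be >= 100 so that 50 ms events are
#'   representable).
#' @param duration segment length in seconds.
#' @param blink_times numeric vector of blink apex times (seconds).
#'   Consecutive blinks must be separated by more than 50 ms plus the full
#'   tent width so that events never overlap.
#' @param blink_amplitude apex amplitude of the blink tent on "Fp" channels.
#' @param rise_ms,fall_ms rising and falling limb durations of the tent in
#'   milliseconds.
#' @param saccade_times numeric vector of saccade-surrogate onset times.
#' @param saccade_amplitude plateau amplitude of the saccade surrogate
#'   (default 0.4 x blink amplitude: small deflection, high velocity).
#' @param noise_sd standard deviation of the additive white Gaussian noise.
#' @param seed integer seed; fully determines the simulated recording.
#' @return an object of class `eeg_sim_config`.
#' @export
eeg_sim_config <- function(channel_labels = FRONTAL_CHANNELS,
                           fs = 250,
                           duration = 180,
                           blink_times = numeric(0),
                           blink_amplitude = 100,
                           rise_ms = 120,
                           fall_ms = 180,
                           saccade_times = numeric(0),
                           saccade_amplitude = 0.4 * blink_amplitude,
                           noise_sd = 15,
                           seed = 1L) {
  stopifnot(length(channel_labels) >= 1, fs > 0, duration > 0,
            noise_sd >= 0, rise_ms > 0, fall_ms > 0, blink_amplitude > 0)
  if (fs < 100) {
    stop("fs must be at least 100 Hz to represent 50 ms blink events")
  }
  blink_times <- sort(as.numeric(blink_times))
  tent_s <- (rise_ms + fall_ms) / 1000
  if (length(blink_times) > 0) {
    if (any(blink_times < 0) || any(blink_times > duration)) {
      stop("all blink_times must lie within [0, duration]")
    }
    if (length(blink_times) > 1 &&
        any(diff(blink_times) <= 0.05 + tent_s)) {
      stop("blink_times overlap: consecutive blinks must be separated by ",
           "more than 50 ms plus the tent width (",
           signif(0.05 + tent_s, 3), " s)")
    }
  }
  structure(list(channel_labels = channel_labels,
                 n_channels = length(channel_labels),
                 fs = fs, duration = duration,
                 blink_times = blink_times,
                 blink_amplitude = blink_amplitude,
                 rise_ms = rise_ms, fall_ms = fall_ms,
                 saccade_times = sort(as.numeric(saccade_times)),
                 saccade_amplitude = saccade_amplitude,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "eeg_sim_config")
}

# Per-channel scaling of ocular deflections: strongest at the prefrontal
# pole, weaker over mid-frontal and fronto-central sites.
frontal_gradient <- function(labels) {
  ifelse(startsWith(labels, "Fp"), 1,
  ifelse(startsWith(labels, "FC"), 0.45,
  ifelse(startsWith(labels, "F"), 0.7, 0.2)))
}

# Draw n event times in (margin, duration - margin) with pairwise gaps
# greater than min_gap, by jittering an equally spaced grid.
#' Draw well-separated event times
#'
#' Utility used by the simulator and the pipeline to place blink (or
#' saccade) apexes so that no two events overlap.
#'
#' @param n number of events.
#' @param duration segment length in seconds.
#' @param min_gap minimal separation between consecutive events (seconds).
#' @param margin keep-out zone at both segment edges (seconds).
#' @return sorted numeric vector of n times.
#' @export
spaced_event_times <- function(n, duration, min_gap, margin = 1) {
  if (n == 0) return(numeric(0))
  usable <- duration - 2 * margin
  if (usable <= (n - 1) * min_gap) {
    stop("cannot place ", n, " events with gap ", min_gap, " in ",
         duration, " s")
  }
  slot <- usable / n
  jitter_max <- max(0, (slot - min_gap) / 2)
  centres <- margin + slot * (seq_len(n) - 0.5)
  centres + stats::runif(n, -jitter_max, jitter_max)
}

#' Simulate a multichannel EEG-like recording with known blink ground truth
#'
#' Builds a samples x channels matrix containing, on every channel, an
#' additive piecewise-linear "tent" at each requested blink time (linear
#' rise over `rise_ms` to the apex, linear fall over `fall_ms`), scaled by
#' a frontal-gradient factor per channel, plus step-like saccade surrogates
#' (20 ms ramp up, 80 ms plateau, 20 ms ramp down) and white Gaussian
#' noise. The tent is piecewise linear by design so that the tent-shape
#' correlation criterion of the detector has an exactly satisfiable case.
#'
#' @param config an [eeg_sim_config()].
#' @return a list with components `recording` (an [eeg_recording()]) and
#'   `truth`, a data.frame of ground-truth blink onset/peak/offset sample
#'   indices (1-based, on the unscaled template).
#' @export
simulate_eeg <- function(config) {
  stopifnot(inherits(config, "eeg_sim_config"))
  n <- round(config$fs * config$duration)
  set.seed(config$seed)
  gains <- frontal_gradient(config$channel_labels)

  template <- numeric(n)
  rise_n <- max(1L, round(config$fs * config$rise_ms / 1000))
  fall_n <- max(1L, round(config$fs * config$fall_ms / 1000))
  truth <- data.frame(onset = integer(0), peak = integer(0),
                      offset = integer(0))
  for (tb in config$blink_times) {
    pk <- round(tb * config$fs) + 1L
    on <- max(1L, pk - rise_n)
    off <- min(n, pk + fall_n)
    idx_up <- on:pk
    idx_dn <- pk:off
    template[idx_up] <- pmax(template[idx_up],
      config$blink_amplitude * (idx_up - on) / (pk - on))
    if (off > pk) {
      template[idx_dn] <- pmax(template[idx_dn],
        config$blink_amplitude * (off - idx_dn) / (off - pk))
    }
    truth <- rbind(truth, data.frame(onset = on, peak = pk, offset = off))
  }

  # saccade surrogate: fast 20 ms ramps flanking an 80 ms plateau -- small
  # amplitude but very high upstroke velocity, so the pAVR criterion is the
  # one that has to reject it.
  ramp_n <- max(1L, round(config$fs * 0.020))
  plat_n <- max(1L, round(config$fs * 0.080))
  for (ts in config$saccade_times) {
    on <- round(ts * config$fs) + 1L
    i1 <- on:min(n, on + ramp_n)
    template[i1] <- template[i1] +
      config$saccade_amplitude * (i1 - on) / ramp_n
    i2 <- min(n, on + ramp_n):min(n, on + ramp_n + plat_n)
    template[i2] <- template[i2] + config$saccade_amplitude
    i3 <- min(n, on + ramp_n + plat_n):min(n, on + 2L * ramp_n + plat_n)
    template[i3] <- template[i3] +
      config$saccade_amplitude * (1 - (i3 - min(i3)) / ramp_n)
  }

  sig <- outer(template, gains)
  if (config$noise_sd > 0) {
    sig <- sig + matrix(stats::rnorm(n * config$n_channels,
                                     sd = config$noise_sd),
                        nrow = n)
  }
  colnames(sig) <- config$channel_labels
  rec <- eeg_recording(sig, fs = config$fs,
                       channel_labels = config$channel_labels)
  list(recording = rec, truth = truth)
}

#' Configuration for the participant-level population simulator
#'
#' Encodes the structural model the analysis assumes: a predictor X (sEBR,
#' blinks/min) drawn from a truncated normal, a mediator M (flexibility)
#' depending on X through linear and quadratic paths, and an outcome Y
#' (originality) depending linearly on M with a weaker quadratic direct
#' path from X.
#'
#' Defaults place the apex of the X->M curve one SD above the mean
#' predictor, with path magnitudes giving a quadratic R-squared around 0.3
#' for the mediator model and a strong linear M->Y slope, i.e. a clear
#' inverted-U mediation structure at realistic signal-to-noise.
#'
#' @param n_participants sample size (>= 4).
#' @param ebr_mean,ebr_sd mean and SD of the predictor (blinks/min);
#'   draws are truncated at 0.5 blinks/min.
#' @param a1,a2 linear and quadratic X->M path coefficients.
#' @param b linear M->Y path coefficient.
#' @param c1,c2 linear and quadratic direct X->Y path coefficients.
#' @param i_m,i_y intercepts of the M and Y equations.
#' @param sigma_m,sigma_y residual standard deviations (>= 0).
#' @param seed integer seed.
#' @return an object of class `population_sim_config`.
#' @export
population_sim_config <- function(n_participants = 73,
                                  ebr_mean = 10.76, ebr_sd = 6.05,
                                  a1 = 0.1345, a2 = -0.004,
                                  b = 1.57,
                                  c1 = 0.02, c2 = -0.001,
                                  i_m = 2.2, i_y = -1.8,
                                  sigma_m = 0.55, sigma_y = 0.5,
                                  seed = 1L) {
  stopifnot(n_participants >= 4, sigma_m >= 0, sigma_y >= 0,
            ebr_sd > 0, ebr_mean > 0)
  structure(list(n_participants = as.integer(n_participants),
                 ebr_mean = ebr_mean, ebr_sd = ebr_sd,
                 a1 = a1, a2 = a2, b = b, c1 = c1, c2 = c2,
                 i_m = i_m, i_y = i_y,
                 sigma_m = sigma_m, sigma_y = sigma_y,
                 seed = as.integer(seed)),
            class = "population_sim_config")
}

#' Simulate participant-level predictor, mediator and outcome
#'
#' Draws X from a normal truncated below at 0.5 blinks/min and generates
#' M = i_m + a1 X + a2 X^2 + e_M and
#' Y = i_y + c1 X + c2 X^2 + b M + e_Y with independent Gaussian errors.
#'
#' @param config a [population_sim_config()].
#' @return data.frame with columns participant_id, sebr (X), flexibility
#'   (M) and originality (Y).
#' @export
simulate_participants <- function(config) {
  stopifnot(inherits(config, "population_sim_config"))
  set.seed(config$seed)
  n <- config$n_participants
  x <- numeric(0)
  while (length(x) < n) {               # rejection sampling, trunc at 0.5
    draw <- stats::rnorm(2 * n, config$ebr_mean, config$ebr_sd)
    x <- c(x, draw[draw > 0.5])
  }
  x <- x[seq_len(n)]
  m <- config$i_m + config$a1 * x + config$a2 * x^2 +
    stats::rnorm(n, sd = config$sigma_m)
  y <- config$i_y + config$c1 * x + config$c2 * x^2 + config$b * m +
    stats::rnorm(n, sd = config$sigma_y)
  data.frame(participant_id = sprintf("P%03d", seq_len(n)),
             sebr = x, flexibility = m, originality = y,
             stringsAsFactors = FALSE)
}

#' Configuration for the AUT response simulator
#'
#' @param n_objects number of task objects (default 5, as in the standard
#'   five-object administration).
#' @param category_codebook named list mapping object id to its vector of
#'   admissible conceptual category labels; `NULL` uses a built-in
#'   five-object demo codebook.
#' @param mean_responses_per_object Poisson mean of the per-object response
#'   count (latent fluency); every participant produces at least one
#'   response per object.
#' @param fluency_log_sd lognormal SD of the participant-level fluency
#'   multiplier.
#' @param vocabulary_size number of distinct response texts per object;
#'   texts are drawn with Zipf weights so common and rare responses coexist.
#' @param rater_noise_sd SD of each judge's independent rating error; when
#'   `NULL` (default) it is calibrated from `target_icc` via the ICC(2,2)
#'   closed form using the realised between-idea quality variance.
#' @param target_icc desired inter-rater ICC(2,2) of the simulated ratings.
#' @param quality_slope how strongly an idea's latent quality tracks its
#'   author's latent originality score.
#' @param quality_sd within-participant SD of idea quality.
#' @param seed integer seed.
#' @return an object of class `response_sim_config`.
#' @export
response_sim_config <- function(n_objects = 5,
                                category_codebook = NULL,
                                mean_responses_per_object = 4.2,
                                fluency_log_sd = 0.25,
                                vocabulary_size = 40,
                                rater_noise_sd = NULL,
                                target_icc = 0.88,
                                quality_slope = 0.5,
                                quality_sd = 0.4,
                                seed = 1L) {
  if (is.null(category_codebook)) {
    category_codebook <- demo_codebook(n_objects)
  }
  if (any(lengths(category_codebook) == 0)) {
    stop("empty category codebook for object: ",
         names(category_codebook)[lengths(category_codebook) == 0][1])
  }
  stopifnot(length(category_codebook) == n_objects,
            is.null(rater_noise_sd) || rater_noise_sd >= 0,
            target_icc > 0, target_icc <= 1)
  structure(list(n_objects = as.integer(n_objects),
                 category_codebook = category_codebook,
                 mean_responses_per_object = mean_responses_per_object,
                 fluency_log_sd = fluency_log_sd,
                 vocabulary_size = as.integer(vocabulary_size),
                 rater_noise_sd = rater_noise_sd,
                 target_icc = target_icc,
                 quality_slope = quality_slope,
                 quality_sd = quality_sd,
                 seed = as.integer(seed)),
            class = "response_sim_config")
}

#' Built-in demo codebook of conceptual categories per object
#'
#' @param n_objects number of objects (at most 5 named objects; beyond 5,
#'   generic object ids are appended).
#' @return named list, object id -> character vector of category labels.
#' @export
demo_codebook <- function(n_objects = 5) {
  base <- list(
    brick     = c("weight", "building", "tool", "weapon", "art",
                  "container", "exercise", "furniture"),
    hat       = c("container", "clothing", "decoration", "toy", "signal",
                  "protection", "collection", "art"),
    hammer    = c("tool", "weapon", "weight", "instrument", "art",
                  "exercise", "lever", "decoration"),
    newspaper = c("packing", "cleaning", "fuel", "art", "insulation",
                  "protection", "toy", "information"),
    shoe      = c("container", "tool", "decoration", "weapon", "toy",
                  "plant-pot", "protection", "art"))
  if (n_objects <= 5) return(base[seq_len(n_objects)])
  extra <- lapply(seq_len(n_objects - 5), function(i) base[[1]])
  names(extra) <- sprintf("object%d", 5 + seq_len(n_objects - 5))
  c(base, extra)
}

# Filler phrases occasionally prepended to raw response text so that the
# normalisation stage is exercised end to end.
RAW_DECORATIONS <- c("", "", "", "used for ", "use as ", "it can be a ")

#' Simulate long-format AUT responses with two raters
#'
#' For each participant and object, draws a response count tied to the
#' participant's latent fluency, picks a number of distinct conceptual
#' categories tracking the participant's latent flexibility, samples
#' response texts from a Zipf-weighted per-object vocabulary (so that
#' frequency-based originality varies), and produces two judge ratings as a
#' shared latent idea quality plus independent rater noise calibrated to
#' the target ICC(2,2). Ratings are clipped to the 1-5 scale.
#'
#' @param participants data.frame from [simulate_participants()] (columns
#'   participant_id, flexibility, originality at minimum).
#' @param config a [response_sim_config()].
#' @return data.frame with columns participant_id, object_id, raw_text,
#'   normalized_text, category_label, rater1_score, rater2_score.
#' @export
simulate_aut_responses <- function(participants, config) {
  stopifnot(inherits(config, "response_sim_config"),
            nrow(participants) > 0)
  if (any(lengths(config$category_codebook) == 0)) {
    stop("empty category codebook for object: ",
         names(config$category_codebook)[
           lengths(config$category_codebook) == 0][1])
  }
  set.seed(config$seed)
  objects <- names(config$category_codebook)
  zipf_w <- 1 / seq_len(config$vocabulary_size)

  n_p <- nrow(participants)
  flu_mult <- exp(stats::rnorm(n_p, 0, config$fluency_log_sd))
  rows <- vector("list", n_p * length(objects))
  k <- 0L
  for (i in seq_len(n_p)) {
    m_i <- participants$flexibility[i]
    for (obj in objects) {
      cats <- config$category_codebook[[obj]]
      n_resp <- 1L + stats::rpois(1,
        max(0, config$mean_responses_per_object * flu_mult[i] - 1))
      k_cat <- round(m_i + stats::runif(1, -0.5, 0.5))
      k_cat <- max(1L, min(n_resp, length(cats), k_cat))
      used <- sample(cats, k_cat)
      texts <- sprintf("%s idea%02d", obj,
                       sample.int(config$vocabulary_size, n_resp,
                                  replace = TRUE, prob = zipf_w))
      k <- k + 1L
      rows[[k]] <- data.frame(
        participant_id = participants$participant_id[i],
        object_id = obj,
        raw_text = paste0(sample(RAW_DECORATIONS, n_resp, replace = TRUE),
                          texts),
        normalized_text = texts,
        category_label = rep_len(used, n_resp),
        quality_mean = 3 + config$quality_slope *
          (participants$originality[i] - mean(participants$originality)),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows[seq_len(k)])

  quality <- stats::rnorm(nrow(tab), tab$quality_mean, config$quality_sd)
  noise_sd <- config$rater_noise_sd
  if (is.null(noise_sd)) {
    # ICC(2,k) closed form: rho = s_q^2 / (s_q^2 + s_e^2 / k)  =>
    # s_e^2 = k s_q^2 (1 - rho) / rho, with the realised quality variance.
    s_q2 <- stats::var(quality)
    noise_sd <- sqrt(2 * s_q2 * (1 - config$target_icc) / config$target_icc)
  }
  clip15 <- function(v) pmin(5, pmax(1, v))
  tab$rater1_score <- clip15(quality + stats::rnorm(nrow(tab), 0, noise_sd))
  tab$rater2_score <- clip15(quality + stats::rnorm(nrow(tab), 0, noise_sd))
  tab$quality_mean <- NULL
  rownames(tab) <- NULL
  tab
}
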