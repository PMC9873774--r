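# stage-specific seeds derived deterministically from the global seed;
# offsets are arbitrary fixed constants kept well below 2^31
stage_seed <- function(seed, stage, i = 0L) {
  offsets <- c(population = 1000L, eeg = 2000L, responses = 3000L,
               mediation = 4000L)
  as.integer((seed + offsets[[stage]] + i) %% .Machine$integer.max)
}

#' Default end-to-end run configuration
#'
#' Nested list mirroring the YAML config file layout accepted by
#' [run_full_analysis()]: a global `seed`, an `output_dir`, and per-stage
#' sections `population`, `eeg`, `responses`, `detection`, `mediation`.
#' Any field supplied in the YAML overrides the default.
#'
#' @param seed global integer seed.
#' @param output_dir directory for all run artifacts.
#' @return nested configuration list.
#' @export
default_run_config <- function(seed = 1L, output_dir = "blinkdt-run") {
  list(
    seed = as.integer(seed),
    output_dir = output_dir,
    population = list(n_participants = 24),
    eeg = list(fs = 125, duration = 60,
               channel_labels = c("Fpz", "Fp1", "Fp2", "Fz"),
               noise_sd = 15, write_eeg = FALSE),
    responses = list(codebook = NULL),   # NULL -> built-in demo codebook
    detection = list(low = 1, high = 20, tent_r_min = 0.90, pavr_min = 3),
    mediation = list(n_boot = 1000, ci_level = 0.95,
                     x_to_m = "quadratic", direct_x_to_y = "quadratic"))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load a run configuration from a YAML file
#'
#' Fields present in the file override [default_run_config()] values.
#'
#' @param path YAML file path.
#' @return nested configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  merge_config(default_run_config(), yaml::read_yaml(path))
}

log_stage <- function(log_path, msg) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg)
  message(line)
  cat(line, "\n", file = log_path, append = TRUE)
}

#' Run the full simulate -> detect -> score -> analyze -> mediate pipeline
#'
#' Simulates a participant population with a known inverted-U structure,
#' synthesises one resting EEG segment per participant with the blink
#' count implied by that participant's blink rate, detects blinks to
#' recover sEBR, simulates and scores Alternative Uses Task responses,
#' then runs the correlation, hierarchical/robust regression and
#' curvilinear mediation analyses. Every intermediate table is written
#' under the output directory and hashed into a run manifest; re-running
#' with the same configuration reproduces identical artifacts.
#'
#' @param config nested list from [default_run_config()] /
#'   [read_run_config()], or a path to a YAML file.
#' @return the run manifest (invisibly also written as
#'   `manifest.json`): inputs, package version, per-stage seeds, and md5
#'   hashes of every output file.
#' @export
run_full_analysis <- function(config = default_run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  config <- merge_config(default_run_config(), config)
  # referenced input paths must exist before any stage runs
  cb_path <- config$responses$codebook
  if (is.character(cb_path) && !file.exists(cb_path)) {
    stop("codebook file not found: ", cb_path)
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)
  log_path <- out("run.log")
  cat("", file = log_path)

  # -- stage 1: population ------------------------------------------------
  log_stage(log_path, "simulating participant population")
  pop_args <- config$population
  pop_args$seed <- stage_seed(config$seed, "population")
  pop_cfg <- do.call(population_sim_config, pop_args)
  participants <- simulate_participants(pop_cfg)
  utils::write.csv(participants, out("participants_latent.csv"),
                   row.names = FALSE)

  # -- stage 2: EEG synthesis + blink detection ---------------------------
  log_stage(log_path, "synthesising EEG and detecting blinks")
  ecfg <- config$eeg
  det <- config$detection
  tent_s <- 0.3 + 0.05  # default tent width + minimal gap
  detected <- numeric(nrow(participants))
  for (i in seq_len(nrow(participants))) {
    sd_i <- stage_seed(config$seed, "eeg", i)
    n_blinks <- max(1L, round(participants$sebr[i] * ecfg$duration / 60))
    set.seed(sd_i)
    times <- spaced_event_times(n_blinks, ecfg$duration, tent_s)
    sim <- simulate_eeg(eeg_sim_config(
      channel_labels = ecfg$channel_labels, fs = ecfg$fs,
      duration = ecfg$duration, blink_times = times,
      noise_sd = ecfg$noise_sd, seed = sd_i))
    series <- detect_blinks(sim$recording, low = det$low, high = det$high,
                            tent_r_min = det$tent_r_min,
                            pavr_min = det$pavr_min)
    detected[i] <- series$rate
    pid <- participants$participant_id[i]
    if (isTRUE(ecfg$write_eeg)) {
      write_eeg_csv(sim$recording, out(sprintf("eeg_%s.csv", pid)))
    }
    write_blink_truth(sim$truth, out(sprintf("blinks_truth_%s.tsv", pid)))
    write_blink_series(series, out(sprintf("blinks_%s.csv", pid)))
  }
  participants$sebr_detected <- detected

  # -- stage 3: AUT responses + scoring -----------------------------------
  log_stage(log_path, "simulating and scoring AUT responses")
  codebook <- config$responses$codebook
  if (is.character(codebook)) codebook <- read_codebook(codebook)
  rcfg <- response_sim_config(
    n_objects = if (is.null(codebook)) 5 else length(codebook),
    category_codebook = codebook,
    seed = stage_seed(config$seed, "responses"))
  responses <- simulate_aut_responses(participants, rcfg)
  utils::write.csv(responses, out("responses.csv"), row.names = FALSE)
  scored <- score_aut(responses)
  scores <- merge(
    data.frame(participant_id = participants$participant_id,
               sebr = participants$sebr_detected),
    scored$participants, by = "participant_id")
  utils::write.csv(scores, out("scores.csv"), row.names = FALSE)

  # -- stage 4: correlations + regressions --------------------------------
  log_stage(log_path, "association analyses")
  cm <- correlation_matrix(scores)
  utils::write.csv(round(cm$r, 6), out("correlations.csv"))
  indices <- c("flexibility", "rb_originality", "fb_originality", "fluency")
  reg <- lapply(indices, function(idx) {
    ols <- hierarchical_quadratic_fit(scores$sebr, scores[[idx]])
    rob <- tryCatch(robust_quadratic_fit(scores$sebr, scores[[idx]]),
                    error = function(e) NULL)
    list(ols = unclass(ols),
         robust = if (is.null(rob)) NULL else unclass(rob))
  })
  names(reg) <- indices

  # -- stage 5: mediation -------------------------------------------------
  log_stage(log_path, "curvilinear mediation")
  mcfg <- config$mediation
  med <- bootstrap_mediation(
    as_mediation_data(scores),
    mediation_spec(x_to_m = mcfg$x_to_m,
                   direct_x_to_y = mcfg$direct_x_to_y,
                   n_boot = mcfg$n_boot, ci_level = mcfg$ci_level,
                   seed = stage_seed(config$seed, "mediation")))
  results <- list(
    icc = unclass(scored$icc),
    correlations = list(r = cm$r, p = cm$p),
    regressions = reg,
    mediation = list(
      paths = med$coefficients[c("a1", "a2", "b", "c1", "c2",
                                 "i_m", "i_y")],
      eval_points = med$eval_points, theta = med$theta,
      ci = med$ci, n_boot = med$n_boot, seed = med$seed))
  jsonlite::write_json(results, out("results.json"), auto_unbox = TRUE,
                       digits = 10, force = TRUE)

  # -- manifest -----------------------------------------------------------
  files <- setdiff(list.files(config$output_dir),
                   c("manifest.json", "run.log"))
  hashes <- tools::md5sum(file.path(config$output_dir, files))
  names(hashes) <- files
  manifest <- list(
    package = "blinkdt",
    version = as.character(utils::packageVersion("blinkdt")),
    seed = config$seed,
    stage_seeds = list(
      population = stage_seed(config$seed, "population"),
      responses = stage_seed(config$seed, "responses"),
      mediation = stage_seed(config$seed, "mediation")),
    config = config,
    outputs = as.list(hashes))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  log_stage(log_path, "done")
  invisible(manifest)
}
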