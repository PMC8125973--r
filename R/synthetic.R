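#' Configuration of the synthetic phasic-pain generator
#'
#' Defaults emulate the structure of a phasic experimental pain study:
#' 7-second stimulus-locked video samples; heat and electrical stimuli at
#' three calibrated intensities plus baseline; facial responses that start
#' about 3 s into the sample for heat (the plateau is reached at second 1
#' and facial activity follows roughly 2 s later) and about 1 s in, with a
#' steeper rise, for electrical stimulation; and a substantial fraction of
#' pain samples with no observable facial response at all ("non-response"
#' noise), which grows as stimulus intensity falls.
#'
#' @param duration_s sample duration in seconds (7).
#' @param fps camera frame rate (25; the source studies do not fix one).
#' @param response_prob_mean population mean probability of any facial
#'   response at intensities 1, 2, 3.
#' @param response_sd subject-level spread (logit scale) of response
#'   probability.
#' @param nonresponder_frac fraction of subjects with expressiveness 0.
#' @param expressiveness_shape,expressiveness_mean gamma parameters of
#'   subject expressiveness (mean 1 scales AU response amplitude).
#' @param baseline_level,baseline_noise_sd_mean resting AU intensity level
#'   and mean subject noise SD (OpenFace AU units, 0-5 scale).
#' @param noise_smooth_window moving-average window (frames) applied to the
#'   baseline noise before clipping at 0.
#' @param amp_per_intensity response amplitude added per stimulus intensity
#'   unit for a subject of expressiveness 1.
#' @param heat_onset_delay_s,elec_onset_delay_s facial response onset after
#'   stimulus start, per modality.
#' @param heat_peak_s,elec_peak_s time from response onset to peak (the
#'   electrical rise is faster).
#' @param elec_onset_per_intensity_s,elec_peak_per_intensity_s how much
#'   earlier and faster the electrical response gets per intensity step:
#'   stronger electrical stimuli shorten response latency and rise time,
#'   while heat timing stays locked to the thermal ramp regardless of
#'   intensity.
#' @param bump_shape shape of the gamma-like response curve.
#' @param heat_onset_jitter_sd,elec_onset_jitter_sd per-sample onset jitter
#'   (s); thermal response latency varies much more across trials than the
#'   near-immediate electrical response.
#' @param heat_amp_jitter_sd,elec_amp_jitter_sd per-sample log-normal
#'   amplitude jitter; thermal response magnitude is likewise the more
#'   variable one.
#' @param pain_aus AU names receiving the response bump.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(duration_s = 7, fps = 25,
                         response_prob_mean = c(0.45, 0.65, 0.80),
                         response_sd = 0.8,
                         nonresponder_frac = 0.08,
                         expressiveness_shape = 4,
                         expressiveness_mean = 1,
                         baseline_level = 0.15,
                         baseline_noise_sd_mean = 0.12,
                         noise_smooth_window = 9,
                         amp_per_intensity = 0.7,
                         heat_onset_delay_s = 3,
                         elec_onset_delay_s = 1,
                         heat_peak_s = 1.6,
                         elec_peak_s = 0.6,
                         elec_onset_per_intensity_s = 0.3,
                         elec_peak_per_intensity_s = 0.15,
                         bump_shape = 3,
                         heat_onset_jitter_sd = 1.0,
                         elec_onset_jitter_sd = 0.15,
                         heat_amp_jitter_sd = 0.5,
                         elec_amp_jitter_sd = 0.15,
                         pain_aus = pain_au_default()) {
  cfg <- as.list(environment())
  stopifnot(duration_s > 0, fps > 0,
            all(response_prob_mean >= 0 & response_prob_mean <= 1),
            !is.unsorted(response_prob_mean),
            nonresponder_frac >= 0, nonresponder_frac <= 1)
  structure(cfg, class = "synth_config")
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Generate synthetic subject profiles
#'
#' Each subject carries an expressiveness factor (gamma-distributed, mean 1;
#' a configurable fraction of subjects is fixed at 0, emulating people who
#' show no facial reaction even to strong stimuli), a probability of showing
#' any facial response at each stimulus intensity (monotone non-decreasing
#' in intensity, drawn on the logit scale around the configured means), and
#' a baseline noise level.
#'
#' @param n_subjects number of subjects (the emulated study has 127).
#' @param seed integer seed; profiles are a pure function of seed + config.
#' @param config a [synth_config()].
#' @param ... config overrides, e.g. `nonresponder_frac = 1`.
#' @return list of `subject_profile` objects with fields `subject_id`,
#'   `expressiveness`, `response_prob` (length 3), `baseline_noise_sd`.
#' @export
make_subjects <- function(n_subjects, seed = 1, config = synth_config(), ...) {
  if (!is.numeric(n_subjects) || n_subjects < 1)
    stop_arg("n_subjects must be a positive integer")
  config[names(list(...))] <- list(...)
  with_local_seed(seed, {
    expr <- rgamma(n_subjects, shape = config$expressiveness_shape,
                   scale = config$expressiveness_mean /
                     config$expressiveness_shape)
    nonresp <- runif(n_subjects) < config$nonresponder_frac
    expr[nonresp] <- 0
    z <- rnorm(n_subjects, 0, config$response_sd)
    noise_sd <- config$baseline_noise_sd_mean *
      rgamma(n_subjects, shape = 6, scale = 1 / 6)
    lapply(seq_len(n_subjects), function(i) {
      p <- stats::plogis(stats::qlogis(config$response_prob_mean) + z[i])
      structure(list(subject_id = i, expressiveness = expr[i],
                     response_prob = cummax(p),
                     baseline_noise_sd = noise_sd[i]),
                class = "subject_profile")
    })
  })
}

#' Describe one stimulus
#'
#' @param modality one of `"none"`, `"heat"`, `"electrical"`.
#' @param intensity integer 0-3; 0 if and only if modality is `"none"`.
#' @param onset_s stimulus onset within the sample (s).
#' @param duration_s stimulus plateau duration (s).
#' @return a `stimulus_spec` list.
#' @export
stimulus_spec <- function(modality = c("none", "heat", "electrical"),
                          intensity = 0, onset_s = 0, duration_s = 5) {
  modality <- match.arg(modality)
  if ((modality == "none") != (intensity == 0))
    stop_arg("intensity must be 0 exactly when modality is 'none'")
  if (intensity < 0 || intensity > 3) stop_arg("intensity must be in 0..3")
  if (onset_s < 0) stop_arg("onset_s must be non-negative")
  structure(list(modality = modality, intensity = as.integer(intensity),
                 onset_s = onset_s, duration_s = duration_s),
            class = "stimulus_spec")
}

stim_label <- function(stim) {
  switch(stim$modality, none = "B",
         heat = paste0("H", stim$intensity),
         electrical = paste0("E", stim$intensity))
}

# Gamma-like response curve: 0 before onset, rises to 1 at `peak` seconds
# after onset, then decays; shape controls steepness.
bump_curve <- function(t, onset, peak, shape) {
  u <- (t - onset) / peak
  out <- numeric(length(t))
  pos <- u > 0
  out[pos] <- u[pos]^shape * exp(shape * (1 - u[pos]))
  out
}

#' Generate one synthetic 7-second AU sample
#'
#' The 17 AU intensity series are baseline noise (smoothed Gaussian noise
#' clipped at 0 around a resting level) plus, with probability
#' `response_prob[intensity]`, a smooth gamma-like response bump on the
#' pain-related AU rows whose amplitude is proportional to
#' `intensity * expressiveness`. Electrical responses start earlier and rise
#' more steeply than heat responses. For `modality = "none"` no bump is ever
#' added and the label is `B`.
#'
#' @param profile a `subject_profile` from [make_subjects()].
#' @param stim a [stimulus_spec()].
#' @param seed integer seed; the sample is a pure function of its arguments.
#' @param fps frames per second (default from config).
#' @param config a [synth_config()].
#' @return an `au_sample`: list with `sample_id` (NA until placed in a
#'   dataset), `subject_id`, `label`, `fps`, `series` (17 x T matrix, T =
#'   `duration_s * fps`), `bump_amp` (0 when no facial response occurred)
#'   and `stim`.
#' @export
generate_sample <- function(profile, stim, seed = 1, fps = NULL,
                            config = synth_config()) {
  fps <- fps %||% config$fps
  if (!is.numeric(fps) || fps <= 0) stop_arg("fps must be positive")
  if (!inherits(profile, "subject_profile")) stop_arg("invalid profile")
  if (!inherits(stim, "stimulus_spec")) stop_arg("invalid stimulus")
  n_au <- length(au_names())
  t_frames <- as.integer(round(config$duration_s * fps))
  tt <- (seq_len(t_frames) - 0.5) / fps
  with_local_seed(seed, {
    level <- runif(n_au, 0.4, 1.2) * config$baseline_level
    noise <- matrix(rnorm(n_au * t_frames, 0, profile$baseline_noise_sd),
                    n_au, t_frames)
    series <- t(apply(noise, 1, smooth_series,
                      window = config$noise_smooth_window)) + level
    bump_amp <- 0
    if (stim$modality != "none") {
      responds <- runif(1) < profile$response_prob[stim$intensity]
      if (responds && profile$expressiveness > 0) {
        jitter_sd <- if (stim$modality == "heat")
          config$heat_onset_jitter_sd else config$elec_onset_jitter_sd
        delay <- if (stim$modality == "heat") config$heat_onset_delay_s
          else max(0.1, config$elec_onset_delay_s -
                     (stim$intensity - 1) * config$elec_onset_per_intensity_s)
        onset <- stim$onset_s + delay + jitter_sd * rnorm(1)
        peak <- if (stim$modality == "heat") config$heat_peak_s
          else max(0.2, config$elec_peak_s -
                     (stim$intensity - 2) * config$elec_peak_per_intensity_s)
        amp_sd <- if (stim$modality == "heat") config$heat_amp_jitter_sd
          else config$elec_amp_jitter_sd
        bump_amp <- stim$intensity * profile$expressiveness *
          config$amp_per_intensity * exp(rnorm(1, 0, amp_sd))
        curve <- bump_curve(tt, onset, peak, config$bump_shape)
        rows <- match(config$pain_aus, au_names())
        w <- runif(length(rows), 0.6, 1)
        series[rows, ] <- series[rows, ] +
          bump_amp * (w %o% curve)
      }
    }
    series <- pmax(series, 0)
    rownames(series) <- au_names()
    structure(list(sample_id = NA_character_,
                   subject_id = profile$subject_id,
                   label = stim_label(stim), fps = fps, series = series,
                   bump_amp = bump_amp, stim = stim,
                   frames_dir = NULL),
              class = "au_sample")
  })
}

#' @export
print.au_sample <- function(x, ...) {
  cat(sprintf("au_sample: subject %d, class %s, %d AUs x %d frames @ %g fps\n",
              x$subject_id, x$label, nrow(x$series), ncol(x$series), x$fps))
  invisible(x)
}

# --- schematic face renderer ------------------------------------------------

# Paints soft-edged primitives on a normalised [0,1]^2 grid. Darkness adds.
face_canvas <- function(size) {
  ax <- (seq_len(size) - 0.5) / size
  list(x = matrix(ax, size, size, byrow = TRUE),  # column -> x
       y = matrix(ax, size, size))                # row    -> y
}

paint_ellipse <- function(cv, cx, cy, rx, ry, darkness, soft = 0.15) {
  d <- sqrt(((cv$x - cx) / rx)^2 + ((cv$y - cy) / ry)^2)
  darkness * pmin(pmax((1 + soft - d) / soft, 0), 1)
}

paint_segment <- function(cv, x0, y0, x1, y1, width, darkness) {
  vx <- x1 - x0; vy <- y1 - y0
  len2 <- vx^2 + vy^2
  t <- pmin(pmax(((cv$x - x0) * vx + (cv$y - y0) * vy) / len2, 0), 1)
  d <- sqrt((cv$x - (x0 + t * vx))^2 + (cv$y - (y0 + t * vy))^2)
  darkness * pmin(pmax((width - d) / (0.4 * width), 0), 1)
}

render_face <- function(au, size) {
  a <- pmin(pmax(au, 0), 5) / 5  # normalised AU activations
  cv <- face_canvas(size)
  dark <- matrix(0, size, size)
  # head outline
  dark <- dark + paint_ellipse(cv, 0.5, 0.5, 0.38, 0.46, 0.25) -
    paint_ellipse(cv, 0.5, 0.5, 0.34, 0.42, 0.22)
  raise <- (a["AU01"] + a["AU02"]) / 2
  lower <- a["AU04"]
  brow_y <- 0.33 - 0.05 * raise + 0.06 * lower
  brow_in <- 0.40 + 0.05 * lower   # AU4 draws brows together
  for (s in c(-1, 1)) {
    xo <- 0.5 + s * (brow_in - 0.40 + 0.26)
    xi <- 0.5 + s * (0.43 - brow_in + 0.07)
    dark <- dark + paint_segment(cv, xi, brow_y + 0.02 * lower, xo,
                                 brow_y - 0.02 * raise,
                                 0.015 + 0.01 * lower, 0.9)
  }
  aperture <- 0.030 * (1 + 0.6 * a["AU05"]) *
    (1 - 0.95 * a["AU45"]) * (1 - 0.4 * a["AU07"])
  for (s in c(-1, 1)) {
    ex <- 0.5 + s * 0.15
    dark <- dark + paint_ellipse(cv, ex, 0.44, 0.065, pmax(aperture, 0.004),
                                 0.85)
    # cheek raiser: crescent under the eye
    dark <- dark + paint_segment(cv, ex - 0.05, 0.52 - 0.02 * a["AU06"],
                                 ex + 0.05, 0.52 - 0.02 * a["AU06"],
                                 0.012, 0.5 * a["AU06"])
  }
  # nose wrinkler
  dark <- dark + paint_segment(cv, 0.44, 0.54, 0.56, 0.54, 0.012,
                               0.7 * a["AU09"])
  # nasolabial furrows (upper-lip raiser / smile)
  nl <- 0.3 + 0.6 * pmax(a["AU10"], a["AU12"])
  for (s in c(-1, 1))
    dark <- dark + paint_segment(cv, 0.5 + s * 0.08, 0.60,
                                 0.5 + s * 0.16, 0.70, 0.010,
                                 0.6 * (nl - 0.3))
  # mouth
  open_h <- 0.012 + 0.07 * (a["AU25"] + a["AU26"]) / 2
  width <- 0.11 * (1 + 0.35 * a["AU12"] + 0.35 * a["AU20"] -
                     0.3 * a["AU23"])
  dark <- dark + paint_ellipse(cv, 0.5, 0.74, pmax(width, 0.02), open_h, 0.9)
  pmin(pmax(1 - dark, 0), 1)  # bright face, dark features
}

#' Render the schematic face frame(s) of a sample
#'
#' The renderer is a deterministic parametric stand-in for real face video:
#' brow height and gathering, eye aperture, nasolabial lines, nose wrinkling
#' and mouth opening are deformed per frame by the sample's AU values. It is
#' schematic, not photorealistic — sufficient for testing that the image
#' branch of the pipeline can extract class signal.
#'
#' @param sample an `au_sample`.
#' @param size image side in pixels (>= 32).
#' @return `render_frames()`: list of `size x size` grayscale matrices in
#'   `[0, 1]`, one per frame; `render_frame()`: a single frame.
#' @export
render_frames <- function(sample, size = 96) {
  if (size < 32) stop_arg("size must be >= 32 pixels")
  lapply(seq_len(ncol(sample$series)), function(i)
    render_face(sample$series[, i], size))
}

#' @rdname render_frames
#' @param frame_index 1-based frame number.
#' @export
render_frame <- function(sample, frame_index, size = 96) {
  if (size < 32) stop_arg("size must be >= 32 pixels")
  if (frame_index < 1 || frame_index > ncol(sample$series))
    stop_arg("frame_index out of range")
  render_face(sample$series[, frame_index], size)
}

#' Generate a full synthetic dataset
#'
#' Per subject, `reps_per_class` samples of each of the 7 classes (baseline,
#' H1-H3, E1-E3), exactly balanced, with a manifest recording sample id,
#' subject and class. The emulated study has 127 subjects and around 30
#' repetitions per stimulus type.
#'
#' @param n_subjects number of subjects.
#' @param reps_per_class samples per class per subject.
#' @param seed master seed; the dataset is a pure function of seed + config.
#' @param fps frames per second.
#' @param config a [synth_config()].
#' @param ... config overrides passed to [make_subjects()] and used for
#'   sample generation.
#' @return a `pain_dataset`: list with `samples` (list of `au_sample`),
#'   `manifest` (data.frame: sample_id, subject_id, class, au_csv,
#'   frames_dir) and `subjects`.
#' @export
generate_dataset <- function(n_subjects = 10, reps_per_class = 2, seed = 1,
                             fps = NULL, config = synth_config(), ...) {
  if (reps_per_class < 1) stop_arg("reps_per_class must be >= 1")
  config[names(list(...))] <- list(...)
  fps <- fps %||% config$fps
  subjects <- make_subjects(n_subjects, seed = seed, config = config)
  combos <- expand.grid(rep = seq_len(reps_per_class),
                        class = class_codes(),
                        subject = seq_len(n_subjects),
                        stringsAsFactors = FALSE)
  seeds <- with_local_seed(seed + 1L,
                           sample.int(.Machine$integer.max - 1L, nrow(combos)))
  samples <- lapply(seq_len(nrow(combos)), function(i) {
    cls <- combos$class[i]
    stim <- if (cls == "B") stimulus_spec("none", 0) else
      stimulus_spec(if (substr(cls, 1, 1) == "H") "heat" else "electrical",
                    as.integer(substr(cls, 2, 2)))
    s <- generate_sample(subjects[[combos$subject[i]]], stim,
                         seed = seeds[i], fps = fps, config = config)
    s$sample_id <- sprintf("S%03d_%s_%02d", combos$subject[i], cls,
                           combos$rep[i])
    s
  })
  manifest <- data.frame(
    sample_id = vapply(samples, `[[`, "", "sample_id"),
    subject_id = combos$subject,
    class = combos$class,
    au_csv = NA_character_, frames_dir = NA_character_,
    stringsAsFactors = FALSE)
  structure(list(samples = samples, manifest = manifest,
                 subjects = subjects, config = config),
            class = "pain_dataset")
}

#' @export
print.pain_dataset <- function(x, ...) {
  cat(sprintf("pain_dataset: %d samples, %d subjects, classes: %s\n",
              nrow(x$manifest), length(unique(x$manifest$subject_id)),
              paste(names(table(x$manifest$class)), collapse = " ")))
  invisible(x)
}
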