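# Synthetic multi-subject EEG cohort with class-conditional band-power
# structure, class-conditional cross-electrode shared components, and
# per-subject gain/offset domain shift. Emulates the shape of a 62-channel,
# 200 Hz, 15-subject emotion study; it makes no attempt at physiological
# realism (no 1/f background, blinks or evoked responses).

#' Scalp region of each electrode
#'
#' Front-to-back thirds of the grid: rows 0-2 frontal, 3-5 central,
#' 6-8 posterior. Class effects are specified per (band, region) cell.
#'
#' @param layout an [electrode_layout()].
#' @return integer vector in 1..3 (frontal, central, posterior).
#' @export
electrode_regions <- function(layout = electrode_layout()) {
  cut(layout$grid[, "row"], breaks = c(-1, 2, 5, 9), labels = FALSE)
}

default_class_effect <- function(n_classes) {
  # multipliers[class, band, region]; band order delta..gamma,
  # regions frontal/central/posterior
  eff <- array(1, c(n_classes, 5, 3))
  boost <- 1.8
  if (n_classes >= 1) eff[1, 3, 3] <- boost   # class 0: alpha, posterior
  if (n_classes >= 2) eff[2, 4, 1] <- boost   # class 1: beta, frontal
  if (n_classes >= 3) eff[3, 5, 2] <- boost   # class 2: gamma, central
  if (n_classes >= 4) eff[4, 2, 3] <- boost   # class 3: theta, posterior
  eff
}

default_topology_effect <- function(n_classes) {
  pairs <- list(
    list(pairs = rbind(c("F3", "P3"), c("F4", "P4"), c("F5", "P5"), c("F6", "P6"))),
    list(pairs = rbind(c("FC3", "CP3"), c("FC4", "CP4"), c("FC5", "CP5"), c("FC6", "CP6"))),
    list(pairs = rbind(c("C3", "O1"), c("C4", "O2"), c("C5", "PO5"), c("C6", "PO6"))),
    list(pairs = rbind(c("F7", "T7"), c("F8", "T8"), c("FT7", "TP7"), c("FT8", "TP8")))
  )
  lapply(seq_len(n_classes), function(k) {
    p <- pairs[[(k - 1L) %% length(pairs) + 1L]]
    p$band <- 3L          # shared component lives in the alpha band
    p$amplitude <- 0.9
    p
  })
}

#' Cohort specification
#'
#' @param n_subjects number of subjects (default 15).
#' @param n_classes 3 or 4 emotion classes.
#' @param trials_per_class trials per subject and class (default 5).
#' @param fs sampling rate, Hz (default 200).
#' @param trial_seconds trial length (default 60 s, i.e. 15 four-second
#'   windows per trial).
#' @param class_effect `[class, band, region]` array of band-amplitude
#'   multipliers; the default gives each class one boosted (band, region)
#'   cell (amplitude-detectable signal).
#' @param topology_effect per-class list of electrode pairs receiving a
#'   shared band-limited component (correlation-detectable signal); each
#'   element has `pairs` (2-column name matrix), `band`, `amplitude`. NULL
#'   disables.
#' @param gain_sd log-normal sd of the per-subject per-channel gain (domain
#'   shift); 0 disables.
#' @param offset_sd sd of the per-subject per-channel DC offset, microvolts.
#' @param noise_sd sd of additive broadband sensor noise.
#' @param seed integer; together with the spec it fully determines the
#'   cohort.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 15L, n_classes = 3L, trials_per_class = 5L,
                        fs = 200, trial_seconds = 60,
                        class_effect = default_class_effect(n_classes),
                        topology_effect = default_topology_effect(n_classes),
                        gain_sd = 0.4, offset_sd = 1, noise_sd = 0.3,
                        seed = 1L) {
  if (!n_classes %in% c(2L, 3L, 4L)) abort("n_classes must be 2, 3 or 4", "invalid_config")
  if (any(class_effect <= 0)) abort("class-effect multipliers must be positive", "invalid_config")
  if (fs * trial_seconds < 4 * fs) abort("trial must cover at least one 4-s window", "invalid_config")
  structure(list(n_subjects = as.integer(n_subjects), n_classes = as.integer(n_classes),
                 trials_per_class = as.integer(trials_per_class), fs = fs,
                 trial_seconds = trial_seconds, class_effect = class_effect,
                 topology_effect = topology_effect, gain_sd = gain_sd,
                 offset_sd = offset_sd, noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Unit-variance noise whose spectrum is confined to [lo, hi) Hz, via FFT
# masking of white noise (exact band separation, no filter transients).
band_noise <- function(n, fs, lo, hi) {
  f <- stats::fft(stats::rnorm(n))
  freq <- (0:(n - 1)) * fs / n
  keep <- (freq >= lo & freq < hi) | (freq > fs - hi & freq <= fs - lo)
  f[!keep] <- 0
  x <- Re(stats::fft(f, inverse = TRUE)) / n
  x / stats::sd(x)
}

subject_shift_draw <- function(spec, subject) {
  with_stream(rng_stream(derive_seed(spec$seed, "subject", subject)), {
    list(gain = exp(stats::rnorm(62, 0, spec$gain_sd)),
         offset = stats::rnorm(62, 0, spec$offset_sd))
  })
}

#' Generate one synthetic trial
#'
#' Each channel is a sum over the five bands of band-limited Gaussian noise
#' with amplitude `class_effect[class, band, region(channel)]`, plus shared
#' band-limited components on the class's electrode pairs, plus broadband
#' noise; the whole channel is then scaled by the subject's gain and offset.
#' A band-amplitude multiplier `a` shifts that band's differential entropy by
#' `ln a`; the subject gain shifts all bands of a channel by `ln gain`.
#'
#' @param spec a [cohort_spec()].
#' @param subject subject index (1-based).
#' @param class class label, 0-based.
#' @param trial trial index within (subject, class), used only to derive the
#'   random stream.
#' @param layout an [electrode_layout()].
#' @return a [raw_recording()] with subject/trial metadata and label set.
#' @export
generate_trial <- function(spec, subject, class, trial = 1L,
                           layout = electrode_layout()) {
  n <- as.integer(round(spec$fs * spec$trial_seconds))
  regions <- electrode_regions(layout)
  bands <- band_scheme()$bands
  shift <- subject_shift_draw(spec, subject)
  stream <- rng_stream(derive_seed(spec$seed, "trial", subject, class, trial))
  samples <- with_stream(stream, {
    x <- matrix(0, 62, n)
    for (b in seq_len(5)) {
      amp <- spec$class_effect[class + 1L, b, ][regions]
      for (e in seq_len(62)) {
        x[e, ] <- x[e, ] + amp[e] * band_noise(n, spec$fs, bands$low_hz[b], bands$high_hz[b])
      }
    }
    te <- spec$topology_effect
    if (!is.null(te)) {
      eff <- te[[class + 1L]]
      for (p in seq_len(nrow(eff$pairs))) {
        comp <- eff$amplitude * band_noise(n, spec$fs, bands$low_hz[eff$band],
                                           bands$high_hz[eff$band])
        ij <- match(eff$pairs[p, ], layout$names)
        x[ij[1], ] <- x[ij[1], ] + comp
        x[ij[2], ] <- x[ij[2], ] + comp
      }
    }
    if (spec$noise_sd > 0) x <- x + spec$noise_sd * matrix(stats::rnorm(62 * n), 62)
    x * shift$gain + shift$offset
  })
  raw_recording(samples, fs = spec$fs, channel_names = layout$names,
                subject_id = sprintf("S%02d", subject),
                trial_id = sprintf("S%02d_c%d_t%02d", subject, class, trial),
                label = class)
}

#' Generate a full cohort
#'
#' Full factorial subjects x classes x trials; the per-subject shift is
#' drawn once per subject and recorded in the ground truth.
#'
#' @param spec a [cohort_spec()].
#' @param layout an [electrode_layout()].
#' @return list with `trials` (list of [raw_recording()]), `truth`
#'   (data.frame of subject, class, trial per recording) and `shifts`
#'   (per-subject gain/offset actually drawn).
#' @export
generate_cohort <- function(spec, layout = electrode_layout()) {
  grid <- expand.grid(trial = seq_len(spec$trials_per_class),
                      class = 0:(spec$n_classes - 1L),
                      subject = seq_len(spec$n_subjects))
  trials <- lapply(seq_len(nrow(grid)), function(i) {
    generate_trial(spec, grid$subject[i], grid$class[i], grid$trial[i], layout)
  })
  truth <- data.frame(subject = grid$subject, class = grid$class, trial = grid$trial,
                      trial_id = vapply(trials, function(t) t$trial_id, character(1)))
  shifts <- lapply(seq_len(spec$n_subjects), function(s) subject_shift_draw(spec, s))
  list(trials = trials, truth = truth, shifts = shifts, spec = spec)
}

#' Featurise a cohort for model input
#'
#' Computes per-window differential-entropy matrices for every trial and
#' assembles the tensors the two branches consume.
#'
#' @param cohort result of [generate_cohort()].
#' @param scheme a [band_scheme()].
#' @param layout an [electrode_layout()].
#' @param window_seconds window length.
#' @return a `cohort_dataset`: list with `features` `(62, 5, N)`, `labels`
#'   (0-based), `subject` (integer), `window` (index within trial).
#' @export
cohort_features <- function(cohort, scheme = band_scheme(),
                            layout = electrode_layout(), window_seconds = 4) {
  per_trial <- lapply(seq_along(cohort$trials), function(i) {
    de <- compute_de_features(cohort$trials[[i]], scheme, layout, window_seconds)
    list(values = vapply(de, function(d) d$values, matrix(0, 62, 5)),
         n = length(de), subject = cohort$truth$subject[i],
         class = cohort$truth$class[i])
  })
  feats <- array(unlist(lapply(per_trial, function(p) p$values)), c(62, 5, sum(vapply(per_trial, function(p) p$n, 0L))))
  structure(list(
    features = feats,
    labels = unlist(lapply(per_trial, function(p) rep(p$class, p$n))),
    subject = unlist(lapply(per_trial, function(p) rep(p$subject, p$n))),
    window = unlist(lapply(per_trial, function(p) seq_len(p$n)))
  ), class = "cohort_dataset")
}

#' Per-feature normalisation statistics
#'
#' Z-scores each of the 62 x 5 entries using statistics of (typically) the
#' training split; stats are stored with checkpoints so evaluation uses the
#' same transform.
#'
#' @param features `(62, 5, N)` array.
#' @return list with `mean` and `sd` (62 x 5 matrices).
#' @export
fit_normalizer <- function(features) {
  n <- dim(features)[3]
  mu <- apply(features, c(1, 2), mean)
  sd_ <- apply(features, c(1, 2), stats::sd)
  sd_[sd_ < 1e-8] <- 1
  list(mean = mu, sd = sd_, n = n)
}

#' @rdname fit_normalizer
#' @param norm a normaliser from `fit_normalizer`.
#' @export
apply_normalizer <- function(features, norm) {
  sweep(sweep(features, c(1, 2), norm$mean, "-"), c(1, 2), norm$sd, "/")
}

# Assemble normalised model inputs (maps + node features) for a window
# subset of a cohort_dataset.
dataset_inputs <- function(ds, idx, norm, layout = electrode_layout(),
                           keep_labels = TRUE) {
  f <- apply_normalizer(ds$features[, , idx, drop = FALSE], norm)
  n <- length(idx)
  maps <- array(0, c(layout$H, layout$W, 5, n))
  rc <- cbind(layout$grid[, "row"] + 1L, layout$grid[, "col"] + 1L)
  for (i in seq_len(n)) {
    for (b in 1:5) {
      plane <- matrix(0, layout$H, layout$W)
      plane[rc] <- f[, b, i]
      maps[, , b, i] <- plane
    }
  }
  list(maps = maps, nodes = f,
       labels = if (keep_labels) ds$labels[idx] else rep(NA_integer_, n))
}
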