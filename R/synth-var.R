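# Synthetic VAR network models with planted sink/source SOZ coupling.

#' Cohort generator configuration
#'
#' Bundles every knob of the synthetic iEEG cohort generator. The defaults
#' describe the study conditions the analysis assumes: roughly 13% of contacts
#' inside the SOZ (with the large between-patient spread seen clinically),
#' 120-s interictal recordings, ictal recordings of variable length, 60-Hz
#' mains contamination and occasional bad channels. Directed coupling is
#' net-inward to the SOZ in interictal mode (sink) and net-outward in ictal
#' mode (source).
#'
#' @param n_patients number of synthetic patients.
#' @param channels_range integer range (min, max) of implanted contacts per
#'   patient.
#' @param soz_fraction_mean,soz_fraction_sd mean and s.d. of the per-patient
#'   proportion of SOZ contacts.
#' @param var_order VAR lag count p of the generative model.
#' @param base_density probability of a baseline directed edge between any
#'   ordered channel pair.
#' @param base_gain magnitude of baseline coupling coefficients (random sign).
#' @param sink_gain added non-SOZ to SOZ coupling magnitude (interictal mode).
#' @param source_gain added SOZ to non-SOZ coupling magnitude (ictal mode).
#' @param planted_prob probability that an eligible directed pair receives a
#'   planted edge (kept below 1 so SOZ contacts vary in strength).
#' @param fs_native simulated native sampling rate in Hz.
#' @param interictal_duration_s interictal recording length, seconds (>= 120
#'   so the early/mid/late epoch scheme applies).
#' @param ictal_duration_range_s range (min, max) of ictal durations, seconds.
#' @param ictal_recordings_range range (min, max) of ictal recordings drawn
#'   per patient.
#' @param line_noise_amp amplitude of the injected 60-Hz sinusoid.
#' @param bad_channel_prob probability a (non-SOZ) channel is flagged bad.
#' @param gain_factor_range range of the per-patient multiplicative gain
#'   factor applied to `sink_gain` and `source_gain`; makes planted effect
#'   sizes vary across patients.
#' @param gain_coupling `"shared"` draws one factor per patient applied to
#'   both periods (patients with strong interictal sinking also source
#'   strongly ictally, producing correlated interictal/ictal effect sizes);
#'   `"independent"` draws separate factors per period.
#' @param seed integer seed; the whole cohort is deterministic given it.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 20L,
                          channels_range = c(20L, 36L),
                          soz_fraction_mean = 0.13,
                          soz_fraction_sd = 0.11,
                          var_order = 2L,
                          base_density = 0.10,
                          base_gain = 0.10,
                          sink_gain = 0.6,
                          source_gain = 0.6,
                          planted_prob = 0.8,
                          fs_native = 512,
                          interictal_duration_s = 120,
                          ictal_duration_range_s = c(20, 180),
                          ictal_recordings_range = c(1L, 5L),
                          line_noise_amp = 1,
                          bad_channel_prob = 0.05,
                          gain_factor_range = c(0.5, 1.5),
                          gain_coupling = c("shared", "independent"),
                          seed = 1L) {
  gain_coupling <- match.arg(gain_coupling)
  if (soz_fraction_mean <= 0 || soz_fraction_mean >= 1)
    stop("config-invalid: soz_fraction_mean must lie in (0, 1)")
  if (interictal_duration_s < 120)
    stop("config-invalid: interictal_duration_s must be >= 120")
  if (channels_range[1] < 4)
    stop("config-invalid: need at least 4 channels")
  cfg <- list(n_patients = as.integer(n_patients),
              channels_range = as.integer(channels_range),
              soz_fraction_mean = soz_fraction_mean,
              soz_fraction_sd = soz_fraction_sd,
              var_order = as.integer(var_order),
              base_density = base_density,
              base_gain = base_gain,
              sink_gain = sink_gain,
              source_gain = source_gain,
              planted_prob = planted_prob,
              fs_native = fs_native,
              interictal_duration_s = interictal_duration_s,
              ictal_duration_range_s = ictal_duration_range_s,
              ictal_recordings_range = as.integer(ictal_recordings_range),
              line_noise_amp = line_noise_amp,
              bad_channel_prob = bad_channel_prob,
              gain_factor_range = gain_factor_range,
              gain_coupling = gain_coupling,
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  cfg
}

#' Build a stable VAR network model with planted SOZ coupling
#'
#' Baseline directed edges appear independently with probability
#' `config$base_density` and magnitude `config$base_gain` (random sign, random
#' lag). On top of that, every eligible directed pair receives a planted edge
#' with probability `config$planted_prob`: non-SOZ source into SOZ destination
#' (`sink_gain`) in interictal mode, SOZ source into non-SOZ destination
#' (`source_gain`) in ictal mode. Self-lags are 0.4 at lag 1 so each channel
#' has autocorrelated dynamics. All lag matrices are jointly rescaled until
#' the companion spectral radius is at most 0.95.
#'
#' @param n_channels number of channels (>= 4).
#' @param soz_mask logical vector, TRUE for SOZ channels (>= 2 of each class).
#' @param mode `"interictal"` (sink planting) or `"ictal"` (source planting).
#' @param config a [cohort_config()].
#' @param seed integer seed; output is deterministic given it.
#' @return list with `model` (class `var_model`: `coefficients` list of lag
#'   matrices with destination rows / source columns, `noise_cov`, `fs`,
#'   `mode`) and `truth` (class `ground_truth`: `soz_mask`, `planted_edges`
#'   data frame, gains).
#' @export
make_var_model <- function(n_channels, soz_mask, mode = c("interictal", "ictal"),
                           config = cohort_config(), seed = 1L) {
  mode <- match.arg(mode)
  n <- as.integer(n_channels)
  if (n < 4L) stop("bad-mask: need n_channels >= 4")
  soz_mask <- as.logical(soz_mask)
  if (length(soz_mask) != n || sum(soz_mask) < 2L || sum(!soz_mask) < 2L)
    stop("bad-mask: soz_mask needs >= 2 SOZ and >= 2 non-SOZ channels")
  p <- config$var_order

  with_seed(seed, {
    A <- replicate(p, matrix(0, n, n), simplify = FALSE)
    A[[1]] <- A[[1]] + diag(0.4, n)
    # baseline edges
    for (s in seq_len(n)) for (d in seq_len(n)) {
      if (s == d) next
      if (stats::runif(1) < config$base_density) {
        lag <- sample.int(p, 1L)
        A[[lag]][d, s] <- A[[lag]][d, s] +
          sample(c(-1, 1), 1L) * config$base_gain
      }
    }
    # planted directional edges
    gain <- if (mode == "interictal") config$sink_gain else config$source_gain
    src_pool <- if (mode == "interictal") which(!soz_mask) else which(soz_mask)
    dst_pool <- if (mode == "interictal") which(soz_mask) else which(!soz_mask)
    planted <- list()
    for (s in src_pool) for (d in dst_pool) {
      if (stats::runif(1) < config$planted_prob && gain != 0) {
        A[[1]][d, s] <- A[[1]][d, s] + gain
        planted[[length(planted) + 1L]] <- data.frame(
          source = s, destination = d, mode = mode, gain = gain)
      }
    }
    planted <- if (length(planted)) do.call(rbind, planted) else
      data.frame(source = integer(), destination = integer(),
                 mode = character(), gain = numeric())

    # joint rescaling to strict stability
    for (it in seq_len(50L)) {
      r <- companion_radius(A)
      if (r <= 0.95) break
      sc <- min(0.95 / r, 0.9)
      A <- lapply(A, function(m) m * sc)
      if (it == 50L && companion_radius(A) > 0.95)
        stop("unstable-model: rescaling failed after 50 iterations")
    }

    model <- structure(list(coefficients = A, noise_cov = diag(n), p = p,
                            fs = config$fs_native, mode = mode, n = n),
                       class = "var_model")
    truth <- structure(list(soz_mask = soz_mask, planted_edges = planted,
                            sink_gain = config$sink_gain,
                            source_gain = config$source_gain),
                       class = "ground_truth")
    list(model = model, truth = truth)
  })
}

#' @export
print.var_model <- function(x, ...) {
  cat(sprintf("VAR(%d) network model: %d channels, fs = %g Hz, mode = %s\n",
              x$p, x$n, x$fs, x$mode))
  cat(sprintf("  companion spectral radius = %.3f\n",
              companion_radius(x$coefficients)))
  invisible(x)
}

#' Simulate a multichannel recording from a VAR model
#'
#' Iterates the VAR recursion on Gaussian innovations (burn-in of 2000 samples
#' discarded), then adds a 60-Hz sinusoid with a random phase per channel and
#' white measurement noise at 5% of the innovation scale.
#'
#' @param model a `var_model` from [make_var_model()].
#' @param duration_s recording length in seconds.
#' @param line_noise_amp amplitude of the 60-Hz line-noise sinusoid.
#' @param seed integer seed.
#' @param patient_id identifier stored in the output.
#' @return an `ieeg_recording` (see [read_recording()] for the fields).
#' @export
simulate_recording <- function(model, duration_s, line_noise_amp = 0,
                               seed = 1L, patient_id = "sim") {
  n <- model$n; p <- model$p; fs <- model$fs
  n_samp <- as.integer(round(duration_s * fs))
  if (n_samp < 10L * p) stop("too-short: need duration_s * fs >= 10 * p")
  burn <- 2000L
  total <- n_samp + burn

  cs <- chol(model$noise_cov)
  A <- model$coefficients
  x <- with_seed(seed, {
    e <- matrix(stats::rnorm(total * n), n, total)
    e <- crossprod(cs, e)              # innovations with covariance Sigma
    x <- matrix(0, n, total)
    x[, 1:p] <- e[, 1:p]
    for (t in (p + 1L):total) {
      acc <- e[, t]
      for (k in seq_len(p)) acc <- acc + A[[k]] %*% x[, t - k]
      x[, t] <- acc
    }
    x <- x[, (burn + 1L):total, drop = FALSE]
    if (!all(is.finite(x))) stop("diverged: non-finite samples generated")
    if (line_noise_amp != 0) {
      tt <- (seq_len(n_samp) - 1) / fs
      ph <- stats::runif(n, 0, 2 * pi)
      for (ch in seq_len(n))
        x[ch, ] <- x[ch, ] + line_noise_amp * sin(2 * pi * 60 * tt + ph[ch])
    }
    x + 0.05 * matrix(stats::rnorm(n * n_samp), n, n_samp)
  })

  new_recording(samples = x, fs = fs,
                channel_names = sprintf("ch%02d", seq_len(n)),
                soz_mask = rep(FALSE, n), status = rep("good", n),
                coords = NULL, period = model$mode, patient_id = patient_id,
                duration_s = n_samp / fs)
}
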