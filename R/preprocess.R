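# Preprocessing: resample to 256 Hz, 60-Hz notch, bad-channel exclusion,
# SOZ-preserving channel subsampling, early/mid/late 2-s epoch extraction.

#' Standardise a recording to the analysis format
#'
#' Removes bad channels, resamples to exactly 256 Hz (polyphase rational
#' resampling) and applies a zero-phase band-stop notch over 58-62 Hz to
#' suppress mains noise. The notch is realised in the frequency domain with
#' sharp band edges, which makes it exactly zero-phase (no lag distortion
#' that would bias directed measures) and exactly idempotent. Channel masks
#' are re-indexed to the retained channels.
#'
#' @param rec an `ieeg_recording` with `fs >= 256`.
#' @return an `ieeg_recording` at 256 Hz with only good channels.
#' @export
standardise_recording <- function(rec) {
  if (rec$fs < 256) stop("unsupported-rate: fs must be >= 256 Hz")
  keep <- rec$status != "bad"
  if (!any(keep)) stop("no-usable-channels: all channels are flagged bad")
  x <- rec$samples[keep, , drop = FALSE]

  if (rec$fs != 256) {
    g <- gcd_int(256L, as.integer(round(rec$fs)))
    p <- 256L %/% g
    q <- as.integer(round(rec$fs)) %/% g
    n_in <- (ncol(x) %/% q) * q          # trim to a whole number of blocks
    n_out <- n_in %/% q * p
    y <- matrix(0, nrow(x), n_out)
    for (ch in seq_len(nrow(x)))
      y[ch, ] <- signal::resample(x[ch, seq_len(n_in)], p, q)[seq_len(n_out)]
    x <- y
  }

  x <- notch_fft(x, fs = 256, band = c(58, 62))
  if (!all(is.finite(x))) stop("diverged: non-finite samples after filtering")

  new_recording(samples = x, fs = 256,
                channel_names = rec$channel_names[keep],
                soz_mask = rec$soz_mask[keep],
                status = rep("good", sum(keep)),
                coords = if (is.null(rec$coords)) NULL else
                  rec$coords[keep, , drop = FALSE],
                period = rec$period, patient_id = rec$patient_id,
                duration_s = ncol(x) / 256)
}

#' @noRd
gcd_int <- function(a, b) if (b == 0L) a else gcd_int(b, a %% b)

#' Zero-phase frequency-domain band-stop filter
#'
#' Zeroes the Fourier coefficients inside `band` (both spectral halves).
#' Real, zero-phase and idempotent by construction.
#' @noRd
notch_fft <- function(x, fs, band) {
  n <- ncol(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  mask <- f >= band[1] & f <= band[2]
  for (ch in seq_len(nrow(x))) {
    X <- stats::fft(x[ch, ])
    X[mask] <- 0i
    x[ch, ] <- Re(stats::fft(X, inverse = TRUE)) / n
  }
  x
}

#' SOZ-preserving random channel subsampling
#'
#' Keeps all SOZ channels and fills up to `cap` total with non-SOZ channels
#' drawn without replacement, each candidate required to be at least 10 mm
#' from every already-selected contact (no distance constraint when
#' coordinates are absent). Repeated `n_runs` times.
#'
#' @param rec a standardised `ieeg_recording`.
#' @param cap maximum channels retained per run (default 30).
#' @param n_runs number of independent sampling runs (default 10).
#' @param seed integer seed; runs are deterministic given it.
#' @param min_dist minimum spacing in mm (default 10).
#' @return list of `n_runs` sorted integer channel-index vectors.
#' @export
subsample_channels <- function(rec, cap = 30L, n_runs = 10L, seed = 1L,
                               min_dist = 10) {
  soz <- which(rec$soz_mask)
  if (length(soz) > cap)
    stop("soz-exceeds-cap: ", length(soz), " SOZ channels exceed cap ", cap)
  nonsoz <- which(!rec$soz_mask)
  lapply(seq_len(n_runs), function(r) {
    with_seed(sub_seed(seed, "subsample", r), {
      sel <- soz
      pool <- sample(nonsoz)
      for (cand in pool) {
        if (length(sel) >= cap) break
        if (!is.null(rec$coords) && length(sel) > 0) {
          d <- sqrt(colSums((t(rec$coords[sel, , drop = FALSE]) -
                               rec$coords[cand, ])^2))
          if (min(d) < min_dist) next
        }
        sel <- c(sel, cand)
      }
      sort(sel)
    })
  })
}

#' Extract early, mid and late 2-s epochs
#'
#' Interictal recordings yield epochs at 0-2 s, 59-61 s and 118-120 s. Ictal
#' recordings of duration D yield early at 0-2 s, late at (D-2)-D s, and mid
#' as the 2-s window whose start is halfway between the early and late starts.
#' Each epoch is exactly 512 samples at 256 Hz, restricted to the requested
#' channel subset.
#'
#' @param rec a standardised `ieeg_recording` (256 Hz).
#' @param subsample integer channel indices to retain (default all).
#' @return object of class `epoch_set`: list with `epochs` (named list early /
#'   mid / late of channels x 512 matrices), `channels`, `period`,
#'   `patient_id`, `soz_mask` (restricted).
#' @export
extract_epochs <- function(rec, subsample = seq_len(nrow(rec$samples))) {
  fs <- rec$fs
  stopifnot(fs == 256)
  n <- ncol(rec$samples)
  D <- n / fs
  if (rec$period == "interictal") {
    if (D < 120) stop("too-short: interictal recording shorter than 120 s")
    starts <- c(early = 0, mid = 59, late = 118)
  } else {
    if (D < 6) stop("too-short: ictal recording shorter than 6 s")
    starts <- c(early = 0, mid = (D - 2) / 2, late = D - 2)
  }
  idx0 <- round(starts * fs)
  epochs <- lapply(idx0, function(s0)
    rec$samples[subsample, (s0 + 1):(s0 + 512), drop = FALSE])
  structure(list(epochs = epochs, start_s = starts,
                 channels = subsample, period = rec$period,
                 patient_id = rec$patient_id,
                 soz_mask = rec$soz_mask[subsample]),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("Epoch set [%s, %s]: 3 x (%d channels x 512 samples), starts %s s\n",
              x$patient_id, x$period, length(x$channels),
              paste(signif(x$start_s, 4), collapse = "/")))
  invisible(x)
}
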