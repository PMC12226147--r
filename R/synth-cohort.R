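# Synthetic patient cohorts with planted sink/source SOZ network structure.

#' Draw synthetic electrode coordinates with minimum spacing
#'
#' Uniform in an 80 x 80 x 80 mm box, rejection-sampled so every contact is at
#' least 10 mm from every other.
#' @noRd
draw_coords <- function(n, min_dist = 10, box = 80, max_tries = 20000L) {
  pts <- matrix(NA_real_, n, 3)
  k <- 0L
  for (i in seq_len(max_tries)) {
    cand <- stats::runif(3, 0, box)
    if (k == 0L ||
        min(sqrt(colSums((t(pts[seq_len(k), , drop = FALSE]) - cand)^2))) >= min_dist) {
      k <- k + 1L
      pts[k, ] <- cand
      if (k == n) return(pts)
    }
  }
  stop("config-invalid: could not place ", n, " contacts with ",
       min_dist, " mm spacing")
}

#' Generate a synthetic patient cohort
#'
#' Each patient gets a channel count drawn from `channels_range`, an SOZ mask
#' whose size is `round(fraction * N)` clipped to `[2, N - 2]`, synthetic
#' electrode coordinates with at least 10 mm pairwise spacing, one interictal
#' and one ictal VAR model ([make_var_model()]), two interictal recordings of
#' `interictal_duration_s`, and an ictal recording count drawn uniformly from
#' `ictal_recordings_range` with durations uniform in `ictal_duration_range_s`.
#' Bad-channel flags are planted among non-SOZ contacts with probability
#' `bad_channel_prob`. The whole cohort is deterministic given `config$seed`.
#'
#' @param config a [cohort_config()].
#' @param dir optional directory; when given, the cohort is also written in
#'   the BIDS-iEEG-lite layout (one sub-directory per patient, plus
#'   `truth.tsv`).
#' @return object of class `soz_cohort`: a list of patients, each with
#'   `patient_id`, `soz_mask`, `coords`, `status`, `recordings` (list of
#'   `ieeg_recording`), `truth` (list of `ground_truth` per period).
#' @export
generate_cohort <- function(config = cohort_config(), dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  patients <- vector("list", config$n_patients)
  for (i in seq_len(config$n_patients)) {
    pid <- sprintf("pt%02d", i)
    pseed <- sub_seed(config$seed, "patient", i)
    layout <- with_seed(pseed, {
      rng <- config$channels_range[1]:config$channels_range[2]
      n_ch <- rng[sample.int(length(rng), 1L)]
      frac <- stats::rnorm(1, config$soz_fraction_mean, config$soz_fraction_sd)
      n_soz <- max(2L, min(n_ch - 2L, as.integer(round(frac * n_ch))))
      soz_idx <- sample.int(n_ch, n_soz)
      soz_mask <- seq_len(n_ch) %in% soz_idx
      status <- rep("good", n_ch)
      bad <- !soz_mask & stats::runif(n_ch) < config$bad_channel_prob
      status[bad] <- "bad"
      coords <- draw_coords(n_ch)
      list(n_ch = n_ch, soz_mask = soz_mask, status = status, coords = coords)
    })

    gf <- with_seed(sub_seed(pseed, "gain"), {
      f <- stats::runif(2, config$gain_factor_range[1],
                        config$gain_factor_range[2])
      if (config$gain_coupling == "shared") f[2] <- f[1]
      f
    })
    mk <- function(mode, factor) {
      cfg_p <- config
      cfg_p$sink_gain <- config$sink_gain * factor
      cfg_p$source_gain <- config$source_gain * factor
      make_var_model(layout$n_ch, layout$soz_mask, mode, cfg_p,
                     seed = sub_seed(pseed, "model", mode))
    }
    inter <- mk("interictal", gf[1])
    ictal <- mk("ictal", gf[2])

    n_ictal <- with_seed(sub_seed(pseed, "nictal"), {
      rng <- config$ictal_recordings_range[1]:config$ictal_recordings_range[2]
      rng[sample.int(length(rng), 1L)]
    })

    recs <- list()
    for (r in 1:2) {
      rec <- simulate_recording(inter$model, config$interictal_duration_s,
                                config$line_noise_amp,
                                seed = sub_seed(pseed, "rec", "interictal", r),
                                patient_id = pid)
      rec$soz_mask <- layout$soz_mask; rec$status <- layout$status
      rec$coords <- layout$coords
      recs[[sprintf("interictal-%02d", r)]] <- rec
    }
    for (r in seq_len(n_ictal)) {
      dur <- with_seed(sub_seed(pseed, "dur", r), {
        stats::runif(1, config$ictal_duration_range_s[1],
                     config$ictal_duration_range_s[2])
      })
      rec <- simulate_recording(ictal$model, dur, config$line_noise_amp,
                                seed = sub_seed(pseed, "rec", "ictal", r),
                                patient_id = pid)
      rec$soz_mask <- layout$soz_mask; rec$status <- layout$status
      rec$coords <- layout$coords
      recs[[sprintf("ictal-%02d", r)]] <- rec
    }

    patients[[i]] <- list(patient_id = pid, soz_mask = layout$soz_mask,
                          status = layout$status, coords = layout$coords,
                          recordings = recs,
                          truth = list(interictal = inter$truth,
                                       ictal = ictal$truth))
  }
  names(patients) <- vapply(patients, `[[`, "", "patient_id")
  cohort <- structure(list(patients = patients, config = config),
                      class = "soz_cohort")
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' @export
print.soz_cohort <- function(x, ...) {
  n_rec <- vapply(x$patients, function(p) length(p$recordings), 0L)
  n_soz <- vapply(x$patients, function(p) sum(p$soz_mask), 0L)
  n_ch <- vapply(x$patients, function(p) length(p$soz_mask), 0L)
  cat(sprintf("Synthetic iEEG cohort: %d patients, %d recordings total\n",
              length(x$patients), sum(n_rec)))
  cat(sprintf("  channels/patient: %d-%d | SOZ contacts/patient: %d-%d\n",
              min(n_ch), max(n_ch), min(n_soz), max(n_soz)))
  invisible(x)
}

#' Write a cohort in the BIDS-iEEG-lite layout
#'
#' @param cohort an `soz_cohort`.
#' @param dir output directory; one sub-directory per patient.
#' @return invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  for (p in cohort$patients) {
    pdir <- file.path(dir, p$patient_id)
    for (rid in names(p$recordings))
      write_recording(p$recordings[[rid]], pdir, rid)
    tr <- do.call(rbind, lapply(p$truth, `[[`, "planted_edges"))
    data.table::fwrite(tr, file.path(pdir, "truth.tsv"), sep = "\t")
  }
  invisible(dir)
}

#' Read a cohort previously written with [write_cohort()]
#'
#' @param dir cohort directory.
#' @return an `soz_cohort` (without the generative models; `truth` holds the
#'   planted-edge table).
#' @export
read_cohort <- function(dir) {
  pdirs <- sort(list.dirs(dir, recursive = FALSE))
  patients <- lapply(pdirs, function(pdir) {
    ids <- sort(sub("_ieeg\\.tsv$", "",
                    basename(list.files(pdir, pattern = "_ieeg\\.tsv$"))))
    recs <- lapply(ids, function(rid) read_recording(pdir, rid))
    names(recs) <- ids
    first <- recs[[1]]
    truth_path <- file.path(pdir, "truth.tsv")
    truth <- if (file.exists(truth_path))
      as.data.frame(data.table::fread(truth_path, sep = "\t")) else NULL
    list(patient_id = first$patient_id, soz_mask = first$soz_mask,
         status = first$status, coords = first$coords,
         recordings = recs, truth = truth)
  })
  names(patients) <- vapply(patients, `[[`, "", "patient_id")
  structure(list(patients = patients, config = NULL), class = "soz_cohort")
}
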