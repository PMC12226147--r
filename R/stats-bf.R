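# JZS Bayes-factor t-tests (Cauchy prior on the standardised effect size)
# and the sink/source hypothesis grid over measures x metrics x periods.

#' One-sample JZS Bayes-factor t-test
#'
#' Bayes factor BF10 for a one-sample (or paired-difference) t-test under the
#' Jeffreys-Zellner-Siow prior: a Cauchy prior with scale `rscale` on the
#' standardised effect size, equivalently a normal prior on the effect with an
#' inverse-gamma(1/2, rscale^2/2) mixing variance. The marginal likelihood
#' ratio is evaluated by adaptive quadrature of the Rouder one-sample integral
#'
#' \deqn{BF_{10} = \int_0^\infty (1 + N g r^2)^{-1/2}
#'   \left(1 + \frac{t^2}{(1 + N g r^2)\,\nu}\right)^{-(\nu+1)/2}
#'   (2\pi)^{-1/2} g^{-3/2} e^{-1/(2g)}\, dg \Big/
#'   \left(1 + \frac{t^2}{\nu}\right)^{-(\nu+1)/2}}
#'
#' with \eqn{\nu = N - 1}. Evidence is categorised with the strict thresholds
#' used throughout the package: BF10 > 10 supports H1, BF10 < 0.1 supports
#' H0, anything between is insufficient.
#'
#' @param x numeric vector of (paired) differences, or NULL when `t_stat` and
#'   `n` are supplied directly.
#' @param t_stat,n optional t statistic and sample size (bypass `x`).
#' @param rscale Cauchy prior scale (default `sqrt(2)/2`, the conventional
#'   medium prior).
#' @return object of class `bf_result`: `bf10`, `t_stat`, `n`, `evidence`
#'   (`"H1"`, `"H0"` or `"insufficient"`).
#' @export
jzs_bf_ttest <- function(x = NULL, t_stat = NULL, n = NULL,
                         rscale = sqrt(2) / 2) {
  if (!is.null(x)) {
    x <- x[is.finite(x)]
    n <- length(x)
    if (n < 3) stop("degenerate-sample: need n >= 3")
    if (stats::sd(x) == 0) stop("degenerate-sample: zero variance")
    t_stat <- mean(x) / (stats::sd(x) / sqrt(n))
  }
  stopifnot(!is.null(t_stat), !is.null(n), n >= 3)
  bf10 <- jzs_bf10(t_stat, n, rscale)
  structure(list(bf10 = bf10, t_stat = t_stat, n = n,
                 evidence = bf_evidence(bf10)),
            class = "bf_result")
}

#' @noRd
bf_evidence <- function(bf10) {
  if (bf10 > 10) "H1" else if (bf10 < 0.1) "H0" else "insufficient"
}

#' Rouder one-sample JZS BF10 by adaptive quadrature
#' @noRd
jzs_bf10 <- function(t_stat, n, rscale = sqrt(2) / 2) {
  nu <- n - 1
  t2 <- t_stat^2
  r2 <- rscale^2
  null_ll <- (1 + t2 / nu)^(-(nu + 1) / 2)
  integrand <- function(g) {
    a <- 1 + n * g * r2
    a^(-0.5) * (1 + t2 / (a * nu))^(-(nu + 1) / 2) *
      (2 * pi)^(-0.5) * g^(-1.5) * exp(-1 / (2 * g))
  }
  # split at g = 1 (the mode region of the inverse-gamma weight)
  num <- stats::integrate(integrand, 0, 1, rel.tol = 1e-8,
                          subdivisions = 500L)$value +
         stats::integrate(integrand, 1, Inf, rel.tol = 1e-8,
                          subdivisions = 500L)$value
  num / null_ll
}

#' @export
print.bf_result <- function(x, ...) {
  cat(sprintf("JZS BF t-test: t = %.3f, n = %d, BF10 = %.4g -> %s\n",
              x$t_stat, x$n, x$bf10, x$evidence))
  invisible(x)
}

#' Sink/source Bayes-factor grid over measures and metrics
#'
#' For every (measure, metric) feature column, the per-patient SOZ-contact
#' mean and non-SOZ-contact mean are computed and their paired differences
#' across patients fed to [jzs_bf_ttest()]. A positive t statistic means the
#' metric is higher in SOZ contacts (e.g. in-strength interictally under the
#' sink-SOZ hypothesis; out-strength ictally under source-SOZ).
#'
#' @param features a `feature_table` pooling the contacts of several patients
#'   (needs >= 3 patients that have both SOZ and non-SOZ contacts).
#' @param period label stored in the output rows.
#' @return data frame with one row per feature: `measure`, `metric`,
#'   `period`, `t`, `n`, `bf10`, `evidence`; the per-patient group means are
#'   attached as attribute `group_means`.
#' @export
sink_source_tests <- function(features, period = NA_character_) {
  fc <- feature_cols(features)
  pats <- split(features, features$patient)
  usable <- Filter(function(p) any(p$soz) && any(!p$soz), pats)
  if (length(usable) < length(pats))
    warning("patients lacking one contact group excluded: ",
            length(pats) - length(usable))
  if (length(usable) < 3) stop("need >= 3 patients with both contact groups")

  gm <- lapply(usable, function(p) {
    soz_m <- colMeans(p[p$soz, fc, drop = FALSE])
    non_m <- colMeans(p[!p$soz, fc, drop = FALSE])
    rbind(soz = soz_m, non_soz = non_m)
  })
  diffs <- vapply(gm, function(m) m["soz", ] - m["non_soz", ],
                  numeric(length(fc)))          # features x patients

  res <- lapply(seq_along(fc), function(i) {
    parts <- strsplit(fc[i], "__", fixed = TRUE)[[1]]
    d <- diffs[i, ]
    if (stats::sd(d) == 0)          # uninformative contrast (e.g. all-zero
      return(data.frame(measure = parts[1], metric = parts[2],   # metric)
                        period = period, t = NA_real_, n = length(d),
                        bf10 = NA_real_, evidence = "insufficient"))
    bf <- jzs_bf_ttest(d)
    data.frame(measure = parts[1], metric = parts[2], period = period,
               t = bf$t_stat, n = bf$n, bf10 = bf$bf10,
               evidence = bf$evidence)
  })
  out <- do.call(rbind, res)
  attr(out, "group_means") <- gm
  out
}

#' Per-patient SOZ minus non-SOZ effect sizes
#'
#' \eqn{\Delta =} mean metric over SOZ contacts minus mean over non-SOZ
#' contacts, per patient and measure, for one metric.
#'
#' @param features a `feature_table` pooling several patients.
#' @param metric node metric to contrast (e.g. `"in_strength"`).
#' @return data frame `patient` x one column per measure.
#' @export
effect_sizes <- function(features, metric = "in_strength") {
  fc <- grep(paste0("__", metric, "$"), feature_cols(features), value = TRUE)
  pats <- split(features, features$patient)
  rows <- lapply(pats, function(p) {
    if (!any(p$soz) || !any(!p$soz)) return(NULL)
    d <- colMeans(p[p$soz, fc, drop = FALSE]) -
         colMeans(p[!p$soz, fc, drop = FALSE])
    as.data.frame(c(list(patient = p$patient[1]), as.list(d)),
                  check.names = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  names(out) <- sub("__.*$", "", names(out))
  names(out)[1] <- "patient"
  rownames(out) <- NULL
  out
}

#' Interictal/ictal effect-size correlations
#'
#' Patient level: for each measure, the Pearson correlation across patients
#' between the interictal in-strength effect size and the ictal out-strength
#' effect size (two-sided p from the t transform). Contact level: within each
#' patient, the correlation across SOZ contacts between interictal
#' in-strength and ictal out-strength, summarised by the cross-patient mean.
#'
#' @param feat_inter,feat_ictal `feature_table`s for the two periods.
#' @return list with `patient_level` (measure, r, p, n) and `contact_level`
#'   (patient x measure matrix of r values plus the `mean_r` row summary).
#' @export
effect_correlations <- function(feat_inter, feat_ictal) {
  d_in <- effect_sizes(feat_inter, "in_strength")
  d_out <- effect_sizes(feat_ictal, "out_strength")
  common <- intersect(d_in$patient, d_out$patient)
  measures <- setdiff(names(d_in), "patient")
  d_in <- d_in[match(common, d_in$patient), ]
  d_out <- d_out[match(common, d_out$patient), ]

  patient_level <- do.call(rbind, lapply(measures, function(m) {
    if (length(common) < 4)
      return(data.frame(measure = m, r = NA_real_, p = NA_real_,
                        n = length(common)))
    ct <- stats::cor.test(d_in[[m]], d_out[[m]])
    data.frame(measure = m, r = unname(ct$estimate), p = ct$p.value,
               n = length(common))
  }))

  contact_level <- vapply(common, function(pid) {
    pi_ <- feat_inter[feat_inter$patient == pid & feat_inter$soz, ]
    pc_ <- feat_ictal[feat_ictal$patient == pid & feat_ictal$soz, ]
    shared <- intersect(pi_$contact, pc_$contact)
    vapply(measures, function(m) {
      if (length(shared) < 4) return(NA_real_)
      a <- pi_[match(shared, pi_$contact), paste0(m, "__in_strength")]
      b <- pc_[match(shared, pc_$contact), paste0(m, "__out_strength")]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
      stats::cor(a, b)
    }, numeric(1))
  }, numeric(length(measures)))
  contact_level <- t(contact_level)          # patients x measures
  rownames(contact_level) <- common

  list(patient_level = patient_level,
       contact_level = contact_level,
       contact_mean_r = colMeans(contact_level, na.rm = TRUE))
}
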