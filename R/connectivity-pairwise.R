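# Bivariate cause-effect scores (ANM, IGCI, CDS, RECI, LMFIT). Samples are
# treated as exchangeable draws: these scores ignore time order and ask which
# direction of a functional model fits better. All raw scores are
# antisymmetric in the pair; the matrix entry [d, s] is the rectified score
# for the s -> d direction.

#' Bivariate cause-effect connectivity scores
#'
#' Channels are standardised to zero mean and unit variance first. For each
#' ordered pair (s -> d) a directional score is computed and entry
#' `[d, s] = max(score, 0)`:
#' \describe{
#'   \item{ANM}{additive-noise model: smoothing-spline regressions in both
#'     directions; the dependence of the residual on the input is measured by
#'     distance correlation, and the direction with the more independent
#'     residual wins: `score = dep(d -> s) - dep(s -> d)`.}
#'   \item{IGCI}{information-geometric score with uniform reference: both
#'     variables are min-max scaled to \[0, 1\], `C(s -> d)` is the mean of
#'     `ln |dd/ds|` over points sorted by `s`, and
#'     `score = C(d -> s) - C(s -> d)`.}
#'   \item{CDS}{conditional-distribution variability: the conditioning
#'     variable is cut into 10 equal-count bins (bins with < 3 points merged
#'     with a neighbour) and the s.d. across bins of the within-bin s.d. of
#'     the other variable is computed; the causal direction shows the more
#'     stable conditionals: `score = v(d -> s) - v(s -> d)`.}
#'   \item{RECI}{regression-error comparison after min-max normalisation to
#'     \[0, 1\]: degree-3 polynomial least squares both ways;
#'     `score = MSE(s from d) - MSE(d from s)`.}
#'   \item{LMFIT}{the degree-1 (linear) version of RECI.}
#' }
#'
#' @param epoch channels x samples matrix.
#' @param kind one of `"ANM"`, `"IGCI"`, `"CDS"`, `"RECI"`, `"LMFIT"`.
#' @return non-negative N x N matrix, zero diagonal.
#' @export
pairwise_measure <- function(epoch, kind = c("ANM", "IGCI", "CDS", "RECI",
                                             "LMFIT")) {
  kind <- match.arg(kind)
  N <- nrow(epoch)
  sds <- apply(epoch, 1, stats::sd)
  if (any(sds == 0)) stop("degenerate-signal: constant channel")
  x <- (epoch - rowMeans(epoch)) / sds
  score_fun <- switch(kind,
    ANM = anm_score, IGCI = igci_score, CDS = cds_score,
    RECI = function(a, b) reci_score(a, b, degree = 3L),
    LMFIT = function(a, b) reci_score(a, b, degree = 1L))
  ctx <- if (kind == "ANM") anm_context(x) else NULL
  out <- matrix(0, N, N)
  for (i in seq_len(N - 1)) for (j in (i + 1):N) {
    sc <- if (kind == "ANM") score_fun(x[i, ], x[j, ], ctx, i, j)
          else score_fun(x[i, ], x[j, ])           # score for i -> j
    out[j, i] <- max(sc, 0)
    out[i, j] <- max(-sc, 0)
  }
  as_conn_matrix(out, kind)
}

# ---- distance correlation (needed by ANM) ----------------------------------
#
# dcov^2 between the double-centred distance matrices A, B of two samples
# expands to mean(Da*Db) - 2*mean(rowMeans(Da)*rowMeans(Db)) +
# mean(Da)*mean(Db), so the raw distance matrices never need centring.

#' Raw distance-matrix summaries of a sample
#' @noRd
dmat_ctx <- function(v) {
  D <- abs(outer(v, v, "-"))
  rm_ <- rowMeans(D)
  m <- mean(rm_)
  list(D = D, rm = rm_, m = m, dvar = mean(D * D) - 2 * mean(rm_ * rm_) + m^2)
}

#' Squared distance covariance from two contexts
#' @noRd
dcov2_ctx <- function(a, b)
  mean(a$D * b$D) - 2 * mean(a$rm * b$rm) + a$m * b$m

#' Distance correlation between a cached context and a new sample
#' @noRd
dcor_ctx <- function(a, v) {
  b <- dmat_ctx(v)
  dvar <- sqrt(a$dvar * b$dvar)
  if (dvar <= 0) return(0)
  sqrt(max(dcov2_ctx(a, b), 0) / dvar)
}

#' Distance-matrix contexts for every channel
#' @noRd
anm_context <- function(x) lapply(seq_len(nrow(x)), function(ch) dmat_ctx(x[ch, ]))

#' ANM score for direction i -> j (positive favours i -> j)
#' @noRd
anm_score <- function(a, b, ctx, i, j) {
  dep_ij <- dcor_ctx(ctx[[i]], spline_resid(a, b))   # residual of j given i vs i
  dep_ji <- dcor_ctx(ctx[[j]], spline_resid(b, a))
  dep_ji - dep_ij
}

#' Smoothing-spline residuals of y regressed on x
#' @noRd
spline_resid <- function(x, y) {
  fit <- stats::smooth.spline(x, y)
  y - stats::predict(fit, x)$y
}

# ---- IGCI ------------------------------------------------------------------

#' @noRd
igci_slope <- function(u, v) {
  o <- order(u)
  du <- diff(u[o]); dv <- diff(v[o])
  ok <- du != 0 & dv != 0
  mean(log(abs(dv[ok] / du[ok])))
}

#' @noRd
igci_score <- function(a, b) {
  u <- minmax01(a)             # uniform-reference scaling to [0, 1]
  v <- minmax01(b)
  c_ab <- igci_slope(u, v)     # C(a -> b)
  c_ba <- igci_slope(v, u)
  c_ba - c_ab                  # positive favours a -> b
}

# ---- CDS -------------------------------------------------------------------

#' Variability of conditional s.d. of `resp` across equal-count bins of `cond`
#' @noRd
cds_variability <- function(cond, resp, n_bins = 10L) {
  br <- stats::quantile(cond, probs = seq(0, 1, length.out = n_bins + 1L))
  br[1] <- -Inf; br[n_bins + 1L] <- Inf
  bins <- cut(cond, unique(br), labels = FALSE)
  cnt <- tabulate(bins)
  # merge undersized bins into their left neighbour
  while (any(cnt < 3L & cnt > 0L) && sum(cnt > 0L) > 1L) {
    k <- which(cnt < 3L & cnt > 0L)[1]
    tgt <- if (k > 1L) k - 1L else which(cnt > 0L)[2]
    bins[bins == k] <- tgt
    cnt <- tabulate(bins)
  }
  sds <- tapply(resp, bins, stats::sd)
  stats::sd(sds[!is.na(sds)])
}

#' @noRd
cds_score <- function(a, b) {
  v_ab <- cds_variability(a, b)   # conditioning on a (a -> b direction)
  v_ba <- cds_variability(b, a)
  v_ba - v_ab                     # positive favours a -> b
}

# ---- RECI / LMFIT ----------------------------------------------------------

#' @noRd
minmax01 <- function(v) (v - min(v)) / (max(v) - min(v))

#' @noRd
poly_mse <- function(x, y, degree) {
  X <- stats::poly(x, degree = degree, raw = TRUE)
  r <- .lm.fit(cbind(1, X), y)$residuals
  mean(r^2)
}

#' @noRd
reci_score <- function(a, b, degree) {
  u <- minmax01(a); v <- minmax01(b)
  mse_ab <- poly_mse(u, v, degree)   # predict b from a
  mse_ba <- poly_mse(v, u, degree)
  mse_ba - mse_ab                    # positive favours a -> b
}
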