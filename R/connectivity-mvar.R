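# Multivariate autoregressive fitting, spectral transfer machinery, and the
# MVAR-based directed measures (DTF, DCOH, PDC, spectral Granger causality).

#' Fit a multivariate autoregressive (VAR) model by ordinary least squares
#'
#' Channels are demeaned; the model order is chosen by minimising AIC over
#' `1:max_order` on a common estimation sample (ties resolved to the smallest
#' order), then the model is refit at the chosen order on all usable samples.
#' The innovation covariance uses the small-sample divisor
#' `max(T - N*p - 1, 1)` where `T` is the number of regression observations.
#'
#' @param epoch channels x samples numeric matrix.
#' @param order `"aic"` for automatic selection, or a fixed integer order.
#' @param max_order largest order tried under `"aic"` (default 10, reduced so
#'   that `N * p` parameters per equation stay below a third of the sample).
#' @param fs sampling rate in Hz, stored for the spectral stage.
#' @return object of class `var_fit`: `A` (list of lag matrices, destination
#'   rows / source columns), `Sigma`, `p`, `fs`, `n_obs`.
#' @export
fit_mvar <- function(epoch, order = "aic", max_order = 10L, fs = 256) {
  x <- epoch - rowMeans(epoch)
  N <- nrow(x); n <- ncol(x)
  cap <- max(1L, floor(n / 3 / N))
  if (identical(order, "aic")) {
    pmax <- min(max_order, cap)
    aic <- rep(NA_real_, pmax)
    for (p in seq_len(pmax)) {
      f <- var_ols(x, p, t_start = pmax + 1L)
      Tn <- n - pmax
      det_s <- determinant(f$Sigma_ml, logarithm = TRUE)$modulus
      aic[p] <- Tn * as.numeric(det_s) + 2 * p * N^2
    }
    p_sel <- which.min(aic)
  } else {
    p_sel <- as.integer(order)
    if (p_sel > cap) stop("order-too-large: N*p parameters exceed n/3")
  }
  f <- var_ols(x, p_sel, t_start = p_sel + 1L)
  Tn <- n - p_sel
  Sigma <- f$rss / max(Tn - N * p_sel - 1, 1)
  structure(list(A = f$A, Sigma = Sigma, p = p_sel, fs = fs, n_obs = n),
            class = "var_fit")
}

#' OLS VAR fit at fixed order on observations t_start..n
#' @noRd
var_ols <- function(x, p, t_start) {
  N <- nrow(x); n <- ncol(x)
  tt <- t_start:n
  Tn <- length(tt)
  X <- matrix(0, Tn, N * p)
  for (k in seq_len(p))
    X[, ((k - 1) * N + 1):(k * N)] <- t(x[, tt - k, drop = FALSE])
  Y <- t(x[, tt, drop = FALSE])
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("singular-fit: rank-deficient regressor matrix")
  B <- qr.coef(qx, Y)                      # (N*p) x N, columns = equations
  E <- Y - X %*% B
  A <- lapply(seq_len(p), function(k)
    t(B[((k - 1) * N + 1):(k * N), , drop = FALSE]))
  list(A = A, rss = crossprod(E), Sigma_ml = crossprod(E) / Tn)
}

#' Spectral transfer set on the 125-bin broadband grid
#'
#' Evaluates the Fourier-domain coefficient matrix
#' \eqn{\bar A(f) = I - \sum_k A_k e^{-i 2\pi f k / f_s}}, the transfer matrix
#' \eqn{H(f) = \bar A(f)^{-1}} and the cross-spectrum
#' \eqn{S(f) = H \Sigma H^*} at 125 uniformly spaced bin centres
#' `f_k = (k + 0.5) * 128/125`, k = 0..124, spanning (0, 128) Hz (the Nyquist
#' band at 256 Hz, avoiding DC).
#'
#' @param fit a `var_fit` (or a `var_model`; its true coefficients are used).
#' @return object of class `spectral_set`: `grid` (125 frequencies), `Abar`,
#'   `H`, `S` (N x N x 125 complex arrays), `Sigma`, `fs`.
#' @export
spectral_transfer <- function(fit) {
  if (inherits(fit, "var_model"))
    fit <- structure(list(A = fit$coefficients, Sigma = fit$noise_cov,
                          p = fit$p, fs = fit$fs), class = "var_fit")
  A <- fit$A; Sigma <- fit$Sigma; fs <- fit$fs
  N <- nrow(Sigma)
  grid <- ((0:124) + 0.5) * 128 / 125
  Abar <- H <- S <- array(0i, c(N, N, 125))
  I_N <- diag(N)
  for (k in seq_along(grid)) {
    om <- 2 * pi * grid[k] / fs
    Ab <- I_N + 0i
    for (l in seq_along(A)) Ab <- Ab - A[[l]] * exp(-1i * om * l)
    Hk <- tryCatch(solve(Ab), error = function(e)
      stop(sprintf("spectral-singularity at %.3f Hz", grid[k])))
    Abar[, , k] <- Ab
    H[, , k] <- Hk
    S[, , k] <- Hk %*% Sigma %*% Conj(t(Hk))
  }
  structure(list(grid = grid, Abar = Abar, H = H, S = S, Sigma = Sigma,
                 fs = fs), class = "spectral_set")
}

#' MVAR-based directed connectivity measures
#'
#' Entry `[d, s]` quantifies directed influence from source `s` to
#' destination `d`, averaged over the 125-bin broadband grid:
#' \describe{
#'   \item{DTF}{row-normalised squared transfer,
#'     \eqn{|H_{ds}|^2 / \sum_m |H_{dm}|^2}.}
#'   \item{DCOH}{directed coherence: transfer weighted by innovation
#'     variances, \eqn{\sigma_s^2 |H_{ds}|^2 / \sum_m \sigma_m^2 |H_{dm}|^2}.}
#'   \item{PDC}{column-normalised coefficient magnitude,
#'     \eqn{|\bar A_{ds}|^2 / \sum_m |\bar A_{ms}|^2}.}
#'   \item{SGC}{Geweke spectral Granger causality from bivariate refits per
#'     channel pair, \eqn{\ln[S_{dd} / (S_{dd} - (\Sigma_{ss} -
#'     \Sigma_{ds}^2/\Sigma_{dd}) |H_{ds}|^2)]}, clipped below at 0.}
#' }
#' The diagonal is zeroed after frequency averaging.
#'
#' @param spec a `spectral_set` from [spectral_transfer()] (DTF/DCOH/PDC).
#' @param kind one of `"DTF"`, `"DCOH"`, `"PDC"`, `"SGC"`.
#' @param epoch channels x samples matrix, required for `"SGC"` (bivariate
#'   refits).
#' @param order order policy passed to [fit_mvar()] for SGC refits.
#' @return non-negative N x N matrix with zero diagonal (rows = destination,
#'   columns = source).
#' @export
mvar_measure <- function(spec, kind = c("DTF", "DCOH", "PDC", "SGC"),
                         epoch = NULL, order = "aic") {
  kind <- match.arg(kind)
  if (kind == "SGC") {
    if (is.null(epoch)) stop("SGC requires the epoch for bivariate refits")
    return(sgc_measure(epoch, order))
  }
  N <- dim(spec$H)[1]
  acc <- matrix(0, N, N)
  sig2 <- diag(spec$Sigma)
  for (k in seq_len(125)) {
    if (kind == "PDC") {
      num <- Mod(spec$Abar[, , k])^2
      acc <- acc + sweep(num, 2, colSums(num), "/")
    } else {
      num <- Mod(spec$H[, , k])^2
      if (kind == "DCOH") num <- sweep(num, 2, sig2, "*")
      acc <- acc + num / rowSums(num)
    }
  }
  as_conn_matrix(acc / 125, kind)
}

#' @noRd
sgc_measure <- function(epoch, order = "aic") {
  N <- nrow(epoch)
  out <- matrix(0, N, N)
  grid <- ((0:124) + 0.5) * 128 / 125
  for (i in seq_len(N - 1)) for (j in (i + 1):N) {
    fit <- fit_mvar(epoch[c(i, j), , drop = FALSE], order = order)
    g <- geweke_pair(fit, grid)
    # within-pair indices: 1 = i, 2 = j
    out[j, i] <- g[1]      # i -> j
    out[i, j] <- g[2]      # j -> i
  }
  as_conn_matrix(out, "SGC")
}

#' Band-averaged Geweke causality for both directions of a bivariate fit
#'
#' Vectorised over the frequency grid via the closed-form 2x2 inverse of
#' Abar(f); returns c(f_{1->2}, f_{2->1}).
#' @noRd
geweke_pair <- function(fit, grid) {
  Sig <- fit$Sigma
  om <- 2 * pi * grid / fit$fs
  a11 <- rep(1 + 0i, length(grid)); a12 <- a21 <- 0i * om; a22 <- a11
  for (l in seq_along(fit$A)) {
    ph <- exp(-1i * om * l)
    A <- fit$A[[l]]
    a11 <- a11 - A[1, 1] * ph; a12 <- a12 - A[1, 2] * ph
    a21 <- a21 - A[2, 1] * ph; a22 <- a22 - A[2, 2] * ph
  }
  det <- a11 * a22 - a12 * a21
  H11 <- a22 / det; H12 <- -a12 / det
  H21 <- -a21 / det; H22 <- a11 / det
  sdd <- function(Hd1, Hd2)
    Re(Mod(Hd1)^2 * Sig[1, 1] + Mod(Hd2)^2 * Sig[2, 2] +
       2 * Re(Hd1 * Sig[1, 2] * Conj(Hd2)))
  gew <- function(Sdd, Hds2, s, d) {
    sig_part <- Sig[s, s] - Sig[d, s]^2 / Sig[d, d]
    intrinsic <- pmax(Sdd - sig_part * Hds2, 1e-12)
    mean(pmax(log(Sdd / intrinsic), 0))
  }
  c(gew(sdd(H21, H22), Mod(H21)^2, s = 1L, d = 2L),
    gew(sdd(H11, H12), Mod(H12)^2, s = 2L, d = 1L))
}
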