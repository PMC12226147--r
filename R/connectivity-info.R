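# Information-theoretic directed measures with Gaussian (linear) estimators:
# directed information and causally conditioned entropy. On 512-sample epochs
# nonparametric entropy estimators are unstable, so conditional variances come
# from linear regression residuals and entropies from the Gaussian formula.

#' Gaussian directed information and causally conditioned entropy
#'
#' For each ordered pair (s -> d), with L = `history` lags:
#' \describe{
#'   \item{DI}{\eqn{\tfrac12 \ln[\mathrm{var}(d_t \mid d^-) /
#'     \mathrm{var}(d_t \mid d^-, s_t, s^-)]} where \eqn{d^-} are lags 1..L of
#'     the destination and the source enters with lags 0..L (the
#'     instantaneous term included).}
#'   \item{CCE}{the entropy-difference form
#'     \eqn{H(d_t \mid d^-) - H(d_t \mid d^-, s^-)} with Gaussian entropies;
#'     the source is restricted to lags 1..L (strictly causal conditioning),
#'     so DI and CCE differ by the instantaneous term.}
#' }
#' Conditional variances are residual variances of OLS regressions; results
#' are clipped below at 0 and variances floored at 1e-12.
#'
#' @param epoch channels x samples matrix.
#' @param kind `"DI"` or `"CCE"`.
#' @param history lag count L (default 5); epoch must have at least
#'   `20 * history` samples.
#' @return non-negative N x N matrix, zero diagonal (rows = destination).
#' @export
info_measure <- function(epoch, kind = c("DI", "CCE"), history = 5L) {
  kind <- match.arg(kind)
  L <- as.integer(history)
  N <- nrow(epoch); n <- ncol(epoch)
  if (n < 20L * L) stop("too-short: epoch needs >= 20 * history samples")
  x <- epoch - rowMeans(epoch)
  tt <- (L + 1L):n
  Tn <- length(tt)
  # lag-embedded design blocks per channel: columns = lags 0..L
  emb <- lapply(seq_len(N), function(ch) {
    m <- matrix(0, Tn, L + 1L)
    for (k in 0:L) m[, k + 1L] <- x[ch, tt - k]
    m
  })
  s_lags <- if (kind == "DI") 1:(L + 1L) else 2:(L + 1L)   # lag-0 only for DI
  out <- matrix(0, N, N)
  for (d in seq_len(N)) {
    y <- emb[[d]][, 1L]
    Yp <- emb[[d]][, -1L, drop = FALSE]
    r0 <- .lm.fit(Yp, y)$residuals
    v0 <- max(sum(r0^2) / Tn, 1e-12)
    for (s in seq_len(N)) {
      if (s == d) next
      X1 <- cbind(Yp, emb[[s]][, s_lags, drop = FALSE])
      r1 <- .lm.fit(X1, y)$residuals
      v1 <- max(sum(r1^2) / Tn, 1e-12)
      out[d, s] <- max(0.5 * log(v0 / v1), 0)
    }
  }
  as_conn_matrix(out, kind)
}
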