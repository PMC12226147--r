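# Independent brute-force oracles used to validate the package's estimators.
# Each oracle deliberately takes a different computational route from the
# implementation it checks.

# ---- spectral oracle: direct complex arithmetic per grid point -------------

# DTF / DCOH / PDC from true VAR coefficients, element by element, without
# any of the package's matrix machinery.
oracle_spectral_measures <- function(A_list, Sigma, fs = 256) {
  N <- nrow(Sigma)
  grid <- ((0:124) + 0.5) * 128 / 125
  dtf <- dcoh <- pdc <- matrix(0, N, N)
  for (f in grid) {
    Ab <- matrix(0i, N, N)
    for (d in 1:N) for (s in 1:N) {
      val <- if (d == s) 1 + 0i else 0i
      for (l in seq_along(A_list))
        val <- val - A_list[[l]][d, s] * exp(-1i * 2 * pi * f * l / fs)
      Ab[d, s] <- val
    }
    H <- solve(Ab)
    for (d in 1:N) {
      den_dtf <- sum(Mod(H[d, ])^2)
      den_dcoh <- sum(diag(Sigma) * Mod(H[d, ])^2)
      for (s in 1:N) {
        dtf[d, s] <- dtf[d, s] + Mod(H[d, s])^2 / den_dtf
        dcoh[d, s] <- dcoh[d, s] + Sigma[s, s] * Mod(H[d, s])^2 / den_dcoh
      }
    }
    for (s in 1:N) {
      den_pdc <- sum(Mod(Ab[, s])^2)
      for (d in 1:N)
        pdc[d, s] <- pdc[d, s] + Mod(Ab[d, s])^2 / den_pdc
    }
  }
  res <- lapply(list(DTF = dtf, DCOH = dcoh, PDC = pdc), function(m) {
    m <- m / 125; diag(m) <- 0; m
  })
  res
}

# ---- stationary covariance of a VAR via the companion Lyapunov equation ----

# Solves vec(G) = (I - C (x) C)^(-1) vec(S) for the companion form; returns
# the lag-0 block G0 and the lag-1 cross-covariance E[x_t x_{t-1}'].
oracle_var_stationary_cov <- function(A_list, Sigma) {
  p <- length(A_list); N <- nrow(Sigma)
  C <- matrix(0, N * p, N * p)
  for (k in seq_len(p)) C[1:N, ((k - 1) * N + 1):(k * N)] <- A_list[[k]]
  if (p > 1) C[(N + 1):(N * p), 1:(N * (p - 1))] <- diag(N * (p - 1))
  S <- matrix(0, N * p, N * p); S[1:N, 1:N] <- Sigma
  vecG <- solve(diag((N * p)^2) - kronecker(C, C), as.vector(S))
  G <- matrix(vecG, N * p, N * p)
  G0 <- G[1:N, 1:N]
  G1 <- (C %*% G)[1:N, 1:N]            # E[x_t x_{t-1}'] for the top block
  list(G0 = G0, G1 = G1)
}

# ---- graph oracles ---------------------------------------------------------

# all-pairs shortest directed path lengths, Floyd-Warshall on 1/weight
oracle_floyd_warshall <- function(C) {
  W <- t(C / max(C))
  N <- nrow(W)
  D <- ifelse(W > 0, 1 / W, Inf)
  diag(D) <- 0
  for (k in 1:N) for (i in 1:N) for (j in 1:N)
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# betweenness by exhaustive shortest-path counting (Floyd-Warshall with
# path counts and intermediate-node dependencies via enumeration)
oracle_betweenness <- function(C) {
  N <- nrow(C)
  D <- oracle_floyd_warshall(C)
  paths <- enumerate_paths(C)
  bc <- numeric(N)
  for (s in 1:N) for (t in 1:N) {
    if (s == t || !is.finite(D[s, t])) next
    sp <- Filter(function(p) abs(path_len(C, p) - D[s, t]) < 1e-9,
                 paths[[s]][[t]])
    if (!length(sp)) next
    for (v in setdiff(1:N, c(s, t))) {
      on_v <- sum(vapply(sp, function(p) v %in% p[-c(1, length(p))],
                         logical(1)))
      bc[v] <- bc[v] + on_v / length(sp)
    }
  }
  bc / ((N - 1) * (N - 2))
}

# all simple directed paths between every ordered pair (small N only)
enumerate_paths <- function(C) {
  W <- t(C / max(C))
  N <- nrow(W)
  adj <- lapply(1:N, function(i) which(W[i, ] > 0))
  res <- lapply(1:N, function(s) lapply(1:N, function(t) list()))
  walk <- function(path, t) {
    v <- path[length(path)]
    if (v == t && length(path) > 1) {
      res[[path[1]]][[t]][[length(res[[path[1]]][[t]]) + 1]] <<- path
      return()
    }
    for (w in adj[[v]]) if (!(w %in% path)) walk(c(path, w), t)
  }
  for (s in 1:N) for (t in 1:N) if (s != t) walk(s, t)
  res
}

path_len <- function(C, p) {
  W <- t(C / max(C))
  sum(vapply(seq_len(length(p) - 1),
             function(i) 1 / W[p[i], p[i + 1]], numeric(1)))
}

# Fagiolo clustering by explicit triple loop over all (j, h) pairs
oracle_clustering <- function(C) {
  W <- t(C / max(C)); diag(W) <- 0
  N <- nrow(W)
  Wh <- W^(1 / 3)
  A <- (W > 0) + 0
  out <- numeric(N)
  for (i in 1:N) {
    t_i <- 0
    for (j in 1:N) for (h in 1:N)
      t_i <- t_i + (Wh[i, j] + Wh[j, i]) * (Wh[i, h] + Wh[h, i]) *
                   (Wh[j, h] + Wh[h, j])
    t_i <- t_i / 2
    d_tot <- sum(A[i, ]) + sum(A[, i])
    d_bi <- sum(A[i, ] * A[, i])
    den <- d_tot * (d_tot - 1) - 2 * d_bi
    out[i] <- if (den > 0) t_i / den else 0
  }
  out
}

# inbound MFPT by value iteration t <- 1 + Q t (route independent of solve())
oracle_mfpt <- function(C, tol = 1e-12, max_iter = 100000L) {
  W <- t(C / max(C))
  N <- nrow(W)
  rs <- rowSums(W)
  P <- W / ifelse(rs > 0, rs, 1)
  for (i in which(rs == 0)) { P[i, ] <- 1 / (N - 1); P[i, i] <- 0 }
  vapply(1:N, function(k) {
    Q <- P[-k, -k, drop = FALSE]
    t_v <- rep(0, N - 1)
    for (it in seq_len(max_iter)) {
      t_new <- 1 + as.vector(Q %*% t_v)
      if (max(abs(t_new - t_v)) < tol) { t_v <- t_new; break }
      t_v <- t_new
    }
    mean(t_v)
  }, numeric(1))
}

# Monte-Carlo hitting times (vectorised over walkers)
oracle_mfpt_mc <- function(C, target, n_walkers = 4000L, max_steps = 5000L,
                           seed = 1) {
  set.seed(seed)
  W <- t(C / max(C))
  N <- nrow(W)
  rs <- rowSums(W)
  P <- W / ifelse(rs > 0, rs, 1)
  for (i in which(rs == 0)) { P[i, ] <- 1 / (N - 1); P[i, i] <- 0 }
  cumP <- t(apply(P, 1, cumsum))
  starts <- rep(setdiff(1:N, target), length.out = n_walkers)
  pos <- starts
  steps <- rep(NA_real_, n_walkers)
  for (st in seq_len(max_steps)) {
    active <- which(is.na(steps))
    if (!length(active)) break
    u <- runif(length(active))
    nxt <- vapply(seq_along(active), function(i)
      which(u[i] <= cumP[pos[active[i]], ])[1], integer(1))
    pos[active] <- nxt
    steps[active[nxt == target]] <- st
  }
  mean(steps, na.rm = TRUE)
}

# ---- JZS Bayes factor oracle: integrate over the effect size ---------------

# BF10 = int T_nu(t | delta sqrt(n)) Cauchy(delta; 0, r) d delta / T_nu(t | 0)
# (marginalises the effect size directly with the noncentral-t likelihood —
# a different parametrisation from the implementation's g-integral)
oracle_jzs_bf10 <- function(t_stat, n, rscale = sqrt(2) / 2) {
  nu <- n - 1
  num <- suppressWarnings(
    integrate(function(delta)
      dt(t_stat, df = nu, ncp = delta * sqrt(n)) *
        dcauchy(delta, 0, rscale),
      -Inf, Inf, rel.tol = 1e-9, subdivisions = 400L)$value)
  num / dt(t_stat, df = nu)
}

# ---- misc helpers ----------------------------------------------------------

random_conn_matrix <- function(N, density = 0.6, seed = 1) {
  set.seed(seed)
  C <- matrix(runif(N * N), N, N) * (matrix(runif(N * N), N, N) < density)
  diag(C) <- 0
  C
}

# small standardised epoch of independent noise
noise_epoch <- function(N = 4, n = 512, seed = 1) {
  set.seed(seed)
  matrix(rnorm(N * n), N, n)
}
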