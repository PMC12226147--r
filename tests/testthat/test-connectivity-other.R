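# Phase, information-theoretic and bivariate cause-effect measures, plus the
# assembled 13-measure stack.

lagged_pair_epoch <- function(lag = 3, n = 512, noise = 0.1, seed = 1) {
  set.seed(seed)
  raw <- as.numeric(stats::filter(rnorm(n + lag + 50), rep(1, 3) / 3,
                                  sides = 1))
  raw <- raw[!is.na(raw)]
  x <- raw[(lag + 1):(lag + n)]
  y <- raw[1:n] + noise * rnorm(n)     # y = x delayed by `lag` samples
  rbind(x, y)
}

test_that("identical channels give zero phase-based directionality", {
  set.seed(2)
  v <- rnorm(512)
  ep <- rbind(v, v)
  psi <- phase_measure(ep, "PSI")
  gd <- phase_measure(ep, "GD")
  expect_lt(max(abs(psi)), 1e-10)
  expect_lt(max(abs(gd)), 1e-10)
})

test_that("a constructed 3-sample lag is detected by PSI and GD", {
  ep <- lagged_pair_epoch(lag = 3)
  psi <- phase_measure(ep, "PSI")
  expect_gt(psi[2, 1], 0)       # x (row 1) drives y (row 2)
  expect_equal(psi[1, 2], 0)    # reverse direction rectified to zero
  gd <- phase_measure(ep, "GD")
  expect_gt(gd[2, 1], 0)
  expect_equal(gd[1, 2], 0)
  # delay estimate within half a sample of 3/256 s
  expect_lt(abs(gd[2, 1] - 3 / 256), 0.5 / 256)
})

test_that("raw phase-slope values are antisymmetric before rectification", {
  # psi_{s->d} = -psi_{d->s}: swapping the two channels must swap the
  # rectified entries exactly
  ep <- lagged_pair_epoch(lag = 2, seed = 5)
  a <- phase_measure(ep, "PSI")
  b <- phase_measure(ep[2:1, ], "PSI")
  expect_equal(a[2, 1], b[1, 2], tolerance = 1e-12)
  expect_equal(a[1, 2], b[2, 1], tolerance = 1e-12)
})

test_that("Gaussian DI matches exact covariance-algebra conditioning", {
  # d_t = b s_{t-1} + e_d with s, e_d unit white noise. Oracle: conditional
  # variances from the true joint covariance of (d_t, d-past, s-present+past)
  # via Schur complements.
  b <- 0.8; L <- 5L
  # exact covariances: var(s)=1, var(d)=1+b^2, cov(d_t, s_{t-1})=b,
  # cov(d_t, d_{t-k})=0 for k>=1 (d is 1-dependent? no: d_t and d_{t-1}
  # share no terms), all other cross terms 0.
  nv <- 2L * (L + 1L)
  # variable order: d_t, d_{t-1..L}, s_t, s_{t-1..L}
  Sg <- diag(c(rep(1 + b^2, L + 1L), rep(1, L + 1L)))
  for (k in 0:L) for (j in 0:L) {
    # cov(d_{t-k}, s_{t-j}) = b when j = k+1
    if (j == k + 1 && j <= L) {
      Sg[1 + k, L + 2 + j] <- b
      Sg[L + 2 + j, 1 + k] <- b
    }
  }
  cond_var <- function(S, y, x) {
    S[y, y] - S[y, x, drop = FALSE] %*% solve(S[x, x]) %*% S[x, y, drop = FALSE]
  }
  v0 <- cond_var(Sg, 1, 2:(L + 1))                       # past of d only
  v1 <- cond_var(Sg, 1, c(2:(L + 1), (L + 2):nv))        # + s present & past
  di_true <- 0.5 * log(as.numeric(v0) / as.numeric(v1))
  expect_equal(di_true, 0.5 * log(1 + b^2))              # sanity of oracle

  set.seed(6)
  n <- 20000
  s <- rnorm(n); d <- b * c(0, s[-n]) + rnorm(n)
  di <- info_measure(rbind(s, d), "DI", history = L)
  expect_lt(abs(di[2, 1] - di_true), 0.02)
  expect_lt(di[1, 2], 0.01)
})

test_that("DI dominates CCE entrywise and both are non-negative", {
  set.seed(7)
  # instantaneous + lagged coupling makes the lag-0 term informative
  n <- 512
  s <- rnorm(n)
  d <- 0.5 * s + 0.5 * c(0, s[-n]) + 0.5 * rnorm(n)
  ep <- rbind(s, d)
  di <- info_measure(ep, "DI")
  cce <- info_measure(ep, "CCE")
  expect_true(all(di >= 0) && all(cce >= 0))
  expect_gte(di[2, 1], cce[2, 1])
})

test_that("independent channels stay below a circular-shift null for DI", {
  set.seed(8)
  ep <- matrix(rnorm(2 * 512), 2, 512)
  obs <- info_measure(ep, "DI")[2, 1]
  null_vals <- vapply(1:60, function(i) {
    sh <- (i * 7) %% 400 + 50
    ep2 <- rbind(ep[1, ], ep[2, c((sh + 1):512, 1:sh)])
    info_measure(ep2, "DI")[2, 1]
  }, numeric(1))
  expect_lt(obs, quantile(null_vals, 0.95) + 0.02)
})

test_that("nonlinear additive models are oriented correctly by ANM/RECI/IGCI", {
  hits <- c(ANM = 0, RECI = 0, IGCI = 0)
  n_seeds <- 25
  for (s in 1:n_seeds) {
    set.seed(s)
    x <- runif(512, -1, 1)
    y <- x^3 + 0.2 * rnorm(512)
    ep <- rbind(x, y)
    for (m in names(hits)) {
      cm <- pairwise_measure(ep, m)
      if (cm[2, 1] > cm[1, 2]) hits[m] <- hits[m] + 1
    }
  }
  for (m in names(hits)) expect_gte(hits[[m]], 0.85 * n_seeds)
})

test_that("pairwise scores are antisymmetric under channel swap", {
  set.seed(9)
  x <- runif(400, -1, 1); y <- x^2 + 0.3 * rnorm(400)
  ep <- rbind(x, y)
  for (m in c("IGCI", "RECI", "LMFIT", "CDS")) {
    a <- pairwise_measure(ep, m)
    b <- pairwise_measure(ep[2:1, ], m)
    expect_equal(a[2, 1], b[1, 2], tolerance = 1e-12)
    expect_equal(a[1, 2], b[2, 1], tolerance = 1e-12)
  }
})

test_that("independent pairs stay below a permutation null for the raw scores", {
  set.seed(10)
  x <- rnorm(512); y <- rnorm(512)
  raw_score <- function(a, b, m) {
    cm <- pairwise_measure(rbind(a, b), m)
    cm[2, 1] - cm[1, 2]
  }
  for (m in c("RECI", "LMFIT", "IGCI")) {
    obs <- abs(raw_score(x, y, m))
    null_vals <- vapply(1:50, function(i) {
      set.seed(100 + i)
      abs(raw_score(x, sample(y), m))
    }, numeric(1))
    expect_lte(obs, quantile(null_vals, 0.98))
  }
})

test_that("constant channels are rejected", {
  ep <- rbind(rnorm(100), rep(1, 100))
  expect_error(pairwise_measure(ep, "RECI"), "degenerate-signal")
  expect_error(phase_measure(ep, "PSI"), "degenerate-signal")
})

test_that("the full stack has 13 keyed matrices in the right categories", {
  set.seed(11)
  ep <- matrix(rnorm(5 * 512), 5, 512)
  st <- compute_stack(ep)
  expect_named(st, c("ANM", "IGCI", "CDS", "RECI", "CCE", "DI",
                     "GD", "PSI", "DTF", "DCOH", "PDC", "SGC", "LMFIT"))
  cats <- attr(st, "categories")
  expect_equal(as.integer(table(cats)[c("info", "freq", "time")]),
               c(6L, 6L, 1L))
  for (m in st) {
    expect_equal(dim(m), c(5, 5))
    expect_true(all(m >= 0))
    expect_equal(unname(diag(m)), rep(0, 5))
    expect_true(all(is.finite(m)))
  }
})

test_that("planted coupling raises DTF above the independent-noise level", {
  set.seed(12)
  mask <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  cfg <- cohort_config(sink_gain = 0.6, base_gain = 0.1, fs_native = 256)
  planted_means <- null_means <- numeric(5)
  for (s in 1:5) {
    mm <- make_var_model(6, mask, "interictal", cfg, seed = s)
    rec <- simulate_recording(mm$model, 4, 0, seed = s)
    sp <- spectral_transfer(fit_mvar(rec$samples[, 1:512]))
    planted_means[s] <- mean(mvar_measure(sp, "DTF"))
    ep0 <- matrix(rnorm(6 * 512), 6, 512)
    sp0 <- spectral_transfer(fit_mvar(ep0))
    null_means[s] <- mean(mvar_measure(sp0, "DTF"))
  }
  expect_gt(mean(planted_means), mean(null_means))
})
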