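# Graph node metrics against hand-computed values and brute-force oracles,
# and the feature-table assembly.

test_that("strengths are plain row/column sums with conservation", {
  C <- matrix(c(0, 1, 0,
                2, 0, 3,
                0, 0, 0), 3, 3, byrow = FALSE)
  # written column-major: C[1,2]=2 etc. Use the spec example directly:
  C <- rbind(c(0, 2, 0), c(1, 0, 0), c(0, 3, 0))
  s <- node_strengths(C)
  expect_equal(unname(s$in_strength), c(2, 1, 3))
  expect_equal(unname(s$out_strength), c(1, 5, 0))
  expect_equal(sum(s$in_strength), sum(s$out_strength))
  z <- node_strengths(matrix(0, 4, 4))
  expect_true(all(z$in_strength == 0) && all(z$out_strength == 0))
  set.seed(1)
  R <- random_conn_matrix(6, seed = 3)
  sr <- node_strengths(R)
  expect_equal(sum(sr$in_strength), sum(sr$out_strength))
})

test_that("mean first passage time matches closed forms and value iteration", {
  # 2-node deterministic swap: one step from the other node
  swap <- rbind(c(0, 1), c(1, 0))
  expect_equal(unname(mean_first_passage(swap)), c(1, 1))
  # directed 3-cycle: hitting times 1 and 2 -> mean 1.5 everywhere
  cyc <- matrix(0, 3, 3)
  cyc[2, 1] <- cyc[3, 2] <- cyc[1, 3] <- 1   # walk 1 -> 2 -> 3 -> 1
  expect_equal(unname(mean_first_passage(cyc)), rep(1.5, 3))
  # random 5-node matrices vs an independent value-iteration oracle
  for (s in 1:5) {
    C <- random_conn_matrix(5, density = 0.8, seed = s)
    expect_equal(mean_first_passage(C), oracle_mfpt(C), tolerance = 1e-8)
  }
})

test_that("mean first passage time agrees with Monte-Carlo hitting times", {
  C <- random_conn_matrix(4, density = 0.9, seed = 7)
  exact <- mean_first_passage(C)
  mc <- vapply(1:4, function(k) oracle_mfpt_mc(C, k, n_walkers = 4000,
                                               seed = k), numeric(1))
  expect_equal(exact, mc, tolerance = 0.05)
})

test_that("weighted-directed clustering matches the triple-loop oracle", {
  expect_equal(unname(clustering_wd(matrix(0, 4, 4))), rep(0, 4))
  # complete directed triangle with unit weights clusters perfectly
  K3 <- matrix(1, 3, 3); diag(K3) <- 0
  expect_equal(unname(clustering_wd(K3)), rep(1, 3))
  for (s in 1:10) {
    C <- random_conn_matrix(6, density = 0.5, seed = 20 + s)
    expect_equal(clustering_wd(C), oracle_clustering(C), tolerance = 1e-12)
  }
})

test_that("eccentricity and betweenness match hand enumeration on a 3-cycle", {
  cyc <- matrix(0, 3, 3)
  cyc[2, 1] <- cyc[3, 2] <- cyc[1, 3] <- 1
  # unit weights -> lengths 1; d(i, i+1) = 1, d(i, i+2) = 2
  expect_equal(unname(node_eccentricity(cyc)), rep(2, 3))
  # each node is the interior of exactly one of the 6 ordered shortest paths:
  # 1/((N-1)(N-2)) = 1/2 each
  expect_equal(unname(node_betweenness(cyc)), rep(0.5, 3))
})

test_that("a star centre carries all shortest paths", {
  N <- 5
  star <- matrix(0, N, N)
  for (leaf in 2:N) {         # centre 1 <-> leaves
    star[leaf, 1] <- 1        # 1 -> leaf
    star[1, leaf] <- 1        # leaf -> 1
  }
  bc <- node_betweenness(star)
  expect_equal(bc[[1]], 1)
  expect_equal(unname(bc[-1]), rep(0, N - 1))
})

test_that("path metrics match Floyd-Warshall and exhaustive enumeration", {
  for (s in 1:8) {
    C <- random_conn_matrix(7, density = 0.4, seed = 40 + s)
    if (max(C) == 0) next
    D_fw <- oracle_floyd_warshall(C)
    D_pkg <- sozflow:::path_lengths(C)
    expect_lt(max(abs(D_fw - D_pkg)[is.finite(D_fw)]), 1e-12)
    expect_identical(is.finite(D_fw), is.finite(unname(D_pkg)))
    expect_equal(unname(node_betweenness(C)), oracle_betweenness(C),
                 tolerance = 1e-12)
  }
})

test_that("unreachable nodes get the documented eccentricity imputation", {
  C <- matrix(0, 4, 4)
  C[2, 1] <- 1; C[3, 2] <- 1      # 1 -> 2 -> 3; node 4 isolated
  ecc <- node_eccentricity(C)
  expect_equal(ecc[[1]], 2)       # reaches 3 in two unit steps
  expect_equal(ecc[[4]], max(ecc[1:3]))  # imputed with the graph max
  expect_error(node_betweenness(matrix(0, 2, 2)), "graph-too-small")
})

test_that("metrics scale the way strengths and shape metrics should", {
  C <- random_conn_matrix(6, density = 0.7, seed = 60)
  k <- 3.7
  s1 <- node_strengths(C); s2 <- node_strengths(k * C)
  expect_equal(s2$in_strength, k * s1$in_strength)
  expect_equal(s2$out_strength, k * s1$out_strength)
  # scale-invariant after the internal [0,1] rescaling
  expect_equal(clustering_wd(k * C), clustering_wd(C))
  expect_equal(node_betweenness(k * C), node_betweenness(C))
  expect_equal(node_eccentricity(k * C), node_eccentricity(C))
  expect_equal(mean_first_passage(k * C), mean_first_passage(C))
})

test_that("feature tables have 78 measure-major columns and average runs", {
  set.seed(2)
  ep <- matrix(rnorm(5 * 512), 5, 512)
  st <- compute_stack(ep)
  soz <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  tab1 <- build_feature_table(list(st), list(1:5), soz, "ptA")
  fc <- sozflow:::feature_cols(tab1)
  expect_length(fc, 78)
  expect_equal(fc[1:6], paste0("ANM__", c("in_strength", "out_strength",
                                          "first_passage", "clustering",
                                          "eccentricity", "betweenness")))
  expect_equal(nrow(tab1), 5)
  expect_identical(tab1$soz, soz)
  expect_true(all(is.finite(as.matrix(tab1[fc]))))
  # averaging identities: one stack = raw metrics; duplicated stack = same
  tab2 <- build_feature_table(list(st, st), list(1:5, 1:5), soz, "ptA")
  expect_equal(tab2[fc], tab1[fc])
  # metric columns line up with direct computation
  expect_equal(unname(tab1[["DTF__in_strength"]]),
               unname(rowSums(st$DTF)))
})

test_that("contacts missing from some runs are averaged over their runs only", {
  set.seed(3)
  ep <- matrix(rnorm(5 * 512), 5, 512)
  st_full <- compute_stack(ep, measures = c("DTF", "LMFIT"))
  st_sub <- compute_stack(ep[1:4, ], measures = c("DTF", "LMFIT"))
  soz <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  tab <- build_feature_table(list(st_full, st_sub), list(1:5, 1:4), soz, "ptB")
  expect_equal(nrow(tab), 5)
  # contact 5 only appears in the first stack
  full_only <- build_feature_table(list(st_full), list(1:5), soz, "ptB")
  fc <- sozflow:::feature_cols(tab)
  expect_equal(unname(unlist(tab[tab$contact == 5, fc])),
               unname(unlist(full_only[full_only$contact == 5, fc])))
})
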