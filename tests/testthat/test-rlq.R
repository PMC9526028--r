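test_that("correspondence analysis: degenerate and diagnostic cases", {
  ## perfect association: diagonal table has a single eigenvalue 1
  ca <- correspondence_analysis(diag(c(5, 5)))
  expect_equal(ca$eig, 1)
  ## independence: rank-1 outer product of margins -> no positive eigenvalues
  L <- outer(c(1, 2, 3), c(2, 5))
  expect_equal(length(correspondence_analysis(L)$eig), 0L)
  ## errors
  expect_error(correspondence_analysis(rbind(c(0, 0), c(1, 2))), "all-zero")
  expect_error(correspondence_analysis(matrix(0, 2, 2)), "total abundance")
})

test_that("correspondence analysis matches ade4 and satisfies score identities", {
  set.seed(61)
  for (rep in 1:5) {
    cm <- random_community(12, 7)
    ca <- correspondence_analysis(cm)
    ref <- ade4::dudi.coa(as.data.frame(cm$abundance), scannf = FALSE, nf = 6)
    expect_equal(ca$eig, ref$eig, tolerance = 1e-10)
    ## masses sum to 1; eigenvalues bounded by 1
    expect_equal(sum(ca$row_weights), 1)
    expect_equal(sum(ca$col_weights), 1)
    expect_true(all(ca$eig <= 1 + 1e-10))
    ## weighted mean 0 and weighted variance = eigenvalue for row scores
    wm <- colSums(ca$row_weights * ca$row_scores)
    expect_equal(unname(wm), rep(0, length(ca$eig)), tolerance = 1e-10)
    wv <- colSums(ca$row_weights * ca$row_scores^2)
    expect_equal(unname(wv), ca$eig, tolerance = 1e-10)
  }
})

test_that("weighted_pca_env normalizes under the CA row masses", {
  set.seed(62)
  cm <- random_community(15, 6)
  ca <- correspondence_analysis(cm)
  R <- data.frame(a = rnorm(15), b = runif(15), c = rnorm(15, 5, 2))
  trip <- weighted_pca_env(R, ca$row_weights)
  expect_equal(unname(colSums(trip$row_weights * trip$Z)), rep(0, 3),
               tolerance = 1e-10)
  expect_equal(unname(colSums(trip$row_weights * trip$Z^2)), rep(1, 3),
               tolerance = 1e-10)
  ## equal weights reduce to plain z-scores (population sd)
  w <- rep(1 / 15, 15)
  tripe <- weighted_pca_env(R, w)
  zs <- scale(as.matrix(R)) * sqrt(15 / 14)
  expect_equal(unname(tripe$Z), matrix(as.numeric(zs), 15), tolerance = 1e-10)
  expect_error(weighted_pca_env(data.frame(a = rep(1, 15)), w), "zero weighted")
})

test_that("hill_smith reduces to weighted PCA and to MCA", {
  set.seed(63)
  w <- runif(10); w <- w / sum(w)
  ## all-quantitative: identical to weighted_pca_env
  Rq <- data.frame(a = rnorm(10), b = runif(10))
  expect_equal(hill_smith(Rq, w)$Z, weighted_pca_env(Rq, w)$Z,
               tolerance = 1e-12)
  ## all-nominal 6x2 toy: triplet eigenvalues equal ade4 MCA eigenvalues
  Qn <- data.frame(f1 = factor(c("a", "a", "b", "b", "c", "c")),
                   f2 = factor(c("x", "y", "x", "y", "x", "y")))
  w6 <- rep(1 / 6, 6)
  ## ade4's MCA divides each variable block's column weights by the number
  ## of variables K, so its eigenvalues are ours scaled by 1/K
  K <- ncol(Qn)
  mine <- triplet_eigenvalues(hill_smith(Qn, w6)) / K
  ref <- ade4::dudi.acm(Qn, scannf = FALSE, nf = 4)$eig
  expect_equal(sort(mine, decreasing = TRUE), sort(ref[ref > 1e-10],
                                                   decreasing = TRUE),
               tolerance = 1e-10)
  ## relabeling nominal levels leaves downstream eigenvalues unchanged
  Qr <- data.frame(f1 = factor(c("zz", "zz", "qq", "qq", "mm", "mm")),
                   f2 = Qn$f2)
  expect_equal(sort(triplet_eigenvalues(hill_smith(Qr, w6)) / K), sort(mine),
               tolerance = 1e-10)
})

test_that("rlq matches ade4 on mixed data and satisfies the trace identity", {
  set.seed(64)
  for (rep in 1:3) {
    cm <- random_community(20, 9)
    R <- data.frame(x1 = rnorm(20), x2 = runif(20), x3 = rnorm(20))
    Q <- data.frame(size = rnorm(9),
                    diet = factor(sample(letters[1:3], 9, TRUE)),
                    rankv = rnorm(9))
    ca <- correspondence_analysis(cm)
    env <- weighted_pca_env(R, ca$row_weights)
    trip <- hill_smith(Q, ca$col_weights)
    out <- rlq(env, ca, trip)
    coaL <- ade4::dudi.coa(as.data.frame(cm$abundance), scannf = FALSE, nf = 5)
    pcaR <- ade4::dudi.pca(R, row.w = coaL$lw, scannf = FALSE, nf = 3)
    hsQ <- ade4::dudi.hillsmith(Q, row.w = coaL$cw, scannf = FALSE, nf = 3)
    ref <- ade4::rlq(pcaR, coaL, hsQ, scannf = FALSE, nf = 2)
    expect_equal(out$eig, ref$eig, tolerance = 1e-8)
    expect_equal(out$total_coinertia, sum(ref$eig), tolerance = 1e-10)
    ## trace identity: sum of eigenvalues = metric-weighted norm of M
    A2 <- sum((sweep(sweep(out$cross, 1, sqrt(env$col_metric), "*"),
                     2, sqrt(trip$col_metric), "*"))^2)
    expect_equal(sum(out$eig), A2, tolerance = 1e-8)
  }
})

test_that("1-env/1-trait leading eigenvalue equals the squared fourth-corner statistic", {
  set.seed(65)
  for (rep in 1:5) {
    cm <- random_community(12, 6)
    ev <- rnorm(12); tv <- rnorm(6)
    ca <- correspondence_analysis(cm)
    env <- weighted_pca_env(data.frame(e = ev), ca$row_weights)
    trip <- hill_smith(data.frame(t = tv), ca$col_weights)
    out <- rlq(env, ca, trip)
    fc <- fourth_corner_stat(cm, ev, tv)
    expect_equal(out$eig[1], fc^2, tolerance = 1e-10)
  }
})

test_that("rlq degenerate inputs error and co-inertia is rotation invariant", {
  set.seed(66)
  cm <- random_community(10, 5)
  ca <- correspondence_analysis(cm)
  expect_error(hill_smith(data.frame(t = rep(1, 5)), ca$col_weights),
               "zero weighted variance")
  R <- matrix(rnorm(30), 10, 3)
  env1 <- weighted_pca_env(as.data.frame(R), ca$row_weights)
  trip <- hill_smith(data.frame(t = rnorm(5)), ca$col_weights)
  t1 <- rlq(env1, ca, trip)$total_coinertia
  ## orthogonal rotation of the standardized env columns
  qrot <- qr.Q(qr(matrix(rnorm(9), 3)))
  env2 <- env1
  env2$Z <- env1$Z %*% qrot
  t2 <- rlq(env2, ca, trip)$total_coinertia
  expect_equal(t1, t2, tolerance = 1e-10)
  ## simultaneous reordering of sites across L and R leaves eigenvalues unchanged
  ord <- sample(10)
  cm2 <- community_matrix(cm$abundance[ord, ], site_ids = cm$site_ids[ord],
                          species_ids = cm$species_ids)
  ca2 <- correspondence_analysis(cm2)
  env2p <- weighted_pca_env(as.data.frame(R[ord, ]), ca2$row_weights)
  trip2 <- hill_smith(data.frame(t = trip$Z[, 1]), ca2$col_weights)
  trip1 <- hill_smith(data.frame(t = trip$Z[, 1]), ca$col_weights)
  expect_equal(rlq(env2p, ca2, trip2)$eig, rlq(env1, ca, trip1)$eig,
               tolerance = 1e-10)
})

test_that("permutation tests: bounds, power construction, sequential combine", {
  set.seed(67)
  ## strongly coupled toy: trait equals mean environment of occupied sites
  n_site <- 20; n_sp <- 10
  ev <- seq(0, 1, length.out = n_site)
  ab <- matrix(0L, n_site, n_sp)
  opt <- seq(0, 1, length.out = n_sp)
  for (j in seq_len(n_sp)) {
    near <- order(abs(ev - opt[j]))[1:5]
    ab[near, j] <- rpois(5, 4) + 1L
  }
  cm <- community_matrix(ab)
  tv <- sapply(seq_len(n_sp), function(j) mean(ev[ab[, j] > 0]))
  st <- data.frame(env = ev)
  tt <- trait_table(data.frame(t = tv), species_ids = cm$species_ids)
  t2 <- rlq_permutation_test(cm, st, tt, "model2", n_perm = 999, seed = 1)
  t4 <- rlq_permutation_test(cm, st, tt, "model4", n_perm = 999, seed = 2)
  expect_lte(sequential_combine(t2$p, t4$p), 0.01)
  expect_gte(t2$p, 1 / 1000)
  ## combined rule
  expect_equal(sequential_combine(0.01, 0.99), 0.99)
  expect_equal(sequential_combine(0.03, 0.04), 0.04)
  ## decision agrees with the reject-both rule on random p-pairs
  set.seed(68)
  p2 <- runif(1000); p4 <- runif(1000)
  comb <- mapply(sequential_combine, p2, p4)
  expect_equal(comb < 0.05, p2 < 0.05 & p4 < 0.05)
  expect_error(rlq_permutation_test(cm, st, tt, "model2", n_perm = 0), "n_perm")
})

test_that("model-2 permutation distribution is invariant to affine env transforms", {
  set.seed(69)
  cm <- random_community(12, 6)
  st <- data.frame(e1 = rnorm(12), e2 = runif(12))
  tt <- trait_table(data.frame(t = rnorm(6),
                               f = factor(sample(c("u", "v"), 6, TRUE))),
                    species_ids = cm$species_ids)
  t_a <- rlq_permutation_test(cm, st, tt, "model2", n_perm = 99, seed = 3)
  st2 <- data.frame(e1 = 5 * st$e1 - 2, e2 = -0.5 * st$e2 + 7)
  t_b <- rlq_permutation_test(cm, st2, tt, "model2", n_perm = 99, seed = 3)
  expect_equal(t_a$observed, t_b$observed, tolerance = 1e-10)
  expect_equal(t_a$perm, t_b$perm, tolerance = 1e-10)
  expect_equal(t_a$p, t_b$p)
})
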