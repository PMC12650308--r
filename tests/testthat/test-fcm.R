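test_that("membership update matches a literal transcription of the formula", {
  set.seed(3)
  x <- matrix(rnorm(15), 5, 3)
  v <- matrix(rnorm(9), 3, 3)
  m <- 2
  u <- update_memberships(x, v, m)
  # brute-force oracle: direct double loop over the defining formula
  oracle <- matrix(0, 5, 3)
  for (i in 1:5) {
    for (k in 1:3) {
      dik <- sqrt(sum((x[i, ] - v[k, ])^2))
      s <- 0
      for (j in 1:3) {
        dij <- sqrt(sum((x[i, ] - v[j, ])^2))
        s <- s + (dik / dij)^(2 / (m - 1))
      }
      oracle[i, k] <- 1 / s
    }
  }
  expect_lt(max(abs(u - oracle)), 1e-12)
  expect_equal(rowSums(u), rep(1, 5), tolerance = 1e-12)
})

test_that("membership update handles symmetry and coincidence", {
  v <- rbind(c(-1, 0), c(1, 0))
  expect_equal(
    as.numeric(update_memberships(matrix(c(0, 0), 1), v, 2)),
    c(0.5, 0.5)
  )
  expect_equal(
    as.numeric(update_memberships(matrix(c(-1, 0), 1), v, 3)),
    c(1, 0)
  )
  # coincident with two identical centroids: split equally
  v2 <- rbind(c(1, 1), c(1, 1), c(5, 5))
  expect_equal(
    as.numeric(update_memberships(matrix(c(1, 1), 1), v2, 2)),
    c(0.5, 0.5, 0)
  )
  expect_error(update_memberships(matrix(0, 1, 2), v, m = 1), "m must be > 1")
})

test_that("centroid update matches the direct-summation oracle", {
  set.seed(4)
  x <- matrix(rnorm(24), 8, 3)
  u <- matrix(runif(16), 8, 2)
  u <- u / rowSums(u)
  m <- 1.7
  v <- update_centroids(x, u, m)
  oracle <- t(sapply(1:2, function(k) {
    colSums(u[, k]^m * x) / sum(u[, k]^m)
  }))
  expect_lt(max(abs(v - oracle)), 1e-12)
  # hard memberships give per-cluster means
  uh <- cbind(rep(c(1, 0), each = 4), rep(c(0, 1), each = 4))
  vh <- update_centroids(x, uh, 2)
  expect_equal(vh[1, ], colMeans(x[1:4, ]))
  expect_equal(vh[2, ], colMeans(x[5:8, ]))
})

test_that("Xie-Beni matches longhand arithmetic and is scale invariant", {
  # 4 points in two tight pairs, centroids at the pair centres
  xp <- rbind(c(0, 0), c(0, 1), c(4, 0), c(4, 1))
  vp <- rbind(c(0, 0.5), c(4, 0.5))
  up <- update_memberships(xp, vp, 2)
  # longhand: every point at squared distance 0.25 from its centre, far
  # memberships small; numerator = sum u^2 d2, denominator = 4 * 16
  num <- sum(up^2 * ((outer(rowSums(xp^2), rowSums(vp^2), `+`) - 2 * xp %*% t(vp))))
  expect_equal(xie_beni(xp, up, vp, 2), num / (4 * 16), tolerance = 1e-12)
  # scaling x and v by alpha leaves XB unchanged
  a <- 3.7
  expect_equal(
    xie_beni(a * xp, up, a * vp, 2),
    xie_beni(xp, up, vp, 2),
    tolerance = 1e-12
  )
  # hard memberships with points on the centroids: XB = 0
  xh <- rbind(c(0, 0), c(4, 4))
  uh <- diag(2)
  expect_equal(xie_beni(xh, uh, xh, 2), 0)
  expect_error(xie_beni(xp, up, rbind(vp[1, ], vp[1, ]), 2), "Duplicate centroids")
})

test_that("fit_fcm separates point clouds, is deterministic, and traces J monotonely", {
  set.seed(5)
  x <- rbind(
    matrix(rnorm(40, 0, 0.4), 10),
    matrix(rnorm(40, 6, 0.4), 10)
  )
  f1 <- fit_fcm(x, c = 2, m = 2, seed = 7)
  f2 <- fit_fcm(x, c = 2, m = 2, seed = 7)
  expect_identical(f1$memberships, f2$memberships)
  hard <- apply(f1$memberships, 1, which.max)
  expect_equal(length(unique(hard[1:10])), 1)
  expect_equal(length(unique(hard[11:20])), 1)
  expect_true(all(diff(f1$objective_trace) <= 1e-8))
  expect_true(all(f1$memberships >= 0 & f1$memberships <= 1))
  expect_equal(rowSums(f1$memberships), rep(1, 20), tolerance = 1e-9)
  expect_error(fit_fcm(x, c = 2, m = 1, seed = 1), "m must be > 1")
  expect_error(fit_fcm(cbind(x, NA), c = 2, m = 2), "Non-finite")
  expect_error(fit_fcm(x, c = 25, m = 2), "more features than clusters")
})

test_that("m near 1 recovers the hard nearest-centroid assignment", {
  set.seed(6)
  x <- rbind(
    matrix(rnorm(30, 0, 0.3), 10),
    matrix(rnorm(30, 5, 0.3), 10)
  )
  fit <- fit_fcm(x, c = 2, m = 1.01, seed = 2)
  d2 <- (outer(rowSums(x^2), rowSums(fit$centroids^2), `+`) -
    2 * x %*% t(fit$centroids))
  expect_equal(
    apply(fit$memberships, 1, which.max),
    apply(d2, 1, which.min)
  )
  expect_gt(min(apply(fit$memberships, 1, max)), 0.999)
})

test_that("multi-start reaches the global objective on small instances", {
  set.seed(8)
  for (rep in 1:3) {
    xs <- matrix(rnorm(16), 8, 2)
    fbest <- fit_fcm(xs, c = 2, m = 2, seed = 1, n_init = 10)
    js <- vapply(
      1:100,
      function(s) fit_fcm(xs, c = 2, m = 2, seed = s, n_init = 1)$objective,
      numeric(1)
    )
    expect_lt(fbest$objective - min(js), 1e-9)
  }
})

test_that("objective agrees with an independent fuzzy c-means implementation", {
  skip_if_not_installed("e1071")
  set.seed(9)
  x <- rbind(
    matrix(rnorm(60, 0, 0.5), 20),
    matrix(rnorm(60, 5, 0.5), 20)
  )
  ours <- fit_fcm(x, c = 2, m = 2, seed = 1)
  ref <- e1071::cmeans(x, 2, m = 2, iter.max = 300)
  j_ref <- sum(ref$membership^2 *
    (outer(rowSums(x^2), rowSums(ref$centers^2), `+`) - 2 * x %*% t(ref$centers)))
  expect_equal(ours$objective, j_ref, tolerance = 1e-6)
})

test_that("planted archetype partitions are recovered perfectly at zero noise", {
  ft <- archetype_table(copies = 25)
  pm <- standardize(pool_subjects(ft))
  fit <- fit_fcm(pm$values, c = 16, m = 1.5, seed = 3, n_init = 5)
  truth <- ft$features$archetype[match(rownames(pm$values), ft$features$feature_id)]
  hard <- apply(fit$memberships, 1, which.max)
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(hard, truth), 1.0)
})

test_that("parameter selection scores a grid and breaks ties deterministically", {
  set.seed(10)
  x <- rbind(
    matrix(rnorm(60, 0, 0.3), 20),
    matrix(rnorm(60, 4, 0.3), 20),
    matrix(rnorm(60, 8, 0.3), 20)
  )
  s1 <- select_parameters(x, c_grid = c(2, 3), m_grid = c(1.5, 2), seed = 1, n_init = 3)
  s2 <- select_parameters(x, c_grid = c(2, 3), m_grid = c(1.5, 2), seed = 1, n_init = 3)
  expect_identical(s1$xb_table, s2$xb_table)
  expect_equal(s1$c_opt, 3)
  expect_equal(nrow(s1$xb_table), 4)
  expect_equal(sum(s1$xb_table$selected), 1)
  expect_error(select_parameters(x, c_grid = 2, m_grid = c(0.9, 2)), "> 1")
  # single blob: runs without crashing, full table recorded
  blob <- matrix(rnorm(100), 50, 2)
  sb <- select_parameters(blob, c_grid = c(2, 3), m_grid = 2, seed = 1, n_init = 2)
  expect_equal(nrow(sb$xb_table), 2)
})

test_that("broom-style accessors expose the fit", {
  set.seed(11)
  x <- rbind(matrix(rnorm(40, 0), 10), matrix(rnorm(40, 6), 10))
  rownames(x) <- sprintf("F%05d", 1:20)
  fit <- fit_fcm(x, c = 2, m = 2, seed = 1)
  g <- glance(fit)
  expect_equal(g$c, 2)
  expect_equal(g$n, 20)
  td <- tidy(fit)
  expect_equal(nrow(td), 2)
  expect_equal(sum(td$membership_mass), 20, tolerance = 1e-9)
  au <- augment(fit)
  expect_equal(nrow(au), 20)
  expect_true(all(au$max_membership > 0.5))
})
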