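test_that("spearman colocalization has the rank-correlation properties", {
  x <- pm(c(1, 2, 3))
  expect_equal(spearman_coloc(x, x)$rho, 1)
  expect_equal(spearman_coloc(x, pm(c(3, 1, 2)))$rho, -0.5)
  # rank invariance under monotone transforms
  y <- pm(rnorm(30))
  expect_equal(spearman_coloc(y, pm(exp(2 * y$values)))$rho, 1)
  expect_equal(spearman_coloc(y, y)$fisher_z, atanh(1 - 1e-15))
  expect_error(spearman_coloc(x, pm(rep(1, 3))), "constant")
})

test_that("colocalization trajectories cover the full age/percentile grid", {
  g <- fx_small_geometry()
  lib <- make_atlas_library(g, 3, length_scale = 10, seed = 2)
  built <- make_ct_trajectories(g, lib, ground_truth(c(1, 0, 0),
                                                     noise_sd = 0,
                                                     seed = 1),
                                age_grid = seq(5, 30, 0.5))
  rho <- coloc_trajectory(lib, built$trajectories)
  expect_identical(dim(rho), c(3L, 51L, 7L, 3L))
  expect_identical(dimnames(rho)[[4]], c("female", "male", "average"))

  # an atlas that is a monotone transform of CT at every age: rho = 1
  tr <- built$trajectories
  atlas_ct <- zscore_map(parcel_map(rank(tr$ct[, 1, 4, 1]),
                                    tr$parcel_ids, tr$hemisphere,
                                    name = "ctlike"))
  # build trajectories whose spatial pattern is age-constant
  tr2 <- tr
  for (a in seq_along(tr$ages)) for (p in 1:7) for (s in 1:2)
    tr2$ct[, a, p, s] <- tr$ct[, 1, 4, 1] * (1 + 0.001 * a)
  rho2 <- coloc_trajectory(atlas_set(list(atlas_ct)), tr2)
  expect_true(all(abs(rho2 - 1) < 1e-12))
})

test_that("univariate scans equal squared correlations with calibrated minima", {
  g <- fx_geometry()
  d <- fx_distances()
  atlas <- sample_gp_map(g, 15, seed = 1, name = "A")
  ens <- generate_surrogates(atlas, d, 99, seed = 2)

  # change identical to the atlas: R2 = 1, p at the minimum
  ch <- relative_change(pm_base <- parcel_map(rep(2, 148), g$parcel_ids),
                        parcel_map(2 * (1 + 0.01 * atlas$values +
                                          0.05), g$parcel_ids),
                        window = c(10, 15))
  res <- univariate_scan(atlas, list(ch), ens)
  expect_equal(res$r2, 1, tolerance = 1e-9)
  expect_equal(res$p, 1 / 100)

  # R2 equals squared Pearson correlation and the lm R2, to 1e-12
  set.seed(3)
  noisy <- relative_change(pm_base,
                           parcel_map(2 * (1 + 0.01 * atlas$values +
                                             0.02 * rnorm(148) + 0.05),
                                      g$parcel_ids),
                           window = c(10, 15))
  res2 <- univariate_scan(atlas, list(noisy), ens)
  expect_equal(res2$r2, cor(atlas$values, noisy$values)^2,
               tolerance = 1e-12)
  expect_equal(res2$r2,
               summary(lm(noisy$values ~ atlas$values))$r.squared,
               tolerance = 1e-12)
  expect_identical(res2$n_nulls, 99L)
})

test_that("multivariate scans recover constructed signal exactly and stably", {
  g <- fx_geometry()
  d <- fx_distances()
  lib <- fx_library()
  nulls <- lapply(lib$maps, function(m)
    generate_surrogates(m, d, 60, seed = 30 + match(m$name,
                                                    names(lib$maps))))
  names(nulls) <- names(lib$maps)

  # exact linear combination: adjusted R2 = 1
  A <- atlas_matrix(lib)
  y <- drop(A %*% c(0.5, 0.3, rep(0, 7)))
  ch <- parcel_map(y, g$parcel_ids, name = "mix")
  attr(ch, "window") <- c(10, 15)
  res <- multivariate_scan(lib, list(ch), nulls)
  expect_equal(res$adj_r2, 1, tolerance = 1e-9)
  expect_equal(res$p, 1 / 61)

  # invariance to predictor order and affine predictor rescaling
  set.seed(4)
  y2 <- y + 0.01 * rnorm(148)
  ch2 <- parcel_map(y2, g$parcel_ids, name = "mix2")
  attr(ch2, "window") <- c(10, 15)
  base <- multivariate_scan(lib, list(ch2), nulls, n_null_iters = 1)
  perm <- sample(9)
  lib_perm <- atlas_set(lib$maps[perm])
  res_perm <- multivariate_scan(lib_perm, list(ch2), nulls,
                                n_null_iters = 1)
  expect_equal(res_perm$r2, base$r2, tolerance = 1e-12)
  scaled <- lib
  scaled$maps[[1]] <- parcel_map(5 * lib$maps[[1]]$values - 3,
                                 g$parcel_ids,
                                 name = names(lib$maps)[1])
  res_scaled <- multivariate_scan(scaled, list(ch2), nulls,
                                  n_null_iters = 1)
  expect_equal(res_scaled$r2, base$r2, tolerance = 1e-12)

  # rank-deficient designs refuse
  dup <- lib
  dup$maps[[2]] <- parcel_map(lib$maps[[1]]$values, g$parcel_ids,
                              name = names(lib$maps)[2])
  expect_error(multivariate_scan(dup, list(ch2), nulls),
               "rank-deficient")
  # missing ensemble named
  expect_error(multivariate_scan(lib, list(ch2), nulls[-3]),
               names(lib$maps)[3])
})

test_that("adding a pure-noise predictor does not inflate adjusted R2 on average", {
  g <- fx_small_geometry()
  set.seed(5)
  n <- 32
  diffs <- replicate(200, {
    X <- matrix(rnorm(n * 3), n, 3)
    y <- X[, 1] + rnorm(n)
    r2a <- summary(lm(y ~ X[, 1:2]))$adj.r.squared
    r2b <- summary(lm(y ~ X))$adj.r.squared
    r2b - r2a
  })
  expect_lt(mean(diffs), 0.01)
})
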