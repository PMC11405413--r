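test_that("parcel geometry is seeded, sized, and hemispherically split", {
  g <- make_parcel_geometry(74, seed = 1)
  expect_length(g$parcel_ids, 148)
  expect_identical(g$centroids, make_parcel_geometry(74, seed = 1)$centroids)
  expect_false(identical(g$centroids,
                         make_parcel_geometry(74, seed = 2)$centroids))
  # disjoint half-spaces along x
  expect_true(all(g$centroids[g$hemisphere == "left", 1] < 0))
  expect_true(all(g$centroids[g$hemisphere == "right", 1] > 0))
  expect_error(make_parcel_geometry(2), ">= 4")
})

test_that("GP maps are seed-deterministic with the stated autocorrelation limits", {
  g <- fx_small_geometry()
  expect_error(sample_gp_map(g, -1), "positive")
  m1 <- sample_gp_map(g, 20, seed = 5)
  expect_identical(m1$values, sample_gp_map(g, 20, seed = 5)$values)

  d <- pairwise_distances(g)
  # long length scale: neighbors much more alike than under no
  # autocorrelation (for the exponential kernel the z-scored lag-1
  # semivariance scales with lag / extent rather than vanishing)
  g1_long <- mean(vapply(1:20, function(s)
    empirical_variogram(sample_gp_map(g, 1000, seed = s), d,
                        n_bins = 5)$semivariance[1], numeric(1)))
  g1_short <- mean(vapply(1:20, function(s)
    empirical_variogram(sample_gp_map(g, 1e-3, seed = s), d,
                        n_bins = 5)$semivariance[1], numeric(1)))
  expect_lt(g1_long, 0.7 * g1_short)
  expect_lt(abs(g1_short - 1), 0.15)

  # vanishing length scale: no neighbor correlation (mean ~ 0 +- 0.1)
  nn <- apply(d + diag(Inf, nrow(d)), 1, which.min)
  r <- vapply(1:60, function(s) {
    v <- sample_gp_map(g, 1e-3, seed = s)$values
    cor(v, v[nn])
  }, numeric(1))
  expect_lt(abs(mean(r)), 0.1)
})

test_that("atlas libraries hit the requested cross-correlation structure", {
  g <- fx_geometry()
  expect_error(make_atlas_library(g, 0), "n_maps")
  expect_error(make_atlas_library(g, 2, cross_correlation = 1.2),
               "cross_correlation")
  expect_length(make_atlas_library(g, 1, seed = 1)$maps, 1)

  lib0 <- make_atlas_library(g, 20, length_scale = 15,
                             cross_correlation = 0, seed = 2)
  C0 <- cor(atlas_matrix(lib0))
  expect_lt(mean(abs(C0[upper.tri(C0)])), 0.2)

  lib9 <- make_atlas_library(g, 20, length_scale = 15,
                             cross_correlation = 0.9, seed = 3)
  ev <- eigen(cor(atlas_matrix(lib9)), only.values = TRUE)$values
  expect_gt(ev[1] / 20, 0.6)   # first PC explains > 60% of variance

  lib5 <- make_atlas_library(g, 10, length_scale = 15,
                             cross_correlation = 0.5, seed = 4)
  C5 <- cor(atlas_matrix(lib5))
  expect_lt(abs(mean(C5[upper.tri(C5)]) - 0.5), 0.15)
})

test_that("CT trajectories realize the designed change-map mixture", {
  g <- fx_geometry()
  lib <- fx_library()
  win <- build_windows(10, 15, 5, 1)

  # all weights zero, no noise: spatially uniform relative change
  flat <- make_ct_trajectories(g, lib, ground_truth(rep(0, 9),
                                                    noise_sd = 0,
                                                    seed = 1))
  ch <- extract_change_series(flat$trajectories, win)[[1]]
  expect_lt(diff(range(ch$values)), 1e-12)

  # single atlas, no noise: change map correlates 1 with that atlas
  w1 <- c(1, rep(0, 8))
  one <- make_ct_trajectories(g, lib, ground_truth(w1, noise_sd = 0,
                                                   seed = 2))
  ch1 <- extract_change_series(one$trajectories, win)[[1]]
  expect_equal(abs(cor(ch1$values, lib$maps[[1]]$values)), 1,
               tolerance = 1e-9)
  expect_equal(one$truth$construction_r2, 1, tolerance = 1e-12)

  # target construction R^2 recovered by regression on the true atlases
  wts <- c(0.5, 0.3, rep(0, 7))
  r2s <- vapply(1:10, function(s) {
    built <- make_ct_trajectories(g, lib, ground_truth(
      wts, target_r2 = 0.6, seed = s))
    chs <- extract_change_series(built$trajectories, win)[[1]]
    A <- atlas_matrix(lib)[, 1:2]
    summary(lm(chs$values ~ A))$r.squared
  }, numeric(1))
  expect_true(all(abs(r2s - 0.6) < 0.1))

  expect_error(make_ct_trajectories(g, lib, ground_truth(c(1, 0),
                                                         noise_sd = 0)),
               "does not match")
  # CT positive everywhere, default grid has 171 points
  expect_true(all(flat$trajectories$ct > 0))
  expect_length(flat$trajectories$ages, 171)
})

test_that("expression generator matches its null and signal constructions", {
  expect_error(make_expression_dataset(n_nonbrain_pool = 0), "pool")
  expect_error(make_expression_dataset(peak_period = c(0.1, 30)),
               "peak_period")
  ds <- make_expression_dataset(n_subjects = 33, n_nonbrain_pool = 100,
                                seed = 1)
  expect_identical(nrow(ds$subjects), 33L)
  expect_identical(nrow(ds$expression), 33L)
  expect_true(all(ds$subjects$age > 0))
  # pool disjoint from brain gene sets
  expect_length(intersect(unlist(ds$gene_sets), ds$nonbrain_pool), 0)

  # effect 0: signal and flat genes indistinguishable in in/out elevation
  null_ds <- make_expression_dataset(effect_size = 0,
                                     n_nonbrain_pool = 50, seed = 2)
  stat <- function(data, gene) {
    curve <- loess_trajectory(gene_set_trajectory(data, gene))
    period_statistics(curve, data$peak_period)$ratio
  }
  r_sig <- vapply(null_ds$signal_genes, function(gg)
    stat(null_ds, gg), numeric(1))
  r_flat <- vapply(null_ds$flat_genes, function(gg)
    stat(null_ds, gg), numeric(1))
  expect_lt(abs(mean(r_sig) - mean(r_flat)), 0.1)
  expect_lt(abs(mean(r_sig) - 1), 0.1)
})

test_that("cohort generator reduces to the population map at zero noise", {
  g <- fx_small_geometry()
  lib <- make_atlas_library(g, 2, length_scale = 10, seed = 1)
  tr <- make_ct_trajectories(g, lib, ground_truth(c(0.6, 0.2),
                                                  target_r2 = 0.8,
                                                  seed = 3))$trajectories
  expect_error(make_cohort(g, tr, n_sites = 0), "n_sites")
  expect_error(make_cohort(g, tr, session_ages = 10), "2 session")
  expect_error(make_cohort(g, tr, session_ages = c(10, 12.3)),
               "age grid")

  coh0 <- make_cohort(g, tr, n_subjects = 8, n_sites = 3,
                      subject_sd = 0, site_sd = 0, noise_sd = 0,
                      session_ages = c(10, 12), seed = 4)
  pop <- cohort_average_change(coh0)
  ch <- subject_change(coh0)
  for (s in seq_along(ch))
    expect_equal(ch[[s]]$values, pop$values, tolerance = 1e-12)

  # site labels balanced within one
  coh <- make_cohort(g, tr, n_subjects = 100, n_sites = 20, seed = 5)
  expect_identical(nrow(coh$subjects), 100L)
  tab <- table(coh$subjects$site)
  expect_lte(diff(range(tab)), 1)
})
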