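# shared synthetic cohort scenario: 148 parcels, 9 atlases, mixture
# signal in the (10, 12) window
fx_cohort_scene <- function() fixture("cohort_scene", function() {
  g <- fx_geometry()
  lib <- fx_library()
  built <- make_ct_trajectories(g, lib,
                                ground_truth(c(0.5, 0.3, rep(0, 7)),
                                             target_r2 = 0.7, seed = 31),
                                target_window = c(10, 12))
  list(g = g, lib = lib, traj = built$trajectories)
})

test_that("subject change maps apply the dCT formula with exclusion logging", {
  sc <- fx_cohort_scene()
  coh <- make_cohort(sc$g, sc$traj, n_subjects = 10, n_sites = 2,
                     subject_sd = 0.02, site_sd = 0.02,
                     noise_sd = 0.01, session_ages = c(10, 12), seed = 1)
  ch <- subject_change(coh)
  expect_length(ch, 10)
  expect_equal(attr(ch, "window"), c(10, 12))
  # formula per subject
  s1 <- coh$ct[1, 1, ]; s2 <- coh$ct[1, 2, ]
  expect_equal(ch[[coh$subjects$id[1]]]$values, unname((s2 - s1) / s1),
               tolerance = 1e-12)

  # subject with a missing session is excluded and logged
  coh_na <- coh
  coh_na$ct[3, 2, ] <- NA
  expect_message(ch2 <- subject_change(coh_na), "excluded")
  expect_length(ch2, 9)
  expect_identical(attr(ch2, "excluded"), coh_na$subjects$id[3])

  expect_error(subject_change(coh, span = c("T0", "T9")), "sessions")

  # cohort-average-of-changes vs change-of-average differ only slightly
  avg_of_subj <- rowMeans(vapply(ch, function(m) m$values,
                                 numeric(148)))
  of_avg <- cohort_average_change(coh)$values
  expect_gt(cor(avg_of_subj, of_avg), 0.99)
  expect_false(isTRUE(all.equal(avg_of_subj, of_avg, tolerance = 1e-12)))
})

test_that("a zero-noise cohort reproduces the population dominance exactly", {
  sc <- fx_cohort_scene()
  coh0 <- make_cohort(sc$g, sc$traj, n_subjects = 12, n_sites = 3,
                      subject_sd = 0, site_sd = 0, noise_sd = 0,
                      session_ages = c(10, 12), seed = 2)
  ch <- subject_change(coh0)
  res <- subject_dominance(ch, sc$lib)
  expect_identical(nrow(res), 12L)
  pop <- total_dominance(sc$lib, cohort_average_change(coh0))
  pop_rank <- order(-pop$total_dominance)
  D <- attr(res, "dominance")
  for (s in seq_len(ncol(D)))
    expect_identical(order(-D[, s]), pop_rank)
  expect_equal(unname(res$r2),
               rep(pop$full_model_r2, 12), tolerance = 1e-12)
})

test_that("measurement noise attenuates subject-level R2 monotonically", {
  sc <- fx_cohort_scene()
  mean_r2 <- vapply(c(0.002, 0.01, 0.05), function(ns) {
    r2s <- vapply(1:3, function(r) {
      coh <- make_cohort(sc$g, sc$traj, n_subjects = 6, n_sites = 2,
                         subject_sd = 0.01, site_sd = 0.01,
                         noise_sd = ns, session_ages = c(10, 12),
                         seed = 100 * r + ns * 1000)
      mean(subject_dominance(subject_change(coh), sc$lib)$r2)
    }, numeric(1))
    mean(r2s)
  }, numeric(1))
  expect_true(all(diff(mean_r2) < 0))
  # and the cohort-average map outperforms the average subject
  coh <- make_cohort(sc$g, sc$traj, n_subjects = 10, n_sites = 2,
                     subject_sd = 0.02, site_sd = 0.02, noise_sd = 0.05,
                     session_ages = c(10, 12), seed = 3)
  subj_r2 <- mean(subject_dominance(subject_change(coh), sc$lib)$r2)
  avg_r2 <- total_dominance(sc$lib,
                            cohort_average_change(coh))$full_model_r2
  expect_gt(avg_r2, subj_r2)
})

test_that("the group-mean permuted-atlas test detects cohort-level signal", {
  sc <- fx_cohort_scene()
  d <- fx_distances()
  nulls <- fixture("cohort_nulls", function() {
    ne <- lapply(sc$lib$maps, function(m)
      generate_surrogates(m, d, 99,
                          seed = 50 + match(m$name, names(sc$lib$maps))))
    names(ne) <- names(sc$lib$maps)
    ne
  })
  coh <- make_cohort(sc$g, sc$traj, n_subjects = 15, n_sites = 3,
                     subject_sd = 0.02, site_sd = 0.02, noise_sd = 0.01,
                     session_ages = c(10, 12), seed = 4)
  ch <- subject_change(coh)
  gt <- group_mean_null_test(ch, sc$lib, nulls, n_null = 99)
  expect_equal(gt$p_full, 1 / 100)        # minimal p for a signal cohort
  expect_lte(gt$p_dominance[[names(sc$lib$maps)[1]]], 2 / 100)
  expect_equal(sum(gt$mean_dominance), gt$mean_r2, tolerance = 1e-10)

  expect_error(group_mean_null_test(ch[1], sc$lib, nulls), "2 subjects")
  expect_error(group_mean_null_test(ch, sc$lib, nulls, n_null = 0),
               "n_null")
})

test_that("cohort tables round-trip through the long format", {
  sc <- fx_cohort_scene()
  g <- fx_small_geometry()
  lib <- make_atlas_library(g, 2, length_scale = 10, seed = 1)
  tr <- make_ct_trajectories(g, lib, ground_truth(c(0.5, 0),
                                                  noise_sd = 0.1,
                                                  seed = 1))$trajectories
  coh <- make_cohort(g, tr, n_subjects = 5, n_sites = 2,
                     session_ages = c(10, 12), seed = 6)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort_table(coh, path)
  back <- read_cohort_table(path)
  expect_equal(back$ct, coh$ct, tolerance = 0)
  expect_identical(back$subjects$site, coh$subjects$site)
  expect_equal(back$sessions$age, coh$sessions$age)
})
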