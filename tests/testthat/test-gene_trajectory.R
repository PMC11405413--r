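test_that("gene-set trajectories average genes per subject", {
  ds <- make_expression_dataset(n_subjects = 20, n_nonbrain_pool = 30,
                                seed = 3)
  g1 <- ds$signal_genes[1]
  tr <- gene_set_trajectory(ds, g1)
  expect_identical(nrow(tr), 20L)
  expect_equal(tr$expression,
               unname(ds$expression[order(ds$subjects$age), g1]))
  # averaging a gene with itself changes nothing
  tr2 <- gene_set_trajectory(ds, c(g1, g1))
  expect_equal(tr2$expression, tr$expression)
  expect_error(gene_set_trajectory(ds, c(g1, "NOPE")), "NOPE")
  expect_error(gene_set_trajectory(ds, character(0)), "empty")
})

test_that("LOESS trajectories are exact on polynomials of the fit degree", {
  ages <- seq(1, 40, length.out = 33)
  const <- data.frame(age = ages, expression = rep(5, 33))
  cv <- loess_trajectory(const, eval_grid = seq(2, 38, 0.5))
  expect_equal(cv$expression, rep(5, 73), tolerance = 1e-9)

  lin <- data.frame(age = ages, expression = 2 + 0.3 * ages)
  lv <- loess_trajectory(lin, eval_grid = seq(5, 35, 1))
  expect_equal(lv$expression, 2 + 0.3 * lv$age, tolerance = 1e-6)

  expect_error(loess_trajectory(lin[1:5, ]), "at least 8")
  expect_error(loess_trajectory(lin, eval_grid = c(0.5, 10)),
               "outside")
})

test_that("period statistics partition the curve correctly", {
  grid <- seq(1, 50, 0.5)
  flat <- data.frame(age = grid, expression = rep(3, length(grid)))
  s <- period_statistics(flat, c(5, 20))
  expect_equal(s$ratio, 1)
  expect_equal(s$mean_in, s$mean_out)

  bump <- flat
  bump$expression <- 3 + as.numeric(grid >= 5 & grid <= 20)
  s2 <- period_statistics(bump, c(5, 20))
  expect_equal(s2$mean_in, 4)
  expect_equal(s2$mean_out, 3)
  expect_equal(s2$ratio, 4 / 3)

  expect_error(period_statistics(flat, c(0, 60)), "partition")
  expect_error(period_statistics(flat, c(20, 5)), "b > a")
})

test_that("trajectory tests separate peaked sets from the non-brain null", {
  ds <- make_expression_dataset(n_subjects = 33, n_signal_genes = 6,
                                n_flat_genes = 5, n_nonbrain_pool = 120,
                                effect_size = 3, seed = 8)
  sets <- c(
    lapply(ds$signal_genes, function(gg)
      list(genes = gg, period = ds$peak_period)),
    lapply(ds$flat_genes[1:3], function(gg)
      list(genes = gg, period = ds$peak_period)))
  names(sets) <- c(paste0("sig", 1:6), paste0("flat", 1:3))
  res <- trajectory_test(ds, sets, n_null = 99, seed = 4)
  expect_identical(nrow(res), 9L)
  # strongly peaked sets: ratio p at or near the minimum
  expect_true(all(res$p_ratio[1:6] <= 5 / 100))
  # flat brain genes are not preferentially peaked
  expect_true(mean(res$p_ratio[7:9] > 0.05) >= 2 / 3)
  # q is BH across all marker x statistic tests at once
  expect_equal(c(res$q_mean, res$q_ratio),
               p.adjust(c(res$p_mean, res$p_ratio), "BH"))

  expect_error(trajectory_test(ds, sets, n_null = 0), "n_null")
  big <- list(toolarge = list(genes = ds$nonbrain_pool, period = c(5, 30)))
  ds_small <- ds; ds_small$nonbrain_pool <- ds$nonbrain_pool[1:3]
  expect_error(trajectory_test(ds_small,
                               list(m = list(genes = ds$signal_genes,
                                             period = c(5, 30))),
                               n_null = 9),
               "smaller")
})

test_that("the mean statistic is shift-invariant but the ratio is not", {
  ds <- make_expression_dataset(n_subjects = 25, n_signal_genes = 2,
                                n_flat_genes = 2, n_nonbrain_pool = 60,
                                effect_size = 2, seed = 5)
  sets <- list(m1 = list(genes = ds$signal_genes[1],
                         period = ds$peak_period))
  r1 <- trajectory_test(ds, sets, n_null = 49, seed = 6)
  ds_shift <- ds
  ds_shift$expression <- ds$expression + 100
  r2 <- trajectory_test(ds_shift, sets, n_null = 49, seed = 6)
  expect_equal(r2$p_mean, r1$p_mean)          # shift cancels in the mean
  expect_equal(r2$mean_in - r1$mean_in, 100, tolerance = 1e-6)
  expect_false(isTRUE(all.equal(r2$ratio, r1$ratio)))  # ratio compresses
})

test_that("expression datasets round-trip through the text formats", {
  ds <- make_expression_dataset(n_subjects = 12, n_signal_genes = 3,
                                n_flat_genes = 2, n_nonbrain_pool = 10,
                                seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_expression_dataset(ds, path)
  back <- read_expression_dataset(path)
  expect_equal(unname(back$expression), unname(ds$expression),
               tolerance = 1e-12)
  expect_identical(back$nonbrain_pool, ds$nonbrain_pool)
  expect_identical(back$gene_sets[names(ds$gene_sets)[1]][[1]],
                   ds$gene_sets[[1]])
  expect_equal(back$subjects$age, ds$subjects$age, tolerance = 1e-6)
})
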