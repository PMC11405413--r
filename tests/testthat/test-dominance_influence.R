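test_that("total dominance equals the orderings-average oracle", {
  set.seed(17)
  for (p in c(2, 4, 5, 6)) {
    n <- 40
    X <- matrix(rnorm(n * p), n, p)
    y <- drop(X %*% runif(p, -1, 1)) + rnorm(n)
    maps <- lapply(seq_len(p), function(k)
      parcel_map(X[, k], sprintf("r%02d", 1:n), name = paste0("x", k)))
    res <- total_dominance(atlas_set(maps),
                           parcel_map(y, sprintf("r%02d", 1:n),
                                      name = "y"))
    oracle <- orderings_dominance_oracle(X, y)
    expect_equal(unname(res$total_dominance), oracle, tolerance = 1e-10)
    expect_equal(sum(res$total_dominance), res$full_model_r2,
                 tolerance = 1e-10)
  }
})

test_that("dominance collapses to known closed forms", {
  n <- 64
  set.seed(3)
  # p = 1: dominance is the single predictor's R2
  x <- rnorm(n); y <- x + rnorm(n)
  ids <- sprintf("r%02d", 1:n)
  res1 <- total_dominance(atlas_set(list(parcel_map(x, ids, name = "x"))),
                          parcel_map(y, ids, name = "y"))
  expect_equal(unname(res1$total_dominance), cor(x, y)^2,
               tolerance = 1e-12)

  # p = 2 exactly orthogonal: dominance_i = squared marginal correlation
  x1 <- rep(c(1, -1), n / 2); x2 <- rep(c(1, 1, -1, -1), n / 4)
  stopifnot(abs(cor(x1, x2)) < 1e-12)
  y2 <- rnorm(n)
  res2 <- total_dominance(
    atlas_set(list(parcel_map(x1, ids, name = "a"),
                   parcel_map(x2, ids, name = "b"))),
    parcel_map(y2, ids, name = "y"))
  expect_equal(unname(res2$total_dominance),
               c(cor(x1, y2)^2, cor(x2, y2)^2), tolerance = 1e-10)
  expect_equal(sum(res2$total_dominance), res2$full_model_r2,
               tolerance = 1e-12)
})

test_that("dominance is symmetric under relabeling and affine rescaling", {
  set.seed(9)
  n <- 50; p <- 5
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X %*% c(1, 0.5, 0, 0, -0.5)) + rnorm(n)
  ids <- sprintf("r%02d", 1:n)
  mk <- function(M, nms) atlas_set(lapply(seq_len(ncol(M)), function(k)
    parcel_map(M[, k], ids, name = nms[k])))
  ym <- parcel_map(y, ids, name = "y")
  base <- total_dominance(mk(X, paste0("x", 1:p)), ym)
  perm <- c(3, 1, 5, 2, 4)
  res_perm <- total_dominance(mk(X[, perm], paste0("x", perm)), ym)
  expect_equal(res_perm$total_dominance[paste0("x", 1:p)],
               base$total_dominance[paste0("x", 1:p)],
               tolerance = 1e-12)
  X2 <- X; X2[, 2] <- -4 * X[, 2] + 7
  res_scaled <- total_dominance(mk(X2, paste0("x", 1:p)), ym)
  expect_equal(res_scaled$total_dominance, base$total_dominance,
               tolerance = 1e-12)
})

test_that("dominance guards its preconditions", {
  n <- 20
  ids <- sprintf("r%02d", 1:n)
  maps <- lapply(1:16, function(k)
    parcel_map(rnorm(n), ids, name = paste0("x", k)))
  expect_error(total_dominance(atlas_set(maps),
                               parcel_map(rnorm(n), ids, name = "y")),
               "cap of 15")
})

test_that("the dominance scan flags constructed signal with joint-surrogate nulls", {
  g <- fx_geometry()
  d <- fx_distances()
  lib <- fx_library()
  built <- make_ct_trajectories(g, lib, ground_truth(
    c(0.5, 0.3, rep(0, 7)), target_r2 = 0.6, seed = 12))
  win <- build_windows(8, 20, 5, 4,
                       extra_windows = list(c(10, 15)))  # 2 + 1 windows
  changes <- extract_change_series(built$trajectories, win)
  nulls <- lapply(lib$maps, function(m)
    generate_surrogates(m, d, 99,
                        seed = 40 + match(m$name, names(lib$maps))))
  names(nulls) <- names(lib$maps)
  scan <- dominance_scan(lib, changes, nulls)
  expect_identical(nrow(scan$windows), 3L)
  expect_identical(nrow(scan$dominance), 27L)     # windows x predictors
  # sum-to-R2 identity holds in every window
  sums <- tapply(scan$dominance$dominance,
                 paste(scan$dominance$i, scan$dominance$j), sum)
  expect_equal(sort(as.numeric(sums)), sort(unname(scan$windows$r2)),
               tolerance = 1e-10)
  # the target window is led by the two constructed predictors
  tw <- scan$dominance[scan$dominance$i == 10 & scan$dominance$j == 15, ]
  top2 <- tw$predictor[order(-tw$dominance)][1:2]
  expect_setequal(top2, names(lib$maps)[1:2])
  expect_lte(scan$windows$p[win$i == 10 & win$j == 15], 2 / 100)
  # one FDR family across full-model and predictor-wise p-values
  expect_true(all(scan$dominance$q >= scan$dominance$p - 1e-15))
})

test_that("influence maps measure per-parcel prediction-error change", {
  g <- fx_small_geometry()
  n <- 32
  set.seed(21)
  X <- matrix(rnorm(n * 3), n, 3)
  ids <- g$parcel_ids
  mk <- function(M, nms) atlas_set(lapply(seq_len(ncol(M)), function(k)
    parcel_map(M[, k], ids, name = nms[k])))
  y <- drop(X %*% c(1, 0.8, 0)) + 0.1 * rnorm(n)
  ym <- parcel_map(y, ids, name = "y")
  infl <- influence_map(mk(X, c("a", "b", "c")), ym, "a")
  # dPE = |reduced residual| - |full residual|, checked against lm
  res_full <- resid(lm(y ~ X))
  res_red <- resid(lm(y ~ X[, 2:3]))
  expect_equal(infl$values, unname(abs(res_red) - abs(res_full)),
               tolerance = 1e-12)
  expect_gt(mean(infl$values), 0)   # informative predictor helps

  # duplicated predictor: dropping one changes nothing
  X2 <- cbind(X[, 1], X[, 1], X[, 2])
  infl2 <- influence_map(mk(X2, c("a", "a2", "b")), ym, "a")
  expect_equal(infl2$values, rep(0, n), tolerance = 1e-8)

  # outcome orthogonal to target given others: mean dPE ~ 0
  set.seed(22)
  means <- replicate(100, {
    Z <- matrix(rnorm(n * 3), n, 3)
    yy <- Z[, 2] + rnorm(n)
    mean(influence_map(mk(Z, c("t", "u", "v")),
                       parcel_map(yy, ids, name = "y"), "t")$values)
  })
  expect_lt(abs(mean(means)), 0.02)

  expect_error(influence_map(mk(X[, 1, drop = FALSE], "a"), ym, "a"),
               "at least 2")
  expect_error(influence_map(mk(X, c("a", "b", "c")), ym, "zz"),
               "not among")
})
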