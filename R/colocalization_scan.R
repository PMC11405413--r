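#' @title Colocalization trajectories and explained-variance scans
#' @description Cross-sectional colocalization (spatial Spearman
#'   correlation between marker atlases and modeled CT at every age and
#'   percentile) and the windowed explained-variance scans: univariate
#'   (one simple regression per atlas and window) and multivariate (one
#'   OLS per window on a whole predictor set), both with empirical
#'   p-values from variogram-matched surrogate predictors.
#' @name colocalization_scan
NULL

#' Spatial Spearman colocalization of two parcel maps
#'
#' @param map_a,map_b Aligned, non-constant [parcel_map()]s.
#' @return List with `rho` (Spearman, average ranks for ties) and
#'   `fisher_z` (`atanh(rho)`).
#' @export
spearman_coloc <- function(map_a, map_b) {
  stopifnot(inherits(map_a, "parcel_map"), inherits(map_b, "parcel_map"))
  check_aligned(map_a, map_b)
  if (stats::sd(map_a$values) == 0 || stats::sd(map_b$values) == 0)
    stop("cannot correlate a constant map")
  rho <- stats::cor(map_a$values, map_b$values, method = "spearman")
  list(rho = rho, fisher_z = atanh(min(max(rho, -1 + 1e-15), 1 - 1e-15)))
}

#' Lifespan colocalization trajectories
#'
#' Spearman correlation between each atlas and the cross-sectional
#' modeled CT map at every age, percentile and sex (plus the
#' female/male average).
#'
#' @param atlases An [atlas_set()] aligned with the trajectories.
#' @param trajectories A `ct_trajectory_set`.
#' @return 4-d array `rho[atlas, age, percentile, sex]`, where the sex
#'   dimension holds the trajectory's sexes plus `"average"`.
#' @export
coloc_trajectory <- function(atlases, trajectories) {
  stopifnot(inherits(atlases, "atlas_set"),
            inherits(trajectories, "ct_trajectory_set"))
  if (!identical(atlases$maps[[1]]$parcel_ids, trajectories$parcel_ids))
    stop("atlases and trajectories have different parcel orderings")
  A <- apply(atlas_matrix(atlases), 2, rank)
  sexes <- c(trajectories$sexes, "average")
  out <- array(NA_real_,
               dim = c(ncol(A), length(trajectories$ages),
                       length(trajectories$percentiles), length(sexes)),
               dimnames = list(colnames(A), NULL,
                               as.character(trajectories$percentiles),
                               sexes))
  for (s in seq_along(sexes)) {
    ct <- if (sexes[s] == "average")
      (trajectories$ct[, , , "female"] + trajectories$ct[, , , "male"]) / 2
    else trajectories$ct[, , , sexes[s]]
    for (p in seq_along(trajectories$percentiles)) {
      r_ct <- apply(ct[, , p], 2, rank)
      out[, , p, s] <- stats::cor(A, r_ct)
    }
  }
  out
}

# internal: R^2 of each column of Y on a single predictor x (simple
# regression R^2 == squared Pearson correlation)
.r2_simple <- function(x, Y) as.vector(stats::cor(x, Y))^2

#' Univariate explained-variance scan of one atlas over windows
#'
#' For each change-map window, the simple linear regression of relative
#' CT change on the atlas: R-squared (identically the squared Pearson
#' correlation), a Spearman rho for the association sign, and a
#' positive-sided empirical p-value obtained by re-running the
#' regression with every surrogate of the atlas as predictor.
#'
#' @param atlas A [parcel_map()] predictor.
#' @param changes List of `ct_change_map`s (one per window).
#' @param nulls A [generate_surrogates()] ensemble for this atlas.
#' @return Data.frame with one row per window: `i`, `j`, `predictor`,
#'   `r2`, `rho`, `p`, `n_nulls`.
#' @export
univariate_scan <- function(atlas, changes, nulls) {
  stopifnot(inherits(atlas, "parcel_map"), inherits(nulls, "null_ensemble"))
  if (nulls$source_name != atlas$name)
    warning("null ensemble was generated for '", nulls$source_name,
            "', scanning '", atlas$name, "'")
  Y <- vapply(changes, function(ch) {
    check_aligned(atlas, ch)
    ch$values
  }, numeric(length(atlas$values)))
  Y <- matrix(Y, ncol = length(changes))
  obs <- .r2_simple(atlas$values, Y)
  null_r2 <- stats::cor(nulls$surrogates, Y)^2   # N x W
  N <- ncol(nulls$surrogates)
  p <- vapply(seq_along(changes), function(w)
    (1 + sum(null_r2[, w] >= obs[w])) / (1 + N), numeric(1))
  rho <- apply(Y, 2, function(y)
    stats::cor(atlas$values, y, method = "spearman"))
  win <- t(vapply(changes, function(ch) attr(ch, "window"), numeric(2)))
  data.frame(i = win[, 1], j = win[, 2], predictor = atlas$name,
             r2 = obs, rho = rho, p = p, n_nulls = N,
             stringsAsFactors = FALSE)
}

# internal: adjusted R^2
.adj_r2 <- function(r2, n, p) 1 - (1 - r2) * (n - 1) / (n - p - 1)

# internal: R^2 of every column of Y on design X (intercept added)
.r2_multi <- function(X, Y) {
  qrX <- qr(cbind(1, X))
  Yc <- sweep(Y, 2, colMeans(Y))
  fitted <- qr.fitted(qrX, Y)
  fc <- sweep(fitted, 2, colMeans(Y))
  colSums(fc^2) / pmax(colSums(Yc^2), .Machine$double.xmin)
}

#' Multivariate explained-variance scan over windows
#'
#' One ordinary least-squares regression per window of the change map on
#' all predictors jointly (predictors z-scored, intercept included).
#' Reports adjusted R-squared; the null distribution re-fits the model
#' with a jointly drawn surrogate predictor set (surrogate t of every
#' atlas in iteration t), and p-values are positive-sided empirical.
#'
#' @param atlases An [atlas_set()] of predictors.
#' @param changes List of `ct_change_map`s.
#' @param nulls Named list of [generate_surrogates()] ensembles, one per
#'   predictor (names matching the atlas names).
#' @param n_null_iters Number of joint null iterations (default: the
#'   smallest ensemble size).
#' @return Data.frame per window: `i`, `j`, `r2`, `adj_r2`, `p`,
#'   `n_nulls`, plus the predictor count as attribute `n_predictors`.
#' @export
multivariate_scan <- function(atlases, changes, nulls,
                              n_null_iters = NULL) {
  stopifnot(inherits(atlases, "atlas_set"))
  X <- scale(atlas_matrix(atlases))
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 1) stop("need more parcels than predictors + 1")
  if (qr(X)$rank < p)
    stop("rank-deficient predictor set (collinear atlases)")
  missing_nulls <- setdiff(colnames(X), names(nulls))
  if (length(missing_nulls))
    stop("no null ensemble for predictor(s): ",
         paste(missing_nulls, collapse = ", "))
  Y <- vapply(changes, function(ch) {
    check_aligned(atlases$maps[[1]], ch)
    ch$values
  }, numeric(n))
  Y <- matrix(Y, ncol = length(changes))
  obs_r2 <- .r2_multi(X, Y)
  N <- min(vapply(nulls[colnames(X)], function(e) ncol(e$surrogates),
                  integer(1)))
  if (!is.null(n_null_iters)) N <- min(N, n_null_iters)
  null_r2 <- matrix(NA_real_, N, ncol(Y))
  for (t in seq_len(N)) {
    Xt <- vapply(colnames(X), function(nm) nulls[[nm]]$surrogates[, t],
                 numeric(n))
    null_r2[t, ] <- .r2_multi(Xt, Y)
  }
  pv <- vapply(seq_len(ncol(Y)), function(w)
    (1 + sum(null_r2[, w] >= obs_r2[w])) / (1 + N), numeric(1))
  win <- t(vapply(changes, function(ch) attr(ch, "window"), numeric(2)))
  out <- data.frame(i = win[, 1], j = win[, 2], r2 = obs_r2,
                    adj_r2 = .adj_r2(obs_r2, n, p), p = pv, n_nulls = N)
  attr(out, "n_predictors") <- p
  out
}
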