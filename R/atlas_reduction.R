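#' @title Factor-analytic reduction of atlas libraries
#' @description Neurobiological atlas libraries are strongly
#'   intercorrelated; before multivariate modeling they are reduced by
#'   common-factor analysis: minimum-residual (unweighted least squares)
#'   extraction on the atlas-by-atlas correlation matrix, retention of
#'   every unrotated factor explaining at least a threshold share
#'   (default 1%) of the set's total variance, oblique promax rotation,
#'   and regression-method factor scores per parcel. Factors are named by
#'   modality prefix (ni / ce / mr) and validated against refits on
#'   parcel-permuted maps.
#' @name atlas_reduction
NULL

# ULS/minres discrepancy: with uniquenesses psi, the best rank-m
# approximation of R - diag(psi) leaves sum_{i>m} eigenvalue^2.
minres_objective <- function(psi, R, m) {
  e <- eigen(R - diag(psi), symmetric = TRUE)
  tail_vals <- e$values[-seq_len(m)]
  sum(tail_vals^2)
}

minres_gradient <- function(psi, R, m) {
  e <- eigen(R - diag(psi), symmetric = TRUE)
  idx <- setdiff(seq_along(psi), seq_len(m))
  -2 * colSums((e$values[idx]) * t(e$vectors[, idx, drop = FALSE]^2))
}

# Minimum-residual extraction of m factors from correlation matrix R.
minres_extract <- function(R, m, tol = 1e-6, max_iter = 1000) {
  p <- ncol(R)
  smc <- 1 - 1 / diag(solve(R))           # squared multiple correlations
  start <- pmin(pmax(1 - smc, 0.005), 1)
  opt <- stats::nlminb(start, minres_objective, minres_gradient,
                       R = R, m = m,
                       lower = 0.001, upper = 1,
                       control = list(iter.max = max_iter,
                                      rel.tol = tol))
  e <- eigen(R - diag(opt$par), symmetric = TRUE)
  lam <- e$values[seq_len(m)]
  L <- e$vectors[, seq_len(m), drop = FALSE] %*%
    diag(sqrt(pmax(lam, 0)), m)
  rownames(L) <- rownames(R)
  list(loadings = L, ss = pmax(lam, 0), uniquenesses = opt$par,
       converged = opt$convergence == 0, objective = opt$objective)
}

#' Fit the factor model of an atlas library
#'
#' Minimum-residual common-factor extraction on the atlas correlation
#' matrix. The number of factors is the count of unrotated factors whose
#' explained-variance proportion (SS loadings / number of maps) is at
#' least `retention_threshold`; the fit is re-run until all retained
#' factors clear the threshold. With 2 or more factors a promax rotation
#' (kappa = 4) is applied; regression-method (Thurstone) factor scores
#' are computed per parcel and z-scored. Each factor is oriented so that
#' its top-loading atlas loads positively.
#'
#' @param atlases An [atlas_set()] of at least 2 maps with more parcels
#'   than maps. Maps are z-scored internally if needed.
#' @param retention_threshold Minimum unrotated explained-variance
#'   proportion for a factor to be retained (default 0.01, i.e. 1% of
#'   the set's total variance).
#' @param promax_kappa Promax power (default 4).
#' @return A `factor_solution`: pattern `loadings`, `structure`,
#'   `factor_correlations` (Phi), `scores` (an [atlas_set()] of z-scored
#'   factor-score maps), `variance_explained_unrotated` (per factor,
#'   proportion of total variable variance),
#'   `variance_explained_rotated` (per factor and cumulative, from
#'   structure-loading SS), `uniquenesses`, `names`, and fit metadata.
#' @export
fit_factor_model <- function(atlases, retention_threshold = 0.01,
                             promax_kappa = 4) {
  stopifnot(inherits(atlases, "atlas_set"))
  p <- length(atlases$maps)
  if (p < 2) stop("factor analysis needs at least 2 maps")
  Z <- atlas_matrix(zscore_atlases(atlases))
  n <- nrow(Z)
  if (n <= p) stop("need more parcels than maps")
  R <- stats::cor(Z)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10)
    stop("atlas correlation matrix is singular ",
         "(duplicated or collinear maps); remove redundant maps")
  # retention: unrotated SS-loading proportion of total variance >= threshold
  m <- sum(ev / p >= retention_threshold)
  if (m < 1)
    stop("no factor reaches the retention threshold ",
         retention_threshold, "; lower the threshold")
  m <- min(m, p - 1)
  fit <- NULL
  repeat {
    fit <- minres_extract(R, m)
    keep <- sum(fit$ss / p >= retention_threshold)
    if (keep < 1)
      stop("no factor reaches the retention threshold ",
           retention_threshold, "; lower the threshold")
    if (keep == m) break
    m <- keep
  }
  L <- fit$loadings
  if (m >= 2) {
    pr <- stats::promax(L, m = promax_kappa)
    pattern <- unclass(pr$loadings)
    Phi <- solve(crossprod(pr$rotmat))
  } else {
    pattern <- L
    Phi <- matrix(1, 1, 1)
  }
  # sign convention: top-loading atlas positive on each factor
  for (k in seq_len(m)) {
    top <- which.max(abs(pattern[, k]))
    if (pattern[top, k] < 0) {
      pattern[, k] <- -pattern[, k]
      Phi[k, ] <- -Phi[k, ]
      Phi[, k] <- -Phi[, k]
    }
  }
  diag(Phi) <- 1
  structure_m <- pattern %*% Phi
  # regression-method factor scores on the parcel-level data
  W <- solve(R, structure_m)
  scores <- Z %*% W
  score_maps <- lapply(seq_len(m), function(k)
    zscore_map(parcel_map(scores[, k], atlases$maps[[1]]$parcel_ids,
                          atlases$maps[[1]]$hemisphere,
                          name = sprintf("factor%02d", k))))
  rot_ss <- colSums(structure_m^2)
  fnames <- sprintf("factor%02d", seq_len(m))
  dimnames(pattern) <- list(names(atlases$maps), fnames)
  dimnames(structure_m) <- dimnames(pattern)
  dimnames(Phi) <- list(fnames, fnames)
  structure(
    list(loadings = pattern, structure = structure_m,
         factor_correlations = Phi,
         scores = atlas_set(score_maps),
         variance_explained_unrotated = fit$ss / p,
         variance_explained_rotated = list(
           per_factor = rot_ss / p,
           cumulative = sum(rot_ss) / p),
         uniquenesses = fit$uniquenesses,
         names = fnames,
         retention_threshold = retention_threshold,
         settings = list(extraction = "minres", rotation = "promax",
                         promax_kappa = promax_kappa,
                         score_method = "regression"),
         converged = fit$converged),
    class = "factor_solution")
}

#' @export
print.factor_solution <- function(x, ...) {
  cat("<factor_solution> ", ncol(x$loadings), " factors x ",
      nrow(x$loadings), " maps (", x$settings$extraction, " + ",
      x$settings$rotation, ")\n", sep = "")
  cat("  unrotated variance proportions: ",
      paste(sprintf("%.3f", x$variance_explained_unrotated),
            collapse = " "), "\n", sep = "")
  cat("  rotated cumulative: ",
      sprintf("%.3f", x$variance_explained_rotated$cumulative),
      "\n", sep = "")
  invisible(x)
}

#' Name factors by modality prefix and report atlas assignments
#'
#' Factor k becomes `<prefix><k>` (e.g. ni1...ni10); every original
#' atlas is assigned to the factor carrying its maximal absolute pattern
#' loading (exact ties go to the lower-index factor).
#'
#' @param solution A [fit_factor_model()] result.
#' @param modality_prefix Prefix string (`"ni"`, `"ce"`, ...).
#' @return The solution with `names` set, score maps renamed, and an
#'   `assignments` data.frame (atlas, factor, loading).
#' @export
name_factors <- function(solution, modality_prefix) {
  stopifnot(inherits(solution, "factor_solution"))
  m <- ncol(solution$loadings)
  fnames <- paste0(modality_prefix, seq_len(m))
  colnames(solution$loadings) <- fnames
  colnames(solution$structure) <- fnames
  dimnames(solution$factor_correlations) <- list(fnames, fnames)
  solution$names <- fnames
  maps <- solution$scores$maps
  for (k in seq_len(m)) maps[[k]]$name <- fnames[k]
  solution$scores <- atlas_set(maps)
  best <- apply(abs(solution$loadings), 1, which.max)  # ties -> lower index
  solution$assignments <- data.frame(
    atlas = rownames(solution$loadings),
    factor = fnames[best],
    loading = solution$loadings[cbind(seq_along(best), best)],
    stringsAsFactors = FALSE)
  solution
}

#' Reduce one modality's atlas library to factor-level marker maps
#'
#' Convenience wrapper: libraries of two or more maps go through
#' [fit_factor_model()] and [name_factors()]; a single-map "modality"
#' (e.g. the lone microstructural MRI marker) is passed through
#' unreduced, z-scored and named `<prefix>1`.
#'
#' @inheritParams fit_factor_model
#' @param modality_prefix Prefix for factor names.
#' @return List with `markers` (an [atlas_set()] of factor-score or
#'   passthrough maps) and `solution` (`NULL` for a passthrough).
#' @export
reduce_modality <- function(atlases, modality_prefix,
                            retention_threshold = 0.01) {
  stopifnot(inherits(atlases, "atlas_set"))
  if (length(atlases$maps) == 1) {
    m <- zscore_map(atlases$maps[[1]])
    m$name <- paste0(modality_prefix, 1)
    return(list(markers = atlas_set(list(m), modality = modality_prefix),
                solution = NULL))
  }
  sol <- name_factors(fit_factor_model(atlases, retention_threshold),
                      modality_prefix)
  markers <- sol$scores
  markers$modality <- rep(modality_prefix, length(markers$maps))
  list(markers = markers, solution = sol)
}

#' Permuted-map validation of a factor solution
#'
#' Tests whether the factor solution fitted on the original atlas
#' library explains more variance than solutions fitted on libraries
#' whose parcel order has been independently permuted within each map
#' (destroying shared spatial structure but keeping each map's value
#' distribution). Each permuted library is refit with the identical
#' retention rule; the comparison statistic is the cumulative rotated
#' explained-variance proportion, and the one-sided empirical p-value is
#' `(1 + #\{null >= observed\}) / (1 + N)`. Permuted refits that retain
#' no factor contribute a null value of 0.
#'
#' @inheritParams fit_factor_model
#' @param n_permutations Number of permuted refits (>= 1).
#' @param seed Integer seed.
#' @return List: `p`, `observed` cumulative rotated variance, `nulls`.
#' @export
validate_against_permuted <- function(atlases, n_permutations = 100,
                                      seed = 1,
                                      retention_threshold = 0.01) {
  stopifnot(inherits(atlases, "atlas_set"))
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  observed <- fit_factor_model(atlases, retention_threshold)
  obs_stat <- observed$variance_explained_rotated$cumulative
  n <- length(atlases$maps[[1]]$values)
  ids <- atlases$maps[[1]]$parcel_ids
  hemi <- atlases$maps[[1]]$hemisphere
  nulls <- with_seed(seed, vapply(seq_len(n_permutations), function(b) {
    perm_maps <- lapply(atlases$maps, function(m)
      parcel_map(m$values[sample.int(n)], ids, hemi, name = m$name))
    fit <- tryCatch(
      fit_factor_model(atlas_set(perm_maps), retention_threshold),
      error = function(e) NULL)
    if (is.null(fit)) 0 else fit$variance_explained_rotated$cumulative
  }, numeric(1)))
  list(p = empirical_p(obs_stat, nulls, "greater"),
       observed = obs_stat, nulls = nulls)
}

#' Tucker congruence between two loading matrices
#'
#' Column-wise congruence `sum(x * y) / sqrt(sum(x^2) * sum(y^2))` after
#' greedily matching columns of `b` to columns of `a` by absolute
#' congruence (sign-invariant).
#'
#' @param a,b Loading matrices with the same number of rows.
#' @return Numeric vector of matched absolute congruences, one per
#'   column of `a`.
#' @export
factor_congruence <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b)) stop("loading matrices must have equal rows")
  cong <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  C <- abs(outer(seq_len(ncol(a)), seq_len(ncol(b)),
                 Vectorize(function(i, j) cong(a[, i], b[, j]))))
  out <- numeric(ncol(a))
  used <- logical(ncol(b))
  for (i in order(-apply(C, 1, max))) {
    j <- which.max(ifelse(used, -Inf, C[i, ]))
    out[i] <- C[i, j]
    used[j] <- TRUE
  }
  out
}

#' Export a factor solution's tables
#'
#' Writes pattern loadings, factor correlations, variance accounting,
#' and factor-score maps as TSV files.
#'
#' @param solution A [fit_factor_model()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
export_factor_solution <- function(solution, dir) {
  stopifnot(inherits(solution, "factor_solution"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(loadings = file.path(dir, "loadings.tsv"),
             phi = file.path(dir, "factor_correlations.tsv"),
             variance = file.path(dir, "variance_explained.tsv"),
             scores = file.path(dir, "factor_scores.tsv"))
  utils::write.table(data.frame(atlas = rownames(solution$loadings),
                                solution$loadings, check.names = FALSE),
                     paths["loadings"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(factor = rownames(solution$factor_correlations),
                                solution$factor_correlations,
                                check.names = FALSE),
                     paths["phi"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  vr <- data.frame(
    factor = solution$names,
    unrotated_proportion = solution$variance_explained_unrotated,
    rotated_proportion = solution$variance_explained_rotated$per_factor)
  utils::write.table(vr, paths["variance"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_parcel_table(solution$scores, paths["scores"])
  invisible(paths)
}
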