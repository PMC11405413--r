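#' @title Dominance analysis and regional influence maps
#' @description Exhaustive dominance analysis decomposes a multivariate
#'   regression's R-squared into per-predictor "total dominance"
#'   contributions: the average, over subset sizes, of the mean
#'   incremental R-squared a predictor adds to every subset model not
#'   containing it. The per-predictor contributions sum exactly to the
#'   full-model R-squared, so dominance apportions explained CT-change
#'   variance across neurobiological markers. Regional influence maps
#'   (delta prediction error) quantify, per parcel, how much a predictor
#'   improves the fit: `dPE = |PE_without_x| - |PE_full|`.
#' @name dominance_influence
NULL

# Cached subset-enumeration metadata for p predictors: bit values,
# subset sizes, and per-predictor lists of masks not containing it.
.dom_cache <- new.env(parent = emptyenv())

dominance_meta <- function(p) {
  key <- as.character(p)
  if (!is.null(.dom_cache[[key]])) return(.dom_cache[[key]])
  masks <- 0:(2^p - 1)
  size <- vapply(masks, function(m) sum(bitwAnd(m, 2^(0:(p - 1))) > 0),
                 integer(1))
  members <- lapply(masks, function(m) which(bitwAnd(m, 2^(0:(p - 1))) > 0))
  without <- lapply(seq_len(p), function(x) masks[bitwAnd(masks, 2^(x - 1)) == 0])
  meta <- list(masks = masks, size = size, members = members,
               without = without)
  .dom_cache[[key]] <- meta
  meta
}

# R^2 of every subset model for one or more outcomes.
# X: n x p predictor matrix; Y: n x q outcomes.
# Returns (2^p) x q matrix, row mask+1; empty subset row is 0.
subset_r2_all <- function(X, Y, meta = dominance_meta(ncol(X))) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  p <- ncol(X)
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  Cxx <- crossprod(Xc)
  Cxy <- crossprod(Xc, Yc)
  vy <- pmax(colSums(Yc^2), .Machine$double.xmin)
  R2 <- matrix(0, 2^p, ncol(Y))
  for (m in meta$masks[-1]) {
    S <- meta$members[[m + 1]]
    ch <- tryCatch(chol(Cxx[S, S, drop = FALSE]),
                   error = function(e)
                     stop("rank-deficient predictor subset {",
                          paste(S, collapse = ","), "}"))
    Z <- forwardsolve(t(ch), Cxy[S, , drop = FALSE])
    R2[m + 1, ] <- colSums(Z^2) / vy
  }
  R2
}

# Total dominance from a subset-R^2 table: for each predictor x, average
# over subset sizes k of the mean incremental R^2 of adding x to size-k
# subsets without x. Returns p x q matrix.
dominance_from_r2 <- function(R2, p, meta = dominance_meta(p)) {
  q <- ncol(R2)
  D <- matrix(NA_real_, p, q)
  for (x in seq_len(p)) {
    m0 <- meta$without[[x]]
    inc <- R2[m0 + 2^(x - 1) + 1, , drop = FALSE] - R2[m0 + 1, , drop = FALSE]
    k <- meta$size[m0 + 1]
    by_size <- rowsum(inc, k) / as.vector(table(k))
    D[x, ] <- colMeans(by_size)
  }
  D
}

#' Exhaustive total dominance for one outcome
#'
#' Decomposes the full-model R-squared of `outcome ~ predictors` into
#' per-predictor total dominance by enumerating all `2^p` subset models.
#' The decomposition uses plain R-squared (additivity holds only for the
#' unadjusted statistic); the full model's adjusted R-squared is
#' reported alongside.
#'
#' @param predictors An [atlas_set()] (at most 15 maps; enumeration is
#'   exact, not approximated).
#' @param outcome A [parcel_map()] / `ct_change_map` aligned with the
#'   predictors.
#' @return A `dominance_result`: `full_model_r2`, `full_model_adj_r2`,
#'   `total_dominance` (named, sums to `full_model_r2`), `spearman_rho`
#'   (marginal association signs), `window` if the outcome carries one.
#' @export
total_dominance <- function(predictors, outcome) {
  stopifnot(inherits(predictors, "atlas_set"),
            inherits(outcome, "parcel_map"))
  check_aligned(predictors$maps[[1]], outcome)
  X <- atlas_matrix(predictors)
  p <- ncol(X)
  if (p > 15)
    stop("exhaustive dominance enumerates 2^p subsets; p = ", p,
         " exceeds the hard cap of 15")
  n <- nrow(X)
  if (n <= p + 1) stop("need more parcels than predictors + 1")
  meta <- dominance_meta(p)
  R2 <- subset_r2_all(X, outcome$values, meta)
  D <- dominance_from_r2(R2, p, meta)[, 1]
  names(D) <- colnames(X)
  full <- R2[2^p, 1]              # full-subset mask is 2^p - 1, row 2^p
  rho <- vapply(seq_len(p), function(k)
    stats::cor(X[, k], outcome$values, method = "spearman"), numeric(1))
  structure(
    list(full_model_r2 = full,
         full_model_adj_r2 = .adj_r2(full, n, p),
         total_dominance = D,
         spearman_rho = stats::setNames(rho, colnames(X)),
         window = attr(outcome, "window")),
    class = "dominance_result")
}

#' @export
print.dominance_result <- function(x, ...) {
  cat("<dominance_result> full R2 = ", sprintf("%.4f", x$full_model_r2),
      " (adj ", sprintf("%.4f", x$full_model_adj_r2), ")\n", sep = "")
  d <- sort(x$total_dominance, decreasing = TRUE)
  cat("  top: ", paste(sprintf("%s=%.4f", names(d)[seq_len(min(4, length(d)))],
                               d[seq_len(min(4, length(d)))]),
                       collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Dominance scan over lifespan windows with surrogate-based inference
#'
#' Runs one exhaustive dominance decomposition per window and derives
#' positive-sided empirical p-values for both the full-model R-squared
#' and every predictor-wise total dominance, from null dominance
#' analyses on jointly drawn surrogate predictor sets (surrogate t of
#' each atlas in iteration t). FDR correction spans the whole analysis
#' as one family (full-model plus all predictor-wise tests, e.g.
#' 82 + 82 x 9 p-values for the lifespan scheme with the extra
#' developmental window).
#'
#' @param predictors An [atlas_set()] (p <= 15).
#' @param changes List of `ct_change_map`s (one per window).
#' @param nulls Named list of [generate_surrogates()] ensembles per
#'   predictor.
#' @param n_null_iters Null iterations (default: smallest ensemble).
#' @return List: `windows` data.frame (i, j, r2, adj_r2, p, q),
#'   `dominance` data.frame (i, j, predictor, dominance, rho, p, q),
#'   `n_nulls`.
#' @export
dominance_scan <- function(predictors, changes, nulls,
                           n_null_iters = NULL) {
  stopifnot(inherits(predictors, "atlas_set"))
  X <- atlas_matrix(predictors)
  n <- nrow(X); p <- ncol(X)
  if (p > 15) stop("p > 15 exceeds the exhaustive enumeration cap")
  missing_nulls <- setdiff(colnames(X), names(nulls))
  if (length(missing_nulls))
    stop("no null ensemble for predictor(s): ",
         paste(missing_nulls, collapse = ", "))
  Y <- vapply(changes, function(ch) {
    check_aligned(predictors$maps[[1]], ch)
    ch$values
  }, numeric(n))
  Y <- matrix(Y, ncol = length(changes))
  W <- ncol(Y)
  meta <- dominance_meta(p)
  R2 <- subset_r2_all(X, Y, meta)
  obs_full <- R2[2^p, ]
  obs_dom <- dominance_from_r2(R2, p, meta)        # p x W
  N <- min(vapply(nulls[colnames(X)], function(e) ncol(e$surrogates),
                  integer(1)))
  if (!is.null(n_null_iters)) N <- min(N, n_null_iters)
  exceed_full <- numeric(W)
  exceed_dom <- matrix(0, p, W)
  for (t in seq_len(N)) {
    Xt <- vapply(colnames(X), function(nm) nulls[[nm]]$surrogates[, t],
                 numeric(n))
    R2t <- subset_r2_all(Xt, Y, meta)
    exceed_full <- exceed_full + (R2t[2^p, ] >= obs_full)
    exceed_dom <- exceed_dom +
      (dominance_from_r2(R2t, p, meta) >= obs_dom)
  }
  p_full <- (1 + exceed_full) / (1 + N)
  p_dom <- (1 + exceed_dom) / (1 + N)
  rho <- stats::cor(X, Y, method = "spearman")     # p x W
  win <- t(vapply(changes, function(ch) attr(ch, "window"), numeric(2)))
  q_all <- fdr_adjust(c(p_full, as.vector(p_dom)))
  windows_df <- data.frame(i = win[, 1], j = win[, 2], r2 = obs_full,
                           adj_r2 = .adj_r2(obs_full, n, p),
                           p = p_full, q = q_all[seq_len(W)])
  dom_df <- data.frame(
    i = rep(win[, 1], each = p), j = rep(win[, 2], each = p),
    predictor = rep(colnames(X), W),
    dominance = as.vector(obs_dom), rho = as.vector(rho),
    p = as.vector(p_dom),
    q = q_all[-seq_len(W)], stringsAsFactors = FALSE)
  list(windows = windows_df, dominance = dom_df, n_nulls = N)
}

#' Regional influence map of one predictor
#'
#' Per parcel, the absolute residual of the model without the target
#' predictor minus the absolute residual of the full model:
#' `dPE = |PE_without_x| - |PE_full|`. Positive values mark parcels where
#' the target improves the prediction of CT change.
#'
#' @param predictors An [atlas_set()] with at least 2 maps.
#' @param outcome Aligned [parcel_map()] outcome.
#' @param target Name of the predictor to drop.
#' @return A [parcel_map()] of delta prediction errors (unitless), named
#'   `dPE_<target>`.
#' @export
influence_map <- function(predictors, outcome, target) {
  stopifnot(inherits(predictors, "atlas_set"),
            inherits(outcome, "parcel_map"))
  X <- atlas_matrix(predictors)
  if (ncol(X) < 2)
    stop("influence requires at least 2 predictors (a reduced model ",
         "must exist)")
  if (!target %in% colnames(X))
    stop("target '", target, "' is not among the predictors")
  check_aligned(predictors$maps[[1]], outcome)
  y <- outcome$values
  res_full <- stats::lm.fit(cbind(1, X), y)$residuals
  res_red <- stats::lm.fit(cbind(1, X[, colnames(X) != target,
                                      drop = FALSE]), y)$residuals
  parcel_map(abs(res_red) - abs(res_full), outcome$parcel_ids,
             outcome$hemisphere, name = paste0("dPE_", target))
}
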