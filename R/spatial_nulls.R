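#' @title Spatially autocorrelated null maps and empirical inference
#' @description Parametric p-values are meaningless for correlations
#'   between smooth brain maps: the effective number of independent
#'   observations is far below the parcel count. All inference in this
#'   package therefore compares observed statistics against null
#'   distributions built from surrogate maps that preserve the predictor's
#'   spatial autocorrelation, via a variogram-matching construction:
#'   permute the map, smooth the permutation at a ladder of neighborhood
#'   scales with a distance-decaying kernel, pick the scale and affine
#'   recombination whose variogram best matches the source map's, and
#'   (by default) restore the source's exact value distribution by rank
#'   mapping.
#' @name spatial_nulls
NULL

#' Euclidean centroid distance matrix
#'
#' @param geometry A [make_parcel_geometry()] object (or any list with a
#'   `centroids` matrix and `parcel_ids`).
#' @return Symmetric distance matrix with zero diagonal, dimnames set to
#'   parcel ids.
#' @export
pairwise_distances <- function(geometry) {
  d <- as.matrix(stats::dist(geometry$centroids))
  dimnames(d) <- list(geometry$parcel_ids, geometry$parcel_ids)
  d
}

# Equal-count distance bins over the upper-triangle pairs.
# Returns pair indices (i, j), bin assignment, and bin centers.
variogram_bins <- function(d, n_bins) {
  n <- nrow(d)
  ut <- which(upper.tri(d))
  dv <- d[ut]
  if (n_bins < 2) stop("n_bins must be >= 2")
  if (n_bins > length(dv))
    stop("n_bins (", n_bins, ") exceeds the number of parcel pairs (",
         length(dv), ")")
  ord <- order(dv)
  bin <- integer(length(dv))
  # equal-count split of the sorted pair distances
  bin[ord] <- as.integer(cut(seq_along(ord), breaks = n_bins, labels = FALSE))
  centers <- vapply(seq_len(n_bins), function(b) mean(dv[bin == b]),
                    numeric(1))
  row <- ((ut - 1) %% n) + 1
  col <- ((ut - 1) %/% n) + 1
  list(i = row, j = col, bin = bin, centers = centers, n_bins = n_bins)
}

# Binned semivariance of a value vector given precomputed bins.
binned_semivariance <- function(values, bins) {
  sq <- 0.5 * (values[bins$i] - values[bins$j])^2
  as.numeric(tapply(sq, bins$bin, mean))[seq_len(bins$n_bins)]
}

#' Empirical variogram of a parcel map
#'
#' Semivariance `gamma(h) = 0.5 * mean (x_u - x_v)^2` over equal-count
#' distance bins (each bin holds the same number of parcel pairs).
#'
#' @param map A [parcel_map()].
#' @param d Distance matrix from [pairwise_distances()], aligned to the
#'   map's parcels.
#' @param n_bins Number of distance bins (default 25).
#' @return List with `distance` (bin centers) and `semivariance`.
#' @export
empirical_variogram <- function(map, d, n_bins = 25) {
  stopifnot(inherits(map, "parcel_map"))
  if (nrow(d) != length(map$values))
    stop("distance matrix does not match the map's parcel count")
  bins <- variogram_bins(d, n_bins)
  list(distance = bins$centers,
       semivariance = binned_semivariance(map$values, bins))
}

#' Kernel-smoothed variogram
#'
#' The low-noise variogram estimator used for surrogate fitting:
#' semivariances of parcel pairs up to the `dist_quantile` quantile of
#' pairwise distances (default 25%) are smoothed with a Gaussian kernel
#' in distance, evaluated at `n_points` equally spaced distances
#' (bandwidth defaults to three times the evaluation spacing). The
#' truncation restricts the match to the distance range where spatial
#' autocorrelation carries information; beyond it the variogram of a
#' brain-scale map is flat noise.
#'
#' @inheritParams empirical_variogram
#' @param n_points Number of evaluation distances (default 25).
#' @param dist_quantile Pair-distance quantile at which to truncate
#'   (default 0.25).
#' @param bandwidth Gaussian kernel bandwidth; default 3x the spacing
#'   between evaluation points.
#' @return List with `distance` and `semivariance`.
#' @export
smoothed_variogram <- function(map, d, n_points = 25,
                               dist_quantile = 0.25, bandwidth = NULL) {
  stopifnot(inherits(map, "parcel_map"))
  sv <- smoothed_variogram_plan(d, n_points, dist_quantile, bandwidth)
  list(distance = sv$h,
       semivariance = smoothed_semivariance(map$values, sv))
}

# Precompute pair selection and kernel weights for the smoothed
# variogram, so repeated evaluations are one matrix-vector product.
smoothed_variogram_plan <- function(d, n_points = 25,
                                    dist_quantile = 0.25,
                                    bandwidth = NULL) {
  n <- nrow(d)
  ut <- which(upper.tri(d))
  dv <- d[ut]
  sel <- ut[dv <= stats::quantile(dv, dist_quantile)]
  dd <- d[sel]
  h <- seq(min(dd), max(dd), length.out = n_points)
  if (is.null(bandwidth)) bandwidth <- 3 * (h[2] - h[1])
  W <- exp(-outer(h, dd, "-")^2 / (2 * bandwidth^2))
  W <- W / rowSums(W)
  list(i = ((sel - 1) %% n) + 1, j = ((sel - 1) %/% n) + 1,
       W = W, h = h, bandwidth = bandwidth,
       dist_quantile = dist_quantile)
}

smoothed_semivariance <- function(values, plan) {
  as.numeric(plan$W %*% (0.5 * (values[plan$i] - values[plan$j])^2))
}

# k-nearest-neighbour exponential smoothing matrix: row i weights the k
# nearest parcels by exp(-d_ij / d_ik) (bandwidth = distance to the kth
# neighbour), normalized to sum 1.
knn_smoother <- function(d, k) {
  n <- nrow(d)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ord <- order(d[i, ])
    nb <- ord[ord != i][seq_len(k)]
    bw <- d[i, nb[k]]
    w <- exp(-d[i, nb] / bw)
    W[i, nb] <- w / sum(w)
  }
  W
}

#' Variogram-matched surrogate maps
#'
#' Generates `n` randomized copies of a map that preserve its spatial
#' autocorrelation structure: each surrogate starts as a random
#' permutation of the map, is smoothed with k-nearest-neighbour
#' exponential kernels at a ladder of neighborhood scales, and the scale
#' plus affine recombination (smoothed term + white-noise term) minimizing
#' the squared distance between surrogate and source variograms is kept.
#' With `resample = TRUE` (default) surrogate values are finally replaced
#' by the source map's values through rank mapping, so each surrogate has
#' exactly the source's value multiset.
#'
#' One ensemble per atlas is generated once and reused across every
#' analysis window (keyed by map name and seed).
#'
#' @param map A non-constant [parcel_map()].
#' @param d Distance matrix aligned with the map.
#' @param n Number of surrogates.
#' @param seed Integer seed (the ensemble is fully reproducible).
#' @param n_points Evaluation points of the smoothed variogram used for
#'   fitting (default 25).
#' @param dist_quantile Distance-quantile truncation of the variogram
#'   used for fitting (default 0.5: constraining the match out to the
#'   median pairwise distance prevents surrogates from smuggling in
#'   long-range structure the short-range variogram cannot see, which
#'   would bias downstream empirical p-values conservative).
#' @param k_ladder Neighborhood sizes to try; default 10 log-spaced
#'   rungs from 2 to half the parcel count.
#' @param resample Restore the exact source value distribution by rank
#'   mapping (default `TRUE`).
#' @return A `null_ensemble`: `source_name`, `surrogates` (parcel x n
#'   matrix), `seed`, `params`.
#' @export
generate_surrogates <- function(map, d, n, seed = 1, n_points = 25,
                                dist_quantile = 0.5, k_ladder = NULL,
                                resample = TRUE) {
  stopifnot(inherits(map, "parcel_map"))
  if (n < 1) stop("n must be >= 1")
  x <- map$values
  np <- length(x)
  if (nrow(d) != np) stop("distance matrix does not match map")
  if (stats::sd(x) == 0) stop("cannot build surrogates for a constant map")
  if (is.null(k_ladder))
    k_ladder <- unique(round(exp(seq(log(2), log(0.5 * np),
                                     length.out = 10))))
  plan <- smoothed_variogram_plan(d, n_points, dist_quantile)
  gamma_src <- smoothed_semivariance(x, plan)
  smoothers <- lapply(k_ladder, function(k) knn_smoother(d, k))
  x_sorted <- sort(x)
  out <- matrix(NA_real_, np, n)
  with_seed(seed, {
    for (s in seq_len(n)) {
      xp <- x[sample.int(np)]
      best <- NULL
      for (m in seq_along(k_ladder)) {
        sm <- drop(smoothers[[m]] %*% xp)
        sm <- sm - mean(sm)
        g_sm <- smoothed_semivariance(sm, plan)
        # source variogram ~ alpha * smoothed-map variogram + beta;
        # beta absorbs the white-noise nugget, alpha the smoothed term
        vx <- g_sm - mean(g_sm)
        alpha <- sum(vx * (gamma_src - mean(gamma_src))) /
          max(sum(vx^2), 1e-300)
        beta <- mean(gamma_src) - alpha * mean(g_sm)
        fit <- alpha * g_sm + beta
        sse <- sum((gamma_src - fit)^2)
        if (is.null(best) || sse < best$sse)
          best <- list(sse = sse, sm = sm, alpha = max(alpha, 0),
                       beta = max(beta, 0))
      }
      ns <- sqrt(best$alpha) * best$sm +
        sqrt(best$beta) * stats::rnorm(np)
      if (resample) ns <- x_sorted[rank(ns, ties.method = "first")]
      out[, s] <- ns
    }
  })
  rownames(out) <- map$parcel_ids
  structure(
    list(source_name = map$name, surrogates = out, seed = seed,
         params = list(n_points = n_points,
                       dist_quantile = dist_quantile,
                       k_ladder = k_ladder,
                       kernel = "exponential-knn", resample = resample)),
    class = "null_ensemble")
}

#' Variogram match quality of a surrogate ensemble
#'
#' Spearman correlation between each surrogate's smoothed variogram and
#' the source map's, plus the surrogate-to-source map correlations
#' (which should center on zero: surrogates share autocorrelation
#' structure, not spatial pattern).
#'
#' @param ensemble A [generate_surrogates()] result.
#' @param map The source [parcel_map()].
#' @param d Distance matrix.
#' @return List: `variogram_spearman` (per surrogate), `map_correlation`
#'   (per surrogate).
#' @export
variogram_match_quality <- function(ensemble, map, d) {
  stopifnot(inherits(ensemble, "null_ensemble"))
  plan <- smoothed_variogram_plan(d, ensemble$params$n_points,
                                  ensemble$params$dist_quantile)
  gsrc <- smoothed_semivariance(map$values, plan)
  vs <- apply(ensemble$surrogates, 2, function(s)
    stats::cor(smoothed_semivariance(s, plan), gsrc,
               method = "spearman"))
  list(variogram_spearman = vs,
       map_correlation = as.numeric(stats::cor(ensemble$surrogates,
                                               map$values)))
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat("<null_ensemble> ", ncol(x$surrogates), " surrogates of '",
      x$source_name, "' (", nrow(x$surrogates), " parcels, seed ",
      x$seed, ")\n", sep = "")
  invisible(x)
}

#' Positive-sided empirical p-value
#'
#' `p = (1 + #\{null >= observed\}) / (1 + N)`: the observation is ranked
#' within its null distribution, ties counting against it. This estimator
#' is valid (never anticonservative) in finite samples and never returns
#' 0; its minimum is `1 / (N + 1)`.
#'
#' @param observed Observed scalar statistic.
#' @param nulls Numeric vector of null statistics (length >= 1).
#' @param side `"greater"` (default; larger statistics more extreme) or
#'   `"less"`.
#' @return The empirical p-value.
#' @export
empirical_p <- function(observed, nulls, side = c("greater", "less")) {
  side <- match.arg(side)
  if (!length(nulls)) stop("empty null distribution")
  k <- if (side == "greater") sum(nulls >= observed) else
    sum(nulls <= observed)
  (1 + k) / (1 + length(nulls))
}

#' Benjamini-Hochberg adjustment within declared groups
#'
#' Applies the BH step-up procedure independently within each level of
#' `grouping`, reproducing the correction families used across analyses
#' (e.g. "within each modality" for univariate scans, one family for a
#' whole dominance analysis).
#'
#' @param pvalues Numeric p-values in `[0, 1]`.
#' @param grouping Vector of group labels (one family per level); `NULL`
#'   adjusts all p-values as a single family.
#' @return q-values, same order as input.
#' @export
fdr_adjust <- function(pvalues, grouping = NULL) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  if (is.null(grouping)) return(stats::p.adjust(pvalues, method = "BH"))
  if (length(grouping) != length(pvalues))
    stop("grouping must have one label per p-value")
  q <- numeric(length(pvalues))
  for (g in unique(grouping)) {
    sel <- grouping == g
    q[sel] <- stats::p.adjust(pvalues[sel], method = "BH")
  }
  q
}
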