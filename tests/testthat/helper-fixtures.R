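# Shared fixtures, built once per test run and cached.
.fx <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

# full-resolution geometry (148 parcels) and its distance matrix
fx_geometry <- function() fixture("geom", function()
  make_parcel_geometry(74, seed = 11))
fx_distances <- function() fixture("dist", function()
  pairwise_distances(fx_geometry()))

# small geometry for cheap structural tests
fx_small_geometry <- function() fixture("geom_small", function()
  make_parcel_geometry(16, seed = 7))

# a 9-map moderately intercorrelated library on the full geometry
fx_library <- function() fixture("library", function()
  make_atlas_library(fx_geometry(), 9, length_scale = 15,
                     cross_correlation = 0.3, seed = 21))

# tiny parcel_map constructor for hand-built examples
pm <- function(values, name = "m") {
  parcel_map(values, sprintf("p%03d", seq_along(values)), name = name)
}

# brute-force dominance oracle: average incremental R^2 over all p!
# predictor orderings (independent of the package's subset enumeration)
orderings_dominance_oracle <- function(X, y) {
  p <- ncol(X)
  all_perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in all_perms(v[-i])) out <- c(out, list(c(v[i], rest)))
    out
  }
  r2 <- function(S) {
    if (!length(S)) return(0)
    summary(stats::lm(y ~ X[, S, drop = FALSE]))$r.squared
  }
  perms <- all_perms(seq_len(p))
  contrib <- matrix(0, length(perms), p)
  for (k in seq_along(perms)) {
    ord <- perms[[k]]
    S <- integer(0)
    for (x in ord) {
      contrib[k, x] <- r2(c(S, x)) - r2(S)
      S <- c(S, x)
    }
  }
  colMeans(contrib)
}

# library built from 3 latent spatial patterns: 10 maps, loadings 0.9,
# additive white noise sd 0.19 (the factor-recovery construction)
make_three_latent_library <- function(geometry, seed = 42,
                                      noise_sd = 0.19) {
  lat <- sapply(1:3, function(k)
    sample_gp_map(geometry, 15, seed = seed * 10 + k)$values)
  truth <- matrix(0, 10, 3)
  for (i in 1:10) truth[i, ((i - 1) %% 3) + 1] <- 0.9
  set.seed(seed)
  maps <- lapply(1:10, function(i) {
    v <- lat %*% truth[i, ] + noise_sd * stats::rnorm(nrow(lat))
    zscore_map(parcel_map(v, geometry$parcel_ids, geometry$hemisphere,
                          name = sprintf("map%02d", i)))
  })
  list(atlases = atlas_set(maps), loadings = truth, latent = lat)
}
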