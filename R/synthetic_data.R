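#' @title Seeded synthetic data with known ground truth
#' @description Generators for every input the pipeline consumes: parcel
#'   geometry, spatially autocorrelated atlas libraries, normative CT
#'   trajectories whose windowed relative change is a known mixture of
#'   atlases, developmental gene-expression datasets, and two-session
#'   longitudinal cohorts. All generators are deterministic given their
#'   seed.
#' @name synthetic_data
NULL

# Run code under a temporary RNG seed, restoring global RNG state after.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Synthetic parcel geometry on two hemispheric caps
#'
#' Places parcel centroids quasi-uniformly (Fibonacci lattice plus a small
#' seeded jitter) on two mirrored spherical caps separated along the x
#' axis, so left/right centroids occupy disjoint half-spaces. The
#' centroids are the substrate for variogram distances; units are
#' arbitrary (sphere radius 50).
#'
#' @param n_per_hemisphere Number of parcels per hemisphere (>= 4);
#'   74 gives the 148-parcel Destrieux-like resolution.
#' @param seed Integer seed for the jitter.
#' @param radius Sphere radius (default 50).
#' @param gap Inter-hemisphere gap along x (default 10).
#' @return A `parcel_geometry` object: `parcel_ids`, `centroids`
#'   (n x 3 matrix), `hemisphere`.
#' @export
make_parcel_geometry <- function(n_per_hemisphere, seed = 1, radius = 50,
                                 gap = 10) {
  n <- as.integer(n_per_hemisphere)
  if (is.na(n) || n < 4) stop("n_per_hemisphere must be >= 4")
  with_seed(seed, {
    i <- seq_len(n)
    golden <- pi * (3 - sqrt(5))
    # quasi-uniform on the hemisphere x < 0
    u <- (i - 0.5) / n                  # |x|-coordinate in (0,1)
    theta <- i * golden
    x <- -u
    r <- sqrt(pmax(0, 1 - x^2))
    pts <- cbind(x, r * cos(theta), r * sin(theta)) * radius
    pts <- pts + matrix(stats::rnorm(3 * n, sd = radius * 0.01), n, 3)
    pts[, 1] <- pmin(pts[, 1], -radius * 0.001)  # keep strictly left
    left <- pts
    right <- pts
    right[, 1] <- -right[, 1]
    left[, 1] <- left[, 1] - gap / 2
    right[, 1] <- right[, 1] + gap / 2
    ids <- c(sprintf("lh_parcel_%03d", i), sprintf("rh_parcel_%03d", i))
    structure(
      list(parcel_ids = ids,
           centroids = rbind(left, right),
           hemisphere = rep(c("left", "right"), each = n)),
      class = "parcel_geometry")
  })
}

#' @export
print.parcel_geometry <- function(x, ...) {
  cat("<parcel_geometry> ", length(x$parcel_ids), " parcels (",
      sum(x$hemisphere == "left"), " left / ",
      sum(x$hemisphere == "right"), " right)\n", sep = "")
  invisible(x)
}

# Cholesky factor of the exponential-covariance GP over centroid
# distances; small nugget for numerical positive-definiteness.
gp_chol <- function(geometry, length_scale) {
  d <- as.matrix(stats::dist(geometry$centroids))
  K <- exp(-d / length_scale)
  diag(K) <- diag(K) + 1e-8
  chol(K)
}

#' Draw a spatially autocorrelated parcel map
#'
#' Samples a zero-mean Gaussian process with exponential covariance
#' `exp(-d / length_scale)` over centroid distances and z-scores the
#' draw. Large length scales give smooth maps (neighboring parcels nearly
#' equal); as `length_scale -> 0` the draw degenerates to white noise.
#'
#' @param geometry A [make_parcel_geometry()] object.
#' @param length_scale Positive correlation length in geometry units.
#' @param seed Integer seed.
#' @param name Map name.
#' @param chol_K Optional precomputed Cholesky factor (upper triangular)
#'   of the covariance, to amortize repeated draws.
#' @return A z-scored [parcel_map()].
#' @export
sample_gp_map <- function(geometry, length_scale, seed = 1,
                          name = "gp_map", chol_K = NULL) {
  stopifnot(inherits(geometry, "parcel_geometry"))
  if (!is.numeric(length_scale) || length_scale <= 0)
    stop("length_scale must be positive")
  U <- if (is.null(chol_K)) gp_chol(geometry, length_scale) else chol_K
  v <- with_seed(seed,
    drop(crossprod(U, stats::rnorm(length(geometry$parcel_ids)))))
  zscore_map(parcel_map(v, geometry$parcel_ids, geometry$hemisphere,
                        name = name))
}

#' Library of intercorrelated autocorrelated atlas maps
#'
#' Builds `n_maps` GP maps sharing a common latent spatial pattern, so
#' that all pairs correlate at about `cross_correlation`
#' (equicorrelation construction: each map is
#' `sqrt(c) * common + sqrt(1 - c) * independent`).
#'
#' @inheritParams sample_gp_map
#' @param n_maps Number of maps (>= 1).
#' @param cross_correlation Target pairwise correlation, `|c| < 1`
#'   (negative values are rejected: an equicorrelated set with negative
#'   common correlation is not realizable for more than 2 maps).
#' @param names Optional map names (default `atlas_01`, ...).
#' @return An [atlas_set()] of z-scored maps.
#' @export
make_atlas_library <- function(geometry, n_maps, length_scale = 15,
                               cross_correlation = 0, seed = 1,
                               names = NULL) {
  stopifnot(inherits(geometry, "parcel_geometry"))
  if (n_maps < 1) stop("n_maps must be >= 1")
  if (!is.numeric(cross_correlation) || cross_correlation < 0 ||
      cross_correlation >= 1)
    stop("cross_correlation must be in [0, 1)")
  if (is.null(names)) names <- sprintf("atlas_%02d", seq_len(n_maps))
  U <- gp_chol(geometry, length_scale)
  n <- length(geometry$parcel_ids)
  with_seed(seed, {
    common <- drop(crossprod(U, stats::rnorm(n)))
    common <- (common - mean(common)) / sqrt(mean((common - mean(common))^2))
    maps <- lapply(seq_len(n_maps), function(k) {
      indep <- drop(crossprod(U, stats::rnorm(n)))
      indep <- (indep - mean(indep)) / sqrt(mean((indep - mean(indep))^2))
      v <- sqrt(cross_correlation) * common +
        sqrt(1 - cross_correlation) * indep
      zscore_map(parcel_map(v, geometry$parcel_ids, geometry$hemisphere,
                            name = names[k]))
    })
    atlas_set(maps, provenance = "synthetic GP library")
  })
}

#' Ground-truth record for synthetic CT-change construction
#'
#' @param mixture_weights Numeric weights, one per atlas in the truth
#'   library, defining the change-map mixture.
#' @param noise_sd SD of the additive GP noise, in units of the z-scored
#'   mixture signal. Exactly one of `noise_sd` / `target_r2` must be
#'   given.
#' @param target_r2 Desired construction R-squared; `noise_sd` is then
#'   solved from the realized signal variance.
#' @param seed Integer seed for the noise draw.
#' @return A `ground_truth` object; `construction_r2` is filled in by
#'   [make_ct_trajectories()] with the realized value
#'   `var(signal) / var(signal + noise)`.
#' @export
ground_truth <- function(mixture_weights, noise_sd = NULL,
                         target_r2 = NULL, seed = 1) {
  if (is.null(noise_sd) == is.null(target_r2))
    stop("give exactly one of noise_sd or target_r2")
  structure(list(mixture_weights = as.numeric(mixture_weights),
                 noise_sd = noise_sd, target_r2 = target_r2,
                 construction_r2 = NA_real_, seed = as.integer(seed)),
            class = "ground_truth")
}

# smoothstep ramp: 0 below a, 1 above b, C1-smooth in between
smoothstep <- function(x, a, b) {
  t <- pmin(1, pmax(0, (x - a) / (b - a)))
  t * t * (3 - 2 * t)
}

#' Synthetic normative CT trajectories with a known change-map mixture
#'
#' Builds per-parcel CT age curves as
#' `baseline_map x age_factor x (1 + m_p * ramp(age))`, where the ramp
#' rises smoothly from 0 at the start to 1 at the end of a designated
#' target window. The relative CT change over that window is then an
#' affine function of the modulation map `m`, which is constructed as the
#' stated mixture of atlas maps plus autocorrelated GP noise — so the
#' target window's change map carries a known signal with a known
#' construction R-squared, while CT stays positive everywhere.
#'
#' Percentile curves are multiplicative offsets of the median; male and
#' female curves are symmetric offsets whose average equals the designed
#' median curve exactly.
#'
#' @param geometry A [make_parcel_geometry()] object.
#' @param atlas_truth [atlas_set()] whose maps enter the mixture.
#' @param truth A [ground_truth()] with one weight per atlas.
#' @param age_grid Strictly increasing ages in years (default 5-90 by
#'   0.5, the 171-point normative grid).
#' @param target_window Length-2 numeric `(i, j)` designating the window
#'   whose change map realizes the mixture (default `c(10, 15)`).
#' @param modulation_amplitude Scale of the modulation map in relative-CT
#'   units (default 0.03, i.e. about a 3-percent-of-CT spatial pattern).
#' @param noise_length_scale Length scale of the GP noise (default 15).
#' @return List with `trajectories` (a `ct_trajectory_set`) and `truth`
#'   (the input with `noise_sd` and realized `construction_r2` filled).
#' @export
make_ct_trajectories <- function(geometry, atlas_truth, truth,
                                 age_grid = seq(5, 90, by = 0.5),
                                 target_window = c(10, 15),
                                 modulation_amplitude = 0.03,
                                 noise_length_scale = 15) {
  stopifnot(inherits(geometry, "parcel_geometry"),
            inherits(atlas_truth, "atlas_set"),
            inherits(truth, "ground_truth"))
  if (any(diff(age_grid) <= 0)) stop("age_grid must be strictly increasing")
  w <- truth$mixture_weights
  if (length(w) != length(atlas_truth$maps))
    stop("mixture_weights length (", length(w),
         ") does not match atlas count (", length(atlas_truth$maps), ")")
  if (target_window[2] <= target_window[1])
    stop("target_window must satisfy j > i")
  n <- length(geometry$parcel_ids)
  A <- atlas_matrix(atlas_truth)
  if (!identical(rownames(A), geometry$parcel_ids))
    stop("atlas_truth parcels do not match geometry")

  signal <- drop(A %*% w)
  popsd <- function(x) sqrt(mean((x - mean(x))^2))
  noise_sd <- truth$noise_sd
  if (is.null(noise_sd)) {
    r2 <- truth$target_r2
    noise_sd <- if (popsd(signal) == 0) 0 else
      popsd(signal) * sqrt((1 - r2) / r2)
  }
  noise <- rep(0, n)
  if (noise_sd > 0) {
    raw <- sample_gp_map(geometry, noise_length_scale,
                         seed = truth$seed, name = "noise")$values
    # orthogonalize against the signal so the realized construction R^2
    # equals var(signal) / (var(signal) + noise_sd^2) by construction
    if (popsd(signal) > 0) {
      raw <- raw - mean(raw)
      sc <- signal - mean(signal)
      raw <- raw - sc * sum(raw * sc) / sum(sc^2)
    }
    noise <- noise_sd * raw / popsd(raw)
  }
  mix <- signal + noise
  # realized construction R^2: var(signal) / var(signal + noise)
  truth$noise_sd <- noise_sd
  truth$construction_r2 <- if (popsd(mix) == 0) 0 else
    (popsd(signal) / popsd(mix))^2
  # modulation map in relative-CT units
  m <- if (popsd(mix) == 0) rep(0, n) else
    modulation_amplitude * (mix - mean(mix)) / popsd(mix)

  # positive baseline map around 2.5 mm with mild autocorrelated variation
  base_map <- sample_gp_map(geometry, noise_length_scale,
                            seed = truth$seed + 7919L, name = "baseline")
  B <- 2.5 * exp(0.06 * base_map$values)
  g <- 0.85 + 0.30 * exp(-(age_grid - min(age_grid)) / 25)  # declining
  ramp <- smoothstep(age_grid, target_window[1], target_window[2])

  percentiles <- c(1, 5, 25, 50, 75, 95, 99)
  sexes <- c("female", "male")
  pct_fac <- 1 + 0.06 * stats::qnorm(percentiles / 100)
  # age-dependent sex offset, symmetric around 1 so the female/male
  # average reproduces the designed median curve exactly
  sex_delta <- 0.02 + 3e-4 * (age_grid - min(age_grid))
  ct <- array(NA_real_,
              dim = c(n, length(age_grid), length(percentiles), 2),
              dimnames = list(geometry$parcel_ids, NULL,
                              as.character(percentiles), sexes))
  med <- outer(B, g) * (1 + outer(m, ramp))   # parcel x age
  for (p in seq_along(percentiles)) {
    ct[, , p, 1] <- sweep(med * pct_fac[p], 2, 1 - sex_delta, "*")
    ct[, , p, 2] <- sweep(med * pct_fac[p], 2, 1 + sex_delta, "*")
  }
  stopifnot(all(ct > 0))
  traj <- structure(
    list(parcel_ids = geometry$parcel_ids,
         hemisphere = geometry$hemisphere,
         ages = age_grid, percentiles = percentiles, sexes = sexes,
         ct = ct, target_window = target_window),
    class = "ct_trajectory_set")
  list(trajectories = traj, truth = truth)
}

#' @export
print.ct_trajectory_set <- function(x, ...) {
  cat("<ct_trajectory_set> ", length(x$parcel_ids), " parcels x ",
      length(x$ages), " ages (", min(x$ages), "-", max(x$ages), ") x ",
      length(x$percentiles), " percentiles x ", length(x$sexes),
      " sexes\n", sep = "")
  invisible(x)
}

#' Synthetic developmental gene-expression dataset
#'
#' Emulates a postnatal brain-development expression resource: a small
#' cross-sectional cohort with log-scale ages, "signal" genes whose
#' trajectories are smoothly elevated inside a peak period (in units of
#' the within-gene noise SD), "flat" brain genes, and a large pool of
#' non-brain genes that are level plus noise (the null resampling pool).
#'
#' @param n_subjects Number of subjects (default 33).
#' @param age_range Postnatal age range in years (default
#'   `c(0.33, 82.05)`); subject ages are uniform on the square-root
#'   scale (dense in childhood, several adults across the upper range,
#'   as in postnatal brain-development expression resources) with the
#'   range endpoints always included.
#' @param n_signal_genes,n_flat_genes Counts of peaked / flat brain genes
#'   (defaults 20 and 50).
#' @param n_nonbrain_pool Size of the non-brain null pool (default 2154).
#' @param peak_period Length-2 ages bounding the elevation (default
#'   `c(5, 30)`, the main developmental period).
#' @param effect_size Elevation inside the peak period in within-gene SD
#'   units (default 2).
#' @param seed Integer seed.
#' @return An `expression_dataset`: `subjects` (data.frame id/age),
#'   `expression` (subjects x genes matrix), `gene_sets` (named list,
#'   initially one set per signal gene plus a pooled `all_signal` set),
#'   `nonbrain_pool`, and ground-truth gene annotations.
#' @export
make_expression_dataset <- function(n_subjects = 33,
                                    age_range = c(0.33, 82.05),
                                    n_signal_genes = 20,
                                    n_flat_genes = 50,
                                    n_nonbrain_pool = 2154,
                                    peak_period = c(5, 30),
                                    effect_size = 2,
                                    seed = 1) {
  if (n_nonbrain_pool < 1) stop("non-brain pool must be non-empty")
  if (n_subjects < 3) stop("need at least 3 subjects")
  if (peak_period[1] <= age_range[1] || peak_period[2] >= age_range[2])
    stop("peak_period must lie strictly inside age_range")
  with_seed(seed, {
    ages <- sort(c(age_range,
                   stats::runif(n_subjects - 2, sqrt(age_range[1]),
                                sqrt(age_range[2]))^2))
    subjects <- data.frame(id = sprintf("S%03d", seq_len(n_subjects)),
                           age = ages, stringsAsFactors = FALSE)
    sig <- sprintf("SIG%03d", seq_len(n_signal_genes))
    flat <- sprintf("FLAT%03d", seq_len(n_flat_genes))
    nb <- sprintf("NB%04d", seq_len(n_nonbrain_pool))
    genes <- c(sig, flat, nb)
    base <- stats::rnorm(length(genes), mean = 6, sd = 1)
    w <- diff(peak_period) / 8
    bump <- stats::plogis((ages - peak_period[1]) / w) *
      stats::plogis((peak_period[2] - ages) / w)
    expr <- matrix(stats::rnorm(n_subjects * length(genes)),
                   n_subjects, length(genes),
                   dimnames = list(subjects$id, genes))
    expr <- sweep(expr, 2, base, "+")
    if (n_signal_genes > 0)
      expr[, sig] <- expr[, sig] + effect_size * bump
    gene_sets <- stats::setNames(as.list(sig), sig)
    if (n_signal_genes > 1) gene_sets$all_signal <- sig
    structure(
      list(subjects = subjects, genes = genes, expression = expr,
           gene_sets = gene_sets, nonbrain_pool = nb,
           signal_genes = sig, flat_genes = flat,
           peak_period = peak_period, effect_size = effect_size),
      class = "expression_dataset")
  })
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("<expression_dataset> ", nrow(x$subjects), " subjects (ages ",
      signif(min(x$subjects$age), 3), "-", signif(max(x$subjects$age), 3),
      ") x ", length(x$genes), " genes; non-brain pool ",
      length(x$nonbrain_pool), "\n", sep = "")
  invisible(x)
}

#' Synthetic two-session longitudinal cohort
#'
#' Per-subject CT at each session = population trajectory (median
#' percentile, sex-average) evaluated at the session age, plus a
#' subject-level random intercept map, a site offset map, and i.i.d.
#' measurement noise. The generator emits already-harmonized data (no
#' site-by-scale interactions).
#'
#' @param geometry A [make_parcel_geometry()] object.
#' @param trajectories A `ct_trajectory_set` (population reference).
#' @param n_subjects,n_sites Cohort size and number of sites (sites
#'   assigned round-robin, so labels are balanced within one).
#' @param subject_sd,site_sd SDs (mm) of the subject-intercept and
#'   site-offset GP maps.
#' @param noise_sd SD (mm) of i.i.d. measurement noise per parcel and
#'   session.
#' @param session_ages Ages (years) of the sessions, on the trajectory
#'   age grid; default `c(10, 12)` (baseline and 2-year follow-up).
#' @param length_scale GP length scale of the offset maps.
#' @param seed Integer seed.
#' @return A `cohort_data` object: `subjects` (id, sex, site), `sessions`
#'   (label, age), `ct` (subject x session x parcel array).
#' @export
make_cohort <- function(geometry, trajectories, n_subjects = 100,
                        n_sites = 20, subject_sd = 0.05, site_sd = 0.05,
                        noise_sd = 0.02, session_ages = c(10, 12),
                        length_scale = 15, seed = 1) {
  stopifnot(inherits(geometry, "parcel_geometry"),
            inherits(trajectories, "ct_trajectory_set"))
  if (length(session_ages) < 2) stop("need at least 2 session ages")
  if (n_sites < 1) stop("n_sites must be >= 1")
  idx <- match(session_ages, trajectories$ages)
  if (anyNA(idx))
    stop("session age(s) not on the trajectory age grid: ",
         paste(session_ages[is.na(idx)], collapse = ", "))
  n <- length(geometry$parcel_ids)
  # population CT: median percentile, sex-average
  p50 <- match(50, trajectories$percentiles)
  pop <- (trajectories$ct[, idx, p50, "female", drop = FALSE] +
            trajectories$ct[, idx, p50, "male", drop = FALSE]) / 2
  pop <- array(pop, dim = c(n, length(idx)))   # parcel x session
  U <- gp_chol(geometry, length_scale)
  with_seed(seed, {
    sites <- rep_len(sprintf("site%02d", seq_len(n_sites)), n_subjects)
    site_maps <- vapply(seq_len(n_sites), function(s) {
      v <- drop(crossprod(U, stats::rnorm(n)))
      site_sd * (v - mean(v)) / max(sqrt(mean((v - mean(v))^2)), 1e-12)
    }, numeric(n))
    ct <- array(NA_real_,
                dim = c(n_subjects, length(session_ages), n),
                dimnames = list(sprintf("sub%04d", seq_len(n_subjects)),
                                sprintf("T%d", seq_along(session_ages) - 1),
                                geometry$parcel_ids))
    for (s in seq_len(n_subjects)) {
      v <- drop(crossprod(U, stats::rnorm(n)))
      b_s <- subject_sd * (v - mean(v)) /
        max(sqrt(mean((v - mean(v))^2)), 1e-12)
      for (j in seq_along(session_ages)) {
        eps <- if (noise_sd > 0) stats::rnorm(n, sd = noise_sd) else 0
        ct[s, j, ] <- pop[, j] + b_s +
          site_maps[, match(sites[s], sprintf("site%02d", seq_len(n_sites)))] +
          eps
      }
    }
    if (any(ct <= 0))
      stop("offset/noise SDs produced non-positive CT; reduce them")
    structure(
      list(subjects = data.frame(
             id = sprintf("sub%04d", seq_len(n_subjects)),
             sex = rep_len(c("female", "male"), n_subjects),
             site = sites, stringsAsFactors = FALSE),
           sessions = data.frame(
             label = sprintf("T%d", seq_along(session_ages) - 1),
             age = session_ages, stringsAsFactors = FALSE),
           parcel_ids = geometry$parcel_ids,
           ct = ct),
      class = "cohort_data")
  })
}

#' @export
print.cohort_data <- function(x, ...) {
  cat("<cohort_data> ", nrow(x$subjects), " subjects x ",
      nrow(x$sessions), " sessions x ", length(x$parcel_ids),
      " parcels; ", length(unique(x$subjects$site)), " sites\n", sep = "")
  invisible(x)
}
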