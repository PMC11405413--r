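#' @title Single-subject longitudinal transfer
#' @description Applies the colocalization framework to two-session
#'   cohorts: per-subject relative CT change maps, one exhaustive
#'   dominance decomposition per subject, and a group-level test that
#'   compares the cohort-mean full-model R-squared (and each
#'   cohort-mean dominance) against null analyses in which the whole
#'   subject-level pipeline is re-run with surrogate predictor sets.
#' @name cohort_subject_level
NULL

#' Per-subject relative CT change maps
#'
#' Applies the relative-change formula `(CT_b - CT_a) / CT_a` per parcel
#' to each subject's session pair. Subjects missing either session (any
#' non-finite CT) are excluded with a message reporting the count.
#'
#' @param cohort A `cohort_data` object (see [make_cohort()] or
#'   [read_cohort_table()]).
#' @param span Length-2 session labels or indices (default: first and
#'   last session).
#' @return Named list of `ct_change_map`s, one per retained subject;
#'   attribute `excluded` carries the dropped subject ids.
#' @export
subject_change <- function(cohort, span = NULL) {
  stopifnot(inherits(cohort, "cohort_data"))
  labs <- cohort$sessions$label
  if (is.null(span)) span <- labs[c(1, length(labs))]
  idx <- if (is.numeric(span)) span else match(span, labs)
  if (anyNA(idx) || length(idx) != 2)
    stop("span must name two sessions among: ",
         paste(labs, collapse = ", "))
  win <- cohort$sessions$age[idx]
  keep <- list()
  excluded <- character(0)
  for (s in seq_len(nrow(cohort$subjects))) {
    a <- cohort$ct[s, idx[1], ]
    b <- cohort$ct[s, idx[2], ]
    if (anyNA(a) || anyNA(b) || any(!is.finite(c(a, b)))) {
      excluded <- c(excluded, cohort$subjects$id[s])
      next
    }
    mi <- parcel_map(a, cohort$parcel_ids, name = "ct_a")
    mj <- parcel_map(b, cohort$parcel_ids, name = "ct_b")
    ch <- relative_change(mi, mj, window = win)
    ch$name <- paste0("dCT_", cohort$subjects$id[s])
    keep[[cohort$subjects$id[s]]] <- ch
  }
  if (!length(keep))
    stop("no subject has both sessions of the requested span")
  if (length(excluded))
    message(length(excluded), " subject(s) excluded (missing session): ",
            paste(utils::head(excluded, 5), collapse = ", "),
            if (length(excluded) > 5) ", ...")
  attr(keep, "excluded") <- excluded
  attr(keep, "window") <- win
  keep
}

#' Cohort-average change map
#'
#' Relative change of the cohort-average CT between two sessions. Note
#' this differs (slightly, by the nonlinearity of ratios) from the
#' average of the per-subject change maps; both are of interest and
#' [subject_change()] provides the other route.
#'
#' @inheritParams subject_change
#' @return A `ct_change_map`.
#' @export
cohort_average_change <- function(cohort, span = NULL) {
  stopifnot(inherits(cohort, "cohort_data"))
  labs <- cohort$sessions$label
  if (is.null(span)) span <- labs[c(1, length(labs))]
  idx <- if (is.numeric(span)) span else match(span, labs)
  a <- colMeans(cohort$ct[, idx[1], , drop = FALSE][, 1, ])
  b <- colMeans(cohort$ct[, idx[2], , drop = FALSE][, 1, ])
  relative_change(parcel_map(a, cohort$parcel_ids, name = "ct_a"),
                  parcel_map(b, cohort$parcel_ids, name = "ct_b"),
                  window = cohort$sessions$age[idx])
}

#' Per-subject dominance decompositions
#'
#' One exhaustive dominance analysis per subject change map (identical
#' machinery to [total_dominance()]).
#'
#' @param changes Named list of per-subject `ct_change_map`s from
#'   [subject_change()].
#' @param predictors An [atlas_set()] (p <= 15), parcel-aligned with the
#'   cohort.
#' @return Data.frame with one row per subject and columns `subject`,
#'   `r2`, `adj_r2`, and `dom_<predictor>` for each predictor; attribute
#'   `dominance` holds the p x subjects matrix.
#' @export
subject_dominance <- function(changes, predictors) {
  stopifnot(inherits(predictors, "atlas_set"))
  X <- atlas_matrix(predictors)
  p <- ncol(X)
  if (p > 15) stop("p > 15 exceeds the exhaustive enumeration cap")
  n <- nrow(X)
  Y <- vapply(changes, function(ch) {
    check_aligned(predictors$maps[[1]], ch)
    ch$values
  }, numeric(n))
  Y <- matrix(Y, ncol = length(changes))
  meta <- dominance_meta(p)
  R2 <- subset_r2_all(X, Y, meta)
  D <- dominance_from_r2(R2, p, meta)
  full <- R2[2^p, ]
  out <- data.frame(subject = names(changes), r2 = full,
                    adj_r2 = .adj_r2(full, n, p),
                    stringsAsFactors = FALSE, row.names = NULL)
  for (k in seq_len(p)) out[[paste0("dom_", colnames(X)[k])]] <- D[k, ]
  rownames(D) <- colnames(X)
  colnames(D) <- names(changes)
  attr(out, "dominance") <- D
  out
}

#' Group-mean permuted-atlas test
#'
#' Tests whether the cohort-mean full-model R-squared and each
#' cohort-mean total dominance are higher than expected under spatially
#' matched null predictors: each null iteration redraws one surrogate
#' per atlas (shared across subjects within the iteration, since the
#' exchangeability argument lives on the atlases), recomputes every
#' subject-level model, and takes the mean statistic. Positive-sided
#' empirical p with the `(k+1)/(N+1)` convention.
#'
#' @param changes Per-subject `ct_change_map`s from [subject_change()].
#' @param predictors An [atlas_set()] (p <= 15).
#' @param nulls Named list of [generate_surrogates()] ensembles per
#'   predictor.
#' @param n_null Number of null iterations (default 1000, the
#'   production setting; tests use less).
#' @return List: `p_full`, `p_dominance` (named), `mean_r2`,
#'   `mean_dominance`, `n_null`.
#' @export
group_mean_null_test <- function(changes, predictors, nulls,
                                 n_null = 1000) {
  if (length(changes) < 2) stop("need at least 2 subjects")
  if (n_null < 1) stop("n_null must be >= 1")
  X <- atlas_matrix(predictors)
  p <- ncol(X)
  missing_nulls <- setdiff(colnames(X), names(nulls))
  if (length(missing_nulls))
    stop("no null ensemble for predictor(s): ",
         paste(missing_nulls, collapse = ", "))
  N <- min(n_null,
           min(vapply(nulls[colnames(X)], function(e) ncol(e$surrogates),
                      integer(1))))
  obs <- subject_dominance(changes, predictors)
  mean_r2 <- mean(obs$r2)
  mean_dom <- rowMeans(attr(obs, "dominance"))
  n <- nrow(X)
  Y <- vapply(changes, function(ch) ch$values, numeric(n))
  Y <- matrix(Y, ncol = length(changes))
  meta <- dominance_meta(p)
  exceed_full <- 0
  exceed_dom <- numeric(p)
  for (t in seq_len(N)) {
    Xt <- vapply(colnames(X), function(nm) nulls[[nm]]$surrogates[, t],
                 numeric(n))
    R2t <- subset_r2_all(Xt, Y, meta)
    exceed_full <- exceed_full + (mean(R2t[2^p, ]) >= mean_r2)
    exceed_dom <- exceed_dom +
      (rowMeans(dominance_from_r2(R2t, p, meta)) >= mean_dom)
  }
  list(p_full = (1 + exceed_full) / (1 + N),
       p_dominance = stats::setNames((1 + exceed_dom) / (1 + N),
                                     colnames(X)),
       mean_r2 = mean_r2,
       mean_dominance = stats::setNames(mean_dom, colnames(X)),
       n_null = N)
}

#' Read / write a cohort as a long-format table
#'
#' Long TSV with columns `subject`, `session`, `age`, `sex`, `site`,
#' `parcel`, `ct`. The hook for externally harmonized data: any table in
#' this layout can enter the subject-level pipeline.
#'
#' @param cohort A `cohort_data`.
#' @param path TSV path.
#' @return `path` invisibly (`write`); a `cohort_data` (`read`).
#' @export
write_cohort_table <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_data"))
  g <- expand.grid(subject = cohort$subjects$id,
                   session = cohort$sessions$label,
                   parcel = cohort$parcel_ids,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$age <- cohort$sessions$age[match(g$session, cohort$sessions$label)]
  g$sex <- cohort$subjects$sex[match(g$subject, cohort$subjects$id)]
  g$site <- cohort$subjects$site[match(g$subject, cohort$subjects$id)]
  g$ct <- sprintf("%.17g", cohort$ct[cbind(
    match(g$subject, cohort$subjects$id),
    match(g$session, cohort$sessions$label),
    match(g$parcel, cohort$parcel_ids))])
  g <- g[, c("subject", "session", "age", "sex", "site", "parcel", "ct")]
  utils::write.table(g, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("subject", "session", "age", "sex", "site", "parcel", "ct")
  if (!all(need %in% names(df)))
    stop("cohort table needs columns: ", paste(need, collapse = ", "))
  subjects <- unique(df[, c("subject", "sex", "site")])
  sessions <- unique(df[, c("session", "age")])
  sessions <- sessions[order(sessions$age), ]
  parcels <- unique(df$parcel)
  ct <- array(NA_real_,
              dim = c(nrow(subjects), nrow(sessions), length(parcels)),
              dimnames = list(subjects$subject, sessions$session, parcels))
  ct[cbind(match(df$subject, subjects$subject),
           match(df$session, sessions$session),
           match(df$parcel, parcels))] <- df$ct
  structure(list(
    subjects = data.frame(id = subjects$subject, sex = subjects$sex,
                          site = subjects$site, stringsAsFactors = FALSE),
    sessions = data.frame(label = sessions$session, age = sessions$age,
                          stringsAsFactors = FALSE),
    parcel_ids = parcels, ct = ct), class = "cohort_data")
}
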