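#' @title Relative CT change maps over lifespan windows
#' @description Windowed relative change of modeled cortical thickness:
#'   `dCT(i, j) = (CT_j - CT_i) / CT_i` per parcel, evaluated on a
#'   sliding-window scheme over the normative age grid (by default
#'   5-year windows advanced in 1-year steps from age 5 to 90, optionally
#'   with extra windows such as the whole 5-30 developmental period).
#' @name ct_change_windows
NULL

#' Relative CT change between two maps
#'
#' Elementwise `(CT_j - CT_i) / CT_i`; unitless, scale-free in the
#' baseline (`relative_change(a, a * (1 + c)) == c`).
#'
#' @param ct_i,ct_j [parcel_map()]s of CT (mm) at ages i and j, aligned;
#'   `ct_i` must be strictly positive.
#' @param window Optional length-2 numeric `(i, j)` recorded on the
#'   result.
#' @return A `ct_change_map`: a [parcel_map()] with attributes `window`,
#'   `percentile`, `sex`.
#' @export
relative_change <- function(ct_i, ct_j, window = c(NA_real_, NA_real_)) {
  stopifnot(inherits(ct_i, "parcel_map"), inherits(ct_j, "parcel_map"))
  check_aligned(ct_i, ct_j)
  if (any(ct_i$values <= 0))
    stop("baseline CT must be strictly positive; found min ",
         signif(min(ct_i$values), 4))
  out <- parcel_map((ct_j$values - ct_i$values) / ct_i$values,
                    ct_i$parcel_ids, ct_i$hemisphere,
                    name = if (all(is.finite(window)))
                      sprintf("dCT_%g_%g", window[1], window[2])
                    else "dCT")
  attr(out, "window") <- window
  class(out) <- c("ct_change_map", class(out))
  out
}

#' Sliding-window scheme over the lifespan
#'
#' Windows `(i, i + length)` for `i = start, start + step, ...,
#' end - length`, with optional extra windows appended (e.g. the full
#' developmental period `(5, 30)`). The default lifespan scheme
#' (5-90 years, 5-year length, 1-year step) yields 81 windows.
#'
#' @param start,end Age bounds in years.
#' @param length Window length in years (> 0).
#' @param step Step between window starts in years (> 0).
#' @param extra_windows Optional list of length-2 numeric windows to
#'   append.
#' @return A data.frame with columns `i`, `j`, and `center`
#'   (the reporting label, midpoint of the window).
#' @export
build_windows <- function(start = 5, end = 90, length = 5, step = 1,
                          extra_windows = list()) {
  if (length <= 0 || step <= 0) stop("length and step must be positive")
  if (end < start + length)
    stop("end must be at least start + length (got ", start, "-", end,
         ", length ", length, ")")
  i <- seq(start, end - length, by = step)
  w <- data.frame(i = i, j = i + length)
  for (ex in extra_windows) {
    if (length(ex) != 2 || ex[2] <= ex[1])
      stop("extra window must be (i, j) with j > i")
    w <- rbind(w, data.frame(i = ex[1], j = ex[2]))
  }
  w$center <- (w$i + w$j) / 2
  w
}

#' Extract change maps for a window scheme from normative trajectories
#'
#' Selects the requested percentile and sex slice of a
#' `ct_trajectory_set` (sex-average = mean of the female and male CT
#' before the change computation) and computes one relative change map
#' per window. Window endpoints must lie exactly on the age grid; there
#' is no interpolation.
#'
#' @param trajectories A `ct_trajectory_set`.
#' @param windows Data.frame from [build_windows()].
#' @param percentile Percentile label (default 50).
#' @param sex `"average"` (default), `"female"`, or `"male"`.
#' @param baseline_correct If `TRUE`, each change map is residualized
#'   across parcels on the baseline CT map of its window (linear fit),
#'   the sensitivity mode controlling for baseline modeled CT.
#' @return List of `ct_change_map`s, one per window row.
#' @export
extract_change_series <- function(trajectories, windows, percentile = 50,
                                  sex = c("average", "female", "male"),
                                  baseline_correct = FALSE) {
  stopifnot(inherits(trajectories, "ct_trajectory_set"))
  sex <- match.arg(sex)
  pidx <- match(percentile, trajectories$percentiles)
  if (is.na(pidx))
    stop("percentile ", percentile, " not in the trajectory set (",
         paste(trajectories$percentiles, collapse = ", "), ")")
  ct_slice <- function(aidx) {
    if (sex == "average")
      (trajectories$ct[, aidx, pidx, "female"] +
         trajectories$ct[, aidx, pidx, "male"]) / 2
    else trajectories$ct[, aidx, pidx, sex]
  }
  lapply(seq_len(nrow(windows)), function(r) {
    ai <- match(windows$i[r], trajectories$ages)
    aj <- match(windows$j[r], trajectories$ages)
    if (is.na(ai) || is.na(aj))
      stop("window (", windows$i[r], ", ", windows$j[r],
           ") endpoints are not on the age grid; no interpolation is done")
    mi <- parcel_map(ct_slice(ai), trajectories$parcel_ids,
                     trajectories$hemisphere, name = "ct_i")
    mj <- parcel_map(ct_slice(aj), trajectories$parcel_ids,
                     trajectories$hemisphere, name = "ct_j")
    ch <- relative_change(mi, mj, window = c(windows$i[r], windows$j[r]))
    attr(ch, "percentile") <- percentile
    attr(ch, "sex") <- sex
    if (baseline_correct) {
      res <- stats::lm.fit(cbind(1, mi$values), ch$values)$residuals
      v <- parcel_map(res, ch$parcel_ids, ch$hemisphere,
                      name = paste0(ch$name, "_blcorr"))
      attributes(v)[c("window", "percentile", "sex")] <-
        attributes(ch)[c("window", "percentile", "sex")]
      class(v) <- class(ch)
      ch <- v
    }
    ch
  })
}

#' Write / read normative CT trajectories as a long-format table
#'
#' Long TSV with columns `parcel`, `age`, `percentile`, `sex`, `ct`.
#'
#' @param trajectories A `ct_trajectory_set`.
#' @param path Output TSV path.
#' @return `path` invisibly (`write`), or a `ct_trajectory_set` (`read`).
#' @export
write_trajectory_table <- function(trajectories, path) {
  stopifnot(inherits(trajectories, "ct_trajectory_set"))
  g <- expand.grid(parcel = trajectories$parcel_ids,
                   age = trajectories$ages,
                   percentile = trajectories$percentiles,
                   sex = trajectories$sexes,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$ct <- sprintf("%.17g", as.vector(trajectories$ct))
  utils::write.table(g, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_table
#' @export
read_trajectory_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("parcel", "age", "percentile", "sex", "ct")
  if (!all(need %in% names(df)))
    stop("trajectory table needs columns: ", paste(need, collapse = ", "))
  parcels <- unique(df$parcel)
  ages <- sort(unique(df$age))
  pct <- sort(unique(df$percentile))
  sexes <- unique(df$sex)
  ct <- array(NA_real_,
              dim = c(length(parcels), length(ages), length(pct),
                      length(sexes)),
              dimnames = list(parcels, NULL, as.character(pct), sexes))
  ct[cbind(match(df$parcel, parcels), match(df$age, ages),
           match(df$percentile, pct), match(df$sex, sexes))] <- df$ct
  if (anyNA(ct)) stop("trajectory table has missing parcel/age cells")
  if (any(ct <= 0)) stop("CT values must be positive")
  structure(list(parcel_ids = parcels,
                 hemisphere = rep("unknown", length(parcels)),
                 ages = ages, percentiles = pct, sexes = sexes, ct = ct),
            class = "ct_trajectory_set")
}
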