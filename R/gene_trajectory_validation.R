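#' @title Developmental gene-expression trajectory validation
#' @description Tests whether the genes underlying a neurobiological
#'   marker are preferentially expressed in cortex during the
#'   developmental period in which that marker explains CT change:
#'   gene-set expression is averaged per subject, smoothed over age with
#'   LOESS, averaged inside versus outside the period, and the mean and
#'   the in/out ratio are compared against the same statistics computed
#'   on size-matched gene sets resampled from a pool of non-brain genes
#'   (positive-sided empirical p, one BH-FDR family across all tests).
#' @name gene_trajectory_validation
NULL

#' Average expression series of a gene set
#'
#' Uniform average across the set's genes per subject.
#'
#' @param data An `expression_dataset` (see
#'   [make_expression_dataset()] or [read_expression_dataset()]).
#' @param genes Nonempty character vector of gene symbols, all present.
#' @return Data.frame with `age` and `expression`, ordered by age.
#' @export
gene_set_trajectory <- function(data, genes) {
  stopifnot(inherits(data, "expression_dataset"))
  if (!length(genes)) stop("empty gene set")
  absent <- setdiff(genes, colnames(data$expression))
  if (length(absent))
    stop("gene(s) not in the expression matrix: ",
         paste(absent, collapse = ", "))
  expr <- rowMeans(data$expression[, genes, drop = FALSE])
  ord <- order(data$subjects$age)
  data.frame(age = data$subjects$age[ord], expression = expr[ord])
}

#' LOESS-smoothed expression trajectory
#'
#' Locally estimated scatterplot smoothing of an expression series over
#' age (span 0.75, locally quadratic, tricube weights), evaluated on a
#' grid strictly inside the observed age range (no extrapolation).
#'
#' @param series Data.frame with `age` and `expression` (>= 8 subjects).
#' @param eval_grid Ages at which to evaluate the curve; default
#'   0.5-year steps across the observed range.
#' @param span,degree LOESS parameters (defaults 0.75 / 2).
#' @return Data.frame with `age` and `expression` (the smoothed curve).
#' @export
loess_trajectory <- function(series, eval_grid = NULL, span = 0.75,
                             degree = 2) {
  if (nrow(series) < 8)
    stop("need at least 8 subjects for a stable LOESS fit")
  rng <- range(series$age)
  if (is.null(eval_grid))
    eval_grid <- seq(ceiling(rng[1] * 2) / 2, floor(rng[2] * 2) / 2,
                     by = 0.5)
  if (min(eval_grid) < rng[1] || max(eval_grid) > rng[2])
    stop("evaluation grid extends outside the observed age range; ",
         "no extrapolation")
  fit <- stats::loess(expression ~ age, data = series, span = span,
                      degree = degree, family = "gaussian",
                      surface = "direct")
  data.frame(age = eval_grid,
             expression = stats::predict(fit, data.frame(age = eval_grid)))
}

#' In-period versus out-of-period statistics of a trajectory
#'
#' Averages the smoothed curve at grid points inside the period
#' (endpoints inclusive) and outside it, and forms the in/out ratio.
#'
#' @param curve Data.frame with `age` and `expression`.
#' @param period Length-2 ages; both partitions must be nonempty.
#' @return List: `mean_in`, `mean_out`, `ratio`.
#' @export
period_statistics <- function(curve, period) {
  if (period[2] <= period[1]) stop("period must be (a, b) with b > a")
  inside <- curve$age >= period[1] & curve$age <= period[2]
  if (!any(inside) || all(inside))
    stop("period must leave both an inside and an outside partition ",
         "of the evaluation grid nonempty")
  mean_in <- mean(curve$expression[inside])
  mean_out <- mean(curve$expression[!inside])
  if (abs(mean_out) < .Machine$double.eps)
    stop("mean outside the period is zero; ratio undefined")
  list(mean_in = mean_in, mean_out = mean_out,
       ratio = mean_in / mean_out)
}

#' Marker gene-set trajectory tests against non-brain null sets
#'
#' For each marker: (i) LOESS trajectory of the marker's gene-set
#' expression, (ii) its significant time period, (iii) mean expression
#' inside/outside that period and their ratio, (iv) positive-sided
#' empirical p-values for the mean and the ratio against `n_null`
#' size-matched gene sets resampled from the non-brain pool through the
#' identical LOESS-and-period pipeline, (v) BH-FDR across all marker-by-
#' statistic tests as a single family. Null draws are shared across
#' markers with equal set size and period.
#'
#' @param data An `expression_dataset`.
#' @param marker_sets Named list; each element is
#'   `list(genes = <character>, period = c(a, b))`.
#' @param n_null Number of null gene-set draws (>= 1; 10000 at
#'   production scale, 1000 in tests).
#' @param seed Integer seed.
#' @param span,degree LOESS parameters passed through.
#' @return Data.frame per marker: `marker`, `set_size`, `period_lo`,
#'   `period_hi`, `mean_in`, `mean_out`, `ratio`, `p_mean`, `p_ratio`,
#'   `q_mean`, `q_ratio`.
#' @export
trajectory_test <- function(data, marker_sets, n_null = 1000, seed = 1,
                            span = 0.75, degree = 2) {
  stopifnot(inherits(data, "expression_dataset"))
  if (n_null < 1) stop("n_null must be >= 1")
  pool <- data$nonbrain_pool
  if (!length(pool)) stop("non-brain pool is empty")
  markers <- names(marker_sets)
  if (is.null(markers) || any(markers == ""))
    stop("marker_sets must be a named list")
  sizes <- vapply(marker_sets, function(m) length(m$genes), integer(1))
  if (any(sizes > length(pool)))
    stop("non-brain pool (", length(pool),
         ") is smaller than the largest marker set (", max(sizes), ")")
  obs <- lapply(marker_sets, function(m) {
    curve <- loess_trajectory(gene_set_trajectory(data, m$genes),
                              span = span, degree = degree)
    period_statistics(curve, m$period)
  })
  # null statistics, cached per (set size, period)
  null_cache <- new.env(parent = emptyenv())
  null_stats <- with_seed(seed, lapply(seq_along(marker_sets), function(k) {
    m <- marker_sets[[k]]
    key <- paste(length(m$genes), m$period[1], m$period[2], sep = "_")
    if (!is.null(null_cache[[key]])) return(null_cache[[key]])
    stats_nb <- vapply(seq_len(n_null), function(b) {
      gs <- sample(pool, length(m$genes))
      curve <- loess_trajectory(gene_set_trajectory(data, gs),
                                span = span, degree = degree)
      s <- period_statistics(curve, m$period)
      c(s$mean_in, s$ratio)
    }, numeric(2))
    null_cache[[key]] <- stats_nb
    stats_nb
  }))
  p_mean <- vapply(seq_along(markers), function(k)
    empirical_p(obs[[k]]$mean_in, null_stats[[k]][1, ]), numeric(1))
  p_ratio <- vapply(seq_along(markers), function(k)
    empirical_p(obs[[k]]$ratio, null_stats[[k]][2, ]), numeric(1))
  q <- fdr_adjust(c(p_mean, p_ratio))
  data.frame(
    marker = markers, set_size = sizes,
    period_lo = vapply(marker_sets, function(m) m$period[1], numeric(1)),
    period_hi = vapply(marker_sets, function(m) m$period[2], numeric(1)),
    mean_in = vapply(obs, `[[`, numeric(1), "mean_in"),
    mean_out = vapply(obs, `[[`, numeric(1), "mean_out"),
    ratio = vapply(obs, `[[`, numeric(1), "ratio"),
    p_mean = p_mean, p_ratio = p_ratio,
    q_mean = q[seq_along(markers)],
    q_ratio = q[-seq_along(markers)],
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Read / write an expression dataset as plain text
#'
#' The matrix is stored as a genes-by-subjects CSV; subject ages go in a
#' sidecar table (`<path>.subjects.tsv`: id, age); gene sets in a simple
#' named-list text format (`marker TAB comma-separated genes`), with the
#' non-brain pool under the reserved name `.nonbrain_pool`.
#'
#' @param data An `expression_dataset`.
#' @param path CSV path for the expression matrix.
#' @return `path` invisibly (`write`); an `expression_dataset` (`read`).
#' @export
write_expression_dataset <- function(data, path) {
  stopifnot(inherits(data, "expression_dataset"))
  m <- t(data$expression)               # genes x subjects
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  utils::write.table(data$subjects, paste0(path, ".subjects.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sets <- c(data$gene_sets, list(.nonbrain_pool = data$nonbrain_pool))
  lines <- vapply(names(sets), function(nm)
    paste0(nm, "\t", paste(sets[[nm]], collapse = ",")), character(1))
  writeLines(lines, paste0(path, ".genesets.tsv"))
  invisible(path)
}

#' @rdname write_expression_dataset
#' @export
read_expression_dataset <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  genes <- df$gene
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(m) <- genes
  subjects <- utils::read.table(paste0(path, ".subjects.tsv"),
                                header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  if (!all(rownames(m) == subjects$id))
    m <- m[subjects$id, , drop = FALSE]
  if (any(subjects$age <= 0))
    stop("ages must be postnatal (> 0 years)")
  gene_sets <- list()
  pool <- character(0)
  gs_path <- paste0(path, ".genesets.tsv")
  if (file.exists(gs_path)) {
    for (ln in readLines(gs_path)) {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      members <- strsplit(parts[2], ",", fixed = TRUE)[[1]]
      if (parts[1] == ".nonbrain_pool") pool <- members
      else gene_sets[[parts[1]]] <- members
    }
  }
  for (nm in names(gene_sets)) {
    absent <- setdiff(gene_sets[[nm]], genes)
    if (length(absent))
      stop("gene set '", nm, "' references unknown gene(s): ",
           paste(absent, collapse = ", "))
  }
  structure(list(subjects = subjects, genes = genes, expression = m,
                 gene_sets = gene_sets, nonbrain_pool = pool),
            class = "expression_dataset")
}
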