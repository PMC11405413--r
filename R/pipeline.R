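#' @title Pipeline orchestration
#' @description End-to-end runs from a single YAML configuration:
#'   synthetic-scenario generation (or user-supplied tables), atlas
#'   reduction, window construction, surrogate ensembles, explained-
#'   variance scans, dominance and influence, gene-trajectory
#'   validation, and subject-level transfer, with every stage's output
#'   written as TSV and a JSON provenance manifest (seeds, parameters,
#'   versions). Fully deterministic given (config, seeds).
#' @name pipeline
NULL

pipeline_defaults <- function() {
  list(
    scenario = "synthetic",
    seed = 1L,
    n_nulls = 1000L,
    output_dir = "ctcoloc_out",
    stages = c("atlases", "windows", "nulls", "scan_univariate",
               "scan_multivariate", "dominance", "influence",
               "gene_validate", "subject_scan"),
    geometry = list(n_per_hemisphere = 74L),
    atlases = list(n_maps = 9L, length_scale = 15,
                   cross_correlation = 0.3),
    truth = list(weights = NULL, target_r2 = 0.6),
    target_window = c(10, 15),
    windows = list(start = 5, end = 90, length = 5, step = 1,
                   extra = list(c(5, 30))),
    percentile = 50, sex = "average",
    gene = list(n_subjects = 33L, n_signal_genes = 10L,
                n_flat_genes = 20L, n_nonbrain_pool = 500L,
                effect_size = 2, n_null = 1000L),
    cohort = list(n_subjects = 50L, n_sites = 10L, subject_sd = 0.05,
                  site_sd = 0.05, noise_sd = 0.02,
                  session_ages = c(10, 12), n_null = 200L),
    inputs = list(atlas_table = NULL, trajectory_table = NULL,
                  expression = NULL, cohort_table = NULL))
}

merge_config <- function(defaults, user, path = "") {
  for (nm in names(user)) {
    if (!nm %in% names(defaults))
      stop("unknown configuration key: ", paste0(path, nm))
    if (is.list(defaults[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(defaults[[nm]])))
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]],
                                     paste0(path, nm, "."))
    else defaults[nm] <- list(user[[nm]])   # keeps explicit NULLs
  }
  defaults
}

#' Validate and resolve a pipeline configuration
#'
#' Reads a YAML configuration (or takes a list), layers it over the
#' documented defaults, and checks consistency: referenced input files
#' must exist, the window spec must fit its age range, unknown keys are
#' rejected.
#'
#' @param config Path to a YAML file, or a list.
#' @return A fully resolved `run_config` list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  cfg <- merge_config(pipeline_defaults(), config)
  w <- cfg$windows
  if (w$end < w$start + w$length)
    stop("window spec inconsistent: length ", w$length,
         " does not fit the range ", w$start, "-", w$end)
  if (cfg$n_nulls < 1) stop("n_nulls must be >= 1")
  for (nm in names(cfg$inputs)) {
    pth <- cfg$inputs[[nm]]
    if (!is.null(pth) && !file.exists(pth))
      stop("configured input '", nm, "' does not exist: ", pth)
  }
  if (is.null(cfg$truth$weights)) {
    wts <- numeric(cfg$atlases$n_maps)
    wts[seq_len(min(2, length(wts)))] <- c(0.5, 0.3)[seq_len(min(2, length(wts)))]
    cfg$truth$weights <- wts
  }
  structure(cfg, class = "run_config")
}

#' Run the full pipeline from a configuration
#'
#' Sequences the stages (each skippable through `stages` in the
#' config): synthetic generation or input loading, sliding-window
#' change maps, surrogate ensembles (generated once per atlas and
#' reused everywhere), univariate and multivariate scans, dominance
#' with influence maps, gene-trajectory validation, and the
#' subject-level cohort transfer. Each stage writes TSV output under
#' `output_dir`; a `manifest.json` records seeds, parameters and
#' package versions. A stage failure halts the run with a stage-scoped
#' message; outputs of completed stages remain on disk.
#'
#' @param config A [validate_config()] result, a list, or a YAML path.
#' @return Invisibly, a list of in-memory stage results plus the output
#'   directory.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "run_config")) config else
    validate_config(config)
  out_dir <- cfg$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list(config = cfg, output_dir = out_dir)
  stage <- function(name, code) {
    if (!name %in% cfg$stages) return(invisible(NULL))
    message("[ctcoloc] stage: ", name)
    tryCatch(force(code),
             error = function(e)
               stop("stage '", name, "' failed: ", conditionMessage(e),
                    call. = FALSE))
  }

  # --- data: synthetic scenario or user tables -------------------------
  geom <- make_parcel_geometry(cfg$geometry$n_per_hemisphere,
                               seed = cfg$seed)
  if (!is.null(cfg$inputs$atlas_table)) {
    atlases <- read_parcel_table(cfg$inputs$atlas_table)
  } else {
    atlases <- make_atlas_library(
      geom, cfg$atlases$n_maps, cfg$atlases$length_scale,
      cfg$atlases$cross_correlation, seed = cfg$seed + 1L)
  }
  res$atlases <- atlases
  stage("atlases", write_parcel_table(
    atlases, file.path(out_dir, "atlases.tsv")))

  if (!is.null(cfg$inputs$trajectory_table)) {
    traj <- read_trajectory_table(cfg$inputs$trajectory_table)
    truth <- NULL
  } else {
    built <- make_ct_trajectories(
      geom, atlases,
      ground_truth(cfg$truth$weights, target_r2 = cfg$truth$target_r2,
                   seed = cfg$seed + 2L),
      target_window = cfg$target_window)
    traj <- built$trajectories
    truth <- built$truth
  }
  res$trajectories <- traj
  res$truth <- truth

  windows <- build_windows(cfg$windows$start, cfg$windows$end,
                           cfg$windows$length, cfg$windows$step,
                           cfg$windows$extra)
  res$windows <- windows
  changes <- stage("windows", {
    ch <- extract_change_series(traj, windows, cfg$percentile, cfg$sex)
    nms <- make.unique(sprintf("dCT_%g_%g", windows$i, windows$j))
    cm <- atlas_set(lapply(seq_along(ch), function(k) {
      m <- ch[[k]]
      m$name <- nms[k]
      class(m) <- "parcel_map"
      attributes(m)[c("window", "percentile", "sex")] <- NULL
      m
    }))
    write_parcel_table(cm, file.path(out_dir, "change_maps.tsv"))
    ch
  })
  if (is.null(changes))
    changes <- extract_change_series(traj, windows, cfg$percentile,
                                     cfg$sex)
  res$changes <- changes

  d <- pairwise_distances(geom)
  nulls <- stage("nulls", {
    ne <- lapply(names(atlases$maps), function(nm)
      generate_surrogates(atlases$maps[[nm]], d, cfg$n_nulls,
                          seed = cfg$seed + 10L +
                            match(nm, names(atlases$maps))))
    names(ne) <- names(atlases$maps)
    ne
  })
  res$nulls <- nulls

  stage("scan_univariate", {
    stopifnot(!is.null(nulls))
    uni <- do.call(rbind, lapply(names(atlases$maps), function(nm)
      univariate_scan(atlases$maps[[nm]], changes, nulls[[nm]])))
    uni$q <- fdr_adjust(uni$p, uni$predictor)
    utils::write.table(uni, file.path(out_dir, "scan_univariate.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$scan_univariate <- uni
  })

  stage("scan_multivariate", {
    stopifnot(!is.null(nulls))
    mv <- multivariate_scan(atlases, changes, nulls)
    mv$q <- fdr_adjust(mv$p)
    utils::write.table(mv, file.path(out_dir, "scan_multivariate.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$scan_multivariate <- mv
  })

  dom <- stage("dominance", {
    stopifnot(!is.null(nulls))
    dres <- dominance_scan(atlases, changes, nulls)
    utils::write.table(dres$windows,
                       file.path(out_dir, "dominance_windows.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(dres$dominance,
                       file.path(out_dir, "dominance_predictors.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    dres
  })
  res$dominance <- dom

  stage("influence", {
    ch1 <- changes[[length(changes)]]   # last window (extra if present)
    infl <- atlas_set(lapply(names(atlases$maps), function(nm)
      influence_map(atlases, ch1, nm)))
    write_parcel_table(infl, file.path(out_dir, "influence_maps.tsv"))
    res$influence <- infl
  })

  stage("gene_validate", {
    g <- cfg$gene
    expr <- if (!is.null(cfg$inputs$expression))
      read_expression_dataset(cfg$inputs$expression)
    else make_expression_dataset(
      n_subjects = g$n_subjects, n_signal_genes = g$n_signal_genes,
      n_flat_genes = g$n_flat_genes,
      n_nonbrain_pool = g$n_nonbrain_pool,
      effect_size = g$effect_size, seed = cfg$seed + 100L)
    sets <- lapply(expr$gene_sets, function(gs)
      list(genes = gs, period = if (!is.null(expr$peak_period))
        expr$peak_period else c(5, 30)))
    tt <- trajectory_test(expr, sets, n_null = g$n_null,
                          seed = cfg$seed + 101L)
    utils::write.table(tt, file.path(out_dir, "gene_trajectory_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$gene_validate <- tt
  })

  stage("subject_scan", {
    stopifnot(!is.null(nulls))
    cc <- cfg$cohort
    cohort <- if (!is.null(cfg$inputs$cohort_table))
      read_cohort_table(cfg$inputs$cohort_table)
    else make_cohort(geom, traj, n_subjects = cc$n_subjects,
                     n_sites = cc$n_sites, subject_sd = cc$subject_sd,
                     site_sd = cc$site_sd, noise_sd = cc$noise_sd,
                     session_ages = cc$session_ages,
                     seed = cfg$seed + 200L)
    ch <- subject_change(cohort)
    sd_res <- subject_dominance(ch, atlases)
    gm <- group_mean_null_test(ch, atlases, nulls, n_null = cc$n_null)
    utils::write.table(sd_res,
                       file.path(out_dir, "subject_dominance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$subject_scan <- list(subjects = sd_res, group_test = gm)
  })

  manifest <- list(
    package = "ctcoloc",
    package_version = as.character(utils::packageVersion("ctcoloc")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$seed, n_nulls = cfg$n_nulls,
    stages = cfg$stages,
    config = cfg[setdiff(names(cfg), "stages")])
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       force = TRUE)
  invisible(res)
}
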