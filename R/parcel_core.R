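#' Parcellated brain maps
#'
#' A `parcel_map` holds one scalar value per cortical parcel together with
#' parcel identity (label strings) and hemisphere tags. It is the common
#' currency of all spatial analyses in this package: marker atlases,
#' cortical-thickness (CT) maps and CT-change maps are all `parcel_map`s.
#'
#' @param values Numeric vector, one value per parcel. No missing values.
#' @param parcel_ids Character vector of unique parcel labels, same length
#'   as `values`.
#' @param hemisphere Character vector of `"left"`/`"right"` tags per parcel,
#'   or `NULL` to infer from a leading `lh_`/`rh_` label prefix (unprefixed
#'   labels are tagged `"unknown"`).
#' @param name Single string naming the map (used as a column name on
#'   export and as the key for surrogate ensembles).
#' @param standardized Logical; `TRUE` marks a map already z-scored across
#'   parcels (checked: mean ~ 0, SD ~ 1 within 1e-9).
#'
#' @return An object of class `parcel_map` with fields `parcel_ids`,
#'   `hemisphere`, `values`, `name`, `standardized`.
#' @seealso [atlas_set()], [zscore_map()], [read_parcel_table()]
#' @export
parcel_map <- function(values, parcel_ids, hemisphere = NULL,
                       name = "map", standardized = FALSE) {
  values <- as.numeric(values)
  parcel_ids <- as.character(parcel_ids)
  if (length(values) != length(parcel_ids))
    stop("`values` and `parcel_ids` must have the same length")
  if (anyNA(values))
    stop("parcel map '", name, "' contains missing values; ",
         "missing parcels are rejected, not imputed")
  if (anyDuplicated(parcel_ids))
    stop("duplicated parcel id(s): ",
         paste(unique(parcel_ids[duplicated(parcel_ids)]), collapse = ", "))
  if (is.null(hemisphere)) {
    hemisphere <- ifelse(startsWith(parcel_ids, "lh_"), "left",
                         ifelse(startsWith(parcel_ids, "rh_"), "right",
                                "unknown"))
  }
  hemisphere <- as.character(hemisphere)
  if (length(hemisphere) != length(values))
    stop("`hemisphere` must have one tag per parcel")
  if (isTRUE(standardized)) {
    n <- length(values)
    if (abs(mean(values)) > 1e-9 ||
        abs(sqrt(sum((values - mean(values))^2) / n) - 1) > 1e-9)
      stop("map '", name, "' is flagged standardized but is not ",
           "(mean 0 / SD 1, population convention, tolerance 1e-9)")
  }
  structure(
    list(parcel_ids = parcel_ids, hemisphere = hemisphere,
         values = values, name = as.character(name)[1],
         standardized = isTRUE(standardized)),
    class = "parcel_map")
}

#' @export
print.parcel_map <- function(x, ...) {
  cat("<parcel_map> '", x$name, "': ", length(x$values), " parcels",
      if (x$standardized) " (z-scored)", "\n", sep = "")
  cat("  values: ", paste(signif(utils::head(x$values, 5), 4),
                          collapse = ", "),
      if (length(x$values) > 5) ", ...", "\n", sep = "")
  invisible(x)
}

#' @export
length.parcel_map <- function(x) length(x$values)

#' Ordered collection of aligned parcel maps
#'
#' An `atlas_set` bundles several [parcel_map()]s that share an identical
#' parcel order, e.g. a library of neurobiological marker atlases or the
#' factor-score maps derived from them. All cross-map operations in the
#' package require their inputs to come from aligned sets and refuse
#' mismatched parcel orderings rather than silently reindexing.
#'
#' @param maps List of `parcel_map` objects with identical `parcel_ids`
#'   (same labels, same order) and unique names.
#' @param modality Optional character vector tagging each map's source
#'   modality (`"ni"` nuclear imaging, `"ce"` cell-type expression,
#'   `"mr"` MRI microstructure); recycled if length 1.
#' @param provenance Optional free-text per map.
#'
#' @return An object of class `atlas_set`.
#' @export
atlas_set <- function(maps, modality = NA_character_, provenance = NA_character_) {
  if (!length(maps)) stop("an atlas_set needs at least one map")
  if (!all(vapply(maps, inherits, logical(1), "parcel_map")))
    stop("all elements must be parcel_map objects")
  ids <- maps[[1]]$parcel_ids
  for (m in maps[-1])
    if (!identical(m$parcel_ids, ids))
      stop("map '", m$name, "' has a different parcel set/order; ",
           "refusing to combine misaligned maps")
  nm <- vapply(maps, function(m) m$name, character(1))
  if (anyDuplicated(nm))
    stop("map names must be unique; duplicated: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  names(maps) <- nm
  structure(
    list(maps = maps,
         modality = rep_len(as.character(modality), length(maps)),
         provenance = rep_len(as.character(provenance), length(maps))),
    class = "atlas_set")
}

#' @export
print.atlas_set <- function(x, ...) {
  cat("<atlas_set> ", length(x$maps), " maps x ",
      length(x$maps[[1]]$values), " parcels\n", sep = "")
  cat("  maps: ", paste(utils::head(names(x$maps), 8), collapse = ", "),
      if (length(x$maps) > 8) ", ...", "\n", sep = "")
  invisible(x)
}

#' @export
length.atlas_set <- function(x) length(x$maps)

#' Matrix view of an atlas set (parcels x maps)
#'
#' @param atlases An [atlas_set()].
#' @return Numeric matrix, rows named by parcel id, columns by map name.
#' @export
atlas_matrix <- function(atlases) {
  stopifnot(inherits(atlases, "atlas_set"))
  m <- vapply(atlases$maps, function(x) x$values,
              numeric(length(atlases$maps[[1]]$values)))
  m <- matrix(m, ncol = length(atlases$maps),
              dimnames = list(atlases$maps[[1]]$parcel_ids,
                              names(atlases$maps)))
  m
}

# Internal: assert two maps (or a map and a set) are parcel-aligned.
check_aligned <- function(a, b) {
  ida <- if (inherits(a, "parcel_map")) a$parcel_ids else a$maps[[1]]$parcel_ids
  idb <- if (inherits(b, "parcel_map")) b$parcel_ids else b$maps[[1]]$parcel_ids
  if (!identical(ida, idb))
    stop("parcel orderings differ between inputs; align parcels explicitly")
  invisible(TRUE)
}

#' Destrieux parcel label registry
#'
#' The 148 cortical parcel labels of the Destrieux surface parcellation
#' (74 per hemisphere, FreeSurfer `aparc.a2009s` naming, prefixed `lh_` /
#' `rh_`). Used to validate user-supplied tables claiming this
#' parcellation; synthetic geometries use their own generated labels.
#'
#' @return Character vector of 148 labels, left hemisphere first.
#' @export
destrieux_labels <- function() {
  base <- c(
    "G_and_S_frontomargin", "G_and_S_occipital_inf", "G_and_S_paracentral",
    "G_and_S_subcentral", "G_and_S_transv_frontopol", "G_and_S_cingul-Ant",
    "G_and_S_cingul-Mid-Ant", "G_and_S_cingul-Mid-Post",
    "G_cingul-Post-dorsal", "G_cingul-Post-ventral", "G_cuneus",
    "G_front_inf-Opercular", "G_front_inf-Orbital", "G_front_inf-Triangul",
    "G_front_middle", "G_front_sup", "G_Ins_lg_and_S_cent_ins",
    "G_insular_short", "G_occipital_middle", "G_occipital_sup",
    "G_oc-temp_lat-fusifor", "G_oc-temp_med-Lingual",
    "G_oc-temp_med-Parahip", "G_orbital", "G_pariet_inf-Angular",
    "G_pariet_inf-Supramar", "G_parietal_sup", "G_postcentral",
    "G_precentral", "G_precuneus", "G_rectus", "G_subcallosal",
    "G_temp_sup-G_T_transv", "G_temp_sup-Lateral", "G_temp_sup-Plan_polar",
    "G_temp_sup-Plan_tempo", "G_temporal_inf", "G_temporal_middle",
    "Lat_Fis-ant-Horizont", "Lat_Fis-ant-Vertical", "Lat_Fis-post",
    "Pole_occipital", "Pole_temporal", "S_calcarine", "S_central",
    "S_cingul-Marginalis", "S_circular_insula_ant", "S_circular_insula_inf",
    "S_circular_insula_sup", "S_collat_transv_ant", "S_collat_transv_post",
    "S_front_inf", "S_front_middle", "S_front_sup", "S_interm_prim-Jensen",
    "S_intrapariet_and_P_trans", "S_oc_middle_and_Lunatus",
    "S_oc_sup_and_transversal", "S_occipital_ant", "S_oc-temp_lat",
    "S_oc-temp_med_and_Lingual", "S_orbital_lateral",
    "S_orbital_med-olfact", "S_orbital-H_Shaped", "S_parieto_occipital",
    "S_pericallosal", "S_postcentral", "S_precentral-inf-part",
    "S_precentral-sup-part", "S_suborbital", "S_subparietal",
    "S_temporal_inf", "S_temporal_sup", "S_temporal_transverse")
  c(paste0("lh_", base), paste0("rh_", base))
}

#' Read an atlas set from a delimited parcel table
#'
#' Reads a TSV/CSV file with one row per parcel, one column of parcel
#' identifiers and one or more numeric map columns. Column order becomes
#' map order; row (parcel) order is preserved as in the file.
#'
#' @param path Path to a delimited text file with a header row.
#' @param id_column Name of the parcel-identifier column (default
#'   `"parcel"`).
#' @param sep Field separator; `"\t"` for `.tsv` (default), `","` for
#'   `.csv`. Guessed from the file extension when `NULL`.
#' @param registry Optional character vector of expected parcel labels
#'   (e.g. [destrieux_labels()]); if supplied, the file must contain
#'   exactly this label set (any order) and a missing or extra parcel is a
#'   validation error naming it.
#' @return An [atlas_set()].
#' @export
read_parcel_table <- function(path, id_column = "parcel", sep = NULL,
                              registry = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#", quote = "\"")
  if (!id_column %in% names(df))
    stop("id column '", id_column, "' not found in ", path,
         " (columns: ", paste(names(df), collapse = ", "), ")")
  ids <- as.character(df[[id_column]])
  val_cols <- setdiff(names(df), id_column)
  if (!length(val_cols)) stop("no numeric map columns in ", path)
  for (cn in val_cols) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))[1]
      stop("non-numeric value in column '", cn, "', row ",
           if (is.na(bad)) "?" else bad, " of ", path)
    }
  }
  if (!is.null(registry)) {
    missing <- setdiff(registry, ids)
    extra <- setdiff(ids, registry)
    if (length(missing) || length(extra))
      stop("parcel set does not match the ", length(registry),
           "-parcel registry",
           if (length(missing)) paste0("; missing: ",
             paste(utils::head(missing, 5), collapse = ", "),
             if (length(missing) > 5) ", ..."),
           if (length(extra)) paste0("; unexpected: ",
             paste(utils::head(extra, 5), collapse = ", "),
             if (length(extra) > 5) ", ..."))
  }
  maps <- lapply(val_cols, function(cn)
    parcel_map(df[[cn]], ids, name = cn))
  atlas_set(maps, provenance = path)
}

#' Write an atlas set to a delimited parcel table
#'
#' Inverse of [read_parcel_table()]: one row per parcel, an id column and
#' one column per map. Values are written with full precision (`%.17g`)
#' so a read/write round trip is bit-exact.
#'
#' @param atlases An [atlas_set()] (a single [parcel_map()] is wrapped).
#' @param path Output file path; extension picks the separator.
#' @param id_column Name for the identifier column.
#' @return `path`, invisibly.
#' @export
write_parcel_table <- function(atlases, path, id_column = "parcel") {
  if (inherits(atlases, "parcel_map")) atlases <- atlas_set(list(atlases))
  stopifnot(inherits(atlases, "atlas_set"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  m <- atlas_matrix(atlases)
  df <- data.frame(id = rownames(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- id_column
  for (j in seq_len(ncol(m))) df[[colnames(m)[j]]] <- sprintf("%.17g", m[, j])
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Z-standardize a parcel map across parcels
#'
#' Centers and scales a map to mean 0, SD 1 across parcels, using the
#' population SD convention (denominator n). Marker atlases are
#' standardized this way before any factor analysis or regression; the
#' convention cancels in rank correlations and R-squared statistics.
#'
#' @param map A [parcel_map()] with non-constant values.
#' @return A standardized `parcel_map` (flag set).
#' @export
zscore_map <- function(map) {
  stopifnot(inherits(map, "parcel_map"))
  v <- map$values
  n <- length(v)
  s <- sqrt(sum((v - mean(v))^2) / n)
  if (s < .Machine$double.eps * 100 * max(1, abs(mean(v))))
    stop("map '", map$name, "' is constant; cannot z-score a ",
         "zero-variance map")
  parcel_map((v - mean(v)) / s, map$parcel_ids, map$hemisphere,
             name = map$name, standardized = TRUE)
}

#' Z-standardize every map of an atlas set
#'
#' @param atlases An [atlas_set()].
#' @return The set with each map passed through [zscore_map()].
#' @export
zscore_atlases <- function(atlases) {
  stopifnot(inherits(atlases, "atlas_set"))
  atlas_set(lapply(atlases$maps, zscore_map),
            modality = atlases$modality, provenance = atlases$provenance)
}
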