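# Readers and writers for the three plain-text tables the pipeline consumes:
# detections (one row per sample x marker x lineage with a read count),
# sample metadata, and functional annotations. Dialect: UTF-8, tab-separated,
# header required, "" = missing.

DETECTION_COLS <- c("sample_id", "marker", RANKS, "reads")
METADATA_COLS <- c("sample_id", "year", "month", "sex", "sample_class",
                   "host_species")
ANNOTATION_COLS <- c("lineage_key", "plant_type", "functional_group")

#' Default marker configuration
#'
#' Maps each amplicon marker to the target group it detects. The default set
#' mirrors a two-markers-per-group design: two plant markers (a chloroplast
#' trnL P6-loop assay and a nuclear ITS2 assay) and two mitochondrial COI
#' assays for metazoans.
#'
#' @return Named character vector: names are marker ids, values are
#'   `"plant"` or `"metazoan"`.
#' @export
default_marker_targets <- function() {
  c(trnL_gh = "plant", ITS2_u34 = "plant",
    COI_ZBJ = "metazoan", COI_mlCOI = "metazoan")
}

read_tsv_strict <- function(path, required, context) {
  if (!file.exists(path)) stop(context, ": file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = NULL,
                          check.names = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s", context,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

blank_to_na <- function(x) {
  x <- trimws(x)
  x[x == ""] <- NA
  x
}

#' Read a detection table
#'
#' Reads a long-format detection TSV (columns `sample_id`, `marker`, the
#' seven rank columns, `reads`) as produced downstream of any
#' denoiser/classifier. Rows with zero reads are retained: all filtering is
#' explicit and happens later. Duplicate rows for the same
#' (sample, marker, lineage) triple are summed with a warning, since
#' classifier outputs often split one taxon across several sequence variants.
#'
#' @param path Path to the TSV file.
#' @param marker_targets Named character vector mapping marker name to
#'   `"plant"`/`"metazoan"`; see [default_marker_targets()].
#' @return A detection data frame: `sample_id`, `marker`, `target_group`,
#'   the seven rank columns, integer `reads`.
#' @export
read_detections <- function(path, marker_targets = default_marker_targets()) {
  df <- read_tsv_strict(path, DETECTION_COLS, "detections")
  df <- df[, DETECTION_COLS, drop = FALSE]
  as_detections(df, marker_targets, context = path)
}

#' Coerce a data frame to a validated detection table
#'
#' @param df Data frame with the detection columns.
#' @param marker_targets Marker-to-target map.
#' @param context Label for error messages.
#' @return Validated detection data frame with a `target_group` column.
#' @export
as_detections <- function(df, marker_targets = default_marker_targets(),
                          context = "detections") {
  if (nrow(df) == 0L) {
    out <- data.frame(sample_id = character(), marker = character(),
                      target_group = character(), stringsAsFactors = FALSE)
    for (r in RANKS) out[[r]] <- character()
    out$reads <- integer()
    return(out)
  }
  df$sample_id <- blank_to_na(as.character(df$sample_id))
  df$marker <- blank_to_na(as.character(df$marker))
  if (anyNA(df$sample_id) || anyNA(df$marker)) {
    stop(context, ": sample_id and marker must be non-empty", call. = FALSE)
  }
  unknown <- setdiff(unique(df$marker), names(marker_targets))
  if (length(unknown)) {
    stop(sprintf("%s: unknown marker(s) not in configuration: %s", context,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  reads_chr <- trimws(as.character(df$reads))
  reads_num <- suppressWarnings(as.numeric(reads_chr))
  bad <- is.na(reads_num) | reads_num < 0 | reads_num != floor(reads_num)
  if (any(bad)) {
    stop(sprintf("%s: non-integer or negative reads in row(s) %s", context,
                 paste(utils::head(which(bad), 10L), collapse = ", ")),
         call. = FALSE)
  }
  df$reads <- as.integer(reads_num)
  for (r in RANKS) df[[r]] <- blank_to_na(as.character(df[[r]]))
  validate_lineages(df, context)
  df$target_group <- unname(marker_targets[df$marker])
  df <- df[, c("sample_id", "marker", "target_group", RANKS, "reads")]
  sum_duplicate_records(df)
}

#' Sum duplicate (sample, marker, lineage) rows
#'
#' @param df Detection data frame.
#' @return Detection data frame with one row per triple; warns when rows were
#'   merged.
#' @export
sum_duplicate_records <- function(df) {
  if (nrow(df) == 0L) return(df)
  key <- paste(df$sample_id, df$marker, lineage_key(df), sep = "\r")
  if (!anyDuplicated(key)) {
    rownames(df) <- NULL
    return(df)
  }
  warning(sprintf("summed %d duplicate (sample, marker, lineage) row(s)",
                  sum(duplicated(key))), call. = FALSE)
  reads <- tapply(df$reads, key, sum)
  keep <- df[!duplicated(key), , drop = FALSE]
  keep$reads <- as.integer(reads[paste(keep$sample_id, keep$marker,
                                       lineage_key(keep), sep = "\r")])
  rownames(keep) <- NULL
  keep
}

#' Write a detection table
#'
#' Inverse of [read_detections()]: writes the same TSV dialect (tab-separated,
#' header, empty cell = missing). The derived `target_group` column and any
#' bookkeeping columns (e.g. the synthetic generator's `origin`) are dropped.
#'
#' @param df Detection data frame.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_detections <- function(df, path) {
  out <- df[, DETECTION_COLS, drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

normalize_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep("unknown", length(x))
  out[x %in% c("f", "female", "fem")] <- "F"
  out[x %in% c("m", "male")] <- "M"
  out[is.na(x) | x == ""] <- "unknown"
  out
}

#' Read a sample metadata table
#'
#' Columns: `sample_id`, `year`, `month`, `sex`, `sample_class`,
#' `host_species`. Sex values are normalized (`"female"`/`"f"` to `"F"`,
#' `"male"`/`"m"` to `"M"`, anything else `"unknown"`). Field samples must
#' carry a valid year and month (the temporal stratum key used downstream);
#' negative controls need not.
#'
#' @param path Path to the TSV file.
#' @return Metadata data frame with typed columns.
#' @export
read_metadata <- function(path) {
  df <- read_tsv_strict(path, METADATA_COLS, "metadata")
  as_metadata(df[, METADATA_COLS, drop = FALSE], context = path)
}

#' Coerce a data frame to validated sample metadata
#'
#' @param df Data frame with metadata columns.
#' @param context Label for error messages.
#' @return Validated metadata data frame.
#' @export
as_metadata <- function(df, context = "metadata") {
  df$sample_id <- blank_to_na(as.character(df$sample_id))
  if (anyNA(df$sample_id)) stop(context, ": empty sample_id", call. = FALSE)
  if (anyDuplicated(df$sample_id)) {
    stop(sprintf("%s: duplicate sample_id(s): %s", context,
                 paste(unique(df$sample_id[duplicated(df$sample_id)]),
                       collapse = ", ")), call. = FALSE)
  }
  df$year <- suppressWarnings(as.integer(blank_to_na(as.character(df$year))))
  df$month <- suppressWarnings(as.integer(blank_to_na(as.character(df$month))))
  df$sex <- normalize_sex(df$sex)
  df$sample_class <- trimws(as.character(df$sample_class))
  classes <- c("field", "mock", "feeding_trial", "negative_control")
  bad_class <- !df$sample_class %in% classes
  if (any(bad_class)) {
    stop(sprintf("%s: invalid sample_class in row(s) %s (must be one of %s)",
                 context, paste(which(bad_class), collapse = ", "),
                 paste(classes, collapse = ", ")), call. = FALSE)
  }
  is_field <- df$sample_class == "field"
  bad_month <- !is.na(df$month) & (df$month < 1L | df$month > 12L)
  if (any(bad_month)) {
    stop(sprintf("%s: month outside 1-12 in row(s) %s", context,
                 paste(which(bad_month), collapse = ", ")), call. = FALSE)
  }
  if (any(is_field & (is.na(df$month) | is.na(df$year)))) {
    stop(context, ": field samples must have year and month", call. = FALSE)
  }
  df$host_species <- trimws(as.character(df$host_species))
  rownames(df) <- NULL
  df
}

#' Write a sample metadata table
#' @param df Metadata data frame.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_metadata <- function(df, path) {
  utils::write.table(df[, METADATA_COLS, drop = FALSE], path, sep = "\t",
                     quote = FALSE, na = "", row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a functional annotation table
#'
#' Maps the deepest rank label of a taxon (`lineage_key` column) to its plant
#' type (herbaceous, tree, fern, other; `n/a` for metazoans) and functional
#' group (non-cultivated / cultivated / trap crop / target crop for plants;
#' zoophagous / phytophagous / detritivorous / other for metazoans). Taxa
#' absent from the table fall back to `"unannotated"` at query time, never an
#' error.
#'
#' @param path Path to the TSV file.
#' @return Annotation data frame keyed by `lineage_key`.
#' @export
read_annotations <- function(path) {
  df <- read_tsv_strict(path, ANNOTATION_COLS, "annotations")
  as_annotations(df[, ANNOTATION_COLS, drop = FALSE], context = path)
}

#' Coerce a data frame to a validated annotation table
#' @param df Data frame with annotation columns.
#' @param context Label for error messages.
#' @return Validated annotation data frame.
#' @export
as_annotations <- function(df, context = "annotations") {
  df$lineage_key <- blank_to_na(as.character(df$lineage_key))
  df$plant_type <- blank_to_na(as.character(df$plant_type))
  df$functional_group <- blank_to_na(as.character(df$functional_group))
  if (anyNA(df$lineage_key)) stop(context, ": empty lineage_key", call. = FALSE)
  df <- unique(df)
  if (anyDuplicated(df$lineage_key)) {
    stop(sprintf("%s: conflicting annotations for: %s", context,
                 paste(unique(df$lineage_key[duplicated(df$lineage_key)]),
                       collapse = ", ")), call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' Look up annotations for taxa
#'
#' @param annotations Annotation data frame from [read_annotations()].
#' @param labels Character vector of deepest-rank labels.
#' @return Data frame with `plant_type` and `functional_group`, one row per
#'   label; unknown labels get `"unannotated"`.
#' @export
annotation_lookup <- function(annotations, labels) {
  idx <- match(labels, annotations$lineage_key)
  out <- data.frame(
    plant_type = ifelse(is.na(idx), "unannotated",
                        annotations$plant_type[idx]),
    functional_group = ifelse(is.na(idx), "unannotated",
                              annotations$functional_group[idx]),
    stringsAsFactors = FALSE)
  out$plant_type[is.na(out$plant_type)] <- "n/a"
  out
}
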