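# End-to-end orchestration: simulate (or read) -> filter -> consolidate ->
# metrics -> CO -> tests, writing every intermediate table so each stage is
# auditable. The command-line front end lives in inst/cli/dietbreadth.R.

#' Pipeline run configuration
#'
#' @param out_dir Output directory (created if needed).
#' @param detections,metadata,nc_detections,annotations Optional input paths;
#'   when `detections` is `NULL` a synthetic cohort is generated.
#' @param rra_pct RRA threshold in percent (default 1).
#' @param min_resolution Rank-inclusion threshold (default `"genus"`).
#' @param co_scheme Bootstrap stratification scheme.
#' @param perm_constraint Permutation-test constraint stratum.
#' @param B_boot,B_perm Bootstrap / permutation iteration counts.
#' @param seed Integer seed; mandatory because the bootstrap and permutation
#'   stages are stochastic.
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir, detections = NULL, metadata = NULL,
                       nc_detections = NULL, annotations = NULL,
                       rra_pct = 1, min_resolution = "genus",
                       co_scheme = "month_x_year",
                       perm_constraint = "month_x_year",
                       B_boot = 2000, B_perm = 10000, seed) {
  if (missing(seed)) stop("run_config(): seed is mandatory", call. = FALSE)
  stopifnot(rra_pct > 0, rra_pct < 100, B_boot >= 1, B_perm >= 1)
  min_resolution <- match.arg(min_resolution, taxon_ranks())
  structure(list(out_dir = out_dir, detections = detections,
                 metadata = metadata, nc_detections = nc_detections,
                 annotations = annotations, rra_pct = rra_pct,
                 min_resolution = min_resolution, co_scheme = co_scheme,
                 perm_constraint = perm_constraint,
                 B_boot = B_boot, B_perm = B_perm, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full diet-breadth pipeline
#'
#' Executes the stages in fixed order — input (or synthetic generation),
#' filter chain, consolidation, diet metrics, coefficient of omnivory with
#' stratified bootstrap, sex permutation test, sex-ratio and diet-type
#' chi-squared tests — and writes every intermediate table, filter report
#' and a final JSON summary under `config$out_dir`. Re-running with the same
#' config and seed reproduces all outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with all in-memory results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)

  if (is.null(config$detections)) {
    cohort <- generate_cohort(cohort_config(seed = config$seed))
    detections <- cohort$detections
    metadata <- cohort$metadata
    nc_records <- cohort$nc_detections
    annotations <- default_annotations()
    write_detections(detections, out("detections.tsv"))
    write_detections(nc_records, out("nc_detections.tsv"))
    write_metadata(metadata, out("metadata.tsv"))
  } else {
    detections <- read_detections(config$detections)
    metadata <- read_metadata(config$metadata)
    nc_records <- if (!is.null(config$nc_detections)) {
      read_detections(config$nc_detections)
    }
    annotations <- if (!is.null(config$annotations)) {
      read_annotations(config$annotations)
    } else {
      default_annotations()
    }
  }

  field_ids <- metadata$sample_id[metadata$sample_class == "field"]
  field <- detections[detections$sample_id %in% field_ids, , drop = FALSE]

  hosts <- host_lineage()
  fc <- filter_chain(field, host_lineages = hosts, nc_records = nc_records,
                     rra_pct = config$rra_pct,
                     min_resolution = config$min_resolution)
  write_filter_reports(fc$reports, out("filter_reports.json"))
  write_detections(fc$statistics, out("filtered.tsv"))

  consolidated <- consolidate_all(fc$statistics, metadata, annotations)
  write_consolidated(consolidated, out("consolidated.tsv"))

  states <- classify_diet_state(consolidated, metadata)
  utils::write.table(states, out("diet_states.tsv"), sep = "\t",
                     quote = FALSE, na = "", row.names = FALSE)

  rra <- compute_rra(consolidated)
  utils::write.table(rra, out("rra.tsv"), sep = "\t", quote = FALSE,
                     na = "", row.names = FALSE)
  foo <- compute_foo(consolidated, field_ids)
  utils::write.table(foo, out("foo.tsv"), sep = "\t", quote = FALSE,
                     na = "", row.names = FALSE)
  periods <- summarize_periods(consolidated, states, metadata)
  utils::write.table(periods, out("period_summary.tsv"), sep = "\t",
                     quote = FALSE, na = "", row.names = FALSE)
  rank_res <- rank_resolution_summary(fc$profiling)
  utils::write.table(rank_res, out("rank_resolution.tsv"), sep = "\t",
                     quote = FALSE, na = "", row.names = FALSE)

  co <- bootstrap_co(states, scheme = config$co_scheme, B = config$B_boot,
                     seed = config$seed)
  perm <- tryCatch(
    permutation_sex_test(states, constraint = config$perm_constraint,
                         B = config$B_perm, seed = config$seed + 1L),
    error = function(e) NULL)
  write_co_report(co, out("co_report.json"), perm = perm)

  diet_counts <- c(phytophagous = sum(states$state == "phytophagous"),
                   omnivorous = sum(states$state == "omnivorous"),
                   zoophagous = sum(states$state == "zoophagous"))
  diet_test <- chisq_goodness_of_fit(unname(diet_counts))
  sr <- sex_ratio(metadata)

  summary <- list(
    n_field = length(field_ids),
    diet_counts = as.list(diet_counts),
    n_undetected = sum(states$state == "undetected"),
    co = co$co, co_ci = c(co$ci_low, co$ci_high), co_scheme = co$scheme,
    sex_test_p = if (!is.null(perm)) perm$p_value else NA,
    diet_chisq = diet_test$statistic, diet_chisq_p = diet_test$p_value,
    proportion_male = sr$proportion_male,
    seed = config$seed)
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(detections = detections, metadata = metadata,
                 filtered = fc, consolidated = consolidated,
                 states = states, foo = foo, periods = periods,
                 rank_resolution = rank_res, co = co, perm = perm,
                 diet_test = diet_test, sex_ratio = sr, summary = summary))
}
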