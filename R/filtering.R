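# Rule-based post-classification filters. Each rule partitions its input into
# retained and removed records and returns an auditable report; the chain
# order is part of the contract: self-host -> negative-control -> singleton ->
# RRA -> rank inclusion.

new_filter_report <- function(rule_name, input, removed) {
  per_sample <- if (nrow(removed)) {
    agg <- stats::aggregate(cbind(records_removed = rep(1L, nrow(removed)),
                                  reads_removed = removed$reads),
                            by = list(sample_id = removed$sample_id), FUN = sum)
    agg[order(agg$sample_id), , drop = FALSE]
  } else {
    data.frame(sample_id = character(), records_removed = integer(),
               reads_removed = integer(), stringsAsFactors = FALSE)
  }
  structure(list(rule_name = rule_name,
                 records_in = nrow(input),
                 reads_in = sum(input$reads),
                 records_removed = nrow(removed),
                 reads_removed = sum(removed$reads),
                 per_sample = per_sample),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("Filter rule '%s': removed %d/%d records (%d/%d reads)\n",
              x$rule_name, x$records_removed, x$records_in,
              x$reads_removed, x$reads_in))
  invisible(x)
}

split_by_mask <- function(records, remove_mask, rule_name) {
  removed <- records[remove_mask, , drop = FALSE]
  retained <- records[!remove_mask, , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained,
       removed = removed,
       report = new_filter_report(rule_name, records, removed))
}

#' Remove self-host (conspecific) reads
#'
#' Gut-content COI data from a predator is dominated by the predator's own
#' DNA; this rule masks every record whose lineage matches a host lineage.
#' Matching is by prefix at the *coarser* of the two resolutions: a
#' genus-level record is removed given a species-level host, because
#' conspecific reads frequently classify only to genus or family.
#'
#' @param records Detection data frame.
#' @param host_lineages Data frame of host lineages (seven rank columns), at
#'   minimum the focal insect; add predator species for feeding-trial samples.
#' @param mask_family If `TRUE`, additionally mask at the hosts' family level
#'   (conservative option for taxa whose self-signal classifies only to
#'   family); default off.
#' @return List with `retained` (detection data frame), `removed`, and
#'   `report` (a `filter_report`).
#' @export
remove_self_host <- function(records, host_lineages, mask_family = FALSE) {
  stopifnot(nrow(host_lineages) > 0L)
  validate_lineages(host_lineages, "host_lineages")
  host_keys <- lineage_key(host_lineages)
  if (mask_family) {
    fam_depth <- pmin(lineage_depth(host_lineages), match("family", RANKS))
    fam <- truncate_lineage(host_lineages, fam_depth)
    host_keys <- unique(c(host_keys, lineage_key(fam)))
  }
  if (nrow(records) == 0L) {
    return(split_by_mask(records, logical(0), "self_host"))
  }
  keys <- lineage_key(records)
  mask <- rep(FALSE, nrow(records))
  for (h in host_keys) {
    mask <- mask | keys == h | is_strict_prefix(h, keys) |
      vapply(keys, is_strict_prefix, logical(1), b = h)
  }
  split_by_mask(records, mask, "self_host")
}

#' Negative-control contaminant filter
#'
#' For every (marker, lineage) detected in PCR negative controls, field
#' records of the same marker and lineage with read counts at or below the
#' maximum negative-control count are removed. The comparison is per marker;
#' ties are removed (the conservative reading of "lower than"). Taxa absent
#' from the controls are untouched.
#'
#' @param records Detection data frame (field samples).
#' @param nc_records Detection data frame drawn only from negative-control
#'   samples. If `NULL` or empty the rule is skipped with a warning.
#' @return List with `retained`, `removed`, and `report`.
#' @export
negative_control_filter <- function(records, nc_records) {
  if (is.null(nc_records) || nrow(nc_records) == 0L) {
    warning("no negative-control records supplied; rule skipped",
            call. = FALSE)
    return(split_by_mask(records, rep(FALSE, nrow(records)), "negative_control"))
  }
  nc_key <- paste(nc_records$marker, lineage_key(nc_records), sep = "\r")
  nc_max <- tapply(nc_records$reads, nc_key, max)
  if (nrow(records) == 0L) {
    return(split_by_mask(records, logical(0), "negative_control"))
  }
  key <- paste(records$marker, lineage_key(records), sep = "\r")
  thr <- nc_max[key]
  mask <- !is.na(thr) & records$reads <= thr
  split_by_mask(records, mask, "negative_control")
}

#' Remove singleton records
#'
#' Records carrying exactly one read (per sample, marker and lineage, after
#' duplicate summing) are removed. Samples whose records are all singletons
#' are retained as samples with zero detections, not deleted.
#'
#' @param records Detection data frame.
#' @return List with `retained`, `removed`, and `report`.
#' @export
remove_singletons <- function(records) {
  split_by_mask(records, records$reads == 1L, "singleton")
}

#' Relative-read-abundance threshold filter
#'
#' Within each (sample, target group) — pooling that group's markers — the
#' RRA of a record is `100 * reads / total group reads` for the sample.
#' Records with RRA strictly below the threshold are removed; abundances are
#' *not* re-normalized afterwards. A per-marker scope is available.
#'
#' @param records Detection data frame.
#' @param threshold_pct Threshold in percent, in (0, 100); default 1.
#' @param scope `"sample_target"` (default: pool a group's markers within a
#'   sample) or `"sample_marker"`.
#' @return List with `retained`, `removed`, and `report`.
#' @export
rra_threshold_filter <- function(records, threshold_pct = 1,
                                 scope = c("sample_target", "sample_marker")) {
  scope <- match.arg(scope)
  stopifnot(threshold_pct > 0, threshold_pct < 100)
  if (nrow(records) == 0L) {
    return(split_by_mask(records, logical(0), "rra"))
  }
  grp <- if (scope == "sample_target") {
    paste(records$sample_id, records$target_group, sep = "\r")
  } else {
    paste(records$sample_id, records$marker, sep = "\r")
  }
  totals <- tapply(records$reads, grp, sum)
  tot <- as.numeric(totals[grp])
  rra <- ifelse(tot > 0, 100 * records$reads / tot, NA_real_)
  mask <- !is.na(rra) & rra < threshold_pct
  split_by_mask(records, mask, "rra")
}

#' Rank-inclusion filter
#'
#' Keeps entries resolved at or below a minimum rank (default genus, i.e.
#' genus or species). Used to build the statistical-analysis dataset while
#' the unfiltered set remains available for resolution profiling.
#'
#' @param x Detection or consolidated data frame (seven rank columns).
#' @param min_resolution Coarsest rank to keep; default `"genus"`.
#' @return The retained subset of `x`.
#' @export
rank_inclusion_filter <- function(x, min_resolution = "genus") {
  min_resolution <- match.arg(min_resolution, RANKS)
  keep <- lineage_depth(x) >= match(min_resolution, RANKS)
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply the full filter chain
#'
#' Applies, in the fixed contract order: self-host masking, negative-control
#' thresholds, singleton removal, RRA threshold, then (separately) the
#' rank-inclusion filter. The order matters — applying RRA before singleton
#' removal can change denominators — so it is part of the contract.
#'
#' @param records Field-sample detection data frame.
#' @param host_lineages Host lineages for [remove_self_host()].
#' @param nc_records Negative-control records, or `NULL` to skip.
#' @param rra_pct RRA threshold in percent (default 1).
#' @param rra_scope RRA pooling scope (see [rra_threshold_filter()]).
#' @param min_resolution Rank threshold for the statistics dataset.
#' @param mask_family Passed to [remove_self_host()].
#' @return List with `statistics` (post-rank dataset), `profiling` (post-RRA,
#'   pre-rank dataset used for resolution profiles), and `reports` (list of
#'   `filter_report`s).
#' @export
filter_chain <- function(records, host_lineages, nc_records = NULL,
                         rra_pct = 1, rra_scope = "sample_target",
                         min_resolution = "genus", mask_family = FALSE) {
  s1 <- remove_self_host(records, host_lineages, mask_family = mask_family)
  s2 <- negative_control_filter(s1$retained, nc_records)
  s3 <- remove_singletons(s2$retained)
  s4 <- rra_threshold_filter(s3$retained, threshold_pct = rra_pct,
                             scope = rra_scope)
  stats_set <- rank_inclusion_filter(s4$retained, min_resolution)
  list(statistics = stats_set,
       profiling = s4$retained,
       reports = list(self_host = s1$report,
                      negative_control = s2$report,
                      singleton = s3$report,
                      rra = s4$report))
}

#' Serialize filter reports to JSON
#'
#' @param reports A `filter_report` or list of them.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_filter_reports <- function(reports, path) {
  if (inherits(reports, "filter_report")) reports <- list(reports)
  jsonlite::write_json(lapply(reports, unclass), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}
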