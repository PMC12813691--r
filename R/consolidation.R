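# Multi-marker consolidation: within a sample and target group, records from
# complementary markers are merged into one set of unique ingested taxa.
# A less resolved lineage compatible with exactly one maximal (most resolved)
# lineage merges into it; a lineage compatible with two or more non-nested
# finer lineages is an ambiguous parent and is retained as its own entry
# (read apportionment would require an abundance model we do not assume).

consolidate_group <- function(records) {
  # records: one sample, one target_group; already duplicate-summed per marker
  key <- lineage_key(records)
  uk <- unique(key)
  # aggregate identical lineages across markers
  agg <- lapply(uk, function(k) {
    rows <- records[key == k, , drop = FALSE]
    list(key = k,
         lineage = rows[1L, RANKS, drop = FALSE],
         markers = sort(unique(rows$marker)),
         reads = sum(rows$reads))
  })
  keys <- vapply(agg, `[[`, character(1), "key")
  # leaves: lineages not a strict ancestor of any other lineage in the set
  has_ext <- vapply(keys, function(k) any(is_strict_prefix(k, keys)), logical(1))
  leaves <- keys[!has_ext]
  out <- list()
  for (i in seq_along(agg)) {
    k <- keys[[i]]
    if (!has_ext[[i]]) next                       # leaf: emitted below
    ext <- leaves[is_strict_prefix(k, leaves)]
    if (length(ext) == 1L) {
      # unique maximal extension: merge reads and markers into that leaf
      j <- which(keys == ext)
      agg[[j]]$reads <- agg[[j]]$reads + agg[[i]]$reads
      agg[[j]]$markers <- sort(unique(c(agg[[j]]$markers, agg[[i]]$markers)))
    } else {
      out[[length(out) + 1L]] <- agg[[i]]         # ambiguous parent retained
    }
  }
  out <- c(out, agg[match(leaves, keys)])
  df <- do.call(rbind, lapply(out, function(e) {
    cbind(e$lineage,
          data.frame(source_markers = paste(e$markers, collapse = ","),
                     total_reads = e$reads, stringsAsFactors = FALSE))
  }))
  df[order(lineage_key(df)), , drop = FALSE]
}

#' Consolidate one sample's detections across markers
#'
#' Within each target group of a single sample: (1) records with identical
#' lineages are pooled (reads summed, markers unioned); (2) a lineage that is
#' a strict ancestor of exactly one maximal lineage in the set is merged into
#' it; (3) a lineage compatible with two or more non-nested finer lineages is
#' kept as its own entry. The result contains no lineage that is a strict
#' prefix of exactly one other, reads are conserved, and the output is
#' independent of input row order.
#'
#' @param records Detection data frame for one sample (filtering already
#'   applied).
#' @return Consolidated data frame: `sample_id`, `target_group`, rank
#'   columns, `resolution`, `source_markers` (comma-joined), `total_reads`.
#' @export
consolidate_sample <- function(records) {
  sid <- unique(records$sample_id)
  if (length(sid) > 1L) {
    stop("consolidate_sample() expects records from a single sample; got: ",
         paste(sid, collapse = ", "), call. = FALSE)
  }
  empty <- data.frame(sample_id = character(), target_group = character(),
                      stringsAsFactors = FALSE)
  for (r in RANKS) empty[[r]] <- character()
  empty$resolution <- character()
  empty$source_markers <- character()
  empty$total_reads <- integer()
  if (nrow(records) == 0L) return(empty)
  parts <- lapply(split(records, records$target_group), consolidate_group)
  out <- do.call(rbind, lapply(names(parts), function(g) {
    df <- parts[[g]]
    data.frame(sample_id = sid, target_group = g, df[, RANKS, drop = FALSE],
               resolution = lineage_resolution(df),
               source_markers = df$source_markers,
               total_reads = as.integer(df$total_reads),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  rownames(out) <- NULL
  out
}

#' Consolidate all samples
#'
#' Applies [consolidate_sample()] independently to every sample and attaches
#' functional annotations by deepest-rank label.
#'
#' @param records Detection data frame (filtering already applied).
#' @param metadata Metadata data frame; every `sample_id` in `records` must
#'   appear in it.
#' @param annotations Optional annotation data frame; taxa without an entry
#'   are labelled `"unannotated"`.
#' @return Consolidated data frame over all samples, with `plant_type` and
#'   `functional_group` columns when annotations are given.
#' @export
consolidate_all <- function(records, metadata, annotations = NULL) {
  unknown <- setdiff(unique(records$sample_id), metadata$sample_id)
  if (length(unknown)) {
    stop("records reference sample_id(s) absent from metadata: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  pieces <- lapply(split(records, records$sample_id), consolidate_sample)
  out <- if (length(pieces)) {
    do.call(rbind, c(pieces, list(make.row.names = FALSE)))
  } else {
    consolidate_sample(records[0, , drop = FALSE])
  }
  if (!is.null(annotations) && nrow(out)) {
    ann <- annotation_lookup(annotations, deepest_label(out))
    out$plant_type <- ann$plant_type
    out$functional_group <- ann$functional_group
  }
  rownames(out) <- NULL
  out
}

#' Write a consolidated table
#' @param df Consolidated data frame.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_consolidated <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
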