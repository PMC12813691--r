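# Descriptive diet statistics: relative read abundance (RRA%), frequency of
# occurrence (FOO%), richness and Shannon diversity, per-individual diet
# states, period summaries, rank-resolution profiles, co-occurrence, and
# community-matrix utilities (Hellinger transform, Bray-Curtis).

#' Per-sample relative read abundance
#'
#' Within each (sample, target group) — or (sample, marker) — the RRA of a
#' record is `100 * reads / total reads` of its scope. Each scope's vector
#' sums to 100 within 1e-9. Scopes with zero total reads yield no rows.
#'
#' @param records Detection or consolidated data frame (the read column may
#'   be `reads` or `total_reads`).
#' @param scope `"sample_target"` (default) or `"sample_marker"`.
#' @return The input with an `rra` column (percent), zero-total scopes
#'   dropped.
#' @export
compute_rra <- function(records, scope = c("sample_target", "sample_marker")) {
  scope <- match.arg(scope)
  reads <- if ("reads" %in% names(records)) records$reads else records$total_reads
  if (nrow(records) == 0L) {
    records$rra <- numeric(0)
    return(records)
  }
  grp <- if (scope == "sample_target") {
    paste(records$sample_id, records$target_group, sep = "\r")
  } else {
    paste(records$sample_id, records$marker, sep = "\r")
  }
  totals <- tapply(reads, grp, sum)
  tot <- as.numeric(totals[grp])
  out <- records[tot > 0, , drop = FALSE]
  out$rra <- 100 * reads[tot > 0] / tot[tot > 0]
  rownames(out) <- NULL
  out
}

#' Frequency of occurrence
#'
#' FOO of a taxon is the percentage of samples (in a stated denominator set)
#' in which the taxon is detected. One consolidated (sample, taxon) pair is
#' one occurrence. With `level = "genus"`, species-level entries roll up to
#' their genus and a genus plus its species in the same sample count once.
#'
#' @param consolidated Consolidated data frame.
#' @param sample_ids Character vector defining the denominator (e.g. all
#'   field samples); must be non-empty.
#' @param level `"consolidated"` (as-is) or `"genus"` (roll up).
#' @return Data frame: `target_group`, rank columns, `taxon` (deepest
#'   label), `n_occurrences`, `foo` (percent).
#' @export
compute_foo <- function(consolidated, sample_ids,
                        level = c("consolidated", "genus")) {
  level <- match.arg(level)
  if (length(sample_ids) == 0L) {
    stop("compute_foo(): empty denominator sample set", call. = FALSE)
  }
  df <- consolidated[consolidated$sample_id %in% sample_ids, , drop = FALSE]
  if (level == "genus") {
    depth <- pmin(lineage_depth(df), match("genus", RANKS))
    df <- truncate_lineage(df, depth)
    df <- df[!duplicated(paste(df$sample_id, df$target_group,
                               lineage_key(df), sep = "\r")), , drop = FALSE]
  }
  if (nrow(df) == 0L) {
    return(data.frame(target_group = character(), taxon = character(),
                      n_occurrences = integer(), foo = numeric()))
  }
  key <- paste(df$target_group, lineage_key(df), sep = "\r")
  occ <- tapply(df$sample_id, key, function(s) length(unique(s)))
  first <- df[!duplicated(key), , drop = FALSE]
  n_occ <- as.integer(occ[paste(first$target_group, lineage_key(first),
                                sep = "\r")])
  out <- data.frame(target_group = first$target_group,
                    first[, RANKS, drop = FALSE],
                    taxon = deepest_label(first),
                    n_occurrences = n_occ,
                    foo = 100 * n_occ / length(sample_ids),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$n_occurrences, out$taxon), , drop = FALSE]
}

#' Richness and Shannon diversity of occurrence counts
#'
#' Richness R is the number of taxa with a positive count; Shannon diversity
#' uses the natural logarithm, `H = -sum(p_i * log(p_i))` with
#' `p_i = count_i / sum(counts)`. An all-zero input returns R = 0 and H = 0
#' with `defined = FALSE`.
#'
#' @param counts Numeric vector of per-taxon occurrence counts (>= 0).
#' @return List with `richness`, `shannon`, and `defined`.
#' @export
shannon_richness <- function(counts) {
  stopifnot(all(counts >= 0))
  counts <- counts[counts > 0]
  if (!length(counts)) {
    return(list(richness = 0L, shannon = 0, defined = FALSE))
  }
  p <- counts / sum(counts)
  list(richness = length(counts), shannon = -sum(p * log(p)), defined = TRUE)
}

#' Classify per-individual diet states
#'
#' An individual with only plant detections is phytophagous (score s = 1),
#' with only metazoan detections zoophagous (s = 0), with both omnivorous
#' (s = 0.5), and with neither undetected (s = NA; excluded from the
#' coefficient of omnivory).
#'
#' @param consolidated Consolidated data frame (post-filtering).
#' @param metadata Metadata data frame; field samples define the cohort.
#' @return Data frame: `sample_id`, `n_plant`, `n_metazoan`, `state`,
#'   `s`, `year`, `month`, `sex`.
#' @export
classify_diet_state <- function(consolidated, metadata) {
  field <- metadata[metadata$sample_class == "field", , drop = FALSE]
  n_plant <- vapply(field$sample_id, function(s) {
    sum(consolidated$sample_id == s & consolidated$target_group == "plant")
  }, integer(1))
  n_met <- vapply(field$sample_id, function(s) {
    sum(consolidated$sample_id == s & consolidated$target_group == "metazoan")
  }, integer(1))
  state <- ifelse(n_plant > 0 & n_met > 0, "omnivorous",
           ifelse(n_plant > 0, "phytophagous",
           ifelse(n_met > 0, "zoophagous", "undetected")))
  s <- ifelse(state == "phytophagous", 1,
       ifelse(state == "omnivorous", 0.5,
       ifelse(state == "zoophagous", 0, NA_real_)))
  data.frame(sample_id = field$sample_id, n_plant = unname(n_plant),
             n_metazoan = unname(n_met), state = state, s = s,
             year = field$year, month = field$month, sex = field$sex,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Period summaries of occurrences and diversity
#'
#' For each (year, month) and target group: `freq` is the total number of
#' occurrences pooled over the period's individuals; richness and Shannon
#' diversity are computed on the pooled per-taxon occurrence counts (one
#' count per individual in which the taxon occurs, not reads); `pct_fed` is
#' the percentage of the period's individuals with at least one detection in
#' the group; `pct_strict` the percentage of *fed* individuals whose
#' detections are only in that group; `pct_female_among_fed` the percentage
#' of females among fed individuals.
#'
#' @param consolidated Consolidated data frame.
#' @param states Diet states from [classify_diet_state()].
#' @param metadata Metadata data frame.
#' @return Data frame with one row per (year, month, target_group).
#' @export
summarize_periods <- function(consolidated, states, metadata) {
  field <- metadata[metadata$sample_class == "field", , drop = FALSE]
  periods <- unique(field[, c("year", "month")])
  periods <- periods[order(periods$year, periods$month), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(periods))) {
    yr <- periods$year[i]; mo <- periods$month[i]
    ids <- field$sample_id[field$year == yr & field$month == mo]
    if (!length(ids)) next
    st <- states[states$sample_id %in% ids, , drop = FALSE]
    sub <- consolidated[consolidated$sample_id %in% ids, , drop = FALSE]
    for (g in c("plant", "metazoan")) {
      gs <- sub[sub$target_group == g, , drop = FALSE]
      counts <- if (nrow(gs)) {
        tapply(gs$sample_id, lineage_key(gs), function(s) length(unique(s)))
      } else numeric(0)
      sh <- shannon_richness(as.numeric(counts))
      fed <- if (g == "plant") st$sample_id[st$n_plant > 0] else
        st$sample_id[st$n_metazoan > 0]
      strict_state <- if (g == "plant") "phytophagous" else "zoophagous"
      n_fed <- length(fed)
      n_strict <- sum(st$sample_id %in% fed & st$state == strict_state)
      n_fem <- sum(st$sample_id %in% fed & st$sex == "F")
      rows[[length(rows) + 1L]] <- data.frame(
        year = yr, month = mo, target_group = g,
        freq = nrow(gs), richness = sh$richness, shannon = sh$shannon,
        pct_fed = 100 * n_fed / length(ids),
        pct_strict = if (n_fed > 0) 100 * n_strict / n_fed else 0,
        pct_female_among_fed = if (n_fed > 0) 100 * n_fem / n_fed else 0,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Rank-resolution profile
#'
#' Percentages of unique taxa — and separately of occurrences — whose
#' resolution is each rank. Used to compare the taxonomic resolving power of
#' markers and of the consolidated set.
#'
#' @param x Detection or consolidated data frame (seven rank columns); each
#'   row is one occurrence.
#' @return Data frame with one row per rank: `rank`, `n_taxa`, `pct_taxa`,
#'   `n_occurrences`, `pct_occurrences`. Empty input gives all zeros.
#' @export
rank_resolution_summary <- function(x) {
  res_occ <- lineage_resolution(x)
  uniq <- x[!duplicated(lineage_key(x)), , drop = FALSE]
  res_taxa <- lineage_resolution(uniq)
  n_taxa <- vapply(RANKS, function(r) sum(res_taxa == r), integer(1))
  n_occ <- vapply(RANKS, function(r) sum(res_occ == r), integer(1))
  data.frame(rank = RANKS,
             n_taxa = unname(n_taxa),
             pct_taxa = if (sum(n_taxa)) 100 * unname(n_taxa) / sum(n_taxa) else 0,
             n_occurrences = unname(n_occ),
             pct_occurrences = if (sum(n_occ)) 100 * unname(n_occ) / sum(n_occ) else 0,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Co-occurrence profile of a focal taxon
#'
#' For a focal taxon occurring in n samples, each partner taxon's
#' co-occurrence is `100 * (#samples containing both) / n`. The measure is
#' asymmetric: %(A given B) need not equal %(B given A).
#'
#' @param consolidated Consolidated data frame.
#' @param focal Focal taxon: its deepest-rank label or full lineage key.
#' @return Data frame: `partner` (deepest label), `partner_key`,
#'   `target_group`, `n_together`, `pct_cooccurrence`, sorted descending.
#' @export
co_occurrence <- function(consolidated, focal) {
  keys <- lineage_key(consolidated)
  labels <- deepest_label(consolidated)
  hit <- keys == focal | labels == focal
  if (!any(hit)) {
    stop("co_occurrence(): focal taxon not present: ", focal, call. = FALSE)
  }
  focal_samples <- unique(consolidated$sample_id[hit])
  n <- length(focal_samples)
  sub <- consolidated[consolidated$sample_id %in% focal_samples & !hit, ,
                      drop = FALSE]
  if (nrow(sub) == 0L) {
    return(data.frame(partner = character(), partner_key = character(),
                      target_group = character(), n_together = integer(),
                      pct_cooccurrence = numeric()))
  }
  k <- lineage_key(sub)
  together <- tapply(sub$sample_id, k, function(s) length(unique(s)))
  first <- sub[!duplicated(k), , drop = FALSE]
  n_tog <- as.integer(together[lineage_key(first)])
  out <- data.frame(partner = deepest_label(first),
                    partner_key = lineage_key(first),
                    target_group = first$target_group,
                    n_together = n_tog,
                    pct_cooccurrence = 100 * n_tog / n,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$pct_cooccurrence, out$partner), , drop = FALSE]
}

#' Build a sample-by-taxon occurrence matrix
#'
#' @param consolidated Consolidated data frame.
#' @param target_group Optional: restrict to `"plant"` or `"metazoan"`.
#' @param mode `"presence"` (0/1, default) or `"reads"` (total reads).
#' @return Numeric matrix, rows = samples, columns = lineage keys.
#' @export
occurrence_matrix <- function(consolidated, target_group = NULL,
                              mode = c("presence", "reads")) {
  mode <- match.arg(mode)
  df <- consolidated
  if (!is.null(target_group)) {
    df <- df[df$target_group == target_group, , drop = FALSE]
  }
  samples <- sort(unique(df$sample_id))
  taxa <- sort(unique(lineage_key(df)))
  m <- matrix(0, nrow = length(samples), ncol = length(taxa),
              dimnames = list(samples, taxa))
  if (nrow(df)) {
    i <- match(df$sample_id, samples)
    j <- match(lineage_key(df), taxa)
    v <- if (mode == "presence") 1 else df$total_reads
    for (r in seq_len(nrow(df))) m[i[r], j[r]] <- m[i[r], j[r]] + v[r]
    if (mode == "presence") m[m > 0] <- 1
  }
  m
}

#' Hellinger transformation
#'
#' Each cell becomes the square root of its row-relative abundance,
#' `sqrt(x_ij / rowsum_i)`. Zero-sum rows transform to all-zero and are
#' flagged in the `"zero_rows"` attribute.
#'
#' @param m Non-negative numeric matrix (samples in rows).
#' @return Transformed matrix with attribute `zero_rows`.
#' @export
hellinger_transform <- function(m) {
  stopifnot(all(m >= 0))
  rs <- rowSums(m)
  zero <- rs == 0
  out <- m
  out[!zero, ] <- sqrt(m[!zero, , drop = FALSE] / rs[!zero])
  out[zero, ] <- 0
  attr(out, "zero_rows") <- rownames(m)[zero]
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(a, b) = sum|a_i - b_i| / sum(a_i + b_i)` between rows; symmetric with
#' a zero diagonal, in [0, 1] on non-negative data. Pairs where both rows sum
#' to zero are set to 0 with a warning.
#'
#' @param m Non-negative numeric matrix (typically Hellinger-transformed).
#' @return Symmetric dissimilarity matrix.
#' @export
bray_curtis <- function(m) {
  # vegan warns about empty rows itself; the package raises its own warning
  d <- as.matrix(suppressWarnings(vegan::vegdist(m, method = "bray")))
  if (any(!is.finite(d))) {
    warning("zero-sum row pair(s): Bray-Curtis undefined, set to 0",
            call. = FALSE)
    d[!is.finite(d)] <- 0
  }
  diag(d) <- 0
  d
}

#' Hellinger transform followed by Bray-Curtis
#'
#' @param m Non-negative numeric matrix.
#' @return List with `transformed` and `dissimilarity`.
#' @export
hellinger_bray_curtis <- function(m) {
  h <- hellinger_transform(m)
  list(transformed = h, dissimilarity = bray_curtis(h))
}
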