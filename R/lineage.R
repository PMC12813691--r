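# Taxonomic lineages are stored "wide": one column per Linnaean rank, NA for
# unassigned ranks. Identity of a taxon is the full rank tuple, never just the
# deepest label, so homonyms across kingdoms cannot collide.

#' Rank ladder used throughout the package
#'
#' The seven Linnaean ranks, coarsest first. Every detection and consolidated
#' table carries one column per rank; an empty cell means the classifier did
#' not assign that rank. Lineages must form a contiguous prefix of this ladder
#' (a missing rank is never followed by an assigned one).
#'
#' @return Character vector of the seven rank names.
#' @export
taxon_ranks <- function() {
  c("kingdom", "phylum", "class", "order", "family", "genus", "species")
}

RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")

#' Build a lineage data frame
#'
#' Convenience constructor for one or more lineages. Arguments are recycled to
#' a common length; trailing ranks may be omitted or `NA`.
#'
#' @param kingdom,phylum,class,order,family,genus,species Rank labels
#'   (character or `NA`).
#' @return A data frame with the seven rank columns.
#' @examples
#' lineage(kingdom = "Viridiplantae", phylum = "Streptophyta",
#'         class = "Magnoliopsida", order = "Solanales",
#'         family = "Solanaceae", genus = "Solanum")
#' @export
lineage <- function(kingdom = NA, phylum = NA, class = NA, order = NA,
                    family = NA, genus = NA, species = NA) {
  df <- data.frame(kingdom = as.character(kingdom),
                   phylum = as.character(phylum),
                   class = as.character(class),
                   order = as.character(order),
                   family = as.character(family),
                   genus = as.character(genus),
                   species = as.character(species),
                   stringsAsFactors = FALSE)
  df
}

rank_matrix <- function(df) {
  m <- as.matrix(df[, RANKS, drop = FALSE])
  m[!is.na(m) & trimws(m) == ""] <- NA
  m[] <- ifelse(is.na(m), NA, trimws(m))
  m
}

#' Depth of each lineage
#'
#' Number of assigned ranks, counting from kingdom. A species-level lineage
#' has depth 7.
#'
#' @param df Data frame containing the seven rank columns.
#' @return Integer vector, one entry per row.
#' @export
lineage_depth <- function(df) {
  m <- rank_matrix(df)
  rowSums(!is.na(m))
}

#' Resolution (deepest assigned rank) of each lineage
#'
#' @param df Data frame containing the seven rank columns.
#' @return Character vector of rank names ("kingdom" ... "species").
#' @export
lineage_resolution <- function(df) {
  d <- lineage_depth(df)
  out <- rep(NA_character_, length(d))
  out[d > 0] <- RANKS[d[d > 0]]
  out
}

#' Validate lineage contiguity
#'
#' Every lineage must be a contiguous prefix of the rank ladder: once a rank
#' is missing, all deeper ranks must be missing too, and at least one rank
#' must be assigned.
#'
#' @param df Data frame containing the seven rank columns.
#' @param context Label used in the error message (e.g. a file name).
#' @return Invisibly `df`; throws an error naming the offending rows.
#' @export
validate_lineages <- function(df, context = "lineage table") {
  m <- rank_matrix(df)
  present <- !is.na(m)
  # a gap exists if any assigned rank follows a missing one
  gap <- apply(present, 1L, function(p) {
    if (!any(p)) return(TRUE)                 # all-missing is also invalid
    last <- max(which(p))
    any(!p[seq_len(last)])
  })
  if (any(gap)) {
    stop(sprintf("%s: invalid lineage (rank gap or empty) in row(s) %s",
                 context, paste(utils::head(which(gap), 10L), collapse = ", ")),
         call. = FALSE)
  }
  invisible(df)
}

#' Lineage identity keys
#'
#' Collapses each lineage's assigned ranks into a single string key
#' (`kingdom|phylum|...`). Keys are the unit of identity for filtering,
#' consolidation and counting; a key is a *strict prefix* of another when the
#' corresponding lineage is a strict ancestor.
#'
#' @param df Data frame containing the seven rank columns.
#' @return Character vector of keys.
#' @export
lineage_key <- function(df) {
  m <- rank_matrix(df)
  apply(m, 1L, function(r) paste(r[!is.na(r)], collapse = "|"))
}

#' Deepest label of each lineage
#'
#' The label at the resolution rank; used to join functional annotations,
#' which are keyed by the deepest label.
#'
#' @param df Data frame containing the seven rank columns.
#' @return Character vector of labels.
#' @export
deepest_label <- function(df) {
  m <- rank_matrix(df)
  apply(m, 1L, function(r) {
    r <- r[!is.na(r)]
    if (length(r)) r[[length(r)]] else NA_character_
  })
}

# TRUE where `a` is a strict ancestor key of `b` (proper prefix on rank
# boundaries). Vectorised over b for a scalar a.
is_strict_prefix <- function(a, b) {
  startsWith(b, paste0(a, "|"))
}

#' Truncate lineages to a given depth
#'
#' Replaces ranks deeper than `depth` with `NA`, yielding a coarser
#' representation (e.g. a genus-level roll-up at `depth = 6`).
#'
#' @param df Data frame containing the seven rank columns.
#' @param depth Integer depth(s), recycled over rows; 7 = species.
#' @return `df` with deeper ranks blanked.
#' @export
truncate_lineage <- function(df, depth) {
  m <- rank_matrix(df)
  for (i in seq_len(nrow(m))) {
    if (depth[min(i, length(depth))] < ncol(m)) {
      m[i, seq(depth[min(i, length(depth))] + 1L, ncol(m))] <- NA
    }
  }
  out <- df
  out[, RANKS] <- m
  out
}
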