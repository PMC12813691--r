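# Synthetic cohort generator. Emulates the statistical structure of a
# two-season field study of an omnivorous mirid: ~70 individuals sampled 10
# per month over 7 (year, month) periods, plant DNA in ~93% of individuals,
# animal DNA in ~27%, both in ~15 of 70, heavy conspecific (self-host) read
# contamination of the metazoan markers, negative-control contaminant taxa,
# singleton artifacts, and two markers per target group with differing
# taxonomic resolution. Every generated record carries a ground-truth origin
# so filter and consolidation recovery can be scored exactly.

plant_lineage <- function(class, order, family, genus, species = NA) {
  lineage(kingdom = "Viridiplantae", phylum = "Streptophyta", class = class,
          order = order, family = family, genus = genus, species = species)
}

animal_lineage <- function(class, order, family, genus, species = NA) {
  lineage(kingdom = "Animalia", phylum = "Arthropoda", class = class,
          order = order, family = family, genus = genus, species = species)
}

#' Default plant taxon pool for the synthetic cohort
#'
#' Fifteen species-level lineages (one species per genus, so consolidation
#' is unambiguous) spanning herbaceous weeds, cultivated species, trap crops,
#' the target crop (strawberry), a tree and a fern.
#'
#' @return Lineage data frame, one row per taxon.
#' @export
plant_taxa_pool <- function() {
  rbind(
    plant_lineage("Magnoliopsida", "Asterales", "Asteraceae", "Ambrosia", "Ambrosia artemisiifolia"),
    plant_lineage("Magnoliopsida", "Asterales", "Asteraceae", "Erigeron", "Erigeron canadensis"),
    plant_lineage("Magnoliopsida", "Brassicales", "Brassicaceae", "Brassica", "Brassica napus"),
    plant_lineage("Magnoliopsida", "Brassicales", "Brassicaceae", "Capsella", "Capsella bursa-pastoris"),
    plant_lineage("Magnoliopsida", "Caryophyllales", "Amaranthaceae", "Amaranthus", "Amaranthus retroflexus"),
    plant_lineage("Magnoliopsida", "Caryophyllales", "Chenopodiaceae", "Chenopodium", "Chenopodium album"),
    plant_lineage("Magnoliopsida", "Caryophyllales", "Polygonaceae", "Persicaria", "Persicaria lapathifolia"),
    plant_lineage("Magnoliopsida", "Caryophyllales", "Polygonaceae", "Fagopyrum", "Fagopyrum esculentum"),
    plant_lineage("Magnoliopsida", "Lamiales", "Plantaginaceae", "Plantago", "Plantago major"),
    plant_lineage("Magnoliopsida", "Lamiales", "Scrophulariaceae", "Verbascum", "Verbascum thapsus"),
    plant_lineage("Magnoliopsida", "Poales", "Poaceae", "Digitaria", "Digitaria sanguinalis"),
    plant_lineage("Magnoliopsida", "Rosales", "Rosaceae", "Fragaria", "Fragaria x ananassa"),
    plant_lineage("Magnoliopsida", "Sapindales", "Rutaceae", "Phellodendron", "Phellodendron amurense"),
    plant_lineage("Magnoliopsida", "Solanales", "Solanaceae", "Solanum", "Solanum dulcamara"),
    plant_lineage("Polypodiopsida", "Polypodiales", "Pteridaceae", "Pteris", "Pteris cretica"))
}

#' Default metazoan (prey) taxon pool for the synthetic cohort
#'
#' Nine species-level arthropod lineages (one per genus) covering zoophagous,
#' phytophagous, detritivorous and hematophagous prey.
#'
#' @return Lineage data frame, one row per taxon.
#' @export
metazoan_taxa_pool <- function() {
  rbind(
    animal_lineage("Arachnida", "Araneae", "Theridiidae", "Achaearanea", "Achaearanea tabulata"),
    animal_lineage("Arachnida", "Araneae", "Philodromidae", "Philodromus", "Philodromus dispar"),
    animal_lineage("Insecta", "Diptera", "Chironomidae", "Cricotopus", "Cricotopus annulator"),
    animal_lineage("Insecta", "Diptera", "Sciaridae", "Bradysia", "Bradysia ocellaris"),
    animal_lineage("Insecta", "Diptera", "Simuliidae", "Simulium", "Simulium venustum"),
    animal_lineage("Insecta", "Ephemeroptera", "Baetidae", "Baetis", "Baetis fuscatus"),
    animal_lineage("Insecta", "Hemiptera", "Anthocoridae", "Orius", "Orius insidiosus"),
    animal_lineage("Insecta", "Hemiptera", "Aphididae", "Myzus", "Myzus persicae"),
    animal_lineage("Insecta", "Lepidoptera", "Tortricidae", "Choristoneura", "Choristoneura rosaceana"))
}

#' Focal-host lineage of the synthetic cohort
#'
#' The tarnished plant bug, whose conspecific reads dominate the metazoan
#' markers before self-host masking.
#'
#' @return One-row lineage data frame (species rank).
#' @export
host_lineage <- function() {
  animal_lineage("Insecta", "Hemiptera", "Miridae", "Lygus", "Lygus lineolaris")
}

#' Default functional annotations for the synthetic taxon pools
#'
#' @return Annotation data frame keyed by deepest label.
#' @export
default_annotations <- function() {
  as_annotations(data.frame(
    lineage_key = c("Ambrosia artemisiifolia", "Erigeron canadensis",
                    "Brassica napus", "Capsella bursa-pastoris",
                    "Amaranthus retroflexus", "Chenopodium album",
                    "Persicaria lapathifolia", "Fagopyrum esculentum",
                    "Plantago major", "Verbascum thapsus",
                    "Digitaria sanguinalis", "Fragaria x ananassa",
                    "Phellodendron amurense", "Solanum dulcamara",
                    "Pteris cretica",
                    "Achaearanea tabulata", "Philodromus dispar",
                    "Cricotopus annulator", "Bradysia ocellaris",
                    "Simulium venustum", "Baetis fuscatus",
                    "Orius insidiosus", "Myzus persicae",
                    "Choristoneura rosaceana"),
    plant_type = c("herbaceous", "herbaceous", "herbaceous", "herbaceous",
                   "herbaceous", "herbaceous", "herbaceous", "herbaceous",
                   "herbaceous", "herbaceous", "herbaceous", "herbaceous",
                   "tree", "herbaceous", "fern",
                   rep("n/a", 9)),
    functional_group = c("non-cultivated", "cultivated", "trap crop",
                         "non-cultivated", "non-cultivated", "non-cultivated",
                         "non-cultivated", "trap crop", "non-cultivated",
                         "trap crop", "non-cultivated", "target crop",
                         "non-cultivated", "cultivated", "non-cultivated",
                         "zoophagous", "zoophagous", "detritivorous",
                         "detritivorous", "other", "other", "zoophagous",
                         "phytophagous", "phytophagous"),
    stringsAsFactors = FALSE))
}

default_nc_contaminants <- function() {
  wheat <- plant_lineage("Magnoliopsida", "Poales", "Poaceae", "Triticum",
                         "Triticum aestivum")
  human <- lineage(kingdom = "Animalia", phylum = "Chordata",
                   class = "Mammalia", order = "Primates",
                   family = "Hominidae", genus = "Homo",
                   species = "Homo sapiens")
  list(list(lineage = wheat, marker = "trnL_gh", max_reads = 40L),
       list(lineage = human, marker = "COI_ZBJ", max_reads = 25L),
       list(lineage = human, marker = "COI_mlCOI", max_reads = 25L))
}

singleton_artifact_pool <- function() {
  list(list(lineage = plant_lineage("Magnoliopsida", "Poales", "Poaceae",
                                    "Zea", "Zea mays"),
            marker = "trnL_gh"),
       list(lineage = animal_lineage("Insecta", "Diptera", "Drosophilidae",
                                     "Drosophila", "Drosophila melanogaster"),
            marker = "COI_ZBJ"))
}

#' Synthetic cohort configuration
#'
#' The defaults are the stated world the generator emulates: 7 (year, month)
#' periods with 10 individuals each (two seasons), female probability 43/70,
#' per-individual diet-state probabilities (50, 15, 4, 1)/70 for
#' (phytophagous, omnivorous, zoophagous, undetected), 1-9 plant taxa per
#' plant-feeding individual (truncated geometric), 1-3 metazoan taxa per
#' animal-feeding individual with 65%/30%/5% weights, two markers per group
#' with differing detection probability and species-level resolution (the
#' trnL assay resolves species in ~52% of detections, the ITS2 assay mostly
#' genus), log-normal read counts clamped to [600, 3000] so every true
#' record survives the singleton/negative-control/1%-RRA thresholds, 85% of
#' metazoan reads assigned to the conspecific host, negative-control
#' contaminants, and sporadic singleton artifacts.
#'
#' @param n_per_month Individuals per (year, month) period.
#' @param months Data frame with `year` and `month` columns.
#' @param female_prob Probability an individual is female.
#' @param state_probs Probabilities of (phytophagous, omnivorous, zoophagous,
#'   undetected); must sum to 1.
#' @param detection_prob Named per-marker detection probability of a true
#'   taxon.
#' @param species_prob Named per-marker probability that a detection is
#'   reported at species rank (otherwise truncated to genus).
#' @param reads_meanlog,reads_sdlog Log-normal read-count model.
#' @param reads_range Clamp range for true-record reads.
#' @param host_read_fraction Fraction of a sample's metazoan reads assigned
#'   to the host lineage.
#' @param nc_contaminants List of `list(lineage, marker, max_reads)`.
#' @param nc_injection_prob Probability a field sample carries each
#'   negative-control contaminant (at reads below the control maximum).
#' @param singleton_rate Probability a field sample carries one singleton
#'   artifact.
#' @param noiseless If `TRUE`, every true taxon is detected by both markers
#'   and the primary marker of each group always resolves species, so
#'   consolidated sets equal truth sets exactly.
#' @param seed Integer seed (mandatory).
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_per_month = 10,
                          months = data.frame(
                            year = c(2019, 2019, 2019, 2019, 2020, 2020, 2020),
                            month = c(7, 8, 9, 10, 7, 8, 9)),
                          female_prob = 43 / 70,
                          state_probs = c(phytophagous = 50 / 70,
                                          omnivorous = 15 / 70,
                                          zoophagous = 4 / 70,
                                          undetected = 1 / 70),
                          detection_prob = c(trnL_gh = 0.9, ITS2_u34 = 0.75,
                                             COI_ZBJ = 0.9, COI_mlCOI = 0.45),
                          species_prob = c(trnL_gh = 0.52, ITS2_u34 = 0.25,
                                           COI_ZBJ = 0.4, COI_mlCOI = 0.2),
                          reads_meanlog = log(1500), reads_sdlog = 0.6,
                          reads_range = c(600, 3000),
                          host_read_fraction = 0.85,
                          nc_contaminants = default_nc_contaminants(),
                          nc_injection_prob = 0.5,
                          singleton_rate = 0.3,
                          noiseless = FALSE,
                          seed) {
  if (missing(seed)) stop("cohort_config(): seed is mandatory", call. = FALSE)
  needed <- c("phytophagous", "omnivorous", "zoophagous", "undetected")
  if (!setequal(names(state_probs), needed)) {
    stop("cohort_config(): state_probs must be named ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  state_probs <- state_probs[needed]
  stopifnot(abs(sum(state_probs) - 1) < 1e-8,
            all(state_probs >= 0),
            host_read_fraction >= 0, host_read_fraction < 1,
            nc_injection_prob >= 0, nc_injection_prob <= 1,
            singleton_rate >= 0, singleton_rate <= 1)
  if (state_probs[["phytophagous"]] + state_probs[["omnivorous"]] +
      state_probs[["zoophagous"]] == 0) {
    stop("cohort_config(): zero probability for every detected state",
         call. = FALSE)
  }
  if (noiseless) {
    detection_prob[] <- 1
    species_prob[c("trnL_gh", "COI_ZBJ")] <- 1
  }
  structure(list(n_per_month = n_per_month, months = months,
                 female_prob = female_prob, state_probs = state_probs,
                 detection_prob = detection_prob, species_prob = species_prob,
                 reads_meanlog = reads_meanlog, reads_sdlog = reads_sdlog,
                 reads_range = reads_range,
                 host_read_fraction = host_read_fraction,
                 nc_contaminants = nc_contaminants,
                 nc_injection_prob = nc_injection_prob,
                 singleton_rate = singleton_rate,
                 noiseless = noiseless,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

draw_reads <- function(n, config) {
  r <- round(stats::rlnorm(n, config$reads_meanlog, config$reads_sdlog))
  pmax(config$reads_range[1], pmin(config$reads_range[2], r))
}

# truncated geometric on 1..9 (mean ~2, matching strict plant-feeders)
draw_n_plant <- function() min(1L + stats::rgeom(1, 0.5), 9L)
draw_n_metazoan <- function() sample.int(3L, 1L, prob = c(0.65, 0.30, 0.05))

detection_row <- function(sample_id, marker, target, lin, reads, origin) {
  data.frame(sample_id = sample_id, marker = marker, target_group = target,
             lin[, RANKS, drop = FALSE], reads = as.integer(reads),
             origin = origin, stringsAsFactors = FALSE, row.names = NULL)
}

#' Generate a synthetic cohort with ground truth
#'
#' Produces a detection table (field samples, with a ground-truth `origin`
#' column classifying every record as `true`, `host`, `nc` or `singleton`),
#' sample metadata including two PCR negative controls, the negative-control
#' detection table, and a `SyntheticTruth` object (per-sample diet states and
#' true ingested taxa). Deterministic under the config seed.
#'
#' @param config A [cohort_config()].
#' @return List of class `synthetic_cohort`: `detections`, `metadata`,
#'   `nc_detections`, `truth` (list with `states`, `taxa`, `config`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  plant_pool <- plant_taxa_pool()
  met_pool <- metazoan_taxa_pool()
  host <- host_lineage()
  markers <- default_marker_targets()
  plant_markers <- names(markers)[markers == "plant"]
  met_markers <- names(markers)[markers == "metazoan"]
  primary <- c(plant = "trnL_gh", metazoan = "COI_ZBJ")

  n_periods <- nrow(config$months)
  n <- n_periods * config$n_per_month
  sample_id <- sprintf("S%03d", seq_len(n))
  year <- rep(config$months$year, each = config$n_per_month)
  month <- rep(config$months$month, each = config$n_per_month)
  sex <- ifelse(stats::runif(n) < config$female_prob, "F", "M")
  state <- sample(names(config$state_probs), n, replace = TRUE,
                  prob = config$state_probs)
  s <- c(phytophagous = 1, omnivorous = 0.5, zoophagous = 0,
         undetected = NA_real_)[state]

  recs <- list()
  truth_taxa <- list()

  emit_true <- function(sid, pool, idx, group, group_markers) {
    out <- list()
    for (t in idx) {
      lin <- pool[t, , drop = FALSE]
      detected <- stats::runif(length(group_markers)) <
        config$detection_prob[group_markers]
      if (!any(detected)) {
        # guarantee at least one observation so the diet state is realized
        forced <- group_markers == primary[[group]]
        out[[length(out) + 1L]] <- detection_row(
          sid, primary[[group]], group, lin, draw_reads(1, config), "true")
        next
      }
      for (mk in group_markers[detected]) {
        use <- if (stats::runif(1) < config$species_prob[[mk]]) lin else
          truncate_lineage(lin, match("genus", RANKS))
        out[[length(out) + 1L]] <- detection_row(
          sid, mk, group, use, draw_reads(1, config), "true")
      }
    }
    out
  }

  for (i in seq_len(n)) {
    sid <- sample_id[i]
    plant_idx <- met_idx <- integer(0)
    if (state[i] %in% c("phytophagous", "omnivorous")) {
      plant_idx <- sample.int(nrow(plant_pool), draw_n_plant())
    }
    if (state[i] %in% c("zoophagous", "omnivorous")) {
      met_idx <- sample.int(nrow(met_pool), draw_n_metazoan())
    }
    rows <- c(emit_true(sid, plant_pool, plant_idx, "plant", plant_markers),
              emit_true(sid, met_pool, met_idx, "metazoan", met_markers))
    if (length(plant_idx)) {
      truth_taxa[[length(truth_taxa) + 1L]] <- data.frame(
        sample_id = sid, target_group = "plant",
        plant_pool[plant_idx, RANKS, drop = FALSE],
        stringsAsFactors = FALSE, row.names = NULL)
    }
    if (length(met_idx)) {
      truth_taxa[[length(truth_taxa) + 1L]] <- data.frame(
        sample_id = sid, target_group = "metazoan",
        met_pool[met_idx, RANKS, drop = FALSE],
        stringsAsFactors = FALSE, row.names = NULL)
    }
    # conspecific host reads dominate the metazoan markers
    m_reads <- sum(vapply(rows, function(r) {
      if (r$target_group == "metazoan") r$reads else 0L
    }, numeric(1)))
    f <- config$host_read_fraction
    h_total <- if (m_reads > 0) round(f / (1 - f) * m_reads) else 8000
    h1 <- max(2, round(0.6 * h_total)); h2 <- max(2, h_total - h1)
    rows[[length(rows) + 1L]] <- detection_row(
      sid, "COI_ZBJ", "metazoan", host, h1, "host")
    rows[[length(rows) + 1L]] <- detection_row(
      sid, "COI_mlCOI", "metazoan",
      truncate_lineage(host, match("genus", RANKS)), h2, "host")
    # negative-control-level contaminants
    for (ncc in config$nc_contaminants) {
      if (stats::runif(1) < config$nc_injection_prob) {
        rows[[length(rows) + 1L]] <- detection_row(
          sid, ncc$marker, unname(markers[ncc$marker]), ncc$lineage,
          sample(2:ncc$max_reads, 1L), "nc")
      }
    }
    # singleton artifacts
    if (stats::runif(1) < config$singleton_rate) {
      art <- singleton_artifact_pool()[[sample.int(2L, 1L)]]
      rows[[length(rows) + 1L]] <- detection_row(
        sid, art$marker, unname(markers[art$marker]), art$lineage, 1L,
        "singleton")
    }
    recs[[i]] <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  detections <- do.call(rbind, c(recs, list(make.row.names = FALSE)))

  # negative-control samples: the first control carries each contaminant at
  # its configured maximum (defining the threshold), the second below it
  nc_ids <- c("NC01", "NC02")
  nc_rows <- list()
  for (ncc in config$nc_contaminants) {
    nc_rows[[length(nc_rows) + 1L]] <- detection_row(
      nc_ids[1], ncc$marker, unname(markers[ncc$marker]), ncc$lineage,
      ncc$max_reads, "nc")
    nc_rows[[length(nc_rows) + 1L]] <- detection_row(
      nc_ids[2], ncc$marker, unname(markers[ncc$marker]), ncc$lineage,
      max(2L, ncc$max_reads %/% 2L), "nc")
  }
  nc_detections <- do.call(rbind, c(nc_rows, list(make.row.names = FALSE)))

  metadata <- as_metadata(data.frame(
    sample_id = c(sample_id, nc_ids),
    year = c(year, rep(NA, 2)),
    month = c(month, rep(NA, 2)),
    sex = c(sex, rep("unknown", 2)),
    sample_class = c(rep("field", n), rep("negative_control", 2)),
    host_species = "Lygus lineolaris",
    stringsAsFactors = FALSE), context = "synthetic cohort")

  truth_states <- data.frame(sample_id = sample_id, state = unname(state),
                             s = unname(s), year = year, month = month,
                             sex = sex, stringsAsFactors = FALSE)
  taxa <- if (length(truth_taxa)) {
    do.call(rbind, c(truth_taxa, list(make.row.names = FALSE)))
  } else {
    data.frame(sample_id = character(), target_group = character())
  }
  structure(list(detections = detections, metadata = metadata,
                 nc_detections = nc_detections,
                 truth = list(states = truth_states, taxa = taxa,
                              config = config)),
            class = "synthetic_cohort")
}

#' Simulate diet states only
#'
#' Draws per-individual phytophagy scores directly (no detection tables),
#' for calibration studies of the CO bootstrap and permutation machinery.
#' Default probabilities (0.725, 0.217, 0.058) over s = (1, 0.5, 0) give a
#' true CO of 0.8335.
#'
#' @param n_per_stratum Individuals per (year, month) period.
#' @param months Data frame of `year`, `month` periods.
#' @param probs Probabilities of s = 1, 0.5, 0 (detected states).
#' @param female_prob Probability of sex F.
#' @param seed Integer seed.
#' @return Diet-state data frame (`sample_id`, `state`, `s`, `year`,
#'   `month`, `sex`).
#' @export
simulate_diet_states <- function(n_per_stratum = 10,
                                 months = data.frame(
                                   year = c(2019, 2019, 2019, 2019,
                                            2020, 2020, 2020),
                                   month = c(7, 8, 9, 10, 7, 8, 9)),
                                 probs = c(50, 15, 4) / 69,
                                 female_prob = 43 / 70,
                                 seed) {
  if (missing(seed)) stop("simulate_diet_states(): seed required", call. = FALSE)
  set.seed(as.integer(seed))
  n <- nrow(months) * n_per_stratum
  svals <- sample(c(1, 0.5, 0), n, replace = TRUE, prob = probs / sum(probs))
  data.frame(sample_id = sprintf("S%03d", seq_len(n)),
             state = c("zoophagous", "omnivorous",
                       "phytophagous")[match(svals, c(0, 0.5, 1))],
             s = svals,
             year = rep(months$year, each = n_per_stratum),
             month = rep(months$month, each = n_per_stratum),
             sex = ifelse(stats::runif(n) < female_prob, "F", "M"),
             stringsAsFactors = FALSE)
}

#' Score pipeline outputs against synthetic ground truth
#'
#' Compares consolidated detections and classified diet states with the
#' generator's truth. A consolidated entry counts as a true positive when
#' its lineage equals, or is an ancestor of, a true taxon of the same sample
#' and target group (a marker may genuinely resolve only to genus); a true
#' taxon is recovered when such an entry exists. Exact-match rate requires
#' the consolidated key set to equal the truth key set.
#'
#' @param consolidated Consolidated data frame (post-filter pipeline).
#' @param states Diet states from [classify_diet_state()].
#' @param truth The `truth` element of [generate_cohort()] output.
#' @return List: `taxa_precision`, `taxa_recall`, `exact_match_rate`,
#'   `state_accuracy`, `co_error`, `n_samples`.
#' @export
truth_check <- function(consolidated, states, truth) {
  if (length(setdiff(states$sample_id, truth$states$sample_id))) {
    stop("truth_check(): sample ids not present in truth", call. = FALSE)
  }
  tt <- truth$taxa
  truth_by <- split(lineage_key(tt), paste(tt$sample_id, tt$target_group))
  cons_by <- if (nrow(consolidated)) {
    split(lineage_key(consolidated),
          paste(consolidated$sample_id, consolidated$target_group))
  } else list()
  tp <- fp <- fn <- 0L
  exact <- logical(0)
  groups <- union(names(truth_by), names(cons_by))
  for (g in groups) {
    tk <- truth_by[[g]] %||% character(0)
    ck <- cons_by[[g]] %||% character(0)
    matched_c <- vapply(ck, function(k) {
      any(k == tk | vapply(tk, function(t) is_strict_prefix(k, t), logical(1)))
    }, logical(1))
    matched_t <- vapply(tk, function(t) {
      any(ck == t | vapply(ck, function(k) is_strict_prefix(k, t), logical(1)))
    }, logical(1))
    tp <- tp + sum(matched_c)
    fp <- fp + sum(!matched_c)
    fn <- fn + sum(!matched_t)
    exact <- c(exact, setequal(tk, ck))
  }
  idx <- match(states$sample_id, truth$states$sample_id)
  state_acc <- mean(states$state == truth$states$state[idx])
  co_true <- compute_co(truth$states)$co
  co_est <- compute_co(states)$co
  list(taxa_precision = if (tp + fp) tp / (tp + fp) else 1,
       taxa_recall = if (tp + fn) tp / (tp + fn) else 1,
       exact_match_rate = if (length(exact)) mean(exact) else 1,
       state_accuracy = state_acc,
       co_error = abs(co_est - co_true),
       n_samples = nrow(states))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
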