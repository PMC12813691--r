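# Published summary counts from the motivating field study of Lygus
# lineolaris (tarnished plant bug) in a strawberry agroecosystem. These are
# the worked-example inputs for the coefficient of omnivory, the diet-type
# and sex-ratio chi-squared tests, and the metazoan rank-resolution profile.
# Only counts are embedded; every derived statistic is computed at run time.

#' Reference diet-state cohort
#'
#' Rebuilds the 70-individual diet-state vector from the published detection
#' rates: plant DNA detected in 93% of individuals, animal DNA in 27%, both
#' in 15 individuals. The counts are derived, not hard-coded: plant-fed
#' `round(0.93 * 70) = 65`, animal-fed `round(0.27 * 70) = 19`, hence
#' plant-only 50 (s = 1), both 15 (s = 0.5), animal-only 4 (s = 0), and one
#' undetected individual (excluded from CO).
#'
#' @param n Cohort size (default 70).
#' @param plant_rate,animal_rate Detection rates (defaults 0.93 and 0.27).
#' @param n_both Individuals with both detections (default 15).
#' @return Diet-state data frame usable with [compute_co()].
#' @export
reference_diet_states <- function(n = 70, plant_rate = 0.93,
                                  animal_rate = 0.27, n_both = 15) {
  n_plant <- round(plant_rate * n)
  n_animal <- round(animal_rate * n)
  n_plant_only <- n_plant - n_both
  n_animal_only <- n_animal - n_both
  n_undetected <- n - n_plant_only - n_animal_only - n_both
  stopifnot(n_plant_only >= 0, n_animal_only >= 0, n_undetected >= 0)
  state <- c(rep("phytophagous", n_plant_only),
             rep("omnivorous", n_both),
             rep("zoophagous", n_animal_only),
             rep("undetected", n_undetected))
  data.frame(sample_id = sprintf("R%03d", seq_len(n)),
             state = state,
             s = c(rep(1, n_plant_only), rep(0.5, n_both),
                   rep(0, n_animal_only), rep(NA_real_, n_undetected)),
             year = NA_integer_, month = NA_integer_, sex = NA_character_,
             stringsAsFactors = FALSE)
}

#' Reference metazoan taxon list
#'
#' The fourteen consolidated metazoan entries of the motivating study: five
#' species-level, seven genus-level, one family-level (Miridae, the focal
#' insect's own family) and one class-level entry. Used for the
#' rank-resolution worked example (35.71% species / 50.00% genus / 7.14%
#' family / 7.14% class).
#'
#' @return Lineage data frame with a `functional_group` column.
#' @export
reference_metazoan_taxa <- function() {
  l <- function(class, order = NA, family = NA, genus = NA, species = NA) {
    lineage(kingdom = "Animalia", phylum = "Arthropoda", class = class,
            order = order, family = family, genus = genus, species = species)
  }
  df <- rbind(
    l("Arachnida", "Araneae", "Philodromidae", "Philodromus"),
    l("Arachnida", "Araneae", "Theridiidae", "Achaearanea", "Achaearanea tabulata"),
    l("Insecta", "Diptera", "Chironomidae", "Cricotopus", "Cricotopus annulator"),
    l("Insecta", "Diptera", "Sciaridae", "Bradysia"),
    l("Insecta", "Diptera", "Sciaridae", "Bradysia", "Bradysia ocellaris"),
    l("Insecta", "Diptera", "Simuliidae", "Simulium"),
    l("Insecta", "Ephemeroptera", "Baetidae", "Baetis", "Baetis fuscatus"),
    l("Insecta", "Hemiptera", "Anthocoridae", "Orius", "Orius insidiosus"),
    l("Insecta", "Hemiptera", "Aphididae", "Myzus"),
    l("Insecta", "Hemiptera", "Coreidae", "Anasa"),
    l("Insecta", "Hemiptera", "Miridae"),
    l("Insecta", "Hemiptera", "Nabidae", "Nabis"),
    l("Insecta", "Lepidoptera", "Tortricidae", "Choristoneura"),
    l("Insecta"))
  df$functional_group <- c("zoophagous", "zoophagous", "detritivorous",
                           "detritivorous", "detritivorous", "other",
                           "other", "zoophagous", "phytophagous", "other",
                           NA, "zoophagous", "phytophagous", NA)
  df
}

#' Reference sex counts per year
#'
#' 2019: 16 males / 24 females; 2020: 11 males / 19 females.
#'
#' @return Metadata data frame of the 70 field individuals.
#' @export
reference_sex_metadata <- function() {
  counts <- data.frame(year = c(2019, 2019, 2020, 2020),
                       sex = c("M", "F", "M", "F"),
                       n = c(16, 24, 11, 19))
  rows <- counts[rep(seq_len(nrow(counts)), counts$n), c("year", "sex")]
  as_metadata(data.frame(sample_id = sprintf("R%03d", seq_len(nrow(rows))),
                         year = rows$year, month = 7L, sex = rows$sex,
                         sample_class = "field",
                         host_species = "Lygus lineolaris",
                         stringsAsFactors = FALSE),
              context = "reference sex metadata")
}

#' Recompute the reference worked examples
#'
#' Runs the package's own estimators on the embedded reference counts and
#' returns: the coefficient of omnivory of the 70-individual cohort, the
#' diet-type chi-squared test (phytophagous/omnivorous/zoophagous counts vs
#' uniform), the sex-ratio chi-squared test and per-year male proportions,
#' the metazoan rank-resolution percentages, and the two closed-form Shannon
#' diversities (one taxon; two equally frequent taxa).
#'
#' @return Named list of results, all computed at call time.
#' @export
reference_worked_examples <- function() {
  states <- reference_diet_states()
  co <- compute_co(states)
  diet_counts <- c(sum(states$state == "phytophagous"),
                   sum(states$state == "omnivorous"),
                   sum(states$state == "zoophagous"))
  diet_test <- chisq_goodness_of_fit(diet_counts)
  sr <- sex_ratio(reference_sex_metadata())
  rr <- rank_resolution_summary(reference_metazoan_taxa())
  list(co = co,
       diet_test = diet_test,
       sex_ratio = sr,
       rank_resolution = rr,
       shannon_one_taxon = shannon_richness(1),
       shannon_two_equal = shannon_richness(c(1, 1)))
}
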