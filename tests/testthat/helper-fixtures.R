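# Shared fixture builders. All fixtures are constructed in code; lineages use
# the package's own constructors so rank layout stays in one place.

plant_lin <- function(genus = NA, species = NA, family = "Solanaceae",
                      order = "Solanales", class = "Magnoliopsida") {
  lineage(kingdom = "Viridiplantae", phylum = "Streptophyta", class = class,
          order = order, family = family, genus = genus, species = species)
}

animal_lin <- function(genus = NA, species = NA, family = "Miridae",
                       order = "Hemiptera", class = "Insecta") {
  lineage(kingdom = "Animalia", phylum = "Arthropoda", class = class,
          order = order, family = family, genus = genus, species = species)
}

# build a detection data frame from rows of (sample, marker, lineage, reads)
make_detections <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(sample_id = r$sample, marker = r$marker,
               r$lin[, taxon_ranks(), drop = FALSE], reads = r$reads,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  as_detections(df)
}

drow <- function(sample, marker, lin, reads) {
  list(sample = sample, marker = marker, lin = lin, reads = reads)
}

make_field_metadata <- function(sample_ids, year = 2019, month = 7,
                                sex = "F") {
  as_metadata(data.frame(sample_id = sample_ids, year = year, month = month,
                         sex = sex, sample_class = "field",
                         host_species = "Lygus lineolaris",
                         stringsAsFactors = FALSE))
}

make_states <- function(s, year = 2019, month = 7, sex = "F") {
  n <- length(s)
  data.frame(sample_id = sprintf("T%03d", seq_len(n)),
             state = ifelse(is.na(s), "undetected",
                            c("zoophagous", "omnivorous",
                              "phytophagous")[match(s, c(0, 0.5, 1))]),
             s = s,
             year = rep_len(year, n), month = rep_len(month, n),
             sex = rep_len(sex, n), stringsAsFactors = FALSE)
}

# random detection fixture over the synthetic pools, for property tests
random_detections <- function(seed, n_samples = 3, max_taxa = 4) {
  set.seed(seed)
  pools <- list(plant = plant_taxa_pool(), metazoan = metazoan_taxa_pool())
  markers <- default_marker_targets()
  rows <- list()
  for (i in seq_len(n_samples)) {
    for (g in names(pools)) {
      pool <- pools[[g]]
      idx <- sample.int(nrow(pool), sample.int(max_taxa, 1))
      for (t in idx) {
        for (mk in sample(names(markers)[markers == g],
                          sample.int(2, 1))) {
          depth <- sample(5:7, 1)   # family, genus or species resolution
          lin <- truncate_lineage(pool[t, , drop = FALSE], depth)
          rows[[length(rows) + 1L]] <- drow(sprintf("P%02d", i), mk, lin,
                                            sample(1:2000, 1))
        }
      }
    }
  }
  suppressWarnings(do.call(make_detections, rows))
}
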