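host <- host_lineage()   # Lygus lineolaris, species rank

test_that("self-host masking matches by prefix at the coarser resolution", {
  recs <- make_detections(
    drow("S1", "COI_ZBJ", animal_lin("Lygus", "Lygus lineolaris"), 5000),
    drow("S1", "COI_mlCOI", animal_lin("Lygus"), 3000),     # genus only
    drow("S1", "COI_ZBJ", animal_lin("Bradysia", "Bradysia ocellaris",
                                     family = "Sciaridae", order = "Diptera"),
         40),
    drow("S1", "trnL_gh", plant_lin("Solanum"), 900))
  res <- remove_self_host(recs, host)
  expect_equal(nrow(res$retained), 2L)
  expect_false(any(res$retained$genus %in% "Lygus"))
  expect_true("Solanum" %in% res$retained$genus)   # plants untouched
  expect_equal(res$report$reads_removed, 8000)

  # empty input
  empty <- remove_self_host(recs[0, ], host)
  expect_equal(nrow(empty$retained), 0L)
  expect_equal(empty$report$records_removed, 0L)

  # family-level masking is opt-in
  fam <- make_detections(
    drow("S1", "COI_ZBJ", animal_lin(), 100))   # Miridae, family rank
  expect_equal(nrow(remove_self_host(fam, host)$retained), 0L)  # ancestor of host
  other_fam <- make_detections(
    drow("S1", "COI_ZBJ", animal_lin(family = "Nabidae", genus = "Nabis"), 9))
  expect_equal(nrow(remove_self_host(other_fam, host)$retained), 1L)
})

test_that("negative-control filter compares per marker with ties removed", {
  nc <- make_detections(
    drow("NC1", "trnL_gh", plant_lin("Triticum", family = "Poaceae",
                                     order = "Poales"), 10),
    drow("NC2", "trnL_gh", plant_lin("Triticum", family = "Poaceae",
                                     order = "Poales"), 4))
  wheat <- plant_lin("Triticum", family = "Poaceae", order = "Poales")
  field <- make_detections(
    drow("S1", "trnL_gh", wheat, 5),      # below NC max -> removed
    drow("S2", "trnL_gh", wheat, 10),     # tie -> removed
    drow("S3", "trnL_gh", wheat, 11),     # above -> retained
    drow("S4", "ITS2_u34", wheat, 5),     # other marker -> retained
    drow("S5", "trnL_gh", plant_lin("Solanum"), 3))  # not in NC -> retained
  res <- negative_control_filter(field, nc)
  expect_setequal(res$retained$sample_id, c("S3", "S4", "S5"))
  expect_equal(res$report$records_removed, 2L)

  # brute-force oracle over every (marker, lineage) pair of the fixture
  nc_max <- tapply(nc$reads, paste(nc$marker, lineage_key(nc)), max)
  expect_removed <- vapply(seq_len(nrow(field)), function(i) {
    k <- paste(field$marker[i], lineage_key(field[i, ]))
    k %in% names(nc_max) && field$reads[i] <= nc_max[[k]]
  }, logical(1))
  expect_equal(res$report$records_removed, sum(expect_removed))

  # no controls: skipped with a warning, nothing removed
  expect_warning(res2 <- negative_control_filter(field, NULL), "skipped")
  expect_equal(nrow(res2$retained), nrow(field))
})

test_that("singleton removal drops reads == 1 and keeps empty samples", {
  set.seed(4)
  reads <- c(rep(1L, 7), sample(2:50, 13))
  rows <- lapply(seq_along(reads), function(i) {
    drow(sprintf("S%d", (i %% 4) + 1), "trnL_gh",
         plant_lin(sprintf("Genus%02d", i), family = sprintf("Fam%02d", i)),
         reads[i])
  })
  recs <- do.call(make_detections, rows)
  res <- remove_singletons(recs)
  expect_equal(res$report$records_removed, 7L)   # count by construction
  expect_true(all(res$retained$reads >= 2))

  solo <- make_detections(drow("S9", "trnL_gh", plant_lin("Solanum"), 1))
  expect_equal(nrow(remove_singletons(solo)$retained), 0L)
})

test_that("RRA threshold uses strict < within (sample, target group)", {
  recs <- make_detections(
    drow("S1", "trnL_gh", plant_lin("GenA", family = "FamA"), 900),
    drow("S1", "ITS2_u34", plant_lin("GenB", family = "FamB"), 95),
    drow("S1", "trnL_gh", plant_lin("GenC", family = "FamC"), 5))
  res <- rra_threshold_filter(recs, 1)
  expect_setequal(res$retained$genus, c("GenA", "GenB"))   # C at 0.5% removed

  # exactly 1.0% is retained (strict <)
  boundary <- make_detections(
    drow("S1", "trnL_gh", plant_lin("GenA", family = "FamA"), 990),
    drow("S1", "trnL_gh", plant_lin("GenB", family = "FamB"), 10))
  expect_equal(nrow(rra_threshold_filter(boundary, 1)$retained), 2L)

  single <- make_detections(drow("S1", "trnL_gh", plant_lin("GenA"), 3))
  expect_equal(nrow(rra_threshold_filter(single, 1)$retained), 1L)
})

test_that("rank inclusion keeps genus and below, configurable", {
  recs <- make_detections(
    drow("S1", "COI_ZBJ", animal_lin(), 100),                  # family
    drow("S1", "trnL_gh", plant_lin("Solanum"), 50),           # genus
    drow("S1", "trnL_gh", plant_lin("Solanum", "Solanum dulcamara"), 60))
  kept <- rank_inclusion_filter(recs)
  expect_equal(nrow(kept), 2L)
  expect_false(any(is.na(kept$genus)))   # the family-only entry is gone
  expect_equal(nrow(rank_inclusion_filter(recs, "family")), 3L)
  expect_equal(nrow(rank_inclusion_filter(recs, "species")), 1L)
})

test_that("every rule partitions its input exactly and is idempotent", {
  for (seed in c(1, 7, 23)) {
    recs <- random_detections(seed)
    nc <- make_detections(
      drow("NC1", "trnL_gh", plant_lin("Triticum", family = "Poaceae",
                                       order = "Poales"), 10))
    rules <- list(
      function(x) remove_self_host(x, host),
      function(x) negative_control_filter(x, nc),
      remove_singletons,
      function(x) rra_threshold_filter(x, 1))
    for (rule in rules) {
      res <- rule(recs)
      # conservation: retained + removed partition input (counts and reads)
      expect_equal(nrow(res$retained) + res$report$records_removed, nrow(recs))
      expect_equal(sum(res$retained$reads) + res$report$reads_removed,
                   sum(recs$reads))
      expect_equal(res$report$records_removed,
                   sum(res$report$per_sample$records_removed))
      # idempotence
      twice <- rule(res$retained)
      expect_equal(twice$retained, res$retained)
      expect_equal(twice$report$records_removed, 0L)
    }
  }
})
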