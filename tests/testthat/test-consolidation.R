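test_that("a genus merges into its unique species across markers", {
  recs <- make_detections(
    drow("S1", "trnL_gh", plant_lin("Persicaria", family = "Polygonaceae",
                                    order = "Caryophyllales"), 100),
    drow("S1", "ITS2_u34", plant_lin("Persicaria", "Persicaria lapathifolia",
                                     family = "Polygonaceae",
                                     order = "Caryophyllales"), 50))
  out <- consolidate_sample(recs)
  expect_equal(nrow(out), 1L)
  expect_equal(out$resolution, "species")
  expect_equal(out$species, "Persicaria lapathifolia")
  expect_equal(out$total_reads, 150L)
  expect_equal(out$source_markers, "ITS2_u34,trnL_gh")
})

test_that("an ambiguous parent (two non-nested children) is retained", {
  pteris <- function(sp = NA) plant_lin("Pteris", sp, family = "Pteridaceae",
                                        order = "Polypodiales",
                                        class = "Polypodiopsida")
  recs <- make_detections(
    drow("S1", "trnL_gh", pteris(), 30),
    drow("S1", "ITS2_u34", pteris("Pteris cretica"), 20),
    drow("S1", "ITS2_u34", pteris("Pteris vittata"), 10))
  out <- consolidate_sample(recs)
  expect_equal(nrow(out), 3L)   # both species plus the genus entry
  expect_setequal(out$species[!is.na(out$species)],
                  c("Pteris cretica", "Pteris vittata"))
  expect_equal(out$total_reads[is.na(out$species)], 30L)

  # oracle: brute-force prefix relations on the 3-lineage fixture
  keys <- lineage_key(recs)
  n_children <- vapply(keys, function(a) {
    sum(vapply(keys, function(b) a != b && startsWith(b, paste0(a, "|")),
               logical(1)))
  }, integer(1))
  expect_equal(unname(n_children), c(2L, 0L, 0L))  # genus is ambiguous
})

test_that("identical lineages from both markers collapse to one entry", {
  recs <- make_detections(
    drow("S1", "trnL_gh", plant_lin("Solanum", "Solanum dulcamara"), 700),
    drow("S1", "ITS2_u34", plant_lin("Solanum", "Solanum dulcamara"), 300))
  out <- consolidate_sample(recs)
  expect_equal(nrow(out), 1L)
  expect_equal(out$total_reads, 1000L)
})

test_that("merging never crosses target groups and chains merge upward", {
  # plant/metazoan never merge even with a (contrived) shared label
  recs <- make_detections(
    drow("S1", "trnL_gh", plant_lin("Solanum"), 10),
    drow("S1", "COI_ZBJ", animal_lin("Bradysia", family = "Sciaridae",
                                     order = "Diptera"), 10))
  expect_equal(nrow(consolidate_sample(recs)), 2L)

  # family -> genus -> species chain collapses into the species leaf
  chain <- make_detections(
    drow("S1", "trnL_gh", plant_lin(), 5),
    drow("S1", "ITS2_u34", plant_lin("Solanum"), 7),
    drow("S1", "trnL_gh", plant_lin("Solanum", "Solanum dulcamara"), 9))
  out <- consolidate_sample(chain)
  expect_equal(nrow(out), 1L)
  expect_equal(out$total_reads, 21L)
})

test_that("consolidation is idempotent, conservative and order-independent", {
  for (seed in c(3, 11, 42)) {
    recs <- random_detections(seed)
    out <- consolidate_sample(recs[recs$sample_id == "P01", , drop = FALSE])
    sub <- recs[recs$sample_id == "P01", , drop = FALSE]

    # read conservation per target group
    for (g in unique(sub$target_group)) {
      expect_equal(sum(out$total_reads[out$target_group == g]),
                   sum(sub$reads[sub$target_group == g]))
    }
    # uniqueness invariant: no lineage is a strict prefix of exactly one other
    for (g in unique(out$target_group)) {
      keys <- lineage_key(out[out$target_group == g, , drop = FALSE])
      for (a in keys) {
        n_ext <- sum(startsWith(setdiff(keys, a), paste0(a, "|")))
        expect_true(n_ext == 0L || n_ext >= 2L)
      }
    }
    # resolution monotonicity: every input is a prefix of (or equal to) some
    # output, or is itself an output
    in_keys <- lineage_key(sub)
    out_keys <- lineage_key(out)
    for (k in in_keys) {
      expect_true(k %in% out_keys ||
                    any(startsWith(out_keys, paste0(k, "|"))))
    }
    # order independence
    perm <- sub[sample(nrow(sub)), , drop = FALSE]
    out2 <- consolidate_sample(perm)
    expect_equal(out2, out)
    # idempotence: re-consolidating the consolidated lineage set is a no-op
    again <- out
    again$marker <- "trnL_gh"
    again$reads <- again$total_reads
    out3 <- consolidate_sample(
      suppressWarnings(as_detections(
        again[, c("sample_id", "marker", taxon_ranks(), "reads")])))
    expect_setequal(lineage_key(out3), out_keys)
  }
})

test_that("consolidate_all validates samples and attaches annotations", {
  recs <- make_detections(
    drow("S1", "trnL_gh", plant_lin("Fragaria", "Fragaria x ananassa",
                                    family = "Rosaceae", order = "Rosales"),
         10),
    drow("S2", "COI_ZBJ", animal_lin("Orius", "Orius insidiosus",
                                     family = "Anthocoridae"), 20))
  md <- make_field_metadata(c("S1", "S2"))
  out <- consolidate_all(recs, md, default_annotations())
  expect_equal(nrow(out), 2L)
  expect_equal(out$functional_group[out$sample_id == "S1"], "target crop")
  expect_equal(out$functional_group[out$sample_id == "S2"], "zoophagous")
  expect_setequal(unique(out$sample_id), c("S1", "S2"))  # partition by sample

  expect_error(consolidate_all(recs, md[1, , drop = FALSE], NULL),
               "absent from metadata")
  expect_equal(nrow(consolidate_all(recs[0, ], md)), 0L)
  expect_error(consolidate_sample(recs), "single sample")
})
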