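test_that("RRA vectors are correct and sum to 100", {
  recs <- make_detections(
    drow("S1", "trnL_gh", plant_lin("GenA", family = "FamA"), 900),
    drow("S1", "trnL_gh", plant_lin("GenB", family = "FamB"), 95),
    drow("S1", "trnL_gh", plant_lin("GenC", family = "FamC"), 5))
  out <- compute_rra(recs)
  expect_equal(out$rra, c(90, 9.5, 0.5))

  single <- make_detections(drow("S1", "trnL_gh", plant_lin("GenA"), 7))
  expect_equal(compute_rra(single)$rra, 100)

  # brute-force oracle on a random fixture + sum invariant
  for (seed in c(2, 9)) {
    recs <- random_detections(seed)
    out <- compute_rra(recs)
    grp <- paste(out$sample_id, out$target_group)
    for (g in unique(grp)) {
      sub <- out[grp == g, ]
      expect_equal(sub$rra, 100 * sub$reads / sum(sub$reads))
      expect_equal(sum(sub$rra), 100, tolerance = 1e-9)
    }
  }
})

test_that("FOO counts occurrences over a stated denominator", {
  cohort <- sprintf("S%03d", 1:70)
  sol <- plant_lin("Solanum")
  rows <- lapply(cohort[1:35], function(s) drow(s, "trnL_gh", sol, 10))
  rows <- c(rows, list(drow("S001", "trnL_gh",
                            plant_lin("Ambrosia", family = "Asteraceae",
                                      order = "Asterales"), 10)))
  cons <- consolidate_all(do.call(make_detections, rows),
                          make_field_metadata(cohort))
  foo <- compute_foo(cons, cohort)
  expect_equal(foo$foo[foo$taxon == "Solanum"], 50)          # 35 of 70
  expect_equal(foo$foo[foo$taxon == "Ambrosia"], 100 / 70)
  expect_false("absent" %in% foo$taxon)                       # 0% absent

  # taxon in every sample -> 100%
  all_rows <- lapply(cohort, function(s) drow(s, "trnL_gh", sol, 10))
  cons2 <- consolidate_all(do.call(make_detections, all_rows),
                           make_field_metadata(cohort))
  expect_equal(compute_foo(cons2, cohort)$foo, 100)
  expect_error(compute_foo(cons, character(0)), "empty denominator")
})

test_that("genus roll-up counts a genus and its species once per sample", {
  recs <- make_detections(
    drow("S1", "trnL_gh", plant_lin("Solanum"), 10),
    drow("S2", "trnL_gh", plant_lin("Solanum", "Solanum dulcamara"), 10),
    drow("S2", "ITS2_u34", plant_lin("Solanum", "Solanum nigrum"), 10))
  cons <- consolidate_all(recs, make_field_metadata(c("S1", "S2")))
  foo <- compute_foo(cons, c("S1", "S2"), level = "genus")
  expect_equal(nrow(foo), 1L)
  expect_equal(foo$foo, 100)   # genus in both samples, counted once each
})

test_that("richness and Shannon diversity use natural log", {
  expect_equal(shannon_richness(1)[c("richness", "shannon")],
               list(richness = 1L, shannon = 0))
  two <- shannon_richness(c(1, 1))
  expect_equal(two$richness, 2L)
  expect_equal(two$shannon, log(2))
  expect_equal(round(two$shannon, 2), 0.69)
  # direct formula evaluation for {2,1,1}
  expect_equal(shannon_richness(c(2, 1, 1))$shannon,
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)))
  expect_equal(round(shannon_richness(c(2, 1, 1))$shannon, 4), 1.0397)
  # equal counts -> H = ln R
  expect_equal(shannon_richness(rep(3, 7))$shannon, log(7))
  zero <- shannon_richness(c(0, 0))
  expect_equal(zero$richness, 0L)
  expect_false(zero$defined)
})

test_that("diet states follow the plant/metazoan detection rule", {
  recs <- make_detections(
    drow("S1", "trnL_gh", plant_lin("Solanum"), 10),
    drow("S2", "trnL_gh", plant_lin("Solanum"), 10),
    drow("S2", "COI_ZBJ", animal_lin("Bradysia", family = "Sciaridae",
                                     order = "Diptera"), 10),
    drow("S3", "COI_ZBJ", animal_lin("Bradysia", family = "Sciaridae",
                                     order = "Diptera"), 10))
  md <- make_field_metadata(c("S1", "S2", "S3", "S4"))
  states <- classify_diet_state(consolidate_all(recs, md), md)
  expect_equal(states$state,
               c("phytophagous", "omnivorous", "zoophagous", "undetected"))
  expect_equal(states$s, c(1, 0.5, 0, NA))
})

test_that("period summaries pool occurrences per (year, month)", {
  # 10 individuals: 9 plant-only, 1 with both
  ids <- sprintf("S%02d", 1:10)
  sol <- plant_lin("Solanum")
  rows <- lapply(ids, function(s) drow(s, "trnL_gh", sol, 10))
  rows <- c(rows, list(drow("S10", "COI_ZBJ",
                            animal_lin("Bradysia", family = "Sciaridae",
                                       order = "Diptera"), 10)))
  md <- make_field_metadata(ids, sex = rep(c("F", "M"), 5))
  cons <- consolidate_all(do.call(make_detections, rows), md)
  states <- classify_diet_state(cons, md)
  ps <- summarize_periods(cons, states, md)
  plant <- ps[ps$target_group == "plant", ]
  met <- ps[ps$target_group == "metazoan", ]
  expect_equal(plant$pct_fed, 100)
  expect_equal(plant$pct_strict, 90)
  expect_equal(met$pct_fed, 10)
  expect_equal(met$pct_strict, 0)
  # consistency: pct_strict(plant) + % omnivorous among plant-fed = 100
  pct_omni_fed <- 100 * sum(states$state == "omnivorous") /
    sum(states$n_plant > 0)
  expect_equal(plant$pct_strict + pct_omni_fed, 100)

  # hand-computed 5-individual oracle: taxa A in 3, B in 2, C in 1
  ids5 <- sprintf("Q%02d", 1:5)
  a <- plant_lin("GenA", family = "FamA"); b <- plant_lin("GenB", family = "FamB")
  cc <- plant_lin("GenC", family = "FamC")
  rows5 <- c(lapply(ids5[1:3], function(s) drow(s, "trnL_gh", a, 10)),
             lapply(ids5[1:2], function(s) drow(s, "ITS2_u34", b, 10)),
             list(drow(ids5[5], "trnL_gh", cc, 10)))
  md5 <- make_field_metadata(ids5)
  cons5 <- consolidate_all(do.call(make_detections, rows5), md5)
  st5 <- classify_diet_state(cons5, md5)
  ps5 <- summarize_periods(cons5, st5, md5)
  plant5 <- ps5[ps5$target_group == "plant", ]
  expect_equal(plant5$freq, 6)          # 3 + 2 + 1 occurrences
  expect_equal(plant5$richness, 3L)
  expect_equal(plant5$shannon,
               -sum(c(3, 2, 1) / 6 * log(c(3, 2, 1) / 6)))
  expect_equal(plant5$pct_fed, 80)      # 4 of 5 individuals

  # all-undetected period
  md0 <- make_field_metadata("Z01")
  cons0 <- consolidate_all(
    make_detections(drow("Z01", "trnL_gh", plant_lin("GenA"), 5))[0, ], md0)
  st0 <- classify_diet_state(cons0, md0)
  ps0 <- summarize_periods(cons0, st0, md0)
  expect_equal(ps0$pct_fed, c(0, 0))
})

test_that("rank-resolution summary profiles unique taxa and occurrences", {
  taxa <- reference_metazoan_taxa()
  rr <- rank_resolution_summary(taxa)
  expect_equal(round(rr$pct_taxa[rr$rank == "species"], 2), 35.71)
  expect_equal(round(rr$pct_taxa[rr$rank == "genus"], 2), 50.00)
  expect_equal(round(rr$pct_taxa[rr$rank == "family"], 2), 7.14)
  expect_equal(sum(rr$pct_taxa), 100)

  all_sp <- make_detections(
    drow("S1", "trnL_gh", plant_lin("Solanum", "Solanum dulcamara"), 5))
  rr2 <- rank_resolution_summary(all_sp)
  expect_equal(rr2$pct_taxa[rr2$rank == "species"], 100)

  mix <- rbind(plant_lin("Solanum", "Solanum dulcamara"),
               plant_lin("Ambrosia"))
  rr3 <- rank_resolution_summary(mix)
  expect_equal(rr3$pct_taxa[rr3$rank %in% c("species", "genus")], c(50, 50))
})

test_that("co-occurrence is per focal occurrence and asymmetric", {
  sol <- plant_lin("Solanum"); amb <- plant_lin("Ambrosia",
                                                family = "Asteraceae",
                                                order = "Asterales")
  pte <- plant_lin("Pteris", family = "Pteridaceae", order = "Polypodiales",
                   class = "Polypodiopsida")
  rows <- c(lapply(sprintf("S%d", 1:4), function(s) drow(s, "trnL_gh", sol, 5)),
            lapply(sprintf("S%d", 1:4), function(s) drow(s, "ITS2_u34", amb, 5)),
            list(drow("S1", "trnL_gh", pte, 5)))
  md <- make_field_metadata(sprintf("S%d", 1:4))
  cons <- consolidate_all(do.call(make_detections, rows), md)
  co <- co_occurrence(cons, "Solanum")
  expect_equal(co$pct_cooccurrence[co$partner == "Ambrosia"], 100)
  expect_equal(co$pct_cooccurrence[co$partner == "Pteris"], 25)
  # asymmetry: Pteris' view of Solanum is 100%
  co2 <- co_occurrence(cons, "Pteris")
  expect_equal(co2$pct_cooccurrence[co2$partner == "Solanum"], 100)
  expect_error(co_occurrence(cons, "Missing"), "not present")

  # brute-force pairwise oracle on a 3-sample fixture
  cons3 <- cons[cons$sample_id %in% c("S1", "S2", "S3"), ]
  for (focal in unique(deepest_label(cons3))) {
    res <- co_occurrence(cons3, focal)
    f_samp <- unique(cons3$sample_id[deepest_label(cons3) == focal])
    for (j in seq_len(nrow(res))) {
      p_samp <- unique(cons3$sample_id[deepest_label(cons3) == res$partner[j]])
      expect_equal(res$pct_cooccurrence[j],
                   100 * length(intersect(f_samp, p_samp)) / length(f_samp))
    }
  }
})

test_that("Hellinger + Bray-Curtis behave as stated", {
  m <- rbind(a = c(1, 2, 3, 0), b = c(1, 2, 3, 0), c = c(0, 0, 0, 4))
  hb <- hellinger_bray_curtis(m)
  expect_equal(hb$dissimilarity["a", "b"], 0)       # identical rows
  expect_equal(hb$dissimilarity["a", "c"], 1)       # disjoint rows
  expect_true(isSymmetric(hb$dissimilarity))
  expect_equal(unname(diag(hb$dissimilarity)), rep(0, 3))
  expect_true(all(hb$dissimilarity >= 0 & hb$dissimilarity <= 1))

  # 3x4 fixture vs brute-force double loop
  set.seed(5)
  m2 <- matrix(rpois(12, 5), nrow = 3, dimnames = list(letters[1:3], NULL))
  h <- hellinger_transform(m2)
  expect_equal(h, sqrt(m2 / rowSums(m2)), ignore_attr = TRUE)
  d <- bray_curtis(h)
  for (i in 1:3) for (j in 1:3) {
    expect_equal(d[i, j], sum(abs(h[i, ] - h[j, ])) / sum(h[i, ] + h[j, ]))
  }

  # zero-sum row flagged, produces a warning in BC
  m3 <- rbind(a = c(0, 0), b = c(0, 0), c = c(1, 1))
  h3 <- hellinger_transform(m3)
  expect_setequal(attr(h3, "zero_rows"), c("a", "b"))
  expect_warning(bray_curtis(h3), "zero-sum")
})
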