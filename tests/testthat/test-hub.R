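test_that("every catalog code survives a parse/compose round trip", {
  codes <- hub_catalog()
  expect_length(codes, 84)
  for (code in codes) {
    expect_identical(compose_hub_string(parse_hub(code)), code)
  }
  # structured fields of representative codes
  p <- parse_hub("AA.J1E1")
  expect_equal(p[[1]]$zone, "AA")
  expect_equal(p[[1]]$substrate, "J")
  expect_equal(p[[1]]$level4, "1")
  expect_equal(p[[1]]$level56, "E1")
  expect_false(p[[1]]$uncertain)
  u <- parse_hub("AA.G+AA.J1E1")
  expect_length(unclass(u), 2)
  expect_equal(u[[1]]$substrate, "G")
  q <- parse_hub("AA.I1E1?")
  expect_true(q[[1]]$uncertain)
  w <- parse_hub("AA.?3L9")
  expect_equal(w[[1]]$substrate, "?")
  expect_equal(w[[1]]$level56, "L9")
})

test_that("malformed codes are rejected with the grammar constraints", {
  expect_error(parse_hub("AC.J3"), "malformed")
  expect_error(parse_hub("AA.X3"), "malformed")
  expect_error(parse_hub("AA.JE1"), "level 4")
  expect_error(parse_hub("AA.J3T"), "requires level 4 = 2")
  expect_error(parse_hub("AA.J2U"), "requires level 4 = 4")
})

test_that("compose_hub completes tokens with zone and substrate", {
  expect_equal(compose_hub(TRUE, "sand", "1E1"), "AA.J1E1")
  expect_equal(compose_hub(FALSE, "mud", "3L3"), "AB.H3L3")
  expect_equal(compose_hub(TRUE, "mixed_sediment_hard", ""), "AA.M")
  expect_equal(compose_hub(TRUE, "peat", ""), "AA.G")
  expect_equal(compose_hub(TRUE, "coarse_sediment", "1E1",
                           uncertain = TRUE), "AA.I1E1?")
  expect_equal(compose_hub(c(TRUE, FALSE), c("sand", "sand"), "3L9"),
               c("AA.J3L9", "AB.J3L9"))
  expect_error(compose_hub(TRUE, "rock_biogenic_reef", "1E1"), "peat")
})

test_that("endobenthic dominance uses a strict 50% biomass share", {
  expect_equal(dominant_endobenthos(c(A = 60, B = 40)), "A")
  expect_true(is.na(dominant_endobenthos(c(A = 50, B = 50))))
  expect_equal(dominant_endobenthos(c(A = 0.1)), "A")
  expect_equal(dominant_endobenthos(c(A = 0, B = 0)), "empty")
  expect_error(dominant_endobenthos(c(A = -1, B = 2)), "non-negative")
})

test_that("endobenthic dominance equals a brute-force scan (fuzz)", {
  brute <- function(b) {
    tot <- sum(b)
    winners <- names(b)[b / tot > 0.5]
    if (length(winners) == 1) winners else NA_character_
  }
  set.seed(99)
  for (i in 1:1000) {
    k <- sample(1:6, 1)
    b <- stats::setNames(round(stats::rexp(k), 3) + 1e-6,
                         paste0("t", seq_len(k)))
    expect_identical(dominant_endobenthos(b), brute(b))
  }
})

test_that("epibenthic dominance uses the 10% total / 90% on-hard criteria", {
  expect_equal(dominant_epibenthos(c(A = 12)), "A")
  expect_equal(dominant_epibenthos(c(A = 9), hard_cover_pct = 9), "A")
  # 9 % of total on 9 % hard cover = 100 % of hard substrate
  expect_true(is.na(dominant_epibenthos(c(A = 5), hard_cover_pct = 10)))
  # explicit on-hard covers
  expect_equal(dominant_epibenthos(c(A = 5), cover_hard = c(A = 95)), "A")
  expect_true(is.na(dominant_epibenthos(c(A = 5), cover_hard = c(A = 50))))
  # hard criterion skipped when no hard substrate present
  expect_true(is.na(dominant_epibenthos(c(A = 9), hard_cover_pct = 0)))
  # largest cover wins among qualifiers; ties fall to precedence
  expect_equal(dominant_epibenthos(c(A = 20, B = 30)), "B")
  expect_equal(dominant_epibenthos(c(A = 20, B = 20),
                                   precedence = c("B", "A")), "B")
  expect_error(dominant_epibenthos(c(A = 120)), "0, 100")
})

test_that("ACFOR midpoints are fixed and monotone", {
  expect_equal(acfor_to_cover(c("A", "C", "F", "O", "R")),
               c(75, 35, 15, 5, 1))
  expect_true(all(diff(acfor_to_cover(c("R", "O", "F", "C", "A"))) > 0))
  expect_error(acfor_to_cover("B"), "valid letters")
})

test_that("conventions merge, collapse and exclude as configured", {
  labels <- data.frame(
    station_id = sprintf("s%03d", 1:200),
    label = c(rep("3L9", 120), rep("3L3", 40), rep("Mya arenaria", 20),
              rep("Ophelia spp.", 10), rep("foliose red algae/sponges", 8),
              rep("Actiniaria", 2)))
  out <- apply_conventions(labels)
  expect_equal(unique(out$harmonized_label[out$label == "Mya arenaria"]),
               "3L9")
  expect_true(all(out$excluded[out$label == "Ophelia spp."]))
  expect_equal(unique(out$reason[out$label == "Ophelia spp."]),
               "unpredictable_dominant")
  # 2 of 200 stations = 1 % -> at the rare threshold, excluded
  expect_true(all(out$excluded[out$label == "Actiniaria"]))
  expect_equal(unique(out$reason[out$label == "Actiniaria"]),
               "rare_dominant")
  expect_equal(
    unique(out$harmonized_label[out$label == "foliose red algae/sponges"]),
    "foliose red algae")
  expect_false(any(out$excluded[out$label == "3L9"]))
})

test_that("a dominant at 0.8% of 1000 stations is excluded", {
  labels <- data.frame(station_id = sprintf("s%04d", 1:1000),
                       label = c(rep("3L9", 992), rep("oddball", 8)))
  out <- apply_conventions(labels)
  expect_true(all(out$excluded[out$label == "oddball"]))
  expect_false(any(out$excluded[out$label == "3L9"]))
})

test_that("apply_conventions is idempotent", {
  set.seed(7)
  labels <- data.frame(
    station_id = sprintf("s%03d", 1:300),
    label = sample(c("3L9", "3L3", "3L1", "Mya arenaria", "Ophelia spp.",
                     "rare1", "foliose red algae/sponges"),
                   300, TRUE, prob = c(30, 25, 25, 10, 5, 1, 4)))
  once <- apply_conventions(labels)
  twice <- apply_conventions(once)
  expect_identical(once, twice)
})

test_that("assign_hub_labels recovers tokens from raw station records", {
  stations <- data.frame(
    station_id = c("g1", "g2", "g3", "v1", "v2"),
    method = c("grab", "grab", "grab", "video", "video"),
    hard_cover_pct = c(NA, NA, NA, 60, 60))
  records <- rbind(
    data.frame(station_id = "g1", taxon = c("Arctica islandica", "x"),
               value = c(80, 20)),
    data.frame(station_id = "g2", taxon = c("a", "b", "c"),
               value = c(40, 35, 25)),
    data.frame(station_id = "g3", taxon = c("Mya arenaria", "x"),
               value = c(70, 30)),
    data.frame(station_id = "v1", taxon = c("Mytilus edulis", "y"),
               value = c(45, 3)),
    data.frame(station_id = "v2", taxon = c("y", "z"), value = c(4, 3)))
  out <- assign_hub_labels(stations, records, conventions = NULL)
  expect_equal(out$raw_label,
               c("3L3", "3", "3L4", "1E1", "2T"))
  harm <- assign_hub_labels(stations, records)
  expect_equal(harm$harmonized_label[harm$station_id == "g3"], "3L9")
})
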