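test_that("majority rasterization keeps the largest share, harder wins ties", {
  fine <- matrix("sand", 4, 4)
  fine[1:2, 1:2] <- "mud"          # 4 of 16 cells
  out <- rasterize_majority(fine, factor = 4)
  expect_equal(out[1, 1], "sand")  # 12 sand vs 4 mud
  tie <- matrix(c("sand", "sand", "mixed_sediment_hard",
                  "mixed_sediment_hard"), 2, 2)
  expect_equal(rasterize_majority(tie, 2)[1, 1], "mixed_sediment_hard")
  # identity at factor 1, and single-class maps are unchanged
  single <- matrix("mud", 3, 3)
  expect_identical(rasterize_majority(single, 1), single)
  # NA handling: an all-NA block stays NA
  gap <- matrix(NA_character_, 2, 2)
  expect_true(is.na(rasterize_majority(gap, 2)[1, 1]))
  expect_error(rasterize_majority(matrix("a", 3, 3), 2), "multiples")
})

test_that("BHT composition maps photic to infralittoral and handles peat", {
  expect_equal(compose_bht(TRUE, "sand"), "Infralittoral sand")
  expect_equal(compose_bht(FALSE, "mud"), "Circalittoral mud")
  expect_equal(compose_bht(TRUE, "peat", peat_with_mussels = TRUE),
               "Infralittoral rock and biogenic reef")
  expect_equal(compose_bht(TRUE, "peat", peat_with_mussels = FALSE),
               "Infralittoral mixed sediment (hard substrate)")
  m <- compose_bht(matrix(c(TRUE, FALSE), 1, 2),
                   matrix("sand", 1, 2))
  expect_equal(as.vector(m), c("Infralittoral sand", "Circalittoral sand"))
})

test_that("patches below one hectare are merged, others retained", {
  # 50 m cells: 1 cell = 0.25 ha
  grid <- matrix("A", 10, 10)
  grid[1, 1:3] <- "B"  # 0.75 ha -> merged
  out <- eliminate_small_patches(grid, 50)
  expect_false(any(out == "B"))
  grid[1, 1:4] <- "B"  # 1.0 ha -> retained (not < 1 ha)
  out <- eliminate_small_patches(grid, 50)
  expect_equal(sum(out == "B"), 4)
  # at 1 km cells every patch is >= 100 ha
  big <- matrix("A", 5, 5)
  big[3, 3] <- "B"
  expect_identical(eliminate_small_patches(big, 1000), big)
  # conservation and closed label set
  set.seed(20)
  rnd <- matrix(sample(c("A", "B", "C"), 400, TRUE), 20, 20)
  out <- eliminate_small_patches(rnd, 50)
  expect_equal(length(out), length(rnd))
  expect_true(all(unique(as.vector(out)) %in% unique(as.vector(rnd))))
  # a patch with no labelled neighbour is left unchanged
  lonely <- matrix(NA_character_, 3, 3)
  lonely[2, 2] <- "B"
  expect_identical(eliminate_small_patches(lonely, 50), lonely)
})

test_that("endo/epi intersection follows hard-substrate dominance", {
  hard <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
  endo <- matrix("3L9", 2, 2)
  epi <- matrix(c("1E1", "1E1", NA, "1E1"), 2, 2)
  out <- intersect_endo_epi(hard, endo, epi)
  expect_equal(out[1, 1], "1E1")   # hard -> epi
  expect_equal(out[2, 1], "3L9")   # soft -> endo
  expect_true(is.na(out[1, 2]))    # hard without epi prediction -> NA
})

test_that("the HUB layer completes tokens with zone and substrate", {
  photic <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  substrate <- matrix(c("sand", "sand", "mixed_sediment_hard", NA), 2, 2)
  token <- matrix(c("3L9", NA, "2T", "3"), 2, 2)
  hl <- build_hub_layer(photic, substrate, token, 1000)
  expect_equal(hl$hub[1, 1], "AA.J3L9")
  expect_equal(hl$hub[2, 1], "AA.J")
  expect_equal(hl$hub[1, 2], "AB.M2T")
  expect_true(is.na(hl$hub[2, 2]))
  expect_equal(sum(hl$areas$km2), 3)  # 3 labelled cells of 1 km2
})

test_that("area summaries are exact and order-invariant", {
  layer <- matrix(c(rep("sand", 60), rep("mud", 40)), 10, 10)
  tab <- area_summary(layer, 1000)
  expect_equal(tab$km2[tab$class == "sand"], 60)
  expect_equal(tab$pct[tab$class == "sand"], 60)
  expect_equal(sum(tab$pct), 100)
  # permuting cells leaves the table unchanged
  set.seed(21)
  shuffled <- matrix(sample(layer), 10, 10)
  expect_identical(area_summary(shuffled, 1000), tab)
  expect_equal(nrow(area_summary(matrix(NA_character_, 2, 2), 1000)), 0)
})

test_that("polygon areas are exact (shoelace oracle)", {
  poly <- list(x = c(0, 200, 200, 0), y = c(0, 0, 100, 100))
  expect_equal(polygon_area(poly), 20000)
  set.seed(22)
  # random star-shaped polygon around a centre
  ang <- sort(runif(12, 0, 2 * pi))
  r <- runif(12, 50, 150)
  p <- list(x = 500 + r * cos(ang), y = 500 + r * sin(ang))
  expect_equal(polygon_area(p), oracle_polygon_area(p$x, p$y))
})

test_that("species-rich detection needs three qualifying stations", {
  sed <- matrix("S", 5, 5)
  sed[2:4, 2:4] <- "Csed"
  base <- data.frame(row = c(2, 3, 4), col = c(2, 3, 4),
                     single_indicator_pct = c(12, 12, 12),
                     combined_pct = c(12, 12, 12),
                     gravel_coarse_shell_pct = c(60, 70, 55))
  res <- detect_species_rich(base, sed)
  expect_true(res$candidate)
  expect_true(res$designated)
  # two stations only
  res2 <- detect_species_rich(base[1:2, ], sed)
  expect_false(res2$candidate)
  # combined share >= 5 qualifies even when no single taxon reaches 10
  comb <- transform(base, single_indicator_pct = c(4, 4, 4),
                    combined_pct = c(5, 6, 7))
  expect_true(detect_species_rich(comb, sed)$candidate)
  # candidate but not designated when substrate share is too low
  soft <- transform(base, gravel_coarse_shell_pct = c(30, 40, 45))
  res3 <- detect_species_rich(soft, sed)
  expect_true(res3$candidate)
  expect_false(res3$designated)
})

test_that("the OHT layer applies inclusion thresholds and reef precedence", {
  geom <- grid_geometry(0, 0, 5, 5, 1000)
  hub <- matrix(NA_character_, 5, 5)
  hub[1, 1:2] <- "AB.H3L3"
  hub[5, 5] <- "AA.J3L9"
  prob <- matrix(0, 5, 5)
  prob[2, 2] <- 55   # included (>= 50 %)
  prob[2, 3] <- 40   # excluded
  dens <- matrix(0, 5, 5)
  dens[3, 3] <- 12   # included (>= 10 / m2)
  dens[3, 4] <- 5    # excluded
  sed <- matrix("S", 5, 5)
  sed[4, 1:4] <- "Csed"
  stations <- data.frame(row = 4, col = 1:3,
                         single_indicator_pct = 12, combined_pct = 12)
  sr <- detect_species_rich(stations, sed)
  # reef polygon over the first species-rich cell (row 4 -> y [1000,2000))
  reef <- list(x = c(0, 1000, 1000, 0), y = c(1000, 1000, 2000, 2000))
  oht <- build_oht_layer(geom, hub, reef_polygons = list(reef),
                         seagrass_prob = prob, seagrass_density = dens,
                         species_rich = sr)
  expect_equal(sum(oht$masks$arctica_aphotic_mud), 2)
  expect_true(oht$masks$seagrass_macrophytes[2, 2])
  expect_false(oht$masks$seagrass_macrophytes[2, 3])
  expect_true(oht$masks$seagrass_macrophytes[3, 3])
  expect_false(oht$masks$seagrass_macrophytes[3, 4])
  # reef wins where it overlaps the species-rich candidate
  expect_false(oht$masks$species_rich_gravel[4, 1])
  expect_true(oht$masks$species_rich_gravel[4, 2])
  expect_false(any(oht$masks$species_rich_gravel & oht$reef_cells))
  # polygon areas are exact, not gridded
  expect_equal(oht$areas$km2[oht$areas$class == "reefs_1170"], 1)
})
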