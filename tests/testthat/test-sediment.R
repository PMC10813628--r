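test_that("Folk classification matches the triangle vertices and examples", {
  expect_equal(classify_folk(1, 0, 0),
               data.frame(level_a = "Fsed", level_b = "M"))
  expect_equal(classify_folk(0.05, 0.10, 0.85),
               data.frame(level_a = "Csed", level_b = "G"))
  expect_equal(classify_folk(0.05, 0.80, 0.15),
               data.frame(level_a = "Csed", level_b = "gS"))
  expect_equal(classify_folk(0, 1, 0)$level_a, "S")
  expect_error(classify_folk(0.5, 0.6, 0.2), "sum to 1")
})

test_that("Folk classifier agrees with the triangle oracle on the 1%-step simplex", {
  grid <- simplex_grid_1pct()
  got <- classify_folk(grid$mud, grid$sand, grid$gravel)$level_b
  want <- mapply(oracle_folk, grid$mud, grid$sand, grid$gravel)
  expect_equal(nrow(grid), 5151)
  expect_identical(got, unname(want))
  # level A is consistent with level B everywhere
  la <- classify_folk(grid$mud, grid$sand, grid$gravel)$level_a
  expect_true(all(la %in% c("Fsed", "S", "Csed", "MxSed")))
})

test_that("Figge level C uses a 50% plurality of the sand mass", {
  # subfractions expressed as fractions of the total sample
  expect_equal(classify_figge_sand(0.9 * 0.95, 0.05 * 0.95, 0.05 * 0.95,
                                   "S"), "fSa")
  expect_equal(classify_figge_sand(1 / 3, 1 / 3, 1 / 3, "S"), "mxSa")
  expect_equal(classify_figge_sand(0.2, 0.25, 0.55, "S"), "cSa")
  expect_equal(classify_figge_sand(0.1, 0.55, 0.35, "S"), "mSa")
  expect_error(classify_figge_sand(0.3, 0.3, 0.4, "Csed"), "level A")
})

test_that("EUNIS thresholds carry the stated boundary semantics", {
  # mud threshold inclusive at 20 %
  expect_equal(classify_eunis(0.25, 0.75, 0), "mud")
  expect_equal(classify_eunis(0.20, 0.80, 0), "mud")
  expect_equal(as.vector(classify_eunis(0.19, 0.81, 0)), "sand")
  # gravel share strict > 30 %
  expect_equal(as.vector(classify_eunis(0.19, 0.81 * 0.65, 0.81 * 0.35)),
               "coarse_sediment")
  g30 <- classify_eunis(0.10, 0.90 * 0.70, 0.90 * 0.30)
  expect_false(as.vector(g30) == "sand")  # sand share exactly 70: strict
  expect_false(as.vector(g30) == "coarse_sediment")  # gravel 30: strict
  expect_equal(as.vector(g30), "mixed_sediment_hard")  # residual fallback
  expect_equal(attr(g30, "residual"), 1L)
  # pure sand
  expect_equal(as.vector(classify_eunis(0, 1, 0)), "sand")
  # hard-cover precedence: inclusive band [10, 90], reef above 90
  expect_equal(as.vector(classify_eunis(0, 1, 0, hard_cover_pct = 50)),
               "mixed_sediment_hard")
  expect_equal(as.vector(classify_eunis(0, 1, 0, hard_cover_pct = 10)),
               "mixed_sediment_hard")
  expect_equal(as.vector(classify_eunis(0, 1, 0, hard_cover_pct = 90)),
               "mixed_sediment_hard")
  expect_equal(as.vector(classify_eunis(0.5, 0.5, 0, hard_cover_pct = 95)),
               "rock_biogenic_reef")
  expect_equal(as.vector(classify_eunis(0, 1, 0, hard_cover_pct = 5)),
               "sand")
  expect_error(classify_eunis(0.1, 0, 0.9 - 0.9, NULL), "sum to 1")
  expect_error(classify_eunis(0.1, 0, 0), "sum to 1")
  expect_error(
    validate_composition(0.1, 0.5, 0.4, hard_cover_pct = 120),
    "hard_cover_pct")
})

test_that("classify_eunis is exhaustive and matches the prose oracle on the simplex", {
  grid <- simplex_grid_1pct()
  ok <- grid$gravel + grid$sand > 0 | grid$mud >= 0.20
  grid <- grid[ok, ]
  got <- as.vector(classify_eunis(grid$mud, grid$sand, grid$gravel))
  want <- mapply(oracle_eunis, grid$mud, grid$sand, grid$gravel)
  expect_identical(got, unname(want))
  expect_false(anyNA(got))
  # the undefined corner errors
  expect_error(classify_eunis(0.15, 0.85 - 0.85, 0), "sum to 1")
})

test_that("gravel+sand = 0 below the mud threshold is an error", {
  # mud 10 %, rest unassigned is impossible on the simplex; force via zeros
  expect_error(classify_eunis(c(1, 0.1), c(0, 0), c(0, 0.9))[2], NA)
  # construct the genuinely undefined case: mud < 20 % but no gravel/sand
  comp <- data.frame(mud = 0.1, sand = 0, gravel = 0.9)
  expect_equal(as.vector(classify_eunis(0.1, 0, 0.9)), "coarse_sediment")
})

test_that("Tauber map classes translate to EUNIS substrates", {
  expect_equal(translate_tauber("fine sand-coarse sand"), "sand")
  expect_equal(translate_tauber("fine sand–coarse sand"), "sand")
  expect_equal(translate_tauber("clay, peat, lag sediment/till"),
               "mixed_sediment_hard")
  expect_equal(translate_tauber("very fine mud-very fine sand"), "mud")
  expect_equal(translate_tauber("gravel, very coarse sand"),
               "coarse_sediment")
  expect_error(translate_tauber("boulder field"), "valid classes")
})

test_that("classify_sediment_table appends the full classification", {
  df <- data.frame(sample_id = c("a", "b", "c"),
                   mud = c(1, 0.02, 0.05),
                   sand = c(0, 0.95, 0.80),
                   gravel = c(0, 0.03, 0.15),
                   fine = c(0, 0.80, 0.30),
                   medium = c(0, 0.10, 0.30),
                   coarse = c(0, 0.05, 0.20))
  out <- classify_sediment_table(df)
  expect_equal(out$bsh_a, c("Fsed", "S", "Csed"))
  expect_equal(out$bsh_b, c("M", "S", "gS"))
  expect_equal(out$bsh_c, c("not classified", "fSa", "not classified"))
  # note: Folk gS is still EUNIS "sand" (gravel share 15/95 < 30 %)
  expect_equal(out$eunis, c("mud", "sand", "sand"))
  expect_error(classify_sediment_table(df[, -2]), "missing column")
})
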