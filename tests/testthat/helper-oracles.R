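# Independent brute-force oracles, deliberately coded differently from the
# package implementations they check.

# Folk triangle oracle: table-driven region lookup over (gravel tier,
# sand:mud ratio band) in EXACT integer-percent arithmetic; fractions are
# rounded to whole percent first, so the oracle is immune to floating-point
# boundary noise (its inputs live on the 1 %-step grid).
oracle_folk <- function(mud, sand, gravel) {
  m <- round(100 * mud); s <- round(100 * sand); g <- round(100 * gravel)
  band <- function(s, m) {          # sand:mud ratio band, exact
    if (s >= 9 * m) 4L              # >= 9:1
    else if (s >= m) 3L             # >= 1:1
    else if (9 * s >= m) 2L         # >= 1:9
    else 1L
  }
  lookup <- rbind(
    c(tier = 4, band = 1, cls = "G"), c(4, 2, "G"), c(4, 3, "G"),
    c(4, 4, "G"),
    c(3, 1, "mG"), c(3, 2, "mG"), c(3, 3, "msG"), c(3, 4, "sG"),
    c(2, 1, "gM"), c(2, 2, "gM"), c(2, 3, "msG"), c(2, 4, "gS"),
    c(1, 1, "M"), c(1, 2, "sM"), c(1, 3, "mS"), c(1, 4, "S"))
  tier <- if (g >= 80) 4L else if (g >= 30) 3L else if (g >= 5) 2L else 1L
  b <- band(s, m)
  lookup[lookup[, 1] == tier & lookup[, 2] == b, 3]
}

# EUNIS oracle: literal transcription of the prose thresholds in exact
# integer-percent arithmetic (share comparisons as cross-multiplications).
oracle_eunis <- function(mud, sand, gravel, hard = NA) {
  if (!is.na(hard)) {
    if (hard > 90) return("rock_biogenic_reef")
    if (hard >= 10 && hard <= 90) return("mixed_sediment_hard")
  }
  m <- round(100 * mud); s <- round(100 * sand); g <- round(100 * gravel)
  if (m >= 20) return("mud")
  if (100 * g > 30 * (g + s)) return("coarse_sediment")
  if (100 * s > 70 * (g + s)) return("sand")
  "mixed_sediment_hard"  # boundary sliver: neither strict criterion met
}

# all mud/sand/gravel compositions on a 1 %-step simplex grid (5151 points)
simplex_grid_1pct <- function() {
  pts <- expand.grid(mud = 0:100, sand = 0:100)
  pts <- pts[pts$mud + pts$sand <= 100, ]
  pts$gravel <- 100 - pts$mud - pts$sand
  pts / 100
}

# hard-substrate rule oracle: exhaustive rule table
oracle_hard <- function(boulder_class, sediment) {
  tab <- expand.grid(cls = 1:3, lag = c(TRUE, FALSE))
  tab$hard <- c(FALSE, TRUE, TRUE,  # lag: class 1 no, 2 yes, 3 yes
                FALSE, FALSE, TRUE) # non-lag: only class 3
  tab$hard[tab$cls == boulder_class & tab$lag == (sediment == "LagSed")]
}

# independent shoelace: area from cross products of vertex vectors relative
# to the first vertex (triangle fan)
oracle_polygon_area <- function(x, y) {
  n <- length(x)
  if (x[1] == x[n] && y[1] == y[n]) {
    x <- x[-n]; y <- y[-n]; n <- n - 1
  }
  a <- 0
  for (i in 2:(n - 1)) {
    a <- a + ((x[i] - x[1]) * (y[i + 1] - y[1]) -
                (x[i + 1] - x[1]) * (y[i] - y[1])) / 2
  }
  abs(a)
}
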