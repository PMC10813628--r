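#' Seeded synthetic seascapes
#'
#' Generates gridded environmental predictor layers, a sediment map, a
#' boulder point field and ground-truth stations whose community labels
#' follow a known rule, so that every downstream stage (classification,
#' station labelling, model fitting, map composition) can be tested against
#' a recoverable truth. Environmental fields are linear gradients plus
#' seeded, spatially smoothed Gaussian noise; sediment patches come from a
#' thresholded smooth latent field; boulders follow a per-sediment-class
#' Poisson process; station biomass tables are Dirichlet draws around
#' rule-determined target shares and cover tables carry truncated-normal
#' noise. Identical configuration and seed give bit-identical outputs.
#'
#' @name seascape
NULL

#' Configuration for a synthetic seascape
#'
#' @param width,height extent in metres; must be exact multiples of
#'   `cell_size`.
#' @param cell_size cell edge length in metres (50 for detail areas, 1000
#'   for the overview grid).
#' @param seed integer random seed.
#' @param gradients per-layer list of `mean`, `range` (signed change along
#'   the axis), `axis` (`"we"` west->east or `"sn"` south->north),
#'   `noise_sd` and `smooth` (noise correlation length, cells).
#' @param sediment_classes,sediment_weights BSH level A class mixture of the
#'   sediment map.
#' @param patch_scale sediment patch correlation length (cells).
#' @param boulder_intensity named expected boulder count per cell and
#'   sediment class; lag sediment defaults to an elevated intensity.
#' @param n_grab,n_video station counts.
#' @param biomass_theta Dirichlet concentration of biomass noise (0 =
#'   noise-free target shares; larger = tighter around the target).
#' @param cover_sd truncated-normal standard deviation of cover noise
#'   (percentage points; 0 = noise-free).
#' @param photic_depth cells shallower than this are photic (m).
#' @return an object of class `seascape_config`.
#' @export
seascape_config <- function(width = 30000, height = 20000, cell_size = 1000,
                            seed = 1,
                            gradients = default_gradients(),
                            sediment_classes = c("Fsed", "S", "Csed",
                                                 "MxSed", "LagSed"),
                            sediment_weights = c(0.25, 0.40, 0.12, 0.13,
                                                 0.10),
                            patch_scale = 3,
                            boulder_intensity = c(Fsed = 0.02, S = 0.05,
                                                  Csed = 0.5, MxSed = 2,
                                                  LagSed = 6, Peat = 1),
                            n_grab = 400, n_video = 150,
                            biomass_theta = 200, cover_sd = 3,
                            photic_depth = 15) {
  if (width <= 0 || height <= 0 || cell_size <= 0) {
    stop("extent and cell size must be positive", call. = FALSE)
  }
  if (width %% cell_size != 0 || height %% cell_size != 0) {
    stop("cell size must divide the extent exactly", call. = FALSE)
  }
  bad <- setdiff(sediment_classes, bsh_level_a())
  if (length(bad)) {
    stop("unknown sediment class(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(length(sediment_weights) == length(sediment_classes),
            all(sediment_weights >= 0), sum(sediment_weights) > 0)
  structure(list(
    width = width, height = height, cell_size = cell_size, seed = seed,
    geom = grid_geometry(0, 0, height %/% cell_size, width %/% cell_size,
                         cell_size),
    gradients = gradients,
    sediment_classes = sediment_classes,
    sediment_weights = sediment_weights / sum(sediment_weights),
    patch_scale = patch_scale, boulder_intensity = boulder_intensity,
    n_grab = n_grab, n_video = n_video,
    biomass_theta = biomass_theta, cover_sd = cover_sd,
    photic_depth = photic_depth), class = "seascape_config")
}

#' Default environmental gradient parameters
#'
#' Magnitudes are plausible for the south-western Baltic (salinity falling
#' west to east across the Darss Sill from ~20 to ~8 PSU, depths to ~40 m,
#' near-bottom temperature around 8 degC); they are free parameters of the
#' generator, not estimates of any surveyed area.
#'
#' @return named list of per-layer gradient settings.
#' @export
default_gradients <- function() {
  list(
    depth          = list(mean = 22, range = 25, axis = "sn", noise_sd = 2,
                          smooth = 3),
    salinity       = list(mean = 14, range = -12, axis = "we",
                          noise_sd = 0.15, smooth = 3),
    temperature    = list(mean = 8, range = 2, axis = "we", noise_sd = 0.3,
                          smooth = 3),
    current_velocity = list(mean = 0.25, range = -0.15, axis = "sn",
                            noise_sd = 0.04, smooth = 2),
    shear_stress   = list(mean = 0.30, range = -0.18, axis = "sn",
                          noise_sd = 0.05, smooth = 2),
    par            = list(mean = 8, range = -6, axis = "sn", noise_sd = 0.8,
                          smooth = 3),
    oxygen         = list(mean = 6, range = 3, axis = "sn", noise_sd = 0.4,
                          smooth = 3),
    hypoxic_days   = list(mean = 12, range = 18, axis = "sn", noise_sd = 3,
                          smooth = 3),
    doc            = list(mean = 4.5, range = 2, axis = "we", noise_sd = 0.3,
                          smooth = 3),
    ammonium       = list(mean = 1.2, range = 0.6, axis = "we",
                          noise_sd = 0.15, smooth = 2),
    nitrate        = list(mean = 3.5, range = 1.5, axis = "we",
                          noise_sd = 0.3, smooth = 2),
    phosphate      = list(mean = 0.8, range = 0.3, axis = "we",
                          noise_sd = 0.08, smooth = 2)
  )
}

# smoothed standard-normal field, rescaled to unit sd after box smoothing
.smooth_noise <- function(nr, nc, smooth) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (smooth > 0) {
    for (rep in seq_len(smooth)) {
      zp <- rbind(z[1, , drop = FALSE], z, z[nr, , drop = FALSE])
      zp <- cbind(zp[, 1, drop = FALSE], zp, zp[, nc, drop = FALSE])
      z <- (zp[2:(nr + 1), 2:(nc + 1)] +
              zp[1:nr, 2:(nc + 1)] + zp[3:(nr + 2), 2:(nc + 1)] +
              zp[2:(nr + 1), 1:nc] + zp[2:(nr + 1), 3:(nc + 2)]) / 5
    }
    s <- stats::sd(z)
    if (s > 0) z <- z / s
  }
  z
}

#' Generate the environmental predictor stack
#'
#' One matrix per predictor (row 1 = north). Each layer is a linear gradient
#' along its axis plus smoothed noise; depth is clamped at 0 and a slope
#' layer (local depth gradient magnitude, m per cell) is derived from it.
#' Salinity decreases monotonically west to east under the default
#' (negative-range) configuration.
#'
#' @param config a [seascape_config()].
#' @return list with `geom` and `layers` (named list of matrices, including
#'   derived `slope`), plus logical `photic` matrix.
#' @export
generate_environment <- function(config) {
  stopifnot(inherits(config, "seascape_config"))
  set.seed(config$seed)
  g <- config$geom
  nr <- g$nrow
  nc <- g$ncol
  col_t <- if (nc > 1) (seq_len(nc) - 1) / (nc - 1) else rep(0.5, 1)
  row_t <- if (nr > 1) (nr - seq_len(nr)) / (nr - 1) else rep(0.5, 1)
  layers <- lapply(config$gradients, function(p) {
    base <- if (p$axis == "we") {
      matrix(p$mean + p$range * (col_t - 0.5), nr, nc, byrow = TRUE)
    } else {
      matrix(p$mean + p$range * (row_t - 0.5), nr, nc)
    }
    if (p$noise_sd > 0) {
      base <- base + p$noise_sd * .smooth_noise(nr, nc, p$smooth)
    }
    base
  })
  layers$depth <- pmax(layers$depth, 0)
  layers$hypoxic_days <- pmax(layers$hypoxic_days, 0)
  layers$current_velocity <- pmax(layers$current_velocity, 0)
  layers$shear_stress <- pmax(layers$shear_stress, 0)
  layers$slope <- .slope_from_depth(layers$depth)
  photic <- layers$depth < config$photic_depth
  list(geom = g, layers = layers, photic = photic)
}

# central-difference gradient magnitude, per cell spacing
.slope_from_depth <- function(depth) {
  nr <- nrow(depth)
  nc <- ncol(depth)
  dx <- (depth[, c(2:nc, nc)] - depth[, c(1, 1:(nc - 1))]) / 2
  dy <- (depth[c(2:nr, nr), ] - depth[c(1, 1:(nr - 1)), ]) / 2
  sqrt(dx^2 + dy^2)
}

#' Generate the sediment map and boulder point field
#'
#' Sediment classes are assigned by quantile-binning a smooth latent field,
#' so requested class weights are met exactly (up to cell rounding) and
#' patches are spatially contiguous. Boulder counts per cell are Poisson
#' with a per-class intensity (elevated on lag sediment) and points are
#' placed uniformly within their cell.
#'
#' @param config a [seascape_config()].
#' @return list with `sediment` (character matrix of BSH level A classes)
#'   and `boulders` (data.frame `x`, `y`).
#' @export
generate_sediment_and_boulders <- function(config) {
  stopifnot(inherits(config, "seascape_config"))
  set.seed(config$seed + 1L)
  g <- config$geom
  nr <- g$nrow
  nc <- g$ncol
  latent <- .smooth_noise(nr, nc, config$patch_scale)
  q <- stats::quantile(latent, cumsum(config$sediment_weights),
                       names = FALSE)
  q[length(q)] <- Inf
  idx <- matrix(findInterval(latent, c(-Inf, q[-length(q)])), nr, nc)
  sediment <- matrix(config$sediment_classes[idx], nr, nc)

  lam <- config$boulder_intensity[sediment]
  lam[is.na(lam)] <- 0
  counts <- stats::rpois(nr * nc, lam)
  cell_row <- rep(seq_len(nr), times = nc)
  cell_col <- rep(seq_len(nc), each = nr)
  total <- sum(counts)
  if (total > 0) {
    rows <- rep(cell_row, counts)
    cols <- rep(cell_col, counts)
    c0 <- g$cell_size
    x <- g$xmin + (cols - 1) * c0 + stats::runif(total) * c0
    y <- g$ymin + (g$nrow - rows) * c0 + stats::runif(total) * c0
    boulders <- data.frame(x = x, y = y)
  } else {
    boulders <- data.frame(x = numeric(0), y = numeric(0))
  }
  list(sediment = sediment, boulders = boulders)
}

#' Community-generating rules
#'
#' A community rule maps per-cell conditions to a probability distribution
#' over HUB level 4-6 community tokens, one rule per realm. The default
#' rules are deterministic (one label per condition) and driven by sediment,
#' salinity and depth (endobenthos) and by depth and salinity (epibenthos),
#' echoing the large-scale drivers of Baltic benthic communities.
#'
#' @param endo,epi functions of `(sediment, salinity, depth, doc, hard)`
#'   returning a named probability vector over community tokens (probabilities
#'   summing to 1), or NULL for a condition the rule does not cover.
#' @param generating_vars named list (`endo`, `epi`) of predictor names that
#'   drive each rule (used by recovery tests).
#' @return object of class `community_rule`.
#' @export
community_rule <- function(endo, epi, generating_vars) {
  structure(list(endo = endo, epi = epi,
                 generating_vars = generating_vars),
            class = "community_rule")
}

#' @rdname community_rule
#' @export
default_community_rule <- function() {
  endo <- function(sediment, salinity, depth, doc, hard) {
    lab <- switch(sediment,
      Fsed = if (depth > 25) "3L3" else "3L1",
      S = if (salinity > 12) "3L9" else "3",
      Csed = "3L10",
      MxSed = , LagSed = , Peat = "1E1",
      NULL)
    if (is.null(lab)) return(NULL)
    stats::setNames(1, lab)
  }
  epi <- function(sediment, salinity, depth, doc, hard) {
    lab <- if (depth > 15) {
      if (salinity > 14) "1C3" else "1G1"
    } else {
      if (salinity > 10) "1E1" else "2T"
    }
    stats::setNames(1, lab)
  }
  community_rule(endo, epi,
                 generating_vars = list(endo = c("sediment", "salinity",
                                                 "depth"),
                                        epi = c("depth", "salinity")))
}

# signature dominant taxon for each endobenthic community token
.endo_signature <- c("3L3" = "Arctica islandica", "3L1" = "Macoma balthica",
                     "3L9" = "Cerastoderma glaucum", "3L10" = "Mya truncata",
                     "1E1" = "Mytilus edulis")
.endo_fillers <- c("Peringia ulvae", "Pygospio elegans", "Diastylis rathkei")

# signature epibenthic taxa per community token
.epi_signature <- c("1E1" = "Mytilus edulis", "1C3" = "Delesseria sanguinea",
                    "1C1" = "Fucus vesiculosus",
                    "1C2" = "Furcellaria lumbricalis", "1G1" = "Hydrozoa")
.epi_fillers <- c("Balanidae", "Einhornia crustulenta")

# taxon -> community token maps used when labelling stations
.endo_taxon_token <- c("Arctica islandica" = "3L3",
                       "Macoma balthica" = "3L1",
                       "Cerastoderma glaucum" = "3L9",
                       "Mya truncata" = "3L10",
                       "Mya arenaria" = "3L4",
                       "Mytilus edulis" = "1E1",
                       "Ophelia rathkei" = "3L11",
                       "Travisia forbesii" = "3L11")
.epi_taxon_token <- c("Mytilus edulis" = "1E1",
                      "Delesseria sanguinea" = "1C3",
                      "Fucus vesiculosus" = "1C1",
                      "Furcellaria lumbricalis" = "1C2",
                      "Hydrozoa" = "1G1")

# target biomass shares for an endobenthic community token
.endo_target_shares <- function(token) {
  if (token == "3") {
    stats::setNames(c(0.40, 0.35, 0.25), .endo_fillers)
  } else {
    sig <- .endo_signature[[token]]
    stats::setNames(c(0.65, 0.20, 0.10, 0.05),
                    c(sig, .endo_fillers))
  }
}

# target covers (percent of total area) for an epibenthic community token
.epi_target_cover <- function(token) {
  if (token == "2T") {
    stats::setNames(c(4, 3), .epi_fillers)
  } else if (token == "4U") {
    stats::setNames(numeric(0), character(0))
  } else {
    sig <- .epi_signature[[token]]
    stats::setNames(c(40, 4, 3), c(sig, .epi_fillers))
  }
}

.dirichlet_around <- function(shares, theta) {
  if (theta <= 0) return(shares)
  draw <- stats::rgamma(length(shares), shape = shares * theta)
  if (sum(draw) <= 0) return(shares)
  stats::setNames(draw / sum(draw), names(shares))
}

.truncnorm01 <- function(x, sd) {
  if (sd <= 0) return(x)
  pmin(pmax(x + stats::rnorm(length(x), 0, sd), 0), 100)
}

# evaluate a realm rule at a cell, argmax or sampled
.rule_label <- function(rule_fn, sediment, salinity, depth, doc, hard,
                        mode) {
  pr <- rule_fn(sediment, salinity, depth, doc, hard)
  if (is.null(pr)) {
    stop("community rule has no entry for condition: sediment=", sediment,
         ", salinity=", round(salinity, 2), ", depth=", round(depth, 2),
         call. = FALSE)
  }
  if (abs(sum(pr) - 1) > 1e-8) {
    stop("community rule probabilities must sum to 1", call. = FALSE)
  }
  if (mode == "argmax" || length(pr) == 1L) {
    names(pr)[which.max(pr)]
  } else {
    sample(names(pr), 1L, prob = pr)
  }
}

#' Generate ground-truth stations
#'
#' Grab stations (endobenthos) and video stations (epibenthos) are sampled
#' uniformly over cells, stratified by sediment class (grabs) or restricted
#' to hard-leaning cells (video), so every class is ground-truthed. Each
#' grab station carries a taxon biomass table whose dominant taxon matches
#' the rule label in deterministic mode; each video station carries a taxon
#' cover table consistent with the rule. True labels are stored alongside.
#'
#' @param config a [seascape_config()].
#' @param sediment character matrix from [generate_sediment_and_boulders()].
#' @param env environment stack from [generate_environment()].
#' @param rule a [community_rule()].
#' @param label_mode `"argmax"` (deterministic) or `"sample"`.
#' @return list with `stations` (station_id, x, y, method, row, col,
#'   hard_cover_pct, true_label) and `records` (station_id, taxon, value) in
#'   long form; `value` is biomass (g) for grabs and percent cover for video.
#' @export
generate_stations <- function(config, sediment, env,
                              rule = default_community_rule(),
                              label_mode = c("argmax", "sample")) {
  stopifnot(inherits(config, "seascape_config"))
  label_mode <- match.arg(label_mode)
  if (config$n_grab < 1) stop("need at least one grab station", call. = FALSE)
  set.seed(config$seed + 2L)
  g <- config$geom
  L <- env$layers

  # --- grab stations, stratified by sediment class ---------------------
  classes <- intersect(config$sediment_classes, unique(as.vector(sediment)))
  per <- rep(config$n_grab %/% length(classes), length(classes))
  per[seq_len(config$n_grab %% length(classes))] <-
    per[seq_len(config$n_grab %% length(classes))] + 1L
  cells <- do.call(rbind, lapply(seq_along(classes), function(i) {
    hit <- which(sediment == classes[i])
    pick <- hit[sample.int(length(hit), per[i], replace = TRUE)]
    data.frame(row = (pick - 1L) %% nrow(sediment) + 1L,
               col = (pick - 1L) %/% nrow(sediment) + 1L)
  }))

  hard_classes <- c("MxSed", "LagSed", "Peat")
  mk_station <- function(i, row, col, method) {
    c0 <- g$cell_size
    data.frame(
      station_id = sprintf("%s%04d", if (method == "grab") "G" else "V", i),
      x = g$xmin + (col - 1) * c0 + stats::runif(1) * c0,
      y = g$ymin + (g$nrow - row) * c0 + stats::runif(1) * c0,
      method = method, row = row, col = col, stringsAsFactors = FALSE)
  }

  stations <- list()
  records <- list()
  for (i in seq_len(nrow(cells))) {
    st <- mk_station(i, cells$row[i], cells$col[i], "grab")
    sed <- sediment[cells$row[i], cells$col[i]]
    tok <- .rule_label(rule$endo, sed,
                       L$salinity[cells$row[i], cells$col[i]],
                       L$depth[cells$row[i], cells$col[i]],
                       L$doc[cells$row[i], cells$col[i]],
                       sed %in% hard_classes, label_mode)
    shares <- .dirichlet_around(.endo_target_shares(tok),
                                config$biomass_theta)
    st$hard_cover_pct <- NA_real_
    st$true_label <- tok
    stations[[length(stations) + 1L]] <- st
    records[[length(records) + 1L]] <-
      data.frame(station_id = st$station_id, taxon = names(shares),
                 value = round(as.numeric(shares) * 100, 6),
                 stringsAsFactors = FALSE)
  }

  # --- video stations on hard-leaning cells ----------------------------
  if (config$n_video > 0) {
    hard_cells <- which(matrix(sediment %in% hard_classes, nrow(sediment)))
    if (!length(hard_cells)) {
      stop("no hard-substrate cells available for video stations",
           call. = FALSE)
    }
    pick <- hard_cells[sample.int(length(hard_cells), config$n_video,
                                  replace = TRUE)]
    vrow <- (pick - 1L) %% nrow(sediment) + 1L
    vcol <- (pick - 1L) %/% nrow(sediment) + 1L
    for (i in seq_len(config$n_video)) {
      st <- mk_station(i, vrow[i], vcol[i], "video")
      sed <- sediment[vrow[i], vcol[i]]
      tok <- .rule_label(rule$epi, sed, L$salinity[vrow[i], vcol[i]],
                         L$depth[vrow[i], vcol[i]],
                         L$doc[vrow[i], vcol[i]], TRUE, label_mode)
      cov <- .epi_target_cover(tok)
      if (length(cov)) cov[] <- .truncnorm01(cov, config$cover_sd)
      st$hard_cover_pct <- 60
      st$true_label <- tok
      stations[[length(stations) + 1L]] <- st
      if (length(cov)) {
        records[[length(records) + 1L]] <-
          data.frame(station_id = st$station_id, taxon = names(cov),
                     value = round(as.numeric(cov), 6),
                     stringsAsFactors = FALSE)
      }
    }
  }

  list(stations = do.call(rbind, stations),
       records = do.call(rbind, records))
}

#' Simulate a complete seascape
#'
#' Convenience wrapper running [generate_environment()],
#' [generate_sediment_and_boulders()] and [generate_stations()].
#'
#' @inheritParams generate_stations
#' @return list with `config`, `geom`, `env`, `sediment`, `boulders`,
#'   `stations`, `records`, `rule`.
#' @export
simulate_seascape <- function(config = seascape_config(),
                              rule = default_community_rule(),
                              label_mode = "argmax") {
  env <- generate_environment(config)
  sb <- generate_sediment_and_boulders(config)
  stn <- generate_stations(config, sb$sediment, env, rule, label_mode)
  list(config = config, geom = config$geom, env = env,
       sediment = sb$sediment, boulders = sb$boulders,
       stations = stn$stations, records = stn$records, rule = rule)
}
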