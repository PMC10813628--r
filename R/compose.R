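#' Map composition: BHT, OHT and HUB layers with area accounting
#'
#' Composes the three output layers from sediment, photic, hard-bottom and
#' prediction inputs. The BHT layer is zone x substrate, generalised by
#' eliminating patches below one hectare; the HUB layer completes predicted
#' community tokens with zone and substrate (and is never generalised); the
#' OHT layer carries reef and sandbank polygons through as provided and adds
#' grid-based categories (seagrass, Arctica mud, species-rich gravel) with a
#' reef-over-species-rich precedence.
#'
#' @name map-composition
NULL

#' Composition constants
#'
#' @return named list: minimum BHT patch (ha), seagrass occurrence
#'   probability and density thresholds, model-confidence threshold, and the
#'   species-rich designation thresholds (station count, single-taxon and
#'   combined biomass shares, gravel/coarse-sand/shell substrate share).
#' @export
composition_config <- function() {
  list(min_patch_ha = 1, seagrass_prob_pct = 50, seagrass_density_m2 = 10,
       confidence_pct = 67,
       species_rich = list(min_stations = 3, single_taxon_pct = 10,
                           combined_pct = 5, substrate_pct = 50))
}

# fixed substrate hardness order for majority tie-breaks (harder wins)
.substrate_hardness <- c(mud = 1, sand = 2, coarse_sediment = 3,
                         mixed_sediment_hard = 4, rock_biogenic_reef = 5)

#' Aggregate a fine categorical grid to a coarser grid by areal majority
#'
#' Each target cell receives the class with the greatest share of its
#' constituent fine cells; ties are broken by the fixed hardness order (mud
#' < sand < coarse < mixed < rock: the harder substrate wins). With
#' `factor = 1` this is the identity. Coverage gaps (NA fine cells) count
#' toward no class; an all-NA block is NA.
#'
#' @param fine character matrix whose dimensions are `factor` times the
#'   target dimensions.
#' @param factor integer aggregation factor (fine cells per target cell and
#'   axis).
#' @return character matrix of majority classes.
#' @export
rasterize_majority <- function(fine, factor = 1L) {
  nr <- nrow(fine) %/% factor
  nc <- ncol(fine) %/% factor
  if (nrow(fine) != nr * factor || ncol(fine) != nc * factor) {
    stop("fine grid dimensions must be multiples of the factor",
         call. = FALSE)
  }
  out <- matrix(NA_character_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      block <- fine[((i - 1) * factor + 1):(i * factor),
                    ((j - 1) * factor + 1):(j * factor)]
      vals <- block[!is.na(block)]
      if (!length(vals)) next
      tab <- table(vals)
      win <- names(tab)[tab == max(tab)]
      if (length(win) > 1L) {
        h <- .substrate_hardness[win]
        h[is.na(h)] <- 0
        win <- win[which.max(h)]
      }
      out[i, j] <- win
    }
  }
  out
}

#' Compose the BHT class of each cell
#'
#' Zone from the photic flag (photic -> infralittoral, aphotic ->
#' circalittoral); substrate as attributed, except that peat bottoms covered
#' by mussels enter as rock and biogenic reef.
#'
#' @param photic logical matrix.
#' @param substrate character matrix of EUNIS substrates (or `"peat"`).
#' @param peat_with_mussels logical matrix (or scalar) marking mussel-covered
#'   peat.
#' @return character matrix of BHT labels, e.g. `"Infralittoral sand"`.
#' @export
compose_bht <- function(photic, substrate, peat_with_mussels = FALSE) {
  zone <- ifelse(photic, "infralittoral", "circalittoral")
  sub <- substrate
  sub[substrate == "peat" & peat_with_mussels] <- "rock_biogenic_reef"
  sub[substrate == "peat" & !peat_with_mussels] <- "mixed_sediment_hard"
  out <- ifelse(is.na(sub) | is.na(zone), NA_character_,
                .bht_label(zone, sub))
  if (is.matrix(substrate)) out <- matrix(out, nrow(substrate),
                                          ncol(substrate))
  out
}

# 4-connected components of equal-label cells; returns integer matrix
.label_patches <- function(grid) {
  nr <- nrow(grid)
  nc <- ncol(grid)
  comp <- matrix(0L, nr, nc)
  nextid <- 0L
  for (start in which(!is.na(grid))) {
    if (comp[start] != 0L) next
    nextid <- nextid + 1L
    queue <- start
    comp[start] <- nextid
    lab <- grid[start]
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      i <- (cur - 1L) %% nr + 1L
      j <- (cur - 1L) %/% nr + 1L
      for (nb in c(if (i > 1) cur - 1L, if (i < nr) cur + 1L,
                   if (j > 1) cur - nr, if (j < nc) cur + nr)) {
        if (comp[nb] == 0L && !is.na(grid[nb]) && grid[nb] == lab) {
          comp[nb] <- nextid
          queue <- c(queue, nb)
        }
      }
    }
  }
  comp
}

#' Eliminate BHT patches below the minimum mapping unit
#'
#' 4-connected same-label patches with an area below `min_patch_ha` are
#' relabelled to the modal label of their boundary neighbours (computed on
#' the input grid); patches without any labelled neighbour are left
#' unchanged. Total cell count is conserved and no new label is created.
#' The HUB layer must never be passed through this generalisation.
#'
#' @param grid character matrix of BHT labels.
#' @param cell_size cell edge length (m).
#' @param min_patch_ha minimum retained patch area (hectares).
#' @return relabelled character matrix.
#' @export
eliminate_small_patches <- function(grid, cell_size,
                                    min_patch_ha =
                                      composition_config()$min_patch_ha) {
  comp <- .label_patches(grid)
  cell_ha <- cell_size^2 / 1e4
  sizes <- tabulate(comp)
  small <- which(sizes * cell_ha < min_patch_ha)
  if (!length(small)) return(grid)
  nr <- nrow(grid)
  nc <- ncol(grid)
  out <- grid
  for (id in small) {
    cells <- which(comp == id)
    nbs <- unique(unlist(lapply(cells, function(cur) {
      i <- (cur - 1L) %% nr + 1L
      j <- (cur - 1L) %/% nr + 1L
      c(if (i > 1) cur - 1L, if (i < nr) cur + 1L,
        if (j > 1) cur - nr, if (j < nc) cur + nr)
    })))
    nbs <- setdiff(nbs, cells)
    nb_labels <- grid[nbs]
    nb_labels <- nb_labels[!is.na(nb_labels)]
    if (!length(nb_labels)) next  # isolated patch: left unchanged
    tab <- table(nb_labels)
    out[cells] <- names(tab)[which.max(tab)]
  }
  out
}

#' Intersect endobenthos and epibenthos predictions
#'
#' The epibenthic community is indicated where hard substrate dominates the
#' cell; elsewhere the endobenthic community applies. A hard cell without an
#' epibenthos prediction is NA.
#'
#' @param hard logical matrix of hard-substrate dominance.
#' @param endo_token,epi_token character matrices of predicted community
#'   tokens.
#' @return character matrix of combined tokens.
#' @export
intersect_endo_epi <- function(hard, endo_token, epi_token) {
  out <- ifelse(hard, epi_token, endo_token)
  if (is.matrix(endo_token)) out <- matrix(out, nrow(endo_token),
                                           ncol(endo_token))
  out
}

#' Build the HUB map layer
#'
#' Completes the combined community token of each cell with its zone and
#' substrate via [compose_hub()]; cells with NA sediment get an NA code.
#'
#' @param photic logical matrix.
#' @param substrate character matrix of EUNIS substrates (or `"peat"`).
#' @param token character matrix of community tokens (NA allowed).
#' @param cell_size cell edge length (m).
#' @return list with `hub` (character matrix of codes) and `areas`
#'   (data.frame `class`, `km2`, `pct`).
#' @export
build_hub_layer <- function(photic, substrate, token, cell_size) {
  sub <- substrate
  # a reef-substrate cell has no single HUB letter; treated as unclassifiable
  sub[sub == "rock_biogenic_reef"] <- "unknown"
  tok <- ifelse(is.na(token), "", token)
  hub <- compose_hub(as.vector(photic), as.vector(sub), as.vector(tok))
  hub <- matrix(hub, nrow(substrate), ncol(substrate))
  list(hub = hub, areas = area_summary(hub, cell_size))
}

#' Per-class area summary of a categorical layer
#'
#' @param layer character matrix (NA = unmapped).
#' @param cell_size cell edge length (m).
#' @return data.frame `class`, `km2`, `pct` (percent of the mapped, non-NA
#'   area; sums to 100 up to rounding). Empty layers give an empty table.
#' @export
area_summary <- function(layer, cell_size) {
  vals <- as.vector(layer)
  vals <- vals[!is.na(vals)]
  if (!length(vals)) {
    return(data.frame(class = character(0), km2 = numeric(0),
                      pct = numeric(0)))
  }
  tab <- sort(table(vals), decreasing = TRUE)
  km2 <- as.numeric(tab) * cell_size^2 / 1e6
  data.frame(class = names(tab), km2 = km2,
             pct = as.numeric(tab) / length(vals) * 100,
             stringsAsFactors = FALSE)
}

#' Detect candidate species-rich gravel/coarse-sand/shell areas
#'
#' An occurrence area (4-connected component of eligible, coarse-leaning
#' sediment cells) is a candidate when at least `min_stations` qualifying
#' stations fall on it: a station qualifies when a single indicator taxon
#' (Ophelia spp. / Travisia forbesii) reaches at least 10 % of total
#' biomass, or both together reach at least 5 %. The stricter designation
#' test — the substrate comprising more than 50 % gravel, coarse sand and
#' shell — is evaluated and reported separately per area.
#'
#' @param stations data.frame with `row`, `col`, `single_indicator_pct`
#'   (largest single indicator-taxon biomass share), `combined_pct`
#'   (combined indicator share) and optionally `gravel_coarse_shell_pct`
#'   (substrate share at the station).
#' @param sediment character matrix of BSH level A classes.
#' @param eligible sediment classes that can host the biotope.
#' @param config see [composition_config()].
#' @return data.frame per occurrence area: `area_id`, `n_stations`,
#'   `n_qualifying`, `candidate`, `substrate_pct`, `designated`, plus an
#'   attribute `area_map` (integer matrix of area ids).
#' @export
detect_species_rich <- function(stations, sediment,
                                eligible = c("Csed", "LagSed"),
                                config = composition_config()) {
  sr <- config$species_rich
  mask <- matrix(ifelse(sediment %in% eligible, "eligible", NA_character_),
                 nrow(sediment), ncol(sediment))
  areas <- .label_patches(mask)
  if ("gravel_coarse_shell_pct" %in% names(stations)) {
    gcs <- stations$gravel_coarse_shell_pct
  } else {
    gcs <- rep(NA_real_, nrow(stations))
  }
  aid <- areas[cbind(stations$row, stations$col)]
  qual <- stations$single_indicator_pct >= sr$single_taxon_pct |
    stations$combined_pct >= sr$combined_pct
  ids <- sort(unique(aid[aid > 0]))
  res <- do.call(rbind, lapply(ids, function(id) {
    on <- which(aid == id)
    nq <- sum(qual[on])
    sub_pct <- if (all(is.na(gcs[on]))) NA_real_
               else mean(gcs[on], na.rm = TRUE)
    data.frame(area_id = id, n_stations = length(on), n_qualifying = nq,
               candidate = nq >= sr$min_stations,
               substrate_pct = sub_pct,
               designated = nq >= sr$min_stations & !is.na(sub_pct) &
                 sub_pct > sr$substrate_pct)
  }))
  if (is.null(res)) {
    res <- data.frame(area_id = integer(0), n_stations = integer(0),
                      n_qualifying = integer(0), candidate = logical(0),
                      substrate_pct = numeric(0), designated = logical(0))
  }
  attr(res, "area_map") <- areas
  res
}

#' Build the OHT layer
#'
#' Reef and sandbank polygons are carried through as provided (exact
#' geometric areas, not re-gridded). Seagrass/Fucus cells are included when
#' the modelled occurrence probability is at least 50 % or the mapped
#' density is at least 10 individuals per square metre. The Arctica category
#' collects cells whose HUB code is the aphotic muddy ocean-quahog class
#' (`AB.H3L3`). Species-rich gravel candidates come from
#' [detect_species_rich()]; where they overlap reef polygons the reef wins
#' and the species-rich area is reduced accordingly.
#'
#' @param geom a [grid_geometry()].
#' @param hub character matrix of HUB codes.
#' @param reef_polygons,sandbank_polygons polygon lists (may be empty).
#' @param seagrass_prob numeric matrix of modelled occurrence (percent), or
#'   NULL.
#' @param seagrass_density numeric matrix (individuals per m^2), or NULL.
#' @param species_rich result of [detect_species_rich()], or NULL.
#' @param config see [composition_config()].
#' @return list with `masks` (named list of logical matrices for the
#'   grid-based categories), `polygons` (reefs/sandbanks as given) and
#'   `areas` (data.frame `class`, `km2`).
#' @export
build_oht_layer <- function(geom, hub, reef_polygons = list(),
                            sandbank_polygons = list(),
                            seagrass_prob = NULL, seagrass_density = NULL,
                            species_rich = NULL,
                            config = composition_config()) {
  nr <- geom$nrow
  nc <- geom$ncol
  masks <- list()

  seagrass <- matrix(FALSE, nr, nc)
  if (!is.null(seagrass_prob)) {
    seagrass <- seagrass | (!is.na(seagrass_prob) &
                              seagrass_prob >= config$seagrass_prob_pct)
  }
  if (!is.null(seagrass_density)) {
    seagrass <- seagrass | (!is.na(seagrass_density) &
                              seagrass_density >= config$seagrass_density_m2)
  }
  masks$seagrass_macrophytes <- seagrass

  masks$arctica_aphotic_mud <- !is.na(hub) & hub == "AB.H3L3"

  # cells covered by a reef polygon (centre-in-polygon), for precedence
  reef_cells <- matrix(FALSE, nr, nc)
  if (length(reef_polygons)) {
    idx <- which(!reef_cells, arr.ind = TRUE)
    ctr <- cell_centres(geom, idx[, 1], idx[, 2])
    inside <- rep(FALSE, nrow(idx))
    for (poly in reef_polygons) {
      inside <- inside | point_in_polygon(ctr$x, ctr$y, poly)
    }
    reef_cells[idx[inside, , drop = FALSE]] <- TRUE
  }

  srg <- matrix(FALSE, nr, nc)
  if (!is.null(species_rich) && any(species_rich$candidate)) {
    area_map <- attr(species_rich, "area_map")
    keep <- species_rich$area_id[species_rich$candidate]
    srg <- matrix(area_map %in% keep, nr, nc)
    # reefs and species-rich areas cannot both be designated: reef wins
    srg <- srg & !reef_cells
  }
  masks$species_rich_gravel <- srg

  cell_km2 <- geom$cell_size^2 / 1e6
  areas <- data.frame(
    class = c("reefs_1170", "sandbanks_1110", names(masks)),
    km2 = c(sum(vapply(reef_polygons, polygon_area, numeric(1))) / 1e6,
            sum(vapply(sandbank_polygons, polygon_area, numeric(1))) / 1e6,
            vapply(masks, function(m) sum(m) * cell_km2, numeric(1))),
    stringsAsFactors = FALSE)
  list(masks = masks,
       polygons = list(reefs = reef_polygons,
                       sandbanks = sandbank_polygons),
       reef_cells = reef_cells,
       areas = areas)
}
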