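#' Controlled vocabularies for sediment and biotope classification
#'
#' Closed vocabularies used throughout the package: BSH sediment levels A-C,
#' EUNIS substrate categories, Tauber map classes, HELCOM HUB grammar tokens,
#' BHT zones/substrates and OHT categories.
#'
#' @name vocabularies
NULL

# BSH hydroacoustic sediment vocabulary (level A -> permitted level B classes)
.bsh_levels <- list(
  Fsed   = c("not specified", "M", "sM", "mS"),
  S      = c("not specified", "S"),
  Csed   = c("not specified", "gS", "sG", "G"),
  MxSed  = c("not specified", "gM", "msG", "mG"),
  Peat   = c("not classified"),
  LagSed = c("not classified")
)

.bsh_level_c <- c("fSa", "mSa", "mxSa", "cSa")

#' @rdname vocabularies
#' @export
bsh_level_a <- function() names(.bsh_levels)

#' @rdname vocabularies
#' @export
bsh_level_b <- function(level_a) {
  if (!level_a %in% names(.bsh_levels)) {
    stop("unknown BSH level A class: ", level_a, call. = FALSE)
  }
  .bsh_levels[[level_a]]
}

#' @rdname vocabularies
#' @export
eunis_substrates <- function() {
  c("mud", "sand", "coarse_sediment", "mixed_sediment_hard",
    "rock_biogenic_reef")
}

# level A for each Folk level B class
.folk_to_level_a <- c(
  M = "Fsed", sM = "Fsed", mS = "Fsed",
  S = "S",
  gS = "Csed", sG = "Csed", G = "Csed",
  gM = "MxSed", msG = "MxSed", mG = "MxSed"
)

#' Map BSH level A sediment classes to EUNIS substrate categories
#'
#' Fine sediments map to mud, sands to sand, coarse sediments to coarse
#' sediment; mixed, lag and peat bottoms map to mixed sediment (hard
#' substrate), mirroring the translation applied to interpolated soft-bottom
#' map classes.
#'
#' @param bsh character vector of BSH level A classes.
#' @return character vector of EUNIS substrate categories.
#' @export
bsh_to_eunis <- function(bsh) {
  map <- c(Fsed = "mud", S = "sand", Csed = "coarse_sediment",
           MxSed = "mixed_sediment_hard", Peat = "mixed_sediment_hard",
           LagSed = "mixed_sediment_hard")
  bad <- setdiff(unique(bsh), c(names(map), NA))
  if (length(bad)) {
    stop("unknown BSH level A class(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(map[bsh])
}

#' OHT categories of the German Baltic Sea
#' @export
oht_categories <- function() {
  c("reefs_1170", "sandbanks_1110", "seagrass_macrophytes",
    "species_rich_gravel", "arctica_aphotic_mud")
}

#' BHT zone and substrate vocabulary
#' @export
bht_substrates <- function() {
  c("rock_biogenic_reef", "mixed_sediment_hard", "coarse_sediment",
    "sand", "mud")
}

#' @rdname bht_substrates
#' @export
bht_zones <- function() c("infralittoral", "circalittoral")

# human-readable BHT labels, e.g. "Infralittoral sand"
.bht_label <- function(zone, substrate) {
  subs <- c(rock_biogenic_reef = "rock and biogenic reef",
            mixed_sediment_hard = "mixed sediment (hard substrate)",
            coarse_sediment = "coarse sediment",
            sand = "sand", mud = "mud")
  paste(ifelse(zone == "infralittoral", "Infralittoral", "Circalittoral"),
        subs[substrate])
}
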