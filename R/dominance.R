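#' Station-level community labelling: dominance criteria and conventions
#'
#' Ground-truth stations are labelled with HUB communities from their raw
#' observations. Endobenthic dominance (grab samples) requires a strict
#' biomass share above 50 % of the station total; epibenthic dominance
#' (video/photo/diver records) requires at least 10 % cover of the total
#' area, or at least 90 % cover when rescaled to the hard-substrate area.
#' Semi-quantitative ACFOR video estimates are converted to percent cover
#' with a fixed monotone midpoint table before the cover criteria apply.
#'
#' @name dominance
NULL

#' Dominance thresholds
#'
#' @return named list: `endo_biomass_pct` (strict >), `epi_total_cover_pct`
#'   (>=), `epi_hard_cover_pct` (>=).
#' @export
dominance_config <- function() {
  list(endo_biomass_pct = 50, epi_total_cover_pct = 10,
       epi_hard_cover_pct = 90)
}

#' Dominant endobenthic taxon of a grab sample
#'
#' @param biomass named non-negative numeric vector (taxon -> biomass in g).
#' @param config see [dominance_config()].
#' @return the taxon name with a strict majority biomass share, or
#'   `NA_character_` if none; a zero-biomass sample returns `"empty"`
#'   (candidate for the no-macrocommunity class).
#' @examples
#' dominant_endobenthos(c(A = 60, B = 40))  # "A"
#' dominant_endobenthos(c(A = 50, B = 50))  # NA (strict threshold)
#' @export
dominant_endobenthos <- function(biomass, config = dominance_config()) {
  if (any(biomass < 0)) stop("biomass must be non-negative", call. = FALSE)
  tot <- sum(biomass)
  if (tot <= 0) return("empty")
  share <- biomass / tot * 100
  hit <- which(share > config$endo_biomass_pct)
  if (length(hit) == 1L) names(biomass)[hit] else NA_character_
}

#' Dominant epibenthic taxon of a cover record
#'
#' A taxon qualifies when its total-area cover is at least 10 %, or its cover
#' expressed on the hard-substrate area is at least 90 %. Among qualifiers
#' the largest total-area cover wins; ties are broken by `precedence`
#' (structuring, long-lived taxa first), then alphabetically.
#'
#' @param cover named numeric vector (taxon -> percent cover of total area).
#' @param hard_cover_pct areal hard-substrate percentage of the field of
#'   view; used to rescale total-area cover onto hard substrate. If 0 (or
#'   NA), the hard-substrate criterion is skipped.
#' @param config see [dominance_config()].
#' @param cover_hard optional named vector of covers already expressed on the
#'   hard-substrate area (overrides the rescaling).
#' @param precedence character vector of taxa for tie-breaking.
#' @return taxon name or `NA_character_`.
#' @export
dominant_epibenthos <- function(cover, hard_cover_pct = NA,
                                config = dominance_config(),
                                cover_hard = NULL, precedence = character()) {
  if (any(cover < 0 | cover > 100)) {
    stop("cover must lie in [0, 100]", call. = FALSE)
  }
  if (!length(cover)) return(NA_character_)
  on_hard <- if (!is.null(cover_hard)) {
    cover_hard[names(cover)]
  } else if (!is.na(hard_cover_pct) && hard_cover_pct > 0) {
    pmin(cover / (hard_cover_pct / 100), 100)
  } else {
    rep(NA_real_, length(cover))  # hard-substrate criterion skipped
  }
  qual <- cover >= config$epi_total_cover_pct |
    (!is.na(on_hard) & on_hard >= config$epi_hard_cover_pct)
  if (!any(qual)) return(NA_character_)
  cand <- names(cover)[qual]
  best <- cand[cover[cand] == max(cover[cand])]
  if (length(best) > 1L) {
    ranked <- match(best, precedence)
    if (any(!is.na(ranked))) {
      best <- best[order(ranked, best, na.last = TRUE)]
    } else {
      best <- sort(best)
    }
  }
  best[1]
}

#' Convert ACFOR cover estimates to percent cover
#'
#' Fixed midpoint mapping: abundant 75, common 35, frequent 15, occasional 5,
#' rare 1. Any monotone mapping preserves dominance ordering; midpoints are
#' used for interpretability.
#'
#' @param acfor character vector of ACFOR letters.
#' @return numeric percent cover.
#' @export
acfor_to_cover <- function(acfor) {
  map <- c(A = 75, C = 35, F = 15, O = 5, R = 1)
  bad <- setdiff(unique(acfor), c(names(map), NA))
  if (length(bad)) {
    stop("unknown ACFOR letter(s): ", paste(bad, collapse = ", "),
         "; valid letters: A C F O R", call. = FALSE)
  }
  unname(map[acfor])
}

#' Modelling conventions for station labels
#'
#' Fixed harmonisation rules applied before community modelling:
#' `rare_taxon_station_pct` removes stations whose dominant taxon accounts
#' for at most that share of all stations; stations dominated by
#' Ophelia/Travisia are removed (unpredictable by the model); the merge map
#' reassigns poorly separable dominants (Mya arenaria, Astarte spp. -> the
#' multiple-infaunal-bivalve community `3L9`; named polychaete dominants and
#' level-5 endings -> the level-4 infaunal-structures class `3`); mixed
#' epibenthic labels collapse to the structuring taxon of the precedence
#' list; epibenthic level-5 labels are promoted to level 6.
#'
#' @return a list of convention parameters.
#' @export
convention_config <- function() {
  list(
    rare_taxon_station_pct = 1,
    delete_taxa = c("Ophelia spp.", "Ophelia rathkei", "Travisia spp.",
                    "Travisia forbesii", "3L11"),
    merge_map = c(
      # taxon-name keys (labels straight from dominance scans)
      "Mya arenaria" = "3L9", "Astarte spp." = "3L9",
      "Astarte borealis" = "3L9",
      "Scoloplos armiger" = "3", "Marenzelleria spp." = "3",
      "Pygospio elegans" = "3", "Hediste diversicolor" = "3",
      # token keys (labels already encoded as HUB levels 4-6)
      "3L4" = "3L9",       # Mya arenaria dominants
      "3M6" = "3",         # named polychaete communities
      "3L"  = "3",         # level-5 bivalve endings
      "3M"  = "3",         # level-5 polychaete endings
      "3C"  = "3"          # level-5 crustacean endings
    ),
    promote_epi_level5 = TRUE,
    precedence = c("foliose red algae", "Fucus spp.", "Mytilus edulis",
                   "Furcellaria lumbricalis", "kelp", "sponges",
                   "filamentous red algae", "bryozoans", "Hydrozoa")
  )
}

#' Harmonise station community labels
#'
#' Applies the modelling conventions to a station label table: mixed labels
#' (`"a/b"`) collapse to their highest-precedence component, the merge map
#' reassigns labels, then stations dominated by the configured
#' delete-list taxa or by taxa at or below the rare-station share are flagged
#' excluded with a reason. The rare-share denominator is the full input
#' station set (stations already flagged excluded keep their flag and are
#' otherwise untouched), which makes the operation idempotent.
#'
#' @param labels data.frame with columns `station_id`, `label` (community
#'   label or dominant-taxon name) and optionally `excluded`, `reason`.
#' @param config see [convention_config()].
#' @return data.frame with columns `station_id`, `label` (input),
#'   `harmonized_label`, `excluded`, `reason`.
#' @export
apply_conventions <- function(labels, config = convention_config()) {
  stopifnot(all(c("station_id", "label") %in% names(labels)))
  n_total <- nrow(labels)
  out <- data.frame(station_id = labels$station_id, label = labels$label,
                    stringsAsFactors = FALSE)
  out$excluded <- if ("excluded" %in% names(labels)) labels$excluded
                  else rep(FALSE, n_total)
  out$reason <- if ("reason" %in% names(labels)) labels$reason
                else rep(NA_character_, n_total)
  harm <- if ("harmonized_label" %in% names(labels)) {
    labels$harmonized_label
  } else {
    labels$label
  }

  # 1. collapse mixed labels to the structuring component
  mixed <- grepl("/", harm, fixed = TRUE) & !out$excluded
  if (any(mixed)) {
    harm[mixed] <- vapply(strsplit(harm[mixed], "/", fixed = TRUE),
                          function(parts) {
                            r <- match(parts, config$precedence)
                            if (all(is.na(r))) parts[1]
                            else parts[which.min(replace(r, is.na(r), Inf))]
                          }, character(1))
  }

  # 2. merge map (Mya/Astarte -> L9; polychaetes & level-5 endings -> level 4)
  hit <- harm %in% names(config$merge_map) & !out$excluded
  harm[hit] <- unname(config$merge_map[harm[hit]])

  # 3. deletions: unpredictable indicator dominants
  del <- harm %in% config$delete_taxa & !out$excluded
  out$excluded[del] <- TRUE
  out$reason[del] <- "unpredictable_dominant"

  # 4. rare dominants (share of the full station set)
  active <- !out$excluded
  freq <- table(harm[active])
  rare_labels <- names(freq)[freq / n_total * 100 <=
                               config$rare_taxon_station_pct]
  rare <- active & harm %in% rare_labels
  out$excluded[rare] <- TRUE
  out$reason[rare] <- "rare_dominant"

  out$harmonized_label <- harm
  out[c("station_id", "label", "harmonized_label", "excluded", "reason")]
}
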