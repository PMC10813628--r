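#' Label ground-truth stations with HUB communities
#'
#' Applies the dominance criteria to raw station observations (grab biomass
#' tables, video/photo cover tables), maps dominant taxa to HUB level 4-6
#' community tokens, and harmonises the labels with the modelling
#' conventions ([apply_conventions()]).
#'
#' @param stations data.frame with columns `station_id`, `method`
#'   (`"grab"`/`"video"`) and optionally `hard_cover_pct`.
#' @param records long data.frame with columns `station_id`, `taxon`,
#'   `value` (biomass for grabs, percent cover for video). Stations absent
#'   from `records` are treated as empty samples.
#' @param config dominance thresholds, see [dominance_config()].
#' @param conventions convention set, see [convention_config()]; NULL skips
#'   harmonisation.
#' @return data.frame: `station_id`, `method`, `raw_label`,
#'   `harmonized_label`, `excluded`, `reason`.
#' @export
assign_hub_labels <- function(stations, records,
                              config = dominance_config(),
                              conventions = convention_config()) {
  stopifnot(all(c("station_id", "method") %in% names(stations)),
            all(c("station_id", "taxon", "value") %in% names(records)))
  recs <- split(records, records$station_id)
  raw <- vapply(seq_len(nrow(stations)), function(i) {
    sid <- stations$station_id[i]
    r <- recs[[sid]]
    if (stations$method[i] == "grab") {
      if (is.null(r) || !nrow(r)) return("4U")
      biomass <- stats::setNames(r$value, r$taxon)
      dom <- dominant_endobenthos(biomass, config)
      if (identical(dom, "empty")) return("4U")
      if (is.na(dom)) return("3")  # infaunal structures, no dominant
      tok <- .endo_taxon_token[dom]
      if (is.na(tok)) dom else unname(tok)
    } else {
      if (is.null(r) || !nrow(r)) return("4U")
      cover <- stats::setNames(r$value, r$taxon)
      hc <- if ("hard_cover_pct" %in% names(stations))
              stations$hard_cover_pct[i] else NA
      dom <- dominant_epibenthos(cover, hc, config)
      if (is.na(dom)) return(if (any(cover > 0)) "2T" else "4U")
      tok <- .epi_taxon_token[dom]
      if (is.na(tok)) dom else unname(tok)
    }
  }, character(1))
  out <- data.frame(station_id = stations$station_id,
                    method = stations$method, label = raw,
                    stringsAsFactors = FALSE)
  if (is.null(conventions)) {
    out$harmonized_label <- raw
    out$excluded <- FALSE
    out$reason <- NA_character_
  } else {
    conv <- apply_conventions(out[c("station_id", "label")], conventions)
    out$harmonized_label <- conv$harmonized_label
    out$excluded <- conv$excluded
    out$reason <- conv$reason
  }
  names(out)[names(out) == "label"] <- "raw_label"
  out
}
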