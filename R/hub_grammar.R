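#' HELCOM HUB code grammar
#'
#' HUB codes are hierarchical biotope identifiers of the form
#' `<zone>.<substrate><level4><level5/6><?>`, e.g. `AA.J3L9`: Baltic photic
#' (`AA`) sand (`J`) with macroscopic infaunal biotic structures (`3`)
#' dominated by multiple infaunal bivalve species (`L9`). Zone `AB` is
#' aphotic. Substrate letters: H muddy sediment, I coarse sediment, J sand,
#' M mixed (hard) substrate, G peat, `?` unclassifiable substrate. Level 4:
#' 1 epibenthic structures, 2 sparse epibenthos, 3 infaunal structures,
#' 4 no macrocommunity. A trailing `?` marks an uncertain assignment and two
#' codes can be joined by `+` (layered bottoms, e.g. mussel-covered peat
#' under thin sand). Codes may stop at any level.
#'
#' @name hub-grammar
NULL

# level 5/6 community tokens (order matters: longest match first)
.hub_tokens <- c("L10", "L11", "C1", "C2", "C3", "C4", "C5", "E1", "S1",
                 "G1", "H2", "I1", "B7", "L1", "L3", "L4", "L9", "M6",
                 "S", "V", "T", "U")

.hub_part_re <- paste0(
  "^(AA|AB)\\.([HIJMG?])([1-4])?(",
  paste(.hub_tokens, collapse = "|"),
  ")?(\\?)?$")

.parse_hub_part <- function(code) {
  m <- regmatches(code, regexec(.hub_part_re, code))[[1]]
  if (!length(m)) stop("malformed HUB code: '", code, "'", call. = FALSE)
  part <- list(zone = m[2], substrate = m[3],
               level4 = if (nzchar(m[4])) m[4] else NA_character_,
               level56 = if (nzchar(m[5])) m[5] else NA_character_,
               uncertain = nzchar(m[6]))
  if (!is.na(part$level56) && is.na(part$level4)) {
    stop("HUB code '", code, "': level 5/6 token without level 4",
         call. = FALSE)
  }
  if (!is.na(part$level56)) {
    if (part$level56 == "T" && part$level4 != "2") {
      stop("HUB code '", code, "': T (sparse) requires level 4 = 2",
           call. = FALSE)
    }
    if (part$level56 == "U" && part$level4 != "4") {
      stop("HUB code '", code, "': U (no macrocommunity) requires level 4 = 4",
           call. = FALSE)
    }
  }
  part
}

#' Parse a HUB code string
#'
#' @param code a single HUB code, possibly a `+` union of two codes.
#' @return an object of class `hub_code`: a list of parts, each with fields
#'   `zone`, `substrate`, `level4`, `level56`, `uncertain`.
#' @examples
#' parse_hub("AA.J3L9")
#' parse_hub("AA.G+AA.J1E1")
#' @export
parse_hub <- function(code) {
  stopifnot(is.character(code), length(code) == 1L)
  parts <- lapply(strsplit(code, "+", fixed = TRUE)[[1]], .parse_hub_part)
  structure(parts, class = "hub_code")
}

#' Reassemble a parsed HUB code into its string form
#'
#' `compose_hub_string(parse_hub(x))` is the identity for every valid code.
#'
#' @param hub a `hub_code` object from [parse_hub()].
#' @return the code string.
#' @export
compose_hub_string <- function(hub) {
  one <- function(p) {
    paste0(p$zone, ".", p$substrate,
           if (!is.na(p$level4)) p$level4 else "",
           if (!is.na(p$level56)) p$level56 else "",
           if (p$uncertain) "?" else "")
  }
  paste(vapply(unclass(hub), one, character(1)), collapse = "+")
}

#' @export
print.hub_code <- function(x, ...) {
  cat("<hub_code>", compose_hub_string(x), "\n")
  invisible(x)
}

#' Compose a HUB code from map attributes and a community token
#'
#' Completes a predicted community (levels 4-6, e.g. `"3L9"`, `"1E1"`, `"2T"`
#' or `""` for none) with the zone and substrate of its cell (levels 1-3).
#'
#' @param photic logical; TRUE -> zone AA, FALSE -> AB.
#' @param substrate EUNIS substrate category, `"peat"`, or `"unknown"`.
#' @param community levels 4-6 token (character; `""` or NA for none).
#' @param uncertain logical; append a `?` suffix.
#' @return HUB code string (vectorised over its arguments).
#' @examples
#' compose_hub(TRUE, "sand", "1E1")    # "AA.J1E1"
#' compose_hub(FALSE, "mud", "3L3")    # "AB.H3L3"
#' compose_hub(TRUE, "mixed_sediment_hard", "")  # "AA.M"
#' @export
compose_hub <- function(photic, substrate, community = "", uncertain = FALSE) {
  map <- c(mud = "H", sand = "J", coarse_sediment = "I",
           mixed_sediment_hard = "M", peat = "G", unknown = "?")
  if (any(substrate == "rock_biogenic_reef", na.rm = TRUE)) {
    stop("no HUB substrate letter for rock_biogenic_reef: only peat bottoms ",
         "enter the reef category (as a peat + mussel union code)",
         call. = FALSE)
  }
  bad <- setdiff(unique(substrate), c(names(map), NA))
  if (length(bad)) {
    stop("unknown substrate(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  n <- max(length(photic), length(substrate), length(community))
  photic <- rep_len(photic, n)
  substrate <- rep_len(substrate, n)
  community <- rep_len(community, n)
  uncertain <- rep_len(uncertain, n)
  community[is.na(community)] <- ""
  out <- paste0(ifelse(photic, "AA", "AB"), ".", map[substrate], community,
                ifelse(uncertain, "?", ""))
  out[is.na(substrate) | is.na(photic)] <- NA_character_
  out
}

#' Catalog of mapped HELCOM HUB biotopes
#'
#' The 84 HUB biotope codes realised in the German Baltic Sea mapping,
#' including union codes (`+`), unclassifiable-substrate codes (`?`
#' substrate letter) and uncertain assignments (`?` suffix). Used as the
#' label vocabulary of the synthetic community rules and as the round-trip
#' fixture for the grammar.
#'
#' @return character vector of HUB code strings.
#' @export
hub_catalog <- function() {
  c("AA.?", "AB.?", "AA.?1E1", "AA.?3", "AA.?3L3", "AB.?3L3", "AA.?3L4",
    "AA.?3L9", "AA.M", "AB.M", "AA.M1", "AB.M1", "AA.M1C1", "AA.M1C2",
    "AA.M1C3", "AB.M1C3", "AA.M1C5", "AA.M1E1", "AA.M1E1?", "AB.M1E1",
    "AA.M1G1", "AB.M1G1", "AA.M1H2", "AB.M1I1", "AA.M1S1", "AA.M1V",
    "AB.M1V", "AA.M2T", "AB.M2T", "AB.M4U", "AA.G+AA.J1E1", "AA.I",
    "AA.I1E1", "AA.I1E1?", "AB.I1E1", "AA.I1C3", "AA.I3", "AB.I3",
    "AA.I3L3", "AB.I3L3", "AA.I3L4", "AA.I3L9", "AB.I3L9", "AA.I3L10",
    "AB.I3L10", "AA.I3L11", "AB.I3M6", "AA.J", "AB.J", "AA.J1B7",
    "AA.J1E1", "AB.J1E1", "AA.J1S", "AA.J3", "AB.J3", "AA.J3L1",
    "AB.J3L1", "AA.J3L3", "AB.J3L3", "AA.J3L4", "AB.J3L4", "AA.J3L9",
    "AB.J3L9", "AA.J3L10", "AB.J3L10", "AA.J3L11", "AA.J3M6", "AB.J3M6",
    "AA.H1B7", "AA.H1E1", "AB.H1E1", "AA.H1S", "AA.H3", "AB.H3",
    "AB.H3L1", "AA.H3L3", "AB.H3L3", "AA.H3L4", "AB.H3L4", "AA.H3L9",
    "AB.H3L9", "AA.H3L10", "AB.H3L10", "AB.H3M6")
}
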