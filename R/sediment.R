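#' Sediment classification: BSH levels, Folk triangle, Figge sands, EUNIS
#'
#' Grain-size compositions are mass fractions of mud (< 63 um), sand
#' (0.063-2 mm) and gravel (> 2 mm) summing to one, optionally with sand
#' subfractions (fine 0.063-0.25 mm, medium 0.25-0.5 mm, coarse 0.5-2 mm,
#' each expressed as a fraction of the total sample) and an areal hard-cover
#' percentage (rock/boulder cover of the sea floor, 0-100). Mass fractions
#' and areal cover are never mixed arithmetically: hard cover, when known,
#' takes precedence over granulometry in the EUNIS rules.
#'
#' @name sediment-classification
NULL

.frac_tol <- 1e-9

#' EUNIS substrate thresholds
#'
#' Fixed constants of the EUNIS substrate definition used for broad habitat
#' types: muddy sediment at >= 20 % fines; coarse sediment when gravel
#' exceeds 30 % of the combined gravel and sand fraction; sand when sand
#' exceeds 70 % of that combined fraction; mixed sediment at 10-90 % hard
#' cover; pure substrate classes (including rock and biogenic reef) above
#' 90 % cover.
#'
#' @return a named list of thresholds (percent).
#' @export
eunis_thresholds <- function() {
  list(mud_min_pct = 20, gravel_share_min_pct = 30, sand_share_min_pct = 70,
       mixed_hard_min_pct = 10, mixed_hard_max_pct = 90, pure_min_pct = 90)
}

#' Validate a grain-size composition
#'
#' @param mud,sand,gravel numeric vectors of mass fractions in \[0, 1\].
#' @param fine,medium,coarse optional sand subfractions (of the total mass).
#' @param hard_cover_pct optional areal hard cover in \[0, 100\] (NA allowed).
#' @return invisibly TRUE; stops with an informative error otherwise.
#' @export
validate_composition <- function(mud, sand, gravel,
                                 fine = NULL, medium = NULL, coarse = NULL,
                                 hard_cover_pct = NULL) {
  n <- length(mud)
  if (length(sand) != n || length(gravel) != n) {
    stop("mud, sand and gravel must have equal length", call. = FALSE)
  }
  all01 <- function(x) all(is.na(x) | (x >= -.frac_tol & x <= 1 + .frac_tol))
  if (!all01(mud) || !all01(sand) || !all01(gravel)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  bad <- which(abs(mud + sand + gravel - 1) > .frac_tol)
  if (length(bad)) {
    stop(sprintf("mud + sand + gravel must sum to 1 (row %d sums to %.12f)",
                 bad[1], (mud + sand + gravel)[bad[1]]), call. = FALSE)
  }
  if (!is.null(fine)) {
    sub <- fine + medium + coarse
    bad <- which(!is.na(sub) & abs(sub - sand) > 1e-6)
    if (length(bad)) {
      stop(sprintf(
        "sand subfractions must sum to the sand fraction (row %d: %.6f vs %.6f)",
        bad[1], sub[bad[1]], sand[bad[1]]), call. = FALSE)
    }
  }
  if (!is.null(hard_cover_pct)) {
    h <- hard_cover_pct
    if (any(!is.na(h) & (h < 0 | h > 100))) {
      stop("hard_cover_pct must lie in [0, 100]", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Classify a composition on the simplified Folk triangle (BSH levels A and B)
#'
#' Uses the canonical Folk triangle with gravel tiers < 5, 5-30, 30-80 and
#' > 80 % and sand:mud ratio boundaries 1:9, 1:1 and 9:1. Only clastic
#' classes are returned; peat and lag sediment are not derivable from
#' granulometry.
#'
#' @inheritParams validate_composition
#' @return a data.frame with columns `level_a` (Fsed/S/Csed/MxSed) and
#'   `level_b` (Folk class: M, sM, mS, S, gS, sG, G, gM, msG, mG).
#' @examples
#' classify_folk(1, 0, 0)            # pure mud -> Fsed / M
#' classify_folk(0.05, 0.80, 0.15)   # gravelly sand -> Csed / gS
#' @export
classify_folk <- function(mud, sand, gravel) {
  validate_composition(mud, sand, gravel)
  # boundary comparisons carry a 1e-9 tolerance so that compositions lying
  # mathematically on a class boundary are not misplaced by rounding
  eps <- 1e-9
  r9 <- sand >= 9 * mud - eps        # sand:mud >= 9:1
  r1 <- sand >= mud - eps            # sand:mud >= 1:1
  r19 <- 9 * sand >= mud - eps       # sand:mud >= 1:9
  g <- gravel
  level_b <- character(length(g))
  top <- g >= 0.80 - eps
  mid <- !top & g >= 0.30 - eps
  low <- !top & !mid & g >= 0.05 - eps
  none <- !top & !mid & !low
  level_b[top] <- "G"
  level_b[mid] <- ifelse(r9[mid], "sG", ifelse(r1[mid], "msG", "mG"))
  level_b[low] <- ifelse(r9[low], "gS", ifelse(r1[low], "msG", "gM"))
  level_b[none] <- ifelse(r9[none], "S",
                          ifelse(r1[none], "mS",
                                 ifelse(r19[none], "sM", "M")))
  data.frame(level_a = unname(.folk_to_level_a[level_b]), level_b = level_b,
             stringsAsFactors = FALSE)
}

#' Subdivide sands into BSH level C (Figge) classes
#'
#' A sand is classified by the subfraction holding at least 50 % of the sand
#' mass (fine -> fSa, medium -> mSa, coarse -> cSa); without such a
#' plurality it is a mixed sand (mxSa). Only defined for samples whose Folk
#' level A class is sand.
#'
#' @param fine,medium,coarse sand subfractions as mass fractions of the total
#'   sample.
#' @param level_a BSH level A class of the sample; must be "S".
#' @return character vector of level C classes.
#' @export
classify_figge_sand <- function(fine, medium, coarse, level_a) {
  if (any(level_a != "S")) {
    stop("classify_figge_sand is only defined for level A class 'S'",
         call. = FALSE)
  }
  tot <- fine + medium + coarse
  if (any(tot <= 0)) stop("sand mass must be positive", call. = FALSE)
  ifelse(fine / tot >= 0.5, "fSa",
         ifelse(medium / tot >= 0.5, "mSa",
                ifelse(coarse / tot >= 0.5, "cSa", "mxSa")))
}

#' Classify a composition into an EUNIS substrate category
#'
#' Rules, in order of precedence: when areal hard cover is known it is tested
#' first (> 90 % -> rock and biogenic reef; 10-90 % inclusive -> mixed
#' sediment). Otherwise granulometry decides: fines >= 20 % -> mud; gravel
#' share of the combined gravel+sand fraction strictly > 30 % -> coarse
#' sediment; sand share strictly > 70 % -> sand. The residual boundary
#' sliver (gravel share exactly 30 %, hence sand share exactly 70 %)
#' satisfies neither strict criterion and is returned as mixed sediment,
#' with attribute `residual` marking the affected rows.
#'
#' @inheritParams validate_composition
#' @param thresholds threshold set, see [eunis_thresholds()].
#' @return character vector of EUNIS substrate categories.
#' @examples
#' classify_eunis(0.25, 0.75, 0)  # "mud"
#' classify_eunis(0.19, 0.81 * 0.65, 0.81 * 0.35)  # "coarse_sediment"
#' @export
classify_eunis <- function(mud, sand, gravel, hard_cover_pct = NULL,
                           thresholds = eunis_thresholds()) {
  validate_composition(mud, sand, gravel, hard_cover_pct = hard_cover_pct)
  n <- length(mud)
  out <- rep(NA_character_, n)
  th <- thresholds
  h <- if (is.null(hard_cover_pct)) rep(NA_real_, n) else hard_cover_pct
  hard_known <- !is.na(h)
  out[hard_known & h > th$pure_min_pct] <- "rock_biogenic_reef"
  out[hard_known & h >= th$mixed_hard_min_pct &
        h <= th$mixed_hard_max_pct] <- "mixed_sediment_hard"

  todo <- is.na(out)
  mud_pct <- mud * 100
  out[todo & mud_pct >= th$mud_min_pct - 1e-9] <- "mud"

  todo <- is.na(out)
  gs <- gravel + sand
  if (any(todo & gs <= 0)) {
    stop("gravel + sand is zero with fines below the mud threshold: ",
         "substrate shares undefined", call. = FALSE)
  }
  # strict thresholds with a 1e-9 tolerance: a share mathematically equal
  # to the boundary never counts as exceeding it
  eps <- 1e-9
  gravel_share <- ifelse(gs > 0, gravel / gs * 100, NA_real_)
  sand_share <- ifelse(gs > 0, sand / gs * 100, NA_real_)
  out[todo & gravel_share > th$gravel_share_min_pct + eps] <-
    "coarse_sediment"
  todo <- is.na(out)
  out[todo & sand_share > th$sand_share_min_pct + eps] <- "sand"
  residual <- is.na(out)
  # the boundary sliver (gravel share exactly 30 = sand share exactly 70)
  # satisfies neither strict criterion; classed as mixed sediment so that
  # the strict coarse/sand thresholds stay exact, and flagged
  out[residual] <- "mixed_sediment_hard"
  if (any(residual)) attr(out, "residual") <- which(residual)
  out
}

#' Translate Tauber soft-bottom map classes to EUNIS substrates
#'
#' The interpolated regional sediment map uses descriptive grain-size spans;
#' each maps to exactly one EUNIS substrate category.
#'
#' @param tauber_class character vector of map classes.
#' @return character vector of EUNIS substrate categories.
#' @export
translate_tauber <- function(tauber_class) {
  map <- c("gravel, very coarse sand" = "coarse_sediment",
           "fine sand-coarse sand" = "sand",
           "very fine mud-very fine sand" = "mud",
           "clay, peat, lag sediment/till" = "mixed_sediment_hard")
  # tolerate en-dash / em-dash variants of the span separator
  key <- gsub("–|—", "-", tauber_class)
  bad <- setdiff(unique(key), names(map))
  if (length(bad)) {
    stop("unknown Tauber class(es): ", paste(bad, collapse = "; "),
         "\nvalid classes: ", paste(names(map), collapse = "; "),
         call. = FALSE)
  }
  unname(map[key])
}

#' Classify a table of grain-size samples
#'
#' Applies [classify_folk()], [classify_figge_sand()] and [classify_eunis()]
#' to a sample table and appends the classification columns. This is the
#' engine behind the `classify-sediment` command.
#'
#' @param samples data.frame with columns `sample_id`, `mud`, `sand`,
#'   `gravel` and optionally `fine`, `medium`, `coarse`, `hard_cover_pct`.
#' @return the input with appended columns `bsh_a`, `bsh_b`, `bsh_c`,
#'   `folk` and `eunis`.
#' @export
classify_sediment_table <- function(samples) {
  req <- c("sample_id", "mud", "sand", "gravel")
  miss <- setdiff(req, names(samples))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  hc <- if ("hard_cover_pct" %in% names(samples)) samples$hard_cover_pct
        else NULL
  folk <- classify_folk(samples$mud, samples$sand, samples$gravel)
  samples$bsh_a <- folk$level_a
  samples$bsh_b <- folk$level_b
  samples$bsh_c <- "not classified"
  is_sand <- folk$level_a == "S"
  if (any(is_sand) && all(c("fine", "medium", "coarse") %in% names(samples))) {
    validate_composition(samples$mud, samples$sand, samples$gravel,
                         samples$fine, samples$medium, samples$coarse)
    samples$bsh_c[is_sand] <- classify_figge_sand(
      samples$fine[is_sand], samples$medium[is_sand],
      samples$coarse[is_sand], folk$level_a[is_sand])
  }
  samples$folk <- folk$level_b
  samples$eunis <- as.vector(classify_eunis(samples$mud, samples$sand,
                                            samples$gravel, hc))
  samples
}
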