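#' Readers and writers for the pipeline's plain-text formats
#'
#' Grids travel as ESRI ASCII rasters (numeric, or categorical via an
#' integer-code grid plus a legend CSV), tables as CSV, results as JSON and
#' polygons as GeoJSON (see [read_geojson_polygons()]). All round-trip:
#' `read(write(x))` reproduces `x`.
#'
#' @name pipeline-io
NULL

#' Write a numeric matrix as an ESRI ASCII grid
#'
#' @param m numeric matrix (row 1 = north).
#' @param path output file.
#' @param geom a [grid_geometry()].
#' @param nodata NODATA sentinel value.
#' @export
write_ascii_grid <- function(m, path, geom, nodata = -9999) {
  stopifnot(nrow(m) == geom$nrow, ncol(m) == geom$ncol)
  header <- c(paste("ncols", geom$ncol), paste("nrows", geom$nrow),
              paste("xllcorner", geom$xmin), paste("yllcorner", geom$ymin),
              paste("cellsize", geom$cell_size),
              paste("NODATA_value", nodata))
  body <- apply(m, 1, function(r) {
    r[is.na(r)] <- nodata
    paste(format(r, trim = TRUE, scientific = FALSE, digits = 15),
          collapse = " ")
  })
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path input file.
#' @return numeric matrix with attribute `geom` (a [grid_geometry()]).
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(trimws(lines[1:6]), "\\s+")
  hdr <- stats::setNames(vapply(kv, function(x) as.numeric(x[2]),
                                numeric(1)),
                         tolower(vapply(kv, `[`, character(1), 1)))
  nr <- as.integer(hdr[["nrows"]])
  nc <- as.integer(hdr[["ncols"]])
  vals <- unlist(lapply(lines[-(1:6)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  if (length(vals) != nr * nc) {
    stop("ASCII grid body has ", length(vals), " values, expected ",
         nr * nc, call. = FALSE)
  }
  m <- matrix(vals, nr, nc, byrow = TRUE)
  m[m == hdr[["nodata_value"]]] <- NA
  attr(m, "geom") <- grid_geometry(hdr[["xllcorner"]], hdr[["yllcorner"]],
                                   nr, nc, hdr[["cellsize"]])
  m
}

#' Write/read a categorical grid as integer codes plus a legend CSV
#'
#' The legend holds the code-to-class bijection; classes are coded in sorted
#' order for stability.
#'
#' @param m character matrix.
#' @param path grid file (its legend lands at `<path>.legend.csv`).
#' @inheritParams write_ascii_grid
#' @export
write_class_grid <- function(m, path, geom) {
  classes <- sort(unique(as.vector(m[!is.na(m)])))
  codes <- matrix(match(m, classes), nrow(m), ncol(m))
  write_ascii_grid(codes, path, geom)
  utils::write.csv(data.frame(code = seq_along(classes), class = classes,
                              stringsAsFactors = FALSE),
                   paste0(path, ".legend.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_class_grid
#' @export
read_class_grid <- function(path) {
  codes <- read_ascii_grid(path)
  legend <- utils::read.csv(paste0(path, ".legend.csv"),
                            stringsAsFactors = FALSE)
  m <- matrix(legend$class[match(codes, legend$code)], nrow(codes),
              ncol(codes))
  attr(m, "geom") <- attr(codes, "geom")
  m
}

#' Read a CSV with a required schema
#'
#' @param path CSV file.
#' @param required character vector of required column names.
#' @return data.frame; stops naming any missing column.
#' @export
read_csv_schema <- function(path, required) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("schema error in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df
}
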