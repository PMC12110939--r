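#' @include elevation-grid.R
NULL

#' Options for reading elevation grid exports
#'
#' Device exports vary by locale and firmware: comma- or semicolon-separated,
#' decimal point or decimal comma, optional leading metadata lines, values in
#' micrometers or millimeters, and several encodings of missing points.
#'
#' @param n expected grid size (default 140); NULL to accept whatever square
#'   size the file has.
#' @param spacing grid step in mm.
#' @param center apex (row, col) index or NULL for the geometric center.
#' @param skip number of leading metadata lines to skip.
#' @param sourceUnits "um" (default) or "mm"; mm values are converted to um.
#' @param missingValues tokens read as missing, besides blank cells; the
#'   numeric sentinel -1000 is always treated as missing.
#' @param side,layer metadata for the resulting grid.
#' @return a list of options for [readElevationCsv()].
#' @export
gridReadConfig <- function(n = 140, spacing = 0.1, center = NULL, skip = 0,
                           sourceUnits = c("um", "mm"),
                           missingValues = c("", "NA", "NaN"),
                           side = "OD", layer = "anterior") {
  list(n = n, spacing = spacing, center = center, skip = skip,
       sourceUnits = match.arg(sourceUnits), missingValues = missingValues,
       side = side, layer = layer)
}

# sniff delimiter and decimal mark from the first data line
.sniffDialect <- function(path, skip) {
  lines <- readLines(path, n = skip + 1L, warn = FALSE)
  if (length(lines) <= skip) stop(sprintf("'%s': no data lines found", path))
  first <- lines[skip + 1L]
  if (grepl(";", first, fixed = TRUE)) {
    list(sep = ";", dec = if (grepl(",", first, fixed = TRUE)) "," else ".")
  } else {
    list(sep = ",", dec = ".")
  }
}

#' Read a corneal elevation grid from a delimited text export
#'
#' Accepts comma-separated (decimal point) and semicolon-separated (decimal
#' comma auto-detected) square numeric grids. Blank cells, \code{NA},
#' \code{NaN} and the sentinel value -1000 are read as missing. Any other
#' non-numeric cell is an error naming its row and column; a dimension
#' mismatch is an error naming the expected and found shape.
#'
#' @param path file path.
#' @param config options from [gridReadConfig()].
#' @return an [ElevationGrid-class] with elevations in micrometers.
#' @seealso [writeElevationCsv()]
#' @export
readElevationCsv <- function(path, config = gridReadConfig()) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  d <- .sniffDialect(path, config$skip)
  df <- utils::read.table(path, sep = d$sep, dec = d$dec, skip = config$skip,
                          header = FALSE, colClasses = "character",
                          strip.white = TRUE, blank.lines.skip = FALSE,
                          na.strings = character())
  m <- as.matrix(df)
  if (!is.null(config$n) && !all(dim(m) == config$n)) {
    stop(sprintf("'%s': expected a %d x %d grid, found %d x %d",
                 path, config$n, config$n, nrow(m), ncol(m)))
  }
  if (nrow(m) != ncol(m)) {
    stop(sprintf("'%s': grid must be square, found %d x %d",
                 path, nrow(m), ncol(m)))
  }
  miss <- m %in% config$missingValues | is.na(m)
  if (d$dec == ",") m <- gsub(",", ".", m, fixed = TRUE)
  num <- suppressWarnings(as.numeric(m))
  bad <- which(is.na(num) & !miss)
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(m))
    stop(sprintf("'%s': non-numeric cell '%s' at row %d, column %d",
                 path, m[bad[1]], i[1], i[2]))
  }
  num[miss] <- NA_real_
  num[!is.na(num) & num == -1000] <- NA_real_
  if (config$sourceUnits == "mm") num <- num * 1000
  vals <- matrix(num, nrow(m), ncol(m))
  ElevationGrid(vals, spacing = config$spacing, center = config$center,
                side = config$side, layer = config$layer,
                meta = list(source = path))
}

#' Write an elevation grid as a comma-separated text file
#'
#' Values are written with 8 significant digits (round-trip safe well beyond
#' the 6 required); missing points are written as empty cells.
#'
#' @param grid an [ElevationGrid-class].
#' @param path destination file.
#' @return the path, invisibly.
#' @export
writeElevationCsv <- function(grid, path) {
  v <- grid@values
  txt <- matrix("", nrow(v), ncol(v))
  ok <- !is.na(v)
  txt[ok] <- sprintf("%.8g", v[ok])
  rows <- apply(txt, 1, paste, collapse = ",")
  ok2 <- tryCatch({ writeLines(rows, path); TRUE },
                  error = function(e) stop(sprintf(
                    "cannot write '%s': %s", path, conditionMessage(e))))
  invisible(path)
}

#' Read a cohort manifest
#'
#' The manifest is a CSV with header columns \code{pair_id},
#' \code{od_anterior_path}, \code{os_anterior_path}, \code{od_posterior_path},
#' \code{os_posterior_path}, \code{label}. Posterior paths may be empty.
#' Relative paths are resolved against the manifest's directory. Labels are
#' normalized to lowercase.
#'
#' @param path manifest file.
#' @param checkPaths verify that all referenced files exist (default TRUE).
#' @return data.frame with the manifest columns (paths resolved).
#' @export
readManifest <- function(path, checkPaths = TRUE) {
  if (!file.exists(path)) stop(sprintf("manifest not found: '%s'", path))
  df <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  need <- c("pair_id", "od_anterior_path", "os_anterior_path",
            "od_posterior_path", "os_posterior_path", "label")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop(sprintf("manifest '%s' is missing columns: %s",
                 path, paste(missing, collapse = ", ")))
  }
  dup <- unique(df$pair_id[duplicated(df$pair_id)])
  if (length(dup)) {
    stop(sprintf("manifest '%s' has duplicate pair_id: %s",
                 path, paste(dup, collapse = ", ")))
  }
  df$label <- tolower(df$label)
  base <- dirname(normalizePath(path))
  pcols <- grep("_path$", names(df), value = TRUE)
  for (cc in pcols) {
    rel <- nzchar(df[[cc]]) & !grepl("^(/|[A-Za-z]:)", df[[cc]])
    df[[cc]][rel] <- file.path(base, df[[cc]][rel])
  }
  if (checkPaths) {
    for (cc in pcols) {
      p <- df[[cc]][nzchar(df[[cc]])]
      gone <- p[!file.exists(p)]
      if (length(gone)) {
        stop(sprintf("manifest '%s' references missing file(s): %s",
                     path, paste(gone, collapse = ", ")))
      }
    }
  }
  df
}

#' Write a cohort manifest
#' @param manifest data.frame as returned by [readManifest()] or
#'   [makeCohort()].
#' @param path destination CSV.
#' @return the path, invisibly.
#' @export
writeManifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- JSON reports -----------------------------------------------------------

.zoneReportAsList <- function(rep) {
  list(
    zone = list(diameter_mm = rep@zone@diameter,
                center_offset_mm = rep@zone@center),
    vbs_um = rep@vbs,
    volume_mm3 = rep@volume,
    n_points = rep@nPoints,
    coverage = rep@coverage,
    rings = rep@rings
  )
}

.paramsAsList <- function(p) {
  list(flip = p@flip, dx_mm = p@dx, dy_mm = p@dy, dz_um = p@dz,
       rot_deg = p@rot, tilt_x_um_per_mm = p@tiltX, tilt_y_um_per_mm = p@tiltY)
}

.patternAsList <- function(pat) {
  list(label = pat@label, scores = as.list(pat@scores),
       rms_um = pat@rms, coefficients_um = as.list(pat@coefficients))
}

.groupComparisonAsList <- function(g) {
  list(mean_um = as.list(g@mean), sd_um = as.list(g@sd), n = as.list(g@n),
       mean_difference_um = g@diff, conf_int_95_um = g@confInt,
       t_statistic = g@statistic, df = g@df, p_value = g@pValue)
}

#' Serialize an analysis report to JSON
#'
#' Writes a versioned JSON document containing, for each analyzed pair, the
#' registration parameters, zone reports (VBS, coverage, rings), pattern
#' label, and optionally the cohort screening table and group comparison.
#' All quantities carry unit-suffixed names; undefined rates (e.g. PPV with
#' no positives) are written as JSON null.
#'
#' @param report a [PairAnalysis-class], or a list with any of the elements
#'   \code{analyses} (list of PairAnalysis), \code{screening} (data.frame
#'   from [screenThresholds()]), \code{comparison}
#'   ([GroupComparison-class]), \code{config} (echoed as-is).
#' @param path destination file.
#' @return the path, invisibly.
#' @seealso [readReport()]
#' @export
writeReport <- function(report, path) {
  if (is(report, "PairAnalysis")) report <- list(analyses = list(report))
  doc <- list(schema = "corneaSym-report/1",
              units = list(elevation = "um", length = "mm", vbs = "um"))
  if (!is.null(report$config)) doc$config <- report$config
  if (!is.null(report$analyses)) {
    doc$analyses <- lapply(report$analyses, function(a) {
      list(layer = a@layer,
           registration = .paramsAsList(a@params),
           converged = a@converged,
           zones = lapply(unname(a@reports), .zoneReportAsList),
           pattern = .patternAsList(a@pattern),
           trace = a@trace)
    })
  }
  if (!is.null(report$screening)) doc$screening <- report$screening
  if (!is.null(report$comparison)) {
    doc$group_comparison <- .groupComparisonAsList(report$comparison)
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "rows")
  invisible(path)
}

#' Read back a JSON analysis report
#' @param path file written by [writeReport()].
#' @return the parsed list.
#' @export
readReport <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
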