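#' Read a site table from CSV
#'
#' Reads the documented wadi site-table layout: a `site` column, numeric
#' environmental parameter columns (units as recorded in the field:
#' depth cm, width m, velocity m/s, temperature deg C, pH, EC uS/cm, TDS
#' mg/L, salinity ppt, DO mg/L, BOD mg/L, turbidity NTU), optional
#' substrate fraction columns (`sand`, `silt`, `clay`, `gravel`) and an
#' `abundance` column. Rows with missing required fields are rejected with
#' their row numbers; a negative abundance is a hard error; unknown extra
#' columns are preserved with a warning.
#'
#' @param path CSV file path.
#' @param required columns that must be present and complete (default
#'   `site` and `abundance`).
#' @return data.frame of typed site records.
#' @export
read_site_table <- function(path, required = c("site", "abundance")) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  missing_c <- setdiff(required, names(d))
  if (length(missing_c))
    abort("missing required column(s): ", paste(missing_c, collapse = ", "))
  bad <- which(!complete.cases(d[required]))
  if (length(bad))
    abort("missing required fields in row(s): ", paste(bad, collapse = ", "))
  if (any(d$abundance < 0)) {
    abort("negative abundance in row(s): ",
          paste(which(d$abundance < 0), collapse = ", "))
  }
  known <- c("site", "abundance", "sand", "silt", "clay", "gravel",
             "depth", "width", "velocity", "temperature", "pH", "ec",
             "tds", "salinity", "do", "bod", "turbidity",
             "season", "true_suitability")
  extra <- setdiff(names(d), known)
  if (length(extra))
    warning("unknown column(s) preserved: ", paste(extra, collapse = ", "),
            call. = FALSE)
  d
}

#' Write a site table to CSV
#'
#' @param data site table data.frame.
#' @param path output CSV path.
#' @export
write_site_table <- function(data, path) {
  write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' Parses the 6-line ESRI ASCII raster header
#' (`ncols`/`nrows`/`xllcorner`/`yllcorner`/`cellsize`/`NODATA_value`)
#' followed by row-major cell values (first row = northernmost). The
#' `xllcenter`/`yllcenter` dialect is accepted and converted to the
#' canonical corner registration. NODATA cells become `NA`.
#'
#' @param path `.asc` file path.
#' @return object of class `"ascii_grid"`: list with `data` (numeric
#'   matrix, row 1 = top), `xllcorner`, `yllcorner`, `cellsize`,
#'   `nodata_value`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, n = 6L)
  kv <- lapply(strsplit(trimws(lines), "\\s+"), function(p) {
    if (length(p) != 2L) abort("malformed header line: ", paste(p, collapse = " "))
    p
  })
  keys <- tolower(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(vapply(kv, `[`, "", 2L))
  names(vals) <- keys
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% keys)) abort("incomplete ESRI ASCII header")
  cs <- vals[["cellsize"]]
  xll <- if ("xllcorner" %in% keys) vals[["xllcorner"]]
         else if ("xllcenter" %in% keys) vals[["xllcenter"]] - cs / 2
         else abort("missing xllcorner/xllcenter")
  yll <- if ("yllcorner" %in% keys) vals[["yllcorner"]]
         else if ("yllcenter" %in% keys) vals[["yllcenter"]] - cs / 2
         else abort("missing yllcorner/yllcenter")
  nodata <- if ("nodata_value" %in% keys) vals[["nodata_value"]] else -9999
  nc <- as.integer(vals[["ncols"]]); nr <- as.integer(vals[["nrows"]])
  vv <- scan(path, skip = 6L, quiet = TRUE)
  if (length(vv) != nc * nr)
    abort("value count (", length(vv), ") does not match header (",
          nc * nr, ")")
  vv[vv == nodata] <- NA_real_
  structure(list(data = matrix(vv, nrow = nr, ncol = nc, byrow = TRUE),
                 xllcorner = xll, yllcorner = yll, cellsize = cs,
                 nodata_value = nodata),
            class = "ascii_grid")
}

#' Write an ESRI ASCII grid
#'
#' @param grid an `"ascii_grid"` object or a plain numeric matrix.
#' @param path output `.asc` path.
#' @param xllcorner,yllcorner,cellsize,nodata_value header fields used when
#'   `grid` is a bare matrix.
#' @export
write_ascii_grid <- function(grid, path, xllcorner = 0, yllcorner = 0,
                             cellsize = 1, nodata_value = -9999) {
  if (!inherits(grid, "ascii_grid"))
    grid <- structure(list(data = as.matrix(grid), xllcorner = xllcorner,
                           yllcorner = yllcorner, cellsize = cellsize,
                           nodata_value = nodata_value),
                      class = "ascii_grid")
  m <- grid$data
  m[is.na(m)] <- grid$nodata_value
  hdr <- c(paste("ncols", ncol(m)), paste("nrows", nrow(m)),
           paste("xllcorner", format(grid$xllcorner, scientific = FALSE)),
           paste("yllcorner", format(grid$yllcorner, scientific = FALSE)),
           paste("cellsize", format(grid$cellsize, scientific = FALSE)),
           paste("NODATA_value", format(grid$nodata_value,
                                        scientific = FALSE)))
  rows <- apply(m, 1L, function(r)
    paste(format(r, trim = TRUE, scientific = FALSE), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @export
print.ascii_grid <- function(x, ...) {
  cat(sprintf("ESRI ASCII grid: %d rows x %d cols, cellsize %g, %d NODATA cells\n",
              nrow(x$data), ncol(x$data), x$cellsize, sum(is.na(x$data))))
  invisible(x)
}

#' Serialize fitted suitability curves
#'
#' Writes (and reads back, losslessly at full double precision) the curve
#' table of an [hsi_fit()] as CSV with columns
#' `parameter, mu, sigma, low, high`.
#'
#' @param fit an [hsi_fit()] object (or a named list of curves).
#' @param path CSV path.
#' @export
write_curves <- function(fit, path) {
  curves <- if (inherits(fit, "hsi_fit")) fit$curves else fit
  d <- do.call(rbind, lapply(curves, function(cv)
    data.frame(parameter = cv$parameter,
               mu = sprintf("%.17g", cv$mu), sigma = sprintf("%.17g", cv$sigma),
               low = sprintf("%.17g", cv$low),
               high = sprintf("%.17g", cv$high))))
  utils::write.table(d, path, sep = ",", row.names = FALSE, qmethod = "double")
  invisible(path)
}

#' @rdname write_curves
#' @return `read_curves()`: named list of `suitability_curve` objects.
#' @export
read_curves <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  curves <- lapply(seq_len(nrow(d)), function(i)
    structure(list(parameter = d$parameter[i], mu = d$mu[i],
                   sigma = d$sigma[i], low = d$low[i], high = d$high[i],
                   type = "frequency"),
              class = "suitability_curve"))
  names(curves) <- d$parameter
  curves
}
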