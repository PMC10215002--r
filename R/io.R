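#' Read a 2D dose map from disk
#'
#' Supported formats:
#' \describe{
#'   \item{`matrix-text`}{Whitespace-separated floats, one grid row per line.
#'     Header lines prefixed `#` may carry `dx`, `dy`, `x0`, `y0`, `units`
#'     metadata (e.g. `# dx 0.1693`).}
#'   \item{`csv`}{RFC-4180 comma-separated values, no header row.  Metadata
#'     uses the same `#` key-value convention in a companion file
#'     `<path>.meta`.}
#'   \item{`tiff`}{Baseline uncompressed TIFF as produced by flatbed film
#'     scanners in transmission mode.  For RGB scans the requested channel
#'     (conventionally red, the most dose-sensitive one for radiochromic
#'     film) is extracted; no dose calibration is applied -- raw signal
#'     passes through.  Spacing and origin must come from arguments or a
#'     `<path>.meta` sidecar; they are never inferred from dpi implicitly
#'     (150 dpi scans correspond to 25.4/150 = 0.1693 mm per pixel).}
#' }
#'
#' Explicit `spacing`/`origin` arguments override sidecar values.  When
#' neither is given, spacing defaults to 1 mm and the origin centers the
#' grid on the isocenter.
#'
#' @param path Input file path.
#' @param format One of `"matrix-text"`, `"csv"`, `"tiff"`.
#' @param channel For TIFF input: `"red"`, `"green"`, `"blue"`, or `"none"`
#'   (single-channel image).
#' @param spacing,origin Optional overrides, see [dose_map()].
#' @param calibration Optional two-column matrix/data.frame
#'   `(signal, dose)` with strictly monotone signal; when supplied, values
#'   are converted to dose by linear interpolation.  The default applies no
#'   calibration.
#' @return A [dose_map()].
#' @export
read_dose_map <- function(path,
                          format = c("matrix-text", "csv", "tiff"),
                          channel = c("none", "red", "green", "blue"),
                          spacing = NULL, origin = NULL,
                          calibration = NULL) {
  format <- match.arg(format)
  channel <- match.arg(channel)
  if (!file.exists(path)) stop("file not found: ", path)

  side <- list()
  if (format == "matrix-text") {
    lines <- readLines(path)
    side <- parse_sidecar(lines[startsWith(trimws(lines), "#")])
    body <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
    values <- parse_numeric_rows(strsplit(trimws(body), "[[:space:]]+"), path)
  } else if (format == "csv") {
    meta_path <- paste0(path, ".meta")
    if (file.exists(meta_path)) side <- parse_sidecar(readLines(meta_path))
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    values <- parse_numeric_rows(strsplit(lines, ",", fixed = TRUE), path)
  } else { # tiff
    meta_path <- paste0(path, ".meta")
    if (file.exists(meta_path)) side <- parse_sidecar(readLines(meta_path))
    img <- read_tiff_image(path)
    if (channel == "none") {
      if (dim(img)[3L] != 1L)
        stop("multi-channel TIFF: specify channel = red/green/blue")
      values <- img[, , 1L]
    } else {
      if (dim(img)[3L] < 3L)
        stop("channel '", channel, "' requested on a ",
             dim(img)[3L], "-channel image")
      values <- img[, , c(red = 1L, green = 2L, blue = 3L)[[channel]]]
    }
  }

  if (is.null(spacing)) {
    if (!is.null(side$dx) || !is.null(side$dy))
      spacing <- c(side$dx %||% side$dy, side$dy %||% side$dx)
    else spacing <- c(1, 1)
  }
  if (is.null(origin) && (!is.null(side$x0) || !is.null(side$y0)))
    origin <- c(side$x0 %||% 0, side$y0 %||% 0)

  if (!is.null(calibration)) values <- apply_calibration(values, calibration)

  meta <- side[setdiff(names(side), c("dx", "dy", "x0", "y0"))]
  dose_map(values, spacing, origin, meta)
}

#' Write a dose map to disk
#'
#' Serializes at full precision (17 significant digits) so that
#' write-then-read round-trips bit-exactly.  `matrix-text` carries the
#' spacing/origin sidecar as `#` header lines; `csv` writes them to a
#' companion `<path>.meta` file.
#'
#' @param map A [dose_map()].
#' @param path Output file path.
#' @param format `"matrix-text"` or `"csv"`.
#' @export
write_dose_map <- function(map, path, format = c("matrix-text", "csv")) {
  format <- match.arg(format)
  stopifnot(is_dose_map(map))
  v <- map$values
  if (!all(is.finite(v))) { # defensive: constructor forbids this
    bad <- which(!is.finite(v), arr.ind = TRUE)[1L, ]
    stop(sprintf("refusing to write non-finite value at pixel (row %d, col %d)",
                 bad[1L], bad[2L]))
  }
  header <- c(sprintf("# dx %.17g", map$spacing[1L]),
              sprintf("# dy %.17g", map$spacing[2L]),
              sprintf("# x0 %.17g", map$origin[1L]),
              sprintf("# y0 %.17g", map$origin[2L]))
  if (!is.null(map$meta$units)) header <- c(header,
                                            paste("# units", map$meta$units))
  sep <- if (format == "csv") "," else " "
  rows <- apply(v, 1L, function(r) paste(sprintf("%.17g", r), collapse = sep))
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "matrix-text") writeLines(c(header, rows), con)
  else {
    writeLines(rows, con)
    writeLines(header, paste0(path, ".meta"))
  }
  invisible(path)
}

#' Read / write 1D profiles as CSV
#'
#' Profiles are exchanged as two-column CSV `position_mm,value`;
#' perturbation profiles as `position_mm,delta_percent`.  A header row is
#' written and tolerated on input.
#'
#' @param profile A [dose_profile()] or [perturbation_profile()].
#' @param path File path.
#' @return `read_profile()` returns a profile of the class indicated by the
#'   header (falling back to `dose_profile`).
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "dose_profile"))
  is_pp <- inherits(profile, "perturbation_profile")
  df <- data.frame(position_mm = profile$positions,
                   value = profile$values)
  names(df)[2L] <- if (is_pp) "delta_percent" else "value"
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  df <- utils::read.csv(path)
  if (ncol(df) < 2L) stop("profile CSV needs two columns: ", path)
  if (names(df)[2L] == "delta_percent")
    perturbation_profile(df[[1L]], df[[2L]])
  else dose_profile(df[[1L]], df[[2L]])
}

# ---- helpers ---------------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_sidecar <- function(lines) {
  out <- list()
  for (ln in lines) {
    ln <- sub("^[[:space:]]*#[[:space:]]*", "", ln)
    parts <- strsplit(trimws(ln), "[[:space:]:=]+")[[1L]]
    if (length(parts) < 2L) next
    key <- parts[1L]
    val <- paste(parts[-1L], collapse = " ")
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (is.na(num)) val else num
  }
  out
}

parse_numeric_rows <- function(tokens, path) {
  ncols <- lengths(tokens)
  if (length(unique(ncols)) != 1L)
    stop(sprintf("non-rectangular matrix in %s: rows have %s columns",
                 path, paste(unique(ncols), collapse = "/")))
  n <- ncols[1L]
  vals <- suppressWarnings(as.numeric(unlist(tokens)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1L]
    stop(sprintf("non-numeric cell at row %d, column %d in %s",
                 (bad - 1L) %/% n + 1L, (bad - 1L) %% n + 1L, path))
  }
  matrix(vals, nrow = length(tokens), ncol = n, byrow = TRUE)
}

apply_calibration <- function(values, calibration) {
  cal <- as.data.frame(calibration)
  if (ncol(cal) < 2L || nrow(cal) < 2L)
    stop("calibration needs >= 2 rows of (signal, dose)")
  sig <- as.numeric(cal[[1L]]); dose <- as.numeric(cal[[2L]])
  o <- order(sig)
  sig <- sig[o]; dose <- dose[o]
  if (any(diff(sig) <= 0)) stop("calibration signal must be strictly monotone")
  out <- stats::approx(sig, dose, xout = values, rule = 2)$y
  matrix(out, nrow = nrow(values))
}
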