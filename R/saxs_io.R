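#' Construct a 1-D SAXS scattering curve
#'
#' A `scattering_curve` holds one buffer-subtracted or raw 1-D SAXS profile:
#' momentum transfer `q` (\eqn{\AA^{-1}}, with \eqn{q = 4\pi \sin\theta /
#' \lambda}), intensity `I(q)` in arbitrary units, and an optional per-point
#' uncertainty `sigma`.
#'
#' @param q Numeric vector of momentum transfer values, strictly increasing,
#'   all positive (\eqn{\AA^{-1}}).
#' @param intensity Numeric vector of intensities, same length as `q`.
#' @param sigma Optional numeric vector of per-point uncertainties (strictly
#'   positive, same length), or `NULL`.
#' @param meta Named list of frame metadata (label, well, frame index,
#'   frame time in s, exposure duration in s, wavelength in \eqn{\AA}).
#' @return An object of class `scattering_curve`.
#' @export
scattering_curve <- function(q, intensity, sigma = NULL, meta = list()) {
  q <- as.numeric(q)
  intensity <- as.numeric(intensity)
  if (length(q) < 3L) stop("a scattering curve needs at least 3 points")
  if (length(intensity) != length(q)) stop("q and intensity lengths differ")
  if (anyNA(q) || anyNA(intensity)) stop("q and intensity must be finite")
  if (any(q <= 0)) stop("q values must be positive")
  dq <- diff(q)
  if (any(dq <= 0)) {
    bad <- which(dq <= 0)[1L] + 1L
    stop(sprintf("q must be strictly increasing (violated at row %d)", bad))
  }
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q)) stop("sigma length differs from q")
    if (anyNA(sigma) || any(sigma <= 0)) stop("sigma must be strictly positive")
  }
  if (any(q > 2)) {
    warning("q values exceed 2; q is interpreted as Å^-1 (not nm^-1)")
  }
  structure(list(q = q, intensity = intensity, sigma = sigma,
                 meta = as.list(meta)),
            class = "scattering_curve")
}

#' @export
print.scattering_curve <- function(x, ...) {
  cat(sprintf("<scattering_curve> %d points, q in [%.4g, %.4g] A^-1%s\n",
              length(x$q), min(x$q), max(x$q),
              if (is.null(x$sigma)) ", no sigma" else ""))
  if (!is.null(x$meta$label)) cat("  label:", x$meta$label, "\n")
  if (!is.null(x$meta$time)) cat("  frame time:", x$meta$time, "s\n")
  invisible(x)
}

#' @export
length.scattering_curve <- function(x) length(x$q)

#' Construct a time-ordered series of frames for one well
#'
#' @param curves List of [scattering_curve()] objects with strictly increasing
#'   frame times in `meta$time`.
#' @param label Sample label for the series.
#' @return A `frame_series` object with fields `label`, `curves`, `times` and
#'   `common_grid` (TRUE when all frames share an identical q grid).
#' @export
frame_series <- function(curves, label = NULL) {
  if (length(curves) < 1L) stop("a frame series needs at least one frame")
  times <- vapply(curves, function(cv) {
    tm <- cv$meta$time
    if (is.null(tm)) NA_real_ else as.numeric(tm)
  }, numeric(1))
  if (anyNA(times)) stop("every frame needs a meta$time (s)")
  if (is.unsorted(times, strictly = TRUE)) {
    ord <- order(times)
    curves <- curves[ord]
    times <- times[ord]
    if (anyDuplicated(times)) stop("frame times must be strictly increasing")
  }
  q0 <- curves[[1L]]$q
  common <- all(vapply(curves, function(cv) {
    length(cv$q) == length(q0) && all(cv$q == q0)
  }, logical(1)))
  structure(list(label = label, curves = curves, times = times,
                 common_grid = common),
            class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  cat(sprintf("<frame_series> '%s': %d frames, t = %.3g..%.3g s%s\n",
              if (is.null(x$label)) "?" else x$label, length(x$curves),
              min(x$times), max(x$times),
              if (x$common_grid) ", common q grid" else ""))
  invisible(x)
}

#' @export
length.frame_series <- function(x) length(x$curves)

#' Read a 1-D SAXS profile from a .dat text file
#'
#' Parses the common 3-column (`q I sigma`) or 2-column (`q I`) whitespace
#' separated text format. Lines starting with `#` are treated as comments; a
#' `# key: value` header written by [write_dat()] is restored into `meta`.
#'
#' @param path Path to the file.
#' @param meta Extra metadata merged into the curve's `meta`.
#' @return A [scattering_curve()].
#' @export
read_dat <- function(path, meta = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  is_comment <- startsWith(trimws(lines), "#")
  header <- lines[is_comment]
  data_lines <- lines[!is_comment]
  if (length(data_lines) < 3L) stop("fewer than 3 data rows in ", path)
  toks <- strsplit(trimws(data_lines), "[ \t]+")
  ncol <- unique(lengths(toks))
  if (length(ncol) != 1L || !ncol %in% c(2L, 3L)) {
    stop("expected 2 or 3 whitespace-separated columns in ", path)
  }
  vals <- suppressWarnings(as.numeric(unlist(toks)))
  if (anyNA(vals)) {
    bad <- which(vapply(toks, function(tk)
      anyNA(suppressWarnings(as.numeric(tk))), logical(1)))[1L]
    stop(sprintf("non-numeric token at data row %d of %s", bad, path))
  }
  m <- matrix(vals, ncol = ncol, byrow = TRUE)
  hmeta <- parse_dat_header(header)
  meta <- utils::modifyList(hmeta, as.list(meta))
  scattering_curve(m[, 1L], m[, 2L],
                   sigma = if (ncol == 3L) m[, 3L] else NULL,
                   meta = meta)
}

# "# key: value" header lines -> named list; numeric values coerced
parse_dat_header <- function(lines) {
  out <- list()
  for (ln in lines) {
    ln <- sub("^\\s*#\\s*", "", ln)
    if (!grepl(":", ln, fixed = TRUE)) next
    key <- trimws(sub(":.*$", "", ln))
    val <- trimws(sub("^[^:]*:", "", ln))
    if (!nzchar(key) || !nzchar(val)) next
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Write a scattering curve to a .dat text file
#'
#' Writes a `# key: value` header from `meta` followed by 3 (or 2, when sigma
#' is absent) numeric columns at 12 significant digits, so a
#' [read_dat()]/[write_dat()] roundtrip preserves values to better than 1e-9
#' relative error.
#'
#' @param curve A [scattering_curve()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_dat <- function(curve, path) {
  stopifnot(inherits(curve, "scattering_curve"))
  hdr <- character(0)
  for (key in names(curve$meta)) {
    val <- curve$meta[[key]]
    if (is.null(val) || length(val) != 1L) next
    if (is.numeric(val)) val <- format(val, digits = 12)
    hdr <- c(hdr, sprintf("# %s: %s", key, val))
  }
  cols <- if (is.null(curve$sigma)) {
    cbind(curve$q, curve$intensity)
  } else {
    cbind(curve$q, curve$intensity, curve$sigma)
  }
  body <- apply(cols, 1L, function(r)
    paste(format(r, digits = 12, scientific = TRUE), collapse = " "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

manifest_roles <- c("sample", "buffer", "monomer-control", "dimer-control")

#' Load a plate manifest and assemble per-well frame series
#'
#' The manifest is a CSV with columns
#' `well,role,compound_id,conc_mM,replicate,path_pattern`; `path_pattern`
#' contains a `{frame}` placeholder expanded with frame indices `1..n` until a
#' file is missing. Frame times default to `frame * exposure` (the first
#' 300-ms frame of a 10-s exposure is labelled t = 0.3 s) unless the .dat
#' header carries a `time` entry.
#'
#' @param manifest_path Path to the manifest CSV.
#' @param base_dir Directory against which relative `path_pattern`s are
#'   resolved; defaults to the manifest's directory.
#' @param exposure Exposure duration per frame (s) used for default frame
#'   times.
#' @param expected_frames Optional expected frame count per well; missing or
#'   extra frames relative to it are reported.
#' @return A list with `sheet` (the validated manifest data.frame), `series`
#'   (named list of [frame_series()], one per well) and `validation` (a
#'   data.frame of missing/extra frames; zero rows when complete).
#' @export
load_manifest <- function(manifest_path, base_dir = dirname(manifest_path),
                          exposure = 0.3, expected_frames = NULL) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  sheet <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  required <- c("well", "role", "compound_id", "conc_mM", "replicate",
                "path_pattern")
  missing_cols <- setdiff(required, names(sheet))
  if (length(missing_cols)) {
    stop("manifest is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(sheet$well)) {
    stop("duplicate well id(s) in manifest: ",
         paste(unique(sheet$well[duplicated(sheet$well)]), collapse = ", "))
  }
  bad_role <- setdiff(unique(sheet$role), manifest_roles)
  if (length(bad_role)) {
    stop("unknown role(s) in manifest: ", paste(bad_role, collapse = ", "))
  }
  if (any(sheet$role == "sample") && !any(sheet$role == "buffer")) {
    stop("manifest has sample wells but no buffer wells")
  }
  series <- list()
  report <- list()
  for (i in seq_len(nrow(sheet))) {
    well <- sheet$well[i]
    pat <- sheet$path_pattern[i]
    curves <- list()
    frame <- 1L
    repeat {
      p <- gsub("{frame}", frame, pat, fixed = TRUE)
      if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(base_dir, p)
      if (!file.exists(p)) break
      cv <- read_dat(p)
      if (is.null(cv$meta$time)) cv$meta$time <- frame * exposure
      if (is.null(cv$meta$exposure)) cv$meta$exposure <- exposure
      cv$meta$frame <- frame
      cv$meta$well <- well
      cv$meta$label <- sheet$compound_id[i]
      curves[[frame]] <- cv
      frame <- frame + 1L
    }
    n_found <- frame - 1L
    if (n_found == 0L) {
      report[[length(report) + 1L]] <-
        data.frame(well = well, frame = NA_integer_, issue = "no frames found")
      next
    }
    # a skipped frame truncates sequential discovery; probe a few beyond
    if (!is.null(expected_frames) && n_found < expected_frames) {
      for (f in seq(n_found + 1L, expected_frames)) {
        p <- gsub("{frame}", f, pat, fixed = TRUE)
        if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(base_dir, p)
        if (file.exists(p)) {
          cv <- read_dat(p)
          if (is.null(cv$meta$time)) cv$meta$time <- f * exposure
          cv$meta$frame <- f
          cv$meta$well <- well
          cv$meta$label <- sheet$compound_id[i]
          curves[[f]] <- cv
        } else {
          report[[length(report) + 1L]] <-
            data.frame(well = well, frame = f, issue = "missing frame")
        }
      }
    }
    curves <- Filter(Negate(is.null), curves)
    series[[well]] <- frame_series(curves, label = sheet$compound_id[i])
  }
  validation <- if (length(report)) {
    do.call(rbind, report)
  } else {
    data.frame(well = character(0), frame = integer(0), issue = character(0))
  }
  list(sheet = sheet, series = series, validation = validation)
}
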