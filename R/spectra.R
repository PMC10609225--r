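# MS/MS spectrum container and readers/writers (MGF + TSV peak-list dialect).
# All spectra are assumed centroided; canonical form is a peak table sorted
# strictly ascending in m/z with near-duplicates (within 1e-6 Th) merged.

#' Construct an MS/MS spectrum
#'
#' @param id Unique text identifier.
#' @param precursor_mz Precursor m/z (Th), > 0.
#' @param mz Numeric vector of fragment m/z values (> 0).
#' @param intensity Numeric vector of intensities (>= 0); `NULL` means
#'   intensities are unknown and defaults to 1 for every peak (ladder logic
#'   never uses them).
#' @param charge Positive integer precursor charge, default 1.
#' @param retention_time Retention time in minutes, optional.
#' @param source Provenance text (file of origin, simulation tag, ...).
#' @return An object of class `msms_spectrum`: list with fields `id`,
#'   `precursor_mz`, `charge`, `retention_time`, `source` and `peaks`
#'   (data.frame `mz`, `intensity`, canonicalized).
#' @examples
#' s <- msms_spectrum("toy", 500.25, mz = c(300.1, 200.05), intensity = c(10, 5))
#' s$peaks  # sorted ascending in m/z
#' @export
msms_spectrum <- function(id, precursor_mz, mz = numeric(0), intensity = NULL,
                          charge = 1L, retention_time = NA_real_, source = "") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("id must be a non-empty string")
  }
  if (!is.numeric(precursor_mz) || length(precursor_mz) != 1L ||
      is.na(precursor_mz) || precursor_mz <= 0) {
    stop("precursor_mz must be a single positive number")
  }
  charge <- as.integer(charge)
  if (is.na(charge) || charge < 1L) stop("charge must be a positive integer")
  if (is.null(intensity)) intensity <- rep(1.0, length(mz))
  if (length(intensity) != length(mz)) {
    stop("mz and intensity must have equal length")
  }
  if (any(!is.finite(mz)) || any(mz <= 0)) stop("peak m/z must be positive")
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    stop("peak intensity must be >= 0")
  }
  peaks <- canonicalize_peaks(data.frame(mz = as.numeric(mz),
                                         intensity = as.numeric(intensity)))
  structure(
    list(id = id, precursor_mz = as.numeric(precursor_mz), charge = charge,
         retention_time = as.numeric(retention_time), source = source,
         peaks = peaks),
    class = "msms_spectrum"
  )
}

#' Canonicalize a peak table
#'
#' Sorts ascending in m/z and merges peaks closer than 1e-6 Th by summing
#' intensities (merged m/z is the intensity-weighted mean). Idempotent.
#'
#' @param peaks data.frame with columns `mz`, `intensity`.
#' @return Canonical peak data.frame.
#' @export
canonicalize_peaks <- function(peaks) {
  if (!nrow(peaks)) {
    return(data.frame(mz = numeric(0), intensity = numeric(0)))
  }
  o <- order(peaks$mz)
  mz <- peaks$mz[o]
  intensity <- peaks$intensity[o]
  grp <- cumsum(c(TRUE, diff(mz) >= 1e-6))
  if (max(grp) < length(mz)) {
    tot <- tapply(intensity, grp, sum)
    wmz <- vapply(split(seq_along(mz), grp), function(ix) {
      w <- intensity[ix]
      if (sum(w) > 0) sum(mz[ix] * w) / sum(w) else mean(mz[ix])
    }, numeric(1))
    mz <- as.numeric(wmz)
    intensity <- as.numeric(tot)
  }
  data.frame(mz = mz, intensity = intensity)
}

#' @export
print.msms_spectrum <- function(x, ...) {
  cat(sprintf("<msms_spectrum> %s  precursor m/z %.4f (%d+)  %d peaks\n",
              x$id, x$precursor_mz, x$charge, nrow(x$peaks)))
  invisible(x)
}

#' Read spectra from a Mascot Generic Format (MGF) file
#'
#' Records are delimited by `BEGIN IONS`/`END IONS`. `PEPMASS=<mz> [<int>]`
#' is required per record; `CHARGE=<n>+` defaults to 1; `TITLE` (or the
#' running record index) becomes the spectrum id. Unknown headers are ignored
#' with a warning. Peaks are canonicalized on read.
#'
#' @param path Path to an MGF file.
#' @return List of [msms_spectrum()] objects (possibly empty).
#' @seealso [write_mgf()]
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(ends < begins)) {
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS in ", path)
  }
  unknown <- character(0)
  spectra <- vector("list", length(begins))
  for (r in seq_along(begins)) {
    block <- lines[seq(begins[r] + 1L, ends[r] - 1L)]
    block_lines <- seq(begins[r] + 1L, ends[r] - 1L)
    pepmass <- NA_real_
    charge <- 1L
    title <- NULL
    mzv <- numeric(0)
    intv <- numeric(0)
    for (k in seq_along(block)) {
      ln <- block[k]
      if (!nzchar(ln) || startsWith(ln, "#")) next
      if (grepl("=", ln, fixed = TRUE)) {
        key <- toupper(sub("=.*$", "", ln))
        val <- sub("^[^=]*=", "", ln)
        if (key == "PEPMASS") {
          pepmass <- suppressWarnings(as.numeric(strsplit(val, "[ \t]+")[[1]][1]))
        } else if (key == "CHARGE") {
          charge <- suppressWarnings(as.integer(gsub("[+ ]", "", val)))
        } else if (key == "TITLE") {
          title <- val
        } else if (!key %in% c("RTINSECONDS", "SCANS")) {
          unknown <- c(unknown, key)
        }
        next
      }
      fields <- strsplit(ln, "[ \t]+")[[1]]
      vals <- suppressWarnings(as.numeric(fields))
      if (anyNA(vals) || !length(vals) %in% c(1L, 2L)) {
        stop(sprintf("malformed MGF record %d: non-numeric peak line %d ('%s')",
                     r, block_lines[k], ln))
      }
      mzv <- c(mzv, vals[1])
      intv <- c(intv, if (length(vals) == 2L) vals[2] else 1.0)
    }
    if (is.na(pepmass)) {
      stop(sprintf("malformed MGF record %d (line %d): missing PEPMASS",
                   r, begins[r]))
    }
    if (is.na(charge) || charge < 1L) charge <- 1L
    spectra[[r]] <- msms_spectrum(
      id = if (is.null(title)) as.character(r) else title,
      precursor_mz = pepmass, mz = mzv, intensity = intv,
      charge = charge, source = path
    )
  }
  if (length(unknown)) {
    warning("ignored unknown MGF headers: ",
            paste(unique(unknown), collapse = ", "))
  }
  spectra
}

#' Write spectra to an MGF file
#'
#' Precursor and fragment masses are written with 6 decimals, so a
#' write-then-read round trip reproduces the canonical form to 1e-6.
#'
#' @param spectra List of [msms_spectrum()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open for writing: ", path)
  })
  on.exit(close(con))
  for (s in spectra) {
    stopifnot(inherits(s, "msms_spectrum"))
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", s$id), con)
    writeLines(sprintf("PEPMASS=%.6f", s$precursor_mz), con)
    writeLines(sprintf("CHARGE=%d+", s$charge), con)
    if (nrow(s$peaks)) {
      writeLines(sprintf("%.6f %.6f", s$peaks$mz, s$peaks$intensity), con)
    }
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

#' Read a single spectrum from the TSV peak-list dialect
#'
#' A two-column numeric table (mz, intensity; the intensity column may be
#' omitted) preceded by `#precursor=<mz>` and optionally `#id=`,
#' `#charge=` header lines. This is the format used to encode published
#' peak lists as plain-text fixtures.
#'
#' @param path Path to a peak-list TSV.
#' @return One [msms_spectrum()].
#' @export
read_peaklist_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  hdr <- lines[startsWith(lines, "#")]
  dat <- lines[!startsWith(lines, "#")]
  get_hdr <- function(key) {
    hit <- grep(paste0("^#", key, "="), hdr, value = TRUE)
    if (!length(hit)) return(NULL)
    sub("^[^=]*=", "", hit[1])
  }
  prec <- get_hdr("precursor")
  if (is.null(prec)) stop("missing '#precursor=' header in ", path)
  id <- get_hdr("id")
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  charge <- get_hdr("charge")
  charge <- if (is.null(charge)) 1L else as.integer(charge)
  mzv <- numeric(0); intv <- numeric(0)
  for (ln in dat) {
    vals <- suppressWarnings(as.numeric(strsplit(ln, "[ \t]+")[[1]]))
    if (anyNA(vals) || !length(vals) %in% c(1L, 2L)) {
      stop("non-numeric peak line in ", path, ": '", ln, "'")
    }
    mzv <- c(mzv, vals[1])
    intv <- c(intv, if (length(vals) == 2L) vals[2] else 1.0)
  }
  msms_spectrum(id = id, precursor_mz = as.numeric(prec), mz = mzv,
                intensity = intv, charge = charge, source = path)
}
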