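# Physical constants. Monoisotopic masses in Da, CODATA 2018 / IUPAC 2021,
# kept to 10 significant figures.
ELEMENT_MASS <- c(
  C = 12.0,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069
)
PROTON_MASS <- 1.007276466
ELECTRON_MASS <- 0.000548579909

#' Monoisotopic element masses used throughout the package
#'
#' @return Named numeric vector of monoisotopic masses (Da) for C, H, N, O, S,
#'   plus the proton and electron masses under names `"proton"` and
#'   `"electron"`.
#' @examples
#' element_masses()[["H"]]
#' @export
element_masses <- function() {
  c(ELEMENT_MASS, proton = PROTON_MASS, electron = ELECTRON_MASS)
}

#' Deoxysugar neutral-loss library
#'
#' The glycosidic losses that generate the diagnostic fragment ladders of
#' anthracycline glycosides: rhodinose (`rho`, C6H10O2, nominal -114 Da),
#' 2-deoxy-L-fucose (`defuc`, C6H10O3, -130 Da) and the innermost amino sugar
#' rhodosamine (`RhN`, C8H15NO2, -157 Da). Exact masses are computed from the
#' element mass table, not transcribed. With `include_dehydro = TRUE`,
#' dehydro variants (residue minus H2, e.g. a double bond in an outermost
#' rhodinose) are appended.
#'
#' @param include_dehydro Append `<name>-2H` variants (residue - H2)?
#' @return A data.frame with columns `name`, `formula`, `exact_mass`
#'   (monoisotopic Da) and `nominal_mass` (integer Da).
#' @examples
#' loss_library()
#' @seealso [detect_ladders()], [read_loss_library()]
#' @export
loss_library <- function(include_dehydro = FALSE) {
  base <- data.frame(
    name = c("rho", "defuc", "RhN"),
    formula = c("C6H10O2", "C6H10O3", "C8H15NO2"),
    nominal_mass = c(114L, 130L, 157L),
    stringsAsFactors = FALSE
  )
  base$exact_mass <- vapply(base$formula, formula_mass, numeric(1))
  if (include_dehydro) {
    deh <- base
    deh$name <- paste0(base$name, "-2H")
    deh$formula <- vapply(base$formula, function(f) {
      counts <- parse_formula(f)
      counts[["H"]] <- counts[["H"]] - 2L
      format_formula(counts)
    }, character(1), USE.NAMES = FALSE)
    deh$exact_mass <- base$exact_mass - 2 * ELEMENT_MASS[["H"]]
    deh$nominal_mass <- base$nominal_mass - 2L
    base <- rbind(base, deh)
  }
  stopifnot(!anyDuplicated(base$name))
  base[, c("name", "formula", "exact_mass", "nominal_mass")]
}

#' Read / write a neutral-loss library as TSV
#'
#' Plain tab-separated representation (columns `name`, `formula`,
#' `exact_mass`, `nominal_mass`) so the loss set can be edited outside R.
#'
#' @param path File path.
#' @return `read_loss_library()` returns the library data.frame;
#'   `write_loss_library()` returns `path` invisibly.
#' @export
read_loss_library <- function(path) {
  lib <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "exact_mass", "nominal_mass")
  if (!all(need %in% names(lib))) {
    stop("loss library must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(lib$name)) stop("duplicate residue names in loss library")
  if (any(abs(lib$exact_mass - lib$nominal_mass) > 0.5)) {
    stop("exact_mass deviates from nominal_mass by more than 0.5 Da")
  }
  lib
}

#' @rdname read_loss_library
#' @param lib A loss-library data.frame as from [loss_library()].
#' @export
write_loss_library <- function(lib, path) {
  write.table(lib, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default mass-difference transforms for analog propagation
#'
#' Small chemical differences routinely observed between members of a
#' polyketide analog family, as signed parent-mass shifts matched by absolute
#' value: oxygenation (O), saturation change (H2), hydration (H2O),
#' methylenation (CH2), acetylation (C2H2O), and gain/loss of one of the three
#' deoxysugar residues. `nominal` is the integer delta the field reports in
#' running text (16, 2, 18, ...).
#'
#' @return data.frame with columns `name`, `delta_mass` (Da, > 0; applied in
#'   both directions) and `nominal` (integer Da).
#' @examples
#' delta_transforms()
#' @seealso [propagate()]
#' @export
delta_transforms <- function() {
  comp <- c(O = "O", H2 = "H2", H2O = "H2O", CH2 = "CH2", C2H2O = "C2H2O",
            rho = "C6H10O2", defuc = "C6H10O3", RhN = "C8H15NO2")
  data.frame(
    name = names(comp),
    delta_mass = vapply(unname(comp), formula_mass, numeric(1)),
    nominal = c(16L, 2L, 18L, 14L, 42L, 114L, 130L, 157L),
    stringsAsFactors = FALSE
  )
}
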