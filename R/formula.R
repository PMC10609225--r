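# Accurate-mass formula arithmetic and bounded CHNOS enumeration.
#
# Convention: even-electron positive ions only. An ion formula's element
# counts describe the ion as written, including any charge-carrying protons
# (C60H87N2O22 with charge 1 is the [M+H]+ cation). The electron mass is
# subtracted, giving the true cation m/z; the 0.00055 Da difference is below
# the reporting precision of the instruments this targets but is kept for
# correctness.

#' Parse an elemental formula string
#'
#' Accepts Hill-style CHNOS strings such as `"C60H87N2O22"`. Only the
#' elements C, H, N, O, S are supported.
#'
#' @param x Formula string.
#' @return Named integer vector over C, H, N, O, S.
#' @examples
#' parse_formula("C6H10O2")
#' @export
parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, nzchar(x))
  m <- gregexpr("[A-Z][a-z]?\\d*", x)[[1]]
  toks <- regmatches(x, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(x)) {
    stop("cannot parse formula: ", x)
  }
  counts <- setNames(integer(5), names(ELEMENT_MASS))
  for (tok in toks) {
    el <- gsub("\\d", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% names(counts)) {
      stop("unsupported element '", el, "' in formula: ", x)
    }
    counts[el] <- counts[el] + n
  }
  counts
}

#' Format element counts as a Hill-order formula string
#'
#' @param counts Named numeric vector with any of C, H, N, O, S.
#' @return Character scalar, e.g. `"C60H87N2O22"`.
#' @export
format_formula <- function(counts) {
  counts <- counts[names(ELEMENT_MASS)[match(names(ELEMENT_MASS), names(counts), nomatch = 0) > 0]]
  full <- setNames(numeric(5), names(ELEMENT_MASS))
  full[names(counts)] <- counts
  parts <- character(0)
  for (el in c("C", "H", "N", "O", "S")) {  # Hill order for organics
    n <- full[[el]]
    if (n > 0) parts <- c(parts, if (n == 1) el else paste0(el, n))
  }
  if (!length(parts)) stop("empty formula")
  paste(parts, collapse = "")
}

# Neutral monoisotopic mass of a formula string (no charge correction).
formula_mass <- function(x) {
  counts <- parse_formula(x)
  sum(counts * ELEMENT_MASS[names(counts)])
}

#' Construct an ion formula
#'
#' @param formula Formula string (counts describe the ion as written,
#'   protons included) or a named count vector.
#' @param charge Positive integer charge (default 1).
#' @return An object of class `ion_formula`: list with `counts` (named
#'   integer vector over CHNOS) and `charge`.
#' @examples
#' ion_formula("C60H87N2O22")            # the [M+H]+ ion of dehydrocosmomycin D
#' theoretical_mz(ion_formula("C60H87N2O22"))
#' @export
ion_formula <- function(formula, charge = 1L) {
  counts <- if (is.character(formula)) parse_formula(formula) else {
    full <- setNames(integer(5), names(ELEMENT_MASS))
    full[names(formula)] <- as.integer(formula)
    full
  }
  charge <- as.integer(charge)
  if (any(counts < 0)) stop("negative element count")
  if (sum(counts) < 1) stop("ion formula needs at least one atom")
  if (is.na(charge) || charge < 1L) stop("charge must be a positive integer")
  structure(list(counts = counts, charge = charge), class = "ion_formula")
}

#' @export
print.ion_formula <- function(x, ...) {
  cat(sprintf("<ion_formula> %s  charge %d+  m/z %.4f\n",
              format_formula(x$counts), x$charge, theoretical_mz(x)))
  invisible(x)
}

#' Theoretical m/z of a positive ion
#'
#' `(sum of atomic masses - charge * electron mass) / charge`, i.e. the true
#' cation mass-to-charge ratio.
#'
#' @param f An [ion_formula()].
#' @return Numeric m/z in Th.
#' @examples
#' theoretical_mz(ion_formula("H"))  # a bare proton: 1.007277
#' @export
theoretical_mz <- function(f) {
  stopifnot(inherits(f, "ion_formula"))
  if (sum(f$counts) < 1) stop("ion formula needs at least one atom")
  m <- sum(f$counts * ELEMENT_MASS[names(f$counts)])
  (m - f$charge * ELECTRON_MASS) / f$charge
}

#' Rings-plus-double-bond equivalents
#'
#' `C - H/2 + N/2 + 1`; O and S contribute nothing. Half-integer values are
#' expected for even-electron cations (the charge-carrying proton is counted
#' in H).
#'
#' @param f An [ion_formula()] or formula string.
#' @return Numeric RDBE (may be half-integer or negative).
#' @examples
#' rdbe(ion_formula("C6H6"))  # benzene radical-free count: 4
#' @export
rdbe <- function(f) {
  counts <- if (inherits(f, "ion_formula")) f$counts else parse_formula(f)
  unname(counts[["C"]] - counts[["H"]] / 2 + counts[["N"]] / 2 + 1)
}

#' Enumerate candidate elemental formulas for an accurate ion mass
#'
#' Exhaustive scan over the bounded CHNOS lattice: every composition whose
#' theoretical m/z lies within `ppm_tol` of the query and whose RDBE and H/C
#' ratio pass the plausibility filters is returned. The scan iterates over
#' (C, N, O, S) and solves for the unique compatible hydrogen counts, which
#' is exact (the ppm window is far narrower than the 1.008 Da hydrogen
#' spacing), so the result equals an unpruned brute force over the full
#' lattice.
#'
#' @param mz Query m/z (Th), > 0.
#' @param charge Positive integer charge; default 1.
#' @param ppm_tol Mass tolerance in ppm; default 5.
#' @param bounds Named vector of per-element maximum counts. Defaults
#'   `c(C = 70, H = 130, N = 6, O = 26, S = 2)` cover glycosylated aromatic
#'   polyketides up to ~1200 Da.
#' @param rdbe_range Length-2 numeric, inclusive RDBE bounds; default
#'   `c(0, 40)`.
#' @param hc_range Inclusive H/C ratio bounds applied when C > 0; default
#'   `c(0.2, 3.2)`.
#' @return data.frame sorted by `abs(ppm_error)` with columns `formula`, the
#'   element counts, `charge`, `theo_mz`, `ppm_error`, `rdbe`. Zero rows if
#'   nothing matches.
#' @examples
#' # the kidamycin epoxide's reported ion, C39H49N2O10 at m/z 705.3298
#' head(enumerate_formulas(705.3298, ppm_tol = 15))
#' @export
enumerate_formulas <- function(mz, charge = 1L, ppm_tol = 5,
                               bounds = c(C = 70, H = 130, N = 6, O = 26, S = 2),
                               rdbe_range = c(0, 40),
                               hc_range = c(0.2, 3.2)) {
  stopifnot(mz > 0, ppm_tol > 0, charge >= 1)
  b <- setNames(rep(0L, 5), names(ELEMENT_MASS))
  b[names(bounds)] <- as.integer(bounds)
  # total atomic mass the composition must account for
  target <- mz * charge + charge * ELECTRON_MASS
  tol_da <- mz * ppm_tol * 1e-6 * charge

  grid <- expand.grid(C = 0:b[["C"]], N = 0:b[["N"]], O = 0:b[["O"]],
                      S = 0:b[["S"]], KEEP.OUT.ATTRS = FALSE)
  rem <- target - (grid$C * ELEMENT_MASS[["C"]] + grid$N * ELEMENT_MASS[["N"]] +
                   grid$O * ELEMENT_MASS[["O"]] + grid$S * ELEMENT_MASS[["S"]])
  keep <- rem >= -tol_da
  grid <- grid[keep, , drop = FALSE]
  rem <- rem[keep]

  h0 <- round(rem / ELEMENT_MASS[["H"]])
  out <- vector("list", 3L)
  for (k in seq(-1L, 1L)) {
    H <- h0 + k
    mass <- grid$C * ELEMENT_MASS[["C"]] + H * ELEMENT_MASS[["H"]] +
      grid$N * ELEMENT_MASS[["N"]] + grid$O * ELEMENT_MASS[["O"]] +
      grid$S * ELEMENT_MASS[["S"]]
    theo <- (mass - charge * ELECTRON_MASS) / charge
    ppm <- (theo - mz) / mz * 1e6
    rd <- grid$C - H / 2 + grid$N / 2 + 1
    ok <- H >= 0 & H <= b[["H"]] &
      abs(ppm) <= ppm_tol &
      rd >= rdbe_range[1] & rd <= rdbe_range[2] &
      (grid$C + H + grid$N + grid$O + grid$S) >= 1 &
      (grid$C == 0 | (H / pmax(grid$C, 1) >= hc_range[1] &
                      H / pmax(grid$C, 1) <= hc_range[2]))
    if (any(ok)) {
      out[[k + 2L]] <- data.frame(
        C = grid$C[ok], H = as.integer(H[ok]), N = grid$N[ok],
        O = grid$O[ok], S = grid$S[ok],
        theo_mz = theo[ok], ppm_error = ppm[ok], rdbe = rd[ok]
      )
    }
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res) || !nrow(res)) {
    return(data.frame(formula = character(0), C = integer(0), H = integer(0),
                      N = integer(0), O = integer(0), S = integer(0),
                      charge = integer(0), theo_mz = numeric(0),
                      ppm_error = numeric(0), rdbe = numeric(0)))
  }
  res <- unique(res)
  res$formula <- apply(res[, c("C", "H", "N", "O", "S")], 1L, function(r) {
    format_formula(setNames(r, c("C", "H", "N", "O", "S")))
  })
  res$charge <- as.integer(charge)
  res <- res[order(abs(res$ppm_error), res$formula), ]
  rownames(res) <- NULL
  res[, c("formula", "C", "H", "N", "O", "S", "charge",
          "theo_mz", "ppm_error", "rdbe")]
}

#' Write a formula candidate table as TSV
#'
#' @param candidates Result of [enumerate_formulas()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_formula_tsv <- function(candidates, path) {
  out <- cbind(rank = seq_len(nrow(candidates)), candidates)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
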