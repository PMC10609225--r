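# Sequential deoxysugar neutral-loss ladder detection.
#
# Anthracycline glycosides dissociate by peeling their sugar chains one
# residue at a time, producing a characteristic cascade of fragment ions
# separated by the residue masses (-114 rhodinose, -130 2-deoxy-L-fucose,
# -157 rhodosamine). A depth-first search from the precursor mass over a
# residue-loss library recovers these cascades and, with them, the glycan
# chain composition of the ion.

#' Detect neutral-loss ladders in a spectrum
#'
#' Depth-first search rooted at the precursor m/z (or, when a peak lies
#' within `tol` of it, at the most intense such peak): at each level and for
#' each library residue, every unused peak within `tol` of
#' `current_mz - residue_mass` opens a branch (candidates ordered
#' closest-mass first). Each maximal root-to-leaf path with at least one
#' step becomes a ladder. In `nominal` mode residue masses are the integer
#' nominal masses (for one-decimal published peak lists); in `exact` mode
#' they are monoisotopic.
#'
#' @param s An [msms_spectrum()].
#' @param lib Loss library data.frame (see [loss_library()]).
#' @param tol Mass tolerance in Da for each step. Published one-decimal
#'   peak lists typically need 0.5 (occasionally wider where printed
#'   roundings are inconsistent); accurate-mass data 0.02-0.03.
#' @param mode `"nominal"` or `"exact"`.
#' @param max_depth Safety cap on ladder length; default 12.
#' @return List of `nl_ladder` objects sorted by (steps descending, total
#'   absolute error ascending); empty list if no step can be taken. Each
#'   ladder has fields `spectrum_id`, `start_mz`, `steps` (data.frame
#'   `from_mz`, `to_mz`, `loss_name`, `observed_delta`, `error`),
#'   `terminal_mz`, `n_steps`.
#' @examples
#' path <- system.file("extdata", "cosmomycin_d.tsv", package = "derepnet")
#' s <- read_peaklist_tsv(path)
#' best_ladder(detect_ladders(s, tol = 0.5, mode = "nominal"))
#' @export
detect_ladders <- function(s, lib = loss_library(), tol = 0.02,
                           mode = c("exact", "nominal"), max_depth = 12L) {
  stopifnot(inherits(s, "msms_spectrum"), tol > 0)
  mode <- match.arg(mode)
  masses <- if (mode == "nominal") as.numeric(lib$nominal_mass) else lib$exact_mass
  names(masses) <- lib$name
  mz <- s$peaks$mz
  intensity <- s$peaks$intensity
  if (!length(mz)) return(list())
  eps <- 1e-9  # guard against representation error at the tolerance boundary

  root <- s$precursor_mz
  used0 <- logical(length(mz))
  near <- which(abs(mz - root) <= tol + eps)
  if (length(near)) {
    anchor <- near[order(-intensity[near], abs(mz[near] - root))][1]
    root <- mz[anchor]
    used0[anchor] <- TRUE
  }

  ladders <- list()
  dfs <- function(current, used, steps, depth) {
    extended <- FALSE
    if (depth < max_depth) {
      for (r in seq_along(masses)) {
        target <- current - masses[r]
        if (target <= 0) next
        cand <- which(!used & abs(mz - target) <= tol + eps)
        if (!length(cand)) next
        cand <- cand[order(abs(mz[cand] - target), mz[cand])]
        for (ci in cand) {
          extended <- TRUE
          step <- data.frame(
            from_mz = current, to_mz = mz[ci],
            loss_name = names(masses)[r],
            observed_delta = current - mz[ci],
            error = (current - mz[ci]) - masses[r],
            stringsAsFactors = FALSE
          )
          used2 <- used; used2[ci] <- TRUE
          dfs(mz[ci], used2, rbind(steps, step), depth + 1L)
        }
      }
    }
    if (!extended && !is.null(steps) && nrow(steps)) {
      ladders[[length(ladders) + 1L]] <<- new_ladder(s$id, steps)
    }
    invisible(NULL)
  }
  dfs(root, used0, NULL, 0L)
  if (!length(ladders)) return(list())
  ladders <- unique_ladders(ladders)
  sort_ladders(ladders)
}

new_ladder <- function(spectrum_id, steps) {
  structure(
    list(spectrum_id = spectrum_id, start_mz = steps$from_mz[1],
         steps = steps, terminal_mz = steps$to_mz[nrow(steps)],
         n_steps = nrow(steps)),
    class = "nl_ladder"
  )
}

ladder_key <- function(l) {
  paste(c(sprintf("%.6f", l$start_mz),
          paste(l$steps$loss_name, sprintf("%.6f", l$steps$to_mz), sep = "@")),
        collapse = "|")
}

unique_ladders <- function(ladders) {
  keys <- vapply(ladders, ladder_key, character(1))
  ladders[!duplicated(keys)]
}

sort_ladders <- function(ladders) {
  n_steps <- vapply(ladders, function(l) l$n_steps, numeric(1))
  tot_err <- vapply(ladders, function(l) sum(abs(l$steps$error)), numeric(1))
  keys <- vapply(ladders, ladder_key, character(1))
  ladders[order(-n_steps, tot_err, keys)]
}

#' @export
print.nl_ladder <- function(x, ...) {
  losses <- paste(sprintf("-%s", x$steps$loss_name), collapse = " ")
  cat(sprintf("<nl_ladder> %s: %.4f -> %.4f  [%d steps: %s]\n",
              x$spectrum_id, x$start_mz, x$terminal_mz, x$n_steps, losses))
  invisible(x)
}

#' Best ladder of a detection result
#'
#' The first ladder after the deterministic sort of [detect_ladders()]
#' (most steps, then smallest total absolute error), or `NULL` on empty
#' input.
#'
#' @param ladders List of `nl_ladder` objects.
#' @return An `nl_ladder` or `NULL`.
#' @export
best_ladder <- function(ladders) {
  if (!length(ladders)) return(NULL)
  sort_ladders(ladders)[[1]]
}

#' Doubly protonated companion m/z
#'
#' The \[M+2H\]2+ m/z of a compound whose \[M+H\]+ is `mh`:
#' `(mh + proton) / 2`. Anthracycline glycosides frequently show this
#' companion in high abundance.
#'
#' @param mh \[M+H\]+ m/z; must exceed the proton mass.
#' @return The \[M+2H\]2+ m/z.
#' @examples
#' charge_companion_mz(1189.5878)  # 595.2975
#' @export
charge_companion_mz <- function(mh) {
  if (any(mh <= PROTON_MASS)) stop("[M+H]+ m/z must exceed the proton mass")
  (mh + PROTON_MASS) / 2
}

#' Find singly/doubly protonated peak pairs in a spectrum
#'
#' Reports every peak pair (p, q) for which q lies within `tol` of
#' [charge_companion_mz()] of p.
#'
#' @param s An [msms_spectrum()].
#' @param tol Tolerance in Da; default 0.02 (use ~0.5 for one-decimal
#'   published peak lists).
#' @return data.frame with columns `mz_1plus`, `mz_2plus`, `error`.
#' @export
find_charge_companions <- function(s, tol = 0.02) {
  stopifnot(inherits(s, "msms_spectrum"), tol > 0)
  mz <- s$peaks$mz
  out <- list()
  for (i in seq_along(mz)) {
    if (mz[i] <= PROTON_MASS) next
    expect <- charge_companion_mz(mz[i])
    hits <- which(abs(mz - expect) <= tol + 1e-9)
    for (h in hits) {
      out[[length(out) + 1L]] <- data.frame(
        mz_1plus = mz[i], mz_2plus = mz[h], error = mz[h] - expect
      )
    }
  }
  if (!length(out)) {
    return(data.frame(mz_1plus = numeric(0), mz_2plus = numeric(0),
                      error = numeric(0)))
  }
  do.call(rbind, out)
}

#' Glycan composition of a ladder
#'
#' Counts of each residue loss along the ladder; the step order is kept in
#' the `"order"` attribute. Positional identity between chains is not
#' resolved (mass-identical residues, e.g. rhodinose vs a dehydroxylated
#' fucose, report the same mass class).
#'
#' @param l An `nl_ladder`.
#' @return Named integer vector of residue counts with attribute `order`
#'   (character vector of losses in ladder order). Empty ladder (or `NULL`)
#'   gives an empty vector.
#' @export
glycan_composition <- function(l) {
  if (is.null(l) || !l$n_steps) {
    out <- integer(0)
    attr(out, "order") <- character(0)
    return(out)
  }
  ord <- l$steps$loss_name
  counts <- table(ord)
  out <- setNames(as.integer(counts), names(counts))
  out <- out[order(names(out))]
  attr(out, "order") <- ord
  out
}

#' Write a ladder report as TSV
#'
#' One row per ladder: spectrum id, start and terminal m/z, the loss path,
#' per-step errors and the composition string.
#'
#' @param ladders List of `nl_ladder` objects (across spectra).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ladder_tsv <- function(ladders, path) {
  rows <- lapply(ladders, function(l) {
    comp <- glycan_composition(l)
    data.frame(
      spectrum_id = l$spectrum_id,
      start_mz = sprintf("%.4f", l$start_mz),
      terminal_mz = sprintf("%.4f", l$terminal_mz),
      n_steps = l$n_steps,
      losses = paste(l$steps$loss_name, collapse = ","),
      path = paste(sprintf("%.4f", c(l$start_mz, l$steps$to_mz)),
                   collapse = ">"),
      errors = paste(sprintf("%.4f", l$steps$error), collapse = ","),
      composition = paste(sprintf("%s:%d", names(comp), comp), collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(spectrum_id = character(0), start_mz = character(0),
               terminal_mz = character(0), n_steps = integer(0),
               losses = character(0), path = character(0),
               errors = character(0), composition = character(0))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
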