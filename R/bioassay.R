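# Turbidometric 96-well antibacterial screening statistic.
#
# Growth inhibition is measured from OD600 readings before (t0) and after
# (t24) incubation, relative to the plate's own negative control:
#   Inhibition % = [1 - (t24 - t0) / (C24 - C0)] * 100
# An inhibition above 60% (strict) calls a well active. The plate is laid
# out as 12 rows x 8 columns: row 1 holds 4 sterility wells (medium only)
# and 4 positive-control wells (levofloxacin), rows 2-11 hold test wells,
# row 12 holds negative-control wells (culture plus solvent).

#' Percent growth inhibition from OD600 readings
#'
#' `[1 - (t24 - t0) / (c24 - c0)] * 100`. Values above 100 (lysis below the
#' starting OD) and below 0 (growth promotion) are possible and are not
#' clamped. Invariant under a common affine rescaling (gain/offset) of all
#' four readings.
#'
#' @param t0,t24 Test-well OD600 before/after incubation.
#' @param c0,c24 Negative-control OD600 before/after incubation (typically
#'   the plate's control mean). The control must have grown: `c24 > c0`.
#' @return Percent inhibition (vectorized).
#' @examples
#' inhibition_percent(0.05, 0.05, 0.05, 0.50)  # no test growth: 100
#' @export
inhibition_percent <- function(t0, t24, c0, c24) {
  if (any(c24 <= c0)) stop("invalid control growth: c24 must exceed c0")
  (1 - (t24 - t0) / (c24 - c0)) * 100
}

#' Default 96-well screening plate layout
#'
#' @param sterility_cols Columns of row 1 holding medium-only sterility
#'   wells; the remaining row-1 columns hold the positive control
#'   (levofloxacin). Default columns 1-4.
#' @return data.frame with columns `row` (1-12), `col` (1-8), `well`
#'   (`"R01C1"` style) and `role` (`sterility`, `positive`, `test`,
#'   `negative`).
#' @export
plate_layout <- function(sterility_cols = 1:4) {
  stopifnot(all(sterility_cols %in% 1:8))
  grid <- expand.grid(col = 1:8, row = 1:12)[, c("row", "col")]
  role <- rep("test", nrow(grid))
  role[grid$row == 1] <- ifelse(grid$col[grid$row == 1] %in% sterility_cols,
                                "sterility", "positive")
  role[grid$row == 12] <- "negative"
  data.frame(row = grid$row, col = grid$col,
             well = sprintf("R%02dC%d", grid$row, grid$col),
             role = role, stringsAsFactors = FALSE)
}

#' Read plate OD readings from long-format CSV
#'
#' Expected columns: `plate_id` (or `replicate`), `row`, `col`, `timepoint`
#' (`t0`/`t24`), `od600`. Rows given as letters A-H are interpreted as a
#' standard landscape plate (A-H x 1-12) and transposed into the 12 x 8
#' screening orientation (letter -> column, number -> row).
#'
#' @param path CSV path.
#' @return Wide data.frame with columns `replicate`, `row`, `col`, `od_t0`,
#'   `od_t24`.
#' @export
read_plate_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("plate_id" %in% names(x) && !"replicate" %in% names(x)) {
    x$replicate <- x$plate_id
  }
  need <- c("replicate", "row", "col", "timepoint", "od600")
  if (!all(need %in% names(x))) {
    stop("plate CSV needs columns: ", paste(need, collapse = ", "))
  }
  if (is.character(x$row) && any(grepl("^[A-Ha-h]$", x$row))) {
    letter <- toupper(x$row)
    x$row <- as.integer(x$col)
    x$col <- match(letter, LETTERS[1:8])
  }
  x$row <- as.integer(x$row); x$col <- as.integer(x$col)
  wide <- merge(
    x[x$timepoint == "t0", c("replicate", "row", "col", "od600")],
    x[x$timepoint == "t24", c("replicate", "row", "col", "od600")],
    by = c("replicate", "row", "col"), suffixes = c("_t0", "_t24")
  )
  names(wide)[names(wide) == "od600_t0"] <- "od_t0"
  names(wide)[names(wide) == "od600_t24"] <- "od_t24"
  wide[order(wide$replicate, wide$row, wide$col), ]
}

#' Validate a plate's controls
#'
#' A replicate plate is invalid if any sterility well grew
#' (`delta OD > sterility_max_delta`, contamination) or if the mean
#' positive-control inhibition falls below `positive_min_inhibition`
#' (assay failure).
#'
#' @param readings Wide readings for one replicate (columns `row`, `col`,
#'   `od_t0`, `od_t24`; a `replicate` column, if present, must hold one
#'   value).
#' @param layout Plate layout data.frame (see [plate_layout()]).
#' @param sterility_max_delta Maximum tolerated sterility-well OD gain;
#'   default 0.05.
#' @param positive_min_inhibition Minimum mean positive-control inhibition
#'   in percent; default 60.
#' @param ctrl_agg Aggregator for the negative-control wells; default
#'   [mean] (use [median] for outlier-robust plates).
#' @return List with `valid` (logical) and `reasons` (character vector,
#'   empty when valid).
#' @export
validate_plate <- function(readings, layout = plate_layout(),
                           sterility_max_delta = 0.05,
                           positive_min_inhibition = 60,
                           ctrl_agg = mean) {
  if ("replicate" %in% names(readings) &&
      length(unique(readings$replicate)) > 1L) {
    stop("validate_plate() expects a single replicate plate")
  }
  r <- merge(layout, readings[, c("row", "col", "od_t0", "od_t24")],
             by = c("row", "col"), all.x = TRUE)
  missing <- r$well[is.na(r$od_t0) | is.na(r$od_t24)]
  if (length(missing)) {
    stop("missing wells: ", paste(sort(missing), collapse = ", "))
  }
  reasons <- character(0)
  ster <- r[r$role == "sterility", ]
  if (any(ster$od_t24 - ster$od_t0 > sterility_max_delta)) {
    reasons <- c(reasons, "contamination")
  }
  neg <- r[r$role == "negative", ]
  c0 <- ctrl_agg(neg$od_t0); c24 <- ctrl_agg(neg$od_t24)
  if (c24 <= c0) {
    reasons <- c(reasons, "no control growth")
  } else {
    pos <- r[r$role == "positive", ]
    pos_inh <- mean(inhibition_percent(pos$od_t0, pos$od_t24, c0, c24))
    if (pos_inh < positive_min_inhibition) {
      reasons <- c(reasons, "assay failure")
    }
  }
  list(valid = !length(reasons), reasons = reasons)
}

#' Call antibacterial activity per sample
#'
#' For each replicate plate, test-well inhibition is computed against that
#' plate's own negative-control aggregate; per-sample inhibition is the
#' mean over replicates, and a sample is active when it exceeds `threshold`
#' (strict inequality: "above 60%").
#'
#' @param readings Wide readings across replicates (columns `replicate`,
#'   `row`, `col`, `od_t0`, `od_t24`).
#' @param samples Mapping of test wells to samples: data.frame with `row`,
#'   `col`, `strain`, `medium`, `pathogen`.
#' @param layout Plate layout; default [plate_layout()].
#' @param threshold Activity threshold in percent; default 60.
#' @param ctrl_agg Negative-control aggregator; default [mean].
#' @return data.frame with one row per sample: `strain`, `medium`,
#'   `pathogen`, `inhibition_pct` (replicate mean), `n_replicates`,
#'   `active`.
#' @export
call_activity <- function(readings, samples, layout = plate_layout(),
                          threshold = 60, ctrl_agg = mean) {
  stopifnot(all(c("replicate", "row", "col", "od_t0", "od_t24") %in%
                  names(readings)),
            all(c("row", "col", "strain", "medium", "pathogen") %in%
                  names(samples)))
  test_wells <- layout[layout$role == "test", c("row", "col")]
  bad <- !paste(samples$row, samples$col) %in%
    paste(test_wells$row, test_wells$col)
  if (any(bad)) {
    stop("samples mapped to non-test wells: ",
         paste(sprintf("R%02dC%d", samples$row[bad], samples$col[bad]),
               collapse = ", "))
  }
  neg_wells <- layout[layout$role == "negative", c("row", "col")]
  per_rep <- list()
  for (rep_id in sort(unique(readings$replicate))) {
    plate <- readings[readings$replicate == rep_id, , drop = FALSE]
    neg <- merge(neg_wells, plate, by = c("row", "col"))
    if (!nrow(neg)) stop("replicate ", rep_id, ": no negative-control wells")
    c0 <- ctrl_agg(neg$od_t0); c24 <- ctrl_agg(neg$od_t24)
    sm <- merge(samples, plate, by = c("row", "col"))
    sm$inhibition <- inhibition_percent(sm$od_t0, sm$od_t24, c0, c24)
    per_rep[[length(per_rep) + 1L]] <-
      sm[, c("strain", "medium", "pathogen", "inhibition")]
  }
  all_rep <- do.call(rbind, per_rep)
  agg <- aggregate(inhibition ~ strain + medium + pathogen, data = all_rep,
                   FUN = mean)
  cnt <- aggregate(inhibition ~ strain + medium + pathogen, data = all_rep,
                   FUN = length)
  out <- merge(agg, cnt, by = c("strain", "medium", "pathogen"),
               suffixes = c("", "_n"))
  names(out)[names(out) == "inhibition"] <- "inhibition_pct"
  names(out)[names(out) == "inhibition_n"] <- "n_replicates"
  out$active <- out$inhibition_pct > threshold
  out[order(out$strain, out$medium, out$pathogen), ]
}

#' Summarize a screening campaign
#'
#' @param calls Activity calls from [call_activity()].
#' @return List of data.frames: `per_pathogen` (strains with at least one
#'   active medium, per pathogen), `per_medium` (active strains per medium),
#'   `per_strain` (each strain's best inhibition and activity).
#' @export
summarize_screen <- function(calls) {
  if (!nrow(calls)) {
    return(list(
      per_pathogen = data.frame(pathogen = character(0),
                                n_active_strains = integer(0)),
      per_medium = data.frame(medium = character(0),
                              n_active_strains = integer(0)),
      per_strain = data.frame(strain = character(0),
                              best_inhibition_pct = numeric(0),
                              any_active = logical(0))
    ))
  }
  act <- calls[calls$active, , drop = FALSE]
  if (nrow(act)) {
    per_pathogen <- aggregate(strain ~ pathogen, data = act,
                              FUN = function(s) length(unique(s)))
    names(per_pathogen)[2] <- "n_active_strains"
    per_medium <- aggregate(strain ~ medium, data = act,
                            FUN = function(s) length(unique(s)))
    names(per_medium)[2] <- "n_active_strains"
  } else {
    per_pathogen <- data.frame(pathogen = character(0),
                               n_active_strains = integer(0))
    per_medium <- data.frame(medium = character(0),
                             n_active_strains = integer(0))
  }
  best <- aggregate(inhibition_pct ~ strain, data = calls, FUN = max)
  names(best)[2] <- "best_inhibition_pct"
  anya <- aggregate(active ~ strain, data = calls, FUN = any)
  names(anya)[2] <- "any_active"
  per_strain <- merge(best, anya, by = "strain")
  list(per_pathogen = per_pathogen, per_medium = per_medium,
       per_strain = per_strain)
}
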