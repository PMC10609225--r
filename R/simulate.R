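# Ground-truthed synthetic data: glycoside MS/MS spectra with planted sugar
# ladders, analog families related by small mass transforms, and OD600 plate
# readings with planted effect sizes. All generators draw from R's global
# RNG; callers fix set.seed() for reproducibility.

#' Simulation settings for glycoside spectra
#'
#' Defaults emulate the structure of anthracycline glycoside MS/MS data:
#' two trisaccharide chains (rho, defuc, RhN), ~0.01 Da centroid jitter,
#' 20 uniform noise peaks, geometric intensity decay down the ladder, and a
#' doubly protonated companion in half of the spectra.
#'
#' @param aglycone_mass_range Aglycone monoisotopic mass range (Da).
#' @param chains List of residue-name vectors, outermost first.
#' @param mz_sigma Gaussian m/z jitter sd (Da) applied to every peak and to
#'   the recorded precursor.
#' @param n_noise_peaks Uniform-random noise peaks per spectrum.
#' @param noise_mz_range m/z range for noise peaks; `NULL` means 100 Da up
#'   to the precursor.
#' @param intensity_decay Geometric decay ratio down the ladder.
#' @param companion_prob Probability of emitting the \[M+2H\]2+ companion.
#' @param randomize_intensity Replace the decay model by uniform random
#'   intensities (ladder detection must not depend on the intensity model).
#' @return List of class `sim_spec`.
#' @export
sim_spec <- function(aglycone_mass_range = c(350, 600),
                     chains = list(c("rho", "defuc", "RhN"),
                                   c("rho", "defuc", "RhN")),
                     mz_sigma = 0.01, n_noise_peaks = 20L,
                     noise_mz_range = NULL, intensity_decay = 0.7,
                     companion_prob = 0.5, randomize_intensity = FALSE) {
  stopifnot(mz_sigma >= 0, n_noise_peaks >= 0, intensity_decay > 0,
            companion_prob >= 0, companion_prob <= 1)
  structure(list(aglycone_mass_range = aglycone_mass_range, chains = chains,
                 mz_sigma = mz_sigma, n_noise_peaks = as.integer(n_noise_peaks),
                 noise_mz_range = noise_mz_range,
                 intensity_decay = intensity_decay,
                 companion_prob = companion_prob,
                 randomize_intensity = randomize_intensity),
            class = "sim_spec")
}

#' Simulate one glycosylated polyketide MS/MS spectrum
#'
#' The \[M+H\]+ precursor is aglycone + sum of residues + proton. Fragments
#' arise by peeling each chain outermost-to-innermost; every chain ordering
#' is emitted (chain loss order is not fixed in collision-induced
#' dissociation), intensities decay geometrically down the ladder, every
#' peak gets Gaussian m/z jitter, and uniform noise peaks weaker than twice
#' the weakest true peak are added.
#'
#' @param spec A [sim_spec()].
#' @param aglycone_mass Aglycone mass (Da); drawn uniformly from the spec
#'   range when `NULL`.
#' @param id Spectrum id.
#' @param lib Loss library supplying residue masses.
#' @return List with `spectrum` (an [msms_spectrum()]) and `truth` (list:
#'   `aglycone_mass`, `chains`, `precursor_mz` true value, `ladder_mz` true
#'   fragment masses per chain order, `residue_sequences`, `has_companion`).
#' @export
simulate_glycoside_spectrum <- function(spec = sim_spec(),
                                        aglycone_mass = NULL, id = "sim",
                                        lib = loss_library(include_dehydro = TRUE)) {
  stopifnot(inherits(spec, "sim_spec"))
  if (is.null(aglycone_mass)) {
    aglycone_mass <- runif(1, spec$aglycone_mass_range[1],
                           spec$aglycone_mass_range[2])
  }
  res_mass <- setNames(lib$exact_mass, lib$name)
  chains <- spec$chains
  unknown <- setdiff(unlist(chains), names(res_mass))
  if (length(unknown)) stop("unknown residues: ", paste(unknown, collapse = ", "))
  total_sugar <- sum(res_mass[unlist(chains)])
  prec_true <- aglycone_mass + total_sugar + PROTON_MASS

  orders <- if (length(chains) > 1L) chain_orderings(length(chains)) else
    list(seq_along(chains))
  ladder_mz <- list()
  seqs <- list()
  frag_mz <- numeric(0)
  frag_level <- integer(0)
  for (o in orders) {
    losses <- unlist(chains[o])
    mzs <- prec_true - cumsum(res_mass[losses])
    ladder_mz[[length(ladder_mz) + 1L]] <- unname(mzs)
    seqs[[length(seqs) + 1L]] <- unname(losses)
    frag_mz <- c(frag_mz, mzs)
    frag_level <- c(frag_level, seq_along(mzs))
  }

  mz <- c(prec_true, frag_mz)
  level <- c(0L, frag_level)
  intensity <- if (spec$randomize_intensity) {
    runif(length(mz), 0.2, 1)
  } else {
    spec$intensity_decay^level
  }
  has_companion <- length(chains) > 0 && runif(1) < spec$companion_prob
  if (has_companion) {
    mz <- c(mz, charge_companion_mz(prec_true))
    intensity <- c(intensity, 1.2)  # companions are typically the base peak
  }
  mz <- mz + rnorm(length(mz), 0, spec$mz_sigma)

  if (spec$n_noise_peaks > 0L) {
    rng <- spec$noise_mz_range
    if (is.null(rng)) rng <- c(100, prec_true)
    noise_cap <- 2 * min(intensity)
    mz <- c(mz, runif(spec$n_noise_peaks, rng[1], rng[2]))
    intensity <- c(intensity, runif(spec$n_noise_peaks, 0, noise_cap))
  }
  s <- msms_spectrum(id = id,
                     precursor_mz = prec_true + rnorm(1, 0, spec$mz_sigma),
                     mz = mz, intensity = intensity, charge = 1L,
                     source = "simulated")
  list(spectrum = s,
       truth = list(aglycone_mass = aglycone_mass, chains = chains,
                    precursor_mz = prec_true, ladder_mz = ladder_mz,
                    residue_sequences = seqs, has_companion = has_companion))
}

chain_orderings <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  perm <- function(v, acc) {
    if (!length(v)) { out[[length(out) + 1L]] <<- acc; return(invisible(NULL)) }
    for (k in seq_along(v)) perm(v[-k], c(acc, v[k]))
  }
  perm(seq_len(n), integer(0))
  out
}

#' Simulate a family of structural analogs
#'
#' One parent spectrum plus `n_analogs` derivatives, each differing from the
#' parent by one random signed transform applied to the aglycone (so every
#' ladder fragment shifts with the precursor and the modified cosine links
#' the family).
#'
#' @param spec A [sim_spec()].
#' @param n_analogs Number of analogs; 0 gives a singleton family.
#' @param transform_set Transform table (default the aglycone
#'   modifications O, H2, H2O, CH2 of [delta_transforms()]).
#' @param family_id Prefix for spectrum ids.
#' @param aglycone_mass Parent aglycone mass; drawn when `NULL`.
#' @return List with `spectra` (list of [msms_spectrum()]; parent first) and
#'   `truth` (parent truth plus per-analog `transform`, `sign`,
#'   `true_delta`).
#' @export
simulate_family <- function(spec = sim_spec(), n_analogs = 3L,
                            transform_set = NULL, family_id = "fam",
                            aglycone_mass = NULL) {
  if (is.null(transform_set)) {
    tf <- delta_transforms()
    transform_set <- tf[tf$name %in% c("O", "H2", "H2O", "CH2"), ]
  }
  parent <- simulate_glycoside_spectrum(spec, aglycone_mass = aglycone_mass,
                                        id = paste0(family_id, "_parent"))
  spectra <- list(parent$spectrum)
  analogs <- list()
  for (k in seq_len(n_analogs)) {
    ti <- sample.int(nrow(transform_set), 1L)
    sgn <- sample(c(-1, 1), 1L)
    ag <- parent$truth$aglycone_mass + sgn * transform_set$delta_mass[ti]
    sim <- simulate_glycoside_spectrum(spec, aglycone_mass = ag,
                                       id = sprintf("%s_a%d", family_id, k))
    spectra[[length(spectra) + 1L]] <- sim$spectrum
    analogs[[k]] <- list(id = sim$spectrum$id,
                         transform = transform_set$name[ti], sign = sgn,
                         true_delta = sgn * transform_set$delta_mass[ti])
  }
  list(spectra = spectra,
       truth = list(family_id = family_id, parent = parent$truth,
                    parent_id = parent$spectrum$id, analogs = analogs))
}

#' Simulate replicate screening plates with planted effects
#'
#' Negative-control growth is `Normal(0.45, 0.03)` OD units (truncated at
#' 0); each test well grows as an independent control draw scaled by
#' `1 - effect` plus `Normal(0, 0.01)` measurement noise. Sterility wells
#' stay near zero; positive-control wells use `positive_effect`. Three
#' replicate plates are generated per call by default.
#'
#' @param effects data.frame with columns `strain`, `medium`, `pathogen`
#'   (single value per plate set) and `effect` (true inhibition fraction in
#'   \[0, 1\], may exceed 1 for lysis); at most 80 rows (the test wells).
#' @param n_replicates Number of replicate plates; default 3.
#' @param control_delta Mean and sd of control OD growth; default
#'   `c(0.45, 0.03)`.
#' @param test_noise_sd Additive OD noise on test wells; default 0.01.
#' @param od_t0 Baseline OD at t0; default 0.05.
#' @param positive_effect True effect of the levofloxacin wells; default
#'   0.98.
#' @param layout Plate layout; default [plate_layout()].
#' @return List with `readings` (wide data.frame: `replicate`, `row`,
#'   `col`, `od_t0`, `od_t24`), `samples` (well-to-sample map) and `truth`
#'   (the effects table).
#' @export
simulate_plate <- function(effects, n_replicates = 3L,
                           control_delta = c(0.45, 0.03),
                           test_noise_sd = 0.01, od_t0 = 0.05,
                           positive_effect = 0.98,
                           layout = plate_layout()) {
  stopifnot(all(c("strain", "medium", "pathogen", "effect") %in%
                  names(effects)))
  test_wells <- layout[layout$role == "test", ]
  if (nrow(effects) > nrow(test_wells)) {
    stop("at most ", nrow(test_wells), " samples fit on one plate")
  }
  samples <- cbind(test_wells[seq_len(nrow(effects)), c("row", "col")],
                   effects[, c("strain", "medium", "pathogen")])
  rownames(samples) <- NULL

  draw_delta <- function(n) pmax(rnorm(n, control_delta[1], control_delta[2]), 0)
  reps <- lapply(seq_len(n_replicates), function(rep_id) {
    r <- layout
    r$od_t0 <- od_t0
    delta <- numeric(nrow(r))
    for (i in seq_len(nrow(r))) {
      delta[i] <- switch(
        r$role[i],
        sterility = abs(rnorm(1, 0, 0.003)),
        negative = draw_delta(1),
        positive = draw_delta(1) * (1 - positive_effect) +
          rnorm(1, 0, test_noise_sd),
        test = NA_real_
      )
    }
    ti <- match(paste(r$row, r$col),
                paste(samples$row, samples$col))
    is_sample <- r$role == "test" & !is.na(ti)
    delta[is_sample] <- draw_delta(sum(is_sample)) *
      (1 - effects$effect[ti[is_sample]]) +
      rnorm(sum(is_sample), 0, test_noise_sd)
    # unused test wells behave like negative controls (extract-free)
    unused <- r$role == "test" & is.na(ti)
    delta[unused] <- draw_delta(sum(unused))
    r$od_t24 <- r$od_t0 + delta
    data.frame(replicate = rep_id, row = r$row, col = r$col,
               od_t0 = r$od_t0, od_t24 = r$od_t24)
  })
  list(readings = do.call(rbind, reps), samples = samples, truth = effects)
}

#' Write simulated plate readings as long-format CSV
#'
#' @param readings Wide readings from [simulate_plate()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(readings, path) {
  long <- rbind(
    data.frame(plate_id = readings$replicate, row = readings$row,
               col = readings$col, timepoint = "t0", od600 = readings$od_t0),
    data.frame(plate_id = readings$replicate, row = readings$row,
               col = readings$col, timepoint = "t24", od600 = readings$od_t24)
  )
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
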