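# Pipeline orchestration: spectra -> network -> ladders -> formulas ->
# seed matching -> propagation -> report, with a JSON run manifest.

#' Pipeline configuration
#'
#' Collects every stage parameter in one validated object. Defaults
#' reproduce the GNPS-style networking parameter set (cosine 0.6,
#' tolerances 0.02 Da, 4 matched peaks, cluster size 2) with nominal-mode
#' ladder detection at 0.5 Da (suitable for one-decimal peak lists; switch
#' to `ladder_mode = "exact"`, `ladder_tol = 0.03` for accurate-mass data).
#'
#' @param spectra Path to an MGF file, a directory of `.mgf`/`.tsv`
#'   peak-list files, or a list of [msms_spectrum()] objects.
#' @param output_dir Directory for stage outputs (created if absent).
#' @param network [network_params()].
#' @param loss_lib Loss library data.frame.
#' @param ladder_tol,ladder_mode Ladder detection tolerance (Da) and mode.
#' @param seed_lib Seed compound library data.frame.
#' @param transforms Transform table for propagation.
#' @param propagation_tol Transform-match tolerance (Da); default 0.01.
#' @param max_hops Propagation hop limit; default 2.
#' @param formula_ppm Formula enumeration tolerance (ppm); default 10.
#' @param run_formulas Enumerate formulas for node precursors? Default TRUE.
#' @param seed RNG seed recorded in the manifest; default 1.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(spectra, output_dir,
                            network = network_params(),
                            loss_lib = loss_library(include_dehydro = TRUE),
                            ladder_tol = 0.5, ladder_mode = "nominal",
                            seed_lib = compound_library(),
                            transforms = delta_transforms(),
                            propagation_tol = 0.01, max_hops = 2L,
                            formula_ppm = 10, run_formulas = TRUE,
                            seed = 1L) {
  stopifnot(inherits(network, "network_params"), ladder_tol > 0,
            ladder_mode %in% c("nominal", "exact"), propagation_tol > 0,
            max_hops >= 1L, formula_ppm > 0)
  structure(list(spectra = spectra, output_dir = output_dir,
                 network = network, loss_lib = loss_lib,
                 ladder_tol = ladder_tol, ladder_mode = ladder_mode,
                 seed_lib = seed_lib, transforms = transforms,
                 propagation_tol = propagation_tol,
                 max_hops = as.integer(max_hops),
                 formula_ppm = formula_ppm, run_formulas = run_formulas,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

load_spectra_input <- function(spectra) {
  if (is.list(spectra) && length(spectra) &&
      inherits(spectra[[1]], "msms_spectrum")) {
    return(spectra)
  }
  if (!is.character(spectra)) stop("cannot interpret spectra input")
  if (dir.exists(spectra)) {
    files <- sort(c(list.files(spectra, "\\.mgf$", full.names = TRUE),
                    list.files(spectra, "\\.tsv$", full.names = TRUE)))
    out <- list()
    for (f in files) {
      out <- c(out, if (grepl("\\.mgf$", f)) read_mgf(f) else
        list(read_peaklist_tsv(f)))
    }
    return(out)
  }
  if (file.exists(spectra)) {
    return(if (grepl("\\.tsv$", spectra)) list(read_peaklist_tsv(spectra))
           else read_mgf(spectra))
  }
  stop("spectra input not found: ", spectra)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full dereplication pipeline
#'
#' Stages run in order: read spectra, build the molecular network, detect
#' the best neutral-loss ladder per node, enumerate formula candidates for
#' each node precursor, match seed compounds, propagate analog labels, and
#' write the joined report, the network (GraphML + edge TSV), the ladder
#' report and a JSON run manifest into `config$output_dir`. Identical
#' configuration yields byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `network`, `ladders`, `formulas`,
#'   `annotations`, `report` and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  spectra <- run_stage("spectra", load_spectra_input(config$spectra))
  if (!length(spectra)) {
    message("no input spectra; nothing to do")
    return(invisible(list(network = NULL, ladders = NULL, formulas = NULL,
                          annotations = NULL, report = NULL,
                          manifest = NULL)))
  }
  net <- run_stage("network", build_network(spectra, config$network))
  by_id <- setNames(spectra, vapply(spectra, function(s) s$id, character(1)))

  ladders <- run_stage("ladders", {
    out <- list()
    for (id in net$nodes$id) {
      bl <- best_ladder(detect_ladders(by_id[[id]], config$loss_lib,
                                       tol = config$ladder_tol,
                                       mode = config$ladder_mode))
      if (!is.null(bl)) out[[id]] <- bl
    }
    out
  })
  formulas <- if (config$run_formulas) run_stage("formulas", {
    out <- list()
    for (i in seq_len(nrow(net$nodes))) {
      out[[net$nodes$id[i]]] <-
        enumerate_formulas(net$nodes$precursor_mz[i],
                           ppm_tol = config$formula_ppm)
    }
    out
  }) else NULL
  seeds <- run_stage("seeds", match_seeds(net, config$seed_lib,
                                          tol = config$network$parent_mass_tol))
  annotations <- run_stage("propagation", {
    propagate(net, seeds, config$transforms,
              tol = config$propagation_tol, max_hops = config$max_hops)
  })
  report <- run_stage("report", {
    export_graphml(net, file.path(config$output_dir, "network.graphml"))
    export_edges_tsv(net, file.path(config$output_dir, "edges.tsv"))
    write_ladder_tsv(ladders, file.path(config$output_dir, "ladders.tsv"))
    export_annotated_graphml(net, annotations,
                             file.path(config$output_dir,
                                       "network_annotated.graphml"))
    annotation_report(net, annotations, ladders, formulas,
                      path = file.path(config$output_dir, "report.tsv"))
  })
  manifest <- list(
    n_spectra = length(spectra),
    n_nodes = nrow(net$nodes), n_edges = nrow(net$edges),
    n_seed_matches = sum(annotations$evidence == "seed_match"),
    n_propagated = sum(annotations$evidence == "propagated"),
    parameters = list(
      network = unclass(config$network),
      ladder = list(tol = config$ladder_tol, mode = config$ladder_mode),
      propagation = list(tol = config$propagation_tol,
                         max_hops = config$max_hops),
      formula_ppm = config$formula_ppm, seed = config$seed
    )
  )
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(network = net, ladders = ladders, formulas = formulas,
                 annotations = annotations, report = report,
                 manifest = manifest))
}
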