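# Seed matching and network-propagated analog annotation.
#
# Known compounds (a seed library of name + [M+H]+ m/z) anchor the network;
# unknown neighbors inherit "analog of" labels when the parent-mass
# difference along an edge matches a small chemical transform (oxygenation,
# saturation, methylenation, a sugar residue, ...). This turns the manual
# "amu difference" reasoning of classical dereplication into a
# deterministic breadth-first algorithm.

#' Load a seed compound library
#'
#' The packaged default library holds the cosmomycin, hedamycin/kidamycin
#' and derivative ions (with the published \[M+H\]+ masses and, where
#' reported, ion formulas). Columns: `name`, `ion_mz`, `ion_formula`
#' (may be empty), `compound_class`.
#'
#' @param path TSV path; defaults to the packaged library.
#' @return data.frame of compound records.
#' @export
compound_library <- function(path = system.file("extdata", "seed_library.tsv",
                                                package = "derepnet")) {
  lib <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "ion_mz")
  if (!all(need %in% names(lib))) {
    stop("seed library must have columns: ", paste(need, collapse = ", "))
  }
  if (any(lib$ion_mz <= 0)) stop("seed library ion_mz must be positive")
  if (!"ion_formula" %in% names(lib)) lib$ion_formula <- ""
  if (!"compound_class" %in% names(lib)) lib$compound_class <- "other"
  lib
}

#' Match network nodes against a seed compound library
#'
#' Each node is labeled with the library compound whose \[M+H\]+ m/z is
#' nearest within `tol`; ties are broken by smaller absolute difference,
#' then by library order.
#'
#' @param net A `molecular_network` (see [build_network()]).
#' @param lib Seed library data.frame (see [compound_library()]).
#' @param tol Parent-mass tolerance in Da; default 0.02.
#' @return Annotation data.frame with columns `node_id`, `label`,
#'   `evidence` (`"seed_match"`), `hops` (0), `cumulative_delta` (0),
#'   `seed`, `delta_error`; one row per matched node.
#' @export
match_seeds <- function(net, lib = compound_library(), tol = 0.02) {
  stopifnot(inherits(net, "molecular_network"), tol > 0)
  rows <- list()
  for (i in seq_len(nrow(net$nodes))) {
    d <- abs(net$nodes$precursor_mz[i] - lib$ion_mz)
    ok <- which(d <= tol + 1e-12)
    if (!length(ok)) next
    best <- ok[order(d[ok], ok)][1]  # ties: library order
    rows[[length(rows) + 1L]] <- data.frame(
      node_id = net$nodes$id[i], label = lib$name[best],
      evidence = "seed_match", hops = 0L, cumulative_delta = 0,
      seed = lib$name[best], delta_error = d[best],
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) return(empty_annotations())
  do.call(rbind, rows)
}

empty_annotations <- function() {
  data.frame(node_id = character(0), label = character(0),
             evidence = character(0), hops = integer(0),
             cumulative_delta = numeric(0), seed = character(0),
             delta_error = numeric(0), stringsAsFactors = FALSE)
}

#' Propagate analog annotations along network edges
#'
#' Breadth-first from the seed-matched nodes: an unannotated neighbor is
#' labeled `"analog of <seed> via <transform chain>"` when the absolute
#' parent-mass difference of the connecting edge matches a single transform
#' (or, when `composite = TRUE`, a sum of two) within `tol`. Shorter hop
#' counts win; within a hop, the assignment with the smallest transform
#' error wins. Deterministic under fixed input ordering.
#'
#' The propagation tolerance is deliberately tighter than the networking
#' parent-mass tolerance: discriminating transforms (O at 15.9949 vs CH2 at
#' 14.0157 plus 2 H) needs ~0.01 Da.
#'
#' @param net A `molecular_network`.
#' @param seeds Annotations from [match_seeds()].
#' @param transforms Transform table (see [delta_transforms()]).
#' @param tol Transform-match tolerance in Da; default 0.01.
#' @param max_hops Maximum propagation distance from a seed; default 2.
#' @param composite Also try sums of two transforms? Default FALSE (single
#'   deltas explain the reported analog series).
#' @return Annotation data.frame (seed rows plus propagated rows) with the
#'   columns of [match_seeds()] plus `transform` and `nominal_delta` (the
#'   field-style integer delta, e.g. 16 for O).
#' @export
propagate <- function(net, seeds, transforms = delta_transforms(),
                      tol = 0.01, max_hops = 2L, composite = FALSE) {
  stopifnot(inherits(net, "molecular_network"), max_hops >= 1L, tol > 0)
  tf <- transform_catalog(transforms, composite)
  ann <- seeds
  if (nrow(ann)) {
    ann$transform <- ""
    ann$nominal_delta <- NA_integer_
  } else {
    ann <- cbind(empty_annotations(),
                 data.frame(transform = character(0),
                            nominal_delta = integer(0)))
  }
  if (!nrow(seeds) || !nrow(net$edges)) return(ann)

  # signed delta node -> neighbor, from the edge table (from - to stored)
  adj <- rbind(
    data.frame(a = net$edges$from, b = net$edges$to,
               delta = -net$edges$delta_parent_mass, stringsAsFactors = FALSE),
    data.frame(a = net$edges$to, b = net$edges$from,
               delta = net$edges$delta_parent_mass, stringsAsFactors = FALSE)
  )  # delta = precursor(b) - precursor(a)

  state <- ann
  for (hop in seq_len(max_hops)) {
    frontier <- state[state$hops == hop - 1L, , drop = FALSE]
    if (!nrow(frontier)) break
    cand <- adj[adj$a %in% frontier$node_id &
                  !(adj$b %in% state$node_id), , drop = FALSE]
    if (!nrow(cand)) next
    new_rows <- list()
    for (nb in sort(unique(cand$b))) {
      inc <- cand[cand$b == nb, , drop = FALSE]
      best <- NULL
      for (k in seq_len(nrow(inc))) {
        err <- abs(abs(inc$delta[k]) - tf$delta_mass)
        hit <- which(err <= tol + 1e-12)
        if (!length(hit)) next
        h <- hit[order(err[hit], hit)][1]
        src <- frontier[frontier$node_id == inc$a[k], , drop = FALSE][1, ]
        row <- list(err = err[h], tf = h, delta = inc$delta[k], src = src)
        if (is.null(best) || row$err < best$err) best <- row
      }
      if (is.null(best)) next
      sign_chr <- if (best$delta < 0) "-" else "+"
      step_lab <- sprintf("%s%s(%d)", sign_chr, tf$name[best$tf],
                          tf$nominal[best$tf])
      chain <- if (nzchar(best$src$transform)) {
        paste(best$src$transform, step_lab)
      } else step_lab
      new_rows[[length(new_rows) + 1L]] <- data.frame(
        node_id = nb,
        label = sprintf("analog of %s via %s", best$src$seed, chain),
        evidence = "propagated", hops = hop,
        cumulative_delta = best$src$cumulative_delta + best$delta,
        seed = best$src$seed, delta_error = best$err,
        transform = chain, nominal_delta = tf$nominal[best$tf],
        stringsAsFactors = FALSE
      )
    }
    if (length(new_rows)) state <- rbind(state, do.call(rbind, new_rows))
  }
  rownames(state) <- NULL
  state
}

# Single transforms plus, optionally, all sums of two (named "a+b").
transform_catalog <- function(transforms, composite) {
  tf <- transforms[, c("name", "delta_mass", "nominal")]
  if (composite && nrow(transforms) >= 1L) {
    idx <- expand.grid(i = seq_len(nrow(transforms)),
                       j = seq_len(nrow(transforms)))
    idx <- idx[idx$i <= idx$j, , drop = FALSE]
    comb <- data.frame(
      name = paste(transforms$name[idx$i], transforms$name[idx$j], sep = "+"),
      delta_mass = transforms$delta_mass[idx$i] + transforms$delta_mass[idx$j],
      nominal = transforms$nominal[idx$i] + transforms$nominal[idx$j],
      stringsAsFactors = FALSE
    )
    tf <- rbind(tf, comb)
  }
  tf
}

#' Joined per-node annotation report
#'
#' One row per node of the reported network: precursor m/z, annotation label
#' and evidence (if any), best-ladder composition (if supplied) and top
#' formula candidates (if supplied). Written as TSV when `path` is given.
#'
#' @param net A `molecular_network`.
#' @param annotations Annotation data.frame ([match_seeds()]/[propagate()]).
#' @param ladders Optional named list (by spectrum id) of `nl_ladder`
#'   objects (e.g. each node's best ladder).
#' @param formulas Optional named list (by node id) of
#'   [enumerate_formulas()] results.
#' @param path Optional output TSV path.
#' @param n_formula How many top formula candidates to join; default 3.
#' @return The report data.frame, invisibly when `path` is given.
#' @export
annotation_report <- function(net, annotations, ladders = NULL,
                              formulas = NULL, path = NULL, n_formula = 3L) {
  stopifnot(inherits(net, "molecular_network"))
  n <- nrow(net$nodes)
  rep_df <- data.frame(
    node_id = net$nodes$id,
    precursor_mz = sprintf("%.4f", net$nodes$precursor_mz),
    label = character(n), evidence = character(n), hops = rep(NA_integer_, n),
    ladder_composition = character(n), ladder_terminal_mz = character(n),
    formula_candidates = character(n),
    stringsAsFactors = FALSE
  )
  if (nrow(annotations)) {
    m <- match(rep_df$node_id, annotations$node_id)
    hit <- !is.na(m)
    rep_df$label[hit] <- annotations$label[m[hit]]
    rep_df$evidence[hit] <- annotations$evidence[m[hit]]
    rep_df$hops[hit] <- annotations$hops[m[hit]]
  }
  if (!is.null(ladders)) {
    for (i in seq_len(nrow(rep_df))) {
      l <- ladders[[rep_df$node_id[i]]]
      if (is.null(l)) next
      comp <- glycan_composition(l)
      rep_df$ladder_composition[i] <-
        paste(sprintf("%s:%d", names(comp), comp), collapse = ";")
      rep_df$ladder_terminal_mz[i] <- sprintf("%.4f", l$terminal_mz)
    }
  }
  if (!is.null(formulas)) {
    for (i in seq_len(nrow(rep_df))) {
      f <- formulas[[rep_df$node_id[i]]]
      if (is.null(f) || !nrow(f)) next
      top <- head(f, n_formula)
      rep_df$formula_candidates[i] <-
        paste(sprintf("%s(%.1fppm)", top$formula, top$ppm_error),
              collapse = ";")
    }
  }
  if (!is.null(path)) {
    write.table(rep_df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(rep_df))
  }
  rep_df
}

#' Export an annotated network as GraphML
#'
#' Like [export_graphml()] but with `label` and `evidence` node attributes
#' for Cytoscape-style viewing.
#'
#' @param net A `molecular_network`.
#' @param annotations Annotation data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_annotated_graphml <- function(net, annotations, path) {
  nodes <- net$nodes
  m <- match(nodes$id, annotations$node_id)
  nodes$label <- ifelse(is.na(m), "", annotations$label[m])
  nodes$evidence <- ifelse(is.na(m), "", annotations$evidence[m])
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
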