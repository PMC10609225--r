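# Molecular network construction with GNPS-style filtering.

#' Networking parameters
#'
#' Defaults reproduce the GNPS parameter set used for anthracycline/
#' angucycline dereplication: minimum cosine 0.6, parent-mass and fragment
#' tolerances 0.02 Da, at least 4 matched peaks, minimum cluster size 2,
#' plus the GNPS workflow defaults TopK = 10 and maximum component size 100.
#'
#' @param min_cosine Minimum modified-cosine score for an edge, in \[0, 1\].
#' @param parent_mass_tol Parent-mass tolerance (Da) used by seed matching.
#' @param frag_tol Fragment-ion tolerance (Da) of the modified cosine.
#' @param min_matched_peaks Minimum matched peak pairs for an edge.
#' @param min_cluster_size Components smaller than this are dropped from the
#'   reported network (2 removes singletons).
#' @param top_k_edges An edge survives only if it ranks in the best `top_k`
#'   by score for both endpoints.
#' @param max_component_size Components are pared down by removing their
#'   lowest-scoring edges until no larger than this.
#' @param max_parent_delta Informational bound (Da) on parent-mass deltas of
#'   interest; pairs beyond it are still scored (analog series can span a
#'   wide mass range).
#' @return Validated list of class `network_params`.
#' @export
network_params <- function(min_cosine = 0.6, parent_mass_tol = 0.02,
                           frag_tol = 0.02, min_matched_peaks = 4L,
                           min_cluster_size = 2L, top_k_edges = 10L,
                           max_component_size = 100L,
                           max_parent_delta = 200) {
  p <- list(min_cosine = min_cosine, parent_mass_tol = parent_mass_tol,
            frag_tol = frag_tol,
            min_matched_peaks = as.integer(min_matched_peaks),
            min_cluster_size = as.integer(min_cluster_size),
            top_k_edges = as.integer(top_k_edges),
            max_component_size = as.integer(max_component_size),
            max_parent_delta = max_parent_delta)
  stopifnot(p$min_cosine >= 0, p$min_cosine <= 1,
            p$parent_mass_tol > 0, p$frag_tol > 0,
            p$min_matched_peaks >= 1L, p$min_cluster_size >= 1L,
            p$top_k_edges >= 1L, p$max_component_size >= 1L)
  class(p) <- "network_params"
  p
}

#' Build a molecular network from MS/MS spectra
#'
#' All spectrum pairs are scored with the modified cosine (after standard
#' preprocessing); edges failing the score or matched-peak thresholds are
#' dropped; each surviving edge must rank within `top_k_edges` by score for
#' both endpoints; oversized connected components are reduced by iteratively
#' removing their lowest-scoring edges; finally components smaller than
#' `min_cluster_size` are removed from the reported network.
#'
#' @param spectra List of [msms_spectrum()] objects with unique ids.
#' @param params A [network_params()] object.
#' @param preprocess Apply [preprocess_spectrum()] before scoring? Default
#'   TRUE.
#' @return Object of class `molecular_network`: list with `nodes`
#'   (data.frame `id`, `precursor_mz`), `edges` (data.frame `from`, `to`,
#'   `score`, `n_matched`, `delta_parent_mass`) and `params`.
#' @export
build_network <- function(spectra, params = network_params(),
                          preprocess = TRUE) {
  stopifnot(length(spectra) >= 1L, inherits(params, "network_params"))
  ids <- vapply(spectra, function(s) s$id, character(1))
  if (anyDuplicated(ids)) stop("spectrum ids must be unique")
  prec <- vapply(spectra, function(s) s$precursor_mz, numeric(1))
  nodes <- data.frame(id = ids, precursor_mz = prec, stringsAsFactors = FALSE)
  scored <- if (preprocess) lapply(spectra, preprocess_spectrum) else spectra

  edges <- empty_edges()
  n <- length(spectra)
  if (n >= 2L) {
    pairs <- combn(n, 2L)
    rows <- vector("list", ncol(pairs))
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1L, k]; j <- pairs[2L, k]
      cs <- modified_cosine(scored[[i]], scored[[j]], params$frag_tol)
      if (cs$score >= params$min_cosine &&
          cs$n_matched >= params$min_matched_peaks) {
        rows[[k]] <- data.frame(
          from = ids[i], to = ids[j], score = cs$score,
          n_matched = cs$n_matched,
          delta_parent_mass = prec[i] - prec[j],
          stringsAsFactors = FALSE
        )
      }
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) edges <- do.call(rbind, rows)
  }

  edges <- filter_top_k(edges, params$top_k_edges)
  edges <- limit_component_size(edges, params$max_component_size)

  # drop components below the minimum cluster size
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = data.frame(name = nodes$id))
  comp <- igraph::components(g)
  keep_nodes <- names(comp$membership)[comp$csize[comp$membership] >=
                                         params$min_cluster_size]
  nodes <- nodes[nodes$id %in% keep_nodes, , drop = FALSE]
  edges <- edges[edges$from %in% keep_nodes & edges$to %in% keep_nodes, ,
                 drop = FALSE]
  rownames(nodes) <- NULL; rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, params = params),
            class = "molecular_network")
}

empty_edges <- function() {
  data.frame(from = character(0), to = character(0), score = numeric(0),
             n_matched = integer(0), delta_parent_mass = numeric(0),
             stringsAsFactors = FALSE)
}

# Keep an edge only if it is among the top_k by score at both endpoints
# (ties by lexicographic partner id, matching the deterministic ordering of
# the rest of the pipeline).
filter_top_k <- function(edges, top_k) {
  if (!nrow(edges)) return(edges)
  inc <- rbind(
    data.frame(node = edges$from, other = edges$to, score = edges$score,
               edge = seq_len(nrow(edges)), stringsAsFactors = FALSE),
    data.frame(node = edges$to, other = edges$from, score = edges$score,
               edge = seq_len(nrow(edges)), stringsAsFactors = FALSE)
  )
  ok <- rep(TRUE, nrow(edges))
  for (nd in unique(inc$node)) {
    sub <- inc[inc$node == nd, , drop = FALSE]
    sub <- sub[order(-sub$score, sub$other), , drop = FALSE]
    if (nrow(sub) > top_k) {
      ok[sub$edge[-seq_len(top_k)]] <- FALSE
    }
  }
  edges[ok, , drop = FALSE]
}

# Iteratively remove the lowest-scoring edge of any component larger than
# max_size (deterministic tie-break on the from/to ids).
limit_component_size <- function(edges, max_size) {
  repeat {
    if (!nrow(edges)) return(edges)
    g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                       directed = FALSE)
    comp <- igraph::components(g)
    big <- which(comp$csize > max_size)
    if (!length(big)) return(edges)
    nodes_big <- names(comp$membership)[comp$membership == big[1]]
    in_big <- edges$from %in% nodes_big & edges$to %in% nodes_big
    cand <- which(in_big)
    cand <- cand[order(edges$score[cand], edges$from[cand], edges$to[cand])]
    edges <- edges[-cand[1], , drop = FALSE]
  }
}

#' @export
print.molecular_network <- function(x, ...) {
  cat(sprintf("<molecular_network> %d nodes, %d edges (min cosine %.2f)\n",
              nrow(x$nodes), nrow(x$edges), x$params$min_cosine))
  invisible(x)
}

#' Convert a molecular network to an igraph graph
#'
#' Node attribute `precursor_mz` and edge attributes `score`, `n_matched`,
#' `delta_parent_mass` are carried over.
#'
#' @param net A `molecular_network`.
#' @return An undirected [igraph::graph].
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "molecular_network"))
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Export a molecular network
#'
#' `export_graphml()` writes standard GraphML (readable by Cytoscape and
#' [igraph::read_graph()]); `export_edges_tsv()` writes the edge table.
#'
#' @param net A `molecular_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(net, path) {
  g <- as_igraph(net)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname export_graphml
#' @export
export_edges_tsv <- function(net, path) {
  edges <- net$edges
  edges$score <- sprintf("%.6f", edges$score)
  edges$delta_parent_mass <- sprintf("%.6f", edges$delta_parent_mass)
  write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
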