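# Helper: hand-built network (nodes + edges) without running the cosine,
# so transform matching is tested in isolation.
manual_network <- function(nodes, edges = NULL) {
  if (is.null(edges)) {
    edges <- data.frame(from = character(0), to = character(0),
                        score = numeric(0), n_matched = integer(0),
                        delta_parent_mass = numeric(0),
                        stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges, params = network_params()),
            class = "molecular_network")
}

test_that("seed matching finds library compounds within tolerance", {
  nodes <- data.frame(id = c("n1", "n2", "n3"),
                      precursor_mz = c(1189.5878, 1189.70, 689.3430),
                      stringsAsFactors = FALSE)
  ann <- match_seeds(manual_network(nodes), tol = 0.02)
  expect_equal(nrow(ann), 2)
  expect_equal(ann$label[ann$node_id == "n1"], "cosmomycin D")
  expect_equal(ann$label[ann$node_id == "n3"], "kidamycin")
  expect_true(all(ann$evidence == "seed_match"))
  expect_true(all(ann$hops == 0L))
  expect_false("n2" %in% ann$node_id)  # 0.11 Da away: no match
})

test_that("equidistant seeds resolve by library order", {
  lib <- data.frame(name = c("first", "second"),
                    ion_mz = c(499.98, 500.02),
                    ion_formula = "", compound_class = "other",
                    stringsAsFactors = FALSE)
  nodes <- data.frame(id = "tie", precursor_mz = 500.00,
                      stringsAsFactors = FALSE)
  ann <- match_seeds(manual_network(nodes), lib, tol = 0.02)
  expect_equal(ann$label, "first")
})

test_that("propagation labels the reported analog mass differences", {
  # cosmomycin A (756.3598) -> compound 15 (740.3627): loss of oxygen, 16 Da
  nodes <- data.frame(id = c("cosA", "c15"),
                      precursor_mz = c(756.3598, 740.3627),
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = "cosA", to = "c15", score = 0.9,
                      n_matched = 6L,
                      delta_parent_mass = 756.3598 - 740.3627,
                      stringsAsFactors = FALSE)
  net <- manual_network(nodes, edges)
  libA <- data.frame(name = "cosmomycin A", ion_mz = 756.3598,
                     ion_formula = "", compound_class = "anthracycline",
                     stringsAsFactors = FALSE)
  ann <- propagate(net, match_seeds(net, libA, tol = 0.02), tol = 0.01)
  row <- ann[ann$node_id == "c15", ]
  expect_equal(nrow(row), 1)
  expect_equal(row$evidence, "propagated")
  expect_equal(row$nominal_delta, 16L)
  expect_match(row$label, "analog of cosmomycin A via -O\\(16\\)")
  expect_equal(row$cumulative_delta, 740.3627 - 756.3598)

  # A447 C (1157.5942) -> compound 13 (1155.5762): 2 Da (H2)
  nodes2 <- data.frame(id = c("a447c", "c13"),
                       precursor_mz = c(1157.5942, 1155.5762),
                       stringsAsFactors = FALSE)
  edges2 <- data.frame(from = "a447c", to = "c13", score = 0.9,
                       n_matched = 6L,
                       delta_parent_mass = 1157.5942 - 1155.5762,
                       stringsAsFactors = FALSE)
  net2 <- manual_network(nodes2, edges2)
  libC <- data.frame(name = "A447 C", ion_mz = 1157.5942, ion_formula = "",
                     compound_class = "anthracycline", stringsAsFactors = FALSE)
  ann2 <- propagate(net2, match_seeds(net2, libC, tol = 0.02), tol = 0.01)
  row2 <- ann2[ann2$node_id == "c13", ]
  expect_equal(row2$nominal_delta, 2L)
  expect_match(row2$label, "via -H2\\(2\\)")
})

test_that("the oxygen delta fails at an over-tight tolerance", {
  # |delta| = 15.9971 vs O = 15.9949: error 0.0022
  nodes <- data.frame(id = c("cosA", "x"),
                      precursor_mz = c(756.3598, 740.3627),
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = "cosA", to = "x", score = 0.9, n_matched = 6L,
                      delta_parent_mass = 756.3598 - 740.3627,
                      stringsAsFactors = FALSE)
  net <- manual_network(nodes, edges)
  libA <- data.frame(name = "cosmomycin A", ion_mz = 756.3598,
                     ion_formula = "", compound_class = "anthracycline",
                     stringsAsFactors = FALSE)
  seeds <- match_seeds(net, libA, tol = 0.02)
  expect_false("x" %in% propagate(net, seeds, tol = 0.002)$node_id)
  expect_true("x" %in% propagate(net, seeds, tol = 0.01)$node_id)
})

test_that("nodes with no matching transform stay unannotated; one label each", {
  nodes <- data.frame(id = c("seed", "odd"),
                      precursor_mz = c(756.3598, 756.3598 + 7.77),
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = "seed", to = "odd", score = 0.8, n_matched = 5L,
                      delta_parent_mass = -7.77, stringsAsFactors = FALSE)
  net <- manual_network(nodes, edges)
  ann <- propagate(net, match_seeds(net, tol = 0.02))
  expect_false("odd" %in% ann$node_id)
  expect_equal(anyDuplicated(ann$node_id), 0)
})

test_that("two-hop propagation chains transforms; shortest hop wins", {
  o <- delta_transforms()$delta_mass[delta_transforms()$name == "O"]
  lib <- data.frame(name = "seedcmpd", ion_mz = 900.1234, ion_formula = "",
                    compound_class = "other", stringsAsFactors = FALSE)
  nodes <- data.frame(id = c("seed", "mid", "far"),
                      precursor_mz = c(900.1234, 900.1234 + o,
                                       900.1234 + 2 * o),
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = c("seed", "mid"), to = c("mid", "far"),
                      score = 0.9, n_matched = 6L,
                      delta_parent_mass = c(-o, -o),
                      stringsAsFactors = FALSE)
  net <- manual_network(nodes, edges)
  ann <- propagate(net, match_seeds(net, lib, tol = 0.02), max_hops = 2)
  expect_equal(ann$hops[ann$node_id == "mid"], 1L)
  expect_equal(ann$hops[ann$node_id == "far"], 2L)
  expect_match(ann$label[ann$node_id == "far"], "\\+O\\(16\\) \\+O\\(16\\)")
  expect_equal(ann$cumulative_delta[ann$node_id == "far"], 2 * o,
               tolerance = 1e-9)
  # with max_hops = 1 the far node is out of reach
  ann1 <- propagate(net, match_seeds(net, lib, tol = 0.02), max_hops = 1)
  expect_false("far" %in% ann1$node_id)
})

test_that("propagation on simulated families recovers analog labels", {
  set.seed(12)
  spec <- sim_spec(mz_sigma = 0.003)
  n_true <- 0; n_recovered <- 0; n_false <- 0
  for (i in 1:100) {
    fam <- simulate_family(spec, n_analogs = 3, family_id = paste0("f", i))
    net <- build_network(fam$spectra)
    lib <- data.frame(name = "parent",
                      ion_mz = fam$truth$parent$precursor_mz,
                      ion_formula = "", compound_class = "anthracycline",
                      stringsAsFactors = FALSE)
    ann <- propagate(net, match_seeds(net, lib, tol = 0.02), tol = 0.01)
    prop <- ann[ann$evidence == "propagated", , drop = FALSE]
    for (a in fam$truth$analogs) {
      n_true <- n_true + 1
      row <- prop[prop$node_id == a$id, , drop = FALSE]
      if (nrow(row) == 1) {
        if (abs(row$cumulative_delta - a$true_delta) <= 0.02) {
          n_recovered <- n_recovered + 1
        } else {
          n_false <- n_false + 1
        }
      }
    }
  }
  expect_gte(n_recovered / n_true, 0.90)
  expect_equal(n_false, 0)
})

test_that("annotation report has one row per network node", {
  nodes <- data.frame(id = c("n1", "n2", "n3"),
                      precursor_mz = c(1189.5878, 740.3627, 500.123),
                      stringsAsFactors = FALSE)
  net <- manual_network(nodes)
  ann <- match_seeds(net, tol = 0.02)
  path <- withr::local_tempfile(fileext = ".tsv")
  rep_df <- annotation_report(net, ann, path = path)
  expect_equal(nrow(rep_df), 3)
  expect_equal(length(readLines(path)) - 1L, 3)
  expect_equal(rep_df$label[rep_df$node_id == "n1"], "cosmomycin D")
  expect_equal(rep_df$label[rep_df$node_id == "n3"], "")
  # empty network: header-only file
  empty <- manual_network(data.frame(id = character(0),
                                     precursor_mz = numeric(0)))
  annotation_report(empty, match_seeds(empty), path = path)
  expect_equal(length(readLines(path)), 1L)
})
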