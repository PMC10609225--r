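# Independent oracles, kept deliberately naive so they share no code path
# with the implementation they check.

# Exhaustive maximum-weight one-to-one matching over candidate peak pairs:
# enumerate every subset assignment recursively.
brute_force_modified_cosine <- function(a, b, frag_tol = 0.02) {
  ia <- a$peaks$intensity; ib <- b$peaks$intensity
  if (!length(ia) || !length(ib) || sum(ia^2) == 0 || sum(ib^2) == 0) {
    return(list(score = 0, n_matched = 0L))
  }
  ia <- ia / sqrt(sum(ia^2)); ib <- ib / sqrt(sum(ib^2))
  shift <- a$precursor_mz - b$precursor_mz
  pairs <- list()
  for (i in seq_along(a$peaks$mz)) {
    for (j in seq_along(b$peaks$mz)) {
      d <- a$peaks$mz[i] - b$peaks$mz[j]
      if (abs(d) <= frag_tol || abs(d - shift) <= frag_tol) {
        pairs[[length(pairs) + 1L]] <- c(i, j)
      }
    }
  }
  best <- list(score = 0, n_matched = 0L)
  n <- length(pairs)
  if (!n) return(best)
  rec <- function(k, used_a, used_b, tot, nm) {
    if (tot > best$score ||
        (tot == best$score && nm > best$n_matched)) {
      best <<- list(score = tot, n_matched = nm)
    }
    if (k > n) return(invisible(NULL))
    rec(k + 1L, used_a, used_b, tot, nm)  # skip this pair
    p <- pairs[[k]]
    if (!used_a[p[1]] && !used_b[p[2]]) {
      ua <- used_a; ua[p[1]] <- TRUE
      ub <- used_b; ub[p[2]] <- TRUE
      w <- ia[p[1]] * ib[p[2]]
      rec(k + 1L, ua, ub, tot + w, nm + as.integer(w > 0))
    }
    invisible(NULL)
  }
  rec(1L, logical(length(ia)), logical(length(ib)), 0, 0L)
  best$score <- min(best$score, 1)
  best
}

# Unpruned brute force over the full CHNOS lattice (H enumerated explicitly).
# The composition grid is built once per bounds and cached.
.bf_grid_cache <- new.env(parent = emptyenv())
brute_force_formulas <- function(mz, charge = 1L, ppm_tol = 5,
                                 bounds = c(C = 70, H = 130, N = 6,
                                            O = 26, S = 2),
                                 rdbe_range = c(0, 40),
                                 hc_range = c(0.2, 3.2)) {
  em <- element_masses()
  key <- paste(bounds, collapse = "_")
  if (is.null(.bf_grid_cache[[key]])) {
    g <- expand.grid(C = 0:bounds[["C"]], H = 0:bounds[["H"]],
                     N = 0:bounds[["N"]], O = 0:bounds[["O"]],
                     S = 0:bounds[["S"]], KEEP.OUT.ATTRS = FALSE)
    g$mass <- g$C * em[["C"]] + g$H * em[["H"]] + g$N * em[["N"]] +
      g$O * em[["O"]] + g$S * em[["S"]]
    .bf_grid_cache[[key]] <- g
  }
  g <- .bf_grid_cache[[key]]
  theo <- (g$mass - charge * em[["electron"]]) / charge
  ppm <- (theo - mz) / mz * 1e6
  rd <- g$C - g$H / 2 + g$N / 2 + 1
  ok <- abs(ppm) <= ppm_tol & rd >= rdbe_range[1] & rd <= rdbe_range[2] &
    (g$C + g$H + g$N + g$O + g$S) >= 1 &
    (g$C == 0 | (g$H / pmax(g$C, 1) >= hc_range[1] &
                 g$H / pmax(g$C, 1) <= hc_range[2]))
  out <- g[ok, c("C", "H", "N", "O", "S")]
  out <- out[order(abs(ppm[ok]), out$C, out$H, out$N, out$O, out$S), ]
  rownames(out) <- NULL
  out
}

# Sorted Hill-string keys for a brute-force composition table (possibly empty).
bf_formula_keys <- function(want) {
  if (!nrow(want)) return(character(0))
  sort(unname(apply(want, 1, function(r) {
    format_formula(c(C = r[["C"]], H = r[["H"]], N = r[["N"]],
                     O = r[["O"]], S = r[["S"]]))
  })))
}

random_small_spectrum <- function(id, n_peaks = NULL, prec_range = c(300, 1200)) {
  if (is.null(n_peaks)) n_peaks <- sample(1:6, 1)
  prec <- runif(1, prec_range[1], prec_range[2])
  msms_spectrum(id, prec,
                mz = sort(runif(n_peaks, 100, prec - 20)),
                intensity = runif(n_peaks, 0.1, 10))
}

fixture_spectrum <- function(name) {
  read_peaklist_tsv(system.file("extdata", paste0(name, ".tsv"),
                                package = "derepnet"))
}
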