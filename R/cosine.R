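# Modified-cosine spectral similarity.
#
# The modified cosine allows a fragment in one spectrum to match a fragment
# in the other either at the same m/z or offset by the difference of the two
# precursor masses; it therefore links structural analogs whose substituent
# shifts a subset of fragments. The score is the maximum total product of
# L2-normalized intensities over one-to-one peak matchings, computed exactly
# by linear assignment (GNPS uses a greedy matching; the exact optimum is
# deterministic, >= greedy, and pinned by a brute-force oracle in the tests).

#' Standard peak preprocessing for networking
#'
#' Removes peaks near the precursor (they carry no structural information and
#' dominate intensity), keeps only the locally strongest peaks, and
#' square-root transforms intensities so single dominant fragments do not
#' swamp the cosine.
#'
#' @param s An [msms_spectrum()].
#' @param precursor_window Peaks within this distance (Da) of the precursor
#'   are removed; default 17 (precursor, its isotopes, and water/ammonia
#'   losses).
#' @param top_k_per_window Keep a peak only if it is among this many most
#'   intense peaks within `window`/2 on either side; default 6.
#' @param window Width (Da) of the sliding intensity-rank window; default 50.
#' @param remove_charge_companion For singly charged precursors, also remove
#'   peaks near the \[M+2H\]2+ companion m/z (within `precursor_window`/2).
#'   Glycoside spectra often carry this precursor-related ion in high
#'   abundance; like the precursor itself it holds no fragment information
#'   and only depresses analog similarity. Default TRUE.
#' @return A new `msms_spectrum` (possibly with zero peaks).
#' @export
preprocess_spectrum <- function(s, precursor_window = 17,
                                top_k_per_window = 6, window = 50,
                                remove_charge_companion = TRUE) {
  stopifnot(inherits(s, "msms_spectrum"))
  mz <- s$peaks$mz
  intensity <- s$peaks$intensity
  keep <- abs(mz - s$precursor_mz) > precursor_window
  if (remove_charge_companion && s$charge == 1L &&
      s$precursor_mz > PROTON_MASS) {
    keep <- keep & abs(mz - charge_companion_mz(s$precursor_mz)) >
      precursor_window / 2
  }
  mz <- mz[keep]; intensity <- intensity[keep]
  if (length(mz)) {
    half <- window / 2
    ok <- vapply(seq_along(mz), function(i) {
      nb <- which(abs(mz - mz[i]) <= half)
      rank_i <- sum(intensity[nb] > intensity[i]) +
        sum(intensity[nb] == intensity[i] & mz[nb] < mz[i]) + 1L
      rank_i <= top_k_per_window
    }, logical(1))
    mz <- mz[ok]; intensity <- sqrt(intensity[ok])
  }
  out <- s
  out$peaks <- data.frame(mz = mz, intensity = intensity)
  out
}

# Exact minimum-cost assignment of n rows to m >= n columns
# (Jonker-Volgenant style shortest augmenting paths). Column m+1 plays the
# role of the virtual "column 0" of the classic formulation.
lsap_min <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  u <- numeric(n)
  v <- numeric(m + 1L)
  p <- integer(m + 1L)      # p[j]: row assigned to column j (0 = free)
  way <- integer(m)
  for (i in seq_len(n)) {
    p[m + 1L] <- i
    j0 <- m + 1L
    minv <- rep(Inf, m)
    used <- logical(m + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf; j1 <- 0L
      uj <- which(!used[seq_len(m)])
      if (length(uj)) {
        cur <- cost[i0, uj] - u[i0] - v[uj]
        upd <- cur < minv[uj]
        if (any(upd)) {
          minv[uj[upd]] <- cur[upd]
          way[uj[upd]] <- j0
        }
        j1 <- uj[which.min(minv[uj])]
        delta <- minv[j1]
      }
      if (!is.finite(delta)) stop("assignment infeasible")  # cannot happen: cost is finite
      us <- which(used)
      v[us] <- v[us] - delta
      u[p[us]] <- u[p[us]] + delta
      minv[uj] <- minv[uj] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == m + 1L) break
    }
  }
  match <- integer(n)
  for (j in seq_len(m)) if (p[j] > 0L) match[p[j]] <- j
  match
}

# Maximum-weight one-to-one matching for a (possibly rectangular) weight
# matrix with nonnegative entries. Returns row -> column indices (0 = no
# profitable assignment is distinguished downstream by zero weight).
lsap_max <- function(w) {
  n <- nrow(w); m <- ncol(w)
  if (n == 0L || m == 0L) return(integer(n))
  if (n > m) {
    tmatch <- lsap_max(t(w))
    match <- integer(n)
    for (j in seq_len(m)) if (tmatch[j] > 0L) match[tmatch[j]] <- j
    return(match)
  }
  lsap_min(-w)
}

#' Modified-cosine similarity between two spectra
#'
#' Candidate peak pairs are those with `|mzA - mzB| <= frag_tol` or
#' `|(mzA - mzB) - (precA - precB)| <= frag_tol`. The score is the maximum
#' total product of L2-normalized intensities over one-to-one matchings of
#' candidate pairs (exact linear assignment; ties broken deterministically
#' toward smaller |m/z difference|). Spectra should already be preprocessed
#' (see [preprocess_spectrum()]); intensities are L2-normalized internally.
#'
#' @param a,b [msms_spectrum()] objects.
#' @param frag_tol Fragment tolerance in Da; default 0.02.
#' @return List with `score` (in \[0, 1\]) and `n_matched` (matched peak
#'   pairs with positive weight). Zero-intensity or empty spectra score 0.
#' @examples
#' s <- msms_spectrum("x", 500, mz = c(100, 200, 300), intensity = c(1, 2, 3))
#' modified_cosine(s, s)$score  # identity: 1
#' @export
modified_cosine <- function(a, b, frag_tol = 0.02) {
  stopifnot(inherits(a, "msms_spectrum"), inherits(b, "msms_spectrum"))
  na <- nrow(a$peaks); nb <- nrow(b$peaks)
  empty <- list(score = 0, n_matched = 0L)
  if (na == 0L || nb == 0L) return(empty)
  ia <- a$peaks$intensity; ib <- b$peaks$intensity
  norm_a <- sqrt(sum(ia^2)); norm_b <- sqrt(sum(ib^2))
  if (norm_a == 0 || norm_b == 0) return(empty)
  ia <- ia / norm_a; ib <- ib / norm_b
  shift <- a$precursor_mz - b$precursor_mz

  d <- outer(a$peaks$mz, b$peaks$mz, "-")
  cand <- abs(d) <= frag_tol | abs(d - shift) <= frag_tol
  if (!any(cand)) return(empty)
  rows <- which(rowSums(cand) > 0)
  cols <- which(colSums(cand) > 0)
  w <- outer(ia[rows], ib[cols])
  w[!cand[rows, cols, drop = FALSE]] <- 0
  # deterministic tie-break: prefer smaller |m/z difference| (direct over
  # shifted where both apply); perturbation far below score tolerance
  mind <- pmin(abs(d[rows, cols, drop = FALSE]),
               abs(d[rows, cols, drop = FALSE] - shift))
  match <- lsap_max(w - 1e-12 * mind)
  score <- 0; nm <- 0L
  for (i in seq_along(match)) {
    j <- match[i]
    if (j > 0L && cand[rows[i], cols[j]] && w[i, j] > 0) {
      score <- score + w[i, j]
      nm <- nm + 1L
    }
  }
  list(score = min(score, 1), n_matched = nm)
}
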