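# Ensemble analytics: ensemble width and inter-ensemble distance, residue
# pair-correlation matrices, local compaction / proximity analysis with
# global Flory fits, and similarity sorting.

#' Ensemble width
#'
#' The population-weighted root-mean-square pairwise CA RMSD among the
#' conformers of an ensemble:
#' `Gamma^2 = sum_{i<j} p_i p_j D_ij^2 / sum_{i<j} p_i p_j`.
#' Zero for a single conformer.
#'
#' @param e An [ensemble()].
#' @param selection Atom indices for the RMSD (default: CA atoms).
#' @param D Optional precomputed [pairwise_rmsd_matrix()].
#' @return Width in Angstrom.
#' @export
ensemble_width <- function(e, selection = NULL, D = NULL) {
  n <- n_conformers(e)
  if (n == 1) return(0)
  if (is.null(D)) D <- pairwise_rmsd_matrix(e, selection)
  p <- e$populations
  iu <- upper.tri(D)
  W <- (p %o% p)[iu]
  sqrt(sum(W * D[iu]^2) / sum(W))
}

#' Distance between two ensembles
#'
#' `Gamma(E1, E2)^2 = sum_i sum_j p_i q_j D_ij^2 / sum_i sum_j p_i q_j`
#' over all cross pairs of conformers. Symmetric; typically not below
#' the geometric mean of the two ensemble widths.
#'
#' @param e1,e2 [ensemble()] objects with compatible atom layouts.
#' @param selection Atom indices for the RMSD (default: CA atoms).
#' @return Distance in Angstrom.
#' @export
ensemble_distance <- function(e1, e2, selection = NULL) {
  if (dim(e1$coords)[1] != dim(e2$coords)[1])
    stop("atom layouts differ between the two ensembles")
  if (is.null(selection)) {
    selection <- ca_selection(e1$atoms)
    if (length(selection) == 0) selection <- seq_len(dim(e1$coords)[1])
  }
  n1 <- n_conformers(e1); n2 <- n_conformers(e2)
  D2 <- matrix(0, n1, n2)
  for (i in seq_len(n1)) {
    xi <- matrix(e1$coords[selection, , i], ncol = 3)
    for (j in seq_len(n2)) {
      D2[i, j] <- rmsd_fit(xi, matrix(e2$coords[selection, , j],
                                      ncol = 3))^2
    }
  }
  W <- e1$populations %o% e2$populations
  sqrt(sum(W * D2) / sum(W))
}

#' Residue pair-correlation analysis
#'
#' Population-weighted mean and standard deviation (no small-sample
#' correction) of every CA-CA distance across the ensemble. A standard
#' deviation of zero denotes perfect order, as within a rigid body.
#'
#' @param e An [ensemble()].
#' @param selection Atom indices of the residue trace (default: CA).
#' @return An object of class `pair_correlation`: symmetric matrices
#'   `mean`, `sd` and `rel` (`sd/mean`, zero diagonal), Angstrom.
#' @export
pair_correlation <- function(e, selection = NULL) {
  if (is.null(selection)) {
    selection <- ca_selection(e$atoms)
    if (length(selection) == 0) selection <- seq_len(dim(e$coords)[1])
  }
  n <- length(selection)
  p <- e$populations
  # two-pass weighted moments: the naive E[d^2] - E[d]^2 form loses ~6
  # digits to cancellation for rigid pairs
  m1 <- matrix(0, n, n)
  dists <- vector("list", n_conformers(e))
  for (c in seq_len(n_conformers(e))) {
    dists[[c]] <- as.matrix(stats::dist(matrix(e$coords[selection, , c],
                                               ncol = 3)))
    m1 <- m1 + p[c] * dists[[c]]
  }
  v <- matrix(0, n, n)
  for (c in seq_len(n_conformers(e)))
    v <- v + p[c] * (dists[[c]] - m1)^2
  sd <- sqrt(pmax(v, 0))
  rel <- sd / ifelse(m1 > 0, m1, 1)
  diag(rel) <- 0
  structure(list(mean = m1, sd = sd, rel = rel),
            class = "pair_correlation")
}

#' Radius of gyration of a chain segment
#'
#' `Rg(m, n)^2` is the mean squared distance of trace atoms `m..n` from
#' their centroid.
#'
#' @param xyz `n_res x 3` matrix of trace coordinates (one conformer).
#' @param m,n Segment limits, `1 <= m < n <= n_res`.
#' @return Rg in Angstrom.
#' @export
segment_radius_of_gyration <- function(xyz, m, n) {
  n_res <- nrow(xyz)
  if (!(m >= 1 && n <= n_res && m < n)) stop("segment indices out of range")
  seg <- xyz[m:n, , drop = FALSE]
  ctr <- colMeans(seg)
  sqrt(mean(rowSums(sweep(seg, 2, ctr)^2)))
}

# ensemble-averaged <Rg^2(m,n)> and <R^2(m,n)> tables over all segments,
# via prefix sums (O(n_res^2) per conformer).
segment_tables <- function(e, selection = NULL) {
  if (is.null(selection)) {
    selection <- ca_selection(e$atoms)
    if (length(selection) == 0) selection <- seq_len(dim(e$coords)[1])
  }
  n <- length(selection)
  p <- e$populations
  rg2 <- matrix(0, n, n); r2 <- matrix(0, n, n)
  len <- outer(seq_len(n), seq_len(n), function(i, j) abs(j - i)) + 1
  for (c in seq_len(n_conformers(e))) {
    x <- matrix(e$coords[selection, , c], ncol = 3)
    x <- sweep(x, 2, colMeans(x))   # centering improves cancellation
    S1 <- apply(rbind(0, x), 2, cumsum)          # (n+1) x 3
    S2 <- cumsum(c(0, rowSums(x^2)))
    # sum2[m, n] = S2[n+1] - S2[m]
    sum2 <- matrix(S2[-1], n, n, byrow = TRUE) - matrix(S2[-(n + 1)], n, n)
    msq <- matrix(0, n, n)
    for (k in 1:3) {
      Sk <- S1[, k]
      mk <- (matrix(Sk[-1], n, n, byrow = TRUE) -
               matrix(Sk[-(n + 1)], n, n)) / len
      msq <- msq + mk^2
    }
    rg2_c <- sum2 / len - msq
    d <- as.matrix(stats::dist(x))
    rg2 <- rg2 + p[c] * rg2_c
    r2 <- r2 + p[c] * d^2
  }
  # only the upper triangle is populated; mirror it
  rg2[lower.tri(rg2)] <- t(rg2)[lower.tri(rg2)]
  list(rg2 = pmax(rg2, 0), r2 = r2, n_res = n)
}

#' Global Flory fit of segment sizes
#'
#' Computes the ensemble-averaged squared segment size (radius of
#' gyration or end-to-end distance) for all residue segments with
#' `n - m >= min_len` and fits the root-mean-square values to the Flory
#' law `R0 * (n - m)^nu` by nonlinear least squares (uniform weights,
#' `nu` constrained to `[0.2, 0.8]`). The exponent `nu` quantifies
#' compactness: ~0.33 for a collapsed coil, 0.5 for an ideal (theta)
#' chain, ~0.6 for an excluded-volume coil.
#'
#' @param e An [ensemble()].
#' @param mode `"gyration"` or `"end_to_end"`.
#' @param min_len Minimum segment length `n - m` entering the fit.
#' @param selection Trace atom indices (default: CA).
#' @param tables Optional precomputed segment-size tables (internal).
#' @return An object of class `flory_fit`: `R0` (Angstrom), `nu`,
#'   `residual` (RMS of the fit), `mode`, `n_segments`.
#' @export
flory_fit <- function(e, mode = c("gyration", "end_to_end"), min_len = 2,
                      selection = NULL, tables = NULL) {
  mode <- match.arg(mode)
  if (is.null(tables)) tables <- segment_tables(e, selection)
  tab <- if (mode == "gyration") tables$rg2 else tables$r2
  n <- tables$n_res
  if (n < 3) stop("need at least 3 trace residues")
  sep <- outer(seq_len(n), seq_len(n), function(i, j) j - i)
  keep <- upper.tri(tab) & sep >= min_len
  x <- sep[keep]
  y <- sqrt(tab[keep])
  if (length(unique(x)) < 2) stop("degenerate segment-length basis")
  fit <- minpack.lm::nlsLM(y ~ R0 * x^nu,
                           start = list(R0 = max(y[x == min(x)][1], 0.1),
                                        nu = 0.5),
                           lower = c(1e-6, 0.2), upper = c(Inf, 0.8),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  structure(list(R0 = unname(cf["R0"]), nu = unname(cf["nu"]),
                 residual = sqrt(mean(stats::resid(fit)^2)),
                 mode = mode, n_segments = length(x), min_len = min_len),
            class = "flory_fit")
}

#' @export
print.flory_fit <- function(x, ...) {
  cat(sprintf("Flory fit (%s): R0 = %.3f A, nu = %.3f (RMS residual %.3f A, %d segments)\n",
              x$mode, x$R0, x$nu, x$residual, x$n_segments))
  invisible(x)
}

#' Compactness and proximity matrices
#'
#' The compactness matrix `G` holds, for every segment `(m, n)`, the
#' relative deviation of the root-mean-square segment radius of gyration
#' from the global Flory fit:
#' `G = (sqrt(<Rg^2>) - R0 (n-m)^nu) / (R0 (n-m)^nu)`;
#' the proximity matrix `P` is the analogue for root-mean-square
#' end-to-end distances with its own fit (`R0_ee`, `nu_ee`). Negative
#' entries mark segments more compact (or closer) than the random-coil
#' description; `P` is the more sensitive of the two.
#'
#' @param e An [ensemble()].
#' @param min_len Minimum segment length (entries below are `NA`).
#' @param selection Trace atom indices (default: CA).
#' @param fit_g,fit_p Optional precomputed [flory_fit()] results.
#' @return An object of class `compaction_matrices`: matrices `G` and
#'   `P`, the underlying `rg2`/`r2` tables and both fits.
#' @export
compaction_matrices <- function(e, min_len = 2, selection = NULL,
                                fit_g = NULL, fit_p = NULL) {
  tables <- segment_tables(e, selection)
  if (is.null(fit_g))
    fit_g <- flory_fit(e, "gyration", min_len, tables = tables)
  if (is.null(fit_p))
    fit_p <- flory_fit(e, "end_to_end", min_len, tables = tables)
  n <- tables$n_res
  sep <- abs(outer(seq_len(n), seq_len(n), `-`))
  valid <- sep >= min_len
  ref_g <- fit_g$R0 * sep^fit_g$nu
  ref_p <- fit_p$R0 * sep^fit_p$nu
  G <- (sqrt(tables$rg2) - ref_g) / ref_g
  P <- (sqrt(tables$r2) - ref_p) / ref_p
  G[!valid] <- NA; P[!valid] <- NA
  structure(list(G = G, P = P, rg2 = tables$rg2, r2 = tables$r2,
                 fit_g = fit_g, fit_p = fit_p, min_len = min_len),
            class = "compaction_matrices")
}

#' Sort and group conformers by similarity
#'
#' Generic similarity sorting: average-linkage hierarchical clustering on
#' the pairwise CA RMSD matrix, cut at the largest gap in merge heights;
#' conformers are reordered by group (groups by total population,
#' descending) and by population within each group. Deterministic.
#'
#' @param e An [ensemble()].
#' @param selection Atom indices for the RMSD (default: CA atoms).
#' @param D Optional precomputed RMSD matrix.
#' @return List with `ensemble` (reordered), `groups` (integer labels
#'   aligned with the new order) and `order` (permutation of the input).
#' @export
sort_group <- function(e, selection = NULL, D = NULL) {
  n <- n_conformers(e)
  if (n == 1)
    return(list(ensemble = e, groups = 1L, order = 1L))
  if (is.null(D)) D <- pairwise_rmsd_matrix(e, selection)
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  h <- hc$height
  if (max(h) < 1e-6) {
    labels <- rep(1L, n)
  } else if (n == 2) {
    labels <- if (h[1] > 1e-6) c(1L, 2L) else c(1L, 1L)
  } else {
    j <- which.max(diff(h))
    cut_h <- (h[j] + h[j + 1]) / 2
    labels <- stats::cutree(hc, h = cut_h)
  }
  p <- e$populations
  grp_pop <- tapply(p, labels, sum)
  grp_rank <- rank(-grp_pop, ties.method = "first")
  new_label <- grp_rank[as.character(labels)]
  ord <- order(new_label, -p, seq_len(n))
  list(ensemble = subset_ensemble(e, ord, renormalize = FALSE),
       groups = as.integer(new_label[ord]), order = ord)
}
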