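# Population fitting of conformer ensembles against heterogeneous
# restraint subsets: distance-distribution overlap, small-angle scattering
# chi-square, combination by minimizing the loss of merit, and
# block-iterative pruning.

#' Default distance grid (0-200 Angstrom, 0.5 Angstrom bins)
#' @return Numeric vector.
#' @export
ddr_grid <- function() seq(0, 200, by = 0.5)

#' Create a distance distribution
#'
#' A probability density on a regular distance grid, normalized to unit
#' area by the trapezoid rule.
#'
#' @param r Regular, strictly increasing distance axis, Angstrom.
#' @param p Non-negative density values.
#' @return An object of class `distance_distribution`.
#' @export
distance_distribution <- function(r, p) {
  r <- as.numeric(r); p <- as.numeric(p)
  stopifnot(length(r) == length(p), length(r) >= 2, all(is.finite(r)))
  if (any(diff(r) <= 0)) stop("distance axis must be strictly increasing")
  if (any(p < -1e-12)) stop("density must be non-negative")
  p <- pmax(p, 0)
  a <- trapz_area(r, p)
  if (a <= 0) stop("distribution has zero area")
  structure(list(r = r, p = p / a), class = "distance_distribution")
}

trapz_area <- function(r, p) sum(diff(r) * (p[-1] + p[-length(p)]) / 2)

resample_distribution <- function(d, r_new) {
  p <- stats::approx(d$r, d$p, xout = r_new, yleft = 0, yright = 0)$y
  if (all(p <= 0)) stop("distribution grids do not overlap")
  distance_distribution(r_new, p)
}

#' Predict a distance distribution from an ensemble
#'
#' The population-weighted sum of per-conformer Gaussians centered at the
#' site-site distance, with a smoothing width representing label-position
#' uncertainty, normalized to unit area.
#'
#' @param e An [ensemble()].
#' @param sites Length-2 site specification: atom row indices, or tags
#'   `"CHAIN.RESNO"` resolved against the CA/P trace atoms of the layout.
#' @param sigma_label Smoothing standard deviation, Angstrom (default 3,
#'   the typical spin-label position uncertainty).
#' @param r Distance grid (default [ddr_grid()]).
#' @return A [distance_distribution()].
#' @export
predict_ddr <- function(e, sites, sigma_label = 3, r = ddr_grid()) {
  idx <- resolve_site_pair(e$atoms, sites)
  d <- site_pair_distances(e, idx)
  dens <- colSums(e$populations *
                    t(vapply(d, function(m) stats::dnorm(r, m, sigma_label),
                             numeric(length(r)))))
  distance_distribution(r, dens)
}

site_pair_distances <- function(e, idx) {
  a <- matrix(e$coords[idx[1], , ], nrow = 3)
  b <- matrix(e$coords[idx[2], , ], nrow = 3)
  sqrt(colSums((a - b)^2))
}

resolve_site_pair <- function(atoms, sites) {
  if (is.numeric(sites)) {
    stopifnot(length(sites) == 2)
    return(as.integer(sites))
  }
  stopifnot(length(sites) == 2)
  tags <- paste0(atoms$chain, ".", atoms$resno)
  trace <- atoms$elety %in% c("CA", "P", "C1'", "C1*")
  vapply(sites, function(s) {
    hit <- which(tags == s & trace)
    if (length(hit) == 0) hit <- which(tags == s)
    if (length(hit) == 0) stop("site '", s, "' not found in atom layout")
    hit[1]
  }, integer(1))
}

#' Overlap of two unit-area distance distributions
#'
#' `o = sum(min(P1, P2)) * dr` on a common grid; 1 for identical
#' distributions, 0 for disjoint supports. Symmetric in its arguments.
#'
#' @param p_pred,p_exp [distance_distribution()] objects (`p_exp` is
#'   resampled onto `p_pred`'s grid when the grids differ).
#' @return Overlap in `[0, 1]`.
#' @export
overlap <- function(p_pred, p_exp) {
  if (!isTRUE(all.equal(p_pred$r, p_exp$r)))
    p_exp <- resample_distribution(p_exp, p_pred$r)
  min(1, trapz_area(p_pred$r, pmin(p_pred$p, p_exp$p)))
}

#' Distance-restraint metric: one minus the geometric mean overlap
#'
#' @param overlaps Vector of per-restraint overlaps in `[0, 1]`.
#' @return `1 - prod(o)^(1/D)`, in `[0, 1]`.
#' @export
ddr_metric <- function(overlaps) {
  if (length(overlaps) == 0) stop("no overlaps given")
  stopifnot(all(overlaps >= 0), all(overlaps <= 1))
  1 - prod(overlaps)^(1 / length(overlaps))
}

#' Create a small-angle scattering curve
#' @param q Scattering vector, 1/Angstrom, strictly increasing.
#' @param intensity Intensities.
#' @param sigma Positive per-point uncertainties.
#' @return An object of class `sas_curve`.
#' @export
sas_curve <- function(q, intensity, sigma) {
  stopifnot(length(q) == length(intensity), length(q) == length(sigma))
  if (any(diff(q) <= 0)) stop("q axis must be strictly increasing")
  if (any(sigma <= 0)) stop("sigma must be > 0")
  structure(list(q = as.numeric(q), intensity = as.numeric(intensity),
                 sigma = as.numeric(sigma)), class = "sas_curve")
}

#' Coarse-grained Debye scattering predictor
#'
#' Computes `I(q) = sum_i sum_j f_i f_j sin(q d_ij)/(q d_ij)` over
#' scattering centers with per-center form-factor weights, with
#' `sinc(0) = 1`. The default method accumulates pair distances into a
#' histogram before evaluating the sine kernel; `method = "direct"`
#' evaluates the full double sum.
#'
#' @param xyz `n x 3` matrix of scattering-center coordinates.
#' @param q Non-negative scattering-vector grid, 1/Angstrom.
#' @param weights Per-center form-factor weights (default 1).
#' @param method `"histogram"` (binned, default) or `"direct"`.
#' @param bin Histogram bin width, Angstrom.
#' @return Vector `I(q)`.
#' @export
debye_predictor <- function(xyz, q, weights = NULL,
                            method = c("histogram", "direct"), bin = 0.02) {
  method <- match.arg(method)
  if (any(q < 0)) stop("q must be non-negative")
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n)
  sinc <- function(x) ifelse(x == 0, 1, sin(x) / x)
  d <- as.matrix(stats::dist(xyz))
  iu <- upper.tri(d)
  dv <- d[iu]
  wv <- (weights %o% weights)[iu]
  self <- sum(weights^2)
  if (method == "direct") {
    I <- vapply(q, function(qq) self + 2 * sum(wv * sinc(qq * dv)),
                numeric(1))
  } else {
    br <- pmax(1L, as.integer(round(dv / bin)))
    W <- tapply(wv, br, sum)
    dc <- as.numeric(names(W)) * bin
    W <- as.numeric(W)
    I <- vapply(q, function(qq) self + 2 * sum(W * sinc(qq * dc)),
                numeric(1))
  }
  I
}

#' Per-conformer scattering curves for an ensemble
#'
#' Evaluates a scattering predictor for every conformer. The predictor
#' hook makes externally computed curves substitutable bit-exactly: pass
#' a function `f(xyz, q)`, a precomputed `n_conf x n_q` matrix, or a
#' vector of file paths (3-column text, one per conformer, in conformer
#' order).
#'
#' @param e An [ensemble()].
#' @param q Scattering-vector grid.
#' @param predictor Function, matrix, or character vector of files;
#'   default: [debye_predictor()] on the CA/P trace.
#' @param selection Atom indices used by the default predictor.
#' @return `n_conf x n_q` matrix of intensities.
#' @export
conformer_sas_curves <- function(e, q, predictor = NULL, selection = NULL) {
  n <- n_conformers(e)
  if (is.matrix(predictor)) {
    stopifnot(nrow(predictor) == n, ncol(predictor) == length(q))
    return(predictor)
  }
  if (is.character(predictor)) {
    stopifnot(length(predictor) == n)
    out <- t(vapply(predictor, function(f) {
      cv <- read_sas_curve(f)
      stats::approx(cv$q, cv$intensity, xout = q, rule = 2)$y
    }, numeric(length(q))))
    rownames(out) <- NULL
    return(out)
  }
  if (is.null(selection)) {
    selection <- ca_selection(e$atoms, include_nucleic = TRUE)
    if (length(selection) == 0) selection <- seq_len(dim(e$coords)[1])
  }
  fun <- if (is.function(predictor)) predictor
         else function(xyz, qq) debye_predictor(xyz, qq)
  t(vapply(seq_len(n),
           function(i) fun(e$coords[selection, , i, drop = TRUE], q),
           numeric(length(q))))
}

# weighted least-squares scale + offset fit of a predicted curve to an
# experimental one; returns fitted curve, coefficients and chi^2 (reduced
# by the number of q points).
fit_curve_chi2 <- function(I_pred, curve) {
  w <- 1 / curve$sigma^2
  X <- cbind(I_pred, 1)
  A <- crossprod(X * w, X)
  bvec <- crossprod(X * w, curve$intensity)
  coef <- solve(A, bvec)
  fit <- as.numeric(X %*% coef)
  chi2 <- mean(w * (fit - curve$intensity)^2)
  list(chi2 = chi2, scale = coef[1], offset = coef[2], fit = fit)
}

#' Scattering metric of an ensemble: summed reduced chi-square
#'
#' The ensemble curve is the population-weighted sum of per-conformer
#' curves; each experimental curve is fitted with a free scale and
#' additive constant by weighted least squares, and
#' `chi^2 = mean(((I_fit - I_exp)/sigma)^2)`. The metric sums over all
#' curves.
#'
#' @param e An [ensemble()].
#' @param curves A [sas_curve()] or list of them.
#' @param predictor Predictor hook (see [conformer_sas_curves()]).
#' @return Summed chi-square.
#' @export
sas_metric <- function(e, curves, predictor = NULL) {
  if (inherits(curves, "sas_curve")) curves <- list(curves)
  total <- 0
  for (cv in curves) {
    C <- conformer_sas_curves(e, cv$q, predictor)
    I_ens <- as.numeric(e$populations %*% C)
    total <- total + fit_curve_chi2(I_ens, cv)$chi2
  }
  total
}

# ---- restraint subsets ----------------------------------------------------

#' Build a distance-restraint subset for population fitting
#'
#' Precomputes the per-conformer Gaussian kernel of every restraint so
#' the predicted distribution for any population vector is a single
#' matrix product.
#'
#' @param e An [ensemble()] (the raw conformer pool).
#' @param targets List of experimental [distance_distribution()] objects.
#' @param sites List of length-2 site specifications, parallel to
#'   `targets`.
#' @param sigma_label Smoothing width, Angstrom.
#' @param r Common grid.
#' @return An object of class `restraint_subset` (kind `"ddr"`).
#' @export
ddr_subset <- function(e, targets, sites, sigma_label = 3, r = ddr_grid()) {
  stopifnot(length(targets) == length(sites))
  dr <- mean(diff(r))
  wts <- rep(dr, length(r)); wts[c(1, length(r))] <- dr / 2
  kernels <- vector("list", length(targets))
  tvals <- vector("list", length(targets))
  for (i in seq_along(targets)) {
    idx <- resolve_site_pair(e$atoms, sites[[i]])
    dd <- site_pair_distances(e, idx)
    K <- t(vapply(as.numeric(dd),
                  function(m) stats::dnorm(r, m, sigma_label),
                  numeric(length(r))))
    # unit-area rows so that p on the simplex gives a unit-area prediction
    K <- K / pmax(as.numeric(K %*% wts), .Machine$double.eps)
    kernels[[i]] <- K
    tg <- targets[[i]]
    if (!isTRUE(all.equal(tg$r, r))) tg <- resample_distribution(tg, r)
    tvals[[i]] <- tg$p
  }
  structure(list(kind = "ddr", kernels = kernels, targets = tvals,
                 dr = dr, wts = wts, r = r),
            class = "restraint_subset")
}

#' Build a scattering subset for population fitting
#'
#' @param e An [ensemble()] (the raw conformer pool).
#' @param curves A [sas_curve()] or list of them.
#' @param predictor Predictor hook (see [conformer_sas_curves()]).
#' @return An object of class `restraint_subset` (kind `"sas"`).
#' @export
sas_subset <- function(e, curves, predictor = NULL) {
  if (inherits(curves, "sas_curve")) curves <- list(curves)
  entries <- lapply(curves, function(cv) {
    list(C = conformer_sas_curves(e, cv$q, predictor), curve = cv)
  })
  structure(list(kind = "sas", entries = entries),
            class = "restraint_subset")
}

subset_rows <- function(subset, idx) {
  if (subset$kind == "ddr") {
    subset$kernels <- lapply(subset$kernels, function(K)
      K[idx, , drop = FALSE])
  } else {
    subset$entries <- lapply(subset$entries, function(en) {
      en$C <- en$C[idx, , drop = FALSE]; en
    })
  }
  subset
}

subset_overlaps <- function(subset, p) {
  vapply(seq_along(subset$kernels), function(i) {
    pred <- as.numeric(p %*% subset$kernels[[i]])
    min(1, sum(pmin(pred, subset$targets[[i]]) * subset$wts))
  }, numeric(1))
}

metric_value <- function(subset, p) {
  if (subset$kind == "ddr") {
    ddr_metric(subset_overlaps(subset, p))
  } else {
    total <- 0
    for (en in subset$entries) {
      I_ens <- as.numeric(p %*% en$C)
      total <- total + fit_curve_chi2(I_ens, en$curve)$chi2
    }
    total
  }
}

metric_grad <- function(subset, p) {
  if (subset$kind == "ddr") {
    D <- length(subset$kernels)
    o <- pmax(subset_overlaps(subset, p), 1e-12)
    G <- prod(o)^(1 / D)
    g <- numeric(length(p))
    for (i in seq_len(D)) {
      K <- subset$kernels[[i]]
      pred <- as.numeric(p %*% K)
      act <- pred < subset$targets[[i]]
      do_dp <- as.numeric(K[, act, drop = FALSE] %*% subset$wts[act])
      g <- g - (G / D) / o[i] * do_dp
    }
    g
  } else {
    g <- numeric(length(p))
    for (en in subset$entries) {
      I_ens <- as.numeric(p %*% en$C)
      f <- fit_curve_chi2(I_ens, en$curve)
      w <- 1 / en$curve$sigma^2
      r <- f$fit - en$curve$intensity
      g <- g + as.numeric(en$C %*% (2 / length(w) * w * r * f$scale))
    }
    g
  }
}

# minimize fn(p) over the probability simplex via p = w^2/sum(w^2),
# quasi-Newton inner solver, multi-start.
simplex_minimize <- function(n, fn, gr, n_starts = 5, seed = 1,
                             p_init = NULL, maxit = 300) {
  obj_w <- function(w) fn(w^2 / sum(w^2))
  grad_w <- function(w) {
    S <- sum(w^2)
    p <- w^2 / S
    g <- gr(p)
    (2 * w / S) * (g - sum(g * p))
  }
  starts <- list(rep(1, n))
  if (!is.null(p_init)) starts[[length(starts) + 1]] <- sqrt(pmax(p_init, 1e-8))
  with_seed(seed, {
    while (length(starts) < n_starts)
      starts[[length(starts) + 1]] <- exp(stats::rnorm(n, 0, 0.5))
  })
  best <- NULL
  for (w0 in starts) {
    opt <- tryCatch(
      stats::optim(w0, obj_w, grad_w, method = "BFGS",
                   control = list(maxit = maxit, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("population optimization failed on all starts")
  p <- best$par^2 / sum(best$par^2)
  list(p = p, value = best$value, convergence = best$convergence)
}

#' Fit conformer populations against restraint subsets
#'
#' With a single subset, minimizes that subset's metric over the
#' probability simplex. With several subsets, first finds each subset's
#' own optimum `m1_k`, then minimizes the loss of merit
#' `L = mean(m2_k/m1_k - 1)` where the `m2_k` are the subset metrics of
#' the common population vector. `L = 0` only if all subsets are
#' perfectly consistent.
#'
#' @param subsets List of `restraint_subset` objects.
#' @param n_conf Number of conformers (rows of the subset kernels).
#' @param p_init Optional initial population vector.
#' @param n_starts Multi-start count for the simplex optimizer.
#' @param seed Integer seed for the random starts.
#' @return List with `p`, per-subset `m1` and `m2`, and `L` (0 when a
#'   single subset is fitted).
#' @export
fit_populations <- function(subsets, n_conf, p_init = NULL, n_starts = 5,
                            seed = 1) {
  if (inherits(subsets, "restraint_subset")) subsets <- list(subsets)
  R <- length(subsets)
  stopifnot(R >= 1)
  if (n_conf == 1) {
    m <- vapply(subsets, metric_value, numeric(1), p = 1)
    return(list(p = 1, m1 = m, m2 = m, L = 0))
  }
  single <- lapply(seq_len(R), function(k)
    simplex_minimize(n_conf, function(p) metric_value(subsets[[k]], p),
                     function(p) metric_grad(subsets[[k]], p),
                     n_starts = n_starts, seed = seed + k,
                     p_init = p_init))
  m1 <- vapply(single, `[[`, numeric(1), "value")
  if (R == 1) {
    p <- single[[1]]$p
    return(list(p = p, m1 = m1, m2 = m1, L = 0))
  }
  m1_safe <- pmax(m1, 1e-6)
  loss <- function(p) {
    mean(vapply(seq_len(R), function(k)
      metric_value(subsets[[k]], p), numeric(1)) / m1_safe - 1)
  }
  loss_grad <- function(p) {
    g <- numeric(length(p))
    for (k in seq_len(R)) g <- g + metric_grad(subsets[[k]], p) / m1_safe[k]
    g / R
  }
  p0 <- single[[which.min(m1)]]$p
  comb <- simplex_minimize(n_conf, loss, loss_grad, n_starts = n_starts,
                           seed = seed, p_init = p0)
  m2 <- vapply(seq_len(R), function(k)
    metric_value(subsets[[k]], comb$p), numeric(1))
  # the combined-fit value is itself attainable by a subset-only fit, so
  # it tightens the numerical estimate of the subset optimum
  m1 <- pmin(m1, m2)
  list(p = comb$p, m1 = m1, m2 = m2,
       L = mean(m2 / pmax(m1, 1e-6) - 1))
}

#' Prune low-population conformers
#'
#' Discards all conformers with `p < 0.01 * max(p)` (strict inequality)
#' and renormalizes the survivors.
#'
#' @param p Population vector on the simplex.
#' @param threshold Relative threshold (default 0.01).
#' @return List with `idx` (retained indices) and `p` (renormalized).
#' @export
prune <- function(p, threshold = 0.01) {
  keep <- which(p >= threshold * max(p))
  list(idx = keep, p = p[keep] / sum(p[keep]))
}

#' Block-iterative population fitting of a large conformer pool
#'
#' Fits populations for a block of at most `block_size` conformers,
#' prunes conformers below `0.01 * max(p)`, refills the block with
#' previously untested conformers, and repeats until the untested pool
#' is empty. A final fit on the retained set yields the reported
#' populations, per-subset metrics and loss of merit.
#'
#' @param subsets List of `restraint_subset` objects built on the full
#'   pool (their rows are indexed per block).
#' @param n_conf Total pool size.
#' @param block_size Block size `N_B` (default 100; useful up to ~250).
#' @param refill `"input"` (default) or `"shuffle"`: order in which
#'   untested conformers refill the block.
#' @param seed Integer seed (shuffle order and optimizer starts).
#' @param n_starts Multi-start count per fit.
#' @return An object of class `fit_result`: `indices` (into the pool),
#'   `p`, `m1`, `m2`, `L`, `n_blocks`, `n_pool`, `n_retained`, and the
#'   per-block pruning `trail`.
#' @export
block_fit <- function(subsets, n_conf, block_size = 100,
                      refill = c("input", "shuffle"), seed = 1,
                      n_starts = 5) {
  refill <- match.arg(refill)
  if (inherits(subsets, "restraint_subset")) subsets <- list(subsets)
  stopifnot(n_conf >= 1)
  order_all <- seq_len(n_conf)
  if (refill == "shuffle")
    order_all <- with_seed(seed, sample.int(n_conf))
  untested <- order_all
  active <- integer(0)
  trail <- list(); n_blocks <- 0
  p_active <- numeric(0)
  repeat {
    take <- min(block_size - length(active), length(untested))
    if (take > 0) {
      active <- c(active, untested[seq_len(take)])
      untested <- untested[-seq_len(take)]
    }
    n_blocks <- n_blocks + 1
    sub_k <- lapply(subsets, subset_rows, idx = active)
    fit <- fit_populations(sub_k, length(active), n_starts = n_starts,
                           seed = seed + n_blocks)
    pr <- prune(fit$p)
    trail[[n_blocks]] <- list(block = active, retained = active[pr$idx])
    active <- active[pr$idx]
    p_active <- pr$p
    if (length(untested) == 0) break
  }
  idx <- active
  m2 <- vapply(seq_along(subsets), function(k)
    metric_value(subset_rows(subsets[[k]], idx), p_active), numeric(1))
  # subset-only optima on the retained set, for the merit report; any
  # achieved combined value upper-bounds the subset optimum
  if (length(subsets) > 1 && length(idx) > 1) {
    m1 <- vapply(seq_along(subsets), function(k) {
      sub <- subset_rows(subsets[[k]], idx)
      simplex_minimize(length(idx), function(p) metric_value(sub, p),
                       function(p) metric_grad(sub, p),
                       n_starts = n_starts, seed = seed + k,
                       p_init = p_active)$value
    }, numeric(1))
    m1 <- pmin(m1, m2)
  } else m1 <- m2
  structure(list(indices = idx, p = p_active, m1 = m1, m2 = m2,
                 L = if (length(subsets) > 1)
                   mean(m2 / pmax(m1, 1e-6) - 1) else 0,
                 n_blocks = n_blocks, n_pool = n_conf,
                 n_retained = length(idx), trail = trail),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("population fit: %d of %d conformers retained (%d blocks)\n",
              x$n_retained, x$n_pool, x$n_blocks))
  cat("  m1:", signif(x$m1, 4), "\n  m2:", signif(x$m2, 4),
      "\n  loss of merit L:", signif(x$L, 4), "\n")
  invisible(x)
}
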