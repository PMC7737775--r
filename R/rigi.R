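# Rigid-body-arrangement generation from distance-distribution restraints:
# enumerated sampling of reference-point distance matrices, distance-geometry
# embedding, restraint testing in order of increasing cost, and
# restraint-limited refinement.

#' Create a distance-distribution restraint
#'
#' A restraint on the distance between two labeled sites, either Gaussian
#' (mean and standard deviation) or as a tabulated distribution. For
#' Gaussian experimental restraints the sampling interval is
#' `[mean - sigma, mean + sigma]`; for undetermined pairs the bounds
#' default to 5 Angstrom (lower) and a configurable upper limit
#' (180 Angstrom by default).
#'
#' @param site_a,site_b Site references: a [label_site()] or a tag string
#'   `"CHAIN.RESNO"` resolved against the rigid bodies at run time.
#' @param mean Mean distance in Angstrom (optional).
#' @param sigma Standard deviation in Angstrom, `> 0` (required with `mean`).
#' @param lower,upper Explicit bounds in Angstrom; derived from
#'   `mean`/`sigma` or defaults when omitted.
#' @param role One of `"reference"`, `"auxiliary"`, `"linker_bound"`,
#'   `"crosslink"`.
#' @param distribution Optional tabulated [distance_distribution()].
#' @param upper_default Upper bound applied when no information is given.
#' @return An object of class `distance_restraint`.
#' @export
distance_restraint <- function(site_a, site_b, mean = NULL, sigma = NULL,
                               lower = NULL, upper = NULL,
                               role = c("reference", "auxiliary",
                                        "linker_bound", "crosslink"),
                               distribution = NULL, upper_default = 180) {
  role <- match.arg(role)
  if (!is.null(mean)) {
    stopifnot(is.numeric(mean), mean > 0)
    if (is.null(sigma) || sigma <= 0)
      stop("a Gaussian restraint needs sigma > 0")
    if (is.null(lower)) lower <- mean - sigma
    if (is.null(upper)) upper <- mean + sigma
  }
  if (is.null(lower)) lower <- 5
  if (is.null(upper)) upper <- upper_default
  if (!(lower > 0 && lower <= upper))
    stop("restraint bounds must satisfy 0 < lower <= upper")
  structure(list(site_a = site_a, site_b = site_b,
                 mean = mean, sigma = sigma,
                 lower = lower, upper = upper, role = role,
                 distribution = distribution),
            class = "distance_restraint")
}

#' Acceptance settings for arrangement testing
#'
#' @param p_thr Probability threshold in `(0, 1]` on the geometric mean of
#'   the per-restraint Gaussian fractions `g_i`; default 0.5.
#' @param coverage Alternative parametrization: central probability mass
#'   whose edge value defines `p_thr` (see [coverage_to_threshold()]);
#'   overrides `p_thr` when given.
#' @param f_x Fraction of crosslink restraints that must be fulfilled.
#' @param peptide_max Maximum peptide linker extension, Angstrom/residue.
#' @param rna_max Maximum RNA linker extension, Angstrom/nucleotide.
#' @param clash_cutoff Inter-body heavy-atom clash cutoff, Angstrom.
#' @return An object of class `acceptance_spec`.
#' @export
acceptance_spec <- function(p_thr = 0.5, coverage = NULL, f_x = 1,
                            peptide_max = 3.8, rna_max = 7,
                            clash_cutoff = 2.0) {
  if (!is.null(coverage)) p_thr <- coverage_to_threshold(coverage)
  stopifnot(p_thr > 0, p_thr <= 1, f_x >= 0, f_x <= 1,
            peptide_max > 0, rna_max > 0, clash_cutoff >= 0)
  structure(list(p_thr = p_thr, f_x = f_x, peptide_max = peptide_max,
                 rna_max = rna_max, clash_cutoff = clash_cutoff),
            class = "acceptance_spec")
}

#' Convert a coverage percentage into a probability threshold
#'
#' For a Gaussian restraint, a central probability mass `coverage`
#' corresponds to a half-width of `z` standard deviations with
#' `z = qnorm((1 + coverage)/2)`; the Gaussian fraction at that edge is
#' `p_thr = exp(-z^2/2)`.
#'
#' @param coverage Central probability mass, in `(0, 1)`.
#' @return Threshold `p_thr` in `(0, 1]`.
#' @export
coverage_to_threshold <- function(coverage) {
  if (!(is.numeric(coverage) && coverage > 0 && coverage < 1))
    stop("coverage must lie in (0, 1)")
  z <- stats::qnorm((1 + coverage) / 2)
  exp(-z^2 / 2)
}

#' Choose three reference sites in a rigid body
#'
#' Selects the candidate triple forming the largest, most nearly
#' equilateral triangle: the triple maximizing the minimum side length,
#' with ties broken by maximal triangle area. A large, near-equilateral
#' reference triangle minimizes linear dependence among the reference
#' distance restraints.
#'
#' @param candidates List of [label_site()] candidates (`>= 3`).
#' @return List of 3 selected [label_site()] objects (in input order).
#' @export
choose_reference_sites <- function(candidates) {
  if (length(candidates) < 3) stop("need at least 3 candidate sites")
  pts <- t(vapply(candidates, function(s) s$position, numeric(3)))
  n <- nrow(pts)
  best <- NULL; best_min <- -Inf; best_area <- -Inf
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    d <- c(sqrt(sum((pts[i, ] - pts[j, ])^2)),
           sqrt(sum((pts[i, ] - pts[k, ])^2)),
           sqrt(sum((pts[j, ] - pts[k, ])^2)))
    mn <- min(d)
    area <- 0.5 * sqrt(sum(.cross3(pts[j, ] - pts[i, ],
                                   pts[k, ] - pts[i, ])^2))
    if (mn > best_min + 1e-12 ||
        (abs(mn - best_min) <= 1e-12 && area > best_area + 1e-12)) {
      best <- c(i, j, k); best_min <- mn; best_area <- area
    }
  }
  if (best_area < 1e-8)
    stop("all candidate triples are collinear")
  candidates[best]
}

#' Triangle-inequality smoothing of distance bounds
#'
#' Tightens a matrix pair of lower/upper distance bounds using the
#' triangle inequality across all point triples (shortest-path transform
#' on the upper bounds; the standard inverse transform on the lower
#' bounds). Bounds only tighten. Inconsistent input (a lower bound ending
#' above an upper bound) raises an error of class `semiflex_infeasible`.
#'
#' @param lower,upper Symmetric matrices (Angstrom), zero diagonal,
#'   `lower <= upper` element-wise.
#' @return List with tightened `lower` and `upper`.
#' @export
smooth_bounds <- function(lower, upper) {
  m <- nrow(upper)
  stopifnot(ncol(upper) == m, nrow(lower) == m, ncol(lower) == m)
  if (any(lower > upper + 1e-12))
    stop("lower bounds exceed upper bounds on input")
  u <- upper; l <- lower
  # Floyd-Warshall on upper bounds
  for (k in seq_len(m)) {
    uk <- u[, k]
    u <- pmin(u, outer(uk, uk, `+`))
  }
  # lower-bound transform, iterated to its fixpoint
  repeat {
    l_old <- l
    for (k in seq_len(m)) {
      l <- pmax(l, outer(l[, k], u[, k], `-`), outer(u[, k], l[, k],
                                                     function(a, b) b - a))
    }
    diag(l) <- 0
    if (max(abs(l - l_old)) < 1e-12) break
  }
  if (any(l > u + 1e-9)) {
    cond <- structure(class = c("semiflex_infeasible", "error", "condition"),
                      list(message = "distance bounds are infeasible after triangle smoothing",
                           call = sys.call()))
    stop(cond)
  }
  list(lower = l, upper = pmin(u, upper))
}

#' Plan enumerated sampling of restrained distances
#'
#' Builds the complete lower/upper bound matrices for the `3n` reference
#' sites (intra-body distances fixed, restrained pairs at their
#' `[l, u]` intervals, undetermined pairs at default bounds), applies
#' triangle-bound smoothing, and finds the minimal sampling resolution
#' `dr` on a 0.01-Angstrom grid such that the total number of trials
#' `T = prod(s_i)` does not exceed `t_max`, with
#' `s_i = ceiling(width_i/dr) + 1` sample points placed equidistantly
#' (endpoints included) on each restrained interval.
#'
#' @param bodies List of [rigid_body()] objects (`n >= 2`).
#' @param restraints List of [distance_restraint()] objects; only
#'   reference-role restraints between reference sites are enumerated.
#' @param t_max Trial cap `T_max` (`>= 1`).
#' @param upper_default Upper bound for undetermined pairs, Angstrom.
#' @return An object of class `sampling_plan` with elements `s`
#'   (per-restraint counts), `dr_i` (per-restraint spacings), `dr`
#'   (max spacing), `t_total`, `pairs` (index pairs into the reference
#'   list), `samples` (per-restraint sample values), `base` (the fixed
#'   part of the distance matrix), and the smoothed `lower`/`upper`.
#' @export
plan_sampling <- function(bodies, restraints, t_max,
                          upper_default = 180) {
  stopifnot(t_max >= 1, length(bodies) >= 2)
  res <- resolve_restraints(bodies, restraints)
  m <- 3 * length(bodies)
  ref_pos <- reference_positions(bodies)
  # bounds: intra-body exact, restrained [l,u], else defaults
  D0 <- as.matrix(stats::dist(ref_pos))
  lower <- matrix(5, m, m); upper <- matrix(upper_default, m, m)
  for (b in seq_along(bodies)) {
    idx <- (3 * b - 3) + 1:3
    lower[idx, idx] <- upper[idx, idx] <- D0[idx, idx]
  }
  ref_r <- res[res$role == "reference" & res$on_ref, , drop = FALSE]
  for (r in seq_len(nrow(ref_r))) {
    i <- ref_r$gi_a[r]; j <- ref_r$gi_b[r]
    lower[i, j] <- lower[j, i] <- ref_r$lower[r]
    upper[i, j] <- upper[j, i] <- ref_r$upper[r]
  }
  diag(lower) <- diag(upper) <- 0
  sm <- smooth_bounds(lower, upper)
  pairs <- cbind(ref_r$gi_a, ref_r$gi_b)
  w <- numeric(nrow(pairs))
  for (r in seq_len(nrow(pairs)))
    w[r] <- sm$upper[pairs[r, 1], pairs[r, 2]] -
      sm$lower[pairs[r, 1], pairs[r, 2]]
  w <- pmax(w, 0)
  counts <- function(dr) ifelse(w <= 1e-9, 1L, ceiling(w / dr - 1e-12) + 1L)
  trials <- function(dr) prod(as.numeric(counts(dr)))
  grid <- 0.01
  hi <- max(c(w, grid)) + grid
  hi <- ceiling(hi / grid)   # grid units
  if (trials(hi * grid) > t_max)
    stop("t_max too small: even the coarsest sampling exceeds it")
  lo <- 1L
  if (trials(lo * grid) <= t_max) {
    hi <- lo
  } else {
    while (hi - lo > 1L) {           # T(dr) is non-increasing in dr
      mid <- (lo + hi) %/% 2
      if (trials(mid * grid) <= t_max) hi <- mid else lo <- mid
    }
  }
  dr_found <- hi * grid
  s <- counts(dr_found)
  samples <- vector("list", length(s))
  dr_i <- numeric(length(s))
  for (r in seq_along(s)) {
    lo_r <- sm$lower[pairs[r, 1], pairs[r, 2]]
    up_r <- sm$upper[pairs[r, 1], pairs[r, 2]]
    samples[[r]] <- seq(lo_r, up_r, length.out = s[r])
    dr_i[r] <- if (s[r] > 1) (up_r - lo_r) / (s[r] - 1) else 0
  }
  # fixed part: intra-body distances plus undetermined pairs at the
  # midpoint of their smoothed bounds
  base <- (sm$lower + sm$upper) / 2
  for (b in seq_along(bodies)) {
    idx <- (3 * b - 3) + 1:3
    base[idx, idx] <- D0[idx, idx]
  }
  diag(base) <- 0
  structure(list(s = as.integer(s), dr_i = dr_i,
                 dr = if (length(dr_i)) max(dr_i) else 0,
                 dr_grid = dr_found,
                 t_total = prod(as.numeric(s)),
                 pairs = pairs, samples = samples, base = base,
                 lower = sm$lower, upper = sm$upper),
            class = "sampling_plan")
}

#' Enumerate complete distance matrices from a sampling plan
#'
#' The Cartesian product of the per-restraint sample points merged into
#' the fixed base matrix, yielding exactly `T` complete symmetric
#' distance matrices in lexicographic order (first restraint most
#' significant). Matrices failing a triangle-inequality screen are
#' flagged skippable rather than omitted.
#'
#' @param plan A [plan_sampling()] result.
#' @return List with `n` (total count `T`), `matrix_at(t)` returning the
#'   t-th matrix, and `passes_screen(mat)` for the triangle screen.
#' @export
enumerate_distance_matrices <- function(plan) {
  s <- plan$s
  m_restraints <- length(s)
  radix_div <- rev(cumprod(rev(c(s[-1], 1))))  # place values, first most significant
  matrix_at <- function(t) {
    stopifnot(t >= 1, t <= plan$t_total)
    M <- plan$base
    if (m_restraints > 0) {
      rem <- t - 1
      for (r in seq_len(m_restraints)) {
        digit <- rem %/% radix_div[r]
        rem <- rem %% radix_div[r]
        val <- plan$samples[[r]][digit + 1]
        i <- plan$pairs[r, 1]; j <- plan$pairs[r, 2]
        M[i, j] <- M[j, i] <- val
      }
    }
    M
  }
  passes_screen <- function(M) {
    m <- nrow(M)
    for (k in seq_len(m)) {
      if (any(M > outer(M[, k], M[, k], `+`) + 1e-9)) return(FALSE)
    }
    TRUE
  }
  list(n = plan$t_total, matrix_at = matrix_at, passes_screen = passes_screen)
}

#' Embed a reference-point distance matrix as rigid-body arrangements
#'
#' Classical metric-matrix distance geometry: the Gram matrix of the
#' centered squared distances is eigendecomposed and the top three
#' components give 3D coordinates for the `3n` reference points. Each
#' body's native reference triangle is then superposed onto its embedded
#' points. Since reference-point distances cannot distinguish mirror
#' images, both enantiomorphs of the embedded point set are returned as
#' candidate arrangements (normalized so body 1 is the identity).
#'
#' @param D Symmetric `3n x 3n` distance matrix, zero diagonal.
#' @param bodies List of [rigid_body()] objects.
#' @param neg_mass_tol Maximum ratio of negative to positive eigenvalue
#'   mass for the matrix to count as embeddable (default 0.01).
#' @param fit_tol Maximum RMSD (Angstrom) between a body's native
#'   reference triangle and its embedded points (default 0.5).
#' @return List of 0, 1, or 2 [rba_model()] candidates. When empty, the
#'   attribute `reason` distinguishes `"non_embeddable"` from `"fit"`.
#' @export
embed_rba <- function(D, bodies, neg_mass_tol = 0.01, fit_tol = 0.5) {
  m <- nrow(D)
  stopifnot(ncol(D) == m, m == 3 * length(bodies))
  D2 <- D^2
  J <- diag(m) - matrix(1 / m, m, m)
  G <- -0.5 * J %*% D2 %*% J
  ev <- eigen((G + t(G)) / 2, symmetric = TRUE)
  lam <- ev$values
  neg <- sum(abs(pmin(lam, 0))); pos <- sum(pmax(lam, 0))
  if (pos <= 0 || neg > neg_mass_tol * pos)
    return(structure(list(), reason = "non_embeddable"))
  X <- ev$vectors[, 1:3, drop = FALSE] %*% diag(sqrt(pmax(lam[1:3], 0)))
  out <- list()
  for (mirror in c(FALSE, TRUE)) {
    Xc <- if (mirror) X %*% diag(c(1, 1, -1)) else X
    rot <- vector("list", length(bodies))
    tra <- vector("list", length(bodies))
    ok <- TRUE
    for (b in seq_along(bodies)) {
      idx <- (3 * b - 3) + 1:3
      native <- t(vapply(bodies[[b]]$ref_sites, function(s) s$position,
                         numeric(3)))
      fit <- superpose(Xc[idx, , drop = FALSE], native)
      if (fit$rmsd > fit_tol) { ok <- FALSE; break }
      rot[[b]] <- fit$rotation; tra[[b]] <- fit$translation
    }
    if (ok) out[[length(out) + 1]] <- rba_model(rot, tra)
  }
  if (length(out) == 0) return(structure(list(), reason = "fit"))
  out
}

#' Gaussian probability score of an arrangement
#'
#' For each Gaussian restraint the simulated distance is converted to the
#' fraction `g_i = exp(-(r_sim - mean)^2 / (2 sigma_eff^2))` of the
#' distribution that still covers it, with the site position
#' uncertainties added in quadrature to the restraint sigma. Returns the
#' geometric mean of all `g_i`. Restraints without a positive sigma are
#' hard bounds and are excluded from the product.
#'
#' @param rba An [rba_model()].
#' @param bodies List of [rigid_body()] objects.
#' @param restraints List of [distance_restraint()] objects.
#' @return Score in `(0, 1]` (1 when no Gaussian restraint applies).
#' @export
probability_score <- function(rba, bodies, restraints) {
  res <- resolve_restraints(bodies, restraints)
  d <- restraint_distances(rba, bodies, res)
  gaussian_score(d, res)
}

gaussian_score <- function(d, res) {
  keep <- !is.na(res$mean) & res$sigma_eff > 0 &
    res$role %in% c("reference", "auxiliary")
  if (!any(keep)) return(1)
  g <- exp(-(d[keep] - res$mean[keep])^2 / (2 * res$sigma_eff[keep]^2))
  exp(mean(log(pmax(g, .Machine$double.xmin))))
}

#' Test an arrangement against all further restraints
#'
#' Tests are executed in order of increasing computational expense:
#' auxiliary distance restraints (interval check), peptide linker maximum
#' extension (3.8 Angstrom per residue), RNA linker maximum extension
#' (default 7 Angstrom per nucleotide), crosslink fraction, rigid-body
#' clashes, and finally the Gaussian probability score against `p_thr`.
#' The first failing test short-circuits with its reason.
#'
#' @param rba An [rba_model()].
#' @param bodies List of [rigid_body()] objects.
#' @param restraints List of [distance_restraint()] objects.
#' @param spec An [acceptance_spec()].
#' @param linkers List of linker declarations (see [linker_spec()]); only
#'   anchor names, types and lengths are used here.
#' @param dr Sampling resolution slack, Angstrom: interval tests are
#'   widened by `dr` and the probability score evaluated with `dr` added
#'   in quadrature to the restraint widths, reflecting that a model
#'   generated at sampling resolution `dr` may deviate by that much from
#'   a fully compliant one (refinement later removes this allowance).
#' @return List with `accept` (logical) and `reason` (string or `NA`).
#' @export
test_rba <- function(rba, bodies, restraints, spec = acceptance_spec(),
                     linkers = list(), dr = 0, resolved = NULL) {
  res <- if (is.null(resolved)) resolve_restraints(bodies, restraints)
         else resolved
  placed <- place_sites(bodies, rba)
  d <- restraint_distances(rba, bodies, res, placed = placed)
  # 1: auxiliary DDR interval check
  aux <- which(res$role == "auxiliary")
  for (r in aux) {
    if (d[r] < res$lower[r] - dr - 1e-9 || d[r] > res$upper[r] + dr + 1e-9)
      return(list(accept = FALSE, reason = "auxiliary_ddr"))
  }
  # 2 + 3: linker maximum extension
  for (lk in linkers) {
    if (is.null(lk$anchor_b)) next
    ga <- resolve_anchor(placed, bodies, lk$anchor_a)
    gb <- resolve_anchor(placed, bodies, lk$anchor_b)
    gap <- sqrt(sum((ga - gb)^2))
    per_unit <- if (lk$type == "peptide") spec$peptide_max else spec$rna_max
    if (gap > per_unit * lk$length + 1e-9)
      return(list(accept = FALSE,
                  reason = paste0("linker_length_", lk$type)))
  }
  # 4: crosslink fraction
  xl <- which(res$role == "crosslink")
  if (length(xl) > 0) {
    frac <- mean(d[xl] <= res$upper[xl] + dr + 1e-9)
    if (frac < spec$f_x - 1e-12)
      return(list(accept = FALSE, reason = "crosslink"))
  }
  # 5: rigid-body clash (atoms transformed only when this point is reached)
  if (body_clash(place_bodies(bodies, rba), spec$clash_cutoff))
    return(list(accept = FALSE, reason = "clash"))
  # 6: probability score, with the sampling resolution as an extra
  # uncertainty contribution
  if (dr > 0) {
    res$sigma_eff <- sqrt(res$sigma_eff^2 + dr^2)
  }
  score <- gaussian_score(d, res)
  if (score < spec$p_thr)
    return(list(accept = FALSE, reason = "probability"))
  list(accept = TRUE, reason = NA_character_)
}

body_clash <- function(placed, cutoff) {
  if (cutoff <= 0) return(FALSE)
  nb <- length(placed$bodies)
  if (nb < 2) return(FALSE)
  for (a in 1:(nb - 1)) for (b in (a + 1):nb) {
    xa <- placed$bodies[[a]]$xyz; xb <- placed$bodies[[b]]$xyz
    # coarse prefilter on bounding spheres
    ca <- colMeans(xa); cb <- colMeans(xb)
    ra <- sqrt(max(rowSums(sweep(xa, 2, ca)^2)))
    rb <- sqrt(max(rowSums(sweep(xb, 2, cb)^2)))
    if (sqrt(sum((ca - cb)^2)) > ra + rb + cutoff) next
    d2 <- outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * xa %*% t(xb)
    if (min(d2) < cutoff^2) return(TRUE)
  }
  FALSE
}

resolve_anchor <- function(placed, bodies, ref) {
  # ref: list(body = k, anchor = name) or "bodyid:name"
  if (is.character(ref)) {
    parts <- strsplit(ref, ":", fixed = TRUE)[[1]]
    k <- match(parts[1], vapply(bodies, `[[`, "", "id"))
    if (is.na(k)) stop("unknown body in anchor reference: ", ref)
    ref <- list(body = k, anchor = parts[2])
  }
  anc <- placed$bodies[[ref$body]]$anchors[[ref$anchor]]
  if (is.null(anc))
    stop("missing anchor point '", ref$anchor, "' on body ", ref$body)
  anc
}

#' Refine an arrangement against restraint intervals
#'
#' Derivative-free local optimization of the `6(n-1)` rotation
#' (axis-angle) and translation parameters, minimizing the summed squared
#' violations of all restraint `[l, u]` intervals. To prevent artificial
#' narrowing of the ensemble, refinement stops immediately once every
#' restraint is fulfilled; a violation-free input is returned unchanged.
#'
#' @param rba An [rba_model()].
#' @param bodies List of [rigid_body()] objects.
#' @param restraints List of [distance_restraint()] objects.
#' @param maxit Iteration cap for the simplex search.
#' @return List with `rba` (refined model), `violation` (residual summed
#'   squared violation) and `converged` (`TRUE` when violation reached 0).
#' @export
refine_rba <- function(rba, bodies, restraints, maxit = 2000,
                       resolved = NULL) {
  res <- if (is.null(resolved)) resolve_restraints(bodies, restraints)
         else resolved
  viol <- function(model) {
    d <- restraint_distances(model, bodies, res)
    lo <- pmax(0, res$lower - d); hi <- pmax(0, d - res$upper)
    lo[res$role == "crosslink"] <- 0    # crosslinks cap only
    sum(lo^2) + sum(hi^2)
  }
  v0 <- viol(rba)
  if (v0 <= 1e-12)
    return(list(rba = rba, violation = 0, converged = TRUE))
  n <- length(bodies)
  par0 <- rba_to_params(rba)
  found <- NULL
  # optimize a displacement from the input so the simplex starts small:
  # the first feasible point encountered stays close to the tested model
  fn <- function(delta) {
    v <- viol(params_to_rba(par0 + delta, n))
    if (v <= 1e-12 && is.null(found)) found <<- delta
    v
  }
  opt <- tryCatch(
    stats::optim(rep(0, length(par0)), fn, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-12)),
    error = function(e) NULL)
  if (!is.null(found)) {
    model <- params_to_rba(par0 + found, n)
    return(list(rba = model, violation = 0, converged = TRUE))
  }
  if (is.null(opt))
    return(list(rba = rba, violation = v0, converged = FALSE))
  model <- params_to_rba(par0 + opt$par, n)
  v <- viol(model)
  list(rba = model, violation = v, converged = v <= 1e-12)
}

rba_to_params <- function(rba) {
  n <- length(rba$rotations)
  if (n < 2) return(numeric(0))
  unlist(lapply(2:n, function(k) {
    c(rba$translations[[k]], rotation_to_axis_angle(rba$rotations[[k]]))
  }))
}

params_to_rba <- function(par, n) {
  rot <- vector("list", n); tra <- vector("list", n)
  rot[[1]] <- diag(3); tra[[1]] <- c(0, 0, 0)
  for (k in seq_len(n - 1)) {
    p <- par[(6 * (k - 1) + 1):(6 * k)]
    tra[[k + 1]] <- p[1:3]
    rot[[k + 1]] <- axis_angle_to_rotation(p[4:6])
  }
  rba_model(rot, tra)
}

#' Axis-angle vector to rotation matrix (Rodrigues formula)
#' @param v Numeric 3-vector; direction = axis, norm = angle in radians.
#' @return 3x3 proper rotation matrix.
#' @export
axis_angle_to_rotation <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3))
  a <- v / th
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rotation matrix to axis-angle vector
#' @param R 3x3 proper rotation matrix.
#' @return Numeric 3-vector (axis scaled by angle in radians).
#' @export
rotation_to_axis_angle <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  ct <- max(-1, min(1, ct))
  th <- acos(ct)
  if (th < 1e-8) return(c(0, 0, 0))
  if (abs(pi - th) < 1e-6) {
    # near 180 degrees: axis from the symmetric part
    B <- (R + diag(3)) / 2
    a <- sqrt(pmax(diag(B), 0))
    i <- which.max(a)
    if (a[i] > 0) {
      a <- B[, i] / a[i]
      a <- a / sqrt(sum(a^2))
    } else a <- c(1, 0, 0)
    return(a * th)
  }
  a <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(th))
  a * th
}

#' Run the full rigid-body-arrangement pipeline
#'
#' Plan sampling, enumerate distance matrices, embed each as candidate
#' arrangements, test against restraints in order of increasing expense,
#' and refine the survivors against the restraint intervals. The run is
#' deterministic for a fixed plan.
#'
#' @param bodies List of [rigid_body()] objects.
#' @param restraints List of [distance_restraint()] objects.
#' @param spec An [acceptance_spec()].
#' @param t_max Trial cap for [plan_sampling()].
#' @param linkers List of [linker_spec()] declarations used for the
#'   maximum-extension tests.
#' @param upper_default Upper bound for undetermined pairs, Angstrom.
#' @param refine Refine accepted arrangements (default TRUE).
#' @return List with `ensemble` (an [ensemble()] of accepted
#'   arrangements, or `NULL` when none), `rbas` (list of accepted
#'   [rba_model()]s) and `report` (trial counts, sampling resolution,
#'   and per-reason rejection counts).
#' @export
run_rigi <- function(bodies, restraints, spec = acceptance_spec(),
                     t_max = 10000, linkers = list(),
                     upper_default = 180, refine = TRUE) {
  plan <- tryCatch(
    plan_sampling(bodies, restraints, t_max, upper_default),
    semiflex_infeasible = function(e) e)
  if (inherits(plan, "semiflex_infeasible")) {
    return(list(ensemble = NULL, rbas = list(),
                report = list(infeasible = TRUE,
                              message = conditionMessage(plan))))
  }
  stream <- enumerate_distance_matrices(plan)
  resolved <- resolve_restraints(bodies, restraints)
  counts <- c(screened = 0, non_embeddable = 0, fit = 0,
              auxiliary_ddr = 0, linker_length_peptide = 0,
              linker_length_rna = 0, crosslink = 0, clash = 0,
              probability = 0, refine_stalled = 0, accepted = 0)
  rbas <- list(); prov <- list()
  for (t in seq_len(stream$n)) {
    M <- stream$matrix_at(t)
    if (!stream$passes_screen(M)) {
      counts["screened"] <- counts["screened"] + 1
      next
    }
    cands <- embed_rba(M, bodies)
    if (length(cands) == 0) {
      r <- attr(cands, "reason")
      counts[r] <- counts[r] + 1
      next
    }
    for (ci in seq_along(cands)) {
      verdict <- test_rba(cands[[ci]], bodies, restraints, spec, linkers,
                          dr = plan$dr, resolved = resolved)
      if (!verdict$accept) {
        counts[verdict$reason] <- counts[verdict$reason] + 1
        next
      }
      model <- cands[[ci]]
      if (refine) {
        ref <- refine_rba(model, bodies, restraints, resolved = resolved)
        if (!ref$converged) {
          counts["refine_stalled"] <- counts["refine_stalled"] + 1
          next
        }
        model <- ref$rba
        placed <- place_bodies(bodies, model)
        if (body_clash(placed, spec$clash_cutoff)) {
          counts["clash"] <- counts["clash"] + 1
          next
        }
      }
      counts["accepted"] <- counts["accepted"] + 1
      rbas[[length(rbas) + 1]] <- model
      prov[[length(prov) + 1]] <- list(trial = t, enantiomorph = ci)
    }
  }
  ens <- NULL
  if (length(rbas) > 0) {
    confs <- lapply(rbas, function(r) place_bodies(bodies, r)$xyz_all)
    atoms <- do.call(rbind, lapply(bodies, `[[`, "atoms"))
    ens <- ensemble(confs, atoms = atoms, provenance = prov)
  }
  list(ensemble = ens, rbas = rbas,
       report = list(infeasible = FALSE, t_total = plan$t_total,
                     dr = plan$dr, dr_grid = plan$dr_grid,
                     counts = counts, n_accepted = length(rbas)))
}

# ---- internal restraint resolution ---------------------------------------

# transform only the labeling sites and anchors (cheap variant of
# place_bodies for restraint testing)
place_sites <- function(bodies, rba) {
  out <- vector("list", length(bodies))
  for (k in seq_along(bodies)) {
    R <- rba$rotations[[k]]; tv <- rba$translations[[k]]
    b <- bodies[[k]]
    ref <- t(vapply(b$ref_sites, function(s) as.numeric(R %*% s$position + tv),
                    numeric(3)))
    aux <- if (length(b$aux_sites))
      t(vapply(b$aux_sites, function(s) as.numeric(R %*% s$position + tv),
               numeric(3))) else matrix(0, 0, 3)
    anc <- lapply(b$anchors, function(a) as.numeric(R %*% a + tv))
    out[[k]] <- list(ref = ref, aux = aux, anchors = anc)
  }
  list(bodies = out)
}

reference_positions <- function(bodies) {
  do.call(rbind, lapply(bodies, function(b)
    t(vapply(b$ref_sites, function(s) s$position, numeric(3)))))
}

# Resolve restraint site references against the bodies. Returns a data
# frame with body/site indexing, global reference indices (NA for
# auxiliary sites), effective sigma, bounds and role.
resolve_restraints <- function(bodies, restraints) {
  site_table <- do.call(rbind, lapply(seq_along(bodies), function(k) {
    b <- bodies[[k]]
    rbind(
      data.frame(body = k, kind = "ref", idx = seq_along(b$ref_sites),
                 tag = vapply(b$ref_sites, `[[`, "", "tag"),
                 unc = vapply(b$ref_sites, `[[`, 0, "uncertainty"),
                 stringsAsFactors = FALSE),
      if (length(b$aux_sites))
        data.frame(body = k, kind = "aux", idx = seq_along(b$aux_sites),
                   tag = vapply(b$aux_sites, `[[`, "", "tag"),
                   unc = vapply(b$aux_sites, `[[`, 0, "uncertainty"),
                   stringsAsFactors = FALSE))
  }))
  find_site <- function(ref) {
    tag <- if (inherits(ref, "label_site")) ref$tag else as.character(ref)
    hit <- which(site_table$tag == tag)
    if (length(hit) == 0)
      stop("restraint site '", tag, "' not found on any body")
    site_table[hit[1], ]
  }
  out <- lapply(restraints, function(r) {
    a <- find_site(r$site_a); b <- find_site(r$site_b)
    sig <- if (is.null(r$sigma)) NA_real_ else r$sigma
    data.frame(body_a = a$body, kind_a = a$kind, idx_a = a$idx,
               body_b = b$body, kind_b = b$kind, idx_b = b$idx,
               gi_a = if (a$kind == "ref") 3 * (a$body - 1) + a$idx else NA,
               gi_b = if (b$kind == "ref") 3 * (b$body - 1) + b$idx else NA,
               mean = if (is.null(r$mean)) NA_real_ else r$mean,
               sigma = sig,
               sigma_eff = if (is.na(sig)) NA_real_ else
                 sqrt(sig^2 + a$unc^2 + b$unc^2),
               lower = r$lower, upper = r$upper, role = r$role,
               stringsAsFactors = FALSE)
  })
  if (length(out) == 0) {
    out <- data.frame(body_a = integer(), kind_a = character(),
                      idx_a = integer(), body_b = integer(),
                      kind_b = character(), idx_b = integer(),
                      gi_a = integer(), gi_b = integer(),
                      mean = numeric(), sigma = numeric(),
                      sigma_eff = numeric(), lower = numeric(),
                      upper = numeric(), role = character(),
                      stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, out)
  }
  out$on_ref <- !is.na(out$gi_a) & !is.na(out$gi_b)
  out
}

site_position <- function(placed, body, kind, idx) {
  pb <- placed$bodies[[body]]
  if (kind == "ref") pb$ref[idx, ] else pb$aux[idx, ]
}

restraint_distances <- function(rba, bodies, res, placed = NULL) {
  if (nrow(res) == 0) return(numeric(0))
  if (is.null(placed)) placed <- place_sites(bodies, rba)
  vapply(seq_len(nrow(res)), function(r) {
    pa <- site_position(placed, res$body_a[r], res$kind_a[r], res$idx_a[r])
    pb <- site_position(placed, res$body_b[r], res$kind_b[r], res$idx_b[r])
    sqrt(sum((pa - pb)^2))
  }, numeric(1))
}
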