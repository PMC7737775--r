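# Coarse-grained flexible-linker construction between anchor points on
# placed rigid bodies: fragment-based chain growth with a feasibility bias,
# anchor closure by uniformly distributed stretch and rotation, and the
# discard rule for arrangements whose linkers cannot be built.
#
# Representation: one interaction center per residue (CA) or nucleotide
# (P), grown unit by unit with bond length, bend angle and pseudo-torsion
# sampled from a fragment library.

PEPTIDE_BOND <- 3.8   # CA-CA virtual bond, Angstrom
RNA_BOND <- 5.9       # P-P virtual bond, Angstrom

#' Synthetic backbone fragment library
#'
#' A fragment library is a table of (bend angle, pseudo-torsion) pairs on
#' a 5-degree grid with occurrence weights. The shipped libraries are
#' synthetic: the peptide library follows a coil-region mixture (bend
#' angles concentrated around extended-to-turn geometries, broad
#' torsions), the RNA library a single broad pseudo-torsion basin.
#' User-supplied libraries in the same 3-column layout can be loaded with
#' [read_fragment_library()].
#'
#' @param type `"peptide"` or `"rna"`.
#' @param resolution Angular grid resolution in degrees (default 5).
#' @return Data frame with columns `angle1` (bend, degrees), `angle2`
#'   (torsion, degrees in `(-180, 180]`) and `weight` (`> 0`), of class
#'   `fragment_library` with attributes `type` and `bond`.
#' @export
make_fragment_library <- function(type = c("peptide", "rna"),
                                  resolution = 5) {
  type <- match.arg(type)
  bend <- seq(60, 175, by = resolution)
  tors <- seq(-175, 180, by = resolution)
  grid <- expand.grid(angle1 = bend, angle2 = tors)
  if (type == "peptide") {
    # coil mixture: extended (bend ~ 130) and turn-like (bend ~ 95)
    wb <- 0.65 * stats::dnorm(grid$angle1, 130, 15) +
      0.35 * stats::dnorm(grid$angle1, 95, 12)
    wt <- 0.5 + 0.5 * stats::dnorm(grid$angle2, 180, 60) +
      0.5 * stats::dnorm(grid$angle2, -180, 60) +
      0.3 * stats::dnorm(grid$angle2, 60, 40)
    bond <- PEPTIDE_BOND
  } else {
    # single broad basin around extended A-form-like pseudo-geometry
    wb <- stats::dnorm(grid$angle1, 120, 25)
    wt <- 0.4 + stats::dnorm(grid$angle2, 170, 70) +
      stats::dnorm(grid$angle2, -170, 70)
    bond <- RNA_BOND
  }
  w <- wb * wt
  w <- pmax(w / max(w), 1e-6)
  lib <- data.frame(angle1 = grid$angle1, angle2 = grid$angle2, weight = w)
  structure(lib, class = c("fragment_library", "data.frame"),
            type = type, bond = bond)
}

#' Read a fragment library from a 3-column text file
#'
#' Whitespace-delimited columns: bend angle (degrees), torsion (degrees),
#' weight. Comment lines start with `#`.
#'
#' @param path File path.
#' @param type Library type (sets the virtual bond length).
#' @return A `fragment_library` data frame.
#' @export
read_fragment_library <- function(path, type = c("peptide", "rna")) {
  type <- match.arg(type)
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("angle1", "angle2", "weight"))
  if (any(!is.finite(as.matrix(tab)))) stop("non-numeric library entries")
  if (any(tab$weight <= 0)) stop("library weights must be > 0")
  if (any(tab$angle2 <= -180 | tab$angle2 > 180))
    stop("torsions must lie in (-180, 180]")
  structure(tab, class = c("fragment_library", "data.frame"),
            type = type,
            bond = if (type == "peptide") PEPTIDE_BOND else RNA_BOND)
}

#' Declare a flexible linker
#'
#' @param type `"peptide"` or `"rna"`.
#' @param length Number of residues/nucleotides (`>= 1`).
#' @param anchor_a Start anchor: a numeric 3-vector, or a reference
#'   `list(body =, anchor =)` / `"bodyid:name"` resolved against placed
#'   bodies.
#' @param anchor_b End anchor (same forms), or `NULL` for a free end.
#' @param max_attempts Growth attempts before giving up.
#' @param runtime_limit Wall-clock limit per linker, seconds.
#' @param chain Chain identifier given to the linker beads.
#' @return An object of class `linker_spec`.
#' @export
linker_spec <- function(type = c("peptide", "rna"), length,
                        anchor_a, anchor_b = NULL,
                        max_attempts = 100, runtime_limit = 30,
                        chain = "L") {
  type <- match.arg(type)
  stopifnot(length >= 1, runtime_limit > 0, max_attempts >= 1)
  structure(list(type = type, length = as.integer(length),
                 anchor_a = anchor_a, anchor_b = anchor_b,
                 max_attempts = max_attempts,
                 runtime_limit = runtime_limit, chain = chain),
            class = "linker_spec")
}

max_extension <- function(type, peptide_max = 3.8, rna_max = 7) {
  if (type == "peptide") peptide_max else rna_max
}

# Place the next bead by bond length, bend angle and torsion (NeRF).
nerf_place <- function(p1, p2, p3, b, theta_deg, tau_deg) {
  th <- theta_deg * pi / 180; ta <- tau_deg * pi / 180
  bc <- p3 - p2; bc <- bc / sqrt(sum(bc^2))
  ab <- p2 - p1
  n <- .cross3(ab, bc)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-10) {            # collinear history: pick any normal
    ref <- if (abs(bc[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    n <- .cross3(ref, bc); nn <- sqrt(sum(n^2))
  }
  n <- n / nn
  m <- .cross3(n, bc)
  d <- c(-b * cos(th), b * sin(th) * cos(ta), b * sin(th) * sin(ta))
  p3 + d[1] * bc + d[2] * m + d[3] * n
}

min_dist2 <- function(pt, pts) {
  if (is.null(pts) || nrow(pts) == 0) return(Inf)
  min(rowSums(sweep(pts, 2, pt)^2))
}

#' Grow a coarse-grained linker backbone
#'
#' Unit-by-unit growth from `anchor_a` sampling bend/torsion fragments
#' from the library, with candidate steps reweighted toward closing the
#' remaining gap to `anchor_b` (when present) and clashing intermediates
#' re-sampled. On reaching the final unit, a moderate terminal miss is
#' repaired by [close_anchor()]. Growth is bit-reproducible for a fixed
#' seed.
#'
#' @param spec A [linker_spec()] whose anchors are numeric 3-vectors.
#' @param library A fragment library (default: synthetic library matching
#'   `spec$type`).
#' @param seed Integer RNG seed.
#' @param environment Optional `m x 3` matrix of fixed atoms the linker
#'   must not clash with.
#' @param clash_cutoff Minimum allowed bead-bead / bead-environment
#'   distance, Angstrom.
#' @param n_candidates Fragment candidates evaluated per step.
#' @param closure_tol Accepted terminal miss after closure, Angstrom.
#' @param moderate_miss Maximum terminal miss that closure will attempt
#'   to repair, Angstrom.
#' @return List with `success`, `coords` (`(length+1) x 3` bead matrix,
#'   first row = `anchor_a`), `reason`, `attempts`.
#' @export
grow_chain <- function(spec, library = NULL, seed = 1,
                       environment = NULL, clash_cutoff = 3.0,
                       n_candidates = 40, closure_tol = 0.5,
                       moderate_miss = 3.0) {
  if (is.null(library)) library <- make_fragment_library(spec$type)
  b <- attr(library, "bond")
  n <- spec$length
  a <- as.numeric(spec$anchor_a)
  target <- if (is.null(spec$anchor_b)) NULL else as.numeric(spec$anchor_b)
  per_unit <- max_extension(spec$type)
  if (!is.null(target)) {
    gap <- sqrt(sum((target - a)^2))
    if (gap > per_unit * n + 1e-9)
      return(list(success = FALSE, coords = NULL,
                  reason = "infeasible_gap", attempts = 0))
  }
  lw <- library$weight / sum(library$weight)
  t0 <- Sys.time()
  with_seed(seed, {
    for (attempt in seq_len(spec$max_attempts)) {
      if (as.numeric(difftime(Sys.time(), t0, units = "secs")) >
          spec$runtime_limit)
        return(list(success = FALSE, coords = NULL,
                    reason = "runtime", attempts = attempt - 1))
      pts <- matrix(NA_real_, n + 1, 3)
      pts[1, ] <- a
      dead <- FALSE
      for (i in seq_len(n)) {
        remaining <- n - i          # bonds left after this step
        idx <- sample.int(nrow(library), n_candidates, replace = TRUE,
                          prob = lw)
        cand <- matrix(NA_real_, n_candidates, 3)
        for (ci in seq_len(n_candidates)) {
          if (i == 1) {
            u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
            cand[ci, ] <- pts[1, ] + b * u
          } else if (i == 2) {
            cand[ci, ] <- nerf_place(pts[1, ] + c(0, 0, 1), pts[1, ],
                                     pts[2, ], b, library$angle1[idx[ci]],
                                     stats::runif(1, -180, 180))
          } else {
            cand[ci, ] <- nerf_place(pts[i - 2, ], pts[i - 1, ], pts[i, ],
                                     b, library$angle1[idx[ci]],
                                     library$angle2[idx[ci]])
          }
        }
        ok <- rep(TRUE, n_candidates)
        for (ci in seq_len(n_candidates)) {
          p <- cand[ci, ]
          if (min_dist2(p, environment) < clash_cutoff^2 ||
              (i > 2 && min_dist2(p, pts[1:(i - 1), , drop = FALSE]) <
                 clash_cutoff^2)) {
            ok[ci] <- FALSE; next
          }
          if (!is.null(target)) {
            d_after <- sqrt(sum((p - target)^2))
            lim <- if (remaining == 0) moderate_miss
                   else remaining * per_unit
            if (d_after > lim + 1e-9) ok[ci] <- FALSE
          }
        }
        if (!any(ok)) { dead <- TRUE; break }
        w <- lw[idx]
        w[!ok] <- 0
        if (!is.null(target)) {
          d_after <- sqrt(rowSums(sweep(cand, 2, target)^2))
          d_cur <- sqrt(sum((pts[i, ] - target)^2))
          d_tgt <- d_cur * remaining / (remaining + 1)
          w <- w * exp(-((d_after - d_tgt) / b)^2)
        }
        if (sum(w) <= 0) { dead <- TRUE; break }
        pick <- sample.int(n_candidates, 1, prob = w)
        pts[i + 1, ] <- cand[pick, ]
      }
      if (dead) next
      if (is.null(target))
        return(list(success = TRUE, coords = pts, reason = NA_character_,
                    attempts = attempt))
      miss <- sqrt(sum((pts[n + 1, ] - target)^2))
      if (miss <= closure_tol)
        return(list(success = TRUE, coords = pts, reason = NA_character_,
                    attempts = attempt))
      if (miss <= moderate_miss) {
        cl <- close_anchor(pts, target, closure_tol = closure_tol,
                           moderate_miss = moderate_miss)
        if (cl$success) {
          # closure may not introduce clashes
          cpts <- cl$coords
          clash <- FALSE
          for (i in 2:(n + 1)) {
            others <- cpts[seq_len(i - 2), , drop = FALSE]
            if (min_dist2(cpts[i, ], environment) < clash_cutoff^2 ||
                (nrow(others) > 0 &&
                 min_dist2(cpts[i, ], others) < clash_cutoff^2)) {
              clash <- TRUE; break
            }
          }
          if (!clash)
            return(list(success = TRUE, coords = cpts,
                        reason = NA_character_, attempts = attempt))
        }
      }
    }
    list(success = FALSE, coords = NULL, reason = "attempts_exhausted",
         attempts = spec$max_attempts)
  })
}

#' Close a moderate terminal miss by distributed deformation
#'
#' Decomposes the required terminal correction into an elongation along
#' the anchor-to-anchor axis, a rotation about that axis, and a residual
#' perpendicular shift, and distributes each uniformly over the backbone
#' units (unit `k` receives a fraction `(k-1)/(N-1)` of the total). The
#' first bead (the a-side anchor) never moves. Fails when the miss
#' exceeds the moderate-miss threshold or the per-unit bond distortion
#' would exceed `max_distortion`.
#'
#' @param backbone `N x 3` bead matrix (first row is the fixed anchor).
#' @param anchor_b Target position of the last bead.
#' @param closure_tol Required terminal accuracy, Angstrom.
#' @param moderate_miss Maximum miss that will be repaired, Angstrom.
#' @param max_distortion Maximum allowed relative bond-length change.
#' @return List with `success`, `coords`, `reason`.
#' @export
close_anchor <- function(backbone, anchor_b, closure_tol = 0.5,
                         moderate_miss = 3.0, max_distortion = 0.10) {
  pts <- as.matrix(backbone)
  N <- nrow(pts)
  a <- pts[1, ]
  target <- as.numeric(anchor_b)
  last <- pts[N, ]
  miss <- sqrt(sum((target - last)^2))
  if (miss < 1e-12)
    return(list(success = TRUE, coords = pts, reason = NA_character_))
  if (miss > moderate_miss)
    return(list(success = FALSE, coords = NULL, reason = "miss_too_large"))
  bonds0 <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                            pts[-N, , drop = FALSE])^2))
  u <- target - a
  un <- sqrt(sum(u^2))
  frac <- (seq_len(N) - 1) / (N - 1)
  if (un < 1e-9) {
    # degenerate axis: distribute the plain shift
    shift <- target - last
    pts <- pts + outer(frac, shift)
  } else {
    u <- u / un
    # 1: stretch along the axis
    dz <- sum((target - last) * u)
    pts <- pts + outer(frac * dz, u)
    # 2: rotation about the axis through the a-side anchor
    last <- pts[N, ]
    v1 <- last - a; v2 <- target - a
    p1 <- v1 - sum(v1 * u) * u
    p2 <- v2 - sum(v2 * u) * u
    n1 <- sqrt(sum(p1^2)); n2 <- sqrt(sum(p2^2))
    if (n1 > 1e-9 && n2 > 1e-9) {
      e1 <- p1 / n1; e2 <- p2 / n2
      ang <- atan2(sum(.cross3(e1, e2) * u), sum(e1 * e2))
      for (k in 2:N) {
        R <- axis_angle_to_rotation(u * ang * frac[k])
        pts[k, ] <- as.numeric(R %*% (pts[k, ] - a)) + a
      }
    }
    # 3: residual perpendicular shift, distributed
    resid <- target - pts[N, ]
    pts <- pts + outer(frac, resid)
  }
  bonds1 <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                            pts[-N, , drop = FALSE])^2))
  if (max(abs(bonds1 - bonds0) / bonds0) > max_distortion)
    return(list(success = FALSE, coords = NULL, reason = "distortion"))
  if (sqrt(sum((pts[N, ] - target)^2)) > closure_tol)
    return(list(success = FALSE, coords = NULL, reason = "closure"))
  list(success = TRUE, coords = pts, reason = NA_character_)
}

#' Build all declared linkers for one placed arrangement
#'
#' Every declared linker is grown against the placed rigid bodies and the
#' previously built linkers; if any linker cannot be built, the whole
#' arrangement is discarded.
#'
#' @param rba An [rba_model()].
#' @param bodies List of [rigid_body()] objects.
#' @param linkers List of [linker_spec()] declarations with anchor
#'   references into the bodies.
#' @param seed Integer seed (each linker uses `seed + its index`).
#' @param libraries Optional named list of fragment libraries
#'   (`peptide`, `rna`).
#' @param clash_cutoff Bead clash cutoff, Angstrom.
#' @return List with `success`, `xyz` (combined coordinates), `atoms`,
#'   and per-linker `stats`.
#' @export
link_rba <- function(rba, bodies, linkers, seed = 1, libraries = NULL,
                     clash_cutoff = 3.0) {
  placed <- place_bodies(bodies, rba)
  env <- placed$xyz_all
  xyz <- placed$xyz_all
  atoms <- placed$atoms_all
  stats_out <- list()
  for (li in seq_along(linkers)) {
    lk <- linkers[[li]]
    sp <- lk
    sp$anchor_a <- resolve_anchor(placed, bodies, lk$anchor_a)
    if (!is.null(lk$anchor_b))
      sp$anchor_b <- resolve_anchor(placed, bodies, lk$anchor_b)
    lib <- if (!is.null(libraries)) libraries[[lk$type]] else NULL
    # the anchors' own neighborhoods are exempt from the clash check so
    # the chain can emerge from the body surface
    keep <- sqrt(rowSums(sweep(env, 2, sp$anchor_a)^2)) > clash_cutoff + 1
    if (!is.null(lk$anchor_b))
      keep <- keep & sqrt(rowSums(sweep(env, 2, sp$anchor_b)^2)) >
        clash_cutoff + 1
    g <- grow_chain(sp, library = lib, seed = seed + li,
                    environment = env[keep, , drop = FALSE],
                    clash_cutoff = clash_cutoff)
    stats_out[[li]] <- list(success = g$success, reason = g$reason,
                            attempts = g$attempts)
    if (!g$success)
      return(list(success = FALSE, xyz = NULL, atoms = NULL,
                  stats = stats_out))
    beads <- g$coords[-1, , drop = FALSE]   # anchor_a belongs to its body
    env <- rbind(env, beads)
    xyz <- rbind(xyz, beads)
    atoms <- rbind(atoms,
                   data.frame(chain = lk$chain, resno = seq_len(nrow(beads)),
                              elety = if (lk$type == "peptide") "CA" else "P",
                              resid = if (lk$type == "peptide") "GLY" else "U",
                              stringsAsFactors = FALSE))
  }
  list(success = TRUE, xyz = xyz, atoms = atoms, stats = stats_out)
}

#' Link every arrangement of a rigid-body run
#'
#' Applies [link_rba()] to each accepted arrangement; arrangements whose
#' linkers cannot all be built are discarded, so the returned accounting
#' always satisfies `n_input = n_linked + n_discarded`.
#'
#' @param rbas List of [rba_model()] objects.
#' @param bodies List of [rigid_body()] objects.
#' @param linkers List of [linker_spec()] declarations.
#' @param seed Integer base seed (arrangement `k` uses `seed + 1000 k`).
#' @param ... Passed to [link_rba()].
#' @return List with `ensemble` (linked conformers, uniform populations;
#'   `NULL` if none) and `report` (`n_input`, `n_linked`, `n_discarded`,
#'   per-arrangement stats).
#' @export
link_ensemble <- function(rbas, bodies, linkers, seed = 1, ...) {
  confs <- list(); atoms <- NULL; stats_all <- list()
  for (k in seq_along(rbas)) {
    lr <- link_rba(rbas[[k]], bodies, linkers, seed = seed + 1000 * k, ...)
    stats_all[[k]] <- lr$stats
    if (lr$success) {
      confs[[length(confs) + 1]] <- lr$xyz
      atoms <- lr$atoms
    }
  }
  ens <- if (length(confs) > 0) ensemble(confs, atoms = atoms) else NULL
  list(ensemble = ens,
       report = list(n_input = length(rbas), n_linked = length(confs),
                     n_discarded = length(rbas) - length(confs),
                     stats = stats_all))
}

# Evaluate an expression with a temporarily seeded RNG, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
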