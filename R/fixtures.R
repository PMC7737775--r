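# Synthetic-data generators: planted rigid-body systems with ground-truth
# arrangement clouds, simulated distance restraints, and random-coil /
# helix-coil chain ensembles. All generators are bit-reproducible from
# (parameters, seed).

random_rotation <- function() {
  # uniform over SO(3) via normalized quaternion
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Generate a planted rigid-body system
#'
#' Random rigid bodies (50-150 pseudo-atoms each) with reference sites
#' chosen by [choose_reference_sites()], plus a ground-truth cloud of
#' arrangements around a base placement. The cloud is a translational
#' distribution scaled so its ensemble width approximates `spread`;
#' `spread = 0` yields a single ground-truth arrangement.
#'
#' @param n_bodies 2 or 3.
#' @param spread Target ensemble width of the ground-truth cloud,
#'   Angstrom.
#' @param seed Integer seed.
#' @param n_truth Conformers in the ground-truth cloud (ignored when
#'   `spread = 0`).
#' @return An object of class `planted_system`: `bodies`, `truth_rbas`
#'   (list of [rba_model()]), `truth_ensemble`, `seed`.
#' @export
make_planted_system <- function(n_bodies = 2, spread = 0, seed = 1,
                                n_truth = 10) {
  stopifnot(n_bodies %in% c(2, 3), spread >= 0)
  with_seed(seed, {
    chains <- c("A", "B", "C")[seq_len(n_bodies)]
    bodies <- lapply(seq_len(n_bodies), function(k) {
      n_atoms <- sample(50:150, 1)
      xyz <- matrix(stats::rnorm(3 * n_atoms, sd = 8), ncol = 3)
      atoms <- data.frame(chain = chains[k], resno = seq_len(n_atoms),
                          elety = "CA", resid = "ALA",
                          stringsAsFactors = FALSE)
      cand_idx <- sample(n_atoms, 12)
      cands <- lapply(cand_idx, function(i)
        label_site(chains[k], i, xyz[i, ]))
      refs <- choose_reference_sites(cands)
      ref_resnos <- vapply(refs, `[[`, 0L, "resno")
      aux_idx <- setdiff(cand_idx, ref_resnos)[1:2]
      auxs <- lapply(aux_idx, function(i) label_site(chains[k], i, xyz[i, ]))
      # anchors on the body surface (extreme atoms along x, the axis
      # separating the bodies in the base arrangement)
      anchors <- list(n = xyz[which.min(xyz[, 1]), ],
                      c = xyz[which.max(xyz[, 1]), ])
      rigid_body(xyz, atoms, ref_sites = refs, aux_sites = auxs,
                 anchors = anchors, id = paste0("body", k))
    })
    base_tra <- list(c(0, 0, 0), c(45, 0, 0), c(0, 50, 8))[seq_len(n_bodies)]
    base_rot <- c(list(diag(3)),
                  replicate(n_bodies - 1, random_rotation(),
                            simplify = FALSE))
    base <- rba_model(base_rot, base_tra)
    if (spread == 0) {
      truth <- list(base)
    } else {
      deltas <- replicate(n_truth, {
        lapply(seq_len(n_bodies), function(k)
          if (k == 1) c(0, 0, 0) else stats::rnorm(3, sd = spread))
      }, simplify = FALSE)
      build <- function(scale) lapply(deltas, function(dl)
        rba_model(base$rotations,
                  lapply(seq_len(n_bodies), function(k)
                    base$translations[[k]] + scale * dl[[k]])))
      truth <- build(1)
      ens <- planted_truth_ensemble(bodies, truth)
      w <- ensemble_width(ens)
      if (w > 0) truth <- build(spread / w)
    }
    ens <- planted_truth_ensemble(bodies, truth)
    structure(list(bodies = bodies, truth_rbas = truth,
                   truth_ensemble = ens, seed = seed),
              class = "planted_system")
  })
}

planted_truth_ensemble <- function(bodies, rbas) {
  confs <- lapply(rbas, function(r) place_bodies(bodies, r)$xyz_all)
  atoms <- do.call(rbind, lapply(bodies, `[[`, "atoms"))
  ensemble(confs, atoms = atoms)
}

#' Simulate Gaussian distance restraints from a system or ensemble
#'
#' For each requested site pair, the population-weighted distance
#' distribution across the ground truth is summarized as a Gaussian
#' restraint (mean = weighted mean, sigma = max of the weighted standard
#' deviation and `sigma_floor`); the empirical tabulated distribution is
#' attached.
#'
#' @param x A `planted_system` (site pairs default to all inter-body
#'   reference pairs, role `reference`, plus all auxiliary-reference
#'   pairs, role `auxiliary`) or an [ensemble()].
#' @param sites For ensembles: character vector of site tags
#'   `"CHAIN.RESNO"`; all pairs are simulated.
#' @param sigma_floor Minimum restraint sigma, Angstrom (default 3, the
#'   label-uncertainty convention).
#' @param r Grid for the attached tabulated distributions.
#' @return List of [distance_restraint()] objects.
#' @export
simulate_ddrs <- function(x, sites = NULL, sigma_floor = 3,
                          r = ddr_grid()) {
  if (inherits(x, "planted_system")) {
    return(simulate_system_ddrs(x, sigma_floor))
  }
  stopifnot(inherits(x, "ensemble"), length(sites) >= 2)
  pairs <- utils::combn(sites, 2, simplify = FALSE)
  lapply(pairs, function(pr) {
    idx <- resolve_site_pair(x$atoms, pr)
    d <- site_pair_distances(x, idx)
    if (any(d < 1e-9)) stop("coincident sites for pair ", pr[1], " ", pr[2])
    p <- x$populations
    mu <- sum(p * d)
    sd_w <- sqrt(max(sum(p * (d - mu)^2), 0))
    sg <- max(sd_w, sigma_floor)
    dens <- colSums(p * t(vapply(d, function(m) stats::dnorm(r, m, sg),
                                 numeric(length(r)))))
    distance_restraint(pr[1], pr[2], mean = mu, sigma = sg,
                       distribution = distance_distribution(r, dens))
  })
}

simulate_system_ddrs <- function(sys, sigma_floor) {
  bodies <- sys$bodies
  site_info <- list()
  for (k in seq_along(bodies)) {
    for (s in bodies[[k]]$ref_sites)
      site_info[[length(site_info) + 1]] <-
        list(body = k, kind = "ref", site = s)
    for (s in bodies[[k]]$aux_sites)
      site_info[[length(site_info) + 1]] <-
        list(body = k, kind = "aux", site = s)
  }
  placed <- lapply(sys$truth_rbas, function(r) place_bodies(bodies, r))
  out <- list()
  n_s <- length(site_info)
  for (a in 1:(n_s - 1)) for (b in (a + 1):n_s) {
    sa <- site_info[[a]]; sb <- site_info[[b]]
    if (sa$body == sb$body) next
    if (sa$kind == "aux" && sb$kind == "aux") next
    role <- if (sa$kind == "ref" && sb$kind == "ref") "reference"
            else "auxiliary"
    d <- vapply(placed, function(pl) {
      pa <- if (sa$kind == "ref")
        pl$bodies[[sa$body]]$ref[match(sa$site$tag,
          vapply(bodies[[sa$body]]$ref_sites, `[[`, "", "tag")), ]
      else pl$bodies[[sa$body]]$aux[match(sa$site$tag,
          vapply(bodies[[sa$body]]$aux_sites, `[[`, "", "tag")), ]
      pb <- if (sb$kind == "ref")
        pl$bodies[[sb$body]]$ref[match(sb$site$tag,
          vapply(bodies[[sb$body]]$ref_sites, `[[`, "", "tag")), ]
      else pl$bodies[[sb$body]]$aux[match(sb$site$tag,
          vapply(bodies[[sb$body]]$aux_sites, `[[`, "", "tag")), ]
      sqrt(sum((pa - pb)^2))
    }, numeric(1))
    mu <- mean(d)
    sg <- if (length(d) > 1) max(stats::sd(d), sigma_floor) else sigma_floor
    out[[length(out) + 1]] <-
      distance_restraint(sa$site$tag, sb$site$tag, mean = mu, sigma = sg,
                         role = role)
  }
  out
}

unit_sphere <- function(n = 1) {
  v <- matrix(stats::rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

coil_chain <- function(n_res, bond, model, persistence = 0,
                       min_sep = 4.5, max_regrow = 60) {
  x <- matrix(0, n_res, 3)
  dir <- as.numeric(unit_sphere(1))
  for (i in 2:n_res) {
    placed <- FALSE
    for (try in seq_len(max_regrow)) {
      nd <- as.numeric(unit_sphere(1))
      step_dir <- persistence * dir + (1 - persistence) * nd
      step_dir <- step_dir / sqrt(sum(step_dir^2))
      cand <- x[i - 1, ] + bond * step_dir
      if (model == "self_avoiding" && i > 2) {
        if (min_dist2(cand, x[1:(i - 2), , drop = FALSE]) < min_sep^2) next
      }
      x[i, ] <- cand; dir <- step_dir; placed <- TRUE; break
    }
    if (!placed) return(NULL)   # dead end; caller restarts the chain
  }
  x
}

#' Generate a random-coil chain ensemble
#'
#' CA-trace chains with fixed 3.8 Angstrom virtual bonds. `ideal` chains
#' are freely jointed (optionally with directional persistence);
#' `self_avoiding` chains additionally reject beads closer than 4.5
#' Angstrom to any non-adjacent bead. Ideal chains scale with Flory
#' exponent 0.5, self-avoiding chains are expanded (larger exponent).
#'
#' @param n_res Residues per chain (`>= 10`).
#' @param n_conf Number of conformers.
#' @param model `"ideal"` or `"self_avoiding"`.
#' @param bond Virtual bond length, Angstrom.
#' @param seed Integer seed.
#' @param persistence Direction-mixing coefficient in `[0, 1)` (0 =
#'   freely jointed).
#' @return An [ensemble()] with uniform populations.
#' @export
make_random_coil_ensemble <- function(n_res, n_conf,
                                      model = c("ideal", "self_avoiding"),
                                      bond = 3.8, seed = 1,
                                      persistence = 0) {
  model <- match.arg(model)
  stopifnot(n_res >= 10, n_conf >= 1)
  with_seed(seed, {
    confs <- vector("list", n_conf)
    for (c in seq_len(n_conf)) {
      repeat {
        x <- coil_chain(n_res, bond, model, persistence)
        if (!is.null(x)) break
      }
      confs[[c]] <- x
    }
    ensemble(confs)
  })
}

helix_template <- function(len, rise = 1.5, twist = 100, radius = 2.3) {
  t <- seq_len(len) - 1
  ang <- t * twist * pi / 180
  cbind(radius * cos(ang), radius * sin(ang), rise * t)
}

#' Generate a helix-coil chain ensemble
#'
#' Residues inside the declared spans follow a rigid ideal-helix CA
#' geometry (1.5 Angstrom rise, 100 degrees per residue); the spans are
#' internally rigid across conformers but reorient freely at their
#' hinges. Coil residues follow a persistent random walk (locally stiff,
#' as real disordered chains are), so helical segments register as
#' locally compact relative to the coil background. With no spans the
#' generator reduces to [make_random_coil_ensemble()].
#'
#' @param n_res Residues per chain.
#' @param spans List of `c(start, end)` helix spans (1-based, inclusive,
#'   non-overlapping).
#' @param n_conf Number of conformers.
#' @param seed Integer seed.
#' @param bond Coil virtual bond length, Angstrom.
#' @param persistence Coil direction persistence (default 0.8).
#' @return An [ensemble()] with uniform populations.
#' @export
make_helix_coil_ensemble <- function(n_res, spans = list(), n_conf,
                                     seed = 1, bond = 3.8,
                                     persistence = 0.8) {
  if (length(spans) == 0)
    return(make_random_coil_ensemble(n_res, n_conf, "ideal", bond, seed,
                                     persistence = persistence))
  spans <- lapply(spans, as.integer)
  ord <- order(vapply(spans, `[`, 0L, 1))
  spans <- spans[ord]
  last_end <- 0
  for (sp in spans) {
    stopifnot(sp[1] >= 1, sp[2] <= n_res, sp[1] < sp[2])
    if (sp[1] <= last_end) stop("overlapping helix spans")
    last_end <- sp[2]
  }
  in_span <- integer(n_res)
  for (si in seq_along(spans)) in_span[spans[[si]][1]:spans[[si]][2]] <- si
  templates <- lapply(spans, function(sp) helix_template(sp[2] - sp[1] + 1))
  with_seed(seed, {
    confs <- vector("list", n_conf)
    for (c in seq_len(n_conf)) {
      x <- matrix(0, n_res, 3)
      dir <- as.numeric(unit_sphere(1))
      i <- 2
      if (in_span[1] > 0) {       # chain opens inside a helix span
        si <- in_span[1]
        tpl_r <- templates[[si]] %*% t(random_rotation())
        rows <- spans[[si]][1]:spans[[si]][2]
        x[rows, ] <- sweep(tpl_r, 2, tpl_r[1, ])
        dir <- tpl_r[nrow(tpl_r), ] - tpl_r[nrow(tpl_r) - 1, ]
        dir <- dir / sqrt(sum(dir^2))
        i <- spans[[si]][2] + 1
      }
      while (i <= n_res) {
        si <- in_span[i]
        if (si > 0 && i == spans[[si]][1]) {
          tpl <- templates[[si]]
          R <- random_rotation()
          tpl_r <- tpl %*% t(R)
          start <- x[i - 1, ] + bond * dir
          tpl_r <- sweep(tpl_r, 2, tpl_r[1, ] - start)
          rows <- spans[[si]][1]:spans[[si]][2]
          x[rows, ] <- tpl_r
          dir <- tpl_r[nrow(tpl_r), ] - tpl_r[nrow(tpl_r) - 1, ]
          dir <- dir / sqrt(sum(dir^2))
          i <- spans[[si]][2] + 1
        } else {
          nd <- as.numeric(unit_sphere(1))
          step_dir <- persistence * dir + (1 - persistence) * nd
          step_dir <- step_dir / sqrt(sum(step_dir^2))
          x[i, ] <- x[i - 1, ] + bond * step_dir
          dir <- step_dir
          i <- i + 1
        }
      }
      confs[[c]] <- x
    }
    ensemble(confs)
  })
}
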