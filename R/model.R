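# Shared geometric domain types and superposition/RMSD primitives.

#' Create a labeling site
#'
#' A labeling site is a point attached to a rigid body or chain where a
#' distance restraint is anchored (e.g. a spin-label attachment site). The
#' positional uncertainty of the label (from linker flexibility, typically
#' 2-3 Angstrom for nitroxide labels) is carried along and added in
#' quadrature to restraint widths when scoring.
#'
#' @param chain Chain identifier (single string).
#' @param resno Residue number (integer, 1-based as in the source PDB).
#' @param position Numeric 3-vector, Angstrom.
#' @param tag Optional site tag; defaults to `"CHAIN.RESNO"`.
#' @param uncertainty Positional uncertainty in Angstrom, `>= 0`.
#' @return An object of class `label_site`.
#' @export
label_site <- function(chain, resno, position, tag = NULL,
                       uncertainty = 0) {
  position <- as.numeric(position)
  stopifnot(length(position) == 3, all(is.finite(position)),
            is.numeric(uncertainty), uncertainty >= 0)
  if (is.null(tag)) tag <- paste0(chain, ".", resno)
  structure(list(chain = as.character(chain), resno = as.integer(resno),
                 tag = as.character(tag), position = position,
                 uncertainty = as.numeric(uncertainty)),
            class = "label_site")
}

#' Create a rigid body
#'
#' A rigid body is a set of atoms whose internal geometry is constant under
#' any rigid-body transform, plus exactly three non-collinear reference
#' sites (used to parametrize its placement through pair distances),
#' optional auxiliary sites, and named anchor points where flexible linkers
#' attach.
#'
#' @param xyz Numeric matrix `n x 3` of atom coordinates (Angstrom).
#' @param atoms Data frame with one row per atom; columns `chain`, `resno`,
#'   `elety` (atom name, e.g. `"CA"`), `resid` (residue name). Created with
#'   defaults if omitted.
#' @param ref_sites List of exactly 3 [label_site()] objects.
#' @param aux_sites List of 0 or more auxiliary [label_site()] objects.
#' @param anchors Named list of 3-vectors where linkers attach.
#' @param id Body identifier.
#' @return An object of class `rigid_body`.
#' @export
rigid_body <- function(xyz, atoms = NULL, ref_sites, aux_sites = list(),
                       anchors = list(), id = "body") {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3, nrow(xyz) >= 1, all(is.finite(xyz)))
  if (is.null(atoms)) {
    atoms <- data.frame(chain = "A", resno = seq_len(nrow(xyz)),
                        elety = "CA", resid = "ALA",
                        stringsAsFactors = FALSE)
  }
  stopifnot(nrow(atoms) == nrow(xyz))
  if (length(ref_sites) != 3)
    stop("a rigid body needs exactly 3 reference sites")
  pts <- t(vapply(ref_sites, function(s) s$position, numeric(3)))
  if (.collinear(pts))
    stop("reference sites are collinear")
  structure(list(id = id, xyz = xyz, atoms = atoms,
                 ref_sites = ref_sites, aux_sites = aux_sites,
                 anchors = anchors),
            class = "rigid_body")
}

.collinear <- function(pts, tol = 1e-8) {
  if (nrow(pts) < 3) return(TRUE)
  v1 <- pts[2, ] - pts[1, ]
  v2 <- pts[3, ] - pts[1, ]
  sqrt(sum(.cross3(v1, v2)^2)) < tol * max(1, sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Create a rigid-body arrangement (RBA) model
#'
#' One proper rotation and one translation per body; body 1 is the
#' reference frame and is pinned to the identity. An arrangement of `n`
#' bodies therefore has `6(n-1)` free parameters.
#'
#' @param rotations List of 3x3 proper rotation matrices (det = +1).
#' @param translations List of numeric 3-vectors (Angstrom).
#' @return An object of class `rba_model`.
#' @export
rba_model <- function(rotations, translations) {
  stopifnot(length(rotations) == length(translations))
  for (R in rotations) {
    stopifnot(is.matrix(R), all(dim(R) == c(3, 3)))
    if (max(abs(crossprod(R) - diag(3))) > 1e-8)
      stop("rotation matrix is not orthogonal")
    if (det(R) < 0) stop("rotation matrix is a reflection (det < 0)")
  }
  # re-express relative to body 1 so that body 1 is exactly the identity:
  # y = R1^T (R_k p + t_k - t1)
  R1 <- rotations[[1]]; t1 <- translations[[1]]
  rot <- vector("list", length(rotations))
  tra <- vector("list", length(rotations))
  for (k in seq_along(rotations)) {
    rot[[k]] <- t(R1) %*% rotations[[k]]
    tra[[k]] <- as.numeric(t(R1) %*% (translations[[k]] - t1))
  }
  rot[[1]] <- diag(3); tra[[1]] <- c(0, 0, 0)
  structure(list(rotations = rot, translations = tra), class = "rba_model")
}

#' Identity arrangement for n bodies
#' @param n Number of bodies.
#' @return An `rba_model` with all transforms equal to the identity.
#' @export
rba_identity <- function(n) {
  rba_model(replicate(n, diag(3), simplify = FALSE),
            replicate(n, c(0, 0, 0), simplify = FALSE))
}

#' Apply an RBA transform to a point set
#' @param xyz `n x 3` matrix.
#' @param R 3x3 rotation.
#' @param tvec translation 3-vector.
#' @return Transformed `n x 3` matrix.
#' @export
transform_points <- function(xyz, R, tvec) {
  sweep(xyz %*% t(R), 2, -as.numeric(tvec))
}

#' Place rigid bodies according to an arrangement
#'
#' @param bodies List of [rigid_body()] objects.
#' @param rba An [rba_model()].
#' @return List with per-body transformed `xyz`, reference/auxiliary site
#'   positions, and anchors, plus concatenated `xyz_all` and `atoms_all`.
#' @export
place_bodies <- function(bodies, rba) {
  stopifnot(length(bodies) == length(rba$rotations))
  placed <- vector("list", length(bodies))
  for (k in seq_along(bodies)) {
    R <- rba$rotations[[k]]; tv <- rba$translations[[k]]
    b <- bodies[[k]]
    ref <- t(vapply(b$ref_sites, function(s) as.numeric(R %*% s$position + tv),
                    numeric(3)))
    aux <- if (length(b$aux_sites))
      t(vapply(b$aux_sites, function(s) as.numeric(R %*% s$position + tv),
               numeric(3))) else matrix(0, 0, 3)
    anc <- lapply(b$anchors, function(a) as.numeric(R %*% a + tv))
    placed[[k]] <- list(xyz = transform_points(b$xyz, R, tv),
                        ref = ref, aux = aux, anchors = anc)
  }
  xyz_all <- do.call(rbind, lapply(placed, `[[`, "xyz"))
  atoms_all <- do.call(rbind, lapply(bodies, `[[`, "atoms"))
  list(bodies = placed, xyz_all = xyz_all, atoms_all = atoms_all)
}

#' Create a conformational ensemble
#'
#' The universal currency of population fitting and ensemble analysis: an
#' ordered set of conformers sharing one atom layout, with non-negative
#' populations that are renormalized to sum to 1 on construction.
#'
#' @param coords 3-dimensional array `n_atoms x 3 x n_conformers`, or a
#'   list of `n_atoms x 3` matrices.
#' @param atoms Data frame describing the shared atom layout (columns
#'   `chain`, `resno`, `elety`, `resid`). Default: consecutive CA pseudo-atoms.
#' @param populations Non-negative weights, one per conformer
#'   (default uniform). Renormalized to unit sum.
#' @param provenance Optional list of per-conformer provenance records.
#' @return An object of class `ensemble`.
#' @export
ensemble <- function(coords, atoms = NULL, populations = NULL,
                     provenance = NULL) {
  if (is.list(coords) && !is.array(coords)) {
    n <- unique(vapply(coords, nrow, integer(1)))
    if (length(n) != 1)
      stop("conformers have differing atom counts")
    coords <- array(unlist(coords), dim = c(n, 3, length(coords)))
  }
  stopifnot(is.array(coords), length(dim(coords)) == 3, dim(coords)[2] == 3)
  n_atoms <- dim(coords)[1]; n_conf <- dim(coords)[3]
  if (is.null(atoms)) {
    atoms <- data.frame(chain = "A", resno = seq_len(n_atoms),
                        elety = "CA", resid = "ALA",
                        stringsAsFactors = FALSE)
  }
  stopifnot(nrow(atoms) == n_atoms)
  if (is.null(populations)) populations <- rep(1, n_conf)
  stopifnot(length(populations) == n_conf, all(populations >= 0))
  s <- sum(populations)
  if (s <= 0) stop("populations sum to zero")
  structure(list(coords = coords, atoms = atoms,
                 populations = populations / s,
                 provenance = provenance),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("ensemble: %d conformers, %d atoms, max population %.3g\n",
              n_conformers(x), dim(x$coords)[1], max(x$populations)))
  invisible(x)
}

#' Number of conformers in an ensemble
#' @param e An [ensemble()].
#' @return Integer count.
#' @export
n_conformers <- function(e) dim(e$coords)[3]

#' Extract one conformer's coordinates
#' @param e An [ensemble()].
#' @param i Conformer index.
#' @return `n_atoms x 3` matrix.
#' @export
conformer_xyz <- function(e, i) e$coords[, , i, drop = TRUE]

#' Subset an ensemble by conformer index
#' @param e An [ensemble()].
#' @param idx Conformer indices to keep.
#' @param renormalize Renormalize populations (default TRUE).
#' @return An [ensemble()].
#' @export
subset_ensemble <- function(e, idx, renormalize = TRUE) {
  p <- e$populations[idx]
  if (renormalize) p <- p / sum(p)
  ensemble(e$coords[, , idx, drop = FALSE], e$atoms, p,
           provenance = if (!is.null(e$provenance)) e$provenance[idx])
}

#' Indices of backbone trace atoms
#'
#' Protein residues are represented by their CA atom; nucleic-acid
#' residues may optionally be included through their C1' atom.
#'
#' @param atoms Atom layout data frame.
#' @param include_nucleic Include C1' atoms of nucleic residues.
#' @return Integer vector of row indices.
#' @export
ca_selection <- function(atoms, include_nucleic = FALSE) {
  sel <- atoms$elety == "CA"
  if (include_nucleic) sel <- sel | atoms$elety %in% c("C1'", "C1*")
  which(sel)
}

#' Optimal rigid superposition of two point sets
#'
#' Kabsch superposition by singular value decomposition of the
#' cross-covariance matrix, with the reflection branch forbidden by
#' flipping the sign of the smallest singular component. Returns the
#' proper rotation and translation mapping `coords_b` onto `coords_a`
#' (i.e. `x -> R x + t`) and the residual RMSD.
#'
#' @param coords_a,coords_b `n x 3` matrices, `n >= 3`, not all collinear.
#' @return List with `rotation` (3x3, det = +1), `translation` (3-vector)
#'   and `rmsd` (Angstrom).
#' @export
superpose <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (nrow(coords_a) != nrow(coords_b))
    stop("point counts differ")
  if (nrow(coords_a) < 3)
    stop("need at least 3 points")
  ca <- colMeans(coords_a); cb <- colMeans(coords_b)
  A <- sweep(coords_a, 2, ca); B <- sweep(coords_b, 2, cb)
  H <- crossprod(B, A)            # 3x3
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tvec <- as.numeric(ca - R %*% cb)
  fitted <- sweep(coords_b %*% t(R), 2, -tvec)
  rmsd <- sqrt(mean(rowSums((fitted - coords_a)^2)))
  list(rotation = R, translation = tvec, rmsd = rmsd)
}

#' RMSD between two point sets after optimal superposition
#' @param coords_a,coords_b `n x 3` matrices.
#' @return RMSD in Angstrom.
#' @export
rmsd_fit <- function(coords_a, coords_b) superpose(coords_a, coords_b)$rmsd

#' Pairwise RMSD matrix of an ensemble
#'
#' Computes the matrix `D_ij` of CA RMSDs between all conformer pairs of
#' an ensemble upon optimal superposition. This is the metric underlying
#' the ensemble width and inter-ensemble distance.
#'
#' @param e An [ensemble()].
#' @param selection Integer atom indices (default: all CA atoms; falls
#'   back to all atoms when the layout has no CA entries).
#' @return Symmetric `N x N` matrix with zero diagonal, Angstrom.
#' @export
pairwise_rmsd_matrix <- function(e, selection = NULL) {
  if (is.null(selection)) {
    selection <- ca_selection(e$atoms)
    if (length(selection) == 0) selection <- seq_len(dim(e$coords)[1])
  }
  if (length(selection) == 0) stop("empty atom selection")
  n <- n_conformers(e)
  D <- matrix(0, n, n)
  if (n == 1) return(D)
  confs <- lapply(seq_len(n), function(i)
    matrix(e$coords[selection, , i], ncol = 3))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- rmsd_fit(confs[[i]], confs[[j]])
    }
  }
  D
}
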