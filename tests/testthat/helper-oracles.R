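# Independent oracles and small fixture builders shared across tests.

# Horn's quaternion method for optimal superposition: an independent
# oracle for the SVD-based Kabsch path.
quaternion_superpose_rmsd <- function(a, b) {
  ca <- colMeans(a); cb <- colMeans(b)
  A <- sweep(a, 2, ca); B <- sweep(b, 2, cb)
  M <- crossprod(B, A)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  ev <- eigen(N, symmetric = TRUE)
  q <- ev$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
              3, 3, byrow = TRUE)
  fitted <- B %*% t(R)
  sqrt(mean(rowSums((fitted - A)^2)))
}

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
         3, 3, byrow = TRUE)
}

# tiny ensemble from a list of coordinate matrices
ens_of <- function(..., populations = NULL) {
  ensemble(list(...), populations = populations)
}

# exhaustive reference-site selection oracle: best triple by
# (min side, then area) over all combinations
brute_force_reference_triple <- function(pts) {
  n <- nrow(pts)
  combs <- utils::combn(n, 3)
  best <- NULL; best_key <- c(-Inf, -Inf)
  for (c in seq_len(ncol(combs))) {
    i <- combs[1, c]; j <- combs[2, c]; k <- combs[3, c]
    d <- c(sqrt(sum((pts[i, ] - pts[j, ])^2)),
           sqrt(sum((pts[i, ] - pts[k, ])^2)),
           sqrt(sum((pts[j, ] - pts[k, ])^2)))
    v1 <- pts[j, ] - pts[i, ]; v2 <- pts[k, ] - pts[i, ]
    cr <- c(v1[2] * v2[3] - v1[3] * v2[2],
            v1[3] * v2[1] - v1[1] * v2[3],
            v1[1] * v2[2] - v1[2] * v2[1])
    key <- c(min(d), 0.5 * sqrt(sum(cr^2)))
    if (key[1] > best_key[1] + 1e-12 ||
        (abs(key[1] - best_key[1]) <= 1e-12 && key[2] > best_key[2])) {
      best <- c(i, j, k); best_key <- key
    }
  }
  best
}

# all-pairs shortest path on upper bounds (independent of smooth_bounds)
shortest_path_upper <- function(u) {
  m <- nrow(u)
  for (k in seq_len(m)) for (i in seq_len(m)) for (j in seq_len(m)) {
    if (u[i, k] + u[k, j] < u[i, j]) u[i, j] <- u[i, k] + u[k, j]
  }
  u
}

# two rigid bodies with simple geometry and anchors at known points
toy_bodies <- function(anchor_gap = 30) {
  tri <- rbind(c(0, 0, 0), c(10, 0, 0), c(5, 8, 0))
  mk <- function(chain, shift) {
    xyz <- rbind(tri, c(5, 3, 5), c(2, 2, 2))
    sites <- lapply(1:3, function(i)
      label_site(chain, i, xyz[i, ]))
    aux <- list(label_site(chain, 4, xyz[4, ]))
    rigid_body(xyz,
               data.frame(chain = chain, resno = 1:5, elety = "CA",
                          resid = "ALA", stringsAsFactors = FALSE),
               ref_sites = sites, aux_sites = aux,
               anchors = list(c = xyz[5, ]),
               id = paste0("body", chain))
  }
  list(mk("A", 0), mk("B", 0))
}
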