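# Independent oracles, implemented without reference to the code paths
# they check.

# Rotation matrix from a unit quaternion (w, x, y, z).
quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Rodrigues rotation from a rotation vector.
rotvec_to_rot <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3))
  k <- v / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Brute-force minimal RMSD over proper rotations: centre both point sets,
# scan a quaternion grid, then polish the best grid point with Nelder-Mead
# on a local rotation-vector perturbation. Translation is optimal at the
# centroids for any rotation, so centring handles it exactly.
brute_force_min_rmsd <- function(mobile, reference, grid_n = 7) {
  mc <- sweep(mobile, 2, colMeans(mobile))
  rc <- sweep(reference, 2, colMeans(reference))
  cost_R <- function(R) sqrt(mean(rowSums((mc %*% t(R) - rc)^2)))
  g <- seq(-1, 1, length.out = grid_n)
  best <- list(val = Inf, R = diag(3))
  for (w in g) for (x in g) for (y in g) for (z in g) {
    n2 <- w^2 + x^2 + y^2 + z^2
    if (n2 < 1e-3) next
    R <- quat_to_rot(c(w, x, y, z))
    v <- cost_R(R)
    if (v < best$val) best <- list(val = v, R = R)
  }
  fit <- stats::optim(c(0, 0, 0),
                      function(v) cost_R(rotvec_to_rot(v) %*% best$R),
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 5000))
  min(best$val, fit$value)
}

# Direct-summation radius of gyration.
rg_direct <- function(xyz, w = rep(1, nrow(xyz))) {
  w <- w / sum(w)
  centroid <- colSums(xyz * w)
  sqrt(sum(w * rowSums(sweep(xyz, 2, centroid)^2)))
}
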