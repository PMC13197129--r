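# Independent oracles used to cross-check the package's own geometry code.
# None of them share code paths with the implementation.

# rotation from ZYZ Euler angles
euler_rotation <- function(a, b, g) {
  rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3)
  ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3)
  rz(a) %*% ry(b) %*% rz(g)
}

# minimum superposition RMSD by a coarse search over Euler-angle rotations
# followed by Nelder-Mead polishing of the best starts; no SVD anywhere
oracle_rmsd <- function(x, y) {
  xc <- sweep(x, 2, colMeans(x)); yc <- sweep(y, 2, colMeans(y))
  f <- function(ang) {
    r <- euler_rotation(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((xc %*% t(r) - yc)^2)))
  }
  step <- pi / 6
  grid <- expand.grid(a = seq(0, 2 * pi - step, step),
                      b = seq(0, pi, step),
                      g = seq(0, 2 * pi - step, step))
  vals <- apply(grid, 1, f)
  starts <- grid[order(vals)[1:3], , drop = FALSE]
  best <- Inf
  for (s in seq_len(nrow(starts))) {
    fit <- stats::optim(as.numeric(starts[s, ]), f, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  best
}

# signed dihedral by projecting the outer bonds onto the plane normal to
# the central bond; sign from the scalar triple product (no atan2)
oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  b2n <- b2 / sqrt(sum(b2^2))
  u <- -b1 + sum(b1 * b2n) * b2n   # component of p1->p2 reversed, in plane
  w <- b3 - sum(b3 * b2n) * b2n
  cosang <- sum(u * w) / sqrt(sum(u^2) * sum(w^2))
  ang <- acos(max(-1, min(1, cosang))) * 180 / pi
  triple <- sum(b2n * c(u[2] * w[3] - u[3] * w[2],
                        u[3] * w[1] - u[1] * w[3],
                        u[1] * w[2] - u[2] * w[1]))
  if (triple < 0) -ang else ang
}

# Pearson correlation from the raw covariance formula
oracle_pcc <- function(a, b) {
  am <- a - mean(a); bm <- b - mean(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

random_rotation_matrix <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
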