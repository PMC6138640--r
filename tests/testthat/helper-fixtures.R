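# Shared in-code fixtures. Everything is generated at test time.

# voxelized ball mask centred in its own grid
make_ball <- function(r_um, spacing, pad = 2) {
  dims <- as.integer(ceiling(2 * (r_um + pad) / spacing)) + 1L
  ctr <- (dims - 1L) * spacing / 2
  rz <- (seq_len(dims[1L]) - 1L) * spacing[1L] - ctr[1L]
  ry <- (seq_len(dims[2L]) - 1L) * spacing[2L] - ctr[2L]
  rx <- (seq_len(dims[3L]) - 1L) * spacing[3L] - ctr[3L]
  d2 <- outer(outer(rz^2, ry^2, `+`), rx^2, `+`)
  voxel_grid(array(d2 <= r_um^2, dims), spacing)
}

# ball mask at an arbitrary centre on a given grid
ball_at <- function(centre, r_um, dims, spacing) {
  rz <- (seq_len(dims[1L]) - 1L) * spacing[1L] - centre[1L]
  ry <- (seq_len(dims[2L]) - 1L) * spacing[2L] - centre[2L]
  rx <- (seq_len(dims[3L]) - 1L) * spacing[3L] - centre[3L]
  d2 <- outer(outer(rz^2, ry^2, `+`), rx^2, `+`)
  voxel_grid(array(d2 <= r_um^2, dims), spacing)
}

# axis-aligned ellipsoid mask (semi-axes az, ay, ax um)
ellipsoid_mask <- function(semi, dims, spacing) {
  ctr <- (dims - 1L) * spacing / 2
  rz <- ((seq_len(dims[1L]) - 1L) * spacing[1L] - ctr[1L]) / semi[1L]
  ry <- ((seq_len(dims[2L]) - 1L) * spacing[2L] - ctr[2L]) / semi[2L]
  rx <- ((seq_len(dims[3L]) - 1L) * spacing[3L] - ctr[3L]) / semi[3L]
  d2 <- outer(outer(rz^2, ry^2, `+`), rx^2, `+`)
  voxel_grid(array(d2 <= 1, dims), spacing)
}

# scene with prescribed division directions (unit (z,y,x) vectors)
scene_with_dirs <- function(dirs, config = scene_config(), ...) {
  nbaxis:::scene_truth_from_directions(dirs, config = config, ...)
}

random_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# independent inter-axis angle oracle via atan2 (numerically distinct
# from the clamped-arccos implementation path)
angle_oracle <- function(v1, v2) {
  cr <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  atan2(sqrt(sum(cr^2)), sum(v1 * v2)) * 180 / pi
}

# brute-force exact Mann-Whitney p oracle by full enumeration of rank
# assignments (no ties assumed)
mwu_enum_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  all_u <- apply(utils::combn(n1 + n2, n1), 2L, function(ix) {
    sum(seq_len(n1 + n2)[ix]) - n1 * (n1 + 1) / 2
  })
  p_le <- mean(all_u <= u_obs)
  p_ge <- mean(all_u >= u_obs)
  list(U = u_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# mean and sd of a normal(mu, sigma) truncated to [lo, hi]
truncnorm_moments <- function(mu, sigma, lo = 0, hi = 180) {
  a <- (lo - mu) / sigma; b <- (hi - mu) / sigma
  Z <- pnorm(b) - pnorm(a)
  lam <- (dnorm(a) - dnorm(b)) / Z
  m <- mu + sigma * lam
  v <- sigma^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / Z - lam^2)
  list(mean = m, sd = sqrt(v))
}
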