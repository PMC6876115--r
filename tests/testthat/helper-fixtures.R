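# shared fixtures, all generated in code

# flat square plane in z = 0, (n+1)^2 vertices at the given spacing
make_plane <- function(n = 10L, spacing = 1) {
  g <- expand.grid(x = seq(0, n) * spacing, y = seq(0, n) * spacing)
  triangle_mesh(cbind(g$x, g$y, 0),
                fiducialign:::grid_faces(n + 1L, n + 1L), name = "plane")
}

# two-triangle square
make_quad <- function() {
  triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                rbind(c(1, 2, 3), c(1, 3, 4)), name = "quad")
}

random_rigid <- function() {
  ax <- stats::rnorm(3)
  rigid_transform(rot_axis_angle(ax, stats::runif(1, -180, 180)),
                  stats::runif(3, -20, 20))
}

# brute-force nearest distance: every point against every triangle
brute_force_distances <- function(pts, mesh) {
  vapply(seq_len(nrow(pts)), function(i) {
    min(vapply(seq_len(nrow(mesh$faces)), function(f) {
      fiducialign:::cpp_point_triangle_distance(
        pts[i, ], mesh$vertices[mesh$faces[f, ], , drop = FALSE])
    }, numeric(1)))
  }, numeric(1))
}

# exact signed-rank two-sided p by enumerating every sign pattern of d
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# exact rank-sum two-sided p by enumerating every group assignment
enum_rank_sum_p <- function(a, b) {
  na <- length(a)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combs <- utils::combn(length(r), na)
  u_all <- apply(combs, 2, function(ix) sum(r[ix]) - na * (na + 1) / 2)
  p_le <- mean(u_all <= u_obs + 1e-9)
  p_ge <- mean(u_all >= u_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}
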