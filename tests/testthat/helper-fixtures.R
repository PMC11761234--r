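# Shared fixtures, computed once per test run.

# A deterministic symmetric base case at the default resolution.
BASE_CASE <- generate_base_face(seed = 1)

# Its pose-normalized mesh/landmarks (the pose of a base face is the
# identity by construction, but tests should not rely on that here).
BASE_POSE <- frankfort_pose(BASE_CASE$landmarks)
BASE_MESH_POSED <- apply_transform(BASE_POSE, BASE_CASE$mesh,
                                   frame_tag = "normalized")
BASE_LM_POSED <- apply_transform(BASE_POSE, BASE_CASE$landmarks)

# A small asymmetric tetrahedron mesh for cheap geometry tests.
tetra_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 2, 0), c(0.5, 0.5, 1.5))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
  face_mesh(v, f)
}

# A random (seeded) modest rigid transform: rotation up to ~max_deg degrees,
# translation up to max_t mm per component.
random_rigid <- function(max_deg = 10, max_t = 5) {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, -max_deg, max_deg) * pi / 180
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  rigid_transform(R, stats::runif(3, -max_t, max_t))
}
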