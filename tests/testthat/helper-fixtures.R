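# Shared fixtures: hand-built frames of single-bead "peptides" give
# exact control over distances; generator-built frames exercise the
# full bead-level machinery.

gnn_topology <- function(n = 2) peptide_topology("GNNQQNY", n)

# Frame of point peptides (one CA bead each) at given positions.
point_frame <- function(positions, box = c(20, 20, 20), time = 0) {
  positions <- as.matrix(positions)
  tibble::tibble(
    frame = 1L, time = time,
    peptide = seq_len(nrow(positions)),
    residue = 1L, role = "CA",
    x = positions[, 1], y = positions[, 2], z = positions[, 3],
    box_x = box[1], box_y = box[2], box_z = box[3]
  )
}

# Frame of two-bead peptides (residue-1 N and C) with given end-to-end
# unit vectors; used for exact Cn constructions.
vector_frame <- function(units, origin_spacing = 5, box = NULL) {
  units <- as.matrix(units)
  n <- nrow(units)
  if (is.null(box)) box <- rep(max(20, n * origin_spacing * 2), 3)
  rows <- lapply(seq_len(n), function(i) {
    o <- c((i - 1) * origin_spacing %% (box[1] * 0.9), 0, 0)
    tibble::tibble(
      frame = 1L, time = 0,
      peptide = i, residue = 1L, role = c("N", "C"),
      x = c(o[1], o[1] + units[i, 1]),
      y = c(o[2], o[2] + units[i, 2]),
      z = c(o[3], o[3] + units[i, 3]),
      box_x = box[1], box_y = box[2], box_z = box[3]
    )
  })
  dplyr::bind_rows(rows)
}

random_unit_rows <- function(n) {
  m <- matrix(stats::rnorm(3 * n), ncol = 3)
  m / sqrt(rowSums(m^2))
}

# Apply a rigid rotation (about the box center) plus translation.
rigid_transform <- function(frame, rot = diag(3), shift = c(0, 0, 0)) {
  ctr <- c(frame$box_x[1], frame$box_y[1], frame$box_z[1]) / 2
  xyz <- as.matrix(frame[, c("x", "y", "z")])
  xyz <- sweep(xyz, 2, ctr) %*% t(rot)
  xyz <- sweep(xyz, 2, ctr + shift, FUN = "+")
  frame$x <- xyz[, 1]; frame$y <- xyz[, 2]; frame$z <- xyz[, 3]
  frame
}

# Wrap each peptide by its own random integer box vector (tests the
# wrapping-invariance contract).
random_peptide_wrap <- function(frame, seed = 1) {
  set.seed(seed)
  box <- c(frame$box_x[1], frame$box_y[1], frame$box_z[1])
  for (p in unique(frame$peptide)) {
    k <- sample(-2:2, 3, replace = TRUE)
    rows <- frame$peptide == p
    frame$x[rows] <- frame$x[rows] + k[1] * box[1]
    frame$y[rows] <- frame$y[rows] + k[2] * box[2]
    frame$z[rows] <- frame$z[rows] + k[3] * box[3]
  }
  frame
}

# m well-separated copies of a bead template (one frame), e.g. for
# conformation-dependent descriptors.
frame_from_helix_template <- function(tpl, m, spacing = 3, box_l = 30) {
  rows <- lapply(seq_len(m), function(i) {
    tibble::tibble(
      frame = 1L, time = 0, peptide = as.integer(i),
      residue = tpl$residue, role = tpl$role,
      x = tpl$x + box_l / 2, y = tpl$y + (i - 1) * spacing + box_l / 3,
      z = tpl$z + box_l / 2,
      box_x = box_l, box_y = box_l, box_z = box_l
    )
  })
  dplyr::bind_rows(rows)
}

# Independent uniform-ish random rotation (QR decomposition).
random_rotation_oracle <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Random compact cluster placed by a center random walk: consecutive
# peptide centers are `step` apart, so the cluster is linked at a
# cutoff moderately above `step` by construction.
walk_cluster <- function(m, seed, box_l = 9, step = 0.6) {
  set.seed(seed)
  tpl <- fibriltwist::peptide_template()
  centers <- matrix(0, nrow = m, ncol = 3)
  for (i in 2:m) {
    u <- stats::rnorm(3)
    centers[i, ] <- centers[i - 1, ] + step * u / sqrt(sum(u^2))
  }
  centers <- sweep(centers, 2, colMeans(centers))
  rows <- lapply(seq_len(m), function(i) {
    q <- random_rotation_oracle()
    xyz <- as.matrix(tpl[, c("x", "y", "z")]) %*% t(q)
    tibble::tibble(
      frame = 1L, time = 0, peptide = as.integer(i),
      residue = tpl$residue, role = tpl$role,
      x = xyz[, 1] + centers[i, 1] + box_l / 2,
      y = xyz[, 2] + centers[i, 2] + box_l / 2,
      z = xyz[, 3] + centers[i, 3] + box_l / 2,
      box_x = box_l, box_y = box_l, box_z = box_l
    )
  })
  dplyr::bind_rows(rows)
}
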