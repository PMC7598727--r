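# Seeded generators of fixture structures with analytically known
# descriptor values. Every generator returns an ordinary trajectory
# tibble (one frame) so the analysis functions see synthetic and real
# data identically; ground truth travels as an attribute.

# Rotation taking unit vector a onto unit vector b (Rodrigues).
rotation_between <- function(a, b) {
  a <- a / vec_norm(a); b <- b / vec_norm(b)
  v <- cross3(a, b)
  c_ <- sum(a * b)
  if (vec_norm(v) < 1e-12) {
    if (c_ > 0) return(diag(3))
    # opposite: rotate pi about any perpendicular axis
    perp <- if (abs(a[1]) < 0.9) cross3(a, c(1, 0, 0)) else cross3(a, c(0, 1, 0))
    return(rotation_about(perp, pi))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx * (1 / (1 + c_))
}

#' Rigid coarse-grained peptide template
#'
#' Builds one idealized peptide chain from internal coordinates: three
#' backbone beads per residue placed with fixed bond length and angle
#' and the requested phi/psi torsions (omega fixed at 180 degrees), plus
#' one side-chain bead per non-glycine residue. The default extended
#' conformation (phi = -135, psi = 135) gives a consecutive-residue
#' spacing of roughly 0.36 nm. The template is centered at its mass
#' center and aligned so its backbone end-to-end vector points along +x.
#'
#' @param sequence One-letter sequence (default `"GNNQQNY"`).
#' @param phi,psi Backbone torsions in degrees, recycled per residue.
#' @param bond Backbone bond length (nm).
#' @param bond_angle Backbone bond angle (degrees).
#' @param sc_bond Side-chain bead distance from CA (nm).
#' @return A tibble with columns `residue`, `role`, `x`, `y`, `z`.
#' @export
peptide_template <- function(sequence = "GNNQQNY", phi = -135, psi = 135,
                             bond = 0.13, bond_angle = 111, sc_bond = 0.25) {
  res <- strsplit(toupper(sequence), "")[[1]]
  n_res <- length(res)
  phi <- rep_len(phi, n_res)
  psi <- rep_len(psi, n_res)
  ang <- bond_angle * pi / 180
  # first residue backbone in the xy-plane
  bb <- matrix(NA_real_, nrow = 3 * n_res, ncol = 3)
  bb[1, ] <- c(0, 0, 0)
  bb[2, ] <- c(bond, 0, 0)
  bb[3, ] <- bb[2, ] + bond * c(-cos(ang), sin(ang), 0)
  idx <- function(i, role) (i - 1) * 3 + match(role, c("N", "CA", "C"))
  for (i in 2:n_res) {
    bb[idx(i, "N"), ] <- nerf_place(bb[idx(i - 1, "N"), ], bb[idx(i - 1, "CA"), ],
                                    bb[idx(i - 1, "C"), ], bond, bond_angle, psi[i - 1])
    bb[idx(i, "CA"), ] <- nerf_place(bb[idx(i - 1, "CA"), ], bb[idx(i - 1, "C"), ],
                                     bb[idx(i, "N"), ], bond, bond_angle, 180)
    bb[idx(i, "C"), ] <- nerf_place(bb[idx(i - 1, "C"), ], bb[idx(i, "N"), ],
                                    bb[idx(i, "CA"), ], bond, bond_angle, phi[i])
  }
  rows <- list()
  for (i in seq_len(n_res)) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      residue = i, role = c("N", "CA", "C"),
      x = bb[idx(i, "N"):idx(i, "C"), 1],
      y = bb[idx(i, "N"):idx(i, "C"), 2],
      z = bb[idx(i, "N"):idx(i, "C"), 3]
    )
    if (res[i] != "G") {
      sc <- nerf_place(bb[idx(i, "N"), ], bb[idx(i, "C"), ], bb[idx(i, "CA"), ],
                       sc_bond, 110, 120)
      rows[[length(rows) + 1]] <- tibble::tibble(
        residue = i, role = "SC", x = sc[1], y = sc[2], z = sc[3]
      )
    }
  }
  tpl <- dplyr::arrange(dplyr::bind_rows(rows), .data$residue,
                        match(.data$role, c("N", "CA", "C", "SC")))
  xyz <- as.matrix(tpl[, c("x", "y", "z")])
  xyz <- sweep(xyz, 2, colMeans(xyz))
  # align backbone end-to-end (N of residue 1 -> C of last residue) to +x
  i_first <- which(tpl$residue == 1 & tpl$role == "N")
  i_last <- which(tpl$residue == n_res & tpl$role == "C")
  rot <- rotation_between(xyz[i_last, ] - xyz[i_first, ], c(1, 0, 0))
  xyz <- xyz %*% t(rot)
  tpl$x <- xyz[, 1]; tpl$y <- xyz[, 2]; tpl$z <- xyz[, 3]
  tpl
}

# Assemble placed peptide bead tables into one frame.
frame_from_peptides <- function(peptides, box, time = 0) {
  dplyr::bind_rows(lapply(seq_along(peptides), function(p) {
    tibble::tibble(
      frame = 1L, time = time,
      peptide = as.integer(p),
      residue = peptides[[p]]$residue,
      role = peptides[[p]]$role,
      x = peptides[[p]]$x, y = peptides[[p]]$y, z = peptides[[p]]$z,
      box_x = box[1], box_y = box[2], box_z = box[3]
    )
  }))
}

place_template <- function(tpl, rot, center) {
  xyz <- as.matrix(tpl[, c("x", "y", "z")]) %*% t(rot)
  tpl$x <- xyz[, 1] + center[1]
  tpl$y <- xyz[, 2] + center[2]
  tpl$z <- xyz[, 3] + center[3]
  tpl
}

#' Ideal helical fibril with known helicity
#'
#' Builds a noise-free (or noise-perturbed) fibril of `n_ribbons`
#' ribbons wound about the z axis: peptide mass centers sit at radius
#' `radius`, rise `rise` per step along the axis, and the azimuth
#' advances by `-twist_deg` per step (a positive twist builds a
#' left-handed fibril). Peptides are rigid template copies oriented
#' radially, so the designated side-chain centers form a concentric
#' helix and the fitted axis is exact for `n_ribbons >= 2` (azimuthal
#' symmetry). The closed-form cluster helicity of this geometry is
#' `-sin(twist_deg)`, independent of rise, radius and ribbon count.
#'
#' @param n_ribbons Number of ribbons (>= 1).
#' @param peptides_per_ribbon Peptides in each ribbon (>= 2).
#' @param rise Axial rise per step (nm, > 0).
#' @param twist_deg Azimuthal step in degrees (sign sets handedness).
#' @param radius Distance of peptide mass centers from the axis (nm, > 0).
#' @param noise Gaussian coordinate noise amplitude (nm, >= 0).
#' @param seed Optional RNG seed (only used when `noise > 0`).
#' @param sequence Peptide sequence for the rigid template.
#' @param box_l Cubic box edge (nm); default encloses the fibril with a
#'   wide margin so nothing is wrapped.
#' @param mirror If `TRUE`, mirror the final structure through the
#'   x = box/2 plane (flips chirality, hence the sign of H).
#' @return A one-frame trajectory tibble with a `ground_truth` attribute
#'   (see [fibril_ground_truth()]).
#' @export
build_helical_fibril <- function(n_ribbons = 3, peptides_per_ribbon = 8,
                                 rise = 0.5, twist_deg = 8, radius = 1.0,
                                 noise = 0, seed = NULL,
                                 sequence = "GNNQQNY", box_l = NULL,
                                 mirror = FALSE) {
  stopifnot(n_ribbons >= 1, peptides_per_ribbon >= 2, rise > 0, radius > 0, noise >= 0)
  if (n_ribbons >= 2) {
    chord <- 2 * radius * sin(pi / n_ribbons)
    if (chord < 0.05) {
      stop("construction error: inter-ribbon center spacing ", round(chord, 3),
           " nm is below the bead clash distance", call. = FALSE)
    }
  }
  tpl <- peptide_template(sequence)
  dphi <- twist_deg * pi / 180
  height <- (peptides_per_ribbon - 1) * rise
  if (is.null(box_l)) box_l <- 2 * (height + radius + 4)
  centerof <- c(box_l / 2, box_l / 2, box_l / 2 - height / 2)
  peptides <- list()
  ribbon_id <- integer(0)
  for (r in seq_len(n_ribbons)) {
    phi0 <- 2 * pi * (r - 1) / n_ribbons
    for (k in seq_len(peptides_per_ribbon) - 1) {
      phi <- phi0 - k * dphi
      center <- c(radius * cos(phi), radius * sin(phi), k * rise) + centerof
      # template +x (the designated side-chain end) points inward so the
      # side-chain beads form the fibril core, as in tyrosine-cored fibrils
      rot <- rotation_about(c(0, 0, 1), phi + pi)
      peptides[[length(peptides) + 1]] <- place_template(tpl, rot, center)
      ribbon_id <- c(ribbon_id, r)
    }
  }
  frame <- frame_from_peptides(peptides, rep(box_l, 3))
  if (noise > 0) {
    if (!is.null(seed)) set.seed(seed)
    frame$x <- frame$x + stats::rnorm(nrow(frame), sd = noise)
    frame$y <- frame$y + stats::rnorm(nrow(frame), sd = noise)
    frame$z <- frame$z + stats::rnorm(nrow(frame), sd = noise)
  }
  h_true <- -sin(dphi)
  if (mirror) {
    frame$x <- box_l - frame$x
    h_true <- -h_true
  }
  attr(frame, "ground_truth") <- list(
    kind = "helical_fibril",
    axis_direction = c(0, 0, 1),
    ribbons = tibble::tibble(peptide = seq_along(ribbon_id), ribbon = ribbon_id),
    h_true = h_true,
    twist_deg = if (mirror) -twist_deg else twist_deg,
    rise = rise, radius = radius, n_ribbons = n_ribbons
  )
  frame
}

#' Ground-truth record of a synthetic structure
#'
#' @param frame A frame built by one of the `build_*()` generators.
#' @return The generator's ground-truth list, or `NULL`.
#' @export
fibril_ground_truth <- function(frame) {
  attr(frame, "ground_truth", exact = TRUE)
}

#' Stack of parallel or antiparallel extended peptides
#'
#' Identical extended template copies stacked along y at the given
#' spacing; in the antiparallel arrangement every second peptide is
#' rotated by 180 degrees about the stacking axis. Both arrangements
#' have end-to-end correlation Cn = 1 (the squared dot product does not
#' distinguish parallel from antiparallel).
#'
#' @param m Number of peptides (>= 2).
#' @param spacing Stacking distance (nm).
#' @param orientation `"parallel"` or `"antiparallel"`.
#' @param sequence Peptide sequence.
#' @param box_l Cubic box edge (nm); default encloses the stack.
#' @return A one-frame trajectory tibble with a `ground_truth` attribute.
#' @export
build_parallel_sheet <- function(m, spacing = 0.48,
                                 orientation = c("parallel", "antiparallel"),
                                 sequence = "GNNQQNY", box_l = NULL) {
  orientation <- match.arg(orientation)
  stopifnot(m >= 2, spacing > 0)
  tpl <- peptide_template(sequence)
  extent <- max(tpl$x) - min(tpl$x)
  if (is.null(box_l)) box_l <- 2 * (m * spacing + extent + 4)
  center0 <- c(box_l / 2, box_l / 2 - (m - 1) * spacing / 2, box_l / 2)
  flip <- rotation_about(c(0, 1, 0), pi)
  peptides <- lapply(seq_len(m) - 1, function(k) {
    rot <- if (orientation == "antiparallel" && k %% 2 == 1) flip else diag(3)
    place_template(tpl, rot, center0 + c(0, k * spacing, 0))
  })
  frame <- frame_from_peptides(peptides, rep(box_l, 3))
  attr(frame, "ground_truth") <- list(
    kind = "sheet", orientation = orientation, spacing = spacing, cn_true = 1
  )
  frame
}

#' Amorphous near-spherical cluster
#'
#' Peptide mass centers drawn uniformly from a ball with
#' minimum-separation rejection sampling; orientations are uniform
#' random rotations. In expectation the aggregate is isotropic
#' (normalized asphericity near 0) with uncorrelated end-to-end vectors
#' (Cn near 1/3).
#'
#' @param m Number of peptides (>= 2).
#' @param radius Ball radius for the mass centers (nm).
#' @param min_separation Smallest allowed center-center distance (nm).
#' @param seed Optional RNG seed.
#' @param sequence Peptide sequence.
#' @param box_l Cubic box edge (nm); default encloses the ball.
#' @param max_tries Rejection-sampling budget per peptide.
#' @return A one-frame trajectory tibble with a `ground_truth` attribute.
#' @export
build_amorphous_cluster <- function(m, radius, min_separation = 0.8, seed = NULL,
                                    sequence = "GNNQQNY", box_l = NULL,
                                    max_tries = 5000) {
  stopifnot(m >= 2, radius > 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(box_l)) box_l <- 2 * (2 * radius + 4)
  tpl <- peptide_template(sequence)
  centers <- matrix(NA_real_, nrow = m, ncol = 3)
  for (i in seq_len(m)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      u <- stats::rnorm(3)
      pt <- u / vec_norm(u) * radius * stats::runif(1)^(1 / 3)
      if (i == 1 || min(row_norms(centers[seq_len(i - 1), , drop = FALSE] -
                                  rep(pt, each = i - 1))) >= min_separation) {
        centers[i, ] <- pt
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("could not place ", m, " centers at separation ", min_separation,
           " nm inside radius ", radius, " nm", call. = FALSE)
    }
  }
  centerof <- rep(box_l / 2, 3)
  peptides <- lapply(seq_len(m), function(i) {
    place_template(tpl, random_rotation(), centers[i, ] + centerof)
  })
  frame <- frame_from_peptides(peptides, rep(box_l, 3))
  attr(frame, "ground_truth") <- list(kind = "amorphous", radius = radius)
  frame
}

#' Randomly placed free monomers in a periodic box
#'
#' The initial condition of an aggregation run: peptides with random
#' positions and orientations, kept apart so that every peptide is a
#' free monomer at the linkage cutoff.
#'
#' @param n_peptides Number of peptides.
#' @param box_l Cubic box edge (nm).
#' @param min_separation Smallest allowed center-center distance (nm),
#'   minimum-image; keep it above the linkage cutoff plus twice the
#'   peptide radius to guarantee monomers.
#' @param seed Optional RNG seed.
#' @param sequence Peptide sequence.
#' @param max_tries Rejection-sampling budget per peptide.
#' @return A one-frame trajectory tibble.
#' @export
build_monomer_gas <- function(n_peptides, box_l, min_separation = 3.0,
                              seed = NULL, sequence = "GNNQQNY",
                              max_tries = 5000) {
  stopifnot(n_peptides >= 1, box_l > 0)
  if (!is.null(seed)) set.seed(seed)
  tpl <- peptide_template(sequence)
  centers <- matrix(NA_real_, nrow = n_peptides, ncol = 3)
  for (i in seq_len(n_peptides)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      pt <- stats::runif(3, 0, box_l)
      if (i == 1) { centers[i, ] <- pt; ok <- TRUE; break }
      d <- min_image(centers[seq_len(i - 1), , drop = FALSE] - rep(pt, each = i - 1),
                     rep(box_l, 3))
      if (min(row_norms(d)) >= min_separation) {
        centers[i, ] <- pt; ok <- TRUE; break
      }
    }
    if (!ok) {
      stop("could not place ", n_peptides, " monomers at separation ",
           min_separation, " nm in a ", box_l, " nm box", call. = FALSE)
    }
  }
  peptides <- lapply(seq_len(n_peptides), function(i) {
    place_template(tpl, random_rotation(), centers[i, ])
  })
  frame_from_peptides(peptides, rep(box_l, 3))
}

#' Translate a frame and wrap it into the box
#'
#' Shifts all coordinates by `shift` and wraps them back into
#' \[0, L) in each dimension, deliberately splitting any cluster that
#' now straddles a box face. With a zero shift (or a shift by a whole
#' box vector) this is the identity on minimum-image structure, making
#' it the canonical round-trip partner of [unwrap_cluster()].
#'
#' @param frame A single-frame trajectory tibble.
#' @param shift Length-3 translation in nm.
#' @return The shifted, wrapped frame.
#' @export
split_across_boundary <- function(frame, shift = c(0, 0, 0)) {
  check_frame_tbl(frame, single_frame = TRUE)
  box <- frame_box(frame)
  frame$x <- (frame$x + shift[1]) %% box[1]
  frame$y <- (frame$y + shift[2]) %% box[2]
  frame$z <- (frame$z + shift[3]) %% box[3]
  frame
}
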