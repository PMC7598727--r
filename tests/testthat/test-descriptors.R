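test_that("gyration shape captures the sphere and rod limits", {
  cube <- expand.grid(x = c(0, 1), y = c(0, 1), z = c(0, 1))
  sh <- gyration_shape(cube)
  expect_equal(sh$b_raw, 0, tolerance = 1e-12) # isotropic eigenvalues
  expect_equal(sh$rg, sqrt(3) / 2, tolerance = 1e-12)

  rod <- cbind(seq(0, 9), 0, 0)
  shr <- gyration_shape(rod)
  expect_equal(shr$b_norm, 1, tolerance = 1e-12) # lambda_x = lambda_y = 0
  expect_equal(shr$lambda_x2, 0, tolerance = 1e-12)

  expect_error(gyration_shape(rbind(c(1, 1, 1), c(1, 1, 1))), "degenerate")
})

test_that("gyration eigenvalues agree with a characteristic-polynomial solve", {
  set.seed(21)
  for (rep in 1:5) {
    pts <- matrix(rnorm(15), ncol = 3)
    sh <- gyration_shape(pts)
    centered <- sweep(pts, 2, colMeans(pts))
    ev <- oracle_eigen3(crossprod(centered) / nrow(pts))
    expect_equal(c(sh$lambda_x2, sh$lambda_y2, sh$lambda_z2), ev, tolerance = 1e-9)
  }
})

test_that("Cn is 1 for aligned vectors, 0 for perpendicular pairs, 1/3 for isotropy", {
  expect_equal(end_to_end_correlation(vector_frame(rbind(c(1, 0, 0), c(1, 0, 0),
                                                         c(1, 0, 0)))), 1)
  # antiparallel counts as aligned (squared dot product)
  expect_equal(end_to_end_correlation(vector_frame(rbind(c(1, 0, 0), c(-1, 0, 0)))), 1)
  expect_equal(end_to_end_correlation(vector_frame(rbind(c(1, 0, 0), c(0, 1, 0)))), 0)

  set.seed(33)
  cn <- replicate(40, end_to_end_correlation(vector_frame(random_unit_rows(60))))
  expect_equal(mean(cn), 1 / 3, tolerance = 0.02)

  expect_error(end_to_end_correlation(vector_frame(rbind(c(0, 0, 0)))),
               "zero-length|at least 2")
})

test_that("backbone dihedrals match the independent torsion oracle", {
  skip_if_not_installed("bio3d")
  set.seed(4)
  f <- build_amorphous_cluster(3, radius = 2, seed = 4)
  dih <- backbone_dihedrals(f)
  bb <- dplyr::arrange(
    dplyr::filter(compact_peptides(f), role %in% c("N", "CA", "C")),
    peptide, residue, match(role, c("N", "CA", "C"))
  )
  for (p in unique(bb$peptide)) {
    xyz <- as.matrix(bb[bb$peptide == p, c("x", "y", "z")])
    for (res in 2:6) {
      i <- (res - 1) * 3 + 1 # N of residue res
      phi_oracle <- bio3d::torsion.xyz(as.numeric(t(xyz[(i - 1):(i + 2), ])))
      psi_oracle <- bio3d::torsion.xyz(as.numeric(t(xyz[i:(i + 3), ])))
      row <- dih[dih$peptide == p & dih$residue == res, ]
      expect_equal(row$phi, as.numeric(phi_oracle), tolerance = 1e-6)
      expect_equal(row$psi, as.numeric(psi_oracle), tolerance = 1e-6)
    }
  }
})

test_that("beta-content counts interior residues in the beta region per peptide", {
  ext <- build_parallel_sheet(4, spacing = 0.9) # extended phi/psi by construction
  expect_equal(beta_content(ext), 5) # all 5 interior residues of each peptide

  # alpha-helical chains sit outside the beta region
  hel_tpl <- peptide_template(phi = -57, psi = -47)
  hel <- frame_from_helix_template(hel_tpl, m = 3, box_l = 30)
  expect_equal(beta_content(hel), 0)

  # mixed cluster: count follows the per-residue dihedral table
  mixed <- dplyr::bind_rows(
    ext,
    dplyr::mutate(hel, peptide = peptide + 4L)
  )
  dih <- backbone_dihedrals(mixed)
  interior <- dih[!is.na(dih$phi) & !is.na(dih$psi), ]
  expected <- sum(interior$phi >= -180 & interior$phi <= -45 &
                    (interior$psi >= 45 | interior$psi <= -120)) / 7
  expect_equal(beta_content(mixed), expected)
})

test_that("distance histograms are normalized and peak at constructed shells", {
  two <- point_frame(rbind(c(1, 1, 1), c(1.2, 1, 1)))
  h2 <- mass_center_histogram(two)
  expect_equal(sum(h2$prob), 1)
  expect_equal(sum(h2$prob > 0), 1)
  expect_true(h2$bin_lo[h2$prob > 0] < 0.2 && h2$bin_hi[h2$prob > 0] >= 0.2)

  tri <- point_frame(rbind(c(0, 0, 0), c(0.6, 0, 0), c(0.3, 0.3 * sqrt(3), 0)))
  h3 <- mass_center_histogram(tri)
  expect_equal(sum(h3$prob > 0), 1) # all three distances in the same bin
  expect_equal(h3$prob[h3$prob > 0], 1)

  # 3x3x3 cubic lattice: mass only in the exact shell distances
  a <- 0.6
  lat <- as.matrix(expand.grid(x = (0:2) * a, y = (0:2) * a, z = (0:2) * a))
  hl <- mass_center_histogram(point_frame(lat, box = rep(30, 3)))
  d <- as.numeric(dist(lat))
  occupied <- unique(ceiling(round(d / 0.02, 9)) - 1)
  expect_setequal(which(hl$prob > 0) - 1, occupied)

  expect_error(mass_center_histogram(tri, bin_width = 0), "configuration")
})

test_that("histogram sharpness separates lattice order from uniform disorder", {
  a <- 0.6
  lat <- as.matrix(expand.grid(x = (0:3) * a, y = (0:3) * a, z = (0:3) * a))
  hl <- mass_center_histogram(point_frame(lat, box = rep(30, 3)))
  ord <- classify_order(hl)
  expect_true(ord$ordered)
  expect_gt(ord$score, 0.9)

  # uniform tail beyond the first peak: flat stretches are not maxima
  flat <- tibble::tibble(
    bin_lo = seq(0, 0.58, 0.02), bin_hi = seq(0.02, 0.6, 0.02),
    mid = seq(0.01, 0.59, 0.02),
    prob = c(rep(0, 9), 0.2, rep(0, 2), rep(0.8 / 18, 18)), m = 10
  )
  dis <- classify_order(flat)
  expect_false(dis$ordered)
  expect_lt(dis$score, 0.3)
})

test_that("fibril fixtures score sharper histograms than amorphous ones", {
  fib <- build_helical_fibril(3, 10, rise = 0.5, twist_deg = 8, radius = 1.2)
  am <- build_amorphous_cluster(30, radius = 3.2, min_separation = 0.8, seed = 8)
  sc_fib <- classify_order(mass_center_histogram(fib))$score
  sc_am <- classify_order(mass_center_histogram(am))$score
  expect_gt(sc_fib, sc_am)
})

test_that("shape, Cn, beta and histogram are rotation/translation invariant", {
  f <- build_amorphous_cluster(10, radius = 2, min_separation = 0.6, seed = 13)
  set.seed(14)
  g <- rigid_transform(f, random_rotation_oracle(), c(0.7, -1.1, 0.4))
  expect_equal(gyration_shape(peptide_mass_centers(g))$rg,
               gyration_shape(peptide_mass_centers(f))$rg, tolerance = 1e-10)
  expect_equal(gyration_shape(peptide_mass_centers(g))$b_norm,
               gyration_shape(peptide_mass_centers(f))$b_norm, tolerance = 1e-10)
  expect_equal(end_to_end_correlation(g), end_to_end_correlation(f),
               tolerance = 1e-10)
  expect_equal(beta_content(g), beta_content(f))
  expect_equal(mass_center_histogram(g)$prob, mass_center_histogram(f)$prob)
})

test_that("the smoothed second maximum finds the second shell", {
  h <- tibble::tibble(
    bin_lo = seq(0, 0.78, 0.02), bin_hi = seq(0.02, 0.8, 0.02),
    mid = seq(0.01, 0.79, 0.02),
    prob = 0, m = 10
  )
  h$prob[c(10, 24)] <- c(0.6, 0.4) # shells at 0.19 and 0.47 nm
  expect_equal(second_maximum(h), h$mid[24])
  expect_true(is.na(second_maximum(h[1:12, ])))
})
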