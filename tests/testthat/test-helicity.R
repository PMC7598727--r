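test_that("axis fitting recovers lines, helices and flags isotropic clouds", {
  line <- cbind(seq(0, 5, by = 0.5), 2 * seq(0, 5, by = 0.5), 1)
  ax <- fit_cluster_axis(line)
  expect_equal(abs(sum(ax$direction * c(1, 2, 0) / sqrt(5))), 1, tolerance = 1e-10)

  two <- rbind(c(0, 0, 0), c(1, 1, 1))
  ax2 <- fit_cluster_axis(two)
  expect_equal(abs(sum(ax2$direction * rep(1 / sqrt(3), 3))), 1, tolerance = 1e-10)

  # helix wound about z: principal direction is the helix axis
  t <- seq(0, 6 * pi, length.out = 60)
  helix <- cbind(cos(t), sin(t), 0.4 * t)
  ax3 <- fit_cluster_axis(helix)
  expect_gt(abs(ax3$direction[3]), 0.99) # slight tilt: finite open-ended helix

  cube <- as.matrix(expand.grid(c(0, 1), c(0, 1), c(0, 1)))
  expect_warning(fit_cluster_axis(cube), "ill-defined")
  expect_error(fit_cluster_axis(rbind(c(1, 1, 1), c(1, 1, 1))), "degenerate")
})

test_that("reference spacing and cutoffs reproduce the fitted constants", {
  # hand arithmetic from the default fit constants
  expect_equal(reference_spacing(72), 9.6192 / 72 - 0.0009, tolerance = 1e-12)
  expect_equal(reference_spacing(72), 0.13270, tolerance = 1e-5)
  expect_equal(reference_spacing(25), 0.38387, tolerance = 1e-5)
  expect_error(reference_spacing(20000), "invalid spacing")
  expect_error(reference_spacing(1), "M >= 2")

  cut <- ribbon_cutoffs(reference_spacing(72))
  expect_equal(cut$d_par0, 0.11678, tolerance = 1e-4)
  expect_equal(cut$d_perp0, 0.06237, tolerance = 1e-4)
  cut25 <- ribbon_cutoffs(reference_spacing(25))
  expect_equal(cut25$d_par0, 0.33781, tolerance = 1e-4)
  expect_equal(cut25$d_perp0, 0.18042, tolerance = 1e-4)
  expect_equal(ribbon_cutoffs(1, 1, 1), list(d_par0 = 1, d_perp0 = 1))
  expect_error(ribbon_cutoffs(1, -1, 0.5), "configuration")
})

test_that("ribbon assignment chains in-criterion consecutive pairs and splits at gaps", {
  axis <- fit_cluster_axis(cbind(0, 0, 0:9))
  centers <- tibble::tibble(peptide = 1:8, x = 0.001 * (1:8), y = 0, z = (1:8) * 0.4)
  cuts <- list(d_par0 = 0.45, d_perp0 = 0.2)
  rd <- assign_ribbons(centers, axis, cuts)
  expect_equal(unique(rd$ribbon), 1L)
  expect_equal(rd$peptide, 1:8) # sorted by projection

  # gap above d_par0 between the two halves: exactly 2 ribbons
  centers2 <- centers
  centers2$z[5:8] <- centers2$z[5:8] + 0.5
  rd2 <- assign_ribbons(centers2, axis, cuts)
  expect_equal(max(rd2$ribbon), 2L)
  expect_equal(rd2$ribbon, rep(1:2, each = 4))

  # interleaved parallel stacks beyond d_perp0 fragment under the
  # consecutive-run rule (documented behavior of the sorted chaining)
  stacks <- tibble::tibble(
    peptide = 1:10,
    x = rep(c(0, 1), 5), y = 0,
    z = rep(seq(0, 1.6, 0.4), each = 2) + rep(c(0, 0.2), 5)
  )
  rd3 <- assign_ribbons(stacks, axis, cuts)
  expect_gt(max(rd3$ribbon), 2L)
})

test_that("pair twist follows the radial/tangential closed form", {
  axis <- structure(list(anchor = c(0, 0, 0), direction = c(0, 0, 1),
                         ill_defined = FALSE), class = "ft_axis")
  # identical azimuth: radial and tangential vectors are perpendicular
  expect_equal(pair_twist(c(1, 0, 0), c(1, 0, 0), axis), 0, tolerance = 1e-12)
  # g parallel to the successor's tangential direction
  expect_equal(pair_twist(c(0, -1, 0), c(1, 0, 0), axis), 1, tolerance = 1e-12)
  # helix step: h = sin(phi_next - phi)
  for (dphi in c(-0.3, -0.1, 0.05, 0.25)) {
    g <- c(cos(0.4), sin(0.4), 0)
    rnext <- c(cos(0.4 + dphi), sin(0.4 + dphi), 0)
    expect_equal(pair_twist(g, rnext, axis), sin(dphi), tolerance = 1e-12)
  }
  expect_error(pair_twist(c(0, 0, 1), c(0, 0, 1), axis), "undefined twist")
  expect_error(pair_twist(c(0, 0, 0), c(1, 0, 0), axis), "undefined twist")
})

test_that("cluster helicity averages pair twists per ribbon and ribbons per cluster", {
  axis <- structure(list(anchor = c(0, 0, 0), direction = c(0, 0, 1),
                         ill_defined = FALSE), class = "ft_axis")
  # two single-ribbon helices with different twists -> H is the mean of the two
  mk_ribbon <- function(dphi, ribbon, offset) {
    k <- 0:4
    phi <- -k * dphi
    tibble::tibble(
      peptide = offset + k, projection = k * 0.5,
      rx = cos(phi), ry = sin(phi), rz = 0, ribbon = ribbon,
      d_par_prev = NA_real_, d_perp_prev = NA_real_
    )
  }
  dec <- dplyr::bind_rows(mk_ribbon(0.1, 1L, 1L), mk_ribbon(0.3, 2L, 10L))
  res <- cluster_helicity(dec, axis)
  expect_equal(res$ribbons$h_rib, c(-sin(0.1), -sin(0.3)), tolerance = 1e-12)
  expect_equal(res$h, mean(-sin(c(0.1, 0.3))), tolerance = 1e-12)
  expect_equal(res$n_rib, 2)
  expect_true(all(abs(res$pairs$h) <= 1))

  # singleton ribbons are excluded from the average
  dec2 <- dplyr::bind_rows(dec, tibble::tibble(
    peptide = 99L, projection = 99, rx = 1, ry = 0, rz = 0, ribbon = 3L,
    d_par_prev = NA_real_, d_perp_prev = NA_real_
  ))
  expect_equal(cluster_helicity(dec2, axis)$n_rib, 2)

  only_singletons <- dec2[c(1, 6, 11), ]
  expect_error(cluster_helicity(only_singletons, axis), "undefined helicity")

  # reversing the axis orientation flips every pair twist (Eq.-level antisymmetry)
  flipped <- axis
  flipped$direction <- -axis$direction
  expect_equal(cluster_helicity(dec, flipped)$h, -res$h, tolerance = 1e-12)
})

test_that("the full pipeline reproduces the closed-form fibril helicity", {
  for (tw in c(0, 5, -15)) {
    fib <- build_helical_fibril(3, 8, twist_deg = tw, radius = 1.2)
    gt <- fibril_ground_truth(fib)
    res <- fibril_helicity(fib, ribbons = gt$ribbons)
    expect_equal(res$h, -sin(tw * pi / 180), tolerance = 1e-9)
    expect_equal(abs(res$axis$direction[3]), 1, tolerance = 1e-9)
  }
  # glance/tidy expose the result as tibbles
  fib <- build_helical_fibril(3, 8, twist_deg = 8, radius = 1.2)
  res <- fibril_helicity(fib, ribbons = fibril_ground_truth(fib)$ribbons)
  expect_equal(glance(res)$h, res$h)
  expect_equal(nrow(tidy(res)), 3)
})

test_that("automatic ribbon assignment handles a single-ribbon helix", {
  fib <- build_helical_fibril(1, 10, rise = 0.45, twist_deg = 8, radius = 0.5)
  res <- fibril_helicity(fib, dm2 = 0.6)
  expect_equal(res$n_rib, 1)
  # finite single helix: fitted axis is slightly tilted, H close to closed form
  expect_lt(abs(res$h - (-sin(8 * pi / 180))), 0.02)
})

test_that("helicity is invariant under rotation/translation and flips under mirroring", {
  fib <- build_helical_fibril(3, 8, twist_deg = 8, radius = 1.2)
  gt <- fibril_ground_truth(fib)
  h0 <- fibril_helicity(fib, ribbons = gt$ribbons)$h

  set.seed(5)
  moved <- rigid_transform(fib, random_rotation_oracle(), c(1.2, -0.8, 2.0))
  h1 <- fibril_helicity(moved, ribbons = gt$ribbons)$h
  expect_equal(h1, h0, tolerance = 1e-10)

  mir <- build_helical_fibril(3, 8, twist_deg = 8, radius = 1.2, mirror = TRUE)
  h2 <- fibril_helicity(mir, ribbons = fibril_ground_truth(mir)$ribbons)$h
  expect_equal(h2, -h0, tolerance = 1e-10)
})

test_that("isotropic coordinate noise shrinks the expected helicity magnitude", {
  h_at_noise <- function(eps) {
    mean(vapply(1:20, function(s) {
      fib <- build_helical_fibril(3, 8, twist_deg = 12, radius = 1.2,
                                  noise = eps, seed = s, box_l = 80)
      abs(fibril_helicity(fib, ribbons = fibril_ground_truth(fib)$ribbons)$h)
    }, numeric(1)))
  }
  h0 <- h_at_noise(0)
  h1 <- h_at_noise(1)
  h2 <- h_at_noise(3)
  expect_gt(h0, h1)
  expect_gt(h1, h2)
})

test_that("helicity_trajectory follows the tracked largest cluster", {
  fib <- build_helical_fibril(1, 10, rise = 0.45, twist_deg = 8, radius = 0.5)
  f2 <- fib
  f2$frame <- 2L
  f2$time <- 1
  traj <- dplyr::bind_rows(fib, f2)
  res <- helicity_trajectory(traj, cutoff = 0.5, dm2 = 0.6)
  expect_equal(nrow(res), 2)
  expect_equal(res$m, c(10, 10))
  expect_true(all(abs(res$h - (-sin(8 * pi / 180))) < 0.02))
})
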