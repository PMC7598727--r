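make_decay_curves <- function(n0 = 72, k = 0.01, t = seq(0, 600, by = 2)) {
  tibble::tibble(
    time = t,
    n_monomers = n0 * exp(-k * t),
    n_clusters = n0 * k * t * exp(-k * t / 2), # unimodal, peak at 2/k
    largest = round(n0 * (1 - exp(-k * t))),
    n0 = n0
  )
}

test_that("half-time interpolates the first crossing of Nm = N0/2", {
  cv <- make_decay_curves(k = 0.01)
  expect_lt(abs(half_time(cv) - log(2) / 0.01), 2) # within one frame interval
  # a frame holding exactly N0/2 returns its own time
  exact <- tibble::tibble(time = c(0, 5, 9), n_monomers = c(10, 5, 1), n0 = 10)
  expect_equal(half_time(exact), 5)
  increasing <- tibble::tibble(time = 0:3, n_monomers = c(4, 5, 6, 7), n0 = 4)
  expect_error(half_time(increasing), "no half-time")
})

test_that("cluster peak time smooths noise and breaks ties early", {
  cv <- make_decay_curves(k = 0.01)
  expect_equal(cluster_peak_time(cv, 1), 200) # exact unimodal peak at 2/k
  flat <- tibble::tibble(time = 0:9, n_clusters = rep(3, 10))
  expect_equal(cluster_peak_time(flat), 0) # tie -> earliest
  set.seed(8)
  t <- seq(0, 400, by = 2)
  noisy <- tibble::tibble(time = t,
                          n_clusters = 50 * exp(-((t - 200) / 20)^2) +
                            rnorm(length(t)))
  expect_lt(abs(cluster_peak_time(noisy, 5) - 200), 5 * 2 + 1e-9) # within one window
})

test_that("scaled curves collapse exactly for time-rescaled kinetics", {
  a <- make_decay_curves(k = 0.01)
  b <- make_decay_curves(k = 0.04, t = seq(0, 600, by = 2) / 4)
  sa <- scale_curves(a)
  sb <- scale_curves(b)
  expect_lt(collapse_gap(sa, sb, "monomer"), 1e-9)
  expect_lt(collapse_gap(sa, sb, "cluster"), 1e-9)
  # unrelated curves do not collapse
  c_ <- a
  c_$n_monomers <- a$n0 / (1 + 0.05 * a$time)
  expect_gt(collapse_gap(sa, scale_curves(c_), "monomer"), 0.01)
})

test_that("descriptor-vs-size pooling matches a two-pass oracle", {
  set.seed(10)
  obs <- tibble::tibble(
    m = sample(2:6, 60, replace = TRUE),
    rg = rnorm(60, mean = 1, sd = 0.2)
  )
  tab <- descriptor_vs_size(obs, rg)
  for (mm in unique(obs$m)) {
    v <- obs$rg[obs$m == mm]
    expect_equal(tab$mean[tab$m == mm], sum(v) / length(v), tolerance = 1e-12)
    expect_equal(tab$se[tab$m == mm],
                 sqrt(sum((v - mean(v))^2) / (length(v) - 1)) / sqrt(length(v)),
                 tolerance = 1e-12)
  }
  single <- descriptor_vs_size(tibble::tibble(m = 2, rg = 1.5), rg)
  expect_equal(single$mean, 1.5)
  expect_true(is.na(single$se))
  const <- descriptor_vs_size(tibble::tibble(m = rep(3, 4), rg = 2), rg)
  expect_equal(const$sd, 0)
})

test_that("power-law fits recover exact exponents to machine precision", {
  m <- 3:24
  expect_equal(fit_power_small(tibble::tibble(m = m, rg = 2 * m^(1 / 3)))$exponent,
               1 / 3, tolerance = 1e-12)
  expect_equal(fit_power_small(tibble::tibble(m = m, rg = 1.1 * m^0.30))$exponent,
               0.30, tolerance = 1e-12)
  mm <- 26:60
  expect_equal(fit_power_shifted(
    tibble::tibble(m = mm, rg = 1.332 + 0.2 * (mm - 25)^1))$exponent,
    1, tolerance = 1e-12)
  expect_equal(fit_power_shifted(
    tibble::tibble(m = mm, rg = 1.332 + 0.2 * (mm - 25)^0.88))$exponent,
    0.88, tolerance = 1e-12)
  expect_error(fit_power_small(tibble::tibble(m = 2:10, rg = -1 * 2:10)), "domain")
  expect_error(fit_power_shifted(tibble::tibble(m = 26:40, rg = 0.5)), "domain")
  expect_error(fit_power_small(tibble::tibble(m = c(3, 4), rg = c(1, 2))), "at least 3")
})

test_that("fit summaries expose tidy/glance tables", {
  fit <- fit_power_small(tibble::tibble(m = 3:24, rg = 2 * (3:24)^0.3))
  td <- tidy(fit)
  expect_equal(td$term, c("intercept", "exponent"))
  gl <- glance(fit)
  expect_equal(gl$exponent, 0.3, tolerance = 1e-10)
  expect_equal(gl$variant, "small")
})

test_that("noisy power-law data recover the exponent without bias", {
  recover <- function(fitter, truth, gen) {
    est <- vapply(1:50, function(s) {
      set.seed(s)
      fitter(gen())$exponent
    }, numeric(1))
    abs(mean(est) - truth)
  }
  m <- round(seq(3, 24, length.out = 20))
  expect_lt(recover(fit_power_small, 0.30, function() {
    tibble::tibble(m = m, rg = 1.2 * m^0.30 * exp(rnorm(length(m), sd = 0.05)))
  }), 0.02)
  mm <- round(seq(27, 70, length.out = 20))
  expect_lt(recover(function(d) fit_power_shifted(d), 0.88, function() {
    tibble::tibble(m = mm, rg = 1.332 + 0.25 * (mm - 25)^0.88 *
                     exp(rnorm(length(mm), sd = 0.05)))
  }), 0.02)
})

test_that("box size and concentration convert consistently with the printed grid", {
  expect_equal(round(concentration_from_box(20, 13.05)), 15)
  expect_equal(concentration_from_box(20, 13.05), 14.94, tolerance = 1e-3)
  # doubling the edge divides the concentration by 8
  expect_equal(concentration_from_box(20, 2 * 13.05),
               concentration_from_box(20, 13.05) / 8, tolerance = 1e-12)
  grid <- tibble::tibble(
    c0 = c(4, 8, 15, 35),
    l20 = c(19.57, 16.31, 13.05, 9.79),
    l72 = c(30.00, 25.00, 20.00, 15.00)
  )
  expect_equal(round(concentration_from_box(20, grid$l20)), grid$c0)
  expect_equal(round(concentration_from_box(72, grid$l72)), grid$c0)

  expect_equal(box_for_concentration(72, 14.94), 20.00, tolerance = 1e-3)
  expect_equal(box_for_concentration(20, 35.4), 9.79, tolerance = 1e-2)
  for (c0 in c(0.5, 4, 35)) {
    expect_equal(concentration_from_box(72, box_for_concentration(72, c0)), c0,
                 tolerance = 1e-12)
  }
})

test_that("equilibrium concentration is the converted tail-mean monomer count", {
  cv <- tibble::tibble(
    time = 0:9,
    n_monomers = c(10, 6, 3, 1, 0, 0, 0, 0, 0, 0),
    largest = c(0, 3, 5, 7, 8, 8, 8, 8, 8, 8)
  )
  expect_equal(equilibrium_concentration(cv, 20), 0)
  cv$n_monomers[5:10] <- 1
  expect_equal(equilibrium_concentration(cv, 20), 0.2076, tolerance = 1e-3)
  cv$n_monomers[5:10] <- c(0, 2, 0, 2, 0, 2)
  expect_equal(equilibrium_concentration(cv, 20),
               concentration_from_box(1, 20), tolerance = 1e-12)
  expect_error(equilibrium_concentration(cv[0, ], 20, tail_start = 0), "empty")
})

test_that("unit conversions reproduce the standard physical bookkeeping", {
  e300 <- thermal_energy(300)
  expect_equal(round(e300 / 1e-21, 1), 4.1) # kB * 300 K, printed precision
  expect_equal(round(convert_units(e300, "J", "kcal/mol"), 1), 0.6)
  expect_equal(convert_units(e300, "J", "kcal/mol"), 0.5962, tolerance = 1e-3)
  expect_equal(convert_units(13.32, "angstrom", "nm"), 1.332)
  expect_equal(convert_units(1.332, "nm", "angstrom"), 13.32)
  expect_equal(convert_units(100, "tau", "ps", tau_ps = 0.16), 16)
  expect_error(convert_units(1, "tau", "ps"), "tau_ps")
  expect_error(convert_units(1, "nm", "kcal/mol"), "unsupported")
})
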