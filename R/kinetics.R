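#' Half-time of the monomer decay
#'
#' First time at which the number of free monomers drops to half its
#' initial value, linearly interpolated between the bracketing frames
#' (exact crossing frames return their own time).
#'
#' @param curves A kinetic-counts tibble with columns `time` and
#'   `n_monomers` (see [kinetic_counts()]).
#' @param n0 Initial peptide count; defaults to the `n0` column if
#'   present, else the first frame's monomer count.
#' @return The half-time, in the time unit of `curves`.
#' @export
half_time <- function(curves, n0 = NULL) {
  stopifnot(all(c("time", "n_monomers") %in% names(curves)))
  if (is.null(n0)) n0 <- if ("n0" %in% names(curves)) curves$n0[1] else curves$n_monomers[1]
  half <- n0 / 2
  nm <- curves$n_monomers
  idx <- which(nm <= half)
  if (length(idx) == 0) {
    stop("no half-time: the monomer count never drops to ", half, call. = FALSE)
  }
  i <- idx[1]
  if (nm[i] == half || i == 1) return(curves$time[i])
  t0 <- curves$time[i - 1]; t1 <- curves$time[i]
  y0 <- nm[i - 1]; y1 <- nm[i]
  t0 + (y0 - half) / (y0 - y1) * (t1 - t0)
}

#' Time of the cluster-count maximum
#'
#' Time at which the number of clusters peaks, after centered
#' moving-average smoothing (the raw peak is noisy when aggregation is
#' fast). Ties resolve to the earliest time.
#'
#' @param curves A kinetic-counts tibble with columns `time`,
#'   `n_clusters`.
#' @param smooth_window Odd window length in frames (default 5); 1
#'   disables smoothing. Edges use the partial window.
#' @return The peak time.
#' @export
cluster_peak_time <- function(curves, smooth_window = 5) {
  stopifnot(all(c("time", "n_clusters") %in% names(curves)))
  if (nrow(curves) < 3) stop("need at least 3 frames", call. = FALSE)
  sm <- moving_average(curves$n_clusters, smooth_window)
  curves$time[which.max(sm)]
}

moving_average <- function(x, window) {
  if (window <= 1) return(x)
  half <- floor(window / 2)
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Scale kinetic curves onto master coordinates
#'
#' Divides the monomer and cluster counts by the initial peptide number
#' and rescales time by the half-time (monomers) or the cluster-peak
#' time (clusters), the reduction under which curves from different
#' system sizes and concentrations collapse when the aggregation
#' mechanism is unchanged.
#'
#' @param curves A kinetic-counts tibble (see [kinetic_counts()]).
#' @param t_half,t_max Optional precomputed scales; computed from
#'   `curves` when `NULL`.
#' @param n0 Initial peptide count (default: `n0` column).
#' @return A long tibble: `series` (`"monomer"`/`"cluster"`), `time`,
#'   `t_scaled`, `value`.
#' @export
scale_curves <- function(curves, t_half = NULL, t_max = NULL, n0 = NULL) {
  if (is.null(n0)) n0 <- if ("n0" %in% names(curves)) curves$n0[1] else curves$n_monomers[1]
  if (is.null(t_half)) t_half <- half_time(curves, n0)
  if (is.null(t_max)) t_max <- cluster_peak_time(curves)
  dplyr::bind_rows(
    tibble::tibble(series = "monomer", time = curves$time,
                   t_scaled = curves$time / t_half,
                   value = curves$n_monomers / n0),
    tibble::tibble(series = "cluster", time = curves$time,
                   t_scaled = curves$time / t_max,
                   value = curves$n_clusters / n0)
  )
}

#' Collapse quality of two scaled curves
#'
#' Maximum vertical gap between two scaled series, evaluated on a common
#' logarithmic time grid over their overlapping positive-time range.
#'
#' @param scaled_a,scaled_b Outputs of [scale_curves()].
#' @param series Which series to compare (`"monomer"` or `"cluster"`).
#' @param n_grid Number of grid points.
#' @return The maximum absolute vertical gap.
#' @export
collapse_gap <- function(scaled_a, scaled_b, series = "monomer", n_grid = 200) {
  a <- dplyr::filter(scaled_a, .data$series == !!series, .data$t_scaled > 0)
  b <- dplyr::filter(scaled_b, .data$series == !!series, .data$t_scaled > 0)
  lo <- max(min(a$t_scaled), min(b$t_scaled))
  hi <- min(max(a$t_scaled), max(b$t_scaled))
  if (hi <= lo) stop("scaled curves do not overlap in time", call. = FALSE)
  grid <- exp(seq(log(lo), log(hi), length.out = n_grid))
  ya <- stats::approx(a$t_scaled, a$value, xout = grid, ties = "ordered", rule = 2)$y
  yb <- stats::approx(b$t_scaled, b$value, xout = grid, ties = "ordered", rule = 2)$y
  max(abs(ya - yb))
}

#' Mean and spread of a descriptor per cluster size
#'
#' Pools cluster observations over frames and runs and reports, per
#' cluster size M, the mean, standard deviation and standard error of
#' the chosen descriptor column.
#'
#' @param obs A tibble of per-cluster observations with a size column
#'   `m` and a descriptor column.
#' @param value Tidy-selected descriptor column (bare name).
#' @return A tibble with columns `m`, `n_obs`, `mean`, `sd`, `se`
#'   (`NA` where a size has a single observation).
#' @export
descriptor_vs_size <- function(obs, value) {
  value <- rlang::enquo(value)
  stopifnot("m" %in% names(obs))
  dplyr::arrange(
    dplyr::summarise(
      dplyr::group_by(obs, .data$m),
      n_obs = dplyr::n(),
      mean = mean(!!value),
      sd = stats::sd(!!value),
      se = stats::sd(!!value) / sqrt(dplyr::n()),
      .groups = "drop"
    ),
    .data$m
  )
}

new_power_fit <- function(fit, variant, domain, m_star = NA_real_, rg_star = NA_real_) {
  # exact synthetic data yields a perfect fit; summary()'s warning about
  # it is expected there and carries no information
  co <- suppressWarnings(summary(fit))$coefficients
  structure(
    list(
      fit = fit,
      exponent = unname(co[2, 1]),
      exponent_se = unname(co[2, 2]),
      intercept = unname(co[1, 1]),
      variant = variant,
      domain = domain,
      m_star = m_star,
      rg_star = rg_star
    ),
    class = "ft_power_fit"
  )
}

#' Power-law fit of cluster compactness below the critical size
#'
#' Small amorphous aggregates grow as \eqn{\bar R_g \propto M^\alpha};
#' the exponent alpha is the slope of an unweighted least-squares line
#' through \eqn{(\ln M, \ln \bar R_g)} for sizes below `m_max`. An
#' exponent of 1/3 corresponds to constant-density three-dimensional
#' growth; smaller values indicate densification with growth.
#'
#' @param table A tibble with columns `m` (cluster size) and `rg`
#'   (mean radius of gyration, nm).
#' @param m_max Upper end of the fit domain (exclusive); sizes at or
#'   above it are ignored. Default 25, the critical size separating
#'   amorphous from fibril-like morphology.
#' @return An `ft_power_fit` object; see also [tidy()] and [glance()].
#' @export
fit_power_small <- function(table, m_max = 25) {
  stopifnot(all(c("m", "rg") %in% names(table)))
  d <- dplyr::filter(table, .data$m < m_max)
  if (nrow(d) < 3) stop("need at least 3 sizes below m_max", call. = FALSE)
  if (any(d$m <= 0) || any(d$rg <= 0)) {
    stop("domain error: sizes and radii must be positive for the log-log fit",
         call. = FALSE)
  }
  fit <- stats::lm(log(rg) ~ log(m), data = d)
  new_power_fit(fit, "small", range(d$m))
}

#' Shifted power-law fit of fibril elongation above the critical size
#'
#' Above the critical size the radius of gyration grows as
#' \eqn{\bar R_g - R_g^\star \propto (M - M^\star)^\beta}, the
#' pseudo-one-dimensional elongation law of fibril-like clusters
#' (beta = 1 for constant-density end growth). The exponent is the
#' slope of an unweighted least-squares line through
#' \eqn{(\ln(M - M^\star), \ln(\bar R_g - R_g^\star))}.
#'
#' @inheritParams fit_power_small
#' @param m_star Critical size (default 25).
#' @param rg_star Radius of gyration at the critical size, nm
#'   (default 1.332 nm = 13.32 Angstroms).
#' @return An `ft_power_fit` object.
#' @export
fit_power_shifted <- function(table, m_star = 25, rg_star = 1.332) {
  stopifnot(all(c("m", "rg") %in% names(table)))
  d <- dplyr::filter(table, .data$m > m_star)
  if (nrow(d) < 3) stop("need at least 3 sizes above m_star", call. = FALSE)
  if (any(d$rg <= rg_star)) {
    stop("domain error: all radii in the fit domain must exceed rg_star",
         call. = FALSE)
  }
  d <- dplyr::mutate(d, mm = .data$m - m_star, rr = .data$rg - rg_star)
  fit <- stats::lm(log(rr) ~ log(mm), data = d)
  new_power_fit(fit, "shifted", range(d$m), m_star, rg_star)
}

#' @export
print.ft_power_fit <- function(x, ...) {
  cat("<ft_power_fit> variant:", x$variant,
      " exponent:", format(x$exponent, digits = 4),
      "+/-", format(x$exponent_se, digits = 3),
      " domain M in [", x$domain[1], ",", x$domain[2], "]\n")
  invisible(x)
}

#' @method tidy ft_power_fit
#' @export
tidy.ft_power_fit <- function(x, ...) {
  co <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(
    term = c("intercept", "exponent"),
    estimate = co[, 1],
    std.error = co[, 2],
    statistic = co[, 3],
    p.value = co[, 4]
  )
}

#' @method glance ft_power_fit
#' @export
glance.ft_power_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))
  tibble::tibble(
    variant = x$variant,
    exponent = x$exponent,
    exponent_se = x$exponent_se,
    r.squared = s$r.squared,
    m_min = x$domain[1],
    m_max = x$domain[2],
    m_star = x$m_star,
    rg_star = x$rg_star,
    n_obs = length(s$residuals)
  )
}

avogadro <- 6.02214076e23
boltzmann <- 1.380649e-23 # J/K

#' Peptide concentration of a periodic cubic box
#'
#' @param n0 Number of peptides.
#' @param l Box edge length in nm.
#' @return Concentration in mM.
#' @examples
#' concentration_from_box(20, 13.05) # ~14.94 mM
#' @export
concentration_from_box <- function(n0, l) {
  stopifnot(n0 >= 0, l > 0)
  mol <- n0 / avogadro
  vol_litre <- l^3 * 1e-24
  1000 * mol / vol_litre
}

#' Box edge length realizing a target concentration
#'
#' Inverse of [concentration_from_box()].
#'
#' @param n0 Number of peptides.
#' @param c0 Target concentration in mM.
#' @return Cubic box edge length in nm.
#' @export
box_for_concentration <- function(n0, c0) {
  stopifnot(n0 >= 1, c0 > 0)
  mol <- n0 / avogadro
  vol_litre <- 1000 * mol / c0
  (vol_litre / 1e-24)^(1 / 3)
}

#' Equilibrium monomer concentration from the trajectory tail
#'
#' After the largest aggregate reaches its final size, the remaining
#' monomer count fluctuates about its equilibrium value; its tail mean
#' converted to a concentration estimates the equilibrium monomer
#' concentration (nominally zero for effectively irreversible
#' aggregation).
#'
#' @param curves A kinetic-counts tibble with columns `time`,
#'   `n_monomers` and `largest`.
#' @param l Box edge length in nm.
#' @param tail_start Optional explicit start time of the tail; default
#'   is the first frame at which `largest` attains its final value.
#' @return Equilibrium monomer concentration in mM.
#' @export
equilibrium_concentration <- function(curves, l, tail_start = NULL) {
  stopifnot(all(c("time", "n_monomers") %in% names(curves)))
  if (is.null(tail_start)) {
    stopifnot("largest" %in% names(curves))
    final <- curves$largest[nrow(curves)]
    tail_start <- curves$time[which(curves$largest == final)[1]]
  }
  tail <- dplyr::filter(curves, .data$time >= tail_start)
  if (nrow(tail) == 0) stop("empty trajectory tail", call. = FALSE)
  concentration_from_box(mean(tail$n_monomers), l)
}

#' Physical unit conversions used in coarse-grained bookkeeping
#'
#' Supported pairs: joules per particle and kcal/mol (via the Avogadro
#' constant), Angstroms and nm, and counts of the intrinsic time unit
#' tau and picoseconds (given a value for tau). The thermal energy
#' kB * T is available through `thermal_energy()`.
#'
#' @param value Numeric value(s) to convert.
#' @param from,to Unit names: `"J"`, `"kcal/mol"`, `"angstrom"`, `"nm"`,
#'   `"tau"`, `"ps"`.
#' @param tau_ps Value of tau in picoseconds (required for tau <-> ps).
#' @return Converted value(s).
#' @export
convert_units <- function(value, from, to, tau_ps = NULL) {
  key <- paste(from, to, sep = "->")
  switch(key,
    "J->kcal/mol" = value * avogadro / 4184,
    "kcal/mol->J" = value * 4184 / avogadro,
    "angstrom->nm" = value * 0.1,
    "nm->angstrom" = value * 10,
    "tau->ps" = {
      if (is.null(tau_ps)) stop("tau <-> ps conversion needs `tau_ps`", call. = FALSE)
      value * tau_ps
    },
    "ps->tau" = {
      if (is.null(tau_ps)) stop("tau <-> ps conversion needs `tau_ps`", call. = FALSE)
      value / tau_ps
    },
    stop("unsupported unit pair: ", from, " -> ", to, call. = FALSE)
  )
}

#' @rdname convert_units
#' @param temperature Temperature in kelvin.
#' @export
thermal_energy <- function(temperature = 300) {
  boltzmann * temperature
}
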