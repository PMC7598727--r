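#' Fit the axis of an elongated cluster
#'
#' The cluster axis is the first principal direction of the point cloud
#' (orthogonal regression through the centroid). Coordinate-wise linear
#' regression would depend on an arbitrary choice of independent axis,
#' so total least squares is used. The orientation of the unit direction
#' is fixed deterministically: the axis points from the first-listed
#' point toward the last (their projections ordered accordingly); if
#' those projections tie, the first nonzero component of the direction
#' is made positive. When the top two principal values are within 1% of
#' each other the cloud has no well-defined elongation axis and the
#' result carries an `ill_defined` flag (with a warning).
#'
#' @param points An n x 3 matrix or data frame with columns `x`, `y`,
#'   `z`: one representative point per peptide (whole-peptide mass
#'   centers, or side-chain-only centers for better stability).
#' @return An object of class `ft_axis`: list with `anchor` (centroid),
#'   `direction` (unit 3-vector), `ill_defined` (logical).
#' @export
fit_cluster_axis <- function(points) {
  m <- points_matrix(points)
  if (nrow(m) < 2) stop("need at least 2 points to fit an axis", call. = FALSE)
  centered <- sweep(m, 2, colMeans(m))
  if (max(abs(centered)) < 1e-12) {
    stop("degenerate geometry: all points identical", call. = FALSE)
  }
  s <- crossprod(centered) / nrow(m)
  es <- eigen(s, symmetric = TRUE)
  v <- es$vectors[, 1]
  ill <- FALSE
  if (nrow(m) >= 3 && es$values[1] > 0 &&
      (es$values[1] - es$values[2]) / es$values[1] < 0.01) {
    ill <- TRUE
    warning("ill-defined axis: top two principal values within 1% of each other",
            call. = FALSE)
  }
  proj <- centered %*% v
  if (proj[nrow(m)] < proj[1]) {
    v <- -v
  } else if (proj[nrow(m)] == proj[1]) {
    nz <- which(abs(v) > 1e-12)[1]
    if (v[nz] < 0) v <- -v
  }
  structure(
    list(anchor = colMeans(m), direction = as.numeric(v), ill_defined = ill),
    class = "ft_axis"
  )
}

#' @export
print.ft_axis <- function(x, ...) {
  cat("<ft_axis> direction (", paste(sprintf("%.4f", x$direction), collapse = ", "),
      ") through (", paste(sprintf("%.3f", x$anchor), collapse = ", "), ")",
      if (x$ill_defined) " [ill-defined]", "\n", sep = "")
  invisible(x)
}

#' Size-dependent reference spacing of a fibrillar cluster
#'
#' The position of the second maximum of the mass-center distance
#' histogram tracks the internal packing of fibrillar clusters and
#' varies linearly with the inverse cluster size:
#' \eqn{d_{m2}(M) = a/M + b}. The default constants (a = 9.6192 nm,
#' b = -0.0009 nm) were fitted for a 72-peptide GNNQQNY system and can
#' be replaced, e.g. by an empirical [second_maximum()].
#'
#' @param m Cluster size(s) M (>= 2).
#' @param a_fit,b_fit Fit constants in nm.
#' @return Reference spacing(s) in nm.
#' @export
reference_spacing <- function(m, a_fit = 9.6192, b_fit = -0.0009) {
  if (any(m < 2)) stop("reference spacing is defined for M >= 2", call. = FALSE)
  dm2 <- a_fit / m + b_fit
  if (any(dm2 <= 0)) {
    stop("invalid spacing: a_fit/M + b_fit is non-positive for M = ",
         paste(m[dm2 <= 0], collapse = ", "), call. = FALSE)
  }
  dm2
}

#' Longitudinal and perpendicular ribbon cutoffs
#'
#' Scales the reference spacing into the two ribbon-assignment cutoffs:
#' `d_par0 = s_par * dm2` along the cluster axis and
#' `d_perp0 = s_perp * dm2` in the perpendicular plane. The default
#' scaling factors (0.88 and 0.47) separate the longitudinal and
#' perpendicular contributions of the nearest in-ribbon neighbor.
#'
#' @param dm2 Reference spacing in nm (> 0); see [reference_spacing()].
#' @param s_par,s_perp Positive scaling factors.
#' @return A list with elements `d_par0` and `d_perp0` (nm).
#' @export
ribbon_cutoffs <- function(dm2, s_par = 0.88, s_perp = 0.47) {
  if (any(dm2 <= 0)) stop("dm2 must be positive", call. = FALSE)
  if (s_par <= 0 || s_perp <= 0) {
    stop("configuration error: scaling factors must be positive", call. = FALSE)
  }
  list(d_par0 = s_par * dm2, d_perp0 = s_perp * dm2)
}

# Projections and radial vectors of centers relative to an axis.
axis_frame <- function(centers, axis) {
  m <- points_matrix(centers)
  rel <- sweep(m, 2, axis$anchor)
  proj <- as.numeric(rel %*% axis$direction)
  radial <- rel - outer(proj, axis$direction)
  list(proj = proj, radial = radial)
}

#' Assign cluster peptides to ribbons
#'
#' Peptide mass centers are projected onto the cluster axis and sorted
#' by projection. Each consecutive sorted pair is tested against the two
#' cutoffs: `d_par` is the projection gap along the axis and `d_perp`
#' the distance between the two centers' projections onto the plane
#' perpendicular to the axis. A pair within both cutoffs extends the
#' current ribbon; otherwise a new ribbon starts. Singleton ribbons are
#' permitted (they are skipped later when helicities are averaged).
#'
#' @param centers Per-peptide mass centers: a tibble with columns
#'   `peptide`, `x`, `y`, `z` (from [peptide_mass_centers()]).
#' @param axis An `ft_axis` from [fit_cluster_axis()].
#' @param cutoffs A list with `d_par0`, `d_perp0` from [ribbon_cutoffs()].
#' @return A tibble of class-ordinary rows sorted by projection:
#'   `peptide`, `projection`, `rx`, `ry`, `rz` (radial vector), `ribbon`,
#'   `d_par_prev`, `d_perp_prev` (`NA` for each ribbon opener).
#' @export
assign_ribbons <- function(centers, axis, cutoffs) {
  stopifnot(inherits(axis, "ft_axis"))
  af <- axis_frame(centers, axis)
  ord <- order(af$proj, centers$peptide)
  proj <- af$proj[ord]
  radial <- af$radial[ord, , drop = FALSE]
  n <- length(proj)
  d_par <- c(NA_real_, diff(proj))
  d_perp <- c(NA_real_, row_norms(radial[-1, , drop = FALSE] - radial[-n, , drop = FALSE]))
  same <- !is.na(d_par) & d_par <= cutoffs$d_par0 & d_perp <= cutoffs$d_perp0
  ribbon <- cumsum(!same)
  out <- tibble::tibble(
    peptide = centers$peptide[ord],
    projection = proj,
    rx = radial[, 1], ry = radial[, 2], rz = radial[, 3],
    ribbon = as.integer(ribbon),
    d_par_prev = ifelse(same, d_par, NA_real_),
    d_perp_prev = ifelse(same, d_perp, NA_real_)
  )
  out
}

#' Twist contribution of one consecutive peptide pair
#'
#' For a pair (i, i+1) along a ribbon, the twist is
#' \eqn{h_{i,i+1} = \hat g_i \cdot \hat e_{i+1}}, where \eqn{\hat g_i}
#' is peptide i's unit radial vector from the cluster axis and
#' \eqn{\hat e_{i+1}} the unit tangential vector of peptide i+1,
#' \eqn{\hat e_{i+1} = (r_{i+1} \times \hat A)/|r_{i+1} \times \hat A|}
#' with \eqn{r_{i+1}} the radial vector. Using the radial vector (rather
#' than the absolute position) in the cross product makes the twist
#' independent of the coordinate origin. h is 0 for an untwisted stack
#' (consecutive peptides at the same azimuth), and its sign encodes the
#' handedness of the twist with respect to the axis orientation.
#'
#' @param g_i Radial vector of peptide i (length-3; need not be unit).
#' @param radial_next Radial vector of peptide i+1.
#' @param axis An `ft_axis`.
#' @return Twist h in \[-1, 1\].
#' @export
pair_twist <- function(g_i, radial_next, axis) {
  stopifnot(inherits(axis, "ft_axis"))
  ng <- vec_norm(g_i)
  if (ng < 1e-12) stop("undefined twist: zero radial vector", call. = FALSE)
  e <- cross3(radial_next, axis$direction)
  ne <- vec_norm(e)
  if (ne < 1e-12) {
    stop("undefined twist: radial vector parallel to axis or zero", call. = FALSE)
  }
  sum((g_i / ng) * (e / ne))
}

#' Ribbon and cluster helicity
#'
#' The helicity of a ribbon is the mean pair twist over its consecutive
#' peptide pairs, \eqn{H_{rib} = \frac{1}{M_{rib}-1}\sum h_{i,i+1}}, and
#' the cluster helicity H is the mean of \eqn{H_{rib}} over all ribbons
#' with at least two peptides (singleton ribbons contribute no pair and
#' are excluded). Pairs whose twist is undefined (radial vector
#' vanishing or parallel to the axis) are skipped and counted.
#'
#' @param decomp A ribbon decomposition from [assign_ribbons()] (or the
#'   same table with a `ribbon` column supplied from ground truth).
#' @param axis The `ft_axis` the decomposition was built with.
#' @return An object of class `ft_helicity`: list with `h` (cluster
#'   helicity), `n_rib` (ribbons contributing), `ribbons` (tibble:
#'   `ribbon`, `size`, `h_rib`), `pairs` (tibble of per-pair twists),
#'   `n_skipped` (undefined pairs).
#' @export
cluster_helicity <- function(decomp, axis) {
  stopifnot(all(c("peptide", "projection", "rx", "ry", "rz", "ribbon") %in% names(decomp)))
  decomp <- dplyr::arrange(decomp, .data$ribbon, .data$projection, .data$peptide)
  pair_rows <- list()
  n_skipped <- 0L
  for (rb in split(decomp, decomp$ribbon)) {
    if (nrow(rb) < 2) next
    for (k in seq_len(nrow(rb) - 1)) {
      g <- c(rb$rx[k], rb$ry[k], rb$rz[k])
      rnext <- c(rb$rx[k + 1], rb$ry[k + 1], rb$rz[k + 1])
      h <- tryCatch(pair_twist(g, rnext, axis), error = function(e) NA_real_)
      if (is.na(h)) n_skipped <- n_skipped + 1L
      pair_rows[[length(pair_rows) + 1]] <- tibble::tibble(
        ribbon = rb$ribbon[1], i = rb$peptide[k], j = rb$peptide[k + 1], h = h
      )
    }
  }
  pairs <- if (length(pair_rows) > 0) dplyr::bind_rows(pair_rows) else {
    tibble::tibble(ribbon = integer(), i = integer(), j = integer(), h = numeric())
  }
  sizes <- dplyr::count(decomp, .data$ribbon, name = "size")
  ribbons <- dplyr::left_join(
    sizes,
    dplyr::summarise(dplyr::group_by(pairs, .data$ribbon),
                     h_rib = mean(.data$h, na.rm = TRUE), .groups = "drop"),
    by = "ribbon"
  )
  contributing <- ribbons[!is.na(ribbons$h_rib) & !is.nan(ribbons$h_rib), , drop = FALSE]
  if (nrow(contributing) == 0) {
    stop("undefined helicity: no ribbon with two or more peptides has a defined twist",
         call. = FALSE)
  }
  structure(
    list(
      h = mean(contributing$h_rib),
      n_rib = nrow(contributing),
      ribbons = ribbons,
      pairs = pairs,
      n_skipped = n_skipped
    ),
    class = "ft_helicity"
  )
}

#' @export
print.ft_helicity <- function(x, ...) {
  cat("<ft_helicity> H =", format(x$h, digits = 6),
      "over", x$n_rib, "ribbon(s)\n")
  invisible(x)
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' @method glance ft_helicity
#' @export
glance.ft_helicity <- function(x, ...) {
  tibble::tibble(
    h = x$h,
    n_rib = x$n_rib,
    n_pairs = nrow(x$pairs),
    n_skipped = x$n_skipped
  )
}

#' @method tidy ft_helicity
#' @export
tidy.ft_helicity <- function(x, ...) x$ribbons

#' Full helicity pipeline for one cluster
#'
#' Chains axis fitting, ribbon assignment and twist averaging for one
#' unwrapped cluster: the axis is fitted to the designated side-chain
#' mass centers by default (more stable for clusters with a compact
#' side-chain core), peptides are assigned to ribbons by the
#' size-dependent cutoffs, and the cluster helicity H is the mean ribbon
#' helicity. A known ribbon membership (e.g. from a synthetic
#' generator's ground truth) can be supplied to bypass the automatic
#' assignment, which cannot recover ribbons that interleave along the
#' axis.
#'
#' @param frame A single-frame trajectory tibble holding the unwrapped
#'   cluster (see [unwrap_cluster()]).
#' @param members Optional peptide indices forming the cluster.
#' @param axis_selection Point set for axis fitting: `"side_chain"`
#'   (designated residue's side-chain centers; default) or `"all_beads"`.
#' @param a_fit,b_fit Reference-spacing constants (nm); see
#'   [reference_spacing()].
#' @param s_par,s_perp Cutoff scaling factors; see [ribbon_cutoffs()].
#' @param dm2 Optional explicit reference spacing (nm), overriding the
#'   fit constants (e.g. an empirical [second_maximum()]).
#' @param ribbons Optional known ribbon membership: a data frame with
#'   columns `peptide` and `ribbon`.
#' @return An `ft_helicity` object (see [cluster_helicity()]) with the
#'   fitted `axis` and the ribbon `decomposition` attached.
#' @export
fibril_helicity <- function(frame, members = NULL,
                            axis_selection = c("side_chain", "all_beads"),
                            a_fit = 9.6192, b_fit = -0.0009,
                            s_par = 0.88, s_perp = 0.47,
                            dm2 = NULL, ribbons = NULL) {
  axis_selection <- match.arg(axis_selection)
  check_frame_tbl(frame, single_frame = TRUE)
  if (!is.null(members)) frame <- dplyr::filter(frame, .data$peptide %in% members)
  centers <- peptide_mass_centers(frame, "all_beads")
  axis_points <- if (axis_selection == "side_chain") {
    peptide_mass_centers(frame, "side_chain")
  } else {
    centers
  }
  axis <- fit_cluster_axis(axis_points)
  m <- nrow(centers)
  if (is.null(dm2)) dm2 <- reference_spacing(m, a_fit, b_fit)
  cutoffs <- ribbon_cutoffs(dm2, s_par, s_perp)
  decomp <- assign_ribbons(centers, axis, cutoffs)
  if (!is.null(ribbons)) {
    stopifnot(all(c("peptide", "ribbon") %in% names(ribbons)))
    decomp$ribbon <- ribbons$ribbon[match(decomp$peptide, ribbons$peptide)]
    if (anyNA(decomp$ribbon)) {
      stop("supplied ribbon membership does not cover all cluster peptides", call. = FALSE)
    }
  }
  res <- cluster_helicity(decomp, axis)
  res$axis <- axis
  res$decomposition <- decomp
  res$dm2 <- dm2
  res$cutoffs <- cutoffs
  res
}

#' Helicity of the tracked largest cluster along a trajectory
#'
#' @param traj A trajectory tibble.
#' @param cutoff Linkage cutoff in nm for cluster detection/unwrapping.
#' @param min_size Smallest cluster size to attempt (helicity of tiny
#'   clusters is noise; frames below this yield `NA`).
#' @param ... Passed on to [fibril_helicity()].
#' @return A tibble with one row per frame: `frame`, `time`, `m`,
#'   `n_rib`, `h`.
#' @export
helicity_trajectory <- function(traj, cutoff = 0.5, min_size = 4, ...) {
  tracked <- track_largest(traj, cutoff)
  frames <- split(traj, traj$frame)
  rows <- lapply(seq_len(nrow(tracked)), function(i) {
    mem <- tracked$members[[i]]
    base <- tibble::tibble(
      frame = tracked$frame[i], time = tracked$time[i],
      m = length(mem), n_rib = NA_integer_, h = NA_real_
    )
    if (length(mem) < min_size) return(base)
    res <- tryCatch(suppressWarnings({
      un <- unwrap_cluster(frames[[i]], mem, cutoff)
      fibril_helicity(un, ...)
    }), error = function(e) NULL)
    if (is.null(res)) return(base)
    base$n_rib <- res$n_rib
    base$h <- res$h
    base
  })
  dplyr::bind_rows(rows)
}
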