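#' Gyration-tensor shape descriptors
#'
#' Computes the gyration tensor of a point set (equal masses) about its
#' centroid and derives the radius of gyration and the asphericity. With
#' eigenvalues sorted as \eqn{\lambda_x^2 \le \lambda_y^2 \le \lambda_z^2},
#' the asphericity is \eqn{b = \lambda_z^2 - (\lambda_x^2+\lambda_y^2)/2}
#' (nm^2); `b_norm` divides by the trace, giving a dimensionless value in
#' \[0, 1\]: 0 for an isotropic (spherical) eigenvalue spectrum and 1 in
#' the rod limit \eqn{\lambda_x = \lambda_y = 0}. Input must already be
#' unwrapped (see [unwrap_cluster()]).
#'
#' @param points An n x 3 matrix, or a data frame with columns `x`, `y`,
#'   `z` (one row per point; per-peptide mass centers or beads).
#' @return A one-row tibble: `n`, `rg` (nm), `b_raw` (nm^2), `b_norm`,
#'   `lambda_x2`, `lambda_y2`, `lambda_z2` (nm^2).
#' @export
gyration_shape <- function(points) {
  m <- points_matrix(points)
  if (nrow(m) < 2) stop("need at least 2 points", call. = FALSE)
  centered <- sweep(m, 2, colMeans(m))
  if (max(abs(centered)) < 1e-12) {
    stop("degenerate geometry: all points identical", call. = FALSE)
  }
  s <- crossprod(centered) / nrow(m)
  ev <- sort(eigen(s, symmetric = TRUE, only.values = TRUE)$values)
  ev[ev < 0] <- 0 # numerical noise
  tr <- sum(ev)
  b_raw <- ev[3] - (ev[1] + ev[2]) / 2
  tibble::tibble(
    n = nrow(m),
    rg = sqrt(tr),
    b_raw = b_raw,
    b_norm = b_raw / tr,
    lambda_x2 = ev[1], lambda_y2 = ev[2], lambda_z2 = ev[3]
  )
}

points_matrix <- function(points) {
  if (is.matrix(points)) {
    stopifnot(ncol(points) == 3)
    points
  } else {
    stopifnot(all(c("x", "y", "z") %in% names(points)))
    as.matrix(points[, c("x", "y", "z")])
  }
}

#' Backbone end-to-end unit vectors of each peptide
#'
#' The end-to-end vector runs from the backbone N bead of the first
#' residue to the backbone C bead of the last residue, normalized to
#' unit length.
#'
#' @param frame A single-frame trajectory tibble.
#' @param members Optional peptide indices to restrict to.
#' @return A tibble with columns `peptide`, `ex`, `ey`, `ez`.
#' @export
end_to_end_vectors <- function(frame, members = NULL) {
  check_frame_tbl(frame, single_frame = TRUE)
  if (!is.null(members)) frame <- dplyr::filter(frame, .data$peptide %in% members)
  frame <- compact_peptides(frame)
  last_res <- max(frame$residue)
  first <- dplyr::filter(frame, .data$residue == 1, .data$role == "N")
  last <- dplyr::filter(frame, .data$residue == last_res, .data$role == "C")
  stopifnot(nrow(first) == nrow(last))
  v <- cbind(last$x - first$x, last$y - first$y, last$z - first$z)
  nrm <- row_norms(v)
  if (any(nrm < 1e-12)) {
    stop("geometry error: zero-length end-to-end vector for peptide ",
         first$peptide[which(nrm < 1e-12)[1]], call. = FALSE)
  }
  v <- v / nrm
  tibble::tibble(peptide = first$peptide, ex = v[, 1], ey = v[, 2], ez = v[, 3])
}

#' End-to-end orientation correlation Cn of a cluster
#'
#' \deqn{C_n = \frac{2}{M(M-1)} \sum_{i<j} (n_i \cdot n_j)^2}
#' over the unit end-to-end vectors \eqn{n_i} of the M cluster peptides.
#' The squared dot product makes parallel and antiparallel alignment
#' equivalent: Cn = 1 for perfectly (anti)parallel vectors and tends to
#' 1/3 for isotropically distributed orientations.
#'
#' @inheritParams end_to_end_vectors
#' @return A single number in \[0, 1\].
#' @export
end_to_end_correlation <- function(frame, members = NULL) {
  u <- end_to_end_vectors(frame, members)
  cn_from_vectors(as.matrix(u[, c("ex", "ey", "ez")]))
}

# Cn from an M x 3 matrix of unit vectors; sum_{i<j}(u_i.u_j)^2 equals
# (||U U^T||_F^2 - M)/2 because the diagonal dot products are 1.
cn_from_vectors <- function(u) {
  m <- nrow(u)
  if (m < 2) stop("Cn needs a cluster of at least 2 peptides", call. = FALSE)
  g <- tcrossprod(u)
  (sum(g^2) - m) / (m * (m - 1))
}

#' Backbone dihedral angles of every peptide in a frame
#'
#' Phi/psi torsions from the three-bead backbone: for residue i,
#' phi uses C(i-1)-N(i)-CA(i)-C(i) and psi uses N(i)-CA(i)-C(i)-N(i+1).
#' Terminal residues lack one of the two angles and are reported as `NA`.
#'
#' @param frame A single-frame trajectory tibble.
#' @param members Optional peptide indices to restrict to.
#' @return A tibble with columns `peptide`, `residue`, `phi`, `psi`
#'   (degrees in (-180, 180\]).
#' @export
backbone_dihedrals <- function(frame, members = NULL) {
  check_frame_tbl(frame, single_frame = TRUE)
  if (!is.null(members)) frame <- dplyr::filter(frame, .data$peptide %in% members)
  frame <- compact_peptides(frame)
  bb <- dplyr::filter(frame, .data$role %in% c("N", "CA", "C"))
  out <- lapply(split(bb, bb$peptide), function(pep) {
    pep <- dplyr::arrange(pep, .data$residue, match(.data$role, c("N", "CA", "C")))
    n_res <- max(pep$residue)
    if (nrow(pep) != 3 * n_res) {
      stop("topology error: peptide ", pep$peptide[1],
           " is missing backbone beads", call. = FALSE)
    }
    xyz <- as.matrix(pep[, c("x", "y", "z")])
    at <- function(res, role) xyz[(res - 1) * 3 + match(role, c("N", "CA", "C")), , drop = FALSE]
    res_idx <- seq_len(n_res)
    phi <- rep(NA_real_, n_res)
    psi <- rep(NA_real_, n_res)
    if (n_res >= 2) {
      inner <- 2:n_res
      phi[inner] <- dihedral_angle(at(inner - 1, "C"), at(inner, "N"),
                                   at(inner, "CA"), at(inner, "C"))
      inner <- 1:(n_res - 1)
      psi[inner] <- dihedral_angle(at(inner, "N"), at(inner, "CA"),
                                   at(inner, "C"), at(inner + 1, "N"))
    }
    tibble::tibble(peptide = pep$peptide[1], residue = res_idx, phi = phi, psi = psi)
  })
  dplyr::bind_rows(out)
}

#' Default beta region of the Ramachandran plane
#'
#' A broad beta-strand region: phi in \[-180, -45\] degrees and psi in
#' \[45, 180\] or \[-180, -120\] degrees. Used by [beta_content()];
#' replace with a list of the same shape to configure.
#'
#' @return A list with elements `phi` (length-2 range) and `psi`
#'   (list of length-2 ranges).
#' @export
beta_region_default <- function() {
  list(phi = c(-180, -45), psi = list(c(45, 180), c(-180, -120)))
}

#' Beta-content of a cluster
#'
#' Number of residues in a beta backbone conformation divided by the
#' number of peptides in the cluster. Only interior residues enter the
#' count (terminal residues lack one of the two dihedrals), so the value
#' is bounded by `residues_per_peptide - 2`.
#'
#' @param frame A single-frame trajectory tibble.
#' @param members Optional peptide indices forming the cluster.
#' @param beta_region Dihedral-region specification; see
#'   [beta_region_default()].
#' @return Beta-content (residues per peptide), a non-negative number.
#' @export
beta_content <- function(frame, members = NULL, beta_region = beta_region_default()) {
  dih <- backbone_dihedrals(frame, members)
  m <- length(unique(dih$peptide))
  interior <- dplyr::filter(dih, !is.na(.data$phi), !is.na(.data$psi))
  in_phi <- interior$phi >= beta_region$phi[1] & interior$phi <= beta_region$phi[2]
  in_psi <- Reduce(`|`, lapply(beta_region$psi, function(rg) {
    interior$psi >= rg[1] & interior$psi <= rg[2]
  }))
  sum(in_phi & in_psi) / m
}

#' Histogram of peptide mass-center distances in a cluster
#'
#' Normalized histogram (probabilities summing to 1) of all M(M-1)/2
#' pairwise distances between peptide mass centers of an unwrapped
#' cluster. The default bin width of 0.02 nm resolves the ~0.2 nm
#' nearest-neighbor shell with ten bins.
#'
#' @param frame A single-frame trajectory tibble holding the (unwrapped)
#'   cluster, or a tibble of per-peptide centers with columns
#'   `peptide`, `x`, `y`, `z`.
#' @param members Optional peptide indices forming the cluster (ignored
#'   when `frame` is already a centers table).
#' @param bin_width Bin width in nm (> 0).
#' @return A tibble with columns `bin_lo`, `bin_hi`, `mid` (nm), `prob`,
#'   `m` (source cluster size).
#' @export
mass_center_histogram <- function(frame, members = NULL, bin_width = 0.02) {
  if (bin_width <= 0) stop("configuration error: bin width must be positive", call. = FALSE)
  centers <- if (all(frame_cols %in% names(frame))) {
    fr <- frame
    if (!is.null(members)) fr <- dplyr::filter(fr, .data$peptide %in% members)
    peptide_mass_centers(fr)
  } else {
    stopifnot(all(c("x", "y", "z") %in% names(frame)))
    frame
  }
  m <- nrow(centers)
  if (m < 2) stop("histogram needs a cluster of at least 2 peptides", call. = FALSE)
  d <- stats::dist(as.matrix(centers[, c("x", "y", "z")]))
  n_bins <- max(1L, ceiling(max(d) / bin_width + 1e-9))
  edges <- seq(0, n_bins * bin_width, by = bin_width)
  counts <- graphics::hist(d, breaks = edges, plot = FALSE)$counts
  tibble::tibble(
    bin_lo = edges[-length(edges)],
    bin_hi = edges[-1],
    mid = (edges[-1] + edges[-length(edges)]) / 2,
    prob = counts / sum(counts),
    m = m
  )
}

# Local maxima of a non-negative vector: >= both neighbors and strictly
# greater than at least one (boundaries count as 0). A flat stretch is
# not a maximum, so uniform tails score zero.
local_maxima <- function(p) {
  n <- length(p)
  left <- c(0, p[-n])
  right <- c(p[-1], 0)
  which(p >= left & p >= right & (p > left | p > right) & p > 0)
}

#' Classify a distance histogram as ordered or disordered
#'
#' Ordered (fibril-like) aggregates show narrow discrete shells in the
#' mass-center distance histogram beyond the first-neighbor peak, while
#' amorphous aggregates show one first-neighbor peak followed by a
#' broad featureless hump. The score is the fraction of probability mass
#' beyond the first peak that sits in local-maximum bins and their
#' immediate neighbors; a cluster is called ordered when the score
#' reaches `sharpness_threshold`.
#'
#' @param hist A histogram tibble from [mass_center_histogram()].
#' @param sharpness_threshold Score above which the cluster is called
#'   ordered (default 0.5).
#' @return A one-row tibble: `score`, `ordered`, `first_peak` (nm).
#' @export
classify_order <- function(hist, sharpness_threshold = 0.5) {
  stopifnot(all(c("mid", "prob") %in% names(hist)))
  p <- hist$prob
  if (length(p) == 0 || sum(p) == 0) stop("empty histogram", call. = FALSE)
  maxima <- local_maxima(p)
  if (length(maxima) == 0) {
    return(tibble::tibble(score = 0, ordered = FALSE, first_peak = NA_real_))
  }
  first_peak <- maxima[1]
  tail_idx <- seq_along(p) > first_peak + 1
  tail_mass <- sum(p[tail_idx])
  if (tail_mass == 0) {
    # no structure beyond the first shell: a single sharp peak is ordered
    return(tibble::tibble(score = 1, ordered = TRUE, first_peak = hist$mid[first_peak]))
  }
  tail_maxima <- maxima[maxima > first_peak + 1]
  keep <- unique(c(tail_maxima - 1, tail_maxima, tail_maxima + 1))
  keep <- keep[keep >= 1 & keep <= length(p)]
  keep <- keep[keep > first_peak + 1]
  score <- sum(p[keep]) / tail_mass
  tibble::tibble(
    score = score,
    ordered = score >= sharpness_threshold,
    first_peak = hist$mid[first_peak]
  )
}

#' Position of the second maximum of a distance histogram
#'
#' The second local maximum (in increasing distance order) of the
#' 3-bin moving-average smoothed histogram. This empirical spacing can
#' replace the fitted reference spacing of [reference_spacing()] when
#' its fit constants do not apply to the system at hand.
#'
#' @param hist A histogram tibble from [mass_center_histogram()].
#' @return Distance (nm) of the second smoothed local maximum, or `NA`
#'   if there is none.
#' @export
second_maximum <- function(hist) {
  p <- hist$prob
  n <- length(p)
  if (n < 3) return(NA_real_)
  sm <- (c(0, p[-n]) + p + c(p[-1], 0)) / 3
  # plateau-aware maxima: a flat run counts once, at its middle bin
  r <- rle(sm)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  vleft <- c(0, r$values[-length(r$values)])
  vright <- c(r$values[-1], 0)
  is_max <- r$values > 0 & r$values > vleft & r$values > vright
  maxima <- floor((starts[is_max] + ends[is_max]) / 2)
  if (length(maxima) < 2) return(NA_real_)
  hist$mid[maxima[2]]
}
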