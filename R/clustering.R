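#' Detect peptide clusters by the bead-distance criterion
#'
#' Two peptides are linked when any bead of one lies within `cutoff`
#' (minimum-image distance) of any bead of the other; clusters are the
#' connected components of the link graph (single linkage). Components
#' of size 1 are free monomers. The default cutoff of 0.5 nm is the
#' standard contact criterion for mid-resolution coarse-grained beads.
#'
#' Candidate peptide pairs are pre-filtered by an exact bounding-radius
#' test on peptide centroids before the bead-level check, so results are
#' identical to the all-pairs computation at a fraction of the cost.
#'
#' @param frame A single-frame trajectory tibble (see [trajectory-table]).
#' @param cutoff Linkage cutoff in nm; must be positive and below half
#'   the smallest box edge (otherwise the minimum image is ambiguous).
#' @return A tibble with one row per peptide: `time`, `peptide`,
#'   `cluster` (integer id, `NA` for monomers). Cluster ids are ordered
#'   by decreasing size, ties broken by smallest member index.
#' @examples
#' top <- peptide_topology("GNNQQNY", 3)
#' @export
find_clusters <- function(frame, cutoff = 0.5) {
  check_frame_tbl(frame, single_frame = TRUE)
  box <- frame_box(frame)
  if (cutoff <= 0) stop("cutoff must be positive", call. = FALSE)
  if (cutoff >= min(box) / 2) {
    stop("ambiguity error: cutoff ", cutoff, " nm is not below half the smallest box edge (",
         min(box) / 2, " nm); the minimum image is not unique", call. = FALSE)
  }
  frame <- compact_peptides(frame)
  edges <- linkage_edges(frame, cutoff, box)
  peptides <- sort(unique(frame$peptide))
  membership <- components_from_edges(peptides, edges)
  tibble::tibble(
    time = frame$time[1],
    peptide = peptides,
    cluster = membership
  )
}

# Bead-level linkage edges between peptides; assumes compacted peptides.
linkage_edges <- function(frame, cutoff, box) {
  peptides <- sort(unique(frame$peptide))
  np <- length(peptides)
  if (np < 2) return(matrix(integer(0), ncol = 2))
  coords <- lapply(peptides, function(p) {
    as.matrix(frame[frame$peptide == p, c("x", "y", "z")])
  })
  centers <- t(vapply(coords, colMeans, numeric(3)))
  radii <- vapply(seq_len(np), function(i) {
    max(sqrt(rowSums((coords[[i]] - rep(centers[i, ], each = nrow(coords[[i]])))^2)))
  }, numeric(1))
  pairs <- utils::combn(np, 2)
  dd <- min_image(centers[pairs[2, ], , drop = FALSE] - centers[pairs[1, ], , drop = FALSE], box)
  cdist <- sqrt(rowSums(dd^2))
  cand <- which(cdist <= cutoff + radii[pairs[1, ]] + radii[pairs[2, ]])
  hits <- vapply(cand, function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    min_pair_beaddist(coords[[i]], coords[[j]], box) < cutoff
  }, logical(1))
  linked <- cand[hits]
  cbind(peptides[pairs[1, linked]], peptides[pairs[2, linked]])
}

# Minimum over all bead pairs of the minimum-image distance.
min_pair_beaddist <- function(a, b, box) {
  na <- nrow(a); nb <- nrow(b)
  ia <- rep(seq_len(na), times = nb)
  ib <- rep(seq_len(nb), each = na)
  d <- min_image(b[ib, , drop = FALSE] - a[ia, , drop = FALSE], box)
  sqrt(min(rowSums(d^2)))
}

components_from_edges <- function(peptides, edges) {
  membership <- rep(NA_integer_, length(peptides))
  names(membership) <- as.character(peptides)
  if (nrow(edges) > 0) {
    g <- igraph::graph_from_edgelist(
      cbind(as.character(edges[, 1]), as.character(edges[, 2])),
      directed = FALSE
    )
    comp <- igraph::components(g)
    sizes <- comp$csize
    # order components: decreasing size, tie -> smallest member index
    first_member <- vapply(seq_along(sizes), function(cid) {
      min(as.integer(names(comp$membership)[comp$membership == cid]))
    }, numeric(1))
    ord <- order(-sizes, first_member)
    relabel <- integer(length(sizes))
    relabel[ord] <- seq_along(sizes)
    membership[names(comp$membership)] <- relabel[comp$membership]
  }
  unname(membership)
}

#' Cluster-level summary of a cluster assignment
#'
#' @param clusters Output of [find_clusters()].
#' @return A tibble with one row per cluster: `time`, `cluster`, `size`,
#'   and a `members` list-column of peptide indices.
#' @export
cluster_summary <- function(clusters) {
  inc <- dplyr::filter(clusters, !is.na(.data$cluster))
  dplyr::arrange(
    dplyr::summarise(
      dplyr::group_by(inc, .data$time, .data$cluster),
      size = dplyr::n(),
      members = list(sort(.data$peptide)),
      .groups = "drop"
    ),
    .data$cluster
  )
}

#' Unwrap a boundary-split cluster into contiguous coordinates
#'
#' A cluster crossing a periodic boundary is stored split across the
#' box. This shifts each member peptide by the integer box vector that
#' makes the cluster spatially contiguous: a breadth-first traversal of
#' the link graph from the smallest member index places each newly
#' reached peptide at the minimum-image position relative to the member
#' it is linked to. Descriptors computed on the result do not depend on
#' which periodic image the input happened to be wrapped into.
#'
#' @param frame A single-frame trajectory tibble.
#' @param members Integer vector of peptide indices forming one cluster
#'   (must be connected under the link graph at `cutoff`).
#' @param cutoff Linkage cutoff in nm, as in [find_clusters()].
#' @return A single-frame trajectory tibble restricted to `members`,
#'   with unwrapped coordinates (possibly outside the box).
#' @export
unwrap_cluster <- function(frame, members, cutoff = 0.5) {
  check_frame_tbl(frame, single_frame = TRUE)
  box <- frame_box(frame)
  sub <- compact_peptides(dplyr::filter(frame, .data$peptide %in% members))
  members <- sort(unique(sub$peptide))
  if (length(members) == 1) return(sub)
  edges <- linkage_edges(sub, cutoff, box)
  if (nrow(edges) == 0 && length(members) > 1) {
    stop("contract violation: peptide set is not connected at cutoff ",
         cutoff, " nm", call. = FALSE)
  }
  adj <- lapply(members, function(p) {
    unique(c(edges[edges[, 1] == p, 2], edges[edges[, 2] == p, 1]))
  })
  names(adj) <- as.character(members)
  coords <- lapply(members, function(p) as.matrix(sub[sub$peptide == p, c("x", "y", "z")]))
  names(coords) <- as.character(members)

  placed <- stats::setNames(rep(FALSE, length(members)), as.character(members))
  seed <- as.character(members[1])
  placed[seed] <- TRUE
  queue <- seed
  while (length(queue) > 0) {
    u <- queue[1]; queue <- queue[-1]
    for (v in as.character(adj[[u]])) {
      if (!placed[v]) {
        # shift v by the whole-box vector that realizes the minimum-image
        # distance of its closest bead pair with the placed neighbor u
        a <- coords[[u]]; b <- coords[[v]]
        ia <- rep(seq_len(nrow(a)), times = nrow(b))
        ib <- rep(seq_len(nrow(b)), each = nrow(a))
        d <- b[ib, , drop = FALSE] - a[ia, , drop = FALSE]
        dmi <- min_image(d, box)
        k <- which.min(rowSums(dmi^2))
        shift <- dmi[k, ] - d[k, ]
        coords[[v]] <- b + rep(shift, each = nrow(b))
        placed[v] <- TRUE
        queue <- c(queue, v)
      }
    }
  }
  if (!all(placed)) {
    stop("contract violation: peptide set is not connected at cutoff ",
         cutoff, " nm", call. = FALSE)
  }
  out <- sub
  for (p in members) {
    rows <- which(sub$peptide == p)
    out[rows, c("x", "y", "z")] <- as.data.frame(coords[[as.character(p)]])
  }
  out
}

#' Per-frame monomer and cluster counts
#'
#' Runs [find_clusters()] on every frame and tabulates the kinetic
#' observables: number of free monomers Nm, number of clusters Nc
#' (aggregates of two or more peptides), size M of the largest cluster,
#' and the scaled size M/N0.
#'
#' @param traj A trajectory tibble (see [trajectory-table]).
#' @param cutoff Linkage cutoff in nm.
#' @return A tibble with columns `frame`, `time`, `n_monomers`,
#'   `n_clusters`, `largest`, `n0`, `m_rel`.
#' @export
kinetic_counts <- function(traj, cutoff = 0.5) {
  check_frame_tbl(traj)
  frames <- split(traj, traj$frame)
  dplyr::bind_rows(lapply(frames, function(fr) {
    cl <- find_clusters(fr, cutoff)
    n0 <- nrow(cl)
    sizes <- table(cl$cluster)
    largest <- if (length(sizes) > 0) max(sizes) else 0L
    tibble::tibble(
      frame = fr$frame[1],
      time = fr$time[1],
      n_monomers = sum(is.na(cl$cluster)),
      n_clusters = length(sizes),
      largest = as.integer(largest),
      n0 = n0,
      m_rel = largest / n0
    )
  }))
}

#' Track the largest cluster through a trajectory
#'
#' Selects the largest cluster in every frame; when several clusters tie
#' for largest, the one sharing the most members with the previously
#' tracked cluster is chosen (then the one containing the smallest
#' peptide index, for determinism).
#'
#' @param traj A trajectory tibble.
#' @param cutoff Linkage cutoff in nm.
#' @return A tibble with one row per frame: `frame`, `time`, `size`, and
#'   a `members` list-column with the tracked cluster's peptide indices
#'   (empty when the frame has no cluster).
#' @export
track_largest <- function(traj, cutoff = 0.5) {
  check_frame_tbl(traj)
  frames <- split(traj, traj$frame)
  prev <- integer(0)
  out <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    cl <- cluster_summary(find_clusters(frames[[i]], cutoff))
    if (nrow(cl) == 0) {
      chosen <- integer(0)
    } else {
      top <- dplyr::filter(cl, .data$size == max(.data$size))
      if (nrow(top) > 1) {
        overlap <- vapply(top$members, function(m) length(intersect(m, prev)), 1L)
        top <- top[overlap == max(overlap), , drop = FALSE]
        if (nrow(top) > 1) {
          first <- vapply(top$members, min, 1L)
          top <- top[which.min(first), , drop = FALSE]
        }
      }
      chosen <- top$members[[1]]
    }
    out[[i]] <- tibble::tibble(
      frame = frames[[i]]$frame[1],
      time = frames[[i]]$time[1],
      size = length(chosen),
      members = list(chosen)
    )
    if (length(chosen) > 0) prev <- chosen
  }
  dplyr::bind_rows(out)
}
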