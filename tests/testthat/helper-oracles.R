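# Independent reference implementations used as test oracles. They
# deliberately avoid the package's pruned/cell-free code paths: plain
# all-pairs loops and union-find components.

min_image_oracle <- function(d, box) d - box * round(d / box)

# All-pairs single-linkage clustering with union-find components.
oracle_find_clusters <- function(frame, cutoff) {
  box <- c(frame$box_x[1], frame$box_y[1], frame$box_z[1])
  peps <- sort(unique(frame$peptide))
  np <- length(peps)
  parent <- seq_len(np)
  findp <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  beads <- lapply(peps, function(p) as.matrix(frame[frame$peptide == p, c("x", "y", "z")]))
  for (i in seq_len(np - 1)) {
    for (j in (i + 1):np) {
      linked <- FALSE
      a <- beads[[i]]; b <- beads[[j]]
      for (r in seq_len(nrow(a))) {
        dx <- min_image_oracle(b[, 1] - a[r, 1], box[1])
        dy <- min_image_oracle(b[, 2] - a[r, 2], box[2])
        dz <- min_image_oracle(b[, 3] - a[r, 3], box[3])
        if (any(dx * dx + dy * dy + dz * dz < cutoff^2)) {
          linked <- TRUE
          break
        }
      }
      if (linked) {
        ri <- findp(i); rj <- findp(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(np), findp, 1L)
  split(peps, roots)
}

# Canonical form of a partition for comparison: sorted list of sorted
# member vectors, singletons dropped (monomers), plus the monomer set.
canonical_partition <- function(groups) {
  groups <- lapply(groups, sort)
  clusters <- groups[vapply(groups, length, 1L) >= 2]
  monomers <- sort(unlist(groups[vapply(groups, length, 1L) == 1]))
  ord <- order(vapply(clusters, `[`, 1L, 1))
  list(clusters = unname(clusters[ord]), monomers = as.integer(monomers))
}

partition_from_find_clusters <- function(cl) {
  groups <- split(cl$peptide, ifelse(is.na(cl$cluster), paste0("m", cl$peptide),
                                     paste0("c", cl$cluster)))
  canonical_partition(groups)
}

# Characteristic-polynomial eigenvalues of a symmetric 3x3 matrix.
oracle_eigen3 <- function(s) {
  cp <- c(
    -det(s),
    s[1, 1] * s[2, 2] + s[1, 1] * s[3, 3] + s[2, 2] * s[3, 3] -
      s[1, 2]^2 - s[1, 3]^2 - s[2, 3]^2,
    -(s[1, 1] + s[2, 2] + s[3, 3]),
    1
  )
  sort(Re(polyroot(cp)))
}

# Exact mean entity count of constant-kernel stochastic coagulation:
# the entity count is a pure death chain with rate K n (n-1) / 2, so
# the master equation is a small linear ODE solved numerically.
oracle_constant_kernel_mean <- function(n0, rate, times) {
  lambda <- rate * (1:n0) * (0:(n0 - 1)) / 2
  deriv <- function(t, p, parms) {
    dp <- -lambda * p
    dp[1:(n0 - 1)] <- dp[1:(n0 - 1)] + lambda[2:n0] * p[2:n0]
    list(dp)
  }
  p0 <- c(rep(0, n0 - 1), 1)
  sol <- deSolve::ode(y = p0, times = c(0, times), func = deriv, parms = NULL)
  counts <- as.matrix(sol[-1, -1, drop = FALSE]) %*% (1:n0)
  as.numeric(counts)
}
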