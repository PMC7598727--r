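#' Stochastic coalescence kinetics (Gillespie simulation)
#'
#' Exact stochastic simulation of well-mixed binary coalescence over the
#' cluster-size state: any two entities of sizes i and j merge with rate
#' K(i, j), and any aggregate of size >= 2 sheds one monomer with rate
#' `detachment_rate`. Starting from free monomers this reproduces the
#' qualitative stages of peptide aggregation: rapid dimerization, a
#' rising-then-falling cluster count, and coalescence into one large
#' aggregate (the absorbing state when detachment is off).
#'
#' @param n0 Initial number of monomers (>= 2).
#' @param kernel Coalescence kernel: `"constant"` (K(i,j) = `rate`),
#'   `"sum"` (K(i,j) = `rate * (i + j)`), or a function of two size
#'   vectors returning rates.
#' @param rate Kernel rate constant (per unit time).
#' @param detachment_rate Monomer-detachment rate per aggregate.
#' @param t_end Stop time (default: run to the absorbing state).
#' @param seed Optional RNG seed.
#' @param max_events Safety cap on the number of events.
#' @return A list of class `ft_coalescence` with elements `curves`
#'   (tibble: `time`, `n_monomers`, `n_clusters`, `largest`, `n0`;
#'   one row per event, including the initial state) and `events`
#'   (tibble: `time`, `type`, `size_a`, `size_b`, `size_new`).
#' @export
simulate_coalescence <- function(n0 = 72, kernel = c("constant", "sum"),
                                 rate = 1, detachment_rate = 0,
                                 t_end = Inf, seed = NULL,
                                 max_events = 100000) {
  stopifnot(n0 >= 2, rate >= 0, detachment_rate >= 0)
  if (!is.null(seed)) set.seed(seed)
  constant_kernel <- !is.function(kernel) && match.arg(kernel) == "constant"
  kfun <- if (is.function(kernel)) {
    kernel
  } else {
    switch(match.arg(kernel),
      constant = function(i, j) rate + 0 * i,
      sum = function(i, j) rate * (i + j)
    )
  }
  sizes <- rep(1L, n0)
  t <- 0
  state_row <- function(t, sizes) {
    agg <- sizes[sizes >= 2]
    tibble::tibble(
      time = t,
      n_monomers = sum(sizes == 1),
      n_clusters = length(agg),
      largest = if (length(agg) > 0) max(agg) else 0L,
      n0 = n0
    )
  }
  curves <- list(state_row(0, sizes))
  events <- list()
  for (ev in seq_len(max_events)) {
    n <- length(sizes)
    if (n <= 1 && detachment_rate == 0) break
    if (constant_kernel) {
      # uniform pair rates: no need to enumerate pairs
      pair_total <- if (n >= 2) rate * n * (n - 1) / 2 else 0
    } else {
      pair_w <- if (n >= 2) {
        idx <- utils::combn(n, 2)
        w <- kfun(sizes[idx[1, ]], sizes[idx[2, ]])
        if (any(w < 0)) stop("kernel returned a negative rate", call. = FALSE)
        w
      } else {
        numeric(0)
      }
      pair_total <- sum(pair_w)
    }
    det_idx <- which(sizes >= 2)
    det_total <- detachment_rate * length(det_idx)
    total <- pair_total + det_total
    if (total <= 0) {
      if (n > 1) {
        stop("stall: all event rates are zero with more than one entity left",
             call. = FALSE)
      }
      break
    }
    t <- t + stats::rexp(1, total)
    if (t > t_end) break
    if (stats::runif(1) * total < pair_total) {
      if (constant_kernel) {
        ij <- sample.int(n, 2)
        i <- ij[1]; j <- ij[2]
      } else {
        k <- sample.int(length(pair_w), 1, prob = pair_w)
        i <- idx[1, k]; j <- idx[2, k]
      }
      sa <- sizes[i]; sb <- sizes[j]
      sizes <- c(sizes[-c(i, j)], sa + sb)
      events[[length(events) + 1]] <- tibble::tibble(
        time = t, type = "coalescence", size_a = sa, size_b = sb, size_new = sa + sb
      )
    } else {
      i <- det_idx[sample.int(length(det_idx), 1)]
      sa <- sizes[i]
      sizes[i] <- sizes[i] - 1L
      sizes <- c(sizes, 1L)
      events[[length(events) + 1]] <- tibble::tibble(
        time = t, type = "detachment", size_a = sa, size_b = NA_integer_,
        size_new = sa - 1L
      )
    }
    curves[[length(curves) + 1]] <- state_row(t, sizes)
    if (sum(sizes) != n0) stop("internal error: mass not conserved", call. = FALSE)
  }
  structure(
    list(curves = dplyr::bind_rows(curves),
         events = if (length(events) > 0) dplyr::bind_rows(events) else
           tibble::tibble(time = numeric(), type = character(),
                          size_a = integer(), size_b = integer(),
                          size_new = integer())),
    class = "ft_coalescence"
  )
}

#' @export
print.ft_coalescence <- function(x, ...) {
  n <- nrow(x$events)
  final <- x$curves[nrow(x$curves), ]
  cat("<ft_coalescence>", n, "events;")
  cat(" final state: Nm =", final$n_monomers,
      "Nc =", final$n_clusters, "M =", final$largest, "\n")
  invisible(x)
}

#' Entity count of a coalescence run at given times
#'
#' Step-function evaluation of the total number of entities
#' (monomers plus aggregates) along a simulated run, for comparison
#' against closed-form coagulation kinetics.
#'
#' @param run An `ft_coalescence` from [simulate_coalescence()].
#' @param times Times at which to evaluate.
#' @return Numeric vector of entity counts.
#' @export
entity_count_at <- function(run, times) {
  cv <- run$curves
  ent <- cv$n_monomers + cv$n_clusters
  idx <- findInterval(times, cv$time)
  idx[idx < 1] <- 1
  ent[idx]
}
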