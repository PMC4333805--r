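# Recurrent MAX microcircuit: excitatory nodes whose recurrent collaterals
# land on distinct dendrites, each gated by dendritic inhibition so that only
# input stronger than the node's own momentary activity passes. The steady
# state of a set of mutually connected nodes is the maximum of their
# feedforward drives; this module provides both the continuous dynamics and
# the equivalent algebraic fixed-point iteration.

#' Construct a recurrent MAX network
#'
#' @param feedforward Numeric vector of nonnegative feedforward drives, one
#'   per node.
#' @param edges Two-column integer matrix of directed connections
#'   `(from, to)`: node `to` receives a recurrent collateral from `from` on a
#'   distinct dendrite. May have zero rows.
#' @param support Logical vector: whether each node may relay recurrent
#'   activity. Nodes outside the support neither send nor receive recurrent
#'   input; they hold their feedforward value. Defaults to all `TRUE`.
#' @param symmetric If `TRUE` (default, the model's mutual-connection wiring)
#'   every edge is mirrored so connections are reciprocal.
#' @return An object of class `max_network`.
#' @export
max_network <- function(feedforward, edges = NULL, support = NULL,
                        symmetric = TRUE) {
  ff <- as.numeric(feedforward)
  n <- length(ff)
  if (n < 1) stop("network needs at least one node")
  if (anyNA(ff) || any(ff < 0)) stop("feedforward drives must be nonnegative")
  if (is.null(support)) support <- rep(TRUE, n)
  support <- as.logical(support)
  if (length(support) != n) stop("`support` must have one entry per node")
  if (is.null(edges)) edges <- matrix(integer(0), ncol = 2)
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0) {
    if (min(edges) < 1 || max(edges) > n) stop("edge endpoints out of range")
    if (symmetric) edges <- rbind(edges, edges[, 2:1, drop = FALSE])
    edges <- unique(edges[edges[, 1] != edges[, 2], , drop = FALSE])
  }
  structure(list(feedforward = ff, edges = edges, support = support,
                 n_nodes = n),
            class = "max_network")
}

#' @export
print.max_network <- function(x, ...) {
  cat(sprintf("<max_network: %d nodes, %d directed edges, %d supported>\n",
              x$n_nodes, nrow(x$edges), sum(x$support)))
  invisible(x)
}

# in-neighbour list restricted to supported sources
in_neighbours <- function(net) {
  nb <- vector("list", net$n_nodes)
  e <- net$edges
  if (nrow(e) > 0) {
    keep <- net$support[e[, 1]]
    e <- e[keep, , drop = FALSE]
    if (nrow(e) > 0) {
      sp <- split(e[, 1], e[, 2])
      nb[as.integer(names(sp))] <- sp
    }
  }
  nb
}

max_state <- function(activity, iterations, converged, residual = 0) {
  structure(list(activity = activity, iterations = iterations,
                 converged = converged, residual = residual),
            class = "max_state")
}

#' @export
print.max_state <- function(x, ...) {
  cat(sprintf("<max_state: %d nodes, %d iterations, converged = %s>\n",
              length(x$activity), x$iterations, x$converged))
  invisible(x)
}

#' Relax a MAX network by synchronous fixed-point iteration
#'
#' Iterates `x_i <- max(ff_i, max over supported in-neighbours j of x_j)` for
#' supported nodes and `x_i <- ff_i` otherwise, starting from the feedforward
#' drive. The iteration is monotone nondecreasing and bounded, so for a
#' finite graph it reaches, exactly, the per-supported-component maximum
#' merged with each node's own feedforward.
#'
#' @param net A [max_network()].
#' @param tol Convergence tolerance on the per-iteration change.
#' @param max_iter Iteration cap (cannot bind for finite graphs; reported if
#'   it somehow does).
#' @return A `max_state` with fields `activity`, `iterations`, `converged`.
#' @export
relax_fixed_point <- function(net, tol = 1e-9, max_iter = NULL) {
  stopifnot(inherits(net, "max_network"))
  if (is.null(max_iter)) max_iter <- net$n_nodes + 1L
  nb <- in_neighbours(net)
  ff <- net$feedforward
  x <- ff
  it <- 0L
  repeat {
    it <- it + 1L
    xn <- ff
    for (i in which(net$support)) {
      js <- nb[[i]]
      if (length(js)) xn[i] <- max(ff[i], x[js])
    }
    delta <- max(abs(xn - x))
    x <- xn
    if (delta <= tol) return(max_state(x, it, TRUE))
    if (it >= max_iter) {
      warning(sprintf("fixed-point iteration hit max_iter with residual %g",
                      delta))
      return(max_state(x, it, FALSE, delta))
    }
  }
}

#' Relax a MAX network by integrating the dendritic-inhibition dynamics
#'
#' Each dendrite carries the rectified difference between the presynaptic
#' activity and the node's own activity (the dendritic interneuron subtracts
#' the node's momentary level), so recurrent excitation influences a node
#' only where it is stronger than the node itself. The soma relaxes with
#' unit leak toward the larger of its feedforward drive and its current
#' activity plus the strongest dendritic signal:
#' `dx_i/dt = -x_i + max(ff_i, x_i + max_j [x_j - x_i]_+)`.
#' Activity therefore never falls below the feedforward drive of a supported
#' node, and mutually connected nodes converge to the component maximum.
#'
#' @param net A [max_network()].
#' @param dt Euler time step.
#' @param t_max Integration horizon in the same time units.
#' @param tol Halt when the maximum activity change per step drops below
#'   `tol`.
#' @return A `max_state`; `converged = FALSE` with a warning (and the
#'   residual in the state) if `t_max` is reached first.
#' @export
relax_dynamics <- function(net, dt = 0.1, t_max = 200, tol = 1e-9) {
  stopifnot(inherits(net, "max_network"), dt > 0, t_max > 0)
  nb <- in_neighbours(net)
  ff <- net$feedforward
  sup <- net$support
  x <- ff
  steps <- ceiling(t_max / dt)
  for (it in seq_len(steps)) {
    drive <- ff
    for (i in which(sup)) {
      js <- nb[[i]]
      r <- if (length(js)) max(c(0, x[js] - x[i])) else 0
      drive[i] <- max(ff[i], x[i] + r)
    }
    dx <- dt * (drive - x)
    x <- x + dx
    delta <- max(abs(dx))
    if (delta < tol) return(max_state(x, it, TRUE))
  }
  warning(sprintf("dynamics did not converge within t_max; residual %g",
                  delta))
  max_state(x, steps, FALSE, delta)
}
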