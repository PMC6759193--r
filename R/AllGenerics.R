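#' Interaction (sign) matrix of a network
#'
#' Builds the [SignMatrix-class] of a signed digraph or Hill model: -1
#' diagonal for first-order self-decay, off-diagonal entry \eqn{(i, j)}
#' equal to the sign of the influence of node j on node i.
#'
#' @param object a [SignedDigraph-class] or [HillModel-class].
#' @param order optional permutation of the node labels fixing the
#'   row/column order.
#' @return a [SignMatrix-class].
#' @examples
#' sm <- interactionMatrix(aarDtcGraph())
#' signPattern(sm)
#' @export
setGeneric("interactionMatrix",
           function(object, order = NULL) standardGeneric("interactionMatrix"))

#' Enumerate elementary cycles and their signs
#'
#' Every elementary directed cycle of the graph, each reported exactly
#' once with canonical rotation (smallest label first) and its sign, the
#' product of its arc signs.  A cycle is negative iff it contains an odd
#' number of inhibitory arcs.
#'
#' @param object a [SignedDigraph-class].
#' @return list of cycles; each element has `nodes` (character vector in
#'   cycle order, canonical start) and `sign` (+1 or -1).
#' @examples
#' cyc <- enumerateCycles(aavGraph())
#' table(vapply(cyc, function(cy) cy$sign, numeric(1)))
#' @export
setGeneric("enumerateCycles", function(object) standardGeneric("enumerateCycles"))

#' Apply a gauge (variable sign change) transformation
#'
#' Flipping the sign of a set of variables flips the sign of every arc
#' incident to them (for a sign matrix: the corresponding rows and
#' columns, leaving the diagonal untouched).  Gauges preserve the sign
#' of every cycle.
#'
#' @param object a [SignedDigraph-class] or [SignMatrix-class].
#' @param gauge named numeric vector of +1/-1 per node (missing nodes
#'   default to +1), or a character vector of node labels to flip.
#' @return object of the same class with transformed arc signs.
#' @export
setGeneric("applyGauge", function(object, gauge) standardGeneric("applyGauge"))

#' Simulate a network of first-order Hill equations
#'
#' Integrates \eqn{\dot x_i = (\mathrm{RHS}_i(x) - x_i)/\Theta_i} on a
#' fixed time grid.
#'
#' @param model a [HillModel-class] without delayed terms.
#' @param init named nonnegative initial state.
#' @param horizon simulation horizon in minutes.
#' @param step output (and, for `method = "rk4"`, integration) step in
#'   minutes.
#' @param method `"rk4"` (fixed-step, default) or `"lsoda"` (adaptive,
#'   for stiff time-scale ratios).
#' @param bias optional named numeric vector of constant additive inputs
#'   per equation (a persistent perturbation protocol).
#' @return a [Trajectory-class].
#' @export
setGeneric("simulateODE",
  function(model, init, horizon, step, method = c("rk4", "lsoda"),
           bias = NULL) standardGeneric("simulateODE"))

#' Simulate a delay differential model
#'
#' Integrates a delayed network, the one-state reduced model, or its
#' linearisation, with constant pre-history.
#'
#' @param model a [HillModel-class] with delayed terms, a
#'   [ReducedAAV-class] or a [LinearizedAAV-class].
#' @param init named initial state (and constant history); for the
#'   reduced and linearised models a scalar.
#' @param horizon simulation horizon in minutes (> 0).
#' @param step output step in minutes.
#' @param ... further arguments passed to methods (e.g. `rtol`, `atol`).
#' @return a [Trajectory-class].
#' @export
setGeneric("simulateDDE",
  function(model, init = NULL, horizon, step, ...)
    standardGeneric("simulateDDE"))

#' Locate equilibria by multistart iteration
#'
#' Fixed points of \eqn{x = \mathrm{RHS}(x)} located by damped
#' fixed-point iteration with a Newton polish, from several random
#' nonnegative starting points; solutions are clustered to count
#' distinct equilibria.
#'
#' @param model a [HillModel-class].
#' @param nStarts number of random starts.
#' @param tol residual tolerance for convergence.
#' @param seed integer seed for the random starts.
#' @param bias optional constant additive input per equation.
#' @param warmStart optional state used as an additional starting point.
#' @return an [EquilibriumReport-class].
#' @export
setGeneric("findEquilibrium",
  function(model, nStarts = 20L, tol = 1e-10, seed = 1L, bias = NULL,
           warmStart = NULL) standardGeneric("findEquilibrium"))

## Small accessors -----------------------------------------------------

#' @rdname accessors
#' @param object a package object.
#' @export
setGeneric("nodeLabels", function(object) standardGeneric("nodeLabels"))

#' @rdname accessors
#' @export
setGeneric("edgeTable", function(object) standardGeneric("edgeTable"))

#' @rdname accessors
#' @export
setGeneric("nodeClasses", function(object) standardGeneric("nodeClasses"))

#' @rdname accessors
#' @export
setGeneric("thetaMinutes", function(object) standardGeneric("thetaMinutes"))

#' @rdname accessors
#' @export
setGeneric("signPattern", function(object) standardGeneric("signPattern"))

#' @rdname accessors
#' @export
setGeneric("influenceClasses", function(object) standardGeneric("influenceClasses"))

#' @rdname accessors
#' @export
setGeneric("timeGrid", function(object) standardGeneric("timeGrid"))

#' @rdname accessors
#' @export
setGeneric("states", function(object) standardGeneric("states"))

#' @rdname accessors
#' @export
setGeneric("rho", function(object) standardGeneric("rho"))

#' @rdname accessors
#' @export
setGeneric("jstar", function(object) standardGeneric("jstar"))

#' @rdname accessors
#' @export
setGeneric("omegaStar", function(object) standardGeneric("omegaStar"))

#' @rdname accessors
#' @export
setGeneric("oscillating", function(object) standardGeneric("oscillating"))

#' @rdname accessors
#' @export
setGeneric("loopGains", function(object) standardGeneric("loopGains"))
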