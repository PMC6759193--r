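#' Construct a Hill network model
#'
#' @param nodes ordered character vector of state labels.
#' @param theta named numeric time constants in minutes (positive).
#' @param rhs named list of term lists (see [fTerm()]); one element per
#'   node, possibly empty.
#' @return a [HillModel-class].
#' @export
hillModel <- function(nodes, theta, rhs) {
  rhs <- rhs[nodes]
  for (v in nodes) if (is.null(rhs[[v]])) rhs[[v]] <- list()
  new("HillModel", nodes = nodes, theta = theta[nodes], rhs = rhs)
}

#' @rdname accessors
#' @export
setMethod("nodeLabels", "HillModel", function(object) object@nodes)

#' @rdname accessors
#' @export
setMethod("thetaMinutes", "HillModel", function(object) object@theta)

setMethod("show", "HillModel", function(object) {
  nterm <- sum(lengths(object@rhs))
  nd <- maxModelDelay(object)
  cat(sprintf("HillModel: %d states, %d interaction terms%s\n",
              length(object@nodes), nterm,
              if (nd > 0) sprintf(", max delay %.3g min", nd) else ""))
})

## Right-hand side of Theta_i dx_i/dt + x_i = RHS_i(x), evaluated at a
## named state vector; `bias` adds persistent constant inputs.
evalRHS <- function(model, state, bias = NULL) {
  getx <- function(lbl, lag) state[[lbl]]
  out <- vapply(model@nodes, function(v)
    evalTermsWith(model@rhs[[v]], getx), numeric(1))
  if (!is.null(bias)) out[names(bias)] <- out[names(bias)] + bias
  out
}

maxModelDelay <- function(model) {
  max(c(0, vapply(model@rhs, termsMaxDelay, numeric(1))))
}

## Directed dependency structure implied by the terms (from source to
## target), as an adjacency list.
modelAdjacency <- function(model) {
  adj <- stats::setNames(vector("list", length(model@nodes)), model@nodes)
  for (v in model@nodes) adj[[v]] <- character(0)
  for (v in model@nodes) {
    for (s in termSources(model@rhs[[v]])) adj[[s]] <- c(adj[[s]], v)
  }
  adj
}

#' @describeIn interactionMatrix sign matrix of a Hill model: entry
#'   (i, j) is the (necessarily consistent) sign with which variable j
#'   enters the right-hand side of variable i, traced through nested
#'   composed terms.  An error is raised if any dependence is not
#'   sign-definite.
#' @export
setMethod("interactionMatrix", "HillModel", function(object, order = NULL) {
  order <- order %||% object@nodes
  if (!setequal(order, object@nodes) || length(order) != length(object@nodes))
    stop("'order' must be a permutation of the node labels")
  n <- length(order)
  m <- matrix(0, n, n, dimnames = list(order, order))
  diag(m) <- -1
  for (i in order) {
    for (j in order) {
      if (i == j) next
      s <- signDepTerms(object@rhs[[i]], j)
      if (length(s) > 1L)
        stop(sprintf("dependence of %s on %s is not sign-definite", i, j))
      if (length(s) == 1L) m[i, j] <- s
    }
  }
  new("SignMatrix", mat = m)
})

#' Eliminate fast nodes by time-scale separation
#'
#' Sets the time constants of the listed fast nodes to zero and
#' substitutes their instantaneous steady-state response
#' \eqn{x_{\mathrm{fast}} = \mathrm{RHS}_{\mathrm{fast}}(x)} into every
#' term that references them (function composition, which preserves the
#' monotonicity classes of the composed interactions).  The fast nodes
#' must not form cycles among themselves, otherwise the composition is
#' ill-defined.
#'
#' @param model a [HillModel-class].
#' @param fastNodes character vector of nodes to eliminate (may be
#'   empty, returning the model unchanged).
#' @return the reduced [HillModel-class].
#' @examples
#' red <- reduceTimeScale(buildAARModel(sampleParameters(aarFullGraph(), seed = 1)),
#'                        c("ASR", "ACR", "NTS", "SFO"))
#' nodeLabels(red)
#' @export
reduceTimeScale <- function(model, fastNodes) {
  if (length(fastNodes) == 0L) return(model)
  unknown <- setdiff(fastNodes, model@nodes)
  if (length(unknown))
    stop("unknown fast nodes: ", paste(unknown, collapse = ", "))
  ## dependency order among the fast nodes themselves
  fadj <- stats::setNames(vector("list", length(fastNodes)), fastNodes)
  for (v in fastNodes) fadj[[v]] <- character(0)
  for (v in fastNodes) {
    for (s in intersect(termSources(model@rhs[[v]]), fastNodes))
      fadj[[s]] <- c(fadj[[s]], v)
  }
  ord <- topoSort(fastNodes, fadj)
  if (is.null(ord))
    stop("fast nodes form internal cycles; composition is ill-defined")
  expr <- list()
  for (v in ord) {
    ## fast dependencies of v appear earlier in ord and are already
    ## expressed in terms of slow nodes
    expr[[v]] <- substituteTerms(model@rhs[[v]], expr)
  }
  keep <- setdiff(model@nodes, fastNodes)
  rhs <- lapply(model@rhs[keep], substituteTerms, mapping = expr)
  hillModel(keep, model@theta[keep], rhs)
}

#' Restrict a model to a subset of its states
#'
#' Drops the other states and removes every reference to them from the
#' interaction terms, as if the dropped variables were absent.
#'
#' @param model a [HillModel-class].
#' @param keep character vector of state labels to retain.
#' @return the restricted [HillModel-class].
#' @export
projectModel <- function(model, keep) {
  unknown <- setdiff(keep, model@nodes)
  if (length(unknown))
    stop("unknown node labels: ", paste(unknown, collapse = ", "))
  keep <- model@nodes[model@nodes %in% keep]
  rhs <- lapply(model@rhs[keep], projectTerms, keep = keep)
  hillModel(keep, model@theta[keep], rhs)
}

#' @describeIn simulateODE fixed-step RK4 (or adaptive lsoda for stiff
#'   time-constant ratios) integration of a delay-free Hill network.
#' @export
setMethod("simulateODE", "HillModel",
  function(model, init, horizon, step, method = c("rk4", "lsoda"),
           bias = NULL) {
    method <- match.arg(method)
    if (step <= 0) stop("step must be positive")
    if (any(init < 0)) stop("initial state must be nonnegative")
    if (maxModelDelay(model) > 0)
      stop("model has delayed terms; use simulateDDE()")
    y0 <- stats::setNames(as.numeric(init[model@nodes]), model@nodes)
    if (any(is.na(y0))) stop("init must cover every state")
    th <- model@theta
    deriv <- function(t, y, parms) {
      names(y) <- model@nodes
      list((evalRHS(model, y, bias) - y) / th)
    }
    times <- seq(0, horizon, by = step)
    sol <- deSolve::ode(y0, times, deriv, parms = NULL, method = method,
                        rtol = 1e-8, atol = 1e-10)
    st <- unname(sol[, -1, drop = FALSE])
    colnames(st) <- model@nodes
    if (!all(is.finite(st)))
      stop("non-finite state encountered; reduce the integration step")
    new("Trajectory", time = sol[, 1], state = st,
        metadata = list(method = method, step = step))
  })

#' @rdname accessors
#' @export
setMethod("timeGrid", "Trajectory", function(object) object@time)

#' @rdname accessors
#' @export
setMethod("states", "Trajectory", function(object) object@state)

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d states over [%.3g, %.3g] min (%d points)\n",
              ncol(object@state), min(object@time), max(object@time),
              length(object@time)))
})

#' @describeIn findEquilibrium damped fixed-point iteration with Newton
#'   polish; solutions from all starts are clustered at relative
#'   distance 1e-6 to count distinct equilibria.
#' @export
setMethod("findEquilibrium", "HillModel",
  function(model, nStarts = 20L, tol = 1e-10, seed = 1L, bias = NULL,
           warmStart = NULL) {
    n <- length(model@nodes)
    bound <- vapply(model@rhs, termsUpperBound, numeric(1))
    if (!is.null(bias)) bound[names(bias)] <- bound[names(bias)] + abs(bias)
    bigB <- pmax(bound, 1)
    Tmap <- function(x) {
      names(x) <- model@nodes
      evalRHS(model, x, bias)
    }
    solveFrom <- function(x) {
      for (k in seq_len(400L)) {
        tx <- Tmap(x)
        x <- 0.5 * x + 0.5 * tx
        if (max(abs(tx - x)) < 1e-8) break
      }
      ## Newton polish on F(x) = T(x) - x
      for (k in seq_len(30L)) {
        fx <- Tmap(x) - x
        if (sqrt(sum(fx^2)) < tol) break
        J <- matrix(0, n, n)
        h <- pmax(abs(x), 1e-4) * 1e-6
        for (j in seq_len(n)) {
          xp <- x; xp[j] <- xp[j] + h[j]
          xm <- x; xm[j] <- pmax(xm[j] - h[j], 0)
          J[, j] <- (Tmap(xp) - Tmap(xm)) / (xp[j] - xm[j])
        }
        delta <- tryCatch(solve(diag(n) - J, fx), error = function(e) NULL)
        if (is.null(delta)) break
        x <- pmax(x + delta, 0)
      }
      x
    }
    set.seed(seed, kind = "Mersenne-Twister")
    starts <- c(list(bound),
                if (!is.null(warmStart)) list(warmStart[model@nodes]),
                lapply(seq_len(max(nStarts - 1L, 0L)), function(i)
                  stats::runif(n, 0, 2 * bigB)))
    sols <- list()
    resids <- numeric(0)
    for (x0 in starts) {
      x <- solveFrom(stats::setNames(as.numeric(x0), model@nodes))
      r <- sqrt(sum((Tmap(x) - x)^2))
      if (!is.finite(r) || r > max(tol, 1e-7)) next
      sols[[length(sols) + 1L]] <- x
      resids <- c(resids, r)
    }
    if (length(sols) == 0L)
      stop("equilibrium search failed to converge from any start")
    ## cluster
    reps <- list(sols[[1L]])
    for (x in sols[-1]) {
      d <- vapply(reps, function(r)
        max(abs(x - r)) / max(max(abs(r)), 1e-12), numeric(1))
      if (all(d > 1e-6)) reps[[length(reps) + 1L]] <- x
    }
    best <- which.min(resids)
    new("EquilibriumReport", state = sols[[best]],
        residual = resids[best], nEquilibria = length(reps),
        agree = length(reps) == 1L, solutions = reps)
  })

setMethod("show", "EquilibriumReport", function(object) {
  cat(sprintf("EquilibriumReport: %d distinct equilibrium cluster(s), residual %.2e\n",
              object@nEquilibria, object@residual))
})

#' Empirical steady-state influence signs
#'
#' Numerical counterpart of the structural influence matrix for one
#' specific parameterisation: for each variable j a persistent constant
#' input `+eps` is added to its equation, the equilibrium is re-solved,
#' and the sign of the steady-state change of every variable i is
#' recorded (`0` below tolerance).  Under a `+` structural determinant,
#' these signs must fall inside the structural classes: an empirical
#' `+` can never land on a structural `-` (and vice versa), while `?`
#' entries may go either way depending on the parameters.
#'
#' @param model a [HillModel-class] with a unique stable equilibrium.
#' @param eps perturbation size; default `1e-3` times the equilibrium
#'   scale.
#' @param tolRel relative tolerance below which a change counts as
#'   zero.
#' @param seed seed for the equilibrium multistarts.
#' @param equilibrium optional precomputed [EquilibriumReport-class].
#' @return character matrix over `{"+", "-", "0"}` with entry (i, j)
#'   the response sign of variable i to an input on equation j.
#' @export
empiricalInfluence <- function(model, eps = NULL, tolRel = 1e-9,
                               seed = 1L, equilibrium = NULL) {
  base <- equilibrium %||% findEquilibrium(model, seed = seed)
  x0 <- base@state
  scale <- max(mean(abs(x0)), 1e-8)
  eps <- eps %||% (1e-3 * scale)
  n <- length(model@nodes)
  out <- matrix("0", n, n, dimnames = list(model@nodes, model@nodes))
  for (j in model@nodes) {
    bias <- stats::setNames(eps, j)
    rep <- findEquilibrium(model, nStarts = 4L, seed = seed, bias = bias,
                           warmStart = x0)
    delta <- rep@state - x0
    tolAbs <- tolRel * pmax(abs(x0), scale)
    cls <- ifelse(abs(delta) <= tolAbs, "0", ifelse(delta > 0, "+", "-"))
    out[, j] <- cls
  }
  out
}
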