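## The delayed AAV model and its one-state reduction.

#' Build the quantitative 20-variable delayed AAV model
#'
#' Hill-parameterised realisation of the AVP-ANP-vascular smooth muscle
#' network: intracellular contraction machinery (states `x_1`..`x_15`,
#' a monotone acyclic cascade driven by the ANP receptor and V1R
#' inputs) closed through the systemic loop `x_16`..`x_20` (heart
#' myocytes, AVP nuclei, NTS and the two stretch-receptor populations).
#' Three arcs carry endocrine transmission delays: the ANP loop into
#' the heart-myocyte node (`tau1`), and the two stretch-receptor routes
#' into NTS (`tau2` aortic/carotid, `tau3` atrial).  Calmodulin
#' (`x_6`) integrates an activating IP3R input and an inhibitory PMCA
#' input through a single bivariate Hill term.
#'
#' @param pars parameter assignment from [sampleParameters()] for the
#'   AAV topology; its `delays` element supplies `tau1`, `tau2`,
#'   `tau3`.
#' @return a [HillModel-class] with 20 states and three delayed terms.
#' @examples
#' m <- buildAAVModel(sampleParameters(aavGraph(), seed = 1))
#' isInternalDag(aavGraph(), paste0("x_", 1:15))
#' @export
buildAAVModel <- function(pars) {
  graph <- aavGraph()
  delays <- pars$delays %||% c(tau1 = 3, tau2 = 3, tau3 = 3)
  e <- graph@edges
  nodes <- graph@nodes
  rhs <- stats::setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) rhs[[v]] <- list()
  hp <- function(from, to) {
    p <- pars$hill[[paste0(from, "->", to)]]
    if (is.null(p)) stop("missing Hill parameters for arc ",
                         from, "->", to)
    p
  }
  for (i in seq_len(nrow(e))) {
    from <- e$from[i]; to <- e$to[i]
    if (to == "x_6") next        # handled as one bivariate term below
    d <- e$delay[i]
    p <- hp(from, to)
    tm <- if (e$sign[i] > 0)
      fTerm(from, alpha = p[[1]], beta = p[[2]], nH = pars$nH, delay = d)
    else
      gTerm(from, gamma = p[[1]], delta = p[[2]], nH = pars$nH, delay = d)
    rhs[[to]] <- c(rhs[[to]], list(tm))
  }
  ## calmodulin: activated by IP3R calcium release, counteracted by the
  ## PMCA pump -> h(x_10, x_13), increasing in x_10, decreasing in x_13
  pa <- hp("x_10", "x_6"); pb <- hp("x_13", "x_6")
  rhs[["x_6"]] <- list(hTerm("x_10", "x_13", sigma = pa[[1]],
                             eps = pa[[2]], eta = pb[[2]], nH = pars$nH))
  th <- pars$theta[nodes]
  ## remap the fixture delays to the sampled ones, if they differ
  m <- hillModel(nodes, th, rhs)
  m <- setAAVDelays(m, delays)
  m
}

## Delay bookkeeping: the three delayed arcs of the AAV model.
aavDelayedArcs <- function() {
  list(tau1 = c("x_19", "x_16"), tau2 = c("x_20", "x_18"),
       tau3 = c("x_19", "x_18"))
}

setAAVDelays <- function(model, delays) {
  arcs <- aavDelayedArcs()
  for (nm in names(arcs)) {
    a <- arcs[[nm]]
    terms <- model@rhs[[a[2]]]
    for (k in seq_along(terms)) {
      if (identical(terms[[k]]$args[[1]], a[1]))
        terms[[k]]$delay <- unname(delays[[nm]])
    }
    model@rhs[[a[2]]] <- terms
  }
  model
}

aavModelDelays <- function(model) {
  arcs <- aavDelayedArcs()
  out <- numeric(0)
  for (nm in names(arcs)) {
    a <- arcs[[nm]]
    for (tm in model@rhs[[a[2]]]) {
      if (identical(tm$args[[1]], a[1])) out[nm] <- tm$delay
    }
  }
  out
}

#' Reduce the AAV model to one state with three delayed feedbacks
#'
#' All nodes except the actomyosin state evolve on time scales
#' dominated by the loop delays, so they are treated as instantaneous
#' monotone maps: the internal cascade (`x_2`..`x_15`, acyclic) becomes
#' a static response to the heart-myocyte and AVP inputs, and the
#' external nodes become delayed static feedback of the state on
#' itself.  The result is a scalar delay differential equation
#' \deqn{\Theta \dot x_1(t) + x_1(t) =
#'   \Phi\big(x_{16}(t), x_{17}(t)\big)}
#' with \eqn{x_{16}} an increasing function of \eqn{x_1(t-\tau_1)}
#' (inhibitory on \eqn{x_1}) and \eqn{x_{17}} a decreasing function of
#' \eqn{x_1(t-\tau_2)} and \eqn{x_1(t-\tau_3)} (activating on
#' \eqn{x_1}).
#'
#' @param model the 20-variable [HillModel-class] from
#'   [buildAAVModel()].
#' @return a [ReducedAAV-class].
#' @export
reduceAAV <- function(model) {
  internal <- paste0("x_", 1:15)
  if (!identical(model@nodes, paste0("x_", 1:20)))
    stop("input is not the 20-variable AAV model")
  g <- graphFromModel(model)
  if (!isInternalDag(g, internal))
    stop("internal subsystem has cycles; reduction is ill-defined")
  tau <- aavModelDelays(model)
  if (length(tau) != 3L) stop("delayed arcs not found in model")
  new("ReducedAAV", model = model, stateNode = "x_1",
      theta = unname(model@theta[["x_1"]]), tau = tau,
      gainScale = 1, anchor = NA_real_)
}

## Signed digraph implied by a model's terms (used for structure
## checks; nested composed terms contribute their leaf sources).
graphFromModel <- function(model) {
  rows <- list()
  for (v in model@nodes) {
    for (s in termSources(model@rhs[[v]])) {
      sg <- signDepTerms(model@rhs[[v]], s)
      rows[[length(rows) + 1L]] <- data.frame(
        from = s, to = v, sign = if (length(sg) == 1L) sg else NA_real_,
        delay = 0)
    }
  }
  signedDigraph(model@nodes, do.call(rbind, rows))
}

setMethod("show", "ReducedAAV", function(object) {
  cat(sprintf(
    "ReducedAAV: state %s, theta = %.3g min, delays (%.3g, %.3g, %.3g) min%s\n",
    object@stateNode, object@theta, object@tau[["tau1"]],
    object@tau[["tau2"]], object@tau[["tau3"]],
    if (object@gainScale != 1)
      sprintf(", gain scale %.3g", object@gainScale) else ""))
})

#' Modulate the effective loop gain of a reduced model
#'
#' Rescales deviations of the delayed state around an anchor (by
#' default the equilibrium) before they enter the feedback maps:
#' `kappa = 1` leaves the model untouched, `kappa = 0` freezes the
#' feedback at the anchor, and other values multiply every linearised
#' loop gain by exactly `kappa` while keeping the equilibrium fixed.
#' Used to probe the oscillation onset predicted by the linear
#' analysis.
#'
#' @param reduced a [ReducedAAV-class].
#' @param kappa nonnegative gain multiplier.
#' @param anchor operating point (defaults to the model equilibrium).
#' @return the modified [ReducedAAV-class].
#' @export
setGainScale <- function(reduced, kappa, anchor = NULL) {
  if (kappa < 0) stop("kappa must be nonnegative")
  anchor <- anchor %||% reducedEquilibrium(reduced)
  initialize(reduced, gainScale = kappa, anchor = anchor)
}

## Core recursive evaluation: the value of any non-state node as a
## static function of delayed state values.  `x1lag(d)` returns the
## state at lag d; term delays accumulate along composition paths.
reducedNodeValue <- function(reduced, node, x1lag) {
  model <- reduced@model
  state <- reduced@stateNode
  kappa <- reduced@gainScale
  anchor <- reduced@anchor
  lagged <- function(d) {
    v <- x1lag(d)
    if (kappa != 1) max(anchor + kappa * (v - anchor), 0) else v
  }
  ev <- function(lbl, d) {
    if (lbl == state) return(lagged(d))
    evalTermsWith(model@rhs[[lbl]], ev, d)
  }
  ev(node, 0)
}

## Right-hand side of the scalar reduced DDE.
reducedRHS <- function(reduced, x1lag) {
  model <- reduced@model
  state <- reduced@stateNode
  kappa <- reduced@gainScale
  anchor <- reduced@anchor
  lagged <- function(d) {
    v <- x1lag(d)
    if (kappa != 1) max(anchor + kappa * (v - anchor), 0) else v
  }
  ev <- function(lbl, d) {
    if (lbl == state) return(lagged(d))
    evalTermsWith(model@rhs[[lbl]], ev, d)
  }
  evalTermsWith(model@rhs[[state]], ev, 0)
}

#' Static composed maps of the reduced AAV model
#'
#' Returns the monotone maps that define the reduction: `phi(x16, x17)`,
#' the instantaneous steady-state response of the actomyosin drive to
#' the two systemic inputs (decreasing in `x16`, increasing in `x17`);
#' `f1(u)`, the heart-myocyte output as a function of the (delayed)
#' state (increasing); and `psi(u2, u3)`, the AVP-nuclei output as a
#' function of the state at the two stretch-receptor delays (decreasing
#' in both).
#'
#' @param reduced a [ReducedAAV-class].
#' @return list of vectorised functions `phi`, `f1`, `psi`.
#' @export
reducedStaticMaps <- function(reduced) {
  model <- reduced@model
  state <- reduced@stateNode
  evalWithInputs <- function(target, inputs, stateValue = 0) {
    ev <- function(lbl, d) {
      if (lbl %in% names(inputs)) return(inputs[[lbl]])
      if (lbl == state) return(stateValue)
      evalTermsWith(model@rhs[[lbl]], ev, d)
    }
    if (target == "rhs") evalTermsWith(model@rhs[[state]], ev, 0)
    else ev(target, 0)
  }
  phi <- function(x16, x17)
    mapply(function(a, b)
      evalWithInputs("rhs", c(x_16 = a, x_17 = b)), x16, x17)
  f1 <- function(u)
    vapply(u, function(v) {
      ev <- function(lbl, d) {
        if (lbl == state) return(v)
        evalTermsWith(model@rhs[[lbl]], ev, d)
      }
      ev("x_16", 0)
    }, numeric(1))
  psi <- function(u2, u3)
    mapply(function(a, b) {
      ev <- function(lbl, d) {
        if (lbl == "x_20") return(evalChain(model, state, "x_20", a))
        if (lbl == "x_19") return(evalChain(model, state, "x_19", b))
        if (lbl == state) stop("unexpected state reference")
        evalTermsWith(model@rhs[[lbl]], ev, d)
      }
      ev("x_17", 0)
    }, u2, u3)
  list(phi = phi, f1 = f1, psi = psi)
}

## Value of `target` when the state takes value u (static chain).
evalChain <- function(model, state, target, u) {
  ev <- function(lbl, d) {
    if (lbl == state) return(u)
    evalTermsWith(model@rhs[[lbl]], ev, d)
  }
  ev(target, 0)
}

#' Equilibrium of the reduced AAV model
#'
#' The unique fixed point of the composed static map: solves
#' \eqn{u = \Phi(F_1(u), \Psi(u, u))} by bracketed root finding on
#' `[0, B]`, `B` a bound from the saturating Hill forms.
#'
#' @param reduced a [ReducedAAV-class].
#' @param tol root tolerance.
#' @return the scalar equilibrium value.
#' @export
reducedEquilibrium <- function(reduced, tol = 1e-12) {
  const <- function(u) function(d) u
  Fmap <- function(u) reducedRHS(reduced, const(u))
  B <- termsUpperBound(reduced@model@rhs[[reduced@stateNode]]) + 1
  lo <- 0
  flo <- Fmap(lo) - lo
  if (abs(flo) < tol) return(lo)
  stats::uniroot(function(u) Fmap(u) - u, c(lo, B), tol = tol)$root
}

## Forward-mode derivative of `target`'s static value with respect to a
## designated free node, all other leaves held at their equilibrium
## statics.
staticPartial <- function(model, state, target, input, eq) {
  ev2 <- function(lbl, d) {
    if (lbl == input) {
      v <- if (input == state) eq else evalChain(model, state, input, eq)
      return(c(v, 1))
    }
    if (lbl == state) return(c(eq, 0))
    evalTermsGradWith(model@rhs[[lbl]], ev2, d)
  }
  if (target == "rhs")
    evalTermsGradWith(model@rhs[[state]], ev2, 0)[2]
  else ev2(target, 0)[2]
}

## As above, but `input` is reached only through a blocked-path choice:
## derivative of x_17 with respect to the state THROUGH a single
## stretch-receptor route, freezing the other route at equilibrium.
pathPartial <- function(model, state, target, via, eq) {
  others <- setdiff(c("x_19", "x_20"), via)
  ev2 <- function(lbl, d) {
    if (lbl %in% others) return(c(evalChain(model, state, lbl, eq), 0))
    if (lbl == state) return(c(eq, 1))
    evalTermsGradWith(model@rhs[[lbl]], ev2, d)
  }
  ev2(target, 0)[2]
}

#' Linearise the reduced AAV model around its equilibrium
#'
#' Computes the absolute derivatives of the composed monotone maps at
#' the equilibrium by exact forward-mode differentiation of the Hill
#' cascade: `k1 = |dPhi/dx16|`, `k2 = |dPhi/dx17|`, `mu1 = |dx16/dx1|`,
#' and `mu2`, `mu3` the sensitivities of the AVP output through the
#' aortic/carotid and atrial stretch-receptor routes.  The deviation
#' dynamics are
#' \eqn{\Theta \dot y + y = -p\,y(t-\tau_1) - q\,y(t-\tau_2)} with
#' `p = k1*mu1` and `q = k2*(mu2 + mu3)` (the two AVP loops share
#' `tau2 = tau3`).
#'
#' @param reduced a [ReducedAAV-class].
#' @param equilibrium optional precomputed equilibrium.
#' @return a [LinearizedAAV-class].
#' @export
linearizeAAV <- function(reduced, equilibrium = NULL) {
  eq <- equilibrium %||% reducedEquilibrium(reduced)
  model <- reduced@model
  state <- reduced@stateNode
  kappa <- reduced@gainScale
  k1 <- abs(staticPartial(model, state, "rhs", "x_16", eq))
  k2 <- abs(staticPartial(model, state, "rhs", "x_17", eq))
  mu1 <- abs(staticPartial(model, state, "x_16", state, eq))
  mu2 <- abs(pathPartial(model, state, "x_17", "x_20", eq))
  mu3 <- abs(pathPartial(model, state, "x_17", "x_19", eq))
  new("LinearizedAAV", theta = reduced@theta, k1 = k1, k2 = k2,
      mu1 = kappa * mu1, mu2 = kappa * mu2, mu3 = kappa * mu3,
      tau = reduced@tau, equilibrium = eq)
}

#' @describeIn accessors loop gains `p = k1*mu1`, `q = k2*(mu2+mu3)` of
#'   a linearised reduced model.
#' @export
setMethod("loopGains", "LinearizedAAV", function(object) {
  c(p = object@k1 * object@mu1,
    q = object@k2 * (object@mu2 + object@mu3))
})

setMethod("show", "LinearizedAAV", function(object) {
  g <- loopGains(object)
  cat(sprintf(
    "LinearizedAAV: theta = %.3g min, p = %.4g, q = %.4g, equilibrium = %.4g\n",
    object@theta, g[["p"]], g[["q"]], object@equilibrium))
})

## ---- DDE simulation -------------------------------------------------

ddeTrajectory <- function(times, ymat, labels, meta) {
  st <- unname(ymat)
  colnames(st) <- labels
  if (!all(is.finite(st))) stop("non-finite state in DDE integration")
  new("Trajectory", time = times, state = st, metadata = meta)
}

#' @describeIn simulateDDE full delayed network: every delayed term
#'   reads the lagged state from the integrator history (constant
#'   pre-history equal to `init`).
#' @param rtol,atol integration tolerances.
#' @export
setMethod("simulateDDE", "HillModel",
  function(model, init, horizon, step, rtol = 1e-8, atol = 1e-10, ...) {
    if (horizon <= 0) stop("horizon must be positive")
    y0 <- stats::setNames(as.numeric(init[model@nodes]), model@nodes)
    if (any(is.na(y0))) stop("init must cover every state")
    th <- model@theta
    idx <- stats::setNames(seq_along(model@nodes), model@nodes)
    deriv <- function(t, y, parms) {
      names(y) <- model@nodes
      getx <- function(lbl, lag) {
        if (lag <= 0) return(y[[lbl]])
        tl <- t - lag
        if (tl <= 0) y0[[lbl]]
        else deSolve::lagvalue(tl, idx[[lbl]])
      }
      rhs <- vapply(model@nodes, function(v)
        evalTermsWith(model@rhs[[v]], getx), numeric(1))
      list((rhs - y) / th)
    }
    times <- seq(0, horizon, by = step)
    sol <- deSolve::dede(y0, times, deriv, parms = NULL,
                         rtol = rtol, atol = atol)
    ddeTrajectory(sol[, 1], sol[, -1, drop = FALSE], model@nodes,
                  list(step = step, delays = aavModelDelays(model)))
  })

#' @describeIn simulateDDE scalar reduced model; `init` is the constant
#'   pre-history of the actomyosin state (default: equilibrium
#'   perturbed by +1 percent in effective feedback units, i.e. the
#'   perturbation shrinks with the gain scale so it stays within the
#'   responsive range of the saturating feedback maps).
#' @export
setMethod("simulateDDE", "ReducedAAV",
  function(model, init = NULL, horizon, step, rtol = 1e-8, atol = 1e-10,
           ...) {
    if (horizon <= 0) stop("horizon must be positive")
    y0 <- init %||% {
      eq <- reducedEquilibrium(model)
      eq * (1 + 0.01 / max(model@gainScale, 1))
    }
    deriv <- function(t, y, parms) {
      x1lag <- function(d) {
        if (d <= 0) return(y[1])
        tl <- t - d
        if (tl <= 0) y0 else deSolve::lagvalue(tl, 1)
      }
      list((reducedRHS(model, x1lag) - y[1]) / model@theta)
    }
    times <- seq(0, horizon, by = step)
    sol <- deSolve::dede(c(x = y0), times, deriv, parms = NULL,
                         rtol = rtol, atol = atol)
    ddeTrajectory(sol[, 1], sol[, -1, drop = FALSE], model@stateNode,
                  list(step = step, delays = model@tau,
                       gainScale = model@gainScale))
  })

#' @describeIn simulateDDE linearised deviation dynamics
#'   \eqn{\Theta\dot y + y = -k_1\mu_1 y(t-\tau_1) - k_2\mu_2
#'   y(t-\tau_2) - k_2\mu_3 y(t-\tau_3)}; `init` is the constant
#'   pre-history of the deviation.
#' @export
setMethod("simulateDDE", "LinearizedAAV",
  function(model, init, horizon, step, rtol = 1e-10, atol = 1e-12, ...) {
    if (horizon <= 0) stop("horizon must be positive")
    y0 <- as.numeric(init)
    tau <- model@tau
    a1 <- model@k1 * model@mu1
    a2 <- model@k2 * model@mu2
    a3 <- model@k2 * model@mu3
    deriv <- function(t, y, parms) {
      lag <- function(d) {
        if (d <= 0) return(y[1])
        tl <- t - d
        if (tl <= 0) y0 else deSolve::lagvalue(tl, 1)
      }
      rhs <- -a1 * lag(tau[["tau1"]]) - a2 * lag(tau[["tau2"]]) -
        a3 * lag(tau[["tau3"]])
      list((rhs - y[1]) / model@theta)
    }
    times <- seq(0, horizon, by = step)
    sol <- deSolve::dede(c(y = y0), times, deriv, parms = NULL,
                         rtol = rtol, atol = atol)
    ddeTrajectory(sol[, 1], sol[, -1, drop = FALSE], "y",
                  list(step = step, delays = tau))
  })

## ---- Oscillation detection ------------------------------------------

#' Detect sustained oscillations in a trajectory
#'
#' Discards an initial transient, splits the remainder into two
#' windows, and declares sustained oscillation when the peak-to-peak
#' amplitude of the final window exceeds `threshold` times the state
#' scale AND is not decaying (final/previous amplitude ratio at least
#' 0.95).  The period is estimated from mean peak spacing in the final
#' window.
#'
#' @param traj a [Trajectory-class].
#' @param transientFraction fraction of the record discarded as
#'   transient.
#' @param threshold relative amplitude below which the signal counts as
#'   settled.
#' @param column state column to analyse (default first).
#' @return an [OscillationReport-class].
#' @examples
#' tt <- seq(0, 100, by = 0.05)
#' tr <- new("Trajectory", time = tt,
#'           state = cbind(y = 1 + sin(tt)), metadata = list())
#' oscillating(detectOscillation(tr))       # TRUE, period ~ 2*pi
#' @export
detectOscillation <- function(traj, transientFraction = 0.5,
                              threshold = 1e-4, column = 1L) {
  t <- traj@time
  y <- traj@state[, column]
  keep <- t >= t[1] + transientFraction * (t[length(t)] - t[1])
  t <- t[keep]; y <- y[keep]
  half <- t[1] + (t[length(t)] - t[1]) / 2
  prev <- y[t < half]
  fin <- y[t >= half]
  tfin <- t[t >= half]
  scale <- max(abs(y), 1e-12)
  ampPrev <- diff(range(prev))
  ampFin <- diff(range(fin))
  sustained <- ampFin >= threshold * scale &&
    (ampPrev <= 0 || ampFin / ampPrev >= 0.95)
  ## cycles counted as upward crossings of the window midline, which is
  ## robust against small high-frequency ripples riding on the
  ## dominant mode
  mid <- (max(fin) + min(fin)) / 2
  nfin <- length(fin)
  up <- which(fin[-nfin] < mid & fin[-1L] >= mid)
  if (sustained && length(up) < 3L)
    stop("oscillation flagged but fewer than 3 cycles resolved; ",
         "lengthen the trajectory or reduce the output step")
  period <- if (sustained) mean(diff(tfin[up])) else NA_real_
  new("OscillationReport", oscillating = sustained,
      amplitude = ampFin, period = period,
      transientFraction = transientFraction, nPeaks = length(up))
}

#' @rdname accessors
#' @export
setMethod("oscillating", "OscillationReport", function(object)
  object@oscillating)

setMethod("show", "OscillationReport", function(object) {
  if (object@oscillating)
    cat(sprintf("OscillationReport: sustained, period %.3g min, amplitude %.3g\n",
                object@period, object@amplitude))
  else
    cat(sprintf("OscillationReport: settled (amplitude %.3g)\n",
                object@amplitude))
})
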