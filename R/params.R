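#' Physiological parameter ranges
#'
#' Default sampling ranges for the synthetic parameter generator.  Time
#' constants follow the four physiological time-scale classes of the
#' networks: endocrine signalling 30-60 min, stretch-receptor
#' responses 2-4.5 min, nerve conduction 0.1-1 min, and intracellular
#' signal transduction 0.01-0.5 min.  Hill coefficients are drawn from
#' moderate ranges chosen so equilibria are interior and positive; loop
#' delays span 2-4 min.
#'
#' @param thetaRanges,hillRanges,delayRange,nH overrides of the
#'   defaults.
#' @return a [ParameterRanges-class].
#' @export
parameterRanges <- function(
    thetaRanges = list(endocrine = c(30, 60), stretch = c(2, 4.5),
                       nerve = c(0.1, 1), intracellular = c(0.01, 0.5)),
    hillRanges = list(alpha = c(0.5, 2), beta = c(0.5, 2),
                      gamma = c(0.5, 2), delta = c(0.5, 2),
                      sigma = c(0.5, 2), eps = c(0.5, 2),
                      eta = c(0.5, 2)),
    delayRange = c(2, 4), nH = 2) {
  new("ParameterRanges", thetaRanges = thetaRanges,
      hillRanges = hillRanges, delayRange = delayRange, nH = nH)
}

setMethod("show", "ParameterRanges", function(object) {
  cat("ParameterRanges:\n")
  for (nm in names(object@thetaRanges))
    cat(sprintf("  theta[%s]: [%g, %g] min\n", nm,
                object@thetaRanges[[nm]][1], object@thetaRanges[[nm]][2]))
  cat(sprintf("  delays: [%g, %g] min; Hill exponent %g\n",
              object@delayRange[1], object@delayRange[2], object@nH))
})

#' Sample a full parameter assignment for a network topology
#'
#' Draws, reproducibly from an integer seed (Mersenne-Twister), a time
#' constant for every node from its class range, a Hill coefficient
#' pair for every arc (activation: `alpha`, `beta`; inhibition:
#' `gamma`, `delta`), and a delay from the delay range for every
#' delayed arc.  With `tieDelays = TRUE` (default) the two
#' stretch-receptor loop delays are set equal (`tau3 = tau2`),
#' reflecting that both AVP feedback routes share the slow endocrine
#' step that dominates their latency.
#'
#' @param topology a [SignedDigraph-class] whose nodes carry time-scale
#'   classes.
#' @param ranges a [ParameterRanges-class].
#' @param seed integer seed.
#' @param tieDelays force `tau3 = tau2` for the AAV topology.
#' @return list with elements `theta` (named), `hill` (named list of
#'   coefficient pairs keyed `"from->to"`), `nH`, `delays` (named, only
#'   when the topology has delayed arcs) and `seed`.
#' @examples
#' pars <- sampleParameters(aarFullGraph(), seed = 42)
#' range(pars$theta[c("ACO", "JGC")])   # inside [30, 60]
#' @export
sampleParameters <- function(topology, ranges = parameterRanges(),
                             seed = 1L, tieDelays = TRUE) {
  cls <- nodeClasses(topology)
  if (any(is.na(cls)))
    stop("every node needs a time-scale class: ",
         paste(names(cls)[is.na(cls)], collapse = ", "))
  unknownCls <- setdiff(unique(cls), names(ranges@thetaRanges))
  if (length(unknownCls))
    stop("no theta range for class: ", paste(unknownCls, collapse = ", "))
  set.seed(seed, kind = "Mersenne-Twister")
  theta <- vapply(cls, function(k) {
    r <- ranges@thetaRanges[[k]]
    stats::runif(1, r[1], r[2])
  }, numeric(1))
  e <- topology@edges
  hill <- list()
  hr <- ranges@hillRanges
  for (i in seq_len(nrow(e))) {
    key <- paste0(e$from[i], "->", e$to[i])
    hill[[key]] <- if (e$sign[i] > 0)
      c(alpha = stats::runif(1, hr$alpha[1], hr$alpha[2]),
        beta = stats::runif(1, hr$beta[1], hr$beta[2]))
    else
      c(gamma = stats::runif(1, hr$gamma[1], hr$gamma[2]),
        delta = stats::runif(1, hr$delta[1], hr$delta[2]))
  }
  out <- list(theta = theta, hill = hill, nH = ranges@nH, seed = seed)
  if (any(e$delay > 0)) {
    dr <- ranges@delayRange
    tau1 <- stats::runif(1, dr[1], dr[2])
    tau2 <- stats::runif(1, dr[1], dr[2])
    tau3 <- if (tieDelays) tau2 else stats::runif(1, dr[1], dr[2])
    out$delays <- c(tau1 = tau1, tau2 = tau2, tau3 = tau3)
  }
  out
}

#' Persistent perturbation protocol
#'
#' Constant additive input `+eps` applied to the dynamic equation of
#' one target variable from time zero — the excitation used to probe
#' steady-state influence signs.  The returned object serialises
#' losslessly through JSON.
#'
#' @param model a [HillModel-class].
#' @param target label of the perturbed equation.
#' @param eps input magnitude (may be zero or negative).
#' @return object of class `"perturbationProtocol"` with fields
#'   `target`, `eps` and `bias` (named vector usable as the `bias`
#'   argument of [simulateODE()] and [findEquilibrium()]).
#' @export
perturbationProtocol <- function(model, target, eps) {
  if (!(target %in% model@nodes)) stop("unknown target: ", target)
  structure(list(target = target, eps = eps,
                 bias = stats::setNames(eps, target)),
            class = "perturbationProtocol")
}

#' @export
print.perturbationProtocol <- function(x, ...) {
  cat(sprintf("perturbationProtocol: +%g on equation %s\n", x$eps,
              x$target))
  invisible(x)
}
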