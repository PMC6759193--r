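## The quantitative AAR model.
##
## Each state obeys Theta_i dx/dt + x_i = sum of monotone Hill terms,
## one term per incoming arc of the full 10-node network: activating
## arcs contribute f terms, inhibitory arcs g terms.

aarEdgeTerm <- function(pars, from, to, sign) {
  key <- paste0(from, "->", to)
  hp <- pars$hill[[key]]
  if (is.null(hp)) stop("missing Hill parameters for arc ", key)
  if (sign > 0) fTerm(from, alpha = hp[[1]], beta = hp[[2]], nH = pars$nH)
  else gTerm(from, gamma = hp[[1]], delta = hp[[2]], nH = pars$nH)
}

modelFromGraph <- function(graph, pars) {
  e <- graph@edges
  rhs <- stats::setNames(vector("list", length(graph@nodes)), graph@nodes)
  for (v in graph@nodes) rhs[[v]] <- list()
  for (i in seq_len(nrow(e))) {
    tm <- aarEdgeTerm(pars, e$from[i], e$to[i], e$sign[i])
    rhs[[e$to[i]]] <- c(rhs[[e$to[i]]], list(tm))
  }
  hillModel(graph@nodes, pars$theta[graph@nodes], rhs)
}

#' Build the quantitative 10-variable AAR model
#'
#' Hill-parameterised realisation of the full AVP-ANP-RAAS network: one
#' activation (`f`) or inhibition (`g`) term per arc of
#' [aarFullGraph()], with per-node time constants.  All qualitative
#' results are independent of the particular Hill forms; the
#' parameterisation exists to simulate, locate equilibria and test the
#' structural predictions numerically.
#'
#' @param pars parameter assignment from [sampleParameters()] for the
#'   AAR topology.
#' @return a [HillModel-class] with states
#'   ACO, JGC, HMY, SPN, DTC, VSM, ASR, ACR, NTS, SFO.
#' @examples
#' m <- buildAARModel(sampleParameters(aarFullGraph(), seed = 1))
#' signPattern(interactionMatrix(m))["ACO", "JGC"]   # +1
#' @export
buildAARModel <- function(pars) {
  modelFromGraph(aarFullGraph(), pars)
}

#' Fast nodes eliminated when reducing the AAR model
#'
#' The stretch-receptor and neural relays respond one to two orders of
#' magnitude faster than the endocrine nodes, so their equations are
#' replaced by instantaneous steady-state responses.
#'
#' @return character vector of node labels.
#' @export
aarFastNodes <- function() c("ASR", "ACR", "NTS", "SFO")

#' Split the reduced AAR model into its two regulation schemes
#'
#' The six-variable reduced network contains two coexisting negative
#' feedback schemes acting on the same monotone core
#' \{ACO, JGC, HMY, SPN\}: one closes through the renal distal tubule
#' and collecting duct (DTC, blood volume route), the other through
#' vascular smooth muscle (VSM, vasoconstriction route).  DTC and VSM
#' do not interact, so each scheme is analysed on its own.
#'
#' @param reduced the 6-variable [HillModel-class] produced by
#'   `reduceTimeScale(model, aarFastNodes())`.
#' @return list with elements `dtc` and `vsm`, each a 5-variable
#'   [HillModel-class].
#' @examples
#' pars <- sampleParameters(aarFullGraph(), seed = 1)
#' schemes <- splitAAR(reduceTimeScale(buildAARModel(pars), aarFastNodes()))
#' identical(signPattern(interactionMatrix(schemes$dtc)),
#'           signPattern(sigmaDTC()))
#' @export
splitAAR <- function(reduced) {
  expect <- c("ACO", "JGC", "HMY", "SPN", "DTC", "VSM")
  if (!setequal(nodeLabels(reduced), expect))
    stop("input is not the 6-variable reduced AAR model")
  list(dtc = projectModel(reduced, setdiff(expect, "VSM")),
       vsm = projectModel(reduced, setdiff(expect, "DTC")))
}

#' Sample a parameterisation and return the two 5-variable schemes
#'
#' Convenience wrapper: samples Hill parameters and time constants for
#' the full AAR topology, builds the model, reduces the fast nodes and
#' splits the result.
#'
#' @param seed integer seed.
#' @param ranges a [ParameterRanges-class].
#' @return list with elements `dtc`, `vsm` (5-variable models),
#'   `reduced` (6-variable model) and `full` (10-variable model).
#' @export
sampleAARSchemes <- function(seed, ranges = parameterRanges()) {
  pars <- sampleParameters(aarFullGraph(), ranges = ranges, seed = seed)
  full <- buildAARModel(pars)
  reduced <- reduceTimeScale(full, aarFastNodes())
  c(splitAAR(reduced), list(reduced = reduced, full = full))
}
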