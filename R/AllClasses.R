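#' @import methods
NULL

SIGN_CLASSES <- c("+", "-", "0", "?")

#' Signed interaction digraph
#'
#' Directed graph whose arcs carry an activation (+1) or inhibition (-1)
#' sign and an optional transmission delay in minutes.  Nodes represent
#' physiological agents (secretory organs, receptors, intracellular
#' species); arcs represent hormonal, mechanical or neural influence.
#' Self-arcs are disallowed: first-order self-degradation is part of the
#' dynamical convention and enters only through the -1 diagonal of the
#' associated [SignMatrix-class].
#'
#' @slot nodes ordered character vector of unique node labels.
#' @slot nodeClass character vector parallel to `nodes`, giving the
#'   time-scale class of each node (`"endocrine"`, `"stretch"`,
#'   `"nerve"`, `"intracellular"`, or `NA`).
#' @slot theta numeric vector parallel to `nodes`: nominal time constant
#'   in minutes (may be `NA` when unspecified).
#' @slot edges `data.frame` with columns `from`, `to`, `sign`
#'   (in `{-1, +1}`) and `delay` (nonnegative minutes).
#'
#' @seealso [signedDigraph()], [interactionMatrix()], [enumerateCycles()]
#' @export
setClass("SignedDigraph",
  representation(nodes = "character", nodeClass = "character",
                 theta = "numeric", edges = "data.frame"),
  validity = function(object) {
    msg <- character(0)
    n <- object@nodes
    if (anyDuplicated(n)) msg <- c(msg, "node labels must be unique")
    if (length(object@nodeClass) != length(n))
      msg <- c(msg, "nodeClass must be parallel to nodes")
    if (length(object@theta) != length(n))
      msg <- c(msg, "theta must be parallel to nodes")
    e <- object@edges
    need <- c("from", "to", "sign", "delay")
    if (!all(need %in% names(e))) {
      msg <- c(msg, "edges must have columns from, to, sign, delay")
    } else if (nrow(e) > 0L) {
      if (!all(e$from %in% n) || !all(e$to %in% n))
        msg <- c(msg, "edge endpoints must be declared nodes")
      if (!all(e$sign %in% c(-1, 1)))
        msg <- c(msg, "edge signs must be +1 or -1")
      if (any(e$from == e$to))
        msg <- c(msg, "self-arcs are not allowed")
      if (any(e$delay < 0))
        msg <- c(msg, "delays must be nonnegative")
      if (anyDuplicated(paste(e$from, e$to)))
        msg <- c(msg, "at most one arc per ordered node pair")
    }
    if (length(msg)) msg else TRUE
  })

#' Sign matrix of a dynamical network
#'
#' Square sign pattern of the Jacobian of a network in the form
#' \eqn{\Theta_i \dot x_i + x_i = \sum \textrm{(monotone terms)}}: the
#' diagonal is identically -1 (first-order self-decay) and the
#' off-diagonal entry \eqn{(i, j)} is the sign of the arc from node j to
#' node i, or 0.
#'
#' @slot mat numeric matrix with entries in `{-1, 0, +1}`, row and
#'   column names equal to the node labels, and -1 on the diagonal.
#' @seealso [signMatrix()], [structuralInfluenceMatrix()]
#' @export
setClass("SignMatrix", representation(mat = "matrix"),
  validity = function(object) {
    m <- object@mat
    if (nrow(m) != ncol(m)) return("matrix must be square")
    if (is.null(rownames(m)) || is.null(colnames(m)) ||
        !identical(rownames(m), colnames(m)))
      return("row and column names must be identical node labels")
    if (!all(m %in% c(-1, 0, 1))) return("entries must be in {-1, 0, +1}")
    if (!all(diag(m) == -1)) return("diagonal entries must all be -1")
    TRUE
  })

#' Structural influence matrix
#'
#' Square matrix over the four qualitative classes `{+, -, 0, ?}`. Entry
#' \eqn{(i, j)} classifies the sign of the steady-state variation of
#' variable i in response to a persistent positive input on the dynamic
#' equation of variable j, over all positive parameter magnitudes
#' compatible with the sign structure: `+` always positive, `-` always
#' negative, `0` always zero, `?` parameter-dependent.
#'
#' @slot mat character matrix with entries in `{"+", "-", "0", "?"}` and
#'   matching row/column labels.
#' @seealso [structuralInfluenceMatrix()], [samplingOracleInfluence()]
#' @export
setClass("InfluenceMatrix", representation(mat = "matrix"),
  validity = function(object) {
    m <- object@mat
    if (nrow(m) != ncol(m)) return("matrix must be square")
    if (!is.character(m)) return("entries must be characters")
    if (!all(m %in% SIGN_CLASSES))
      return("entries must be one of '+', '-', '0', '?'")
    TRUE
  })

#' Hill-parameterised network model
#'
#' Labelled dynamical network in which every state obeys
#' \eqn{\Theta_i \dot x_i + x_i = \sum_k T_{ik}(x)}, the terms
#' \eqn{T_{ik}} being monotone Hill-type interaction functions (see
#' [fTerm()], [gTerm()], [hTerm()]).  Terms may be nested (a Hill
#' function applied to a sum of terms), which is how time-scale
#' reduction represents composed static responses, and may carry a
#' transmission delay in minutes, which makes the model a delay
#' differential system.
#'
#' @slot nodes ordered character vector of state labels.
#' @slot theta named numeric vector of time constants (minutes, > 0).
#' @slot rhs named list, one element per node, each a list of
#'   interaction terms.
#' @seealso [hillModel()], [buildAARModel()], [buildAAVModel()],
#'   [simulateODE()], [reduceTimeScale()]
#' @export
setClass("HillModel",
  representation(nodes = "character", theta = "numeric", rhs = "list"),
  validity = function(object) {
    n <- object@nodes
    if (anyDuplicated(n)) return("node labels must be unique")
    if (!identical(names(object@theta), n))
      return("theta must be named by the node labels, in order")
    if (any(!is.finite(object@theta)) || any(object@theta <= 0))
      return("time constants must be positive and finite")
    if (!identical(names(object@rhs), n))
      return("rhs must be named by the node labels, in order")
    src <- unique(unlist(lapply(object@rhs, termSources), use.names = FALSE))
    bad <- setdiff(src, n)
    if (length(bad))
      return(paste("terms reference unknown nodes:",
                   paste(bad, collapse = ", ")))
    TRUE
  })

#' Simulated trajectory
#'
#' @slot time strictly increasing numeric time grid (minutes).
#' @slot state numeric matrix, one column per state label.
#' @slot metadata list of run details (solver, step, seed, delays).
#' @export
setClass("Trajectory",
  representation(time = "numeric", state = "matrix", metadata = "list"),
  validity = function(object) {
    if (length(object@time) != nrow(object@state))
      return("time grid and state rows must agree")
    if (any(diff(object@time) <= 0))
      return("time grid must be strictly increasing")
    if (!all(is.finite(object@state)))
      return("all states must be finite")
    TRUE
  })

#' Equilibrium search report
#'
#' @slot state named numeric equilibrium state vector (best solution).
#' @slot residual numeric residual norm of `x - RHS(x)` at the solution.
#' @slot nEquilibria integer count of distinct solution clusters found.
#' @slot agree logical: did all converged starts agree on one cluster?
#' @slot solutions list of distinct equilibrium vectors.
#' @export
setClass("EquilibriumReport",
  representation(state = "numeric", residual = "numeric",
                 nEquilibria = "integer", agree = "logical",
                 solutions = "list"))

#' Reduced AVP-ANP-VSM model: one state, three delayed feedbacks
#'
#' One-state reduction of the 20-variable AVP-ANP-vascular smooth muscle
#' network.  The actomyosin state retains its first-order dynamics with
#' time constant `theta`; every other node is treated as an
#' instantaneous monotone map, so the three delayed arcs (through the
#' heart-myocyte/ANP loop and the two stretch-receptor/AVP loops) turn
#' into delayed static feedback of the state on itself.
#'
#' @slot model the full [HillModel-class] the reduction was derived from.
#' @slot stateNode label of the retained dynamic state.
#' @slot theta time constant of the retained state (minutes).
#' @slot tau named numeric delays `c(tau1, tau2, tau3)` in minutes.
#' @slot gainScale numeric multiplier applied to deviations of the
#'   delayed state around `anchor`; 1 leaves the model untouched.  Used
#'   to modulate the effective loop gain around an operating point.
#' @slot anchor numeric anchor for gain scaling (`NA` when unused).
#' @seealso [reduceAAV()], [linearizeAAV()], [simulateDDE()]
#' @export
setClass("ReducedAAV",
  representation(model = "HillModel", stateNode = "character",
                 theta = "numeric", tau = "numeric",
                 gainScale = "numeric", anchor = "numeric"),
  validity = function(object) {
    if (!(object@stateNode %in% object@model@nodes))
      return("stateNode must be a node of the model")
    if (object@theta <= 0) return("theta must be positive")
    if (length(object@tau) != 3L || any(object@tau < 0))
      return("tau must be three nonnegative delays")
    TRUE
  })

#' Linearisation of the reduced AVP-ANP-VSM model
#'
#' Around the unique equilibrium, the deviation y of the actomyosin
#' state obeys
#' \deqn{\Theta \dot y(t) + y(t) = -p\, y(t-\tau_1) - q\, y(t-\tau_2)}
#' with loop gains \eqn{p = k_1 \mu_1} and \eqn{q = k_2(\mu_2+\mu_3)},
#' the k's and mu's being absolute derivatives of the composed monotone
#' maps at equilibrium (q groups the two stretch-receptor loops, which
#' share the delay \eqn{\tau_2 = \tau_3}).
#'
#' @slot theta time constant (minutes).
#' @slot k1,k2,mu1,mu2,mu3 absolute derivatives at equilibrium.
#' @slot tau named numeric delays `c(tau1, tau2, tau3)`.
#' @slot equilibrium equilibrium value of the state.
#' @export
setClass("LinearizedAAV",
  representation(theta = "numeric", k1 = "numeric", k2 = "numeric",
                 mu1 = "numeric", mu2 = "numeric", mu3 = "numeric",
                 tau = "numeric", equilibrium = "numeric"))

#' Characteristic-curve specification
#'
#' Parameters of the characteristic function
#' \eqn{j\omega\Theta + 1 + p e^{j\tau_1\omega} + q e^{j\tau_2\omega}}
#' of the linearised delayed double feedback: time constant, the two
#' nonnegative loop gains and the two delays.
#'
#' @slot theta time constant (minutes, >= 0).
#' @slot p,q loop gains (>= 0).
#' @slot tau1,tau2 delays (minutes, > 0).
#' @seealso [charValue()], [oscillationPropensity()]
#' @export
setClass("CharSpec",
  representation(theta = "numeric", p = "numeric", q = "numeric",
                 tau1 = "numeric", tau2 = "numeric"),
  validity = function(object) {
    if (object@theta < 0) return("theta must be nonnegative")
    if (object@p < 0 || object@q < 0) return("gains must be nonnegative")
    if (object@tau1 <= 0 || object@tau2 <= 0)
      return("delays must be positive")
    TRUE
  })

#' Oscillation-propensity result
#'
#' @slot rho minimal distance of the characteristic curve from the
#'   origin over pulsations `omega > 0`.
#' @slot jstar propensity index `1/rho` (`Inf` when `rho` is zero to
#'   numerical tolerance).
#' @slot omegaStar argmin pulsation (rad/min).
#' @slot spec the [CharSpec-class] analysed.
#' @export
setClass("PropensityResult",
  representation(rho = "numeric", jstar = "numeric",
                 omegaStar = "numeric", spec = "CharSpec"))

#' Oscillation-propensity surface over delay pairs
#'
#' @slot tau numeric delay grid shared by both axes (minutes).
#' @slot jstar,rhoMat numeric matrices over the grid (`jstar[i, j]` for
#'   `tau1 = tau[i]`, `tau2 = tau[j]`).
#' @slot theta,p,q scalar parameters used.
#' @export
setClass("PropensitySurface",
  representation(tau = "numeric", jstar = "matrix", rhoMat = "matrix",
                 theta = "numeric", p = "numeric", q = "numeric"))

#' Oscillation detection report
#'
#' @slot oscillating logical verdict.
#' @slot amplitude peak-to-peak amplitude in the final window.
#' @slot period estimated period in minutes (`NA` when not oscillating).
#' @slot transientFraction fraction of the trajectory discarded.
#' @slot nPeaks number of peaks found in the final window.
#' @export
setClass("OscillationReport",
  representation(oscillating = "logical", amplitude = "numeric",
                 period = "numeric", transientFraction = "numeric",
                 nPeaks = "integer"),
  validity = function(object) {
    if (isTRUE(object@oscillating) &&
        (!is.finite(object@period) || object@period <= 0))
      return("period must be positive when oscillating")
    TRUE
  })

#' Physiological parameter ranges for the synthetic generator
#'
#' Sampling ranges for node time constants by physiological class, Hill
#' interaction parameters and loop delays.  The class ranges encode the
#' four time-scale groups of the networks: endocrine signalling 30-60
#' min, stretch-receptor responses 2-4.5 min, nerve conduction below 1
#' min, intracellular transduction faster still.
#'
#' @slot thetaRanges named list of `c(lo, hi)` ranges (minutes) per
#'   class.
#' @slot hillRanges named list of `c(lo, hi)` ranges per Hill parameter
#'   (`alpha`, `beta`, `gamma`, `delta`, `sigma`, `eps`, `eta`).
#' @slot delayRange `c(lo, hi)` range for loop delays (minutes).
#' @slot nH Hill exponent used for every interaction.
#' @seealso [parameterRanges()], [sampleParameters()]
#' @export
setClass("ParameterRanges",
  representation(thetaRanges = "list", hillRanges = "list",
                 delayRange = "numeric", nH = "numeric"),
  validity = function(object) {
    rg <- c(object@thetaRanges, object@hillRanges,
            list(delay = object@delayRange))
    for (nm in names(rg)) {
      r <- rg[[nm]]
      if (length(r) != 2L || any(r <= 0) || r[1] > r[2])
        return(sprintf("range '%s' must be positive and ordered", nm))
    }
    if (object@nH < 1) return("Hill exponent must be >= 1")
    TRUE
  })
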