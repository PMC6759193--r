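#' Structural sign of the determinant of the negated interaction matrix
#'
#' Classifies \eqn{\det(-A)} over all real matrices A sharing the sign
#' pattern of `sigma` with free positive magnitudes, by exact
#' permutation expansion: every nonzero permutation term carries a
#' definite sign (permutation parity times the product of entry signs
#' of -A), and with independent magnitudes any single monomial can be
#' made to dominate, so the classification over `{+, -, 0, ?}` is
#' exact.
#'
#' A `+` determinant class is the precondition for reading steady-state
#' response signs off the adjugate (see
#' [structuralInfluenceMatrix()]).
#'
#' @param sigma a [SignMatrix-class] (or plain square sign-pattern
#'   matrix).
#' @return one of `"+"`, `"-"`, `"0"`, `"?"`.
#' @examples
#' structuralDeterminantSign(sigmaDTC())  # "+"
#' structuralDeterminantSign(sigmaVSM())  # "+"
#' @export
structuralDeterminantSign <- function(sigma) {
  m <- if (is(sigma, "SignMatrix")) sigma@mat else sigma
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("input must be square")
  signSetToClass(detSignSet(-m))
}

#' Structural (parameter-free) influence matrix
#'
#' Computes \eqn{M = \mathrm{sign}[\mathrm{adj}(-\Sigma)]} entrywise
#' over the classes `{+, -, 0, ?}`: entry \eqn{(i, j)} classifies the
#' cofactor \eqn{\mathrm{adj}(-A)_{ij}} over all positive magnitude
#' assignments compatible with the sign pattern, by exact expansion of
#' the corresponding \eqn{(n-1)\times(n-1)} minor into permutation
#' terms.  When the structural determinant class is `+`, entry
#' \eqn{(i, j)} is the sign of the steady-state variation of variable i
#' under a persistent positive input on the equation of variable j;
#' otherwise a warning is emitted and the adjugate sign classes are
#' still returned.
#'
#' @param sigma a [SignMatrix-class] (or square sign-pattern matrix).
#' @return an [InfluenceMatrix-class].
#' @examples
#' M <- structuralInfluenceMatrix(sigmaDTC())
#' influenceClasses(M)["HMY", ]   # all "+": every input raises ANP tone
#' @export
structuralInfluenceMatrix <- function(sigma) {
  m <- if (is(sigma, "SignMatrix")) sigma@mat else sigma
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("input must be square")
  if (structuralDeterminantSign(m) != "+")
    warning("det(-sigma) is not structurally positive; ",
            "adjugate signs may not equal steady-state influence signs")
  n <- nrow(m)
  neg <- -m
  out <- matrix("0", n, n, dimnames = dimnames(m))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      minor <- neg[-j, -i, drop = FALSE]
      cls <- signSetToClass(detSignSet(minor))
      if ((i + j) %% 2L == 1L) cls <- flipSignClass(cls)
      out[i, j] <- cls
    }
  }
  new("InfluenceMatrix", mat = out)
}

#' @rdname accessors
#' @export
setMethod("influenceClasses", "InfluenceMatrix", function(object) object@mat)

#' @rdname accessors
#' @export
setMethod("nodeLabels", "InfluenceMatrix", function(object)
  rownames(object@mat))

setMethod("show", "InfluenceMatrix", function(object) {
  cat(sprintf("InfluenceMatrix (%d x %d):\n", nrow(object@mat),
              ncol(object@mat)))
  print(object@mat, quote = FALSE)
})

#' Monte-Carlo oracle for the structural influence classification
#'
#' Independent check of [structuralInfluenceMatrix()]: draws magnitudes
#' log-uniformly from `magRange` for every nonzero entry of the sign
#' pattern, computes the numeric adjugate of the negated matrix per
#' sample, and classifies each entry `+` if positive in every sample,
#' `-` if negative in every sample, `0` if below tolerance in every
#' sample, and `?` if both signs occur.  Sampling can only refine `?`
#' towards a definite class by missing a sign, never contradict the
#' exact classification.
#'
#' @param sigma a [SignMatrix-class] (or square sign-pattern matrix).
#' @param nSamples number of magnitude draws (>= 1).
#' @param seed integer seed.
#' @param magRange positive range sampled log-uniformly; the wide
#'   default stresses dominance of different monomials.
#' @return an [InfluenceMatrix-class].
#' @export
samplingOracleInfluence <- function(sigma, nSamples = 10000L, seed = 1L,
                                    magRange = c(1e-2, 1e2)) {
  m <- if (is(sigma, "SignMatrix")) sigma@mat else sigma
  if (nSamples < 1L) stop("nSamples must be >= 1")
  n <- nrow(m)
  nz <- which(m != 0)
  set.seed(seed, kind = "Mersenne-Twister")
  lo <- log(magRange[1]); hi <- log(magRange[2])
  sawPos <- matrix(FALSE, n, n)
  sawNeg <- matrix(FALSE, n, n)
  for (s in seq_len(nSamples)) {
    A <- matrix(0, n, n)
    A[nz] <- m[nz] * exp(stats::runif(length(nz), lo, hi))
    negA <- -A
    adj <- det(negA) * solve(negA)
    tol <- 1e-12 * max(abs(adj))
    sawPos <- sawPos | (adj > tol)
    sawNeg <- sawNeg | (adj < -tol)
  }
  out <- matrix("0", n, n, dimnames = dimnames(m))
  out[sawPos & !sawNeg] <- "+"
  out[sawNeg & !sawPos] <- "-"
  out[sawPos & sawNeg] <- "?"
  new("InfluenceMatrix", mat = out)
}
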