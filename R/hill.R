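## Hill-type interaction terms.
##
## A term is a plain list of class "hillTerm" with fields
##   kind  : "f" (activation), "g" (inhibition) or "h" (bivariate,
##           increasing in the first argument, decreasing in the second)
##   pars  : named positive parameters (f: alpha, beta; g: gamma, delta;
##           h: sigma, eps, eta)
##   nH    : Hill exponent (>= 1)
##   args  : list of arguments; each is either a node label (character)
##           or a list of terms, meaning the Hill function is applied to
##           the SUM of those terms (this is how time-scale reduction
##           represents composed static responses)
##   delay : transmission delay in minutes applied to the term's
##           arguments (0 for instantaneous interactions)

newHillTerm <- function(kind, pars, nH, args, delay) {
  if (any(!is.finite(pars)) || any(pars <= 0))
    stop("Hill parameters must be positive", call. = FALSE)
  if (!is.finite(nH) || nH < 1)
    stop("Hill exponent must be >= 1", call. = FALSE)
  if (!is.finite(delay) || delay < 0)
    stop("delay must be nonnegative", call. = FALSE)
  structure(list(kind = kind, pars = pars, nH = nH, args = args,
                 delay = delay), class = "hillTerm")
}

isTerm <- function(x) inherits(x, "hillTerm")

#' Hill interaction term constructors
#'
#' Monotone Hill-type interaction functions used as right-hand-side
#' terms of the network models:
#' \deqn{f(x) = \frac{\alpha x^{n}}{1 + \beta x^{n}}, \qquad
#'       g(x) = \frac{\gamma}{1 + \delta x^{n}}, \qquad
#'       h(x, y) = \frac{\sigma x^{n}}{1 + \epsilon x^{n} + \eta y^{n}}}
#' with all coefficients positive and Hill exponent \eqn{n \ge 1}.
#' `f` is increasing with `f(0) = 0`; `g` is decreasing with
#' `g(0) = gamma`; `h` is increasing in its first and decreasing in its
#' second argument.
#'
#' @param x,y a node label (character) or, for composed terms, a list of
#'   terms whose sum is the argument.
#' @param alpha,beta,gamma,delta,sigma,eps,eta positive coefficients.
#' @param nH Hill exponent (>= 1).
#' @param delay transmission delay in minutes applied to the term's
#'   arguments.
#' @return an object of class `"hillTerm"`.
#' @examples
#' evalInteraction(fTerm("x", alpha = 1, beta = 1, nH = 1), 1) # 0.5
#' evalInteraction(gTerm("x", gamma = 2), 0)                   # 2
#' @export
fTerm <- function(x, alpha = 1, beta = 1, nH = 2, delay = 0)
  newHillTerm("f", c(alpha = alpha, beta = beta), nH, list(x), delay)

#' @rdname fTerm
#' @export
gTerm <- function(x, gamma = 1, delta = 1, nH = 2, delay = 0)
  newHillTerm("g", c(gamma = gamma, delta = delta), nH, list(x), delay)

#' @rdname fTerm
#' @export
hTerm <- function(x, y, sigma = 1, eps = 1, eta = 1, nH = 2, delay = 0)
  newHillTerm("h", c(sigma = sigma, eps = eps, eta = eta), nH,
              list(x, y), delay)

hillValue <- function(term, vals) {
  n <- term$nH
  p <- term$pars
  switch(term$kind,
    f = p[["alpha"]] * vals[[1]]^n / (1 + p[["beta"]] * vals[[1]]^n),
    g = p[["gamma"]] / (1 + p[["delta"]] * vals[[1]]^n),
    h = p[["sigma"]] * vals[[1]]^n /
          (1 + p[["eps"]] * vals[[1]]^n + p[["eta"]] * vals[[2]]^n),
    stop("unknown term kind"))
}

## Partial derivatives of the Hill forms with respect to each argument.
hillPartials <- function(term, vals) {
  n <- term$nH
  p <- term$pars
  switch(term$kind,
    f = {
      den <- 1 + p[["beta"]] * vals[[1]]^n
      p[["alpha"]] * n * vals[[1]]^(n - 1) / den^2
    },
    g = {
      den <- 1 + p[["delta"]] * vals[[1]]^n
      -p[["gamma"]] * p[["delta"]] * n * vals[[1]]^(n - 1) / den^2
    },
    h = {
      den <- 1 + p[["eps"]] * vals[[1]]^n + p[["eta"]] * vals[[2]]^n
      c(p[["sigma"]] * n * vals[[1]]^(n - 1) * (1 + p[["eta"]] * vals[[2]]^n) / den^2,
        -p[["sigma"]] * vals[[1]]^n * p[["eta"]] * n * vals[[2]]^(n - 1) / den^2)
    })
}

## Monotonicity of each argument slot: +1 increasing, -1 decreasing.
hillMonotonicity <- function(kind) {
  switch(kind, f = 1L, g = -1L, h = c(1L, -1L))
}

#' Evaluate a single Hill interaction term at numeric arguments
#'
#' @param term a `"hillTerm"` built by [fTerm()], [gTerm()] or
#'   [hTerm()].
#' @param x,y nonnegative numeric argument(s); `y` only for bivariate
#'   terms.
#' @return the nonnegative term value.
#' @export
evalInteraction <- function(term, x, y = NULL) {
  stopifnot(isTerm(term))
  if (any(x < 0) || (!is.null(y) && any(y < 0)))
    stop("Hill arguments must be nonnegative", call. = FALSE)
  vals <- if (term$kind == "h") {
    if (is.null(y)) stop("bivariate term needs two arguments", call. = FALSE)
    list(x, y)
  } else list(x)
  hillValue(term, vals)
}

## --- Recursive evaluation over term trees ----------------------------

## getx(label, lag) supplies the value of a node at accumulated delay
## `lag`; nested term lists accumulate their own delay.
evalTermsWith <- function(terms, getx, lag = 0) {
  total <- 0
  for (tm in terms) {
    lag2 <- lag + tm$delay
    vals <- lapply(tm$args, function(a) {
      if (is.character(a)) getx(a, lag2) else evalTermsWith(a, getx, lag2)
    })
    total <- total + hillValue(tm, vals)
  }
  total
}

## Forward-mode value+derivative: getx2(label, lag) returns c(value,
## derivative).  Chain rule through the Hill forms.
evalTermsGradWith <- function(terms, getx2, lag = 0) {
  v <- 0
  d <- 0
  for (tm in terms) {
    lag2 <- lag + tm$delay
    pairs <- lapply(tm$args, function(a) {
      if (is.character(a)) getx2(a, lag2) else evalTermsGradWith(a, getx2, lag2)
    })
    vals <- lapply(pairs, `[[`, 1L)
    grads <- vapply(pairs, `[[`, numeric(1), 2L)
    v <- v + hillValue(tm, vals)
    part <- hillPartials(tm, vals)
    d <- d + sum(part * grads)
  }
  c(v, d)
}

## Union of node labels referenced anywhere in a term list.
termSources <- function(terms) {
  out <- character(0)
  for (tm in terms) {
    for (a in tm$args) {
      out <- c(out, if (is.character(a)) a else termSources(a))
    }
  }
  unique(out)
}

## Signs with which `var` influences the sum of `terms`: integer subset
## of {-1, +1} (empty = no dependence).  Mixed signs mean the dependence
## is not sign-definite.
signDepTerms <- function(terms, var) {
  out <- integer(0)
  for (tm in terms) {
    mono <- hillMonotonicity(tm$kind)
    for (k in seq_along(tm$args)) {
      a <- tm$args[[k]]
      s <- if (is.character(a)) {
        if (a == var) 1L else integer(0)
      } else signDepTerms(a, var)
      out <- unique(c(out, mono[[k]] * s))
    }
  }
  out
}

## Largest possible value of the sum of `terms` (each Hill form is
## bounded: f < alpha/beta, g <= gamma, h < sigma/eps).  Used to bound
## equilibrium search boxes.
termsUpperBound <- function(terms) {
  total <- 0
  for (tm in terms) {
    p <- tm$pars
    total <- total + switch(tm$kind,
      f = p[["alpha"]] / p[["beta"]],
      g = p[["gamma"]],
      h = p[["sigma"]] / p[["eps"]])
  }
  total
}

## Substitute node references by term lists (used by time-scale
## reduction): any character argument found in names(mapping) is
## replaced by the corresponding list of terms.
substituteTerms <- function(terms, mapping) {
  lapply(terms, function(tm) {
    tm$args <- lapply(tm$args, function(a) {
      if (is.character(a)) {
        if (a %in% names(mapping)) mapping[[a]] else a
      } else substituteTerms(a, mapping)
    })
    tm
  })
}

## Restrict a term list to the nodes in `keep`: references to dropped
## nodes are removed as if the dropped variable were absent (zero).  A
## univariate term whose argument is dropped vanishes; a bivariate term
## with its second (inhibitory) argument dropped degenerates to the
## activation form with the same coefficients; with its first argument
## dropped it vanishes.
projectTerms <- function(terms, keep) {
  out <- list()
  for (tm in terms) {
    pruned <- vector("list", length(tm$args))
    dropped <- logical(length(tm$args))
    for (k in seq_along(tm$args)) {
      a <- tm$args[[k]]
      if (is.character(a)) {
        if (a %in% keep) pruned[[k]] <- a else dropped[k] <- TRUE
      } else {
        sub <- projectTerms(a, keep)
        if (length(sub) == 0L) dropped[k] <- TRUE else pruned[[k]] <- sub
      }
    }
    if (tm$kind %in% c("f", "g")) {
      if (dropped[1L]) next
      tm$args <- pruned
      out[[length(out) + 1L]] <- tm
    } else {                              # bivariate
      if (dropped[1L]) next               # numerator argument gone
      if (dropped[2L]) {
        rep <- fTerm(pruned[[1L]], alpha = tm$pars[["sigma"]],
                     beta = tm$pars[["eps"]], nH = tm$nH, delay = tm$delay)
        out[[length(out) + 1L]] <- rep
      } else {
        tm$args <- pruned
        out[[length(out) + 1L]] <- tm
      }
    }
  }
  out
}

## Maximum accumulated delay over a term tree.
termsMaxDelay <- function(terms) {
  m <- 0
  for (tm in terms) {
    inner <- 0
    for (a in tm$args) if (!is.character(a))
      inner <- max(inner, termsMaxDelay(a))
    m <- max(m, tm$delay + inner)
  }
  m
}
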