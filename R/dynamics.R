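# Discrete-time expression dynamics: the interaction matrix w, signed by
# the activator/repressor roles, drives a steep sigmoid map iterated to
# a steady state. Viability = reaching a steady state within the
# iteration limit.

#' Parameters of the expression dynamics
#'
#' @param alpha Sigmoid steepness (default 20).
#' @param tau Length of the stability window in iterations (default 10).
#' @param tol Stability tolerance on the windowed variance measure
#'   (default 1e-4).
#' @param max_iter Iteration limit beyond which the system is declared
#'   unstable (default 100).
#' @return Object of class `dynamics_params`.
#' @export
dynamics_params <- function(alpha = 20, tau = 10L, tol = 1e-4,
                            max_iter = 100L) {
  tau <- as.integer(tau)
  max_iter <- as.integer(max_iter)
  if (alpha <= 0) stop("alpha must be positive")
  if (tau < 1L || tau >= max_iter) stop("need 1 <= tau < max_iter")
  if (tol <= 0) stop("tol must be positive")
  structure(list(alpha = alpha, tau = tau, tol = tol, max_iter = max_iter),
            class = "dynamics_params")
}

#' One step of the expression map
#'
#' `s_i(t+1) = sigmoid(alpha * sum_j v_j * w_ij * s_j(t))` with
#' `sigmoid(u) = 1 / (1 + exp(-u))`.
#'
#' @param s Expression state (numeric vector in [0, 1]).
#' @param network A `regulatory_network` or plain w matrix.
#' @param tf_signs Vector over {-1, +1}.
#' @param alpha Sigmoid steepness.
#' @return The next expression state, entries in (0, 1).
#' @export
expression_step <- function(s, network, tf_signs, alpha = 20) {
  w <- if (inherits(network, "regulatory_network")) network$w else network
  u <- as.numeric(w %*% (tf_signs * s))
  1 / (1 + exp(-alpha * u))
}

#' Iterate the expression dynamics to a steady state
#'
#' Starting from the genotype's initial state, the map is iterated; from
#' iteration tau onward a variance-like measure V over the last tau
#' states (mean squared distance to the window-mean expression) is
#' evaluated, and the system is stable once V < tol. The phenotype is
#' the window-mean expression vector. If no window satisfies the
#' criterion within `max_iter` iterations the individual is unstable.
#'
#' @param genotype A `genotype` (supplies the initial state and signs).
#' @param network Its `regulatory_network` (or w matrix).
#' @param params A [dynamics_params()] object.
#' @param init Optional replacement initial state.
#' @return Object of class `development_result`: `stable` (flag),
#'   `phenotype` (window-mean state; NULL if unstable), `iterations`.
#' @export
develop <- function(genotype, network, params = dynamics_params(),
                    init = NULL) {
  w <- if (inherits(network, "regulatory_network")) network$w else network
  if (is.null(init)) init <- genotype$initial_state
  develop_w(w, genotype$tf_signs, init, params)
}

# Core loop on the bare matrix; also used by the evolution engine.
develop_w <- function(w, tf_signs, init, params = dynamics_params()) {
  n <- length(init)
  alpha <- params$alpha
  tau <- params$tau
  tol <- params$tol
  max_iter <- params$max_iter
  a <- w * rep(tf_signs, each = n) # column-scaled: a %*% s = w %*% (v*s)

  window <- matrix(0, nrow = tau, ncol = n)
  s <- as.numeric(init)
  for (t in seq_len(max_iter)) {
    s <- 1 / (1 + exp(-alpha * as.numeric(a %*% s)))
    row <- ((t - 1L) %% tau) + 1L
    window[row, ] <- s
    if (t >= tau) {
      cm <- colMeans(window)
      v <- mean(window * window) - mean(cm * cm)
      if (v < tol) {
        return(structure(list(stable = TRUE, phenotype = cm,
                              iterations = t),
                         class = "development_result"))
      }
    }
  }
  structure(list(stable = FALSE, phenotype = NULL, iterations = max_iter),
            class = "development_result")
}

#' Distance between two expression states
#'
#' Root-mean-square distance `sqrt(mean((a - b)^2))`, normalized so the
#' value lies in [0, 1] for states in the unit cube regardless of the
#' number of genes.
#'
#' @param a,b Numeric vectors of equal length.
#' @return Non-negative scalar.
#' @export
phenotype_distance <- function(a, b) {
  if (length(a) != length(b)) stop("expression vectors differ in length")
  sqrt(mean((a - b)^2))
}

#' @export
print.development_result <- function(x, ...) {
  if (x$stable) {
    cat("<development_result> stable after", x$iterations, "iterations\n")
    cat("  phenotype:", paste(format(x$phenotype, digits = 3),
                              collapse = " "), "\n")
  } else {
    cat("<development_result> unstable (", x$iterations, " iterations)\n",
        sep = "")
  }
  invisible(x)
}
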