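#' Couplings of the two-stimulus environment
#'
#' Constructs the parameter set of the coupled pair of stimuli
#' \deqn{dX_1/dt = -\alpha_1 (X_1 - X_2) + \beta_1 \eta_1,}
#' \deqn{dX_2/dt = -\alpha_2 (X_2 - X_1) + \beta_2 \eta_2,}
#' where \eqn{\eta_1, \eta_2} are independent unit white noises.  The
#' \eqn{\alpha_i \ge 0} (units 1/time) are the deterministic couplings pulling
#' each process toward the other; the \eqn{\beta_i \ge 0} (units
#' length/sqrt(time)) scale the stochastic forcing.
#'
#' Four derived quantities are attached:
#' \describe{
#'   \item{`a`}{deterministic asymmetry \eqn{(\alpha_1-\alpha_2)/(\alpha_1+\alpha_2) \in [-1,1]}.}
#'   \item{`b`}{stochastic asymmetry \eqn{(\beta_1-\beta_2)/(\beta_1+\beta_2) \in [-1,1]}.}
#'   \item{`tau`}{natural time scale \eqn{1/(\alpha_1+\alpha_2)}, the decay
#'     time of transients in the separation \eqn{X_1-X_2}.}
#'   \item{`ell`}{natural length scale \eqn{(\beta_1+\beta_2)/(\alpha_1+\alpha_2)},
#'     the size of stationary fluctuations of the separation.}
#' }
#'
#' @param alpha1,alpha2 deterministic couplings, both `>= 0`, not both zero.
#' @param beta1,beta2 stochastic couplings, both `>= 0`, not both zero.
#' @return An object of class `qualia_params`.
#' @examples
#' p <- make_params(0.55, 0.45, 0.5, 0.5)
#' p$a      # 0.1
#' p$tau    # 1
#' @seealso [make_params_ab()] for the dimensionless parameterization,
#'   [swap_processes()] for the 1<->2 relabeling.
#' @export
make_params <- function(alpha1, alpha2, beta1, beta2) {
  vals <- c(alpha1 = alpha1, alpha2 = alpha2, beta1 = beta1, beta2 = beta2)
  if (any(!is.finite(vals))) stop("couplings must be finite numbers")
  if (any(vals < 0)) stop("couplings must be non-negative")
  if (alpha1 + alpha2 <= 0)
    stop("alpha1 + alpha2 must be positive (deterministic couplings cannot both vanish)")
  if (beta1 + beta2 <= 0)
    stop("beta1 + beta2 must be positive (stochastic couplings cannot both vanish)")
  structure(list(
    alpha1 = alpha1, alpha2 = alpha2, beta1 = beta1, beta2 = beta2,
    a   = (alpha1 - alpha2) / (alpha1 + alpha2),
    b   = (beta1 - beta2) / (beta1 + beta2),
    tau = 1 / (alpha1 + alpha2),
    ell = (beta1 + beta2) / (alpha1 + alpha2)
  ), class = "qualia_params")
}

#' Environment couplings from asymmetries, in natural units
#'
#' Convenience constructor fixing the natural scales `tau = ell = 1` (i.e.
#' `alpha1 + alpha2 = 1`, `beta1 + beta2 = 1`) so that the model is fully
#' specified by the two dimensionless asymmetries.
#'
#' @param a deterministic asymmetry in `(-1, 1)`.
#' @param b stochastic asymmetry in `(-1, 1)`.
#' @return A `qualia_params` object with `tau = ell = 1`.
#' @export
make_params_ab <- function(a, b) {
  stopifnot(is.finite(a), is.finite(b), abs(a) < 1, abs(b) < 1)
  make_params((1 + a) / 2, (1 - a) / 2, (1 + b) / 2, (1 - b) / 2)
}

#' Relabel the two processes
#'
#' Swapping the labels 1 and 2 negates both asymmetries and leaves the
#' natural scales unchanged.  Useful for direction-symmetry arguments: the
#' transfer entropy from 2 to 1 under the swapped parameters equals the
#' transfer entropy from 1 to 2 under the original ones.
#'
#' @param params a `qualia_params` object.
#' @return A `qualia_params` object with indices 1 and 2 exchanged.
#' @export
swap_processes <- function(params) {
  stopifnot(inherits(params, "qualia_params"))
  make_params(params$alpha2, params$alpha1, params$beta2, params$beta1)
}

#' Natural scales of the environment
#'
#' @param params a `qualia_params` object.
#' @return Named numeric vector with elements `tau` and `ell`.
#' @export
natural_scales <- function(params) {
  stopifnot(inherits(params, "qualia_params"))
  c(tau = params$tau, ell = params$ell)
}

#' Rescale couplings to dimensionless (natural) units
#'
#' Internally all information measures are invariant under measuring time in
#' units of `tau` and length in units of `ell`; this helper returns the
#' rescaled parameter set together with the scales needed to map back.
#'
#' @param params a `qualia_params` object.
#' @return A list with elements `params` (a `qualia_params` with
#'   `tau = ell = 1`) and `scales` (the original `c(tau, ell)`).
#' @export
nondimensionalize <- function(params) {
  stopifnot(inherits(params, "qualia_params"))
  sc <- natural_scales(params)
  list(params = make_params_ab(params$a, params$b), scales = sc)
}

#' @export
print.qualia_params <- function(x, ...) {
  cat("Two-stimulus environment couplings\n")
  cat(sprintf("  alpha: (%g, %g)   beta: (%g, %g)\n",
              x$alpha1, x$alpha2, x$beta1, x$beta2))
  cat(sprintf("  asymmetries: a = %g, b = %g\n", x$a, x$b))
  cat(sprintf("  natural scales: tau = %g, ell = %g\n", x$tau, x$ell))
  invisible(x)
}

#' Cognitive architecture of an observing agent
#'
#' An agent is characterized by the number of past snapshots `N` it stores
#' and the sampling interval `dt` between consecutive snapshots.  Its
#' look-back window is `T = N * dt`.
#'
#' @param N integer memory size, `>= 1`.
#' @param dt sampling interval, `> 0` (same time units as the environment).
#' @return An object of class `architecture` with fields `N`, `dt`, `window`.
#' @examples
#' architecture(4, 0.5)
#' @export
architecture <- function(N, dt) {
  if (!is.numeric(N) || length(N) != 1 || N < 1 || N != round(N))
    stop("N must be a single integer >= 1")
  if (!is.numeric(dt) || length(dt) != 1 || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive number")
  structure(list(N = as.integer(N), dt = dt, window = N * dt),
            class = "architecture")
}

#' @export
print.architecture <- function(x, ...) {
  cat(sprintf("Cognitive architecture: N = %d snapshots, dt = %g (window T = %g)\n",
              x$N, x$dt, x$window))
  invisible(x)
}
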