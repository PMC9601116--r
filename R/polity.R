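# Populations of agents over the space of cognitive architectures, and the
# belief distributions their pooled influence estimates form.

#' Population law over cognitive architectures
#'
#' Describes a polity in which memory size `N` is geometric on `{1, 2, ...}`
#' with mean `mean_N` (success parameter `1 - x`, `x = 1 - 1/mean_N`) and the
#' sampling interval `dt` is log-normal with mean `mean_dt` and log-standard
#' deviation `theta`, independent of `N`.  Optional censoring bounds
#' `N1 < N2` mark the memory classes used by [censored_two_camp_belief()] and
#' the rejection option of [sample_agents()].
#'
#' @param mean_N mean memory size, `> 1` (use `point_mass_N1 = TRUE` for the
#'   degenerate population with `N` identically 1).
#' @param mean_dt mean sampling interval, `> 0`.
#' @param theta log-RMS spread of `dt`, `> 0`.
#' @param N1,N2 optional integer censoring bounds, `1 <= N1 < N2`.
#' @param point_mass_N1 if `TRUE`, the memory marginal is the point mass at
#'   `N = 1` (and `mean_N` must be 1).
#' @return An object of class `polity_spec`; its field `x` is `1 - 1/mean_N`.
#' @examples
#' polity_spec(mean_N = 6, mean_dt = 1, theta = 0.5)
#' @export
polity_spec <- function(mean_N, mean_dt, theta, N1 = NULL, N2 = NULL,
                        point_mass_N1 = FALSE) {
  if (point_mass_N1) {
    if (!missing(mean_N) && mean_N != 1)
      stop("point_mass_N1 = TRUE requires mean_N = 1")
    mean_N <- 1
  } else if (!is.numeric(mean_N) || mean_N <= 1) {
    stop("mean_N must exceed 1 (or set point_mass_N1 = TRUE for N == 1)")
  }
  stopifnot(is.numeric(mean_dt), mean_dt > 0, is.numeric(theta), theta > 0)
  if (!is.null(N1) || !is.null(N2)) {
    stopifnot(!is.null(N1), !is.null(N2),
              N1 >= 1, N1 == round(N1), N2 == round(N2), N1 < N2)
  }
  structure(list(mean_N = mean_N, mean_dt = mean_dt, theta = theta,
                 N1 = N1, N2 = N2, point_mass_N1 = point_mass_N1,
                 x = 1 - 1 / mean_N,
                 # log-normal with E[dt] = mean_dt and Var[log dt] = theta^2
                 meanlog = log(mean_dt) - theta^2 / 2),
            class = "polity_spec")
}

#' @export
print.polity_spec <- function(x, ...) {
  cat(sprintf("Polity: <N> = %g (geometric), <dt> = %g, theta = %g (log-normal)\n",
              x$mean_N, x$mean_dt, x$theta))
  if (!is.null(x$N1))
    cat(sprintf("  censoring bounds: N1 = %d, N2 = %d\n", x$N1, x$N2))
  invisible(x)
}

#' Joint population density over architectures
#'
#' `P(N) * p(dt)` with `P` geometric (mean `mean_N`) and `p` log-normal
#' (mean `mean_dt`, log-variance `theta^2`).
#'
#' @param spec a [polity_spec()].
#' @param N integer memory size(s), `>= 1`.
#' @param dt sampling interval(s), `> 0`.
#' @return Density values (probability mass in `N` times density in `dt`).
#' @export
polity_pdf <- function(spec, N, dt) {
  stopifnot(inherits(spec, "polity_spec"))
  if (any(N < 1) || any(N != round(N))) stop("N must be integer >= 1")
  if (any(dt <= 0)) stop("dt must be positive")
  pN <- if (spec$point_mass_N1) as.numeric(N == 1) else
    (1 - spec$x) * spec$x^(N - 1)
  pN * stats::dlnorm(dt, meanlog = spec$meanlog, sdlog = spec$theta)
}

#' Draw agents from a polity
#'
#' @param spec a [polity_spec()].
#' @param n number of agents.
#' @param seed optional seed.
#' @param reject_censored if `TRUE` and the spec has censoring bounds, agents
#'   with `N > N2` are rejected and redrawn.
#' @return A list of `n` [architecture()] objects.
#' @export
sample_agents <- function(spec, n, seed = NULL, reject_censored = FALSE) {
  stopifnot(inherits(spec, "polity_spec"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  draw_N <- function(m) {
    if (spec$point_mass_N1) rep(1L, m)
    else stats::rgeom(m, prob = 1 - spec$x) + 1L
  }
  Ns <- draw_N(n)
  if (reject_censored && !is.null(spec$N2)) {
    while (any(bad <- Ns > spec$N2)) Ns[bad] <- draw_N(sum(bad))
  }
  dts <- stats::rlnorm(n, meanlog = spec$meanlog, sdlog = spec$theta)
  mapply(architecture, Ns, dts, SIMPLIFY = FALSE)
}

#' Mixture of agent beliefs about the influence
#'
#' A `belief_distribution` is a normalized mixture of point masses and/or
#' Gaussian components over influence values in `[-1, 1]`, each component
#' one (class of) agent estimate.
#'
#' @param weight non-negative mixture weights (renormalized to sum to 1).
#' @param kind `"point"` or `"gaussian"` per component.
#' @param location component location (point value or Gaussian mean).
#' @param scale Gaussian standard deviation (`NA` for point masses).
#' @param meta optional list of metadata.
#' @return An object of class `belief_distribution`.
#' @export
belief_distribution_new <- function(weight, kind, location, scale = NA_real_,
                                    meta = list()) {
  n <- length(weight)
  kind <- rep_len(kind, n); location <- rep_len(location, n)
  scale <- rep_len(scale, n)
  stopifnot(all(weight >= 0), sum(weight) > 0,
            all(kind %in% c("point", "gaussian")),
            all(is.finite(location)))
  if (any(kind == "gaussian" & !(is.finite(scale) & scale > 0)))
    stop("gaussian components need positive scales")
  structure(list(components = data.frame(
    weight = weight / sum(weight), kind = kind,
    location = location, scale = scale), meta = meta),
    class = "belief_distribution")
}

#' @export
print.belief_distribution <- function(x, ...) {
  cmp <- x$components
  cat(sprintf("Belief distribution over influence: %d component(s)\n", nrow(cmp)))
  show <- utils::head(cmp[order(-cmp$weight), ], 5)
  for (i in seq_len(nrow(show)))
    cat(sprintf("  w = %.4f  %s at %+.4f%s\n", show$weight[i], show$kind[i],
                show$location[i],
                if (show$kind[i] == "gaussian") sprintf(" (sd %.3g)", show$scale[i]) else ""))
  if (nrow(cmp) > 5) cat(sprintf("  ... and %d more\n", nrow(cmp) - 5))
  invisible(x)
}

#' Pool per-architecture influence estimates over a polity
#'
#' Forms the population belief distribution
#' \deqn{\rho(T_{12}) = \sum_{N} \int dt\; \rho_N(dt)\, \rho(T_{12} \mid N, dt)}
#' by Gauss-Legendre quadrature in `log dt` (64 nodes) and summation over `N`
#' until the geometric tail mass falls below `1e-10`.
#'
#' @param spec a [polity_spec()].
#' @param influence_given_arch function of an [architecture()] returning
#'   either a single influence value (a point estimate) or `c(mean, sd)` (a
#'   Gaussian estimate).
#' @param n_nodes quadrature nodes in `log dt`.
#' @return A `belief_distribution`.
#' @examples
#' spec <- polity_spec(3, 1, 0.5)
#' bel <- belief_distribution(spec, function(arch) 0.3)
#' summarize_belief(bel)
#' @export
belief_distribution <- function(spec, influence_given_arch, n_nodes = 64) {
  stopifnot(inherits(spec, "polity_spec"), is.function(influence_given_arch))
  gl <- .gauss_legendre(n_nodes)
  # quadrature in z = log dt over +- 8 theta around the log-mean
  lo <- spec$meanlog - 8 * spec$theta; hi <- spec$meanlog + 8 * spec$theta
  z <- (hi + lo) / 2 + (hi - lo) / 2 * gl$nodes
  wz <- (hi - lo) / 2 * gl$weights * stats::dnorm(z, spec$meanlog, spec$theta)
  Nmax <- if (spec$point_mass_N1) 1L else
    max(1L, stats::qgeom(1 - 1e-10, prob = 1 - spec$x) + 1L)
  Ns <- seq_len(Nmax)
  pN <- if (spec$point_mass_N1) 1 else (1 - spec$x) * spec$x^(Ns - 1)
  wt <- c(); kd <- c(); loc <- c(); scl <- c()
  for (i in seq_along(Ns)) for (j in seq_along(z)) {
    est <- influence_given_arch(architecture(Ns[i], exp(z[j])))
    w <- pN[i] * wz[j]
    if (length(est) == 1) {
      wt <- c(wt, w); kd <- c(kd, "point"); loc <- c(loc, est); scl <- c(scl, NA)
    } else {
      wt <- c(wt, w); kd <- c(kd, "gaussian"); loc <- c(loc, est[1]); scl <- c(scl, est[2])
    }
  }
  belief_distribution_new(wt, kd, loc, scl,
                          meta = list(spec = spec, n_nodes = n_nodes))
}

# Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch)
.gauss_legendre <- function(n) {
  if (n == 1) return(list(nodes = 0, weights = 2))
  k <- seq_len(n - 1)
  beta <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- beta; J[cbind(k + 1, k)] <- beta
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = 2 * e$vectors[1, ]^2)
}

#' Two-camp belief from a sharp crossover in the sampling interval
#'
#' If every agent sampling faster than a critical interval `tau_star`
#' concludes influence `t_lo` and every slower agent concludes `t_hi`, the
#' polity belief is bimodal with weights `(1-f)/2` and `(1+f)/2`, where
#' `f = 1 - 2 F(tau_star)` and `F` is the log-normal CDF of the sampling
#' interval under `spec`.
#'
#' @param spec a [polity_spec()].
#' @param tau_star critical sampling interval, `> 0`.
#' @param t_lo,t_hi influence values concluded below / above `tau_star`.
#' @return A two-point `belief_distribution`; its `meta$f` holds `f`.
#' @export
step_model_belief <- function(spec, tau_star, t_lo, t_hi) {
  stopifnot(inherits(spec, "polity_spec"), tau_star > 0)
  Fts <- stats::plnorm(tau_star, meanlog = spec$meanlog, sdlog = spec$theta)
  f <- 1 - 2 * Fts
  belief_distribution_new(weight = c((1 - f) / 2, (1 + f) / 2),
                          kind = "point",
                          location = c(t_lo, t_hi),
                          meta = list(spec = spec, tau_star = tau_star, f = f))
}

#' Censored two-camp Gaussian belief from memory classes
#'
#' Agents with memory `N <= N1` form camp 1 (influence mean `mu1`, sd
#' `sigma1`), agents with `N1 < N <= N2` form camp 2, and agents with
#' `N > N2` are censored (do not contribute).  Under the geometric memory
#' law the camp weights are
#' `(1 - x^N1) / (1 - x^N2)` and `(x^N1 - x^N2) / (1 - x^N2)` with
#' `x = 1 - 1/mean_N`; `N2 = Inf` disables the upper censoring.
#'
#' @param spec a [polity_spec()].
#' @param N1,N2 memory bounds, `1 <= N1 < N2` (`N2` may be `Inf`); default to
#'   the spec's censoring bounds.
#' @param mu1,sigma1,mu2,sigma2 camp means and standard deviations.
#' @return A two-component Gaussian `belief_distribution`.
#' @export
censored_two_camp_belief <- function(spec, N1 = spec$N1, N2 = spec$N2,
                                     mu1, sigma1, mu2, sigma2) {
  stopifnot(inherits(spec, "polity_spec"),
            !is.null(N1), !is.null(N2), N1 >= 1, N1 < N2,
            sigma1 > 0, sigma2 > 0)
  x <- spec$x
  xN2 <- if (is.infinite(N2)) 0 else x^N2
  w1 <- (1 - x^N1) / (1 - xN2)
  w2 <- (x^N1 - xN2) / (1 - xN2)
  belief_distribution_new(weight = c(w1, w2), kind = "gaussian",
                          location = c(mu1, mu2), scale = c(sigma1, sigma2),
                          meta = list(spec = spec, N1 = N1, N2 = N2))
}

#' Summary statistics of a belief distribution
#'
#' @param belief a `belief_distribution`.
#' @param tol point masses within `tol` of zero count as "undecided".
#' @return A list with `mean`, `median` (by CDF inversion) and
#'   `camp_fractions`, a named numeric `c(negative, zero, positive)`.
#' @export
summarize_belief <- function(belief, tol = 1e-12) {
  stopifnot(inherits(belief, "belief_distribution"))
  cmp <- belief$components
  mean_val <- sum(cmp$weight * cmp$location)
  cdf <- function(q) {
    v <- ifelse(cmp$kind == "point", as.numeric(cmp$location <= q),
                stats::pnorm(q, cmp$location, cmp$scale))
    sum(cmp$weight * v)
  }
  neg <- {
    v <- ifelse(cmp$kind == "point", as.numeric(cmp$location < -tol),
                stats::pnorm(0, cmp$location, cmp$scale))
    sum(cmp$weight * v)
  }
  zero <- sum(cmp$weight * (cmp$kind == "point" & abs(cmp$location) <= tol))
  pos <- 1 - neg - zero
  # median by CDF inversion; atoms make the CDF a step function, so take the
  # midpoint of the median interval [inf{q: F >= 1/2}, inf{q: F > 1/2}]
  # (for continuous mixtures the two endpoints coincide)
  lo0 <- min(cmp$location - 10 * ifelse(is.na(cmp$scale), 0, cmp$scale)) - 1
  hi0 <- max(cmp$location + 10 * ifelse(is.na(cmp$scale), 0, cmp$scale)) + 1
  invert <- function(strict) {
    lo <- lo0; hi <- hi0
    hit <- if (strict) function(q) cdf(q) > 0.5 else function(q) cdf(q) >= 0.5
    if (hit(lo)) return(lo)
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (hit(mid)) hi <- mid else lo <- mid
    }
    hi
  }
  med <- (invert(FALSE) + invert(TRUE)) / 2
  list(mean = mean_val, median = med,
       camp_fractions = c(negative = neg, zero = zero, positive = max(pos, 0)))
}

#' Does a polity have the consensus problem?
#'
#' A polity has the consensus problem when substantial camps sit on both
#' sides of zero influence: both the negative and the positive camp fraction
#' exceed `threshold`.
#'
#' @param belief a `belief_distribution`.
#' @param threshold minority-camp fraction required, default 0.1.
#' @return Logical.
#' @export
has_consensus_problem <- function(belief, threshold = 0.1) {
  cf <- summarize_belief(belief)$camp_fractions
  cf["negative"] > threshold && cf["positive"] > threshold
}
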