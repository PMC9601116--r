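# Exact simulation of the coupled pair.
#
# The linear system diagonalizes into the separation D = X1 - X2, an
# Ornstein-Uhlenbeck process with rate lambda = alpha1 + alpha2 and noise
# intensity beta1^2 + beta2^2, and the drift-free centre of mass
# C = (alpha2 X1 + alpha1 X2) / lambda, a pure diffusion.  Both are driven by
# the same two white noises, so their increments over a step are correlated;
# the exact joint Gaussian transition kernel is sampled step by step, which
# makes the simulator free of discretization bias at any step size.

# second moments of the diagonalized pair, shared by the simulator and the
# covariance assembly
.diag_coeffs <- function(params) {
  l <- params$alpha1 + params$alpha2
  list(
    lambda = l,
    qD  = params$beta1^2 + params$beta2^2,                               # D noise intensity
    sD2 = (params$beta1^2 + params$beta2^2) / (2 * l),                   # stationary Var(D)
    sC2 = (params$alpha2^2 * params$beta1^2 + params$alpha1^2 * params$beta2^2) / l^2,
    qCD = (params$alpha2 * params$beta1^2 - params$alpha1 * params$beta2^2) / l,
    w1  = params$alpha1 / l,   # X1 = C + w1 D
    w2  = params$alpha2 / l    # X2 = C - w2 D
  )
}

#' Simulate exact trajectories of the coupled stimuli
#'
#' Draws `n_reps` independent trajectories of \eqn{(X_1, X_2)} on an arbitrary
#' strictly increasing time grid using the exact Gaussian transition kernel of
#' the diagonalized system (no Euler discretization bias), including the
#' cross-covariance between the centre-of-mass and separation increments
#' induced by the shared noises.
#'
#' @param params a [make_params()] object.
#' @param x0_pair numeric length-2 initial values `c(x1, x2)` at `t_grid[1]`.
#'   Defaults to a separation of `10 * ell` centred on zero.
#' @param t_grid strictly increasing numeric vector of observation times; the
#'   first element is the (deterministic) initial time.
#' @param n_reps number of replicates, `>= 1`.
#' @param seed optional integer seed for reproducibility.
#' @return An object of class `path_ensemble`: a list with `t` (time grid),
#'   `x1` and `x2` (matrices, rows = replicates), `params`, `x0`, `seed`.
#' @examples
#' p <- make_params_ab(0, 0)
#' ens <- simulate_paths(p, t_grid = seq(0, 10, by = 0.1), n_reps = 3, seed = 1)
#' @export
simulate_paths <- function(params, x0_pair = NULL, t_grid, n_reps = 1, seed = NULL) {
  stopifnot(inherits(params, "qualia_params"))
  if (length(t_grid) < 2 || any(diff(t_grid) <= 0))
    stop("t_grid must be strictly increasing with at least two points")
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (!is.null(seed)) {
    if (!is.numeric(seed) || !is.finite(seed)) stop("invalid seed")
    set.seed(seed)
  }
  if (is.null(x0_pair)) x0_pair <- c(5 * params$ell, -5 * params$ell)
  stopifnot(length(x0_pair) == 2, all(is.finite(x0_pair)))

  co <- .diag_coeffs(params)
  nt <- length(t_grid)
  D <- matrix(0, n_reps, nt)
  C <- matrix(0, n_reps, nt)
  D[, 1] <- x0_pair[1] - x0_pair[2]
  C[, 1] <- co$w2 * x0_pair[1] + co$w1 * x0_pair[2]
  hs <- diff(t_grid)
  uniform <- diff(range(hs)) < 1e-12 * max(hs)
  step_mom <- function(h) {
    e <- exp(-co$lambda * h)
    vD <- co$sD2 * (1 - e^2)
    vC <- co$sC2 * h
    cv <- co$qCD * (1 - e) / co$lambda
    list(e = e, vD = vD, vC = vC, cv = cv,
         condv = if (vC > 0) max(vD - cv^2 / vC, 0) else max(vD, 0))
  }
  if (uniform) {
    # one kernel for every step: draw all innovations at once and apply the
    # AR(1) recursion for D along time with a fast filter
    m <- step_mom(hs[1])
    ZC <- matrix(stats::rnorm(n_reps * (nt - 1)), n_reps)
    ZD <- matrix(stats::rnorm(n_reps * (nt - 1)), n_reps)
    if (m$vC > 0) {
      incC <- sqrt(m$vC) * ZC
      incD <- (m$cv / m$vC) * incC + sqrt(m$condv) * ZD
    } else {
      incC <- ZC * 0
      incD <- sqrt(m$condv) * ZD
    }
    C[, -1] <- C[, 1] + t(apply(incC, 1, cumsum))
    ek <- m$e^(seq_len(nt - 1))
    for (r in seq_len(n_reps))
      D[r, -1] <- ek * D[r, 1] +
        as.numeric(stats::filter(incD[r, ], m$e, method = "recursive"))
  } else {
    for (i in 2:nt) {
      m <- step_mom(hs[i - 1])
      zc <- stats::rnorm(n_reps)
      zd <- stats::rnorm(n_reps)
      if (m$vC > 0) {
        incC <- sqrt(m$vC) * zc
        incD <- (m$cv / m$vC) * incC + sqrt(m$condv) * zd
      } else {
        incC <- rep(0, n_reps)
        incD <- sqrt(m$condv) * zd
      }
      D[, i] <- D[, i - 1] * m$e + incD
      C[, i] <- C[, i - 1] + incC
    }
  }
  structure(list(t = t_grid,
                 x1 = C + co$w1 * D,
                 x2 = C - co$w2 * D,
                 params = params, x0 = x0_pair, seed = seed),
            class = "path_ensemble")
}

#' @export
print.path_ensemble <- function(x, ...) {
  cat(sprintf("Path ensemble: %d replicate(s), %d time points on [%g, %g]\n",
              nrow(x$x1), length(x$t), min(x$t), max(x$t)))
  invisible(x)
}

#' @describeIn simulate_paths tidy long-format view (columns `replicate`,
#'   `t`, `x1`, `x2`).
#' @param x a `path_ensemble`.
#' @param row.names,optional,... passed for S3 compatibility; unused.
#' @export
as.data.frame.path_ensemble <- function(x, row.names = NULL, optional = FALSE, ...) {
  nr <- nrow(x$x1)
  data.frame(
    replicate = rep(seq_len(nr), each = length(x$t)),
    t  = rep(x$t, times = nr),
    x1 = as.vector(t(x$x1)),
    x2 = as.vector(t(x$x2))
  )
}

#' Export a path ensemble to CSV with a YAML parameter sidecar
#'
#' Writes the tidy trajectory table (`replicate, t, x1, x2`) to `path` and the
#' generating parameters to `<path>.yml`.
#'
#' @param ensemble a `path_ensemble`.
#' @param path output CSV file path.
#' @return `path`, invisibly.
#' @export
write_paths_csv <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "path_ensemble"))
  utils::write.csv(as.data.frame(ensemble), path, row.names = FALSE)
  side <- list(
    alpha1 = ensemble$params$alpha1, alpha2 = ensemble$params$alpha2,
    beta1 = ensemble$params$beta1, beta2 = ensemble$params$beta2,
    a = ensemble$params$a, b = ensemble$params$b,
    tau = ensemble$params$tau, ell = ensemble$params$ell,
    x0 = as.numeric(ensemble$x0),
    seed = if (is.null(ensemble$seed)) NA else ensemble$seed,
    n_reps = nrow(ensemble$x1), n_times = length(ensemble$t)
  )
  yaml::write_yaml(side, paste0(path, ".yml"))
  invisible(path)
}
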