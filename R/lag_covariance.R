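# Joint Gaussian structure of the present and the lagged history.
#
# The centre of mass C is a drift-free diffusion, so raw covariances of the
# sampled coordinates diverge in the long-time limit.  All coordinates are
# therefore expressed relative to the oldest stored own-history sample
# X1(t - N dt); in these "reduced" coordinates the stationary covariance is
# finite, and conditional mutual informations (hence transfer entropy) are
# unchanged because the reference is a deterministic function of the
# conditioning set and the absolute level decouples as t -> infinity.
#
# Building blocks, with s measured from the reference time and
# DC(s) = C(s) - C(0):
#   Cov(DC(s), DC(u)) = sC2 * min(s, u)
#   Cov(D(s),  D(u))  = sD2 * exp(-lambda |s - u|)              (stationary)
#   Cov(DC(s), D(u))  = (qCD/lambda) (e^{-lambda (u - min(s,u))} - e^{-lambda u})
# and X1(s) - X1(0) = DC(s) + w1 (D(s) - D(0)),
#     X2(s) - X1(0) = DC(s) - w2 D(s) - w1 D(0).

.cov_DC_D <- function(s, u, lambda, qCD) {
  (qCD / lambda) * (exp(-lambda * (u - pmin(s, u))) - exp(-lambda * u))
}

# covariance matrix of reduced coordinates X_{proc[i]}(times[i]) - X1(0),
# stationary (t -> infinity) limit; times >= 0 measured from the reference
.reduced_cov <- function(params, times, procs) {
  co <- .diag_coeffs(params)
  cc <- ifelse(procs == 1L, co$w1, -co$w2)   # weight of D(s)
  dd <- rep(-co$w1, length(procs))           # weight of D(0)
  n <- length(times)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(i)) {
    si <- times[i]; sj <- times[j]
    v <- co$sC2 * min(si, sj) +
      cc[j] * .cov_DC_D(si, sj, co$lambda, co$qCD) +
      cc[i] * .cov_DC_D(sj, si, co$lambda, co$qCD) +
      cc[i] * cc[j] * co$sD2 * exp(-co$lambda * abs(si - sj)) +
      cc[i] * dd[j] * co$sD2 * exp(-co$lambda * si) +
      dd[i] * cc[j] * co$sD2 * exp(-co$lambda * sj) +
      dd[i] * dd[j] * co$sD2
    M[i, j] <- M[j, i] <- v
  }
  M
}

#' Stationary covariance of the present and the stored history
#'
#' Exact long-time covariance of the `2N + 1` coordinates an agent with
#' architecture `(N, dt)` works with: the present value \eqn{X_1(t)} and the
#' stored snapshots \eqn{X_1(t - k\,dt)}, \eqn{X_2(t - k\,dt)},
#' \eqn{k = 1, \dots, N}.  Because the centre of mass diffuses without bound,
#' every coordinate is expressed relative to the oldest own-history sample
#' \eqn{X_1(t - N\,dt)} (whose own row and column are therefore exactly
#' zero); all information measures computed from this matrix equal their
#' unreduced long-time limits.
#'
#' @param params a [make_params()] object.
#' @param arch an [architecture()] object.
#' @return A `lag_covariance` object: the `(2N+1) x (2N+1)` matrix with
#'   dimnames naming each coordinate, and attributes `params`, `arch`,
#'   `reference`.
#' @examples
#' lc <- stationary_lag_covariance(make_params_ab(0, 0), architecture(2, 0.5))
#' eigen(unclass(lc), only.values = TRUE)$values  # all >= 0
#' @seealso [finite_time_lag_covariance()] for the unreduced finite-time
#'   cross-check.
#' @export
stationary_lag_covariance <- function(params, arch) {
  stopifnot(inherits(params, "qualia_params"), inherits(arch, "architecture"))
  N <- arch$N; dt <- arch$dt
  # coordinate times measured from the reference t - N dt
  times <- c(N * dt, (N - seq_len(N)) * dt, (N - seq_len(N)) * dt)
  procs <- c(1L, rep(1L, N), rep(2L, N))
  M <- .reduced_cov(params, times, procs)
  labs <- c("x1[t]",
            sprintf("x1[t-%ddt]", seq_len(N)),
            sprintf("x2[t-%ddt]", seq_len(N)))
  dimnames(M) <- list(labs, labs)
  structure(M, class = c("lag_covariance", "matrix"),
            params = params, arch = arch, reference = sprintf("x1[t-%ddt]", N))
}

#' @export
print.lag_covariance <- function(x, ...) {
  arch <- attr(x, "arch")
  cat(sprintf("Stationary lag covariance (reduced coordinates), N = %d, dt = %g\n",
              arch$N, arch$dt))
  cat(sprintf("  reference coordinate: %s (zero row/column)\n", attr(x, "reference")))
  print(round(unclass(x), 6))
  invisible(x)
}

#' Finite-time covariance of the unreduced history coordinates
#'
#' Covariance of the raw (not reference-shifted) coordinates
#' \eqn{X_1(t)}, \eqn{X_1(t-k\,dt)}, \eqn{X_2(t-k\,dt)} for a process started
#' from a deterministic initial condition at time 0 and observed at time
#' `t_now`.  At finite `t_now` all entries are finite; as `t_now` grows the
#' implied conditional information measures converge to those of
#' [stationary_lag_covariance()], which is used as an independent
#' cross-check of the reduced construction.
#'
#' @param params a [make_params()] object.
#' @param arch an [architecture()] object.
#' @param t_now observation time, `> N * dt`.
#' @return A `(2N+1) x (2N+1)` covariance matrix with the same coordinate
#'   order and dimnames as [stationary_lag_covariance()].
#' @export
finite_time_lag_covariance <- function(params, arch, t_now) {
  stopifnot(inherits(params, "qualia_params"), inherits(arch, "architecture"))
  N <- arch$N; dt <- arch$dt
  if (t_now <= N * dt) stop("t_now must exceed the look-back window N * dt")
  co <- .diag_coeffs(params)
  times <- c(t_now, t_now - seq_len(N) * dt, t_now - seq_len(N) * dt)
  procs <- c(1L, rep(1L, N), rep(2L, N))
  cc <- ifelse(procs == 1L, co$w1, -co$w2)
  n <- length(times)
  covDD <- function(s, u)
    co$sD2 * (exp(-co$lambda * abs(s - u)) - exp(-co$lambda * (s + u)))
  covCD <- function(s, u)   # Cov(C(s), D(u)), C started at 0
    (co$qCD / co$lambda) * (exp(-co$lambda * (u - pmin(s, u))) - exp(-co$lambda * u))
  M <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(i)) {
    si <- times[i]; sj <- times[j]
    v <- co$sC2 * min(si, sj) +
      cc[j] * covCD(si, sj) + cc[i] * covCD(sj, si) +
      cc[i] * cc[j] * covDD(si, sj)
    M[i, j] <- M[j, i] <- v
  }
  labs <- c("x1[t]",
            sprintf("x1[t-%ddt]", seq_len(N)),
            sprintf("x2[t-%ddt]", seq_len(N)))
  dimnames(M) <- list(labs, labs)
  M
}

# Well-conditioned covariance for the transfer-entropy computation in the
# direction 2 -> 1: consecutive-increment coordinates spanning the same
# blocks as the reduced ones.  Unit-triangular (determinant-one) within-block
# transforms leave every block determinant unchanged while keeping all
# entries on the scale of one sampling step, which matters for dt << tau.
#
# Coordinates (reference time 0 = t - N dt, sample times j*dt, j = 0..N):
#   F   = X1(N dt)      - X1((N-1) dt)
#   O_k = X1((N-k) dt)  - X1((N-k-1) dt),  k = 1..N-1
#   S_k = X2((N-k) dt)  - X2((N-k-1) dt),  k = 1..N-1
#   S_N = X2(0) - X1(0) = -D(0)
# Returns the coordinate covariance and the index sets of the three blocks.
.te_increment_cov <- function(params, N, dt) {
  co <- .diag_coeffs(params)
  m <- N + 1                     # sample times 0..N in units of dt
  ts <- (0:N) * dt
  # basis: DC(ts[1..m]) then D(ts[1..m])
  S <- matrix(ts, m, m); U <- t(S)
  CC <- co$sC2 * pmin(S, U)
  DD <- co$sD2 * exp(-co$lambda * abs(S - U))
  CD <- (co$qCD / co$lambda) * (exp(-co$lambda * (U - pmin(S, U))) -
                                  exp(-co$lambda * U))
  SB <- rbind(cbind(CC, CD), cbind(t(CD), DD))
  wdiff <- function(jhi, jlo, w) {          # X(ts[jhi]) - X(ts[jlo]), D-weight w
    v <- numeric(2 * m)
    v[jhi] <- 1; v[jlo] <- v[jlo] - 1
    v[m + jhi] <- w; v[m + jlo] <- v[m + jlo] - w
    v
  }
  W <- matrix(0, 2 * N, 2 * m)
  W[1, ] <- wdiff(N + 1, N, co$w1)                       # F
  if (N > 1) for (k in seq_len(N - 1)) {
    W[1 + k, ] <- wdiff(N + 1 - k, N - k, co$w1)         # O_k
    W[N + k, ] <- wdiff(N + 1 - k, N - k, -co$w2)        # S_k
  }
  W[2 * N, m + 1] <- -1                                  # S_N = -D(0)
  M <- W %*% SB %*% t(W)
  list(M = (M + t(M)) / 2,
       iF = 1L,
       iO = if (N > 1) 2:N else integer(0),
       iS = (N + 1):(2 * N))
}
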