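# Gaussian information measures in bits.

# log-determinant of a symmetric covariance block; -Inf signals singularity.
# Cholesky is the fast path; near-singular blocks fall back to an eigen
# decomposition with a relative threshold.
.logdet <- function(M, tol = 1e-12) {
  if (length(M) == 0) return(0)
  R <- tryCatch(chol(M), error = function(e) NULL)
  if (!is.null(R)) {
    d <- diag(R)
    sc <- max(d)
    if (sc > 0 && min(d) > sqrt(tol) * sc) return(2 * sum(log(d)))
  }
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  scale <- max(abs(ev), 0)
  if (scale == 0 || min(ev) <= tol * scale) return(-Inf)
  sum(log(ev))
}

#' Mutual information of two blocks of a Gaussian vector
#'
#' For jointly Gaussian blocks A and B with marginal covariances
#' \eqn{\Sigma_{AA}}, \eqn{\Sigma_{BB}} and joint covariance \eqn{\Sigma},
#' \deqn{M[A{:}B] = \tfrac12 \log_2 \frac{|\Sigma_{AA}||\Sigma_{BB}|}{|\Sigma|}.}
#'
#' A singular joint covariance with non-singular marginals (a deterministic
#' relation between the blocks) yields `Inf`, not an error.
#'
#' @param joint_cov symmetric positive semi-definite covariance matrix.
#' @param idx_A,idx_B disjoint, non-empty integer index vectors into
#'   `joint_cov` selecting the two blocks.
#' @return Mutual information in bits (`>= 0`, possibly `Inf`).
#' @examples
#' S <- matrix(c(1, 0.5, 0.5, 1), 2)
#' gaussian_mutual_information(S, 1, 2)   # -0.5 * log2(1 - 0.25)
#' @export
gaussian_mutual_information <- function(joint_cov, idx_A, idx_B) {
  joint_cov <- unclass(joint_cov)
  stopifnot(is.matrix(joint_cov), nrow(joint_cov) == ncol(joint_cov))
  idx_A <- as.integer(idx_A); idx_B <- as.integer(idx_B)
  if (length(idx_A) == 0 || length(idx_B) == 0)
    stop("index sets must be non-empty")
  if (length(intersect(idx_A, idx_B)) > 0)
    stop("index sets must be disjoint")
  ldA <- .logdet(joint_cov[idx_A, idx_A, drop = FALSE])
  ldB <- .logdet(joint_cov[idx_B, idx_B, drop = FALSE])
  ldJ <- .logdet(joint_cov[c(idx_A, idx_B), c(idx_A, idx_B), drop = FALSE])
  if (!is.finite(ldA) || !is.finite(ldB)) {
    # a singular marginal carries a deterministic coordinate; drop nothing,
    # treat the degenerate direction as shared only if the joint is equally
    # singular -- conservatively report Inf only when the joint is *more*
    # singular than the marginals combined
    if (is.finite(ldJ)) return(Inf)
    return(0)
  }
  if (!is.finite(ldJ)) return(Inf)
  mi <- 0.5 * (ldA + ldB - ldJ) / log(2)
  max(mi, 0)
}

# conditional mutual information I(A;B|C) in bits from a joint covariance
# I = 1/2 log2( |S_AC| |S_BC| / (|S_C| |S_ABC|) );  C may be empty
.gaussian_cmi <- function(M, iA, iB, iC = integer(0)) {
  ld <- function(ix) .logdet(M[ix, ix, drop = FALSE])
  v <- 0.5 * (ld(c(iA, iC)) + ld(c(iB, iC)) - ld(iC) - ld(c(iA, iB, iC))) / log(2)
  if (is.nan(v)) stop("conditional mutual information undefined: singular covariance")
  v
}

#' A pair of directed transfer entropies
#'
#' Container pairing the two directed transfer entropies between the
#' stimuli, in bits, for a given architecture.
#'
#' @param te_2to1,te_1to2 non-negative transfer entropies in bits.
#' @param arch the [architecture()] they were computed for (optional).
#' @param source one of `"analytic"`, `"simulated"`, `"empirical"`.
#' @param se_2to1,se_1to2 optional standard errors.
#' @return An object of class `te_pair`.
#' @export
te_pair <- function(te_2to1, te_1to2, arch = NULL,
                    source = c("analytic", "simulated", "empirical"),
                    se_2to1 = NA_real_, se_1to2 = NA_real_) {
  source <- match.arg(source)
  stopifnot(is.finite(te_2to1), is.finite(te_1to2),
            te_2to1 >= 0, te_1to2 >= 0)
  structure(list(te_2to1 = te_2to1, te_1to2 = te_1to2, arch = arch,
                 source = source, se_2to1 = se_2to1, se_1to2 = se_1to2),
            class = "te_pair")
}

#' @export
print.te_pair <- function(x, ...) {
  cat(sprintf("Transfer entropy (%s): T[2->1] = %.6g bits, T[1->2] = %.6g bits\n",
              x$source, x$te_2to1, x$te_1to2))
  if (is.finite(x$se_2to1))
    cat(sprintf("  bootstrap SE: %.3g / %.3g\n", x$se_2to1, x$se_1to2))
  invisible(x)
}

#' Exact transfer entropy of the two-stimulus environment
#'
#' Long-time transfer entropy, in bits, seen by an agent with architecture
#' `(N, dt)`: the conditional mutual information between the present of the
#' target process and the stored history of the source process given the
#' stored history of the target,
#' \deqn{T_{2\to1} = I\left(X_{1,t};\, \{X_{2,t-k\,dt}\}_k \,\middle|\, \{X_{1,t-k\,dt}\}_k\right).}
#' This equals the difference of the two mutual informations
#' \eqn{M[X_{1,t} : \mathrm{both\ pasts}] - M[X_{1,t} : \mathrm{own\ past}]},
#' but unlike those individually divergent terms it stays finite in the
#' long-time limit.  Internally the computation uses determinant-preserving
#' consecutive-increment coordinates, keeping it well conditioned from
#' `dt` far below to far above the natural time scale.
#'
#' @param params a [make_params()] object.
#' @param arch an [architecture()] object.
#' @param direction `"2->1"` (default) or `"1->2"`.
#' @return Transfer entropy in bits (non-negative; values below `1e-12` are
#'   clamped to zero).
#' @examples
#' p <- make_params_ab(0.2, 0.3)
#' transfer_entropy_analytic(p, architecture(4, 1))
#' @export
transfer_entropy_analytic <- function(params, arch, direction = c("2->1", "1->2")) {
  stopifnot(inherits(params, "qualia_params"), inherits(arch, "architecture"))
  direction <- match.arg(direction)
  if (direction == "1->2") params <- swap_processes(params)
  ic <- .te_increment_cov(params, arch$N, arch$dt)
  te <- .gaussian_cmi(ic$M, ic$iF, ic$iS, ic$iO)
  if (te < 1e-12) 0 else te
}

#' @describeIn transfer_entropy_analytic both directions as a [te_pair()].
#' @export
analytic_te_pair <- function(params, arch) {
  te_pair(transfer_entropy_analytic(params, arch, "2->1"),
          transfer_entropy_analytic(params, arch, "1->2"),
          arch = arch, source = "analytic")
}

#' Normalized influence between the two stimuli
#'
#' The antisymmetric ratio of directed information flows,
#' \deqn{T_{12} = \frac{T_{1\to2} - T_{2\to1}}{T_{1\to2} + T_{2\to1}} \in [-1, 1].}
#' Positive values mean the history of process 1 is the more informative
#' direction.  When the total flow is below `tol` the influence is defined
#' to be exactly 0.
#'
#' @param te a [te_pair()], or a non-negative numeric `c(te_2to1, te_1to2)`.
#' @param tol total-flow threshold below which the influence is set to 0.
#' @return An `influence_value`: numeric in `[-1, 1]` with the pair attached
#'   as attributes.
#' @export
influence <- function(te, tol = 1e-12) {
  if (is.numeric(te) && length(te) == 2) te <- te_pair(te[1], te[2])
  stopifnot(inherits(te, "te_pair"))
  tot <- te$te_1to2 + te$te_2to1
  val <- if (tot < tol) 0 else (te$te_1to2 - te$te_2to1) / tot
  structure(val, class = "influence_value", te = te)
}

#' @export
print.influence_value <- function(x, ...) {
  cat(sprintf("Influence T12 = %+.6g\n", as.numeric(x)))
  invisible(x)
}

# influence straight from parameters (internal fast path used by scans)
.influence_analytic <- function(params, N, dt, tol = 1e-12) {
  t21 <- transfer_entropy_analytic(params, architecture(N, dt), "2->1")
  t12 <- transfer_entropy_analytic(params, architecture(N, dt), "1->2")
  tot <- t12 + t21
  if (tot < tol) 0 else (t12 - t21) / tot
}

#' Influence for an agent, from the exact model
#'
#' @param params a [make_params()] object.
#' @param arch an [architecture()] object.
#' @inheritParams influence
#' @return An `influence_value`.
#' @export
influence_analytic <- function(params, arch, tol = 1e-12) {
  influence(analytic_te_pair(params, arch), tol = tol)
}

#' Small-asymmetry expansion of the influence at N = 1
#'
#' Two-term expansion of the long-time influence for a single-snapshot agent
#' in the regime \eqn{(a+b) \sim \epsilon}, \eqn{|b-a| \sim \epsilon^2},
#' \eqn{dt \sim \epsilon^2}:
#' \deqn{T_{12}(dt, 1) \approx 2\,(b - a) - \tfrac14\,(a + b)\,dt,}
#' with error of order \eqn{\epsilon^4}.  This expansion was derived for, and
#' validated against, the exact computation in this package (see the methods
#' vignette for the derivation route and the coefficient checks); its zero
#' \eqn{dt^* = 8\,(b-a)/(a+b)} marks the sampling interval at which slow- and
#' fast-sampling agents reverse their conclusions about the direction of
#' information flow.
#'
#' @param a,b dimensionless asymmetries.
#' @param dt sampling interval in units of the natural time `tau`.
#' @return The expansion value (the caller judges regime validity).
#' @export
influence_small_limit <- function(a, b, dt) {
  2 * (b - a) - (a + b) * dt / 4
}

#' Plug-in Gaussian transfer entropy from paired series
#'
#' Delay-embeds the two series at the architecture's memory depth and stride,
#' forms the unbiased sample covariance of the `2N + 1` embedding
#' coordinates, and evaluates the Gaussian conditional mutual information in
#' both directions.  The estimator is invariant under affine rescaling of
#' either series.
#'
#' @param x1,x2 numeric series of equal length (`x1` is the target of the
#'   `2->1` direction).
#' @param arch an [architecture()]; `arch$dt` is interpreted as the stride in
#'   units of the native sampling step and must be a positive integer.
#' @param n_boot if `> 0`, number of circular block-bootstrap resamples of
#'   the embedding rows used for standard errors.
#' @param shrinkage ridge weight in `[0, 1)` toward the scaled identity,
#'   for short series; `0` (default) uses the raw sample covariance.
#' @param seed optional seed for the bootstrap.
#' @return A [te_pair()] with `source = "empirical"`.
#' @examples
#' p <- make_params_ab(0.1, 0)
#' xy <- gen_coupled_ou(p, architecture(2, 0.5), n_points = 5000, seed = 1)
#' transfer_entropy_empirical(xy$x1, xy$x2, architecture(2, 1))
#' @export
transfer_entropy_empirical <- function(x1, x2, arch, n_boot = 0,
                                       shrinkage = 0, seed = NULL) {
  stopifnot(inherits(arch, "architecture"))
  N <- arch$N
  stride <- arch$dt
  if (stride != round(stride) || stride < 1)
    stop("arch$dt must be a positive integer stride for the empirical estimator")
  stride <- as.integer(stride)
  n <- length(x1)
  if (length(x2) != n) stop("x1 and x2 must have equal length")
  if (n <= 2 * N + 10) stop("series too short for the requested memory depth")
  if (!is.null(seed)) set.seed(seed)

  emb <- .delay_embed(x1, x2, N, stride)
  est <- function(rows) {
    M <- stats::cov(emb[rows, , drop = FALSE])
    if (shrinkage > 0) {
      d <- mean(diag(M))
      M <- (1 - shrinkage) * M + shrinkage * d * diag(nrow(M))
    }
    .embedded_te_both(M, N, n = length(rows))
  }
  all_rows <- seq_len(nrow(emb))
  point <- est(all_rows)
  se <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    bl <- max(25L, 10L * N * stride)          # block length, native steps
    nb <- nrow(emb)
    draws <- replicate(n_boot, {
      starts <- sample.int(nb, ceiling(nb / bl), replace = TRUE)
      rows <- as.vector(outer(0:(bl - 1), starts, "+")) %% nb + 1L
      unlist(est(rows[seq_len(nb)]))
    })
    se <- apply(draws, 1, stats::sd)
  }
  te_pair(point$te_2to1, point$te_1to2, arch = arch, source = "empirical",
          se_2to1 = se[1], se_1to2 = se[2])
}

# rows = time, cols = (x1[t], x2[t], x1 lags 1..N, x2 lags 1..N) at the
# given stride; one embedding serves both directions
.delay_embed <- function(x1, x2, N, stride) {
  n <- length(x1)
  idx <- (N * stride + 1):n
  emb <- matrix(0, length(idx), 2 * N + 2)
  emb[, 1] <- x1[idx]
  emb[, 2] <- x2[idx]
  for (k in seq_len(N)) {
    emb[, 2 + k] <- x1[idx - k * stride]
    emb[, 2 + N + k] <- x2[idx - k * stride]
  }
  emb
}

# expected excess of log|S| over log|Sigma| for the sample covariance of
# n iid Gaussian rows in dimension k (log-Wishart first moment)
.logdet_bias <- function(n, k) {
  if (k == 0) return(0)
  sum(digamma((n - seq_len(k)) / 2)) + k * log(2 / (n - 1))
}

# both directed TEs from an embedding covariance at memory depth N (which may
# be smaller than the depth the embedding was built with, Nmax); errors name
# the rank-deficient block.  When the number of rows n is supplied, the
# plug-in is debiased by the exact Gaussian log-determinant moments (the
# plug-in otherwise inflates both directions by about N/(2 n ln 2) bits,
# which shrinks the influence ratio toward zero as N grows).
.embedded_te_both <- function(M, N, Nmax = N, n = NULL) {
  iO <- 2L + seq_len(N)            # x1 lags 1..N
  iS <- 2L + Nmax + seq_len(N)     # x2 lags 1..N
  chk <- function(ix, what) {
    if (!is.finite(.logdet(M[ix, ix, drop = FALSE])))
      stop(sprintf("rank-deficient embedding covariance in the %s block", what))
  }
  chk(iO, "x1 history"); chk(iS, "x2 history")
  corr <- 0
  if (!is.null(n) && n > 2 * N + 4) {
    b <- function(k) .logdet_bias(n, k)
    corr <- (b(N + 1) + b(2 * N) - b(N) - b(2 * N + 1)) / (2 * log(2))
  }
  list(te_2to1 = max(.gaussian_cmi(M, 1L, iS, iO) - corr, 0),
       te_1to2 = max(.gaussian_cmi(M, 2L, iO, iS) - corr, 0))
}

#' Locate sign changes of the influence along the sampling interval
#'
#' Scans the exact influence on a log-spaced grid of sampling intervals at
#' fixed memory size and brackets every sign change, refining each bracket by
#' bisection to a relative width of `1e-3`.  An exact zero at a grid node is
#' treated as a crossing.
#'
#' @param params a [make_params()] object.
#' @param N memory size (snapshots).
#' @param dt_range length-2 positive range of sampling intervals to scan.
#' @param n_grid number of log-spaced grid points (`>= 50`).
#' @return A data frame with one row per crossing: columns `dt_lo`, `dt_hi`
#'   (the refined bracket) and `dt_cross` (its geometric midpoint).  Zero
#'   rows if the influence does not change sign.
#' @examples
#' crossover_scan(make_params_ab(0.2, 0.3), N = 4)
#' @export
crossover_scan <- function(params, N, dt_range = c(1e-3, 1e3), n_grid = 60) {
  stopifnot(inherits(params, "qualia_params"),
            length(dt_range) == 2, all(dt_range > 0), dt_range[1] < dt_range[2])
  if (n_grid < 50) stop("n_grid must be at least 50")
  g <- exp(seq(log(dt_range[1]), log(dt_range[2]), length.out = n_grid))
  v <- vapply(g, function(dt) .influence_analytic(params, N, dt), numeric(1))
  out <- data.frame(dt_lo = numeric(0), dt_hi = numeric(0), dt_cross = numeric(0))
  sgn <- sign(v)
  for (i in seq_len(n_grid - 1)) {
    hit <- FALSE
    if (sgn[i] == 0) {                       # exact zero at a node
      lo <- hi <- g[i]; hit <- TRUE
    } else if (sgn[i] * sgn[i + 1] < 0) {
      lo <- g[i]; hi <- g[i + 1]
      while ((hi - lo) / hi > 1e-3) {
        mid <- sqrt(lo * hi)
        vm <- .influence_analytic(params, N, mid)
        if (vm == 0) { lo <- hi <- mid; break }
        if (sign(vm) == sgn[i]) lo <- mid else hi <- mid
      }
      hit <- TRUE
    }
    if (hit)
      out <- rbind(out, data.frame(dt_lo = lo, dt_hi = hi,
                                   dt_cross = sqrt(lo * hi)))
  }
  if (sgn[n_grid] == 0)
    out <- rbind(out, data.frame(dt_lo = g[n_grid], dt_hi = g[n_grid],
                                 dt_cross = g[n_grid]))
  out
}

#' Stabilization of the crossover locus with growing memory
#'
#' For fixed stochastic asymmetry `b`, the set of `(a, dt)` points where the
#' influence vanishes forms a locus whose `dt` locations move as the memory
#' size `N` grows.  This helper computes, for each `a` on a grid, the
#' principal (largest-`dt`) sign change of the influence at every `N`, and
#' the maximum relative displacement of those locations between consecutive
#' memory sizes.  The reported `stable_N` is the smallest `N` whose locus is
#' displaced by less than `threshold` relative to `N + 1`.
#'
#' @param b stochastic asymmetry (couplings taken in natural units,
#'   `tau = ell = 1`).
#' @param a_grid deterministic asymmetries to scan.
#' @param N_values increasing integer memory sizes (consecutive values are
#'   compared).
#' @param dt_range sampling-interval range for [crossover_scan()].
#' @param threshold relative-displacement threshold (default 2%).
#' @param n_grid grid size passed to [crossover_scan()].
#' @return A list with `locus` (matrix of principal crossing `dt`s,
#'   rows = `a_grid`, cols = `N_values`, `NA` where no crossing),
#'   `max_shift` (named vector, per consecutive-`N` step) and `stable_N`.
#' @export
crossover_locus_stability <- function(b, a_grid, N_values = 1:16,
                                      dt_range = c(1e-3, 1e3),
                                      threshold = 0.02, n_grid = 50) {
  N_values <- sort(as.integer(N_values))
  locus <- matrix(NA_real_, length(a_grid), length(N_values),
                  dimnames = list(NULL, N_values))
  for (i in seq_along(a_grid)) {
    if (abs(a_grid[i]) >= 1) next
    p <- make_params_ab(a_grid[i], b)
    for (j in seq_along(N_values)) {
      cr <- crossover_scan(p, N_values[j], dt_range, n_grid)
      if (nrow(cr) > 0) locus[i, j] <- max(cr$dt_cross)
    }
  }
  nstep <- length(N_values) - 1
  max_shift <- rep(NA_real_, nstep)
  names(max_shift) <- sprintf("%d->%d", N_values[-length(N_values)], N_values[-1])
  for (j in seq_len(nstep)) {
    both <- which(!is.na(locus[, j]) & !is.na(locus[, j + 1]))
    if (length(both))
      max_shift[j] <- max(abs(locus[both, j] - locus[both, j + 1]) /
                            locus[both, j + 1])
  }
  ok <- which(is.finite(max_shift) & max_shift < threshold)
  list(locus = locus, max_shift = max_shift,
       stable_N = if (length(ok)) N_values[ok[1]] else NA_integer_)
}
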