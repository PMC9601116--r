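test_that("Gaussian mutual information matches closed forms and is symmetric", {
  # independent blocks
  S <- diag(c(1, 2, 3))
  expect_equal(gaussian_mutual_information(S, 1, 2:3), 0)
  # bivariate with correlation 0.5
  S2 <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(gaussian_mutual_information(S2, 1, 2),
               -0.5 * log2(1 - 0.25), tolerance = 1e-12)
  # symmetry in the arguments
  S3 <- crossprod(matrix(rnorm(16), 4))
  expect_equal(gaussian_mutual_information(S3, 1:2, 3:4),
               gaussian_mutual_information(S3, 3:4, 1:2), tolerance = 1e-12)
  # overlapping or empty index sets are rejected
  expect_error(gaussian_mutual_information(S3, 1:2, 2:3), "disjoint")
  expect_error(gaussian_mutual_information(S3, integer(0), 1), "non-empty")
})

test_that("a deterministic relation between blocks gives infinite information", {
  S <- matrix(c(1, 1, 1, 1), 2)   # B == A, singular joint, regular marginals
  expect_identical(gaussian_mutual_information(S, 1, 2), Inf)
})

test_that("transfer entropy equals the difference of mutual informations (finite-time check)", {
  p <- make_params_ab(0.25, 0.1)
  arch <- architecture(3, 0.8)
  M <- finite_time_lag_covariance(p, arch, t_now = 500 * p$tau)
  iF <- 1; iO <- 2:4; iS <- 5:7
  diff_mi <- gaussian_mutual_information(M, iF, c(iO, iS)) -
    gaussian_mutual_information(M, iF, iO)
  expect_equal(diff_mi, transfer_entropy_analytic(p, arch, "2->1"),
               tolerance = 1e-3)
})

test_that("both transfer entropies are non-negative and influence is antisymmetric", {
  as <- seq(-0.8, 0.8, length.out = 5)
  bs <- seq(-0.8, 0.8, length.out = 5)
  for (a in as) for (b in bs) for (N in c(1, 4)) for (dt in c(0.01, 1, 100)) {
    p <- make_params_ab(a, b)
    arch <- architecture(N, dt)
    t21 <- transfer_entropy_analytic(p, arch, "2->1")
    t12 <- transfer_entropy_analytic(p, arch, "1->2")
    expect_gte(t21, 0)
    expect_gte(t12, 0)
    v <- as.numeric(influence(te_pair(t21, t12)))
    vs <- as.numeric(influence_analytic(swap_processes(p), arch))
    expect_equal(v, -vs, tolerance = 1e-9)
    expect_lte(abs(v), 1)
  }
})

test_that("influence handles equal, one-sided and vanishing flows", {
  expect_equal(as.numeric(influence(te_pair(0.3, 0.3))), 0)
  expect_equal(as.numeric(influence(te_pair(0, 0.2))), 1)
  expect_equal(as.numeric(influence(te_pair(0.2, 0))), -1)
  expect_equal(as.numeric(influence(te_pair(0, 0))), 0)
  expect_equal(as.numeric(influence(te_pair(1e-14, 1e-14))), 0)
})

test_that("the small-asymmetry expansion tracks the exact influence", {
  # symmetric case: zero at all dt
  expect_equal(influence_small_limit(0.01, 0.01, 0.5), -0.02 * 0.5 / 4)
  expect_equal(influence_small_limit(0.01, -0.01, 3), 2 * (-0.02))

  # dt-slope of the exact influence at N = 1, divided by (a + b), approaches
  # -1/4 as the asymmetry shrinks
  slopes <- sapply(c(0.04, 0.01), function(eps) {
    p <- make_params_ab(eps / 2, eps / 2)
    arch <- function(dt) architecture(1, dt)
    d1 <- as.numeric(influence_analytic(p, arch(1e-4)))
    d2 <- as.numeric(influence_analytic(p, arch(2e-4)))
    (d2 - d1) / 1e-4 / eps
  })
  expect_equal(slopes[1], -0.25, tolerance = 0.02)
  expect_equal(slopes[2], -0.25, tolerance = 0.01)

  # expansion root agrees with the exact root to second order in the
  # asymmetry scale
  a <- (0.02 - 1e-4) / 2; b <- (0.02 + 1e-4) / 2
  p <- make_params_ab(a, b)
  root_exact <- uniroot(function(dt)
    as.numeric(influence_analytic(p, architecture(1, dt))), c(1e-4, 10))$root
  root_exp <- 8 * (b - a) / (a + b)
  expect_equal(root_exact, root_exp, tolerance = 5e-3 / root_exp * root_exp + 0.02)

  # quartic-order error: along (a+b) = eps, dt = eps^2, the expansion error
  # shrinks at least like eps^3.5 (log-log slope >= 3)
  eps <- c(0.2, 0.1, 0.05, 0.025)
  err <- sapply(eps, function(e) {
    p <- make_params_ab(e / 2, e / 2)
    abs(as.numeric(influence_analytic(p, architecture(1, e^2))) -
          influence_small_limit(e / 2, e / 2, e^2))
  })
  fit <- lm(log(err) ~ log(eps))
  expect_gte(unname(coef(fit)[2]), 3)
})

test_that("crossover structure across the deterministic asymmetry (b = 0.3, N = 4)", {
  expect_equal(nrow(crossover_scan(make_params_ab(-0.1, 0.3), 4)), 0)
  cr <- crossover_scan(make_params_ab(0.2, 0.3), 4)
  expect_equal(nrow(cr), 1)
  expect_true(cr$dt_cross > 1 && cr$dt_cross < 100)
  expect_lt((cr$dt_hi - cr$dt_lo) / cr$dt_hi, 1e-3)
  expect_equal(nrow(crossover_scan(make_params_ab(0.5, 0.3), 4)), 0)
})

test_that("the set of asymmetries with a crossover forms a contiguous band", {
  a_grid <- seq(0.0, 0.045, by = 0.005)
  has <- sapply(a_grid, function(a) {
    if (a == 0) return(FALSE)
    nrow(crossover_scan(make_params_ab(a, 0.03), 4, n_grid = 50)) > 0
  })
  runs <- rle(has)
  expect_equal(sum(runs$values), 1)   # a single contiguous TRUE run
  expect_true(has[which(a_grid == 0.02)])
})

test_that("at a fixed look-back window the sign of influence depends on its discretization", {
  p <- make_params_ab(0.7, 0.75)
  signs <- sapply(c(1, 2, 4, 8, 16, 32), function(N)
    sign(as.numeric(influence_analytic(p, architecture(N, 5 / N)))))
  expect_true(any(signs > 0) && any(signs < 0))
})

test_that("the empirical estimator matches the analytic transfer entropy", {
  p <- make_params_ab(0.2, 0.3)
  arch <- architecture(3, 1)
  xy <- gen_coupled_ou(p, architecture(3, 1), n_points = 1e5, seed = 21)
  est <- transfer_entropy_empirical(xy$x1, xy$x2, arch, n_boot = 30, seed = 1)
  expect_lt(abs(est$te_2to1 - transfer_entropy_analytic(p, arch, "2->1")),
            3 * est$se_2to1)
  expect_lt(abs(est$te_1to2 - transfer_entropy_analytic(p, arch, "1->2")),
            3 * est$se_1to2)
})

test_that("the empirical estimator is affine invariant and rejects degenerate input", {
  p <- make_params_ab(0.1, 0)
  xy <- gen_coupled_ou(p, architecture(2, 1), n_points = 5000, seed = 5)
  arch <- architecture(2, 1)
  base <- transfer_entropy_empirical(xy$x1, xy$x2, arch)
  scaled <- transfer_entropy_empirical(5 * xy$x1 + 7, xy$x2, arch)
  expect_equal(base$te_2to1, scaled$te_2to1, tolerance = 1e-8)
  expect_equal(base$te_1to2, scaled$te_1to2, tolerance = 1e-8)
  expect_error(transfer_entropy_empirical(xy$x1, rep(1, 5000), arch),
               "rank-deficient.*x2")
  expect_error(transfer_entropy_empirical(xy$x1, xy$x2[1:10], arch), "equal length")
})

test_that("estimator error shrinks as the series grows", {
  p <- make_params_ab(0.3, 0.1)
  arch <- architecture(2, 1)
  truth <- transfer_entropy_analytic(p, arch, "2->1")
  errs <- sapply(c(20000, 80000), function(n) {
    e <- sapply(1:3, function(s) {
      xy <- gen_coupled_ou(p, arch, n_points = n, seed = 100 + s)
      transfer_entropy_empirical(xy$x1, xy$x2, arch)$te_2to1
    })
    mean(abs(e - truth))
  })
  expect_lt(errs[2], errs[1])
})
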