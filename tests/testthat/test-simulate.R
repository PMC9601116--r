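test_that("near-noiseless separation decays deterministically at rate alpha1+alpha2", {
  p <- make_params(0.6, 0.4, 1e-9, 1e-9)
  tg <- seq(0, 5, by = 0.5)
  ens <- simulate_paths(p, x0_pair = c(3, -3), t_grid = tg, n_reps = 2, seed = 1)
  D <- ens$x1 - ens$x2
  expect_equal(D[1, ], 6 * exp(-1 * tg), tolerance = 1e-6)
  expect_equal(D[2, ], 6 * exp(-1 * tg), tolerance = 1e-6)
})

test_that("long-run separation variance matches the OU stationary value", {
  p <- make_params(0.5, 0.5, 0.7, 0.3)
  sD2 <- (0.7^2 + 0.3^2) / (2 * 1)
  tg <- seq(0, 30 * p$tau, by = 0.5)
  ens <- simulate_paths(p, t_grid = tg, n_reps = 4000, seed = 42)
  v <- var(ens$x1[, length(tg)] - ens$x2[, length(tg)])
  se <- sD2 * sqrt(2 / 4000)
  expect_lt(abs(v - sD2), 4 * se)
})

test_that("ensemble centre of mass is driftless", {
  p <- make_params(0.8, 0.2, 0.5, 0.5)
  tg <- seq(0, 10, by = 1)
  ens <- simulate_paths(p, x0_pair = c(5, -5), t_grid = tg, n_reps = 5000, seed = 7)
  com <- 0.2 / 1 * ens$x1 + 0.8 / 1 * ens$x2   # alpha2 x1 + alpha1 x2, lambda = 1
  m <- colMeans(com)
  expect_lt(max(abs(m - m[1])), 4 * max(apply(com, 2, sd)) / sqrt(5000))
})

test_that("sampled lag covariances agree with the closed form across asymmetries", {
  cases <- list(c(-0.5, 0.2), c(0, 0), c(0.7, 0.4))
  for (cs in cases) {
    p <- make_params_ab(cs[1], cs[2])
    arch <- architecture(2, 0.7)
    burn <- 20 * p$tau
    tg <- seq(0, burn + arch$N * arch$dt, by = arch$dt)
    nreps <- 10000
    ens <- simulate_paths(p, t_grid = tg, n_reps = nreps, seed = 99)
    nt <- length(tg)
    ref <- ens$x1[, nt - arch$N]
    V <- cbind(ens$x1[, nt] - ref,
               ens$x1[, nt - 1] - ref,
               ens$x2[, nt - 1] - ref, ens$x2[, nt - 2] - ref)
    S <- cov(V)
    L <- unclass(stationary_lag_covariance(p, arch))
    A <- L[c(1, 2, 4, 5), c(1, 2, 4, 5)]   # drop the zero reference coordinate
    se <- sqrt((outer(diag(A), diag(A)) + A^2) / nreps)
    expect_true(all(abs(S - A) < 4 * se + 1e-12),
                label = sprintf("lag covariance MC agreement at a=%g b=%g", cs[1], cs[2]))
  }
})

test_that("exact kernels match an independent Euler-Maruyama integration", {
  p <- make_params_ab(0.2, 0.3)
  em <- euler_pair_oracle(p, dt_obs = 1, n_obs = 60000, h = 0.02, seed = 3)
  te_em <- transfer_entropy_empirical(em$x1, em$x2, architecture(2, 1))
  ex <- gen_coupled_ou(p, architecture(2, 1), n_points = 60000, seed = 3)
  te_ex <- transfer_entropy_empirical(ex$x1, ex$x2, architecture(2, 1))
  expect_equal(te_em$te_2to1, te_ex$te_2to1, tolerance = 0.12)
  expect_equal(te_em$te_1to2, te_ex$te_1to2, tolerance = 0.12)
})

test_that("simulation is reproducible given a seed and rejects bad grids", {
  p <- make_params_ab(0.1, 0)
  tg <- seq(0, 5, by = 0.5)
  e1 <- simulate_paths(p, t_grid = tg, n_reps = 3, seed = 5)
  e2 <- simulate_paths(p, t_grid = tg, n_reps = 3, seed = 5)
  expect_identical(e1$x1, e2$x1)
  expect_error(simulate_paths(p, t_grid = c(0, 1, 1)), "strictly increasing")
  expect_error(simulate_paths(p, t_grid = tg, seed = NaN), "invalid seed")
})

test_that("trajectory export round-trips through CSV with a YAML sidecar", {
  p <- make_params_ab(0, 0.2)
  ens <- simulate_paths(p, t_grid = seq(0, 2, by = 1), n_reps = 2, seed = 8)
  path <- file.path(tempdir(), "paths.csv")
  write_paths_csv(ens, path)
  df <- read.csv(path)
  expect_equal(names(df), c("replicate", "t", "x1", "x2"))
  expect_equal(nrow(df), 6)
  expect_equal(df$x1, as.vector(t(ens$x1)))
  side <- yaml::read_yaml(paste0(path, ".yml"))
  expect_equal(side$b, 0.2)
  expect_equal(side$seed, 8)
  unlink(c(path, paste0(path, ".yml")))
})
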