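test_that("the architecture law is correctly normalized with the stated moments", {
  spec <- polity_spec(mean_N = 4, mean_dt = 2, theta = 0.6)
  # geometric marginal sums to 1 and has the requested mean
  Ns <- 1:2000
  pN <- polity_pdf(spec, Ns, 1) / dlnorm(1, spec$meanlog, spec$theta)
  expect_equal(sum(pN), 1, tolerance = 1e-10)
  expect_equal(sum(Ns * pN), 4, tolerance = 1e-8)
  # dt marginal integrates to 1 with mean <dt> (quadrature oracle)
  dens <- function(dt) polity_pdf(spec, 1, dt) / pN[1]
  expect_equal(integrate(dens, 0, Inf, rel.tol = 1e-10)$value, 1,
               tolerance = 1e-8)
  expect_equal(integrate(function(u) u * dens(u), 0, Inf, rel.tol = 1e-10)$value,
               2, tolerance = 1e-8)
  expect_error(polity_spec(mean_N = 1, mean_dt = 1, theta = 1), "exceed 1")
  expect_error(polity_pdf(spec, 0, 1), "integer")
})

test_that("theta is the log-RMS spread: ln(<dt^2>/<dt>^2) recovers theta^2", {
  spec <- polity_spec(mean_N = 2, mean_dt = 1.5, theta = 0.5)
  set.seed(11)
  dts <- rlnorm(1e6, spec$meanlog, spec$theta)
  expect_equal(log(mean(dts^2) / mean(dts)^2), 0.25, tolerance = 0.01)
})

test_that("sampled agents reproduce the population law", {
  spec <- polity_spec(mean_N = 5, mean_dt = 1, theta = 0.4, N1 = 2, N2 = 8)
  ag <- sample_agents(spec, 1e5, seed = 3)
  Ns <- vapply(ag, `[[`, 1, "N")
  se <- sd(Ns) / sqrt(length(Ns))
  expect_lt(abs(mean(Ns) - 5), 3 * se)
  one <- sample_agents(spec, 1, seed = 1)
  expect_s3_class(one[[1]], "architecture")
  cens <- sample_agents(spec, 5000, seed = 4, reject_censored = TRUE)
  expect_true(all(vapply(cens, `[[`, 1, "N") <= 8))
})

test_that("a constant influence collapses the belief to a point mass", {
  spec <- polity_spec(mean_N = 3, mean_dt = 1, theta = 0.5)
  bel <- belief_distribution(spec, function(arch) 0.3)
  expect_true(all(bel$components$location == 0.3))
  expect_equal(sum(bel$components$weight), 1, tolerance = 1e-12)
  s <- summarize_belief(bel)
  expect_equal(s$mean, 0.3)
  expect_equal(unname(s$camp_fractions), c(0, 0, 1))
})

test_that("a step-function influence reproduces the closed-form two-camp weights", {
  spec <- polity_spec(mean_N = 3, mean_dt = 1, theta = 0.7)
  tau_star <- 1.4
  bel <- belief_distribution(spec, function(arch)
    if (arch$dt < tau_star) -0.4 else 0.25, n_nodes = 64)
  s <- summarize_belief(bel)
  ref <- step_model_belief(spec, tau_star, t_lo = -0.4, t_hi = 0.25)
  w_lo <- ref$components$weight[ref$components$location == -0.4]
  # fixed-order quadrature of a discontinuous integrand is only ~1% accurate
  expect_equal(unname(s$camp_fractions["negative"]), w_lo, tolerance = 0.02)
  # and the closed-form weights agree with brute-force architecture sampling
  set.seed(2)
  frac_mc <- mean(rlnorm(1e6, spec$meanlog, spec$theta) < tau_star)
  se <- sqrt(w_lo * (1 - w_lo) / 1e6)
  expect_lt(abs(frac_mc - w_lo), 3 * se)
})

test_that("step-model weights behave correctly in the limits", {
  spec <- polity_spec(mean_N = 2, mean_dt = 1, theta = 0.5)
  near_zero <- step_model_belief(spec, 1e-12, t_lo = -1, t_hi = 1)
  expect_equal(near_zero$meta$f, 1, tolerance = 1e-9)
  # tau* at the log-normal median splits the polity in half
  med <- exp(spec$meanlog)
  half <- step_model_belief(spec, med, t_lo = -1, t_hi = 1)
  expect_equal(half$components$weight, c(0.5, 0.5), tolerance = 1e-12)
})

test_that("censored two-camp weights equal geometric CDF ratios exactly", {
  spec <- polity_spec(mean_N = 6, mean_dt = 1, theta = 0.5)
  x <- 1 - 1 / 6
  bel <- censored_two_camp_belief(spec, N1 = 3, N2 = 10,
                                  mu1 = -0.3, sigma1 = 0.05,
                                  mu2 = 0.2, sigma2 = 0.05)
  w <- bel$components$weight
  pgeo <- function(k) 1 - x^k          # P(N <= k) under the geometric law
  expect_equal(w[1], pgeo(3) / pgeo(10), tolerance = 1e-14)
  expect_equal(w[2], (pgeo(10) - pgeo(3)) / pgeo(10), tolerance = 1e-14)
  # no upper censoring
  bel_inf <- censored_two_camp_belief(spec, N1 = 3, N2 = Inf,
                                      mu1 = -0.3, sigma1 = 0.05,
                                      mu2 = 0.2, sigma2 = 0.05)
  expect_equal(bel_inf$components$weight, c(1 - x^3, x^3), tolerance = 1e-14)
  # mean memory near 1: everyone is in camp 1
  spec1 <- polity_spec(mean_N = 1.0001, mean_dt = 1, theta = 0.5)
  bel1 <- censored_two_camp_belief(spec1, N1 = 3, N2 = 10,
                                   mu1 = -0.3, sigma1 = 0.05,
                                   mu2 = 0.2, sigma2 = 0.05)
  expect_gt(bel1$components$weight[1], 1 - 1e-10)
})

test_that("belief summaries match closed forms for mixtures", {
  sym <- belief_distribution_new(c(0.5, 0.5), "point", c(-0.4, 0.4))
  s <- summarize_belief(sym)
  expect_equal(s$mean, 0)
  expect_lt(abs(s$median), 1e-9)
  expect_equal(unname(s$camp_fractions), c(0.5, 0, 0.5))

  g <- belief_distribution_new(c(0.3, 0.7), "gaussian", c(-0.2, 0.3),
                               scale = c(0.1, 0.15))
  s2 <- summarize_belief(g)
  expect_equal(unname(s2$camp_fractions["negative"]),
               0.3 * pnorm(0.2 / 0.1) + 0.7 * pnorm(-0.3 / 0.15),
               tolerance = 1e-12)
  expect_equal(s2$mean, 0.3 * (-0.2) + 0.7 * 0.3)
})

test_that("a polity straddling the crossover holds camps on both sides of zero", {
  p <- make_params_ab(0.2, 0.3)
  cr <- crossover_scan(p, 4)
  tau_star <- cr$dt_cross[1]
  spec <- polity_spec(mean_N = 4.0001, mean_dt = tau_star, theta = 0.8)
  bel <- belief_distribution(spec, function(arch)
    as.numeric(influence_analytic(p, architecture(4, arch$dt))), n_nodes = 32)
  expect_true(has_consensus_problem(bel, threshold = 0.1))
  # a tightly peaked polity well below the crossover does not
  spec2 <- polity_spec(mean_N = 4.0001, mean_dt = tau_star / 50, theta = 0.1)
  bel2 <- belief_distribution(spec2, function(arch)
    as.numeric(influence_analytic(p, architecture(4, arch$dt))), n_nodes = 32)
  expect_false(has_consensus_problem(bel2, threshold = 0.1))
})

test_that("spreading the sampling law across a crossover moves the minority camp toward one half", {
  # hold the median sampling interval fixed below tau*, widen theta
  tau_star <- 2
  med <- 0.8
  minority <- sapply(c(0.3, 0.6, 1.2, 2.4), function(th) {
    spec <- polity_spec(mean_N = 2, mean_dt = med * exp(th^2 / 2), theta = th)
    bel <- step_model_belief(spec, tau_star, t_lo = -0.5, t_hi = 0.5)
    min(bel$components$weight)
  })
  expect_true(all(diff(minority) > 0))
  expect_lt(minority[4], 0.5)
})
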