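# Synthetic fixtures with known ground truth: stationary coupled-pair
# samples and "climate-like" paired monthly records (secular trend +
# seasonal harmonics + coupled stochastic residuals + instrument rounding).

#' Stationary samples of the coupled pair at an agent's cadence
#'
#' Simulates one long exact trajectory, discards a burn-in of `20 tau`, and
#' returns the pair sampled every `arch$dt`.  The output is what an agent
#' with that architecture would record from a stationary environment.
#'
#' @param params a [make_params()] object.
#' @param arch an [architecture()]; only `arch$dt` matters here.
#' @param n_points number of retained samples.
#' @param seed optional seed.
#' @return A list with numeric `x1`, `x2` of length `n_points` and the
#'   generating `params`, `arch`, `seed`.
#' @export
gen_coupled_ou <- function(params, arch, n_points, seed = NULL) {
  stopifnot(inherits(params, "qualia_params"), inherits(arch, "architecture"),
            n_points >= 1)
  burn <- ceiling(20 * params$tau / arch$dt)
  tg <- seq(0, (burn + n_points) * arch$dt, by = arch$dt)
  ens <- simulate_paths(params, x0_pair = c(5 * params$ell, -5 * params$ell),
                        t_grid = tg, n_reps = 1, seed = seed)
  keep <- (burn + 2):(burn + n_points + 1)
  list(x1 = ens$x1[1, keep], x2 = ens$x2[1, keep],
       params = params, arch = arch, seed = seed)
}

#' Specification of a climate-like paired monthly record
#'
#' Stream A carries an exponential secular trend (a CO2-like record), stream
#' B a linear one (a temperature-like record); both carry seasonal
#' harmonics and share a coupled stochastic residual pair generated by the
#' exact environment model at monthly cadence, scaled per stream and rounded
#' to the instrument precision.
#'
#' @param length record length in months, `>= 120`.
#' @param trend_a exponential trend coefficients `c(c0, c1, c2)`:
#'   `c0 + c1 exp(c2 t)` with `t` in months.
#' @param trend_b linear trend coefficients `c(c0, c1)`.
#' @param harmonics_a,harmonics_b data frames with columns `freq`
#'   (cycles/month), `amp`, `phase`.
#' @param residual_params a [make_params()] object for the coupled residuals,
#'   time unit = months.
#' @param residual_scales length-2 positive scalings applied to the
#'   dimensionful residuals of streams A and B.
#' @param precisions length-2 instrument precisions (significant digits).
#' @param start_year first calendar year of the record.
#' @param seed integer seed.
#' @return An object of class `climate_like_spec`.
#' @export
climate_like_spec <- function(length = 768,
                              trend_a = c(c0 = 257, c1 = 57.7, c2 = 0.00125),
                              trend_b = c(c0 = 7.0, c1 = 0.00165),
                              harmonics_a = data.frame(freq = c(1 / 12, 1 / 6),
                                                       amp = c(3.0, 1.0),
                                                       phase = c(0.4, 1.1)),
                              harmonics_b = data.frame(freq = c(1 / 12, 1 / 6),
                                                       amp = c(2.5, 0.8),
                                                       phase = c(2.4, 0.9)),
                              residual_params = make_params(0.3625, 0.1375, 0.7, 0.3),
                              residual_scales = c(0.5, 1.0),
                              precisions = c(0.01, 0.1),
                              start_year = 1958,
                              seed = 1) {
  stopifnot(length >= 120, all(harmonics_a$amp >= 0), all(harmonics_b$amp >= 0),
            inherits(residual_params, "qualia_params"),
            all(residual_scales > 0), all(precisions > 0))
  structure(list(length = length, trend_a = trend_a, trend_b = trend_b,
                 harmonics_a = harmonics_a, harmonics_b = harmonics_b,
                 residual_params = residual_params,
                 residual_scales = residual_scales,
                 precisions = precisions, start_year = start_year,
                 seed = seed),
            class = "climate_like_spec")
}

#' Generate a climate-like paired monthly record
#'
#' Deterministic given the spec (which includes the seed).  Noise is
#' injected before rounding to the instrument precision, so the recorded
#' series carry genuine quantization like archived observations do.  The
#' clean components are returned in a ground-truth sidecar for recovery
#' tests.
#'
#' @param spec a [climate_like_spec()].
#' @return A list with `a`, `b` (two [monthly_series()]) and `truth` (clean
#'   trend/seasonal components, unrounded residuals, and the residual
#'   parameters).
#' @examples
#' pair <- gen_climate_like(climate_like_spec(length = 240, seed = 7))
#' pair$a
#' @export
gen_climate_like <- function(spec) {
  stopifnot(inherits(spec, "climate_like_spec"))
  L <- spec$length
  t <- 0:(L - 1)
  harm <- function(h) {
    if (is.null(h) || nrow(h) == 0) return(rep(0, L))
    rowSums(vapply(seq_len(nrow(h)), function(i)
      h$amp[i] * cos(2 * pi * h$freq[i] * t + h$phase[i]), numeric(L)))
  }
  trend_a <- spec$trend_a[1] + spec$trend_a[2] * exp(spec$trend_a[3] * t)
  trend_b <- spec$trend_b[1] + spec$trend_b[2] * t
  seas_a <- harm(spec$harmonics_a)
  seas_b <- harm(spec$harmonics_b)
  res <- gen_coupled_ou(spec$residual_params, architecture(1, 1),
                        n_points = L, seed = spec$seed)
  # per-stream affine scaling leaves every information measure unchanged
  r_a <- spec$residual_scales[1] * res$x1
  r_b <- spec$residual_scales[2] * res$x2
  clean_a <- trend_a + seas_a + r_a
  clean_b <- trend_b + seas_b + r_b
  year <- spec$start_year + (t %/% 12)
  month <- (t %% 12) + 1
  q <- function(v, p) round(v / p) * p
  list(
    a = monthly_series(year, month, q(clean_a, spec$precisions[1]),
                       precision = spec$precisions[1], name = "stream_a"),
    b = monthly_series(year, month, q(clean_b, spec$precisions[2]),
                       precision = spec$precisions[2], name = "stream_b"),
    truth = list(trend_a = trend_a, trend_b = trend_b,
                 seasonal_a = seas_a, seasonal_b = seas_b,
                 residual_a = r_a, residual_b = r_b,
                 residual_params = spec$residual_params,
                 spec = spec)
  )
}

#' Write climate-like fixtures to disk
#'
#' Writes both streams as generic monthly CSVs plus a YAML ground-truth
#' sidecar describing the generating spec.
#'
#' @param spec a [climate_like_spec()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_climate_fixtures <- function(spec, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pair <- gen_climate_like(spec)
  pa <- file.path(dir, "stream_a.csv")
  pb <- file.path(dir, "stream_b.csv")
  write_monthly_csv(pair$a, pa)
  write_monthly_csv(pair$b, pb)
  rp <- spec$residual_params
  side <- list(length = spec$length,
               trend_a = as.list(spec$trend_a), trend_b = as.list(spec$trend_b),
               harmonics_a = as.list(spec$harmonics_a),
               harmonics_b = as.list(spec$harmonics_b),
               residual_params = list(alpha1 = rp$alpha1, alpha2 = rp$alpha2,
                                      beta1 = rp$beta1, beta2 = rp$beta2),
               residual_scales = spec$residual_scales,
               precisions = spec$precisions,
               start_year = spec$start_year, seed = spec$seed)
  py <- file.path(dir, "ground_truth.yml")
  yaml::write_yaml(side, py)
  invisible(c(pa, pb, py))
}
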