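# The empirical pipeline: bootstrap substreams of a paired monthly record,
# transfer entropy and influence versus memory size, and polity beliefs.

#' Bootstrap paired substreams with instrument-level noise
#'
#' Each replicate picks a start month uniformly at random inside
#' `start_year_range`, keeps both series from that month to the end of the
#' record, and adds i.i.d. Gaussian noise with standard deviation equal to
#' each series' measurement precision (its significant digit).  This turns a
#' single paired record into an ensemble of agents of different ages reading
#' the same instruments.
#'
#' @param pair list of two aligned [monthly_series()] (same months).
#' @param n_boot number of replicates.
#' @param start_year_range length-2 integer range of admissible start years
#'   (inclusive); the start month is uniform over the months of those years
#'   present in the record.
#' @param seed optional seed.
#' @param noise_sd optional length-2 override of the noise standard
#'   deviations (defaults to the series precisions).
#' @return A list of replicates, each a list with `x1`, `x2` (numeric,
#'   possibly containing `NA` where months are masked) and `start_index`.
#' @export
bootstrap_substreams <- function(pair, n_boot, start_year_range, seed = NULL,
                                 noise_sd = NULL) {
  stopifnot(length(pair) == 2,
            inherits(pair[[1]], "monthly_series"),
            inherits(pair[[2]], "monthly_series"))
  s1 <- pair[[1]]; s2 <- pair[[2]]
  if (length(s1) != length(s2) || any(s1$year != s2$year) || any(s1$month != s2$month))
    stop("the two series must be aligned month by month")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(noise_sd)) noise_sd <- c(s1$precision, s2$precision)
  eligible <- which(s1$year >= start_year_range[1] & s1$year <= start_year_range[2])
  if (length(eligible) == 0) stop("empty start range")
  lapply(seq_len(n_boot), function(r) {
    st <- sample(eligible, 1)
    idx <- st:length(s1$value)
    n <- length(idx)
    list(x1 = s1$value[idx] + stats::rnorm(n, 0, noise_sd[1]),
         x2 = s2$value[idx] + stats::rnorm(n, 0, noise_sd[2]),
         start_index = st)
  })
}

#' Transfer entropy and influence versus memory size
#'
#' For every bootstrap replicate and every memory size in `N_grid`, computes
#' the plug-in Gaussian transfer entropy in both directions (sampling
#' interval fixed at one native step, i.e. one month for monthly data) and
#' the influence.  A single delay embedding at `max(N_grid)` is reused for
#' all memory depths.  Replicates too short for the deepest embedding, or
#' whose embedding window touches a masked month, are skipped and counted.
#'
#' @param replicates list of replicates from [bootstrap_substreams()], or a
#'   single `list(x1 =, x2 =)` pair.
#' @param N_grid integer memory sizes (months), e.g. `1:36`.
#' @param stride sub-sampling stride in native steps (default 1).
#' @param min_length minimum usable replicate length; defaults to
#'   `12 + 2 * max(N_grid)` native steps.
#' @param band_probs quantile levels for the bootstrap bands (default 10%
#'   steps centred on the median).
#' @return An `influence_curve`: list with `N` (the grid), `influence`
#'   (point estimate per N: replicate mean), `influence_bands` (quantile
#'   matrix), `te_2to1`, `te_1to2` (replicate means), `replicates` (the
#'   per-replicate influence matrix), `n_used`, `n_skipped`.
#' @export
influence_vs_memory <- function(replicates, N_grid, stride = 1,
                                min_length = NULL,
                                band_probs = seq(0.1, 0.9, by = 0.1)) {
  if (!is.null(replicates$x1)) replicates <- list(replicates)
  N_grid <- sort(unique(as.integer(N_grid)))
  stopifnot(all(N_grid >= 1))
  Nmax <- max(N_grid)
  if (is.null(min_length)) min_length <- 12 + 2 * Nmax
  vals21 <- vals12 <- infl <- matrix(NA_real_, length(replicates), length(N_grid))
  skipped <- 0L
  for (r in seq_along(replicates)) {
    x1 <- replicates[[r]]$x1; x2 <- replicates[[r]]$x2
    if (length(x1) < min_length) { skipped <- skipped + 1L; next }
    # embedding vectors touching a masked month are dropped, not imputed
    emb <- .delay_embed(x1, x2, Nmax, as.integer(stride))
    emb <- emb[stats::complete.cases(emb), , drop = FALSE]
    if (nrow(emb) < min_length) { skipped <- skipped + 1L; next }
    M <- stats::cov(emb)
    for (j in seq_along(N_grid)) {
      te <- tryCatch(.embedded_te_both(M, N_grid[j], Nmax, n = nrow(emb)),
                     error = function(e) NULL)
      if (is.null(te)) next
      vals21[r, j] <- te$te_2to1
      vals12[r, j] <- te$te_1to2
      tot <- te$te_1to2 + te$te_2to1
      infl[r, j] <- if (tot < 1e-12) 0 else (te$te_1to2 - te$te_2to1) / tot
    }
  }
  used <- which(stats::complete.cases(infl))
  if (length(used) == 0) stop("no replicate long enough for the requested N_grid")
  bands <- apply(infl[used, , drop = FALSE], 2, stats::quantile, probs = band_probs)
  structure(list(N = N_grid,
                 influence = colMeans(infl[used, , drop = FALSE]),
                 influence_bands = bands,
                 te_2to1 = colMeans(vals21[used, , drop = FALSE]),
                 te_1to2 = colMeans(vals12[used, , drop = FALSE]),
                 replicates = infl[used, , drop = FALSE],
                 n_used = length(used), n_skipped = skipped,
                 stride = stride),
            class = "influence_curve")
}

#' @export
print.influence_curve <- function(x, ...) {
  cat(sprintf("Influence vs memory: N in [%d, %d], %d replicate(s) used, %d skipped\n",
              min(x$N), max(x$N), x$n_used, x$n_skipped))
  sw <- which(diff(sign(x$influence)) != 0)
  if (length(sw))
    cat(sprintf("  point-estimate sign change(s) near N = %s\n",
                paste(x$N[sw], collapse = ", ")))
  invisible(x)
}

#' Memory size at which the influence point estimate changes sign
#'
#' @param curve an `influence_curve`.
#' @return The smallest `N` after which the sign flips (`NA` if none).
#' @export
influence_sign_change <- function(curve) {
  stopifnot(inherits(curve, "influence_curve"))
  sw <- which(diff(sign(curve$influence)) != 0)
  if (length(sw) == 0) return(NA_integer_)
  curve$N[sw[1]]
}

#' Polity beliefs from an influence-versus-memory curve
#'
#' For each requested mean memory `mean_N`, pools the per-replicate,
#' per-memory influence estimates into a belief distribution, weighting
#' memory classes geometrically (truncated to the curve's grid and
#' renormalized) and replicates uniformly within a class.  Reports, per
#' polity, the mixture mean, median and camp fractions, and locates the
#' `mean_N` at which the median belief crosses zero.
#'
#' @param curve an `influence_curve` (its `replicates` matrix is used).
#' @param mean_N_values numeric vector of mean memory sizes (`> 1`).
#' @return A list with `beliefs` (one `belief_distribution` per `mean_N`),
#'   `summary` (data frame: mean_N, mean, median, negative/zero/positive
#'   fractions) and `median_zero_mean_N` (linear interpolation of the median
#'   sign change; `NA` if the median does not change sign).
#' @export
polity_belief_from_curve <- function(curve, mean_N_values) {
  stopifnot(inherits(curve, "influence_curve"), all(mean_N_values > 1))
  reps <- curve$replicates
  beliefs <- list()
  sm <- data.frame()
  for (mN in mean_N_values) {
    x <- 1 - 1 / mN
    wN <- (1 - x) * x^(curve$N - 1)
    wN <- wN / sum(wN)
    w <- rep(wN / nrow(reps), each = nrow(reps))
    bel <- belief_distribution_new(weight = w, kind = "point",
                                   location = as.vector(reps),
                                   meta = list(mean_N = mN))
    s <- summarize_belief(bel)
    beliefs[[length(beliefs) + 1]] <- bel
    sm <- rbind(sm, data.frame(mean_N = mN, mean = s$mean, median = s$median,
                               negative = s$camp_fractions["negative"],
                               zero = s$camp_fractions["zero"],
                               positive = s$camp_fractions["positive"],
                               row.names = NULL))
  }
  med <- sm$median
  mz <- NA_real_
  sw <- which(diff(sign(med)) != 0)
  if (length(sw)) {
    i <- sw[1]
    mz <- sm$mean_N[i] + (0 - med[i]) * (sm$mean_N[i + 1] - sm$mean_N[i]) /
      (med[i + 1] - med[i])
  }
  list(beliefs = beliefs, summary = sm, median_zero_mean_N = mz)
}

#' Run the full paired-series pipeline
#'
#' Detrend both series (configurable trend kind per series, then optional
#' harmonic removal), bootstrap substreams with instrument noise, compute
#' the influence-versus-memory curve, and pool polity beliefs.
#'
#' @param pair list of two aligned [monthly_series()]; the first is treated
#'   as the exponential-trend stream by default.
#' @param n_boot bootstrap replicates (default 1000).
#' @param N_grid memory sizes in months (default `1:36`).
#' @param detrend one of `"none"`, `"trend"`, `"trend+harmonics"`.
#' @param k_harmonics harmonics removed per series when requested (default 2).
#' @param trend_kinds character length-2, trend kind per series.
#' @param start_year_range start-year range for the substreams; defaults to
#'   the first year through the year 12 years before the end of the record.
#' @param mean_N_values polity mean memories to evaluate.
#' @param seed random seed.
#' @return A list with `curve` (an `influence_curve`), `polity` (from
#'   [polity_belief_from_curve()]), `detrend_reports`, and the call
#'   configuration.
#' @export
run_climate_pipeline <- function(pair, n_boot = 1000, N_grid = 1:36,
                                 detrend = c("trend+harmonics", "trend", "none"),
                                 k_harmonics = 2,
                                 trend_kinds = c("exponential", "linear"),
                                 start_year_range = NULL,
                                 mean_N_values = c(1.5, seq(2, 30, by = 1)),
                                 seed = NULL) {
  detrend <- match.arg(detrend)
  stopifnot(length(pair) == 2)
  reports <- list()
  if (detrend != "none") {
    for (i in 1:2) {
      out <- fit_remove_trend(pair[[i]], trend_kinds[i])
      reports[[length(reports) + 1]] <- out$report
      pair[[i]] <- out$series
      if (detrend == "trend+harmonics") {
        out <- remove_top_harmonics(pair[[i]], k_harmonics)
        reports[[length(reports) + 1]] <- out$report
        pair[[i]] <- out$series
      }
    }
  }
  if (is.null(start_year_range)) {
    yrs <- range(pair[[1]]$year)
    start_year_range <- c(yrs[1], max(yrs[1], yrs[2] - 12))
  }
  reps <- bootstrap_substreams(pair, n_boot, start_year_range, seed = seed)
  curve <- influence_vs_memory(reps, N_grid)
  pol <- polity_belief_from_curve(curve, mean_N_values)
  list(curve = curve, polity = pol, detrend_reports = reports,
       config = list(n_boot = n_boot, N_grid = N_grid, detrend = detrend,
                     k_harmonics = k_harmonics, trend_kinds = trend_kinds,
                     start_year_range = start_year_range, seed = seed))
}
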