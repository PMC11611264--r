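# Cross-replicate and cross-line aggregation: fixed-effects meta-analysis,
# percent-of-control depletion summaries, screen-wide effect-size regressions
# and co-zonal driver pairing.

#' Fixed-effects inverse-variance meta-analysis
#'
#' Combines replicate effect sizes with weights `w_i = 1 / s_i^2`:
#' `theta_weighted = sum(theta_i * w_i) / sum(w_i)`, with standard error
#' `sqrt(1 / sum(w_i))`. `s_i^2` is the pooled control+test variance of
#' replicate i (see [replicate_variance()]).
#'
#' @param theta Replicate effect sizes.
#' @param s2 Replicate variances (all `> 0`), same length as `theta`.
#' @return A list of class `meta_result`: `theta_weighted`, `se_weighted`,
#'   `ci_low`, `ci_high` (normal 95%), `theta`, `s2`, `weights`, `k`.
#' @export
#' @examples
#' fixed_effects_meta(c(0.2, 0.4), c(0.01, 0.04))  # weighted mean 0.24
fixed_effects_meta <- function(theta, s2) {
  stopifnot(length(theta) == length(s2), length(theta) >= 1)
  if (any(!is.finite(s2)) || any(s2 <= 0))
    stop("all replicate variances must be positive", call. = FALSE)
  w <- 1 / s2
  theta_w <- sum(theta * w) / sum(w)
  se <- sqrt(1 / sum(w))
  structure(list(theta_weighted = theta_w, se_weighted = se,
                 ci_low = theta_w - stats::qnorm(0.975) * se,
                 ci_high = theta_w + stats::qnorm(0.975) * se,
                 theta = theta, s2 = s2, weights = w, k = length(theta)),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("<meta_result> weighted effect = %.3f (SE %.3f) over k = %d replicates\n",
              x$theta_weighted, x$se_weighted, x$k))
  invisible(x)
}

#' Pooled control+test variance of one replicate
#'
#' Operationalizes the per-replicate variance entering the fixed-effects
#' weights as the variance of the replicate's mean difference: the variance
#' of the test group mean plus the variance of the shared-control reference
#' mean (a difference of independent means). Computed from an
#' [mean_difference()] result as the variance of its bootstrap distribution,
#' which estimates exactly that quantity.
#'
#' @param es An `effect_size` from [mean_difference()].
#' @return The replicate variance (scalar).
#' @export
replicate_variance <- function(es) {
  stopifnot(inherits(es, "effect_size"))
  stats::var(es$bootstrap_draws)
}

#' Percent-of-control summary of an intervention effect
#'
#' Expresses an intervention's effect size as a percentage of the mean
#' control effect at the same light intensity: the control reference is the
#' simple (unweighted) average of the replicate control effect sizes at that
#' intensity, and `percent = 100 * intervention / control mean`. Undefined
#' (flagged) when the control mean is 0.
#'
#' @param intervention_delta The intervention's effect size.
#' @param replicate_control_deltas Control effect sizes across replicates at
#'   the matching intensity.
#' @param intensity Light intensity, uW/mm^2 (carried through).
#' @return A list of class `percent_of_control`: `percent`,
#'   `control_mean_delta`, `intervention_delta`, `intensity`, `defined`.
#' @export
percent_of_control <- function(intervention_delta, replicate_control_deltas,
                               intensity = NA_real_) {
  stopifnot(length(replicate_control_deltas) >= 1)
  ctrl <- mean(replicate_control_deltas)
  defined <- is.finite(ctrl) && ctrl != 0
  if (!defined)
    warning("control mean effect is 0; percent of control undefined",
            call. = FALSE)
  structure(list(percent = if (defined) 100 * intervention_delta / ctrl
                           else NA_real_,
                 control_mean_delta = ctrl,
                 intervention_delta = intervention_delta,
                 intensity = intensity, defined = defined),
            class = "percent_of_control")
}

#' Average percent-of-control across interventions and intensities
#'
#' Unweighted mean of the defined percents (each intervention x intensity
#' cell contributing equally); an inverse-variance weighted variant is
#' available when per-cell variances are supplied.
#'
#' @param percents A list of [percent_of_control()] results.
#' @param weights Optional positive weights (e.g. inverse variances).
#' @return The average percent (scalar).
#' @export
average_percent_of_control <- function(percents, weights = NULL) {
  p <- vapply(percents, `[[`, numeric(1), "percent")
  ok <- is.finite(p)
  if (!any(ok)) return(NA_real_)
  if (is.null(weights)) mean(p[ok])
  else {
    stopifnot(length(weights) == length(p), all(weights[ok] > 0))
    sum(p[ok] * weights[ok]) / sum(weights[ok])
  }
}

#' Per-line effect sizes for all behavioral metrics
#'
#' Runs the shared-control [mean_difference()] machinery for each requested
#' metric of one driver line (test + two control groups), from the per-fly
#' metric tables of [summarize_group()]. Censored flies propagate as `NA`
#' and are dropped per metric; a metric whose groups lose too many flies to
#' censoring is omitted with a notice.
#'
#' @param test,ctrl1,ctrl2 Per-fly metric tables from [summarize_group()].
#' @param metrics Metric columns to difference.
#' @param resamples,seed Passed to [mean_difference()].
#' @param line Line label carried into the output.
#' @return A tibble, one row per metric: `line`, `metric`, `delta`,
#'   `ci_low`, `ci_high`, `hedges_g`, `n_test`, `n_ctrl1`, `n_ctrl2`.
#' @export
line_delta_metrics <- function(test, ctrl1, ctrl2,
                               metrics = c("pi", "lsr", "chi", "pedl", "peld"),
                               resamples = 3000, seed = 1L, line = "line") {
  rows <- list()
  for (i in seq_along(metrics)) {
    m <- metrics[i]
    es <- tryCatch(
      mean_difference(test[[m]], ctrl1[[m]], ctrl2[[m]],
                      resamples = resamples,
                      seed = fly_seed(seed, 0L, i), metric = m),
      error = function(e) {
        message(sprintf("line '%s', metric '%s' omitted: %s",
                        line, m, conditionMessage(e)))
        NULL
      })
    if (is.null(es)) next
    rows[[length(rows) + 1L]] <- tibble::tibble(
      line = line, metric = m, delta = es$delta,
      ci_low = es$ci_low, ci_high = es$ci_high, hedges_g = es$hedges_g,
      n_test = es$n_test, n_ctrl1 = es$n_control_1, n_ctrl2 = es$n_control_2)
  }
  if (length(rows) == 0L)
    return(tibble::tibble(line = character(0), metric = character(0),
                          delta = numeric(0), ci_low = numeric(0),
                          ci_high = numeric(0), hedges_g = numeric(0),
                          n_test = integer(0), n_ctrl1 = integer(0),
                          n_ctrl2 = integer(0)))
  do.call(rbind, rows)
}

#' Regress a locomotor effect size against valence across lines
#'
#' Ordinary least squares of `y` (per-line valence effect, ΔPreference) on
#' `x` (a per-line locomotor effect size), reporting slope, intercept, R²,
#' adjusted R² `= 1 - (1 - R²)(n - 1)/(n - 2)`, the regression p-value, and
#' a 95% BCa bootstrap CI on R² obtained by resampling lines (x,y pairs)
#' with replacement.
#'
#' @param x,y Per-line effect sizes (equal length, `n >= 3`); `NA` pairs
#'   dropped.
#' @param resamples Bootstrap resamples for the R² CI.
#' @param seed Integer seed.
#' @return A list of class `regression_result`: `slope`, `intercept`,
#'   `r_squared`, `r_squared_adj`, `r2_ci_low`, `r2_ci_high`, `p`, `n`,
#'   `r2_draws`.
#' @export
regress_effects <- function(x, y, resamples = 3000, seed = 1L) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("regression needs at least 3 lines", call. = FALSE)
  if (stats::var(x) == 0)
    stop("zero variance in x; slope undefined", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  r2 <- sm$r.squared
  r2_of <- function(idx) {
    xs <- x[idx]; ys <- y[idx]
    if (stats::var(xs) == 0 || stats::var(ys) == 0) return(NA_real_)
    stats::cor(xs, ys)^2
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed %% 2147483647))
  draws <- vapply(seq_len(resamples), function(b)
    r2_of(sample.int(n, n, replace = TRUE)), numeric(1))
  jack <- vapply(seq_len(n), function(i) r2_of(seq_len(n)[-i]), numeric(1))
  ci <- bca_interval(draws, r2, jack)
  p_val <- if (nrow(sm$coefficients) >= 2) sm$coefficients[2, 4] else NA_real_
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 r_squared_adj = 1 - (1 - r2) * (n - 1) / (n - 2),
                 r2_ci_low = ci$ci[1], r2_ci_high = ci$ci[2],
                 p = p_val, n = n, r2_draws = draws),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> slope = %.3f, R^2 = %.3f (adj %.3f) [%.3f, %.3f], n = %d\n",
              x$slope, x$r_squared, x$r_squared_adj, x$r2_ci_low,
              x$r2_ci_high, x$n))
  invisible(x)
}

#' Pair driver lines by shared mushroom-body zone and regress their effects
#'
#' Emits one pair for every dopaminergic (PAM) line and output-neuron (MBON)
#' line that both have major anatomical staining (intensity `>=`
#' `staining_threshold`) in at least one common mushroom-body zone, then
#' regresses the MBON valence effect on the PAM valence effect over the
#' pairs.
#'
#' @param pam_table,mbon_table Data frames with columns `line`, `zone`,
#'   `staining` (intensity score) and `delta_pi` (the line's valence effect
#'   size); one row per line x zone. An editable template with synthetic
#'   placeholder values ships at
#'   `system.file("extdata", "zone_staining_synthetic.csv", package =
#'   "optovalence")`; real anatomical scores are user-supplied.
#' @param staining_threshold Minimum intensity counting as major staining.
#' @return A list: `pairs` (tibble `pam_line`, `mbon_line`, `shared_zones`,
#'   `pam_delta_pi`, `mbon_delta_pi`) and `regression` (a
#'   `regression_result`, or `NULL` when fewer than 3 pairs).
#' @export
pair_cozonal <- function(pam_table, mbon_table, staining_threshold = 3) {
  need <- c("line", "zone", "staining", "delta_pi")
  stopifnot(all(need %in% names(pam_table)), all(need %in% names(mbon_table)))
  major <- function(tab) tab[tab$staining >= staining_threshold, , drop = FALSE]
  pam <- major(pam_table); mbon <- major(mbon_table)
  pam_lines <- unique(pam$line); mbon_lines <- unique(mbon$line)
  rows <- list()
  for (pl in pam_lines) {
    pz <- unique(pam$zone[pam$line == pl])
    for (ml in mbon_lines) {
      mz <- unique(mbon$zone[mbon$line == ml])
      shared <- intersect(pz, mz)
      if (length(shared) == 0L) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        pam_line = pl, mbon_line = ml,
        shared_zones = paste(shared, collapse = ";"),
        pam_delta_pi = pam$delta_pi[pam$line == pl][1],
        mbon_delta_pi = mbon$delta_pi[mbon$line == ml][1])
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows)
           else tibble::tibble(pam_line = character(0),
                               mbon_line = character(0),
                               shared_zones = character(0),
                               pam_delta_pi = numeric(0),
                               mbon_delta_pi = numeric(0))
  reg <- if (nrow(pairs) >= 3)
    tryCatch(regress_effects(pairs$pam_delta_pi, pairs$mbon_delta_pi),
             error = function(e) NULL)
  else NULL
  list(pairs = pairs, regression = reg)
}
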