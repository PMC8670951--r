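# Log-log allometric machinery: major-axis regression with bootstrap CIs,
# two-phase (single change point) segmented regression fitted by exhaustive
# maximum-likelihood grid search, change-point standardization to body length,
# and stage assignment of change points.

#' Major-axis regression of log lengths
#'
#' Fits the first principal axis of the `(x, y)` scatter. The slope is the
#' allometric coefficient of `y` on `x` when both are natural-log lengths:
#' `b = (s_yy - s_xx + sqrt((s_yy - s_xx)^2 + 4 s_xy^2)) / (2 s_xy)`.
#' The confidence interval is a seeded pairs-bootstrap percentile interval.
#'
#' @param x,y numeric vectors (log lengths), `n >= 3`, finite.
#' @param boot number of bootstrap replicates (default 1000; 0 skips the CI).
#' @param seed seed for the bootstrap.
#' @param level confidence level (default 0.95).
#' @return an `ma_fit` list: `slope`, `intercept`, `ci`, `n`, `boot`, `seed`.
#' @export
ma_fit <- function(x, y, boot = 1000L, seed = NULL, level = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop_fmt("major-axis regression needs n >= 3 (got %d)", n)
  slope <- ma_slope(x, y)
  if (!is.finite(slope)) stop_fmt("major-axis slope undefined (isotropic scatter)")
  ci <- c(NA_real_, NA_real_)
  if (boot > 0) {
    slopes <- with_seed(seed, vapply(seq_len(boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      ma_slope(x[idx], y[idx])
    }, 0))
    slopes <- slopes[is.finite(slopes)]
    if (length(slopes))
      ci <- unname(quantile(slopes, c((1 - level) / 2, 1 - (1 - level) / 2)))
  }
  out <- list(slope = slope, intercept = mean(y) - slope * mean(x),
              ci = ci, n = n, boot = boot, seed = seed, level = level)
  class(out) <- "ma_fit"
  out
}

# slope of the first principal axis; NA for degenerate scatter
ma_slope <- function(x, y) {
  sxx <- var(x); syy <- var(y); sxy <- cov(x, y)
  if (!is.finite(sxx) || !is.finite(sxy)) return(NA_real_)
  if (abs(sxy) < 1e-300) {
    if (abs(sxx - syy) < 1e-300) return(NA_real_)  # isotropic: axis undefined
    return(if (sxx > syy) 0 else NA_real_)         # vertical axis: undefined slope
  }
  (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
}

#' @export
print.ma_fit <- function(x, ...) {
  cat(sprintf("major-axis slope %.4f [%.4f, %.4f], n = %d\n",
              x$slope, x$ci[1], x$ci[2], x$n))
  invisible(x)
}

#' Allometric coefficient profile across body parts
#'
#' Major-axis regressions of each thoracic segment's log length on log trunk
#' length, of the cephalic parts (FAL, PGL, ORL) on log cephalic length, and
#' of CEL and TRL on log body length, within one developmental period.
#' Segments represented by fewer than 3 complete specimens are omitted with a
#' warning.
#'
#' @param x a specimen or derived table.
#' @param period `"meraspid"` or `"holaspid"`.
#' @param boot,seed,level passed to [ma_fit()].
#' @return a data frame with columns `part`, `reference`, `period`, `slope`,
#'   `lo`, `hi`, `n`.
#' @export
segment_coefficient_profile <- function(x, period = c("meraspid", "holaspid"),
                                        boot = 1000L, seed = NULL, level = 0.95) {
  period <- match.arg(period)
  d <- as_derived(x)
  d <- d[d$period == period, , drop = FALSE]
  if (nrow(d) == 0L) stop_fmt("no %s specimens", period)
  pairs <- rbind(
    data.frame(part = paste0("LTS", 1:MAX_SEGMENTS), reference = "TRL"),
    data.frame(part = c("FAL", "PGL", "ORL"), reference = "CEL"),
    data.frame(part = c("CEL", "TRL"), reference = "BOL"))
  rows <- list()
  skipped <- character(0)
  for (r in seq_len(nrow(pairs))) {
    p <- pairs$part[r]; ref <- pairs$reference[r]
    ok <- is.finite(d[[p]]) & is.finite(d[[ref]])
    if (sum(ok) < 3L) {
      skipped <- c(skipped, p)
      next
    }
    fit <- tryCatch(ma_fit(log(d[[ref]][ok]), log(d[[p]][ok]), boot = boot,
                           seed = child_seed(seed, r), level = level),
                    error = function(e) NULL)
    if (is.null(fit)) {  # degenerate scatter (e.g. a segment present at one stage only)
      skipped <- c(skipped, p)
      next
    }
    rows[[length(rows) + 1L]] <-
      data.frame(part = p, reference = ref, period = period,
                 slope = fit$slope, lo = fit$ci[1], hi = fit$ci[2], n = fit$n)
  }
  if (length(skipped))
    warn_fmt("omitted (too few specimens or degenerate scatter): %s",
             paste(skipped, collapse = ", "))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-phase (single change point) segmented regression
#'
#' Fits `y = b0 + b1 x + b2 (x - tau)_+` for every candidate threshold `tau`
#' among the observed `x` values that leave at least a `trim` fraction of
#' points strictly on each side, keeping the residual-sum-of-squares minimizer
#' (the Gaussian maximum-likelihood threshold). The model is continuous at the
#' change point by construction. Inputs are natural-log lengths; the change
#' point is also reported back-transformed to mm.
#'
#' @param x,y numeric vectors (log lengths), `n >= 8`.
#' @param trim minimum fraction of points required strictly on each side of a
#'   candidate threshold (default 0.10).
#' @return a `hinge_fit` list: `coef` (`b0`, `b1`, `b2`), `slope_pre`,
#'   `slope_post`, `tau` (log scale), `cp` (`exp(tau)`, mm), `rss`, `sigma`,
#'   `n`, `x_range`, `candidates`, `candidate_rss`, `no_change`.
#' @export
hinge_fit <- function(x, y, trim = 0.10) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 8L) stop_fmt("hinge fit needs n >= 8 (got %d)", n)
  if (diff(range(x)) <= 0) stop_fmt("x has degenerate range")
  need <- ceiling(trim * n)
  cand <- sort(unique(x))
  cand <- cand[vapply(cand, function(t) sum(x < t) >= need && sum(x > t) >= need,
                      TRUE)]
  if (length(cand) < 2L)
    stop_fmt("insufficient span: fewer than 2 admissible thresholds")
  rss <- vapply(cand, function(t) {
    sum(.lm.fit(cbind(1, x, pmax(x - t, 0)), y)$residuals^2)
  }, 0)
  best <- which.min(rss)
  tau <- cand[best]
  fit <- .lm.fit(cbind(1, x, pmax(x - tau, 0)), y)
  b <- fit$coefficients
  out <- list(coef = setNames(b, c("b0", "b1", "b2")),
              slope_pre = b[2], slope_post = b[2] + b[3],
              tau = tau, cp = exp(tau),
              rss = rss[best], sigma = sqrt(rss[best] / n), n = n,
              x_range = range(x), candidates = cand, candidate_rss = rss,
              no_change = abs(b[3]) < 1e-8 * max(1, abs(b[2])),
              trim = trim)
  class(out) <- "hinge_fit"
  out
}

#' @export
print.hinge_fit <- function(x, ...) {
  cat(sprintf("two-phase fit: change point %.4g mm (tau = %.4f), n = %d\n",
              x$cp, x$tau, x$n))
  cat(sprintf("pre-AC %.4f -> post-AC %.4f; RSS %.6g%s\n", x$slope_pre,
              x$slope_post, x$rss,
              if (x$no_change) " [no detectable change]" else ""))
  invisible(x)
}

#' Predict from a two-phase fit
#'
#' @param object a `hinge_fit`.
#' @param newx log-scale predictor values.
#' @param ... unused.
#' @return predicted log-scale responses.
#' @export
predict.hinge_fit <- function(object, newx, ...) {
  b <- object$coef
  unname(b[1] + b[2] * newx + b[3] * pmax(newx - object$tau, 0))
}

#' Bootstrap confidence interval for a change point
#'
#' Pairs (case) resampling with refit, percentile interval of the
#' back-transformed change point `exp(tau)`. Deterministic given `seed`.
#' Errors if more than 20% of replicate refits fail.
#'
#' @param x,y log-scale data, as in [hinge_fit()].
#' @param reps bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @param trim candidate trimming fraction, as in [hinge_fit()].
#' @param level confidence level (default 0.95).
#' @return list with `ci` (mm), `reps_used`, `fail_rate`.
#' @export
hinge_bootstrap_ci <- function(x, y, reps = 1000L, seed = NULL, trim = 0.10,
                               level = 0.95) {
  base <- hinge_fit(x, y, trim = trim)  # errors if the full fit fails
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  cps <- with_seed(seed, vapply(seq_len(reps), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    tryCatch(hinge_fit(x[idx], y[idx], trim = trim)$cp,
             error = function(e) NA_real_)
  }, 0))
  fail <- mean(!is.finite(cps))
  if (fail > 0.2)
    stop_fmt("bootstrap failure rate %.1f%% exceeds 20%%", 100 * fail)
  cps <- cps[is.finite(cps)]
  ci <- unname(quantile(cps, c((1 - level) / 2, 1 - (1 - level) / 2)))
  list(ci = ci, reps_used = length(cps), fail_rate = fail, point = base$cp)
}

#' Standardize a change point to the body-length scale
#'
#' Re-expresses a change point estimated on a part scale (CEL or TRL, mm) as
#' the body length predicted by a reference two-phase fit of log BOL on the
#' log of that part. Extrapolation beyond the reference fit's observed
#' predictor range is refused.
#'
#' @param cp change point in mm on the reference fit's predictor scale.
#' @param reference a `hinge_fit` of log BOL on the log predictor.
#' @return the equivalent change point in mm on the BOL scale.
#' @export
standardize_changepoint_to_bol <- function(cp, reference) {
  stopifnot(inherits(reference, "hinge_fit"), cp > 0)
  lx <- log(cp)
  if (lx < reference$x_range[1] || lx > reference$x_range[2])
    stop_fmt("change point %.4g mm lies outside the reference fit's range", cp)
  exp(predict(reference, lx))
}

#' Developmental stages whose size range contains a value
#'
#' Returns every stage (meraspid degree, plus `"H"` for holaspides) whose
#' observed `[min, max]` of `variable` contains `value`. An empty set is a
#' valid answer.
#'
#' @param value size in mm.
#' @param variable a measured or derived column name (e.g. `"BOL"`, `"TRL"`,
#'   `"CEL"`).
#' @param x a specimen or derived table.
#' @return character vector of stage labels; attribute `formatted` carries the
#'   compact rendering from [format_stage_set()].
#' @export
stage_for_size <- function(value, variable, x) {
  d <- as_derived(x)
  if (!variable %in% names(d)) stop_fmt("unknown variable: %s", variable)
  grp <- ifelse(d$period == "holaspid", "H", paste0("D", d$degree))
  v <- d[[variable]]
  keep <- is.finite(v) & !is.na(grp)
  labs <- character(0)
  for (g in unique(grp[keep])) {
    vv <- v[keep & grp == g]
    if (length(vv) && value >= min(vv) && value <= max(vv)) labs <- c(labs, g)
  }
  ds <- labs[labs != "H"]
  ord <- order(as.integer(sub("^D", "", ds)))
  labs <- c(ds[ord], labs[labs == "H"])
  attr(labs, "formatted") <- format_stage_set(labs)
  labs
}
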