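# Segmental-gradient (SG) and trunk-gradient (TG) models of thoracic segment
# growth, nonlinear least-squares fitting, AICc model comparison, and the
# pygidial stasis test.
#
# Observed quantities are stage means over meraspid degrees s = 1..12:
#   RLS(i, s)  relative length of thoracic segment i at stage s
#   RPS(i, s)  relative position of segment i's posterior boundary
# with 1 <= i <= s (segment i exists only from its release stage i onward).
#
# SG hypothesis: segments grow autonomously after release into the thorax.
#   SG-R  RLS(i,s) = A * B^(i-1) * r^(s-i)        constant ratio of segment to
#                                                 trunk growth rates
#   SG-A  RLS(i,s) = A * B^(i-1) * (TRL_s/TRL_i)^(k-1)
#                                                 constant allometric
#                                                 coefficient k of segment
#                                                 length on trunk length
# In both, A * B^(i-1) is the relative size of segment i at its release
# (released-segment size declines geometrically with release stage).
#
# TG hypothesis: segment boundaries are landmarks in a continuous trunk growth
# field g(p) proportional to exp(b * p) in relative position p. One moult maps
# a boundary at p to
#   phi_b(p) = (exp(b p) - 1) / (exp(b) - 1)       (identity at b = 0)
# with per-moult gradient steepness
#   TG-T  b_s = c0 + c1 * ln(TRG_s)                trunk growth rate as driver
#   TG-D  b_s = c0 + c1 * s                        stage as driver
# and release boundary RPS(i,i) = 1 - q0 * q1^i (the new segment's posterior
# boundary sits at the thorax/pygidium junction, whose relative size declines
# geometrically). RLS follows by differencing consecutive boundaries.

#' Names of the supported growth-gradient models
#'
#' Two segmental-gradient variants (`SG-R`, `SG-A`; 3 parameters, RLS
#' response) and two trunk-gradient variants (`TG-T`, `TG-D`; 4 parameters,
#' RLS or RPS response).
#' @format character vector of length 4.
#' @export
GRADIENT_MODELS <- c("SG-R", "SG-A", "TG-T", "TG-D")

#' Predicted relative segment length under the SG-R model
#'
#' `RLS(i, s) = A * B^(i-1) * r^(s-i)`: release size `A * B^(i-1)` followed by
#' a constant per-stage relative growth factor `r`.
#'
#' @param A,B,r positive model parameters.
#' @param i segment index (release stage), `1 <= i <= s`.
#' @param s stage; `i` and `s` are recycled against each other.
#' @return predicted RLS values.
#' @export
sg_r_predict <- function(A, B, r, i, s) {
  stopifnot(A > 0, B > 0, r > 0)
  if (any(i > s)) stop_fmt("segment i=%d not yet released at stage s=%d",
                           i[which(i > s)[1]], s[which(i > s)[1]])
  if (any(i < 1)) stop_fmt("segment index must be >= 1")
  A * B^(i - 1) * r^(s - i)
}

#' Predicted relative segment length under the SG-A model
#'
#' `RLS(i, s) = A * B^(i-1) * (TRL_s / TRL_i)^(k-1)`: constant allometric
#' coefficient `k` of segment length with respect to trunk length after
#' release.
#'
#' @param A,B positive parameters; `k` allometric coefficient (1 = isometry).
#' @param i,s segment and stage indices (recycled), `1 <= i <= s`.
#' @param trl numeric vector of stage-mean trunk lengths indexed by stage
#'   (`trl[s]` is the mean TRL at degree `s`).
#' @return predicted RLS values.
#' @export
sg_a_predict <- function(A, B, k, i, s, trl) {
  stopifnot(A > 0, B > 0)
  if (any(i > s)) stop_fmt("segment i=%d not yet released at stage s=%d",
                           i[which(i > s)[1]], s[which(i > s)[1]])
  if (max(s) > length(trl) || any(!is.finite(trl[unique(c(i, s))])))
    stop_fmt("trunk length covariate missing for some requested stage")
  A * B^(i - 1) * (trl[s] / trl[i])^(k - 1)
}

#' Relative-position image of a trunk boundary after one moult
#'
#' Under a growth field `g(p) = exp(b * p)` along relative trunk position
#' `p` in `[0, 1]`, a material boundary at `p` maps to
#' `phi_b(p) = (exp(b p) - 1)/(exp(b) - 1)`; `b = 0` gives the identity.
#' Endpoints are conserved: `phi_b(0) = 0`, `phi_b(1) = 1`.
#'
#' @param p relative position(s) in `[0, 1]`.
#' @param b gradient steepness (finite; sign sets polarity).
#' @return mapped position(s).
#' @export
tg_position_map <- function(p, b) {
  stopifnot(all(p >= 0 & p <= 1), is.finite(b))
  if (b == 0) return(p)
  expm1(b * p) / expm1(b)
}

#' Predicted boundary positions and segment lengths under a TG model
#'
#' Boundaries are released at `RPS(i, i) = 1 - q0 * q1^i` and advected by
#' [tg_position_map()] with per-moult steepness `b_s = c0 + c1 * ln(TRG_s)`
#' (TG-T) or `b_s = c0 + c1 * s` (TG-D). Relative segment lengths follow by
#' differencing: `RLS(i, s) = RPS(i, s) - RPS(i-1, s)` with `RPS(0, s) = 0`.
#'
#' @param c0,c1 gradient link parameters.
#' @param q0,q1 positive release-boundary parameters; `q0 * q1^i` must lie in
#'   (0, 1) for every fitted stage.
#' @param model `"TG-T"` or `"TG-D"`.
#' @param stages contiguous stage range starting at 1 (default `1:12`).
#' @param trg per-stage trunk growth rates `TRG_s = TRL(s+1)/TRL(s)` indexed
#'   by stage; required for TG-T (stages `1..max(stages)-1` used).
#' @return list with matrices `RPS` and `RLS` (`[i, s]`, `NA` for `i > s`).
#' @export
tg_predict <- function(c0, c1, q0, q1, model = c("TG-T", "TG-D"),
                       stages = 1:12, trg = NULL) {
  model <- match.arg(model)
  stopifnot(q0 > 0, q1 > 0, identical(stages, seq_len(length(stages))))
  S <- length(stages)
  rel <- 1 - q0 * q1^seq_len(S)
  if (any(rel <= 0 | rel >= 1))
    stop_fmt("release boundary outside (0,1) for q0=%g, q1=%g at segment %d",
             q0, q1, which(rel <= 0 | rel >= 1)[1])
  if (model == "TG-T") {
    if (is.null(trg) || (S > 1 && (length(trg) < S - 1 ||
                                   any(!is.finite(trg[seq_len(S - 1)])))))
      stop_fmt("TG-T requires the TRG covariate for stages 1..%d", S - 1)
    b <- c0 + c1 * log(trg[seq_len(max(S - 1, 1))])
  } else {
    b <- c0 + c1 * seq_len(max(S - 1, 1))
  }
  RPS <- matrix(NA_real_, S, S, dimnames = list(segment = NULL, stage = NULL))
  for (i in seq_len(S)) {
    RPS[i, i] <- rel[i]
    if (i < S) for (s in i:(S - 1L)) RPS[i, s + 1L] <- tg_position_map(RPS[i, s], b[s])
  }
  RLS <- RPS - rbind(0, RPS[-S, , drop = FALSE])
  list(RPS = RPS, RLS = RLS)
}

#' Stage-mean gradient observations from a summary table
#'
#' Extracts the `(i, s, value)` triplets of stage-mean RLS or RPS for
#' `1 <= i <= s` over the requested stages, together with the trunk-length and
#' trunk-growth-rate covariate series used by the SG-A and TG-T models.
#'
#' @param summaries a `trilo_stage_summary` table covering the stages.
#' @param response `"RLS"` or `"RPS"`.
#' @param stages stages to fit (default `1:12`; D0 has no thoracic segments
#'   and is excluded).
#' @return list with data frame `obs` (`i`, `s`, `value`), vectors `trl` and
#'   `trg` indexed by stage, and `response`.
#' @export
gradient_observations <- function(summaries, response = c("RLS", "RPS"),
                                  stages = 1:12) {
  response <- match.arg(response)
  stopifnot(identical(stages, seq_len(length(stages))))
  S <- length(stages)
  trl <- rep(NA_real_, S)
  trg <- rep(NA_real_, S)
  idx <- match(stages, summaries$degree)
  if (anyNA(idx))
    stop_fmt("summaries missing stage(s): %s",
             paste0("D", stages[is.na(idx)], collapse = ", "))
  trl[stages] <- summaries$TRL[idx]
  trg[stages] <- summaries$TRG[idx]
  obs <- do.call(rbind, lapply(stages, function(s) {
    i <- seq_len(s)
    v <- as.numeric(summaries[idx[s], paste0(response, i)])
    data.frame(i = i, s = s, value = v)
  }))
  obs <- obs[is.finite(obs$value), , drop = FALSE]
  rownames(obs) <- NULL
  list(obs = obs, trl = trl, trg = trg, response = response)
}

# ---- Levenberg-Marquardt ----------------------------------------------------

# numeric forward-difference Jacobian of a residual function
num_jacobian <- function(fn, theta, r0) {
  p <- length(theta)
  J <- matrix(NA_real_, length(r0), p)
  h <- 1e-7 * (abs(theta) + 1e-7)
  for (j in seq_len(p)) {
    th <- theta
    th[j] <- th[j] + h[j]
    rj <- fn(th)
    if (is.null(rj) || any(!is.finite(rj))) return(NULL)
    J[, j] <- (rj - r0) / h[j]
  }
  J
}

# damped Gauss-Newton (Levenberg-Marquardt) least squares on an unconstrained
# parameter vector; resid_fn returns residuals or NULL for an inadmissible
# point (treated as a rejected step).
marquardt <- function(resid_fn, theta0, max_iter = 200L, ftol = 1e-13,
                      rss_floor = 1e-28) {
  r <- resid_fn(theta0)
  if (is.null(r) || any(!is.finite(r)))
    return(list(converged = FALSE, message = "inadmissible start"))
  theta <- theta0
  rss <- sum(r^2)
  lambda <- 1e-3
  for (iter in seq_len(max_iter)) {
    if (rss < rss_floor) break
    J <- num_jacobian(resid_fn, theta, r)
    if (is.null(J) || any(!is.finite(J))) break
    g <- crossprod(J, r)
    A <- crossprod(J)
    dA <- pmax(diag(A), 1e-12)
    moved <- FALSE
    for (tries in 1:40) {
      H <- A + lambda * diag(dA, nrow = length(theta))
      delta <- tryCatch(solve(H, -g), error = function(e) NULL)
      if (!is.null(delta)) {
        cand <- theta + as.vector(delta)
        rc <- resid_fn(cand)
        if (!is.null(rc) && all(is.finite(rc)) && sum(rc^2) <= rss) {
          drop_rel <- (rss - sum(rc^2)) / max(rss, .Machine$double.xmin)
          theta <- cand; r <- rc; rss <- sum(rc^2)
          lambda <- max(lambda / 3, 1e-12)
          moved <- TRUE
          if (drop_rel < ftol) return(list(par = theta, rss = rss,
                                           converged = TRUE, iter = iter))
          break
        }
      }
      lambda <- lambda * 5
      if (lambda > 1e12) break
    }
    if (!moved) return(list(par = theta, rss = rss, converged = TRUE, iter = iter))
  }
  list(par = theta, rss = rss, converged = TRUE, iter = max_iter)
}

# per-model parameter transforms (optimizer scale <-> natural scale)
gradient_par_names <- function(model) {
  switch(model,
         "SG-R" = c("A", "B", "r"),
         "SG-A" = c("A", "B", "k"),
         "TG-T" = ,
         "TG-D" = c("c0", "c1", "q0", "q1"))
}

to_optim_scale <- function(model, par) {
  switch(model,
         "SG-R" = log(par),
         "SG-A" = c(log(par[1:2]), par[3]),
         c(par[1:2], log(par[3:4])))
}

to_natural_scale <- function(model, theta) {
  par <- switch(model,
                "SG-R" = exp(theta),
                "SG-A" = c(exp(theta[1:2]), theta[3]),
                c(theta[1:2], exp(theta[3:4])))
  setNames(par, gradient_par_names(model))
}

# prediction at the observation triplets; NULL if inadmissible
gradient_predict <- function(model, par, obs, response, trl, trg, S = 12L) {
  ok <- tryCatch({
    switch(model,
           "SG-R" = {
             if (response != "RLS") stop("SG models predict RLS only")
             sg_r_predict(par["A"], par["B"], par["r"], obs$i, obs$s)
           },
           "SG-A" = {
             if (response != "RLS") stop("SG models predict RLS only")
             sg_a_predict(par["A"], par["B"], par["k"], obs$i, obs$s, trl)
           },
           {
             m <- tg_predict(par["c0"], par["c1"], par["q0"], par["q1"],
                             model = model, stages = seq_len(S), trg = trg)
             # boundary crossings (negative segment lengths) are inadmissible
             if (any(m$RLS < 0, na.rm = TRUE)) stop("boundary crossing")
             m[[response]][cbind(obs$i, obs$s)]
           })
  }, error = function(e) NULL)
  if (is.null(ok) || any(!is.finite(ok))) return(NULL)
  ok
}

# Deterministic multistart policy. The release-stage observations identify the
# size-decline submodels almost directly: RLS(i,i) ~ A * B^(i-1) for SG models
# and sum_i RLS(i,s) = RPS(s,s) = 1 - q0 * q1^s for TG models, so log-linear
# regressions give sharp starting values; the remaining parameter(s) get a
# small grid, and fixed fallback starts guard against degenerate data.
default_gradient_starts <- function(model, data = NULL) {
  fallback <- switch(model,
                     "SG-R" = list(c(A = 0.2, B = 0.9, r = 0.95),
                                   c(A = 0.4, B = 0.75, r = 0.85)),
                     "SG-A" = list(c(A = 0.2, B = 0.9, k = 0.9),
                                   c(A = 0.4, B = 0.75, k = 1.2)),
                     list(c(c0 = 0.3, c1 = 0, q0 = 0.5, q1 = 0.85),
                          c(c0 = -0.5, c1 = 2, q0 = 0.4, q1 = 0.9)))
  starts <- list()
  if (!is.null(data)) {
    obs <- data$obs
    if (startsWith(model, "SG")) {
      rel <- obs[obs$i == obs$s & obs$value > 0, ]
      if (nrow(rel) >= 2L) {
        cf <- coef(lm(log(value) ~ I(i - 1), data = rel))
        A0 <- exp(cf[1]); B0 <- exp(cf[2])
        if (is.finite(A0) && is.finite(B0) && A0 > 0 && B0 > 0) {
          third <- if (model == "SG-R") c(r = 0.85, r = 0.95, r = 1.05)
                   else c(k = 0.6, k = 0.9, k = 1.2)
          starts <- lapply(seq_len(3), function(j)
            setNames(c(A0, B0, third[j]), gradient_par_names(model)))
        }
      }
    } else {
      # per-stage pygidial complement: RPS(s,s) directly, or the RLS column sum
      ss <- sort(unique(obs$s))
      relb <- vapply(ss, function(s) {
        if (data$response == "RPS") obs$value[obs$i == s & obs$s == s][1]
        else sum(obs$value[obs$s == s])
      }, 0)
      comp <- 1 - relb
      keep <- is.finite(comp) & comp > 0 & comp < 1
      if (sum(keep) >= 2L) {
        cf <- coef(lm(log(comp[keep]) ~ ss[keep]))
        q00 <- exp(cf[1]); q10 <- exp(cf[2])
        if (all(is.finite(c(q00, q10))) && q00 > 0 && q10 > 0) {
          cgrid <- if (model == "TG-T") expand.grid(c0 = c(-0.5, 0.5),
                                                    c1 = c(-2, 0, 2, 4))
                   else expand.grid(c0 = c(-0.5, 0.5, 1.2),
                                    c1 = c(-0.2, 0, 0.2))
          starts <- lapply(seq_len(nrow(cgrid)), function(j)
            c(c0 = cgrid$c0[j], c1 = cgrid$c1[j], q0 = unname(q00),
              q1 = unname(q10)))
        }
      }
    }
  }
  c(starts, fallback)
}

#' Fit a segmental growth-gradient model by nonlinear least squares
#'
#' Minimizes the sum of squared deviations between observed stage-mean RLS (or
#' RPS for TG models) and model predictions using a Levenberg-Marquardt
#' iteration from a deterministic multistart grid (3 values per parameter by
#' default); the best converged start wins, ties broken by start order.
#' Positive parameters are optimized on the log scale; inadmissible parameter
#' points (e.g. TG release boundaries outside (0,1)) are rejected during the
#' line search, so returned parameters always satisfy the model constraints.
#'
#' @param model one of `"SG-R"`, `"SG-A"`, `"TG-T"`, `"TG-D"`.
#' @param data observations as produced by [gradient_observations()].
#' @param starts optional list of named start vectors on the natural scale.
#' @return a `gradient_fit` list: `model`, `response`, `par` (natural scale),
#'   `rss`, `tss`, `n`, `K` (parameters counted for AICc, model parameters
#'   plus the residual variance), `pct_var`, `fitted`, `obs`, `n_converged`.
#' @export
fit_gradient_model <- function(model = GRADIENT_MODELS, data, starts = NULL) {
  model <- match.arg(model)
  response <- data$response
  if (startsWith(model, "SG") && response != "RLS")
    stop_fmt("%s is defined for the RLS response only", model)
  obs <- data$obs
  S <- max(obs$s)
  resid_of <- function(theta) {
    par <- to_natural_scale(model, theta)
    pred <- gradient_predict(model, par, obs, response, data$trl, data$trg, S)
    if (is.null(pred)) return(NULL)
    obs$value - pred
  }
  starts <- starts %||% default_gradient_starts(model, data)
  best <- NULL
  n_conv <- 0L
  diagnostics <- character(0)
  for (st in starts) {
    theta0 <- to_optim_scale(model, st[gradient_par_names(model)])
    if (any(!is.finite(theta0))) next
    fit <- marquardt(resid_of, theta0)
    if (!isTRUE(fit$converged)) {
      diagnostics <- c(diagnostics,
                       sprintf("start (%s): %s", paste(signif(st, 3), collapse = ", "),
                               fit$message %||% "failed"))
      next
    }
    n_conv <- n_conv + 1L
    if (is.null(best) || fit$rss < best$rss) best <- fit
  }
  if (is.null(best))
    stop_fmt("no start converged for %s:\n%s", model,
             paste(diagnostics, collapse = "\n"))
  par <- to_natural_scale(model, best$par)
  pred <- gradient_predict(model, par, obs, response, data$trl, data$trg, S)
  tss <- sum((obs$value - mean(obs$value))^2)
  p <- length(par)
  out <- list(model = model, response = response, par = par,
              rss = best$rss, tss = tss, n = nrow(obs), K = p + 1L,
              pct_var = 100 * (1 - best$rss / tss),
              fitted = pred, obs = obs, n_converged = n_conv,
              iterations = best$iter)
  class(out) <- "gradient_fit"
  out
}

#' @export
print.gradient_fit <- function(x, ...) {
  cat(sprintf("%s fit (%s response), n = %d\n", x$model, x$response, x$n))
  print(signif(x$par, 6))
  cat(sprintf("RSS = %.6g, %% variance explained = %.2f\n", x$rss, x$pct_var))
  invisible(x)
}

# ---- AICc machinery ---------------------------------------------------------

#' Small-sample Akaike information criterion for a least-squares fit
#'
#' `AICc = n log(RSS/n) + 2K + 2K(K+1)/(n-K-1)`, with `K` counting the
#' residual variance alongside the model parameters.
#'
#' @param rss residual sum of squares.
#' @param n number of observations.
#' @param K number of estimated parameters including the residual variance.
#' @return the AICc score.
#' @export
aicc_ls <- function(rss, n, K) {
  stopifnot(n > K + 1)
  n * log(rss / n) + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Akaike weights from a set of AICc scores
#'
#' @param aicc numeric vector of AICc scores on the same data.
#' @return list with `delta` (differences from the minimum) and `weight`
#'   (normalized model probabilities, summing to 1).
#' @export
akaike_weights <- function(aicc) {
  stopifnot(length(aicc) >= 2, all(is.finite(aicc)))
  delta <- aicc - min(aicc)
  w <- exp(-delta / 2)
  list(delta = delta, weight = w / sum(w))
}

#' Compare fitted gradient models with AICc
#'
#' All fits must share the same response variable and observation count;
#' comparing fits to different responses is refused (their likelihoods are not
#' commensurable).
#'
#' @param ... `gradient_fit` objects, or a single list of them.
#' @return a `model_comparison` data frame with columns `model`, `n_par`,
#'   `K`, `RSS`, `pct_var`, `AICc`, `dAICc`, `wAICc`, sorted by AICc.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && !inherits(fits[[1]], "gradient_fit")) fits <- fits[[1]]
  stopifnot(length(fits) >= 2, all(vapply(fits, inherits, TRUE, "gradient_fit")))
  resp <- unique(vapply(fits, `[[`, "", "response"))
  if (length(resp) != 1L)
    stop_fmt("direct AICc comparison across responses (%s) is not appropriate",
             paste(resp, collapse = " vs "))
  ns <- unique(vapply(fits, `[[`, 0L, "n"))
  if (length(ns) != 1L) stop_fmt("fits have differing observation counts")
  aicc <- vapply(fits, function(f) aicc_ls(f$rss, f$n, f$K), 0)
  aw <- akaike_weights(aicc)
  out <- data.frame(model = vapply(fits, `[[`, "", "model"),
                    response = resp,
                    n_par = vapply(fits, function(f) length(f$par), 0L),
                    K = vapply(fits, `[[`, 0L, "K"),
                    RSS = vapply(fits, `[[`, 0, "rss"),
                    pct_var = vapply(fits, `[[`, 0, "pct_var"),
                    AICc = aicc, dAICc = aw$delta, wAICc = aw$weight)
  out <- out[order(out$AICc), ]
  rownames(out) <- NULL
  class(out) <- c("model_comparison", "data.frame")
  out
}

#' Evidential ratio between two models in a comparison
#'
#' @param comparison a `model_comparison` table.
#' @param a,b model names (default: best and second-best).
#' @return `wAICc[a] / wAICc[b]`.
#' @export
evidence_ratio <- function(comparison, a = comparison$model[1],
                           b = comparison$model[2]) {
  ia <- match(a, comparison$model)
  ib <- match(b, comparison$model)
  if (is.na(ia) || is.na(ib)) stop_fmt("model not present in comparison")
  comparison$wAICc[ia] / comparison$wAICc[ib]
}

# ---- pygidial stasis --------------------------------------------------------

#' Test for pygidial size stasis across meraspid stages
#'
#' Specimen-level ordinary least squares regression of pygidial length on
#' meraspid degree with a two-sided t-test on the slope. With zero residual
#' variance (e.g. exactly constant PYL) the p-value is reported as 1 when the
#' slope is zero.
#'
#' @param x a specimen table.
#' @param stages degrees to include; must be given explicitly (the analysis
#'   window materially changes the test).
#' @return list with `slope`, `t`, `p`, `n`, `df`.
#' @export
pyl_stasis_test <- function(x, stages) {
  if (missing(stages)) stop_fmt("'stages' must be given explicitly")
  d <- as.data.frame(x)
  d <- d[d$period == "meraspid" & !is.na(d$degree) & d$degree %in% stages &
           is.finite(d$PYL), , drop = FALSE]
  if (nrow(d) < 3L) stop_fmt("need at least 3 specimens with PYL")
  if (length(unique(d$degree)) < 2L) stop_fmt("need at least 2 distinct stages")
  fit <- lm(PYL ~ degree, data = d)
  n <- nrow(d)
  slope <- unname(coef(fit)[2])
  rss <- sum(fit$residuals^2)
  sxx <- sum((d$degree - mean(d$degree))^2)
  if (rss < 1e-24) {
    p <- if (abs(slope) < 1e-12) 1 else 0
    tval <- if (abs(slope) < 1e-12) 0 else Inf
  } else {
    se <- sqrt(rss / (n - 2) / sxx)
    tval <- slope / se
    p <- 2 * pt(-abs(tval), df = n - 2)
  }
  list(slope = slope, t = tval, p = p, n = n, df = n - 2L)
}
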