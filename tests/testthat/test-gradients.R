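test_that("SG-R predictions match the release-recursion oracle", {
  A <- 0.12; B <- 0.9; r <- 0.95
  # oracle: RLS(i,i) = A*B^(i-1), then RLS(i,s+1) = r * RLS(i,s)
  for (i in 1:12) {
    v <- A * B^(i - 1)
    for (s in i:12) {
      expect_equal(sg_r_predict(A, B, r, i, s), v)
      v <- v * r
    }
  }
  # limits: constant field and s-independence at r = 1
  expect_equal(sg_r_predict(0.1, 1, 1, 3, 9), 0.1)
  expect_equal(sg_r_predict(A, B, 1, 4, 4), sg_r_predict(A, B, 1, 4, 11))
  expect_error(sg_r_predict(A, B, r, 5, 4), "not yet released")
})

test_that("SG-A predictions telescope over stepwise trunk growth", {
  trl <- cumprod(c(1, 1.3, 1.25, 1.2, 1.16, 1.12, 1.1))
  A <- 0.2; B <- 0.85; k <- 0.8
  trg <- trl[-1] / trl[-length(trl)]
  for (i in 1:5) for (s in i:7) {
    stepwise <- if (s > i) prod(trg[i:(s - 1)]^(k - 1)) else 1
    expect_equal(sg_a_predict(A, B, k, i, s, trl),
                 A * B^(i - 1) * stepwise)
  }
  # isometric limit: no stage dependence at k = 1
  expect_equal(sg_a_predict(A, B, 1, 2, 2, trl), sg_a_predict(A, B, 1, 2, 7, trl))
  # negative allometry: decreasing in s for fixed i
  vals <- vapply(3:7, function(s) sg_a_predict(A, B, 0.8, 3, s, trl), 0)
  expect_true(all(diff(vals) < 0))
})

test_that("the TG position map conserves endpoints and matches quadrature", {
  for (b in c(-3, -0.5, 0, 1.7, 4)) {
    expect_equal(tg_position_map(0, b), 0)
    expect_equal(tg_position_map(1, b), 1)
  }
  # small-b limit approaches the identity
  p <- seq(0, 1, by = 0.05)
  expect_lt(max(abs(tg_position_map(p, 1e-8) - p)), 1e-7)
  # quadrature oracle: phi_b(p) = int_0^p e^(bu) du / int_0^1 e^(bu) du
  for (b in c(2, -1.3, 0.4)) for (pp in c(0.25, 0.5, 0.8)) {
    num <- integrate(function(u) exp(b * u), 0, pp, rel.tol = 1e-12)$value
    den <- integrate(function(u) exp(b * u), 0, 1, rel.tol = 1e-12)$value
    expect_equal(tg_position_map(pp, b), num / den, tolerance = 1e-10)
  }
  expect_equal(tg_position_map(0.5, 2), 0.26894, tolerance = 1e-5)
})

test_that("TG predictions keep boundaries ordered and consistent", {
  trg <- 1 + 0.35 * exp(-0.12 * (1:11))
  # frozen field: boundaries never move when b = 0
  frozen <- tg_predict(0, 0, 0.5, 0.9, "TG-D", 1:12)
  for (i in 1:11)
    expect_equal(unique(frozen$RPS[i, i:12]), frozen$RPS[i, i])
  # positive gradient: anteriorward relative drift (RPS decreasing in s)
  m <- tg_predict(0.3, 2, 0.5, 0.88, "TG-T", 1:12, trg = trg)
  for (i in 1:11) expect_true(all(diff(m$RPS[i, i:12]) < 0))
  # randomized admissible parameters (non-negative gradient steepness, the
  # polarity under which release order is provably preserved): no boundary
  # crossing, differencing reproduces RLS, and column sums telescope to the
  # last boundary
  trilogrowth:::with_seed(77, {
    for (rep in 1:25) {
      q0 <- runif(1, 0.2, 0.7); q1 <- runif(1, 0.75, 0.98)
      c0 <- runif(1, 0.05, 1); c1 <- runif(1, -c0 / 12, 0.25)
      mm <- tg_predict(c0, c1, q0, q1, "TG-D", 1:12)
      for (s in 2:12) {
        col <- mm$RPS[1:s, s]
        expect_true(all(diff(col) > 0))
        expect_equal(sum(mm$RLS[1:s, s]), mm$RPS[s, s])
        expect_lte(mm$RPS[s, s], 1)
      }
    }
  })
  expect_error(tg_predict(0, 0, 2, 0.9, "TG-D", 1:12), "outside \\(0,1\\)")
  expect_error(tg_predict(0, 1, 0.5, 0.9, "TG-T", 1:12), "TRG covariate")
})

test_that("nonlinear fitting recovers generating parameters at zero noise", {
  trl <- 1.2 * cumprod(c(1, 1 + 0.35 * exp(-0.12 * (1:11))))
  trg <- c(trl[-1] / trl[-12], NA)
  grid <- do.call(rbind, lapply(1:12, function(s) data.frame(i = 1:s, s = s)))

  truthA <- c(A = 0.3, B = 0.72, k = 0.85)
  datA <- list(obs = transform(grid, value = sg_a_predict(0.3, 0.72, 0.85,
                                                          grid$i, grid$s, trl)),
               trl = trl, trg = trg, response = "RLS")
  fitA <- fit_gradient_model("SG-A", datA)
  expect_lt(max(abs(fitA$par - truthA) / truthA), 1e-6)
  expect_lt(fitA$rss, 1e-20)

  truthT <- c(c0 = 0.2, c1 = 4, q0 = 0.47, q1 = 0.84)
  predT <- tg_predict(0.2, 4, 0.47, 0.84, "TG-T", 1:12, trg = trg)$RLS
  datT <- list(obs = transform(grid, value = predT[cbind(grid$i, grid$s)]),
               trl = trl, trg = trg, response = "RLS")
  fitT <- fit_gradient_model("TG-T", datT)
  expect_lt(max(abs(fitT$par - truthT) / abs(truthT)), 1e-4)
  fitR <- fit_gradient_model("SG-R", datT)
  expect_gt(fitR$rss, fitT$rss * 1e6)

  # permutation invariance of the observations
  datP <- datT
  datP$obs <- datP$obs[rev(seq_len(nrow(datP$obs))), ]
  fitP <- fit_gradient_model("TG-T", datP)
  expect_equal(fitP$par, fitT$par, tolerance = 1e-8)

  # SG models are defined for RLS only
  datR <- datT; datR$response <- "RPS"
  expect_error(fit_gradient_model("SG-A", datR), "RLS response only")
})

test_that("AICc comparison machinery is coherent", {
  # equal scores split the weight evenly
  w <- akaike_weights(c(-100, -100))
  expect_equal(w$weight, c(0.5, 0.5))
  # weights always normalize
  trilogrowth:::with_seed(5, {
    for (rep in 1:20) {
      scores <- rnorm(sample(2:8, 1), sd = 50)
      expect_lt(abs(sum(akaike_weights(scores)$weight) - 1), 1e-12)
    }
  })
  # AICc converges to AIC for large n
  n <- 1e6; K <- 5; rss <- 123.4
  aic <- n * log(rss / n) + 2 * K
  expect_lt(abs(aicc_ls(rss, n, K) - aic), 1e-3)
  # comparing fits across responses is refused
  f1 <- structure(list(model = "TG-T", response = "RLS", par = 1:4, rss = 1,
                       tss = 2, n = 78, K = 5L, pct_var = 50), class = "gradient_fit")
  f2 <- f1; f2$response <- "RPS"
  expect_error(compare_models(f1, f2), "not appropriate")
})

test_that("pygidial stasis test matches closed-form OLS", {
  # degenerate: exactly constant PYL
  sp <- specimen_table(
    specimen_row("a", degree = 1, lts = .5, PYL = .5),
    specimen_row("b", degree = 2, lts = c(.5, .4), PYL = .5),
    specimen_row("c", degree = 3, lts = c(.5, .4, .3), PYL = .5))
  res <- pyl_stasis_test(sp, stages = 0:10)
  expect_equal(res$slope, 0)
  expect_equal(res$p, 1)
  # closed-form oracle on a hand-computable 4-point dataset
  x <- 1:4; y <- c(1.0, 1.1, 0.9, 1.0)
  sp4 <- specimen_table(
    specimen_row("p1", degree = 1, lts = .5, PYL = 1.0),
    specimen_row("p2", degree = 2, lts = c(.5, .4), PYL = 1.1),
    specimen_row("p3", degree = 3, lts = c(.5, .4, .3), PYL = 0.9),
    specimen_row("p4", degree = 4, lts = c(.5, .4, .3, .2), PYL = 1.0))
  res4 <- pyl_stasis_test(sp4, stages = 1:4)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  rss <- sum((y - mean(y) - slope * (x - mean(x)))^2)
  tval <- slope / sqrt(rss / 2 / sxx)
  expect_equal(res4$slope, slope)
  expect_equal(res4$t, tval)
  expect_equal(res4$p, 2 * pt(-abs(tval), 2))
  # zero-noise default world: exactly zero slope over D0-D10
  specs <- simulate_ontogeny(quiet_sim())
  res0 <- pyl_stasis_test(specs, stages = 0:10)
  expect_lt(abs(res0$slope), 1e-12)
  expect_equal(res0$p, 1)
  # the stage window is never defaulted silently
  expect_error(pyl_stasis_test(specs), "explicitly")
})

test_that("fitted parameters respect model constraints on noisy data", {
  cfg <- default_sim_config(seed = 21, model = "SG-A",
                            model_par = c(A = 0.3, B = 0.72, k = 0.85, k_slope = 0),
                            sigma_part = 0.03, bookkeeping = "exact-model")
  dat <- gradient_observations(stage_summaries(simulate_ontogeny(cfg)), "RLS")
  for (m in GRADIENT_MODELS) {
    f <- fit_gradient_model(m, dat)
    p <- f$par
    if (startsWith(m, "SG")) {
      expect_true(p["A"] > 0 && p["B"] > 0)
      if (m == "SG-R") expect_gt(p["r"], 0)
    } else {
      expect_true(p["q0"] > 0 && p["q1"] > 0)
      expect_true(all(p["q0"] * p["q1"]^(1:12) > 0 &
                        p["q0"] * p["q1"]^(1:12) < 1))
    }
    expect_lte(f$pct_var, 100)
  }
})
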