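test_that("CSV round trip is the identity on all fields", {
  cfg <- default_sim_config(seed = 42)
  specs <- simulate_ontogeny(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_specimens(specs, path)
  back <- load_specimens(path)
  expect_identical(attr(back, "n_rejected"), 0L)
  expect_identical(nrow(back), nrow(specs))
  expect_identical(back$specimen_id, specs$specimen_id)
  expect_identical(back$degree, specs$degree)
  for (cl in c("FAL", "PGL", "ORL", paste0("LTS", 1:13), "PYL"))
    expect_identical(back[[cl]], specs[[cl]])
})

test_that("loader validates schema and rows", {
  path <- withr::local_tempfile(fileext = ".csv")

  ok3 <- specimen_table(
    specimen_row("a", degree = 1, FAL = .2, PGL = .3, ORL = .1,
                 lts = .4, PYL = .5),
    specimen_row("b", degree = 2, FAL = .2, PGL = .3, ORL = .1,
                 lts = c(.4, .3), PYL = .5),
    specimen_row("c", period = "holaspid", FAL = 1, PGL = 1.2, ORL = .4,
                 lts = rep(.3, 13), PYL = .5))
  write_specimens(ok3, path)
  expect_no_warning(got <- load_specimens(path))
  expect_identical(nrow(got), 3L)

  # thoracic segment count inconsistent with degree -> rejected, named
  bad <- rbind(ok3, specimen_row("odd-one", degree = 3,
                                 lts = c(.4, .3), PYL = .5))
  write_specimens(bad, path)
  expect_warning(got <- load_specimens(path), "odd-one")
  expect_identical(nrow(got), 3L)
  expect_identical(attr(got, "n_rejected"), 1L)

  # non-positive length -> rejected with warning
  neg <- ok3
  neg$FAL[1] <- -0.2
  write_specimens(neg, path)
  expect_warning(got <- load_specimens(path), "non-positive")
  expect_identical(nrow(got), 2L)

  # unknown column -> hard error naming it
  txt <- readLines(path)
  txt[1] <- paste0(txt[1], ",bogus")
  txt[-1] <- paste0(txt[-1], ",1")
  writeLines(txt, path)
  expect_error(load_specimens(path), "bogus")
})

test_that("derive_parts computes sums, ratios and respects missingness", {
  sp <- specimen_table(
    specimen_row("t1", degree = 2, FAL = 1, PGL = 1, ORL = 1,
                 lts = c(1, 1), PYL = 1))
  d <- derive_parts(sp)
  expect_equal(d$CEL, 3)
  expect_equal(d$TRL, 3)
  expect_equal(d$BOL, 6)
  expect_equal(c(d$RLS1, d$RLS2), c(1, 1) / 3)
  expect_equal(c(d$RPS1, d$RPS2), c(1, 2) / 3)
  expect_equal(d$RPYL, 1 / 3)

  # missing FAL: cephalic composites absent, trunk quantities present
  sp2 <- specimen_table(
    specimen_row("t2", degree = 2, FAL = NA, PGL = 1, ORL = 1,
                 lts = c(1, 1), PYL = 1))
  d2 <- derive_parts(sp2)
  expect_true(is.na(d2$CEL) && is.na(d2$BOL))
  expect_equal(d2$TRL, 3)
  expect_equal(d2$RLS1, 1 / 3)
  expect_equal(d2$RPS2, 2 / 3)
})

test_that("conservation and ordering hold for random complete specimens", {
  d <- derive_parts(random_specimens(60, seed = 9))
  rls <- as.matrix(d[, paste0("RLS", 1:13)])
  total <- rowSums(rls, na.rm = TRUE) + d$RPYL
  expect_lt(max(abs(total - 1)), 1e-12)
  expect_lt(max(abs(d$CEL + d$TRL - d$BOL)), 1e-12)
  rps <- as.matrix(d[, paste0("RPS", 1:13)])
  for (r in seq_len(nrow(d))) {
    v <- rps[r, !is.na(rps[r, ])]
    if (length(v) > 1) expect_true(all(diff(v) > 0))
  }
})

test_that("stage summaries average parts and compute TRG", {
  sp <- specimen_table(
    specimen_row("a", degree = 3, lts = c(.5, .4, .3), PYL = .8),   # TRL 2
    specimen_row("b", degree = 3, lts = c(1.2, 1, .8), PYL = 1),    # TRL 4
    specimen_row("c", degree = 4, lts = c(.7, .6, .5, .4), PYL = 1.4)) # TRL 3.6
  expect_warning(summ <- stage_summaries(sp, stages = 2:4), "D2")
  expect_equal(summ$TRL[summ$degree == 3], 3)
  expect_equal(summ$n, c(2L, 1L))
  expect_equal(summ$TRG[summ$degree == 3], 3.6 / 3)
  # mean-of-ratios vs ratio-of-means differ for unequal-size specimens
  s2 <- stage_summaries(sp, ratio_rule = "ratio-of-means", stages = 3:4)
  expect_equal(s2$RLS1[1], mean(c(.5, 1.2)) / 3)
  s1 <- stage_summaries(sp, stages = 3:4)
  expect_equal(s1$RLS1[1], mean(c(.5 / 2, 1.2 / 4)))
})

test_that("default simulation reproduces the configured per-stage counts", {
  specs <- simulate_ontogeny(default_sim_config(seed = 1))
  counts <- table(specs$degree[specs$period == "meraspid"])
  expect_identical(as.integer(counts[as.character(1:12)]),
                   c(7L, 3L, 8L, 7L, 4L, 8L, 16L, 11L, 7L, 6L, 14L, 6L))
  expect_identical(sum(specs$period == "meraspid"), 99L)
  expect_identical(sum(specs$period == "holaspid"), 135L)
})

test_that("average growth rate is the per-stage geometric factor", {
  sp <- specimen_table(
    specimen_row("a", degree = 1, lts = .5, PYL = .5),   # TRL 1
    specimen_row("b", degree = 2, lts = c(1, 1), PYL = 0.1))
  sp$PYL[2] <- 1  # TRL 3 -> not used below; direct summaries built instead
  summ <- data.frame(degree = 1:5, TRL = c(1, 2, 3.1, 3.9, 4.4))
  expect_equal(average_growth_rate(summ, "TRL", 1, 2), 2)
  expect_equal(average_growth_rate(summ, "TRL", 1, 3), sqrt(3.1))
  # brute-force oracle: product of stepwise ratios
  step <- summ$TRL[-1] / summ$TRL[-5]
  for (to in 2:5)
    expect_equal(average_growth_rate(summ, "TRL", 1, to),
                 prod(step[1:(to - 1)])^(1 / (to - 1)))
  expect_error(average_growth_rate(summ, "TRL", 3, 3), "exceed")
})
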