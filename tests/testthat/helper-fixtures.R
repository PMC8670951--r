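# shared fixtures: tiny specimen builders and small simulation configs

# one specimen row as a data frame; lts is a numeric vector (possibly empty)
specimen_row <- function(id, period = "meraspid", degree = length(lts),
                         FAL = NA, PGL = NA, ORL = NA, lts = numeric(0),
                         PYL = NA) {
  row <- data.frame(specimen_id = id, period = period,
                    degree = if (period == "holaspid") NA_integer_
                             else as.integer(degree),
                    FAL = FAL, PGL = PGL, ORL = ORL)
  v <- rep(NA_real_, 13)
  v[seq_along(lts)] <- lts
  row <- cbind(row, t(setNames(v, paste0("LTS", 1:13))))
  row$PYL <- PYL
  row
}

specimen_table <- function(...) {
  df <- do.call(rbind, list(...))
  structure(df[, specimen_columns()], class = c("trilo_specimens", "data.frame"))
}

# a fast, small zero-noise world used by several suites
quiet_sim <- function(seed = 11, ...) {
  default_sim_config(seed = seed, sigma_size = 0, sigma_part = 0, ...)
}

# random complete meraspid specimens for property tests
random_specimens <- function(n, seed) {
  with_seed(seed, {
    rows <- lapply(seq_len(n), function(j) {
      s <- sample(1:12, 1)
      specimen_row(sprintf("R%03d", j), degree = s,
                   FAL = runif(1, .1, 2), PGL = runif(1, .1, 2),
                   ORL = runif(1, .1, 2),
                   lts = runif(s, .05, 1), PYL = runif(1, .1, 1))
    })
    do.call(specimen_table, rows)
  })
}
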