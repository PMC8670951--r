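# Specimen measurement schema, CSV I/O and derived axial quantities.
#
# One row per fossil specimen. Axial part lengths (mm):
#   FAL  frontal area length            PGL  pre-occipital glabellar length
#   ORL  occipital ring length          LTS1..LTS13 thoracic segment lengths
#   PYL  pygidial length
# plus `specimen_id`, `period` ("meraspid"/"holaspid") and the meraspid
# `degree` (number of articulated thoracic segments, 0-12; holaspides have
# none). Any length may be absent (partially preserved specimen).

MAX_SEGMENTS <- 13L

lts_columns <- function() paste0("LTS", seq_len(MAX_SEGMENTS))

length_columns <- function() c("FAL", "PGL", "ORL", lts_columns(), "PYL")

#' Column order of the specimen CSV dialect
#'
#' @return character vector of column names.
#' @export
specimen_columns <- function() {
  c("specimen_id", "period", "degree", "FAL", "PGL", "ORL", lts_columns(), "PYL")
}

new_specimen_table <- function(df) {
  df <- df[, specimen_columns()]
  rownames(df) <- NULL
  class(df) <- c("trilo_specimens", "data.frame")
  df
}

# Row-level schema checks. Returns a character message per offending row ("" if
# valid). The thorax is all-or-nothing: a meraspid of degree s carries either
# no segment measurements or exactly LTS1..LTSs; a holaspid either none or all
# 13. Partial thoraces cannot yield trunk lengths and are treated as
# malformed rather than silently propagated.
specimen_row_problems <- function(df) {
  lts <- as.matrix(df[, lts_columns()])
  msgs <- character(nrow(df))
  for (r in seq_len(nrow(df))) {
    id <- df$specimen_id[r]
    present <- unname(which(!is.na(lts[r, ])))
    vals <- unlist(df[r, length_columns()])
    if (any(!is.na(vals) & vals <= 0)) {
      msgs[r] <- sprintf("specimen '%s': non-positive length", id)
      next
    }
    if (is.na(df$period[r]) || !df$period[r] %in% c("meraspid", "holaspid")) {
      msgs[r] <- sprintf("specimen '%s': period must be 'meraspid' or 'holaspid'", id)
      next
    }
    if (df$period[r] == "meraspid") {
      s <- df$degree[r]
      if (is.na(s) || s < 0 || s > 12 || s != round(s)) {
        msgs[r] <- sprintf("specimen '%s': meraspid degree must be an integer in 0-12", id)
        next
      }
      if (length(present) > 0 && !identical(present, seq_len(s))) {
        msgs[r] <- sprintf(
          "specimen '%s': thoracic segment count (%d) does not match degree %d",
          id, length(present), s)
        next
      }
    } else {
      if (!is.na(df$degree[r])) {
        msgs[r] <- sprintf("specimen '%s': holaspides carry no degree", id)
        next
      }
      if (length(present) > 0 && !identical(present, seq_len(MAX_SEGMENTS))) {
        msgs[r] <- sprintf(
          "specimen '%s': holaspid thorax must be unmeasured or complete (13 segments)", id)
        next
      }
    }
  }
  msgs
}

#' Read a specimen measurement table from CSV
#'
#' Expects the dialect written by [write_specimens()]: columns
#' `specimen_id,period,degree,FAL,PGL,ORL,LTS1..LTS13,PYL`, empty cells for
#' absent measurements, decimal point, lengths in mm. Unknown columns are a
#' hard error; malformed rows (non-positive lengths, thoracic segment count
#' inconsistent with degree) are dropped with a warning naming the specimen.
#'
#' @param path path to a CSV file.
#' @return a `trilo_specimens` data frame; attribute `n_rejected` carries the
#'   number of dropped rows.
#' @export
load_specimens <- function(path) {
  if (!file.exists(path)) stop_fmt("specimen file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  unknown <- setdiff(names(df), specimen_columns())
  if (length(unknown))
    stop_fmt("unknown column(s) in %s: %s", path, paste(unknown, collapse = ", "))
  missing <- setdiff(specimen_columns(), names(df))
  if (length(missing))
    stop_fmt("missing column(s) in %s: %s", path, paste(missing, collapse = ", "))
  df$specimen_id <- as.character(df$specimen_id)
  df$period <- as.character(df$period)
  df$degree <- as.integer(df$degree)
  for (cl in length_columns()) df[[cl]] <- as.numeric(df[[cl]])
  probs <- specimen_row_problems(df)
  bad <- which(nzchar(probs))
  if (length(bad)) {
    warn_fmt("rejected %d row(s):\n%s", length(bad),
             paste(sprintf("  row %d: %s", bad, probs[bad]), collapse = "\n"))
    df <- df[-bad, , drop = FALSE]
  }
  out <- new_specimen_table(df)
  attr(out, "n_rejected") <- length(bad)
  out
}

#' Write a specimen measurement table to CSV
#'
#' Numeric cells are rendered with `%.17g` so that a write/read round trip
#' reproduces every double bit-identically; absent values become empty cells.
#'
#' @param x a `trilo_specimens` data frame (or compatible data frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_specimens <- function(x, path) {
  df <- as.data.frame(x)[, specimen_columns()]
  for (cl in length_columns()) {
    v <- df[[cl]]
    df[[cl]] <- ifelse(is.na(v), "", sprintf("%.17g", v))
  }
  df$degree <- ifelse(is.na(df$degree), "", as.character(df$degree))
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Derive composite axial quantities per specimen
#'
#' Adds to the specimen table:
#' \describe{
#'   \item{CEL}{cephalic length, `FAL + PGL + ORL`}
#'   \item{TRL}{trunk length, `sum(LTS) + PYL` (requires a complete thorax)}
#'   \item{BOL}{body length, `CEL + TRL`}
#'   \item{RLS1..RLS13}{relative thoracic segment lengths, `LTS_i / TRL`}
#'   \item{RPS1..RPS13}{relative posterior boundary positions,
#'     `cumsum(LTS)_i / TRL`}
#'   \item{RPYL}{relative pygidial length, `PYL / TRL`}
#' }
#' A derived value whose ingredients are absent is itself absent. For every
#' complete specimen `CEL + TRL == BOL` and `sum(RLS) + RPYL == 1` hold to
#' numerical round-off by construction.
#'
#' @param x a `trilo_specimens` data frame.
#' @return a `trilo_derived` data frame (original columns plus derived ones).
#' @export
derive_parts <- function(x) {
  df <- as.data.frame(x)
  n <- nrow(df)
  lts <- as.matrix(df[, lts_columns()])
  df$CEL <- df$FAL + df$PGL + df$ORL

  # expected segment count: degree for meraspides, 13 for holaspides
  expected <- ifelse(df$period == "meraspid", df$degree, MAX_SEGMENTS)
  npresent <- rowSums(!is.na(lts))
  thor_ok <- !is.na(expected) & npresent == expected
  thor <- ifelse(thor_ok, rowSums(lts, na.rm = TRUE), NA_real_)
  trl <- thor + df$PYL
  if (any(!is.na(trl) & trl <= 0)) stop_fmt("non-positive trunk length encountered")
  df$TRL <- trl
  df$BOL <- df$CEL + df$TRL

  rls <- lts / trl
  cum <- t(apply(lts, 1L, function(v) cumsum(ifelse(is.na(v), 0, v))))
  cum[is.na(lts)] <- NA_real_
  rps <- cum / trl
  colnames(rls) <- paste0("RLS", seq_len(MAX_SEGMENTS))
  colnames(rps) <- paste0("RPS", seq_len(MAX_SEGMENTS))
  df <- cbind(df, rls, rps)
  df$RPYL <- df$PYL / trl
  rownames(df) <- NULL
  class(df) <- c("trilo_derived", "trilo_specimens", "data.frame")
  df
}

as_derived <- function(x) {
  if (inherits(x, "trilo_derived")) x else derive_parts(x)
}

#' Per-stage summary of a meraspid series
#'
#' Computes, for each meraspid degree present, the arithmetic mean of every
#' part length and derived quantity, the specimen count, and the per-stage
#' trunk growth rate `TRG_s = meanTRL(s+1) / meanTRL(s)` (absent when the next
#' consecutive stage is missing). Relative quantities (RLS/RPS/RPYL) are
#' averaged either as means of per-specimen ratios (default; ratios are the
#' modelled response downstream) or as ratios of stage-mean lengths.
#'
#' @param x a specimen or derived table.
#' @param ratio_rule `"mean-of-ratios"` (default) or `"ratio-of-means"`.
#' @param stages integer degrees to include (default `0:12`); empty stages are
#'   omitted with a warning.
#' @return a `trilo_stage_summary` data frame, one row per stage, columns
#'   `degree`, `n`, `FAL`, `PGL`, `ORL`, `LTS1..13`, `PYL`, `CEL`, `TRL`,
#'   `BOL`, `RLS1..13`, `RPS1..13`, `RPYL`, `TRG`.
#' @export
stage_summaries <- function(x, ratio_rule = c("mean-of-ratios", "ratio-of-means"),
                            stages = 0:12) {
  ratio_rule <- match.arg(ratio_rule)
  d <- as_derived(x)
  d <- d[d$period == "meraspid" & !is.na(d$degree) & d$degree %in% stages, ,
         drop = FALSE]
  if (nrow(d) == 0L) stop_fmt("no meraspid specimens in the requested stages")
  empty <- setdiff(stages, unique(d$degree))
  if (length(empty))
    warn_fmt("stage(s) with no specimens omitted: %s",
             paste0("D", sort(empty), collapse = ", "))
  degs <- sort(unique(d$degree))
  num_cols <- c("FAL", "PGL", "ORL", lts_columns(), "PYL", "CEL", "TRL", "BOL")
  rel_cols <- c(paste0("RLS", 1:MAX_SEGMENTS), paste0("RPS", 1:MAX_SEGMENTS), "RPYL")
  out <- do.call(rbind, lapply(degs, function(s) {
    sub <- d[d$degree == s, , drop = FALSE]
    row <- data.frame(degree = s, n = nrow(sub))
    for (cl in num_cols) row[[cl]] <- mean(sub[[cl]], na.rm = TRUE)
    for (cl in rel_cols) {
      row[[cl]] <- if (ratio_rule == "mean-of-ratios") {
        mean(sub[[cl]], na.rm = TRUE)
      } else {
        # numerators re-derived from stage-mean lengths
        NA_real_  # filled below
      }
    }
    row
  }))
  if (ratio_rule == "ratio-of-means") {
    ltsm <- as.matrix(out[, lts_columns()])
    out[, paste0("RLS", 1:MAX_SEGMENTS)] <- ltsm / out$TRL
    cum <- t(apply(ltsm, 1L, function(v) cumsum(ifelse(is.na(v), 0, v))))
    cum[is.na(ltsm)] <- NA_real_
    out[, paste0("RPS", 1:MAX_SEGMENTS)] <- cum / out$TRL
    out$RPYL <- out$PYL / out$TRL
  }
  out[is.na(out)] <- NA_real_
  # nan from empty means -> NA
  for (cl in names(out)) out[[cl]][is.nan(out[[cl]])] <- NA_real_
  out$TRG <- NA_real_
  for (k in seq_len(nrow(out) - 1L)) {
    if (out$degree[k + 1L] == out$degree[k] + 1L &&
        is.finite(out$TRL[k]) && is.finite(out$TRL[k + 1L]))
      out$TRG[k] <- out$TRL[k + 1L] / out$TRL[k]
  }
  rownames(out) <- NULL
  class(out) <- c("trilo_stage_summary", "data.frame")
  out
}

#' Average (geometric per-stage) growth rate of a body part
#'
#' `AGR = (mean length at `to` / mean length at `from`)^(1/(to - from))`,
#' the per-stage geometric growth factor of a part between two stages.
#'
#' @param summaries a `trilo_stage_summary` table.
#' @param part column name of the part (e.g. `"TRL"`, `"LTS3"`).
#' @param from,to stage degrees, `to > from`, both present in `summaries`.
#' @return dimensionless growth factor.
#' @export
average_growth_rate <- function(summaries, part, from, to) {
  if (to <= from) stop_fmt("'to' stage (%s) must exceed 'from' stage (%s)", to, from)
  if (!part %in% names(summaries)) stop_fmt("unknown part: %s", part)
  i <- match(from, summaries$degree)
  j <- match(to, summaries$degree)
  if (is.na(i) || is.na(j)) stop_fmt("stage D%s or D%s not present in summaries", from, to)
  a <- summaries[[part]][i]
  b <- summaries[[part]][j]
  if (!is.finite(a) || !is.finite(b) || a <= 0)
    stop_fmt("mean %s must be positive and present at both stages", part)
  (b / a)^(1 / (to - from))
}

#' Export a stage summary table to CSV
#'
#' @param summaries a `trilo_stage_summary` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stage_summaries <- function(summaries, path) {
  write.csv(as.data.frame(summaries), path, row.names = FALSE, na = "")
  invisible(path)
}
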