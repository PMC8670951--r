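# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded at `seed`,
#' restoring the previous RNG state afterwards so callers never perturb the
#' session stream. A `NULL` seed evaluates `code` unchanged.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# derive a child seed from a base seed, staying inside 32-bit integer range
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 7919 + 104729 * k) %% .Machine$integer.max)
}

#' Render a set of developmental stage labels compactly
#'
#' Collapses runs of consecutive meraspid degrees into range notation, e.g.
#' `c("D8","D9","D10")` becomes `"D8-10"`; the holaspid label `"H"` is kept
#' as-is and placed last.
#'
#' @param labels character vector of stage labels (`"D<k>"` and/or `"H"`).
#' @return a single character string (`""` for an empty set).
#' @export
format_stage_set <- function(labels) {
  if (length(labels) == 0L) return("")
  has_h <- "H" %in% labels
  ds <- sort(as.integer(sub("^D", "", labels[labels != "H"])))
  out <- character(0)
  if (length(ds)) {
    runs <- split(ds, cumsum(c(1L, diff(ds) != 1L)))
    out <- vapply(runs, function(r) {
      if (length(r) == 1L) paste0("D", r) else paste0("D", r[1], "-", r[length(r)])
    }, character(1))
  }
  if (has_h) out <- c(out, "H")
  paste(out, collapse = ", ")
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)
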