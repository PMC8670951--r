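# End-to-end analysis pipeline and command-line entry point:
# simulate/load -> derive -> stage summaries -> threshold allometry ->
# coefficient profiles -> gradient model comparison -> report bundle.

#' Assemble a pipeline configuration
#'
#' @param input path to a specimen CSV, or `NULL` to simulate.
#' @param sim a `sim_config` used when `input` is `NULL` (default:
#'   [default_sim_config()] with `seed`).
#' @param seed master seed; child seeds are derived per analysis stage and
#'   recorded in the manifest.
#' @param boot_reps bootstrap replicates for threshold and MA CIs.
#' @param threshold_models character vector of `"response~predictor"` pairs to
#'   fit as two-phase models; `NULL` disables threshold fitting.
#' @param gradient_models gradient models to fit and compare; `NULL` disables
#'   gradient fitting.
#' @param response `"RLS"` or `"RPS"` for the gradient comparison.
#' @param out_dir output directory for the report bundle.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, sim = NULL, seed = 1L,
                            boot_reps = 1000L,
                            threshold_models = c("TRL~BOL", "CEL~BOL",
                                                 "FAL~CEL", "PGL~CEL"),
                            gradient_models = GRADIENT_MODELS,
                            response = "RLS", out_dir = "trilogrowth-report") {
  cfg <- list(input = input,
              sim = sim %||% default_sim_config(seed = seed),
              seed = as.integer(seed), boot_reps = as.integer(boot_reps),
              threshold_models = threshold_models,
              gradient_models = gradient_models,
              response = response, out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

fit_named_threshold <- function(spec, d, boot_reps, seed) {
  parts <- strsplit(spec, "~", fixed = TRUE)[[1]]
  yv <- trimws(parts[1]); xv <- trimws(parts[2])
  ok <- is.finite(d[[xv]]) & is.finite(d[[yv]]) & d[[xv]] > 0 & d[[yv]] > 0
  fit <- hinge_fit(log(d[[xv]][ok]), log(d[[yv]][ok]))
  ci <- hinge_bootstrap_ci(log(d[[xv]][ok]), log(d[[yv]][ok]),
                           reps = boot_reps, seed = seed)
  list(model = spec, x = xv, y = yv, fit = fit, ci = ci)
}

#' Run the full axial-growth analysis pipeline
#'
#' Produces, under `cfg$out_dir`: `specimens.csv` (when simulated),
#' `stage_summary.csv`, `threshold_table.csv` (change points with bootstrap
#' CIs, body-length standardization and stage assignment),
#' `coefficient_profile.csv` (per-part major-axis allometric coefficients by
#' period), `model_comparison.csv` (gradient models, AICc, weights), and
#' `manifest.json` recording package version, seeds and produced files.
#' Output numerics are serialized with 6 significant digits; reruns with the
#' same seeds are byte-identical.
#'
#' @param cfg a `pipeline_config`.
#' @param quiet suppress progress banners on stderr.
#' @return (invisibly) a list with all in-memory results.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "trilogrowth",
                   version = as.character(packageVersion("trilogrowth")),
                   seed = cfg$seed, outputs = list(), partial = FALSE)
  res <- list()

  say("== stage 1: data ==")
  if (!is.null(cfg$input)) {
    specs <- load_specimens(cfg$input)
    manifest$input <- cfg$input
  } else {
    specs <- simulate_ontogeny(cfg$sim)
    write_specimens(specs, file.path(cfg$out_dir, "specimens.csv"))
    manifest$outputs$specimens <- "specimens.csv"
    manifest$sim_seed <- cfg$sim$seed
    manifest$sim_model <- cfg$sim$model
  }
  res$specimens <- specs
  d <- derive_parts(specs)
  res$derived <- d
  say("  %d specimens (%d meraspid, %d holaspid)", nrow(d),
      sum(d$period == "meraspid"), sum(d$period == "holaspid"))

  say("== stage 2: stage summaries ==")
  summ <- stage_summaries(d)
  res$summaries <- summ
  write_stage_summaries(round_df(summ), file.path(cfg$out_dir, "stage_summary.csv"))
  manifest$outputs$stage_summary <- "stage_summary.csv"

  if (!is.null(cfg$threshold_models)) {
    say("== stage 3: threshold allometry ==")
    refs <- list(
      CEL = tryCatch(fit_named_threshold("BOL~CEL", d, cfg$boot_reps,
                                         child_seed(cfg$seed, 90))$fit,
                     error = function(e) NULL),
      TRL = tryCatch(fit_named_threshold("BOL~TRL", d, cfg$boot_reps,
                                         child_seed(cfg$seed, 91))$fit,
                     error = function(e) NULL))
    rows <- list()
    fits <- list()
    for (k in seq_along(cfg$threshold_models)) {
      spec <- cfg$threshold_models[k]
      th <- fit_named_threshold(spec, d, cfg$boot_reps, child_seed(cfg$seed, k))
      fits[[spec]] <- th
      say("  %s: change point %.4g mm [%.4g, %.4g]", spec, th$fit$cp,
          th$ci$ci[1], th$ci$ci[2])
      bol_cp <- if (th$x == "BOL") th$fit$cp
      else if (!is.null(refs[[th$x]]))
        tryCatch(standardize_changepoint_to_bol(th$fit$cp, refs[[th$x]]),
                 error = function(e) NA_real_)
      else NA_real_
      stages <- stage_for_size(th$fit$cp, th$x, d)
      rows[[k]] <- data.frame(
        model = spec, changepoint_mm = th$fit$cp,
        bol_changepoint_mm = bol_cp,
        stage = attr(stages, "formatted"),
        pre_AC = th$fit$slope_pre, post_AC = th$fit$slope_post,
        ci_lo_mm = th$ci$ci[1], ci_hi_mm = th$ci$ci[2], n = th$fit$n)
    }
    res$threshold_fits <- fits
    res$threshold_table <- do.call(rbind, rows)
    write.csv(round_df(res$threshold_table),
              file.path(cfg$out_dir, "threshold_table.csv"), row.names = FALSE)
    manifest$outputs$threshold_table <- "threshold_table.csv"
  }

  say("== stage 4: coefficient profiles ==")
  prof <- rbind(
    suppressWarnings(segment_coefficient_profile(d, "meraspid",
                                                 boot = cfg$boot_reps,
                                                 seed = child_seed(cfg$seed, 40))),
    suppressWarnings(segment_coefficient_profile(d, "holaspid",
                                                 boot = cfg$boot_reps,
                                                 seed = child_seed(cfg$seed, 41))))
  res$profile <- prof
  write.csv(round_df(prof), file.path(cfg$out_dir, "coefficient_profile.csv"),
            row.names = FALSE)
  manifest$outputs$coefficient_profile <- "coefficient_profile.csv"

  if (!is.null(cfg$gradient_models)) {
    say("== stage 5: growth gradient models ==")
    data <- gradient_observations(summ, response = cfg$response)
    models <- cfg$gradient_models
    if (cfg$response == "RPS") models <- setdiff(models, c("SG-R", "SG-A"))
    gfits <- lapply(models, function(m) {
      f <- fit_gradient_model(m, data)
      say("  %s: RSS %.6g (%d starts converged)", m, f$rss, f$n_converged)
      f
    })
    res$gradient_fits <- gfits
    comp <- compare_models(gfits)
    res$comparison <- comp
    write.csv(round_df(as.data.frame(comp)),
              file.path(cfg$out_dir, "model_comparison.csv"), row.names = FALSE)
    manifest$outputs$model_comparison <- "model_comparison.csv"
    say("  best model: %s (wAICc %.3f)", comp$model[1], comp$wAICc[1])
  }

  say("== stage 6: pygidial stasis ==")
  res$pyl_stasis <- tryCatch(pyl_stasis_test(specs, stages = 0:10),
                             error = function(e) NULL)

  manifest$pyl_stasis <- if (!is.null(res$pyl_stasis))
    lapply(res$pyl_stasis, signif, digits = 6) else NULL
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  res$manifest <- manifest
  invisible(res)
}

# round numeric columns to 6 significant digits for stable serialization
round_df <- function(df) {
  df <- as.data.frame(df)
  for (cl in names(df)) if (is.numeric(df[[cl]])) df[[cl]] <- signif(df[[cl]], 6)
  df
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic specimen CSV), `report` (run the
#' full pipeline). Flags: `--input CSV`, `--seed INT`, `--boot-reps INT`,
#' `--response {rls,rps}`, `--out DIR`, `--no-gradients`, `--no-thresholds`.
#'
#' @param args character vector of command-line arguments (default: the
#'   process arguments).
#' @return exit status, invisibly (0 on success).
#' @export
pipeline_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  parser <- optparse::OptionParser(
    usage = "%prog [simulate|report] [options]",
    option_list = list(
      optparse::make_option("--input", type = "character", default = NULL,
                            help = "specimen CSV (default: simulate)"),
      optparse::make_option("--seed", type = "integer", default = 1L),
      optparse::make_option("--boot-reps", type = "integer", default = 1000L,
                            dest = "boot_reps"),
      optparse::make_option("--response", type = "character", default = "rls"),
      optparse::make_option("--out", type = "character",
                            default = "trilogrowth-report"),
      optparse::make_option("--no-gradients", action = "store_true",
                            default = FALSE, dest = "no_gradients"),
      optparse::make_option("--no-thresholds", action = "store_true",
                            default = FALSE, dest = "no_thresholds")))
  parsed <- optparse::parse_args2(parser, args = args)
  cmd <- if (length(parsed$args)) parsed$args[1] else "report"
  o <- parsed$options
  status <- tryCatch({
    if (cmd == "simulate") {
      specs <- simulate_ontogeny(default_sim_config(seed = o$seed))
      dir.create(o$out, showWarnings = FALSE, recursive = TRUE)
      write_specimens(specs, file.path(o$out, "specimens.csv"))
      message(sprintf("wrote %d specimens to %s/specimens.csv", nrow(specs), o$out))
    } else if (cmd == "report") {
      cfg <- pipeline_config(
        input = o$input, seed = o$seed, boot_reps = o$boot_reps,
        threshold_models = if (o$no_thresholds) NULL
        else c("TRL~BOL", "CEL~BOL", "FAL~CEL", "PGL~CEL"),
        gradient_models = if (o$no_gradients) NULL else GRADIENT_MODELS,
        response = toupper(o$response), out_dir = o$out)
      run_pipeline(cfg)
    } else {
      stop_fmt("unknown subcommand: %s", cmd)
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
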