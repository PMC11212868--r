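## End-to-end orchestration: simulate -> analyze -> fit -> report.
## A single global seed is expanded to per-stage seeds by the documented
## rule seed_stage = seed + 1009 * stage_index, so every stage is
## independently reproducible.

.stageSeed <- function(globalSeed, idx) as.integer(globalSeed + 1009L * idx)

.knownStages <- c("simulate_traces", "analyze_coupling", "simulate_cohort",
                  "fit_biphasic", "score_images", "mech_scenario")

#' Run a multi-stage analysis pipeline
#'
#' Executes the stages of a configuration (YAML file or equivalent list) in
#' order and writes a manifest of all outputs with MD5 hashes and the seeds
#' used. Reruns with the same configuration are bit-identical for the
#' deterministic stages. A failing stage aborts with the partial manifest
#' written next to the outputs.
#'
#' Recognized stages and their parameters:
#' \describe{
#'   \item{simulate_traces}{\code{preset}, \code{n_cells}, optional
#'     \code{noiseSD}, \code{nCycles}; writes a trace CSV.}
#'   \item{analyze_coupling}{per-cell coupling metrics and group summary
#'     CSVs from the last simulated traces (or a \code{traces} CSV path).}
#'   \item{simulate_cohort}{\code{\link{cohortSpec}} fields; writes the
#'     cohort CSV.}
#'   \item{fit_biphasic}{breakpoint fit of the last cohort (or
#'     \code{cohort} path); writes fit JSON and loess curve CSV.}
#'   \item{score_images}{\code{preset}, \code{n}, \code{mode}; generates a
#'     seeded image cohort, scores it, writes the per-nucleus CSV and a
#'     summary JSON.}
#'   \item{mech_scenario}{\code{name} plus optional \code{config} (YAML for
#'     \code{\link{readMechConfig}}); writes summary JSON and field CSV.}
#' }
#'
#' @param config path to a YAML file or a list with fields \code{seed},
#'   \code{outDir} and \code{stages} (list of blocks, each with a
#'   \code{stage} name).
#' @return The manifest, invisibly (also written as manifest.json).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(!is.null(config$stages), !is.null(config$outDir))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  stages <- config$stages
  bad <- setdiff(vapply(stages, `[[`, "", "stage"), .knownStages)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "),
         "; known: ", paste(.knownStages, collapse = ", "))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = seed, outputs = list())
  ctx <- new.env()
  addOutput <- function(stage, file, stageSeed) {
    manifest$outputs[[length(manifest$outputs) + 1]] <<- list(
      stage = stage, file = file,
      md5 = unname(tools::md5sum(file)), seed = stageSeed)
  }
  writeManifest <- function() {
    path <- file.path(config$outDir, "manifest.json")
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    path
  }
  for (i in seq_along(stages)) {
    st <- stages[[i]]
    sSeed <- .stageSeed(seed, i)
    message(sprintf("[cardionuc] stage %d/%d %s seed=%d params=%s",
                    i, length(stages), st$stage, sSeed,
                    paste(names(st)[names(st) != "stage"], collapse = ",")))
    ok <- tryCatch({
      switch(st$stage,
        simulate_traces = {
          args <- st[setdiff(names(st), c("stage", "preset", "n_cells"))]
          args$seed <- sSeed
          params <- do.call(genotypePreset,
                            c(list(st$preset, type = "trace"), args))
          traces <- generateTraces(params,
                                   if (is.null(st$n_cells)) 1 else
                                     st$n_cells)
          f <- file.path(config$outDir,
                         sprintf("traces_%s.csv", st$preset))
          writeTraces(traces, f)
          ctx$traces <- traces
          addOutput(st$stage, f, sSeed)
        },
        analyze_coupling = {
          traces <- if (!is.null(st$traces)) readTraces(st$traces) else
            ctx$traces
          if (is.null(traces)) stop("no traces available for coupling")
          res <- lapply(traces, analyzeCoupling)
          f1 <- file.path(config$outDir, "coupling_metrics.csv")
          utils::write.csv(couplingTable(res), f1, row.names = FALSE)
          f2 <- file.path(config$outDir, "coupling_groups.csv")
          utils::write.csv(summarizeGroup(res), f2, row.names = FALSE)
          ctx$coupling <- res
          addOutput(st$stage, f1, sSeed); addOutput(st$stage, f2, sSeed)
        },
        simulate_cohort = {
          args <- st[setdiff(names(st), "stage")]
          args$seed <- sSeed
          co <- generateCohort(do.call(cohortSpec, args))
          f <- file.path(config$outDir, "cohort.csv")
          utils::write.csv(co, f, row.names = FALSE)
          ctx$cohort <- co
          addOutput(st$stage, f, sSeed)
        },
        fit_biphasic = {
          co <- if (!is.null(st$cohort)) utils::read.csv(st$cohort) else
            ctx$cohort
          if (is.null(co)) stop("no cohort available for the biphasic fit")
          fit <- piecewiseLinearFit(co)
          f1 <- file.path(config$outDir, "biphasic_fit.json")
          jsonlite::write_json(list(
            breakpoint = fit@breakpoint, slope_below = fit@slopeBelow,
            slope_above = fit@slopeAbove, intercept = fit@intercept,
            slope_se = as.list(fit@slopeSE),
            slope_p = as.list(fit@slopePValues),
            flat_above = fit@flatAbove, n = fit@nPoints),
            f1, auto_unbox = TRUE, digits = NA, pretty = TRUE)
          f2 <- file.path(config$outDir, "loess_curve.csv")
          utils::write.csv(fit@loessCurve, f2, row.names = FALSE)
          ctx$fit <- fit
          addOutput(st$stage, f1, sSeed); addOutput(st$stage, f2, sSeed)
        },
        score_images = {
          n <- if (is.null(st$n)) 20 else st$n
          mode <- if (is.null(st$mode)) "protrusion" else st$mode
          imgs <- lapply(seq_len(n), function(k)
            generateNucleusImage(genotypePreset(st$preset, type = "image",
                                                seed = sSeed + k)))
          sc <- scoreCohort(imgs, mode = mode, seed = sSeed)
          f1 <- file.path(config$outDir,
                          sprintf("morpho_%s.csv", st$preset))
          utils::write.csv(sc$table, f1, row.names = FALSE)
          f2 <- file.path(config$outDir,
                          sprintf("morpho_%s_summary.json", st$preset))
          jsonlite::write_json(list(preset = st$preset, mode = mode,
                                    estimate = sc$estimate, ci = sc$ci,
                                    n = sc$n),
                               f2, auto_unbox = TRUE, digits = NA,
                               pretty = TRUE)
          ctx$morpho <- sc
          addOutput(st$stage, f1, sSeed); addOutput(st$stage, f2, sSeed)
        },
        mech_scenario = {
          extra <- if (!is.null(st$config)) readMechConfig(st$config) else
            list()
          sol <- do.call(runScenario, c(list(st$name), extra))
          f1 <- file.path(config$outDir,
                          sprintf("mech_%s_summary.json", st$name))
          jsonlite::write_json(list(
            scenario = st$name, aspect_ratio = sol@nuclearAspectRatio,
            volume_change_pct = sol@nuclearVolumeChange,
            probes = as.list(sol@probes),
            lamina_stress_location = sol@laminaStressLocation,
            tip_instability = sol@tipInstability),
            f1, auto_unbox = TRUE, digits = NA, pretty = TRUE)
          f2 <- file.path(config$outDir,
                          sprintf("mech_%s_fields.csv", st$name))
          writeSolutionFields(sol, f2)
          ctx$mech <- sol
          addOutput(st$stage, f1, sSeed); addOutput(st$stage, f2, sSeed)
        })
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) {
      writeManifest()
      stop("stage '", st$stage, "' failed: ", conditionMessage(ok),
           " (partial manifest written)")
    }
  }
  path <- writeManifest()
  message("[cardionuc] wrote ", path)
  invisible(manifest)
}

#' Summary report from a pipeline manifest
#'
#' Collects the stage outputs listed in a manifest into per-assay Markdown
#' tables (group means with standard errors, fit parameters, cohort
#' prevalences, mechanics summaries). Stages absent from the manifest are
#' noted, not fatal.
#'
#' @param manifest path to manifest.json or the manifest list.
#' @param file optional output path for the Markdown report.
#' @return character vector of report lines, invisibly if written to file.
#' @export
pipelineReport <- function(manifest, file = NULL) {
  if (is.character(manifest)) manifest <- jsonlite::read_json(manifest)
  outs <- manifest$outputs
  byStage <- split(outs, vapply(outs, `[[`, "", "stage"))
  lines <- c("# cardionuc pipeline report", "")
  mdTable <- function(df) {
    hdr <- paste("|", paste(names(df), collapse = " | "), "|")
    sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
    rows <- apply(df, 1, function(r)
      paste("|", paste(format(r, trim = TRUE), collapse = " | "), "|"))
    c(hdr, sep, rows, "")
  }
  if (!is.null(byStage$analyze_coupling)) {
    f <- byStage$analyze_coupling[[2]]$file
    lines <- c(lines, "## Strain coupling (group mean +/- SE)", "",
               mdTable(utils::read.csv(f)))
  } else lines <- c(lines, "## Strain coupling", "", "_not run_", "")
  if (!is.null(byStage$fit_biphasic)) {
    fit <- jsonlite::read_json(byStage$fit_biphasic[[1]]$file)
    lines <- c(lines, "## Aspect ratio vs MT enrichment (biphasic fit)", "",
               sprintf("- breakpoint: %.3f", fit$breakpoint),
               sprintf("- slope below: %.3f (p = %.3g)", fit$slope_below,
                       fit$slope_p$below),
               sprintf("- slope above: %.3f (p = %.3g, flat: %s)",
                       fit$slope_above, fit$slope_p$above,
                       fit$flat_above), "")
  } else lines <- c(lines, "## Biphasic fit", "", "_not run_", "")
  if (!is.null(byStage$score_images)) {
    for (o in byStage$score_images) {
      if (!grepl("summary[.]json$", o$file)) next
      s <- jsonlite::read_json(o$file)
      lines <- c(lines, sprintf("## Image cohort: %s (%s)", s$preset,
                                s$mode), "",
                 sprintf("- estimate: %.4g (95%% CI %.4g-%.4g, n = %d)",
                         s$estimate, s$ci[[1]], s$ci[[2]], s$n), "")
    }
  } else lines <- c(lines, "## Image cohorts", "", "_not run_", "")
  if (!is.null(byStage$mech_scenario)) {
    for (o in byStage$mech_scenario) {
      if (!grepl("summary[.]json$", o$file)) next
      s <- jsonlite::read_json(o$file)
      lines <- c(lines, sprintf("## Mechanics: %s", s$scenario), "",
                 sprintf("- nuclear aspect ratio: %.3f", s$aspect_ratio),
                 sprintf("- volume change: %.2f%%", s$volume_change_pct),
                 sprintf("- tip instability: %s", s$tip_instability), "")
    }
  } else lines <- c(lines, "## Mechanics", "", "_not run_", "")
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}
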