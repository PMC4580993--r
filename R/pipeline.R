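# Pipeline orchestration: run the stages in dependency order from a single
# configuration, with checksummed manifests and report tables.

#' Assemble (or read) a pipeline configuration
#'
#' The configuration is a plain nested list; `read_pipeline_config()`
#' loads the same structure from a YAML file. All randomness in the
#' pipeline flows from the single top-level `seed`.
#'
#' @param seed Top-level integer seed.
#' @param outdir Output directory (created if needed).
#' @param stages Character vector of enabled stages, in any order; the
#'   pipeline runs them in dependency order. Available:
#'   `"simulate"`, `"calls"`, `"filter"`, `"counts"`, `"lmm"`, `"meta"`,
#'   `"fit"`, `"ppc"`, `"report"`.
#' @param input Optional list with a `meioses` path to start from an
#'   existing meiosis table instead of simulating.
#' @param simulate List: `scale` (multiplier on the default cohort
#'   sizes), `parent_sex`.
#' @param filter List: `prob_threshold`, `artifact_rate`, `low_conf_rate`.
#' @param models Character vector of model ids to fit (see
#'   [model_spec()]).
#' @param mcmc List of [mcmc_control()] overrides for the fits.
#' @param ppc List: `n_replicates`, `mode`.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1, outdir = "crossage-run",
                            stages = c("simulate", "calls", "filter", "counts",
                                       "lmm", "meta", "fit", "report"),
                            input = NULL,
                            simulate = list(scale = 0.05, parent_sex = "F"),
                            filter = list(prob_threshold = 0.5,
                                          artifact_rate = 0.1,
                                          low_conf_rate = 0.1),
                            models = "M2star",
                            mcmc = list(n_chains = 2, n_draws = 2000),
                            ppc = list(n_replicates = 200, mode = "map_draw")) {
  structure(list(seed = as.integer(seed), outdir = outdir, stages = stages,
                 input = input, simulate = simulate, filter = filter,
                 models = models, mcmc = mcmc, ppc = ppc),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path Path to a YAML configuration file.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

.md5 <- function(path) unname(tools::md5sum(path))

#' Run the analysis pipeline
#'
#' Executes the enabled stages in dependency order: simulate the
#' multi-cohort data (or load a meiosis table), expand to call level,
#' filter calls (posterior threshold, then the double-crossover filter),
#' aggregate to counts, fit per-cohort linear mixed models and the
#' meta-analysis, fit the requested hierarchical models, run posterior
#' predictive checks, and write the report tables. Every written
#' artifact is recorded in a manifest (`manifest.tsv`) with its MD5
#' checksum and the run seed, so identical configurations produce
#' identical manifests. A stage failure halts the pipeline with the
#' failing stage named; artifacts already written are preserved.
#'
#' @param config A [pipeline_config()] (or a path handled by
#'   [read_pipeline_config()]).
#' @return Invisibly, a list with the stage outputs (`meioses`, `calls`,
#'   `counts`, `lmm_fits`, `meta`, `fits`, `ppc`, `report`) and the
#'   manifest data frame.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) {
    stop("`config` must be a pipeline_config or a YAML path", call. = FALSE)
  }
  # validate referenced inputs before any stage runs
  if (!is.null(config$input$meioses) && !file.exists(config$input$meioses)) {
    stop("input file does not exist: ", config$input$meioses, call. = FALSE)
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  note <- function(stage, path) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, artifact = basename(path), md5 = .md5(path),
      seed = config$seed, stringsAsFactors = FALSE)
  }
  out <- list()
  run_stage <- function(name, fn) {
    if (!(name %in% config$stages)) return(invisible(NULL))
    tryCatch(fn(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  specs <- default_cohort_specs(scale = config$simulate$scale %||% 0.05)
  truth <- NULL
  run_stage("simulate", function() {
    if (!is.null(config$input$meioses)) {
      out$meioses <<- read_meiosis_table(config$input$meioses)
    } else {
      sim <- simulate_cohorts(specs, default_generative_params(specs),
                              seed = config$seed,
                              parent_sex = config$simulate$parent_sex %||% "F")
      out$meioses <<- sim$meioses
      truth <<- sim$truth
      p <- file.path(config$outdir, "meioses.tsv")
      write_meiosis_table(sim$meioses, p); note("simulate", p)
    }
  })
  run_stage("calls", function() {
    if (is.null(truth)) stop("call-level simulation requires the simulate stage")
    out$calls <<- simulate_call_table(out$meioses, truth,
                                      artifact_rate = config$filter$artifact_rate %||% 0.1,
                                      low_conf_rate = config$filter$low_conf_rate %||% 0.1,
                                      seed = config$seed + 1L)
    p <- file.path(config$outdir, "calls.tsv")
    write_call_table(out$calls, p); note("calls", p)
  })
  run_stage("filter", function() {
    if (is.null(out$calls)) stop("no call table to filter")
    thr <- threshold_calls(out$calls, config$filter$prob_threshold %||% 0.5)
    x <- if (!is.null(truth)) truth$snps_per_mb else
      stats::setNames(vapply(specs, function(s) s$snps_per_mb, numeric(1)),
                      vapply(specs, function(s) s$cohort_id, character(1)))
    dbl <- filter_double_crossovers(thr, x)
    out$calls <<- dbl$calls
    audit <- rbind(attr(thr, "removed"), dbl$removed_pairs)
    p <- file.path(config$outdir, "filter_audit.tsv")
    write_filter_audit(audit, p); note("filter", p)
    message(sprintf("filter: %d calls removed (%d low-probability, %d tight pairs)",
                    nrow(audit), nrow(attr(thr, "removed")), nrow(dbl$removed_pairs)))
  })
  run_stage("counts", function() {
    if (is.null(out$calls)) stop("no filtered calls to aggregate")
    out$counts <<- calls_to_counts(out$calls, out$meioses)
    p <- file.path(config$outdir, "counts.tsv")
    write_meiosis_table(out$counts, p); note("counts", p)
  })
  counts_or_meioses <- function() out$counts %||% out$meioses
  run_stage("lmm", function() {
    m <- apply_exclusion_rules(
      counts_or_meioses()[counts_or_meioses()$configuration %in% c(2L, 6L), ],
      min_meioses = 20)
    fits <- lapply(split(m, m$cohort), function(mc) {
      tryCatch(fit_lmm(mc), error = function(e) NULL)
    })
    out$lmm_fits <<- do.call(rbind, fits[!vapply(fits, is.null, logical(1))])
    p <- file.path(config$outdir, "lmm_fits.tsv")
    utils::write.table(out$lmm_fits, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note("lmm", p)
  })
  run_stage("meta", function() {
    if (is.null(out$lmm_fits)) stop("no per-cohort fits to meta-analyse")
    out$meta <<- meta_fixed_effects(out$lmm_fits)
    p <- file.path(config$outdir, "meta.json")
    jsonlite::write_json(unclass(out$meta), p, auto_unbox = TRUE, digits = NA)
    note("meta", p)
  })
  run_stage("fit", function() {
    mc <- do.call(mcmc_control, utils::modifyList(
      list(seed = config$seed), config$mcmc %||% list()))
    out$fits <<- lapply(config$models, function(id) {
      sp <- model_spec(id, parent_sex = config$simulate$parent_sex %||% "F")
      fit_model(counts_or_meioses(), sp, mcmc = mc)
    })
    names(out$fits) <<- config$models
    for (id in config$models) {
      p <- file.path(config$outdir, sprintf("summary_%s.tsv", id))
      bn <- grep("^beta_age", .parameter_names(out$fits[[id]]), value = TRUE)[1L]
      utils::write.table(summarize_draws(out$fits[[id]], bn), p, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      note("fit", p)
    }
  })
  run_stage("ppc", function() {
    if (is.null(out$fits)) stop("no hierarchical fits to check")
    out$ppc <<- lapply(out$fits, function(f) {
      posterior_predictive_check(f, n_replicates = config$ppc$n_replicates %||% 200,
                                 mode = config$ppc$mode %||% "map_draw",
                                 seed = config$seed + 2L)
    })
    for (id in names(out$ppc)) {
      p <- file.path(config$outdir, sprintf("ppc_%s.tsv", id))
      utils::write.table(out$ppc[[id]]$replicate_stats, p, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      note("ppc", p)
    }
  })
  run_stage("report", function() {
    rep <- list()
    if (!is.null(out$fits)) {
      t2 <- make_table2(out$fits)
      p <- file.path(config$outdir, "table2.tsv")
      utils::write.table(t2, p, sep = "\t", quote = FALSE, row.names = FALSE)
      note("report", p)
      rep$table2 <- t2
    }
    cm <- counts_or_meioses()
    if (!is.null(cm)) {
      binned <- binned_age_summary(cm)
      p <- file.path(config$outdir, "binned_age.tsv")
      utils::write.table(binned, p, sep = "\t", quote = FALSE, row.names = FALSE)
      note("report", p)
      rep$binned_age <- binned
    }
    if (!is.null(out$meta)) rep$meta <- out$meta
    out$report <<- rep
  })

  man <- if (length(manifest)) do.call(rbind, manifest) else
    data.frame(stage = character(0), artifact = character(0),
               md5 = character(0), seed = integer(0))
  utils::write.table(man, file.path(config$outdir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  out$manifest <- man
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Posterior-summary table across models
#'
#' Builds the summary table of the age-effect posteriors: one row per
#' fitted model, with the 2.5/25/50/75/97.5% quantiles and the posterior
#' probability that the age effect is positive. Multiplicative
#' (negative-binomial) models report the quantiles of `exp(beta_age)`.
#'
#' @param fits Named list of `"posterior_draws"` objects (names are used
#'   as model labels, in input order).
#' @return Data frame with columns `parent`, `model`, `q2.5`, `q25`,
#'   `q50`, `q75`, `q97.5`, `pr_gt0`.
#' @export
make_table2 <- function(fits) {
  if (length(fits) == 0L) stop("no model summaries supplied", call. = FALSE)
  if (is.null(names(fits))) names(fits) <- vapply(fits, function(f) f$spec$model_id,
                                                  character(1))
  rows <- lapply(names(fits), function(id) {
    f <- fits[[id]]
    bn <- grep("^beta_age", .parameter_names(f), value = TRUE)[1L]
    s <- summarize_draws(f, bn)
    data.frame(parent = if (f$spec$parent_sex == "F") "Maternal" else "Paternal",
               model = id,
               s[, c("q2.5", "q25", "q50", "q75", "q97.5", "pr_gt0")],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
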