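#' Configuration for an end-to-end analysis run
#'
#' Collects the per-stage simulation configs, the analysis thresholds and the
#' global seed of a full run. Any stage can instead read its inputs from disk
#' by naming files in `inputs` (e.g. `inputs = list(transitions = "t.csv",
#' b2m = "b.csv")`); referenced paths are checked for existence before any
#' computation starts.
#'
#' @param stages which stages to run, subset of
#'   `c("mrm", "fp", "pulsechase", "proteome")`.
#' @param seed global integer seed. Per-stage sub-seeds are derived from it
#'   deterministically and recorded in the manifest.
#' @param mrm,fp_assoc,fp_dissoc,lfq stage simulation configs (NULL uses the
#'   stage defaults, re-seeded from `seed`).
#' @param gel_args list of arguments for [gen_pulsechase_gels()].
#' @param classifier a [classifier_config()].
#' @param fdr_target,s0,impute_width,impute_downshift proteome-stage
#'   thresholds.
#' @param fix_baseline,mp_free FP fitting options.
#' @param inputs optional named list of input file paths overriding
#'   simulation: `transitions`, `b2m`, `fp_assoc`, `fp_dissoc`, `gels`,
#'   `lfq`, `lfq_groups`.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(stages = c("mrm", "fp", "pulsechase", "proteome"),
                            seed = 1L,
                            mrm = NULL, fp_assoc = NULL, fp_dissoc = NULL,
                            lfq = NULL, gel_args = list(),
                            classifier = classifier_config(),
                            fdr_target = 0.05, s0 = 1,
                            impute_width = 0.3, impute_downshift = 1.8,
                            fix_baseline = TRUE, mp_free = 50,
                            inputs = list()) {
  check_that(all(stages %in% c("mrm", "fp", "pulsechase", "proteome")),
             "stages", "must be a subset of mrm/fp/pulsechase/proteome")
  check_that(is.numeric(seed) && length(seed) == 1, "seed", "must be a scalar integer")
  for (nm in names(inputs)) {
    if (!file.exists(inputs[[nm]])) {
      abort(sprintf("input file for '%s' does not exist: %s", nm, inputs[[nm]]))
    }
  }
  structure(list(stages = stages, seed = as.integer(seed), mrm = mrm,
                 fp_assoc = fp_assoc, fp_dissoc = fp_dissoc, lfq = lfq,
                 gel_args = gel_args, classifier = classifier,
                 fdr_target = fdr_target, s0 = s0,
                 impute_width = impute_width, impute_downshift = impute_downshift,
                 fix_baseline = fix_baseline, mp_free = mp_free, inputs = inputs),
            class = "pipeline_config")
}

stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 97 + offset) %% 2147483647)
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order — simulate (or read) the inputs of
#' each data family, then run its analysis — and writes per-stage CSV/TSV
#' outputs plus a JSON manifest (seed, derived sub-seeds, parameter values,
#' package version) under `out_dir`. Reruns with an identical config produce
#' byte-identical numeric outputs. A stage failure halts the run with an
#' error naming the stage.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory; `sim/` and `results/` are created inside.
#'   NULL skips all file output and just returns the result bundle.
#' @return (invisibly) a named list with one entry per executed stage:
#'   `mrm` (`sim`, `profiles`, `calls`, `summary`), `fp` (`assoc`, `dissoc`,
#'   fits and `enhancement`), `pulsechase` (`gels`, `maturation`,
#'   `thermostability` with replicate summaries) and `proteome` (`results`
#'   with the significance flags), plus `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "sim"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, "results"), recursive = TRUE, showWarnings = FALSE)
  }
  res <- list()
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), parent = e)
    })
  }

  if ("mrm" %in% config$stages) {
    res$mrm <- run_stage("mrm", function() {
      if (!is.null(config$inputs$transitions)) {
        sim <- list(transitions = read_transitions(config$inputs$transitions),
                    b2m = read_b2m(config$inputs$b2m), truth = NULL)
      } else {
        cfg <- config$mrm %||% mrm_sim_config(seed = stage_seed(config$seed, 1))
        sim <- gen_mrm_dataset(cfg)
      }
      profiles <- quantify(sim$transitions, sim$b2m)
      calls <- classify_peptides(profiles, config$classifier)
      list(sim = sim, profiles = profiles, calls = calls,
           summary = summarise_categories(calls))
    })
  }

  if ("fp" %in% config$stages) {
    res$fp <- run_stage("fp", function() {
      if (!is.null(config$inputs$fp_assoc)) {
        assoc <- list(traces = read_fp_traces(config$inputs$fp_assoc), truth = NULL)
        dissoc <- list(traces = read_fp_traces(config$inputs$fp_dissoc), truth = NULL)
      } else {
        assoc <- gen_fp_trace(config$fp_assoc %||%
                                fp_sim_config(seed = stage_seed(config$seed, 2)),
                              mode = "association")
        dissoc <- gen_fp_trace(config$fp_dissoc %||%
                                 fp_sim_config(times_h = seq(0, 24, by = 0.5),
                                               seed = stage_seed(config$seed, 3)),
                               mode = "dissociation")
      }
      assoc_fits <- fit_fp_traces(assoc$traces, "association",
                                  fix_baseline = config$fix_baseline,
                                  mp_free = config$mp_free)
      dissoc_fits <- fit_fp_traces(dissoc$traces, "dissociation",
                                   fix_baseline = config$fix_baseline,
                                   mp_free = config$mp_free)
      intr <- dplyr::filter(assoc$traces, .data$condition == "intrinsic")
      enh <- NULL
      if (nrow(intr) > 0) {
        others <- setdiff(unique(assoc$traces$condition), "intrinsic")
        enh <- dplyr::bind_rows(lapply(others, function(cond) {
          ef <- enhancement_factor(intr,
                                   dplyr::filter(assoc$traces, .data$condition == cond))
          tibble::tibble(condition = cond, factor_pct = ef$factor, n = ef$n)
        }))
      }
      list(assoc = assoc, dissoc = dissoc, assoc_fits = assoc_fits,
           dissoc_fits = dissoc_fits, enhancement = enh)
    })
  }

  if ("pulsechase" %in% config$stages) {
    res$pulsechase <- run_stage("pulsechase", function() {
      if (!is.null(config$inputs$gels)) {
        sim <- list(gels = read_gels(config$inputs$gels), truth = NULL)
      } else {
        args <- modifyList(list(seed = stage_seed(config$seed, 4)), config$gel_args)
        sim <- do.call(gen_pulsechase_gels, args)
      }
      mat <- maturation_timecourse(sim$gels)
      thermo <- thermostability_timecourse(sim$gels)
      list(sim = sim,
           maturation = mat,
           maturation_summary = summarise_timecourse(mat, .data$percent_ehr,
                                                     .data$chase_min),
           thermostability = thermo,
           thermostability_summary = summarise_timecourse(
             thermo, .data$percent_recovery, .data$chase_min, .data$temperature_C))
    })
  }

  if ("proteome" %in% config$stages) {
    res$proteome <- run_stage("proteome", function() {
      if (!is.null(config$inputs$lfq)) {
        mat <- read_lfq_matrix(config$inputs$lfq)
        grp <- readr::read_csv(config$inputs$lfq_groups, show_col_types = FALSE)
        sim <- list(matrix = mat, groups = grp, truth = NULL)
      } else {
        cfg <- config$lfq %||% lfq_sim_config(seed = stage_seed(config$seed, 5))
        sim <- gen_lfq_matrix(cfg)
      }
      results <- proteome_compare(sim$matrix, sim$groups,
                                  fdr_target = config$fdr_target, s0 = config$s0,
                                  width = config$impute_width,
                                  downshift = config$impute_downshift,
                                  seed = stage_seed(config$seed, 6))
      list(sim = sim, results = results, d_cut = attr(results, "d_cut"))
    })
  }

  res$manifest <- list(
    package = "peptidrift",
    version = as.character(utils::packageVersion("peptidrift")),
    seed = config$seed,
    stage_seeds = setNames(lapply(1:6, function(i) stage_seed(config$seed, i)),
                           c("mrm", "fp_assoc", "fp_dissoc", "gels", "lfq", "impute")),
    stages = config$stages,
    parameters = list(slope_threshold = config$classifier$slope_threshold,
                      constant_ratio_threshold = config$classifier$constant_ratio_threshold,
                      fdr_target = config$fdr_target, s0 = config$s0,
                      impute_width = config$impute_width,
                      impute_downshift = config$impute_downshift,
                      mp_free = config$mp_free))

  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  invisible(res)
}

write_pipeline_outputs <- function(res, out_dir) {
  simdir <- file.path(out_dir, "sim")
  outdir <- file.path(out_dir, "results")
  if (!is.null(res$mrm)) {
    if (!is.null(res$mrm$sim$truth)) write_mrm_dataset(res$mrm$sim, simdir)
    readr::write_csv(dplyr::select(res$mrm$profiles, -"norm_replicates"),
                     file.path(outdir, "profiles.csv"))
    readr::write_csv(res$mrm$calls, file.path(outdir, "calls.csv"))
    jsonlite::write_json(
      list(category_counts = res$mrm$summary$category_counts,
           cterm_tally = res$mrm$summary$cterm_tally),
      file.path(outdir, "mrm_summary.json"), dataframe = "rows", pretty = TRUE)
  }
  if (!is.null(res$fp)) {
    readr::write_csv(res$fp$assoc$traces, file.path(simdir, "fp_association.csv"))
    readr::write_csv(res$fp$dissoc$traces, file.path(simdir, "fp_dissociation.csv"))
    fits <- dplyr::bind_rows(res$fp$assoc_fits, res$fp$dissoc_fits)
    readr::write_csv(dplyr::select(fits, -"fitted"), file.path(outdir, "fp_fits.csv"))
    curves <- dplyr::bind_rows(lapply(seq_len(nrow(fits)), function(i) {
      cv <- fits$fitted[[i]]
      if (is.null(cv)) return(NULL)
      dplyr::mutate(cv, condition = fits$condition[i], mode = fits$mode[i])
    }))
    readr::write_csv(curves, file.path(outdir, "fp_fitted_curves.csv"))
    if (!is.null(res$fp$enhancement)) {
      readr::write_csv(res$fp$enhancement, file.path(outdir, "enhancement.csv"))
    }
  }
  if (!is.null(res$pulsechase)) {
    readr::write_csv(res$pulsechase$sim$gels, file.path(simdir, "gels.csv"))
    readr::write_csv(res$pulsechase$maturation_summary,
                     file.path(outdir, "maturation.csv"))
    readr::write_csv(res$pulsechase$thermostability_summary,
                     file.path(outdir, "thermostability.csv"))
  }
  if (!is.null(res$proteome)) {
    readr::write_tsv(res$proteome$sim$matrix, file.path(simdir, "lfq_matrix.tsv"))
    readr::write_csv(res$proteome$sim$groups, file.path(simdir, "lfq_groups.csv"))
    readr::write_tsv(res$proteome$results, file.path(outdir, "proteome_results.tsv"))
  }
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
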