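#' Pipeline configuration
#'
#' Parameter blocks for every stage of [run_pipeline()]. Each block is a
#' list of overrides merged over the corresponding spec constructor's
#' defaults ([mosaic_spec()], [choroid_phantom_spec()], [observer_spec()],
#' [cohort_spec()], [detect_params()], [niblack_params()]).
#'
#' @param n_eyes Number of simulated eyes imaged in the `cones` and `csf`
#'   stages (the cohort table itself always has the full group structure).
#' @param mosaic,phantom,observer,cohort,detection,niblack Stage parameter
#'   overrides.
#' @param psi List with `n_trials` and `frequencies` for the CSF stage.
#' @param stats List with `outcome` and `predictors` for the regression
#'   screen of the `stats` stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_eyes = 2, mosaic = list(), phantom = list(),
                            observer = list(), cohort = list(),
                            detection = list(), niblack = list(),
                            psi = list(n_trials = 45,
                                       frequencies = c(1.5, 3, 6, 12, 18, 24)),
                            stats = list(outcome = "aulcsf",
                                         predictors = c("al",
                                                        "cone_density_outer",
                                                        "ct_inner",
                                                        "cvi_inner",
                                                        "is_inner"))) {
  cfg <- structure(as.list(environment()), class = "pipeline_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (!is.numeric(cfg$n_eyes) || cfg$n_eyes < 0)
    stop("invalid config field 'n_eyes': must be a non-negative number")
  if (is.null(cfg$psi$n_trials) || !is.numeric(cfg$psi$n_trials) ||
      cfg$psi$n_trials < 0)
    stop("invalid config field 'psi.n_trials': must be a non-negative number")
  if (!is.null(cfg$psi$frequencies) && any(diff(cfg$psi$frequencies) <= 0))
    stop("invalid config field 'psi.frequencies': must be strictly increasing")
  invisible(cfg)
}

.pipeline_stages <- c("simulate", "cones", "choroid", "csf", "stats")

#' Run the analysis pipeline end-to-end
#'
#' Executes the selected stages in dependency order
#' (simulate, cones, choroid, csf, stats), writing tidy CSV outputs and a
#' JSON run manifest (seed, config hash, package version, output files) to
#' `out_dir`. Reruns with the same config and seed produce byte-identical
#' payloads.
#'
#' @param out_dir Output directory (created if needed).
#' @param stages Subset of `c("simulate", "cones", "choroid", "csf",
#'   "stats")`, or `"all"`.
#' @param config A [pipeline_config()].
#' @param seed Global integer seed; per-stage streams are derived from it.
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(out_dir, stages = "all", config = pipeline_config(),
                         seed = 1, quiet = FALSE) {
  validate_config(config)
  if (identical(stages, "all")) stages <- .pipeline_stages
  bad <- setdiff(stages, .pipeline_stages)
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- .pipeline_stages[.pipeline_stages %in% stages]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  outputs <- character(0)
  put <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
    outputs <<- c(outputs, name)
  }
  need_cohort <- function() {
    f <- file.path(out_dir, "cohort.csv")
    if (!file.exists(f))
      stop("missing upstream output 'cohort.csv'; run the 'simulate' stage first")
    utils::read.csv(f)
  }

  if ("simulate" %in% stages) {
    say("[simulate] generating synthetic cohort")
    cohort <- gen_cohort(do.call(cohort_spec,
                                 utils::modifyList(list(seed = seed),
                                                   config$cohort)))
    put(cohort, "cohort.csv")
  }

  if ("cones" %in% stages) {
    cohort <- need_cohort()
    n <- min(config$n_eyes, nrow(cohort))
    say(sprintf("[cones] imaging %d synthetic eyes", n))
    rows <- lapply(seq_len(n), function(e) {
      ms <- do.call(mosaic_spec,
                    utils::modifyList(
                      list(density = cohort$cone_density_inner[e],
                           seed = seed + 10 + e),
                      config$mosaic))
      sim <- gen_mosaic(ms)
      dp <- do.call(detect_params, config$detection)
      det <- detect_cones(sim$image, params = dp)
      m <- mosaic_metrics(det)
      data.frame(subject = cohort$id[e], region = "inner",
                 density_true = ms$density, density = m$density,
                 spacing = m$spacing, regularity = m$regularity,
                 n_cones = m$n_cones)
    })
    put(do.call(rbind, rows), "cone_metrics.csv")
  }

  if ("choroid" %in% stages) {
    say("[choroid] quantifying choroid phantom")
    ph <- gen_choroid_phantom(
      do.call(choroid_phantom_spec,
              utils::modifyList(list(seed = seed + 100), config$phantom)))
    lin <- linearize(ph$scan, ph$boundaries)
    np <- do.call(niblack_params, config$niblack)
    cmask <- choroid_mask(lin$scan, lin$boundaries)
    lumen <- niblack_binarize(lin$scan, cmask, np)
    rows <- lapply(c("inner", "outer"), function(sfl) {
      sf <- subfield(sfl)
      q <- choroid_metrics(lin$scan, lin$boundaries, lumen, sf)
      th <- sublayer_thickness(lin$scan, lin$boundaries, sf)
      cbind(data.frame(subfield = sfl, CT = q$CT, LA = q$LA, SA = q$SA,
                       TCA = q$TCA, CVI = q$CVI,
                       lumen_fraction_true = ph$lumen_fraction),
            as.data.frame(as.list(th)))
    })
    put(do.call(rbind, rows), "choroid_metrics.csv")
  }

  if ("csf" %in% stages) {
    n <- config$n_eyes
    say(sprintf("[csf] running %d adaptive sessions", n))
    rows <- lapply(seq_len(n), function(e) {
      obs <- gen_observer(do.call(observer_spec,
                                  utils::modifyList(list(seed = seed + 200 + e),
                                                    config$observer)))
      res <- run_session(obs, n_trials = config$psi$n_trials,
                         frequencies = config$psi$frequencies,
                         seed = seed + 200 + e)
      data.frame(subject = sprintf("obs%02d", e),
                 frequency_cpd = res$frequencies,
                 threshold = res$thresholds,
                 log_sensitivity = res$log_sensitivities,
                 aulcsf = res$aulcsf, cutoff_sf = as.numeric(res$cutoff_sf),
                 n_trials = config$psi$n_trials)
    })
    put(do.call(rbind, rows), "csf_results.csv")
  }

  if ("stats" %in% stages) {
    cohort <- need_cohort()
    say("[stats] group comparisons and regression screen")
    t1_rows <- lapply(c("age", "se", "al", "iop"), function(v) {
      gc <- compare_groups(cohort, v)
      data.frame(variable = v,
                 t(stats::setNames(sprintf("%.2f +/- %.2f", gc$summary$mean,
                                           gc$summary$sd),
                                   gc$summary$group)),
                 p = gc$p_overall, check.names = FALSE)
    })
    put(do.call(rbind, t1_rows), "table1.csv")
    outcomes <- intersect(c("aulcsf", "cutoff_sf", "cone_density_inner",
                            "cone_density_outer", "cone_spacing_inner",
                            "cone_spacing_outer", "cone_regularity",
                            "ct_inner", "ct_outer", "cvi_inner", "cvi_outer"),
                          names(cohort))
    t2_rows <- lapply(outcomes, function(v) {
      gc <- compare_groups(cohort, v)
      data.frame(outcome = v, P0 = gc$p_overall,
                 t(stats::setNames(gc$pairwise$p, gc$pairwise$label)))
    })
    put(do.call(rbind, t2_rows), "group_comparisons.csv")
    sx <- sex_distribution_test(cohort)
    put(data.frame(statistic = sx$statistic, df = sx$df, p = sx$p),
        "sex_chisq.csv")
    rs <- regression_screen(cohort, config$stats$outcome,
                            intersect(config$stats$predictors, names(cohort)))
    put(rs$univariate, "regression_univariate.csv")
    put(rs$final, "regression_final.csv")
  }

  manifest <- list(package = "myoretina",
                   version = as.character(utils::packageVersion("myoretina")),
                   seed = seed,
                   stages = stages,
                   config_hash = digest::digest(config),
                   outputs = outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
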