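# Experiment orchestration and fixture generation -----------------------------
#
# Ties the stages into one reproducible run: (optional) simulation ->
# eligibility filtering -> labeling -> fold planning -> repeated grouped CV,
# with every output artifact stamped with the configuration hash and seed.

#' Bundle a full experiment configuration
#'
#' @param input path to a cohort CSV, or \code{NULL} to simulate.
#' @param simulate a \code{\link{generation_config}} (required when
#'   \code{input} is \code{NULL}).
#' @param preset predictor preset: \code{"SD"}, \code{"IMAGE"} or
#'   \code{"MERGED"}.
#' @param k,repeats cross-validation folds and repeats (defaults 10 and 25).
#' @param n_trees trees per cascade stage (default 3000).
#' @param seed root seed fanned out to named substreams (simulation, fold
#'   plan, per-cell stage forests).
#' @param out_dir optional directory for the results JSON and exclusion
#'   report.
#' @return Object of class \code{run_config}.
#' @export
run_config <- function(input = NULL, simulate = NULL, preset = "MERGED",
                       k = 10, repeats = 25, n_trees = 3000, seed = 1L,
                       out_dir = NULL) {
  if (is.null(input) && is.null(simulate)) {
    stop_kneecast("provide either an input CSV path or a simulation config",
                  class = "kneecast_config_error")
  }
  if (!is.null(input) && !file.exists(input)) {
    stop_kneecast("input cohort not found: %s", input,
                  class = "kneecast_config_error")
  }
  if (!preset %in% c("SD", "IMAGE", "MERGED")) {
    stop_kneecast("unknown predictor preset: %s", preset,
                  class = "kneecast_config_error")
  }
  structure(list(input = input, simulate = simulate, preset = preset,
                 k = as.integer(k), repeats = as.integer(repeats),
                 n_trees = as.integer(n_trees), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#' @param config a \code{\link{run_config}}.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  lst <- unclass(config)
  lst$simulate <- if (!is.null(lst$simulate)) {
    sim <- unclass(lst$simulate)
    sim$predictor_means <- as.list(sim$predictor_means)
    sim$predictor_sds <- as.list(sim$predictor_sds)
    sim$class_prevalence <- as.list(sim$class_prevalence)
    sim$effect_sizes <- as.list(sim$effect_sizes)
    sim
  }
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lst <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(lst$simulate)) {
    s <- lst$simulate
    sim <- generation_config(
      n_subjects = s$n_subjects,
      bilateral_prob = s$bilateral_prob %||% 1,
      predictor_means = unlist(s$predictor_means),
      predictor_sds = unlist(s$predictor_sds),
      class_prevalence = unlist(s$class_prevalence),
      effect_sizes = unlist(s$effect_sizes),
      within_subject_corr = s$within_subject_corr %||% 0.6,
      noise_sd = s$noise_sd %||% 1,
      seed = s$seed %||% 1L)
  }
  run_config(input = lst$input, simulate = sim, preset = lst$preset,
             k = lst$k, repeats = lst$repeats, n_trees = lst$n_trees,
             seed = lst$seed, out_dir = lst$out_dir)
}

#' Run a full experiment
#'
#' Executes simulate (optional) -> filter -> label -> fold plan -> repeated
#' grouped CV for the configured preset. When \code{out_dir} is set, writes
#' \code{results_<preset>.json} (per-cell metrics, summary, pooled confusion,
#' provenance stamp) and \code{exclusion_report.json}.
#'
#' @param config a \code{\link{run_config}}.
#' @param plan optional pre-built \code{\link{make_fold_plan}} (so several
#'   presets can be compared on identical folds).
#' @return List with \code{cohort} (filtered, labeled), \code{report},
#'   \code{plan}, \code{cv} (a \code{cv_result}), \code{summary}, and
#'   \code{provenance}.
#' @export
run_experiment <- function(config, plan = NULL) {
  stopifnot(inherits(config, "run_config"))
  cohort <- if (!is.null(config$input)) {
    read_cohort_csv(config$input)
  } else {
    sim <- config$simulate
    sim$seed <- derive_seed(config$seed, paste0("simulate-", sim$seed))
    simulate_cohort(sim)
  }
  filt <- apply_exclusions(cohort)
  eligible <- label_cohort(filt$cohort)
  if (is.null(plan)) {
    plan <- make_fold_plan(eligible$subject_id, eligible$severity,
                           k = config$k, r = config$repeats,
                           seed = derive_seed(config$seed, "folds"))
  }
  ens_cfg <- balanced_ensemble_config(n_trees = config$n_trees,
                                      seed = derive_seed(config$seed, "forest"))
  cv <- run_cv(eligible, preset = config$preset, config = ens_cfg,
               plan = plan, tag = config$preset)
  summ <- summary(cv)
  hashed <- unclass(config)
  hashed$out_dir <- NULL    # identical analyses hash equal wherever written
  provenance <- list(package = "kneecast",
                     version = as.character(utils::packageVersion("kneecast")),
                     config_hash = config_hash(hashed),
                     seed = config$seed)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    res <- list(provenance = provenance,
                class_distribution = class_distribution(eligible$severity),
                per_cell = cv$per_cell,
                summary = summ[setdiff(names(summ), "pooled_confusion")],
                pooled_confusion = summ$pooled_confusion,
                failures = cv$failures)
    jsonlite::write_json(res,
                         file.path(config$out_dir,
                                   paste0("results_", config$preset, ".json")),
                         auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
    exclusion_report_json(filt$report,
                          file.path(config$out_dir, "exclusion_report.json"))
  }
  list(cohort = eligible, report = filt$report, plan = plan, cv = cv,
       summary = summ, provenance = provenance)
}

#' Hand-enumerated eligibility toy cohort
#'
#' A 6-subject, 12-knee cohort built so that exactly one subject trips each of
#' the four subject-level exclusion rules, one knee is dropped for incomplete
#' follow-up without rescue, and one knee is rescued by an early KL-3
#' observation; 3 knees remain eligible. Used by the filter tests and shipped
#' as a plain-text fixture by \code{\link{make_fixtures}}.
#'
#' @return Cohort \code{data.frame}, 12 rows.
#' @export
toy_exclusion_cohort <- function() {
  base <- function(subject, age, kl_base = c(0L, 0L), injury = FALSE,
                   weight = 75) {
    df <- data.frame(subject_id = subject, knee_side = c("L", "R"),
                     age = age, height = 165, weight = weight,
                     medial_js = 4.7, lateral_js = 6.7, femur_width = 76.5,
                     intercondylar_distance = 48.8, ft_angle = -6.7,
                     vv_angle = 4.6, proximal_tibia_width = 77,
                     distal_tibia_width = 27.4, kl_baseline = kl_base,
                     stringsAsFactors = FALSE)
    for (yv in FOLLOWUP_YEARS) df[[paste0("kl_y", yv)]] <- c(0L, 1L)
    for (yv in FOLLOWUP_YEARS) df[[paste0("weight_y", yv)]] <- weight
    df$injury_flag <- injury
    df$surgery_flag <- FALSE
    df$tkr_flag <- FALSE
    df
  }
  s1 <- base("T1", 55, kl_base = c(2L, 0L))       # baseline KL >= 2
  s2 <- base("T2", 70)                            # age outside [45, 67]
  s3 <- base("T3", 55, injury = TRUE)             # prior injury
  s4 <- base("T4", 55)                            # weight drift > 10 kg
  s4$weight_y6 <- s4$weight + 15
  s5 <- base("T5", 55)                            # L: incomplete, no rescue
  s5[1, c("kl_y6", "kl_y8")] <- NA
  s6 <- base("T6", 55)                            # L: incomplete, rescued
  s6[1, c("kl_y6", "kl_y8")] <- NA
  s6[1, "kl_y4"] <- 3L
  out <- rbind(s1, s2, s3, s4, s5, s6)
  out[, cohort_columns()]
}

#' Write the plain-text fixtures used by the acceptance suite
#'
#' Writes three seeded cohort CSVs into \code{dir}: the hand-enumerated
#' exclusion toy cohort, a small strongly separable cohort
#' (\code{separation = 10}) and a null cohort (\code{separation = 0}).
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @return Named character vector of the written paths.
#' @export
make_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- function(n, s) generation_config(n_subjects = n,
                                          seed = derive_seed(seed, s))
  paths <- c(
    toy = file.path(dir, "toy_exclusion_cohort.csv"),
    separable = file.path(dir, "separable_cohort.csv"),
    null = file.path(dir, "null_cohort.csv"))
  write_cohort_csv(toy_exclusion_cohort(), paths["toy"])
  write_cohort_csv(simulate_separable_cohort(cfg(60, "separable"), 10),
                   paths["separable"])
  write_cohort_csv(simulate_separable_cohort(cfg(60, "null"), 0),
                   paths["null"])
  invisible(paths)
}
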