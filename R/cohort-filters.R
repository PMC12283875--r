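# Cohort eligibility filters and outcome re-categorisation --------------------

# Exclusion rules fire in this fixed order; each removal is attributed to the
# FIRST rule that applies. Rules 1-4 act on whole subjects (never splitting a
# subject), rules 5-7 on individual knees.
EXCLUSION_RULES <- c(
  "baseline_kl_ge2",      # subject: any knee KL >= 2 at baseline
  "age_outside_45_67",    # subject: age outside [45, 67] (inclusive window)
  "injury_or_surgery",    # subject: prior knee injury or surgery
  "weight_change_gt10kg", # subject: any follow-up weight > 10 kg from baseline
  "incomplete_followup",  # knee: no 8-year KL unless already progressed to KL3+
  "missing_morphology",   # knee: radiograph measures unavailable
  "unlabeled"             # knee: no follow-up KL at all and no TKR
)

#' Apply the eligibility exclusion pipeline
#'
#' Filters a knee-level cohort with the study's eligibility rules, in fixed
#' order, attributing every removal to the first rule that fires:
#' \enumerate{
#'   \item subjects with any knee at baseline KL grade >= 2;
#'   \item subjects with age outside the closed window [45, 67] years;
#'   \item subjects with a prior knee injury or knee surgery;
#'   \item subjects whose weight at any follow-up visit differs from baseline
#'     by more than 10 kg (strict inequality);
#'   \item knees without an 8-year KL observation, \emph{unless} a follow-up
#'     KL grade >= 3 (or TKR) was already observed - such knees are retained
#'     ("rescued"), because progression is assumed not to reverse;
#'   \item knees with missing morphology measurements;
#'   \item knees with no follow-up KL information and no TKR (unlabelable).
#' }
#' Subject-level rules remove all of a subject's knees together; the
#' early-progression rescue is knee-level, so some subjects contribute a
#' single knee.
#'
#' @param cohort a cohort \code{data.frame} with columns
#'   \code{\link{cohort_columns}}.
#' @return A list with \code{cohort} (the retained rows) and \code{report}
#'   (an \code{exclusion_report}: per-rule knee and subject removal counts,
#'   rescued-knee count, retained count).
#' @export
apply_exclusions <- function(cohort) {
  validate_cohort(cohort)
  n_input <- nrow(cohort)
  kl_cols <- paste0("kl_y", FOLLOWUP_YEARS)
  w_cols <- paste0("weight_y", FOLLOWUP_YEARS)

  knees_removed <- stats::setNames(integer(length(EXCLUSION_RULES)),
                                   EXCLUSION_RULES)
  subjects_removed <- stats::setNames(integer(4), EXCLUSION_RULES[1:4])
  alive <- rep(TRUE, n_input)

  subject_hit <- function(flag_by_row) {
    # lift a row-level flag to all knees of any flagged subject still alive
    bad_subj <- unique(cohort$subject_id[alive & flag_by_row])
    alive & cohort$subject_id %in% bad_subj
  }

  # 1-4: subject-level rules
  rule_flags <- list(
    baseline_kl_ge2 = cohort$kl_baseline >= 2,
    age_outside_45_67 = cohort$age < 45 | cohort$age > 67,
    injury_or_surgery = cohort$injury_flag | cohort$surgery_flag,
    weight_change_gt10kg = apply(abs(cohort[, w_cols] - cohort$weight) > 10,
                                 1, any, na.rm = TRUE)
  )
  for (rule in names(rule_flags)) {
    hit <- subject_hit(rule_flags[[rule]])
    knees_removed[rule] <- sum(hit)
    subjects_removed[rule] <- length(unique(cohort$subject_id[hit]))
    alive <- alive & !hit
  }

  # 5: knee-level incomplete follow-up, with early-KL3 rescue
  kl_obs <- as.matrix(cohort[, kl_cols])
  max_kl <- suppressWarnings(apply(kl_obs, 1, max, na.rm = TRUE))
  max_kl[is.infinite(max_kl)] <- NA
  incomplete <- is.na(cohort$kl_y8)
  rescued <- incomplete & ((!is.na(max_kl) & max_kl >= 3) | cohort$tkr_flag)
  hit5 <- alive & incomplete & !rescued
  knees_removed["incomplete_followup"] <- sum(hit5)
  n_rescued <- sum(alive & rescued)
  alive <- alive & !hit5

  # 6: knee-level missing morphology
  hit6 <- alive & apply(is.na(cohort[, morphology_names()]), 1, any)
  knees_removed["missing_morphology"] <- sum(hit6)
  alive <- alive & !hit6

  # 7: knees that cannot be labeled at all
  hit7 <- alive & is.na(max_kl) & !cohort$tkr_flag
  knees_removed["unlabeled"] <- sum(hit7)
  alive <- alive & !hit7

  report <- structure(list(n_input = n_input,
                           knees_removed = knees_removed,
                           subjects_removed = subjects_removed,
                           rescued_early_kl3 = n_rescued,
                           retained = sum(alive)),
                      class = "exclusion_report")
  stopifnot(report$retained + sum(knees_removed) == n_input)
  out <- cohort[alive, , drop = FALSE]
  rownames(out) <- NULL
  list(cohort = out, report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("Eligibility filtering: %d knees in\n", x$n_input))
  for (rule in names(x$knees_removed)) {
    subj <- if (rule %in% names(x$subjects_removed)) {
      sprintf(" (%d subjects)", x$subjects_removed[[rule]])
    } else ""
    cat(sprintf("  |- %-22s -%d knees%s\n", rule, x$knees_removed[[rule]], subj))
  }
  cat(sprintf("  |- rescued by early KL>=3: %d knees kept\n", x$rescued_early_kl3))
  cat(sprintf("  `- retained: %d knees\n", x$retained))
  invisible(x)
}

#' Serialise an exclusion report as JSON
#' @param report an \code{exclusion_report}.
#' @param path optional file path; when omitted the JSON string is returned.
#' @export
exclusion_report_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(path))
  }
  js
}

#' Re-categorise a knee's 8-year outcome into the ordinal severity class
#'
#' The outcome is the maximum KL grade observed over the follow-up visits
#' (missing visits are skipped, not imputed): \code{KL01} if the maximum is
#' 0-1, \code{KL2} if exactly 2, \code{KL34} if 3 or more \emph{or} the knee
#' underwent total knee replacement. A TKR with no recorded follow-up grades
#' is labeled KL34 (replacement is itself the severe endpoint).
#'
#' @param kl_grades numeric vector of follow-up KL grades for one knee
#'   (\code{NA} = missing visit).
#' @param tkr logical, total knee replacement during follow-up.
#' @return A length-1 severity factor (see \code{\link{severity_factor}}).
#' @export
recategorize_target <- function(kl_grades, tkr = FALSE) {
  obs <- kl_grades[!is.na(kl_grades)]
  if (!length(obs) && !isTRUE(tkr)) {
    stop_kneecast("knee has no follow-up KL information and no TKR: unlabelable",
                  class = "kneecast_label_error")
  }
  if (isTRUE(tkr) || (length(obs) && max(obs) >= 3)) {
    return(severity_factor("KL34"))
  }
  if (max(obs) == 2) severity_factor("KL2") else severity_factor("KL01")
}

#' Label every knee of a cohort with its severity class
#'
#' Vectorised \code{\link{recategorize_target}} over the follow-up columns;
#' adds (or overwrites) the \code{severity} column.
#'
#' @param cohort cohort \code{data.frame}.
#' @export
label_cohort <- function(cohort) {
  kl_cols <- paste0("kl_y", FOLLOWUP_YEARS)
  validate_cohort(cohort, required = c(kl_cols, "tkr_flag"))
  kl <- as.matrix(cohort[, kl_cols])
  lab <- vapply(seq_len(nrow(cohort)), function(r) {
    as.character(recategorize_target(kl[r, ], cohort$tkr_flag[r]))
  }, character(1))
  cohort$severity <- severity_factor(lab)
  cohort
}

#' Select a predictor preset as a feature table
#'
#' The three experiment presets: \code{SD} uses the subject demographics plus
#' baseline KL grade (4 features); \code{IMAGE} uses the eight radiographic
#' morphology measures plus baseline KL grade (9 features); \code{MERGED}
#' uses all 12 predictors. Column order is fixed to the canonical predictor
#' order.
#'
#' @param cohort cohort \code{data.frame}.
#' @param preset one of \code{"SD"}, \code{"IMAGE"}, \code{"MERGED"}.
#' @return \code{data.frame} of numeric feature columns (row names preserved).
#' @export
select_predictors <- function(cohort, preset = c("MERGED", "SD", "IMAGE")) {
  if (length(preset) == 1 && !preset %in% c("MERGED", "SD", "IMAGE")) {
    stop_kneecast("unknown predictor preset: %s", preset,
                  class = "kneecast_config_error")
  }
  preset <- match.arg(preset)
  cols <- switch(preset,
                 SD = c("age", "height", "weight", "kl_baseline"),
                 IMAGE = c(morphology_names(), "kl_baseline"),
                 MERGED = predictor_names())
  validate_cohort(cohort, required = cols)
  cohort[, cols, drop = FALSE]
}
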