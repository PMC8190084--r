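#' Harmonization configuration
#'
#' Thresholds and adjustment factors for phenotype curation: statin
#' adjustment divisors (LDL 0.7, TG 0.85), clinical dichotomization cut-offs
#' (high LDL >= 190, low LDL <= 80, high HDL >= 70, high TG >= 200 mg/dL,
#' obesity BMI >= 30 kg/m2) and glycemia criteria (diabetes: HbA1c >= 6.5%
#' or a diabetes record flag; prediabetes: HbA1c >= 5.7%, fasting glucose
#' >= 100 mg/dL or 2-hour OGTT glucose >= 140 mg/dL). All inequalities are
#' boundary-inclusive.
#'
#' @param statinLdlDivisor,statinTgDivisor divisors in (0, 1].
#' @param thresholds named numeric dichotomization cut-offs.
#' @param glycemia named numeric glycemia cut-offs.
#' @return a list of class "harmonizationConfig".
#' @export
harmonizationConfig <- function(statinLdlDivisor = 0.7, statinTgDivisor = 0.85,
                                thresholds = c(high_ldl = 190, low_ldl = 80,
                                               high_hdl = 70, high_tg = 200,
                                               obesity = 30),
                                glycemia = c(diabetes_hba1c = 6.5,
                                             prediabetes_hba1c = 5.7,
                                             prediabetes_fg = 100,
                                             prediabetes_ogtt = 140)) {
  stopifnot(statinLdlDivisor > 0, statinLdlDivisor <= 1,
            statinTgDivisor > 0, statinTgDivisor <= 1,
            all(thresholds > 0))
  structure(list(statinLdlDivisor = statinLdlDivisor,
                 statinTgDivisor = statinTgDivisor,
                 thresholds = thresholds, glycemia = glycemia),
            class = "harmonizationConfig")
}

#' Adjust lipid values for lipid-lowering medication
#'
#' Observed LDL of treated individuals is divided by 0.7 and observed
#' triglycerides by 0.85 to estimate the untreated value; HDL is never
#' adjusted and untreated values pass through unchanged.
#'
#' @param value observed lipid value, mg/dL.
#' @param trait "ldl" or "tg" ("hdl" is accepted and returned unchanged).
#' @param onMedication logical, lipid-lowering treatment flag.
#' @param config a \code{\link{harmonizationConfig}}.
#' @return adjusted value, mg/dL.
#' @examples
#' adjustLipids(140, "ldl", TRUE)   # 200
#' adjustLipids(170, "tg", TRUE)    # 200
#' @export
adjustLipids <- function(value, trait, onMedication,
                         config = harmonizationConfig()) {
  stopifnot(all(value >= 0, na.rm = TRUE))
  div <- switch(trait,
                ldl = config$statinLdlDivisor,
                tg = config$statinTgDivisor,
                hdl = 1,
                stop("unknown trait '", trait, "'"))
  ifelse(rep_len(onMedication, length(value)), value / div, value)
}

#' Convert lipid measurements from mmol/L to mg/dL
#'
#' Uses the standard molar-mass factors: 38.67 for cholesterol fractions
#' (LDL, HDL, total) and 88.57 for triglycerides.
#'
#' @param value concentration in mmol/L.
#' @param trait "ldl", "hdl", "cholesterol" or "tg".
#' @return concentration in mg/dL.
#' @examples
#' convertUnits(5, "ldl")  # 193.35
#' @export
convertUnits <- function(value, trait) {
  stopifnot(all(value >= 0, na.rm = TRUE))
  factor <- switch(trait,
                   ldl = , hdl = , cholesterol = 38.67,
                   tg = 88.57,
                   stop("unknown trait '", trait, "'"))
  value * factor
}

#' Classify glycemic status
#'
#' Diabetes when any diabetes criterion or record flag holds (HbA1c >=
#' 6.5%, or the diabetes record flag); otherwise prediabetes when any
#' prediabetes criterion holds (HbA1c >= 5.7%, fasting glucose >= 100
#' mg/dL, OGTT 2h >= 140 mg/dL); otherwise normoglycemic. Missing inputs
#' are skipped; when every input is missing the status is indeterminate and
#' the individual is excluded from penetrance denominators.
#'
#' @param hba1c HbA1c, percent.
#' @param fastingGlucose fasting glucose, mg/dL.
#' @param ogtt2h 2-hour OGTT glucose, mg/dL.
#' @param recordFlag logical diabetes record flag (clinical codes).
#' @param config a \code{\link{harmonizationConfig}}.
#' @return character vector in
#'   \{"diabetes", "prediabetes", "normoglycemic", "indeterminate"\}.
#' @examples
#' classifyGlycemia(hba1c = 6.6)              # diabetes
#' classifyGlycemia(fastingGlucose = 100)     # prediabetes (inclusive)
#' @export
classifyGlycemia <- function(hba1c = NA_real_, fastingGlucose = NA_real_,
                             ogtt2h = NA_real_, recordFlag = NA,
                             config = harmonizationConfig()) {
  n <- max(length(hba1c), length(fastingGlucose), length(ogtt2h),
           length(recordFlag))
  hba1c <- rep_len(hba1c, n); fastingGlucose <- rep_len(fastingGlucose, n)
  ogtt2h <- rep_len(ogtt2h, n); recordFlag <- rep_len(recordFlag, n)
  g <- config$glycemia
  or3 <- function(...) Reduce(`|`, lapply(list(...), function(x) !is.na(x) & x))
  allMissing <- is.na(hba1c) & is.na(fastingGlucose) & is.na(ogtt2h) &
    is.na(recordFlag)
  diab <- or3(hba1c >= g["diabetes_hba1c"], recordFlag)
  pre <- or3(hba1c >= g["prediabetes_hba1c"],
             fastingGlucose >= g["prediabetes_fg"],
             ogtt2h >= g["prediabetes_ogtt"])
  ifelse(allMissing, "indeterminate",
         ifelse(diab, "diabetes", ifelse(pre, "prediabetes", "normoglycemic")))
}

#' Dichotomize a harmonized cohort for one condition
#'
#' Applies the clinical diagnosis cut-off, boundary inclusive, to the
#' medication-adjusted trait: high LDL >= 190, low LDL <= 80, high HDL >=
#' 70, high TG >= 200 mg/dL, obesity BMI >= 30 kg/m2; "mody" is classified
#' by glycemic status (diabetes, or diabetes-or-prediabetes with
#' \code{outcome = "diabetes_or_prediabetes"}). Missing trait values give
#' missing flags, excluded from penetrance denominators.
#'
#' @param cohort harmonized phenotype data.frame (see
#'   \code{\link{harmonizeCohort}}).
#' @param condition one of "high_ldl", "low_ldl", "high_hdl", "high_tg",
#'   "obesity", "mody".
#' @param outcome for "mody": "diabetes" (default) or
#'   "diabetes_or_prediabetes".
#' @param config a \code{\link{harmonizationConfig}}.
#' @return logical vector of case flags (NA where indeterminate).
#' @export
dichotomize <- function(cohort, condition,
                        outcome = c("diabetes", "diabetes_or_prediabetes"),
                        config = harmonizationConfig()) {
  th <- config$thresholds
  if (condition == "mody") {
    outcome <- match.arg(outcome)
    st <- if ("glycemia" %in% colnames(cohort)) cohort$glycemia
          else classifyGlycemia(cohort$hba1c, cohort$fasting_glucose,
                                cohort$ogtt_2h, cohort$diabetes_record_flag,
                                config)
    res <- switch(outcome,
                  diabetes = st == "diabetes",
                  diabetes_or_prediabetes = st %in% c("diabetes", "prediabetes"))
    res[st == "indeterminate"] <- NA
    return(res)
  }
  switch(condition,
         high_ldl = cohort$ldl_adj >= th["high_ldl"],
         low_ldl = cohort$ldl_adj <= th["low_ldl"],
         high_hdl = cohort$hdl >= th["high_hdl"],
         high_tg = cohort$tg_adj >= th["high_tg"],
         obesity = cohort$bmi >= th["obesity"],
         stop("unknown condition '", condition, "'"))
}

#' Harmonize a cohort phenotype table
#'
#' Applies medication adjustment (adding \code{ldl_adj} and \code{tg_adj}),
#' classifies glycemic status (\code{glycemia}) and dichotomizes every
#' condition (\code{case_<condition>} columns). Idempotent: running it on an
#' already-harmonized table reproduces the same columns, and classification
#' is row-wise, hence order independent.
#'
#' @param cohort phenotype data.frame with observed \code{ldl}, \code{tg},
#'   \code{hdl}, \code{bmi}, \code{on_lipid_med}, glycemic inputs.
#' @param config a \code{\link{harmonizationConfig}}.
#' @param conditions conditions to dichotomize.
#' @return the table with harmonized columns appended.
#' @export
harmonizeCohort <- function(cohort, config = harmonizationConfig(),
                            conditions = c("high_ldl", "low_ldl", "high_hdl",
                                           "high_tg", "obesity", "mody")) {
  cohort$ldl_adj <- adjustLipids(cohort$ldl, "ldl", cohort$on_lipid_med, config)
  cohort$tg_adj <- adjustLipids(cohort$tg, "tg", cohort$on_lipid_med, config)
  cohort$glycemia <- classifyGlycemia(cohort$hba1c, cohort$fasting_glucose,
                                      cohort$ogtt_2h,
                                      cohort$diabetes_record_flag, config)
  for (cond in conditions) {
    if (cond == "mody") {
      cohort$case_mody <- dichotomize(cohort, "mody", "diabetes", config)
      cohort$case_mody_any_dysglycemia <-
        dichotomize(cohort, "mody", "diabetes_or_prediabetes", config)
    } else {
      cohort[[paste0("case_", cond)]] <- dichotomize(cohort, cond, config = config)
    }
  }
  cohort
}

#' Collapse repeat biobank visits
#'
#' Multiple measurement visits are collapsed before classification: the
#' mean across visits for lipids and BMI, the maximum observed across
#' visits for HbA1c.
#'
#' @param visits long data.frame with columns \code{id}, \code{trait},
#'   \code{value}.
#' @return wide data.frame, one row per individual.
#' @export
collapseVisits <- function(visits) {
  stopifnot(all(c("id", "trait", "value") %in% colnames(visits)))
  agg <- function(tr, f) {
    d <- visits[visits$trait == tr, , drop = FALSE]
    if (nrow(d) == 0L) return(NULL)
    out <- tapply(d$value, d$id, f, na.rm = TRUE)
    data.frame(id = names(out), value = as.numeric(out),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  ids <- unique(visits$id)
  res <- data.frame(id = ids, stringsAsFactors = FALSE)
  for (tr in unique(visits$trait)) {
    f <- if (tr == "hba1c") max else mean
    a <- agg(tr, f)
    res[[tr]] <- a$value[match(ids, a$id)]
  }
  res
}
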