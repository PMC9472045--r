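# Seeded synthetic-EHR cohort generator with planted ground-truth cognitive
# status. Note text is template-based: clinical-sounding sentences with
# keyword slots, so every emission probability is controlled and the whole
# pipeline is testable without any protected health information. Two cohort
# templates are provided: an elderly high-dementia-prevalence cohort
# ("aco") and a larger mixed-age cohort with a sizeable sparse-record
# undetermined fraction ("covid").

IMPAIRED_SENTENCES <- c(
  "Family reports progressive memory loss over the past year.",
  "Patient appears confused about recent events and appointments.",
  "Exam notable for cognitive decline compared to prior visit.",
  "She has become increasingly forgetful per her daughter.",
  "Assessment consistent with mild cognitive impairment."
)

INTACT_SENTENCES <- c(
  "Language, attention, and memory function are intact with good fund of knowledge.",
  "Cognition is grossly normal on screening today.",
  "Patient is cognitively intact and manages her own finances.",
  "Alert and oriented x3 throughout the interview.",
  "Cognition appears normal with excellent recall of recent events."
)

ADL_IMPAIRED_SENTENCES <- c(
  "He now needs assistance with dressing and bathing.",
  "Patient has stopped driving after several near misses.",
  "Reports difficulty managing medications without supervision."
)

ADL_INTACT_SENTENCES <- c(
  "Independent in all ADLs and continues to drive.",
  "She manages her own medications and continues to work part time.",
  "Independent with finances and household tasks."
)

NEUTRAL_SENTENCES <- c(
  "Patient presents for routine follow up visit.",
  "Blood pressure well controlled on current regimen.",
  "Reviewed recent laboratory results and updated the plan of care.",
  "Discussed diet and exercise; will continue current management.",
  "Vaccinations are up to date; return in six months.",
  "Knee pain improving with physical therapy.",
  "No acute complaints today; plan unchanged."
)

BACKGROUND_MEDS <- c("metformin 500 mg tablet", "lisinopril 10 mg tablet",
                     "atorvastatin 20 mg tablet", "omeprazole 20 mg capsule",
                     "amlodipine 5 mg tablet")
DEMENTIA_MEDS <- c("Donepezil 10 mg tablet", "Memantine 10 mg tablet",
                   "Rivastigmine 4.6 mg/24 hr patch", "Galantamine 8 mg tablet")
BACKGROUND_ICD <- data.frame(
  code = c("E11.9", "I10", "M17.11", "K21.9"),
  system = "ICD10",
  description = c("Type 2 diabetes", "Essential hypertension",
                  "Osteoarthritis of knee", "GERD"),
  stringsAsFactors = FALSE
)
DEMENTIA_ICD <- data.frame(
  code = c("G30.9", "G31.84", "331.0", "294.10", "290.0", "780.93"),
  system = c("ICD10", "ICD10", "ICD9", "ICD9", "ICD9", "ICD9"),
  description = c("Alzheimer disease, unspecified", "Mild cognitive impairment",
                  "Alzheimer disease", "Dementia in other diseases",
                  "Senile dementia", "Memory loss"),
  stringsAsFactors = FALSE
)

#' Synthetic cohort configuration
#'
#' Defines the statistical shape of a generated cohort: prevalence of the
#' planted cognitive-status labels, per-note keyword emission
#' probabilities, structured-evidence rates, utilization rates, and the
#' age/period template. The defaults describe the mixed-age template: 30%
#' cognitively impaired, 20% sparse-record undetermined patients, and
#' keyword/ICD/medication rates under which impaired evidence recurs
#' across a patient's chart the way documented cognitive concerns do.
#'
#' @param n_patients cohort size.
#' @param template `"covid"` (age ~ N(52.6, 15), 2-year look-back window)
#'   or `"aco"` (age ~ N(78.8, 7.4), fixed 2017-2018 window with higher
#'   dementia-signal prevalence defaults).
#' @param prevalence_ci,frac_undetermined marginal fractions of planted CI
#'   and undetermined labels (the remainder is CN); their sum must be <= 1.
#' @param notes_min,notes_lambda labeled patients receive
#'   `notes_min + Poisson(notes_lambda)` notes; undetermined patients
#'   receive 1-2 sparse notes.
#' @param p_impaired_given_ci,p_intact_given_ci,p_impaired_given_cn,p_intact_given_cn
#'   per-note probabilities of emitting an impaired/intact cognition
#'   keyword sentence by true status (the CN impaired rate is a small
#'   documentation-noise leak).
#' @param p_adl per-note probability of an ADL sentence (impaired phrasing
#'   for CI patients, intact for CN).
#' @param p_icd_given_ci,p_med_given_ci,p_icd_given_cn,p_med_given_cn
#'   probabilities of carrying a dementia ICD code / medication.
#' @param confounder_frac_cn fraction of CN patients given a transient
#'   early impaired mention followed by a later intact note.
#' @param encounter_lambda,no_show_rate,cancellation_rate,refill_lambda
#'   utilization parameters.
#' @param seed mandatory integer seed; the whole cohort is a deterministic
#'   function of the configuration.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 500L, template = c("covid", "aco"),
                          prevalence_ci = 0.3, frac_undetermined = 0.2,
                          notes_min = 5L, notes_lambda = 5,
                          p_impaired_given_ci = 0.6, p_intact_given_ci = 0.05,
                          p_impaired_given_cn = 0.01, p_intact_given_cn = 0.35,
                          p_adl = 0.2,
                          p_icd_given_ci = 0.5, p_med_given_ci = 0.4,
                          p_icd_given_cn = 0.01, p_med_given_cn = 0.01,
                          confounder_frac_cn = 0.05,
                          encounter_lambda = 20, no_show_rate = 0.07,
                          cancellation_rate = 0.12, refill_lambda = 3,
                          seed) {
  template <- match.arg(template)
  if (missing(seed)) stop("a seed is mandatory for cohort generation")
  probs <- c(prevalence_ci, frac_undetermined, p_impaired_given_ci,
             p_intact_given_ci, p_impaired_given_cn, p_intact_given_cn, p_adl,
             p_icd_given_ci, p_med_given_ci, p_icd_given_cn, p_med_given_cn,
             confounder_frac_cn, no_show_rate, cancellation_rate)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (prevalence_ci + frac_undetermined > 1) {
    stop("prevalence_ci + frac_undetermined must not exceed 1")
  }
  if (n_patients < 0) stop("n_patients must be non-negative")
  cfg <- as.list(environment())
  if (template == "aco") {
    cfg$age_mean <- 78.8; cfg$age_sd <- 7.4
    cfg$period_start <- as.Date("2017-01-01"); cfg$period_end <- as.Date("2018-12-31")
  } else {
    cfg$age_mean <- 52.6; cfg$age_sd <- 15
    cfg$period_start <- as.Date("2019-01-01"); cfg$period_end <- as.Date("2020-12-31")
  }
  structure(cfg, class = "cohort_config")
}

random_dates <- function(n, start, end) {
  span <- as.integer(end - start)
  start + sample.int(span + 1L, n, replace = TRUE) - 1L
}

make_note_text <- function(kind) {
  body <- sample(NEUTRAL_SENTENCES, 2L)
  extra <- switch(kind,
    impaired = sample(IMPAIRED_SENTENCES, 1L),
    intact = sample(INTACT_SENTENCES, 1L),
    adl_impaired = sample(ADL_IMPAIRED_SENTENCES, 1L),
    adl_intact = sample(ADL_INTACT_SENTENCES, 1L),
    neutral = sample(NEUTRAL_SENTENCES, 1L)
  )
  paste(c(body[1L], extra, body[2L]), collapse = " ")
}

generate_patient <- function(pid, truth, cfg) {
  start <- cfg$period_start
  end <- cfg$period_end
  age <- max(20, stats::rnorm(1, cfg$age_mean, cfg$age_sd))
  birth <- end - round(age * 365.25) - sample.int(364L, 1L)
  patient <- data.frame(
    patient_id = pid,
    birth_date = birth,
    sex = sample(c("male", "female"), 1L),
    ethnic_group = sample(c("white", "black", "hispanic", "asian", "indigenous",
                            "other", "missing"),
                          1L, prob = c(0.55, 0.15, 0.13, 0.05, 0.01, 0.06, 0.05)),
    marital_status = sample(MARITAL_LEVELS, 1L, prob = c(0.45, 0.5, 0.05)),
    education = sample(EDUCATION_LEVELS, 1L, prob = c(0.35, 0.55, 0.1)),
    pcp_id = if (stats::runif(1) < 0.8) sprintf("pcp%03d", sample.int(40L, 1L)) else NA_character_,
    care_coordination_note = NA_character_,
    stringsAsFactors = FALSE
  )

  n_notes <- if (truth == "undetermined") sample(1:2, 1L) else
    cfg$notes_min + stats::rpois(1, cfg$notes_lambda)
  note_dates <- sort(random_dates(n_notes, start, end))
  kinds <- character(n_notes)
  for (i in seq_len(n_notes)) {
    kinds[i] <- if (truth == "CI") {
      if (stats::runif(1) < cfg$p_impaired_given_ci) "impaired"
      else if (stats::runif(1) < cfg$p_intact_given_ci) "intact"
      else if (stats::runif(1) < cfg$p_adl) "adl_impaired"
      else "neutral"
    } else if (truth == "CN") {
      if (stats::runif(1) < cfg$p_impaired_given_cn) "impaired"
      else if (stats::runif(1) < cfg$p_intact_given_cn) "intact"
      else if (stats::runif(1) < cfg$p_adl) "adl_intact"
      else "neutral"
    } else "neutral"
  }
  confounder <- truth == "CN" && n_notes >= 2L &&
    stats::runif(1) < cfg$confounder_frac_cn
  if (confounder) {
    # transient early deficit later adjudicated normal: first note impaired,
    # last note explicitly intact
    kinds[1L] <- "impaired"
    kinds[n_notes] <- "intact"
  }
  notes <- data.frame(
    note_id = sprintf("%s-n%03d", pid, seq_len(n_notes)),
    patient_id = pid,
    date = note_dates,
    reason_for_visit = "follow up",
    text = unname(vapply(kinds, make_note_text, "")),
    encounter_type = "office visit",
    provider_department = "internal medicine",
    provider_specialty = if (truth == "CI") "geriatrics" else "primary care",
    provider_qualifications = "MD",
    stringsAsFactors = FALSE
  )

  n_enc <- 1L + stats::rpois(1, if (truth == "undetermined") 2 else cfg$encounter_lambda)
  encounters <- data.frame(
    encounter_id = sprintf("%s-e%03d", pid, seq_len(n_enc)),
    patient_id = pid,
    date = random_dates(n_enc, start, end),
    status = sample(ENCOUNTER_STATUS, n_enc, replace = TRUE,
                    prob = c(1 - cfg$no_show_rate - cfg$cancellation_rate,
                             cfg$no_show_rate, cfg$cancellation_rate)),
    kind = "ambulatory",
    stringsAsFactors = FALSE
  )

  meds <- data.frame(
    patient_id = pid,
    name = sample(BACKGROUND_MEDS, sample(1:3, 1L)),
    date = as.Date(NA),
    current = TRUE,
    stringsAsFactors = FALSE
  )
  p_med <- if (truth == "CI") cfg$p_med_given_ci else if (truth == "CN") cfg$p_med_given_cn else 0
  if (stats::runif(1) < p_med) {
    meds <- rbind(meds, data.frame(patient_id = pid,
                                   name = sample(DEMENTIA_MEDS, 1L),
                                   date = random_dates(1L, start, end),
                                   current = TRUE, stringsAsFactors = FALSE))
  }

  dx_bg <- BACKGROUND_ICD[sample.int(nrow(BACKGROUND_ICD), sample(1:3, 1L)), , drop = FALSE]
  diagnoses <- data.frame(patient_id = pid, code = dx_bg$code, system = dx_bg$system,
                          description = dx_bg$description,
                          date = random_dates(nrow(dx_bg), start, end),
                          stringsAsFactors = FALSE)
  p_icd <- if (truth == "CI") cfg$p_icd_given_ci else if (truth == "CN") cfg$p_icd_given_cn else 0
  if (stats::runif(1) < p_icd) {
    dx <- DEMENTIA_ICD[sample.int(nrow(DEMENTIA_ICD), 1L), , drop = FALSE]
    diagnoses <- rbind(diagnoses, data.frame(patient_id = pid, code = dx$code,
                                             system = dx$system,
                                             description = dx$description,
                                             date = random_dates(1L, start, end),
                                             stringsAsFactors = FALSE))
  }

  labs <- empty_table("labs")
  if (stats::runif(1) < 0.3) {
    labs <- data.frame(patient_id = pid,
                       test_name = c("TSH", "Vitamin B12"),
                       value = c(sprintf("%.2f", stats::runif(1, 0.5, 4.5)),
                                 sprintf("%.0f", stats::runif(1, 200, 900))),
                       units = c("uIU/mL", "pg/mL"),
                       date = random_dates(2L, start, end),
                       stringsAsFactors = FALSE)
  }

  imaging <- empty_table("imaging")
  if (stats::runif(1) < 0.15) {
    imaging <- data.frame(patient_id = pid,
                          modality = sample(c("MRI", "CT"), 1L),
                          body_site = "brain",
                          date = random_dates(1L, start, end),
                          stringsAsFactors = FALSE)
  }

  n_refill <- stats::rpois(1, if (truth == "undetermined") 0.5 else cfg$refill_lambda)
  refills <- if (n_refill > 0L) {
    data.frame(patient_id = pid, date = random_dates(n_refill, start, end),
               medication_name = sample(BACKGROUND_MEDS, n_refill, replace = TRUE),
               stringsAsFactors = FALSE)
  } else empty_table("refills")

  patient_chart(patient, notes = notes, encounters = encounters,
                medications = meds, diagnoses = diagnoses, labs = labs,
                imaging = imaging, refills = refills,
                period_start = start, period_end = end)
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Draws each patient's true status from
#' (CI, undetermined, CN) = (`prevalence_ci`, `frac_undetermined`, rest),
#' then generates a chart consistent with that status: CI patients emit
#' impaired-keyword sentences and carry dementia ICD codes/medications at
#' the configured rates; CN patients emit intact-keyword and wellness
#' text (with a configurable transient-deficit confounder); undetermined
#' patients get sparse, evidence-free charts. Ground-truth labels are
#' returned separately and never written into the charts themselves.
#'
#' @param config a [cohort_config()].
#' @return list(charts = `chart_bundle`-style list, truth = data.frame of
#'   patient_id and true_label).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  if (n == 0L) {
    return(list(charts = structure(list(), class = "chart_bundle",
                                   rejects = data.frame(), manifest = list()),
                truth = data.frame(patient_id = character(0),
                                   true_label = character(0),
                                   stringsAsFactors = FALSE)))
  }
  with_seed(config$seed, {
    truth <- sample(c("CI", "undetermined", "CN"), n, replace = TRUE,
                    prob = c(config$prevalence_ci, config$frac_undetermined,
                             1 - config$prevalence_ci - config$frac_undetermined))
    ids <- sprintf("p%05d", seq_len(n))
    charts <- lapply(seq_len(n), function(i) generate_patient(ids[i], truth[i], config))
    names(charts) <- ids
    list(charts = structure(charts, class = "chart_bundle",
                            rejects = data.frame(table = character(0),
                                                 row = integer(0),
                                                 reason = character(0),
                                                 stringsAsFactors = FALSE),
                            manifest = list()),
         truth = data.frame(patient_id = ids, true_label = truth,
                            stringsAsFactors = FALSE))
  })
}

#' Generate a paired timing study
#'
#' Simulates paired (tool, manual) adjudication times with a configurable
#' multiplicative speed-up and log-normal noise: tool times are log-normal
#' and `manual = tool * speedup * exp(N(0, noise_sdlog))`.
#'
#' @param n_pairs number of patients timed with both methods.
#' @param speedup multiplicative manual/tool time ratio (1 = no effect).
#' @param seed integer seed.
#' @param tool_meanlog,tool_sdlog log-normal parameters of the tool time
#'   in minutes.
#' @param noise_sdlog standard deviation of the log-ratio noise.
#' @return data.frame with patient_id, tool_min, manual_min.
#' @export
generate_timing_study <- function(n_pairs = 32L, speedup = 2.2, seed,
                                  tool_meanlog = log(1.2), tool_sdlog = 0.4,
                                  noise_sdlog = 0.5) {
  stopifnot(n_pairs >= 1L)
  if (missing(seed)) stop("a seed is mandatory for timing-study generation")
  with_seed(seed, {
    tool <- stats::rlnorm(n_pairs, tool_meanlog, tool_sdlog)
    manual <- tool * speedup * exp(stats::rnorm(n_pairs, 0, noise_sdlog))
    data.frame(patient_id = sprintf("t%04d", seq_len(n_pairs)),
               tool_min = tool, manual_min = manual,
               stringsAsFactors = FALSE)
  })
}
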