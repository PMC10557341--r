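# Outcome derivation: incident vs prevalent acute myocardial infarction
# (AMI) and follow-up time from diagnosis and mortality records.

#' Match ICD codes for acute myocardial infarction
#'
#' AMI is identified by ICD-9 code 410 and ICD-10 codes I21 and I22.
#' Matching is by prefix on the normalized code (upper-cased, dots and
#' whitespace stripped), so "I21.4" and "i214" both match.
#'
#' @param code Character vector of ICD-9/ICD-10 codes.
#' @return Logical vector.
#' @examples
#' is_ami_code(c("I21.4", "410", "I50", "I22"))
#' @export
is_ami_code <- function(code) {
  if (any(is.na(code) | !nzchar(trimws(code)))) {
    abort("Malformed (empty or NA) diagnosis code.")
  }
  norm <- gsub("[.[:space:]]", "", toupper(code))
  startsWith(norm, "410") | startsWith(norm, "I21") | startsWith(norm, "I22")
}

#' Derive outcome status and follow-up time for one participant
#'
#' Follow-up runs from enrolment until the first AMI hospitalization or AMI
#' death, death from another cause, or the administrative end of follow-up,
#' whichever comes first. An AMI-matching record dated on or before the
#' enrolment date makes the participant a prevalent case (to be excluded
#' from analysis); the first AMI-matching record after enrolment is the
#' incident event. An AMI-coded death with no prior hospital record counts
#' as the incident event on the death date.
#'
#' @param enrolment_date Enrolment date (`Date` or parseable string).
#' @param diagnoses Tibble of diagnosis records with columns `code`, `date`
#'   and optionally `source`; may have zero rows.
#' @param death_date Date of death or `NULL`/`NA`.
#' @param death_cause_code Underlying-cause ICD code for the death, or
#'   `NULL`/`NA`.
#' @param end_of_followup_date Administrative end of follow-up.
#'
#' @return A one-row tibble with `status` (`"prevalent"`, `"incident"`,
#'   `"censored"`), `time` (years from enrolment) and `event` (0/1).
#'   Prevalent cases get `time = 0`, `event = 0` and must be excluded before
#'   modelling; they are flagged, never silently dropped.
#' @examples
#' derive_followup("2008-01-01",
#'                 tibble::tibble(code = "I21.4", date = "2010-01-01"),
#'                 end_of_followup_date = "2021-03-23")
#' @export
derive_followup <- function(enrolment_date, diagnoses = NULL,
                            death_date = NULL, death_cause_code = NULL,
                            end_of_followup_date) {
  enrol <- as.Date(enrolment_date)
  end <- as.Date(end_of_followup_date)
  if (is.na(enrol) || is.na(end)) abort("Dates must be parseable.")
  if (end < enrol) abort("End of follow-up precedes enrolment.")
  death <- if (is.null(death_date) || all(is.na(death_date))) {
    as.Date(NA)
  } else {
    as.Date(death_date)
  }

  ami_dates <- as.Date(character(0))
  if (!is.null(diagnoses) && nrow(diagnoses) > 0L) {
    check_columns(diagnoses, c("code", "date"), "diagnoses")
    hit <- is_ami_code(diagnoses$code)
    ami_dates <- as.Date(diagnoses$date)[hit]
  }
  if (!is.na(death) && !is.null(death_cause_code) &&
      !all(is.na(death_cause_code)) && any(is_ami_code(death_cause_code))) {
    ami_dates <- c(ami_dates, death)
  }

  years <- function(d) as.numeric(d - enrol) / 365.25

  # A diagnosis on the enrolment date itself counts as prevalent
  # (conservative tie-break); prevalent status wins over any later record.
  if (length(ami_dates) > 0L && min(ami_dates) <= enrol) {
    return(tibble(status = "prevalent", time = 0, event = 0L))
  }
  if (length(ami_dates) > 0L) {
    first_ami <- min(ami_dates)
    stop_at <- min(first_ami, death, end, na.rm = TRUE)
    if (first_ami <= stop_at) {
      return(tibble(status = "incident", time = years(first_ami), event = 1L))
    }
  }
  stop_at <- min(death, end, na.rm = TRUE)
  tibble(status = "censored", time = years(stop_at), event = 0L)
}

#' Derive outcomes for a whole cohort
#'
#' Applies [derive_followup()] per participant, joining long-format
#' diagnosis records (`sample_id`, `code`, `date`, optionally `source`) and
#' optional mortality columns in the phenotype table.
#'
#' @param phenotypes Tibble with `sample_id`, `enrolment_date` and optional
#'   `death_date`, `death_cause_code` columns.
#' @param diagnoses Long-format diagnosis tibble (may be empty).
#' @param end_of_followup_date Administrative end of follow-up, fixed for
#'   the run.
#' @return `phenotypes` with `status`, `time` and `event` columns appended.
#' @export
derive_followup_tbl <- function(phenotypes, diagnoses,
                                end_of_followup_date) {
  check_columns(phenotypes, c("sample_id", "enrolment_date"), "phenotypes")
  if (nrow(diagnoses) > 0L) {
    check_columns(diagnoses, c("sample_id", "code", "date"), "diagnoses")
  }
  by_id <- split(diagnoses, factor(diagnoses$sample_id,
                                   levels = phenotypes$sample_id))
  res <- purrr::pmap(
    list(
      phenotypes$enrolment_date,
      by_id[phenotypes$sample_id],
      phenotypes[["death_date"]] %||% rep(NA, nrow(phenotypes)),
      phenotypes[["death_cause_code"]] %||% rep(NA, nrow(phenotypes))
    ),
    function(enrol, dx, dd, dc) {
      derive_followup(enrol, dx, dd, dc, end_of_followup_date)
    }
  )
  dplyr::bind_cols(phenotypes, dplyr::bind_rows(res))
}

#' Participant-flow arithmetic under the prevalent-exclusion rule
#'
#' Given the number of genotyped participants with phenotype data, the
#' number ever diagnosed with the outcome, and the number of prevalent cases
#' among them, returns the analysis sample size, incident case count
#' (ever-diagnosed minus prevalent; diagnosis counts are conserved) and
#' incidence percentages relative to both the genotyped total and the
#' analysis sample.
#'
#' @param n_total Participants passing genetic QC with phenotype data.
#' @param n_ever_diagnosed Participants ever diagnosed with the outcome.
#' @param n_prevalent Prevalent cases (diagnosed before enrolment).
#' @return A one-row tibble with `analysis_n`, `incident`,
#'   `incident_pct_of_total` and `incident_pct_of_analysis`.
#' @examples
#' participant_flow(336262, 11399, 3586)
#' @export
participant_flow <- function(n_total, n_ever_diagnosed, n_prevalent) {
  check_scalar_number(n_total, "n_total", lower = 1)
  check_scalar_number(n_ever_diagnosed, "n_ever_diagnosed", lower = 0,
                      upper = n_total)
  check_scalar_number(n_prevalent, "n_prevalent", lower = 0,
                      upper = n_ever_diagnosed)
  analysis_n <- n_total - n_prevalent
  incident <- n_ever_diagnosed - n_prevalent
  tibble(
    analysis_n = analysis_n,
    incident = incident,
    incident_pct_of_total = 100 * incident / n_total,
    incident_pct_of_analysis = 100 * incident / analysis_n
  )
}
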