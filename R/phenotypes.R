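# Questionnaire-derived sleep phenotypes. Each classifier is total on its
# declared response vocabulary, vectorized, and returns "yes"/"no"/NA
# ("missing"); an undeclared response string is an error naming the value.

tristate <- function(yes, no) {
  out <- rep(NA_character_, length(yes))
  out[no] <- "no"
  out[yes] <- "yes"
  out
}

check_vocab <- function(x, vocab, what) {
  bad <- setdiff(unique(x[!is.na(x)]), vocab)
  if (length(bad) > 0L) {
    abort(sprintf("Unknown %s response: %s", what,
                  paste0('"', bad, '"', collapse = ", ")))
  }
  invisible(x)
}

#' Classify insomnia symptoms from the UK Biobank-style question
#'
#' Responses to "Do you have trouble falling asleep at night or do you wake
#' up in the middle of the night?" are classified as insomnia symptoms when
#' "Usually", no symptoms for "Never/rarely" or "Sometimes", and missing
#' otherwise ("Prefer not to answer" or an absent answer).
#'
#' @param response Character vector of responses (NA allowed).
#' @return Character vector with values `"yes"`, `"no"` or `NA`.
#' @examples
#' classify_insomnia_ukbb(c("Usually", "Sometimes", "Prefer not to answer"))
#' @export
classify_insomnia_ukbb <- function(response) {
  vocab <- c("Never/rarely", "Sometimes", "Usually", "Prefer not to answer")
  check_vocab(response, vocab, "insomnia")
  tristate(yes = !is.na(response) & response == "Usually",
           no = !is.na(response) & response %in% c("Never/rarely", "Sometimes"))
}

#' Classify insomnia symptoms from the two HUNT2-style questions
#'
#' Two night-time symptom questions (difficulty falling asleep; waking too
#' early) with responses "Never", "Sometimes", "Often", "Almost every night".
#' A participant has insomnia symptoms if either answer is "Often" or
#' "Almost every night" (even if the other question is unanswered). A single
#' benign answer ("Never"/"Sometimes") with the other question unanswered is
#' coded missing, to avoid misclassifying someone whose unanswered symptom
#' may be present. Both answered and neither often: no symptoms. Both absent:
#' missing.
#'
#' @param q_fall_asleep,q_wake_early Character vectors of responses (NA =
#'   unanswered).
#' @return Character vector with values `"yes"`, `"no"` or `NA`.
#' @examples
#' classify_insomnia_hunt2("Often", NA)        # yes
#' classify_insomnia_hunt2("Sometimes", NA)    # missing (excluded)
#' classify_insomnia_hunt2("Never", "Sometimes") # no
#' @export
classify_insomnia_hunt2 <- function(q_fall_asleep, q_wake_early) {
  vocab <- c("Never", "Sometimes", "Often", "Almost every night")
  check_vocab(q_fall_asleep, vocab, "insomnia (falling asleep)")
  check_vocab(q_wake_early, vocab, "insomnia (waking early)")
  n <- max(length(q_fall_asleep), length(q_wake_early))
  a <- rep_len(q_fall_asleep, n)
  b <- rep_len(q_wake_early, n)
  often <- function(x) !is.na(x) & x %in% c("Often", "Almost every night")
  yes <- often(a) | often(b)
  no <- !yes & !is.na(a) & !is.na(b)
  tristate(yes = yes, no = no)
}

#' Derive sleep-duration variables from reported hours
#'
#' Reported 24-hour sleep (integer hours) is cleaned by dropping implausible
#' extremes (< 3 or > 18 hours), then dichotomized into short sleep
#' (<= 6 h vs 7-8 h) and long sleep (>= 9 h vs 7-8 h). Each binary contrast
#' excludes the other tail: a short sleeper is missing in the long-sleep
#' contrast and vice versa, so `short` and `long` are never both `"yes"`.
#'
#' @param hours Integer vector of reported hours (NA allowed).
#' @return A tibble with columns `duration` (integer or NA), `short` and
#'   `long` (`"yes"`/`"no"`/NA).
#' @examples
#' derive_sleep_duration_vars(c(2, 6, 7, 9))
#' @export
derive_sleep_duration_vars <- function(hours) {
  if (any(!is.na(hours) & hours != as.integer(hours))) {
    abort("`hours` must contain integer values (questionnaire responses).")
  }
  hours <- as.integer(hours)
  dur <- ifelse(!is.na(hours) & (hours < 3L | hours > 18L), NA_integer_, hours)
  normal <- !is.na(dur) & dur >= 7L & dur <= 8L
  short <- tristate(yes = !is.na(dur) & dur <= 6L, no = normal)
  long <- tristate(yes = !is.na(dur) & dur >= 9L, no = normal)
  tibble(duration = dur, short = short, long = long)
}

#' Classify chronotype from the UK Biobank-style question
#'
#' "Do you consider yourself to be?" with six options; the two morning
#' options code `"yes"` (morning chronotype), the two evening options
#' `"no"`, and "Do not know" / "Prefer not to answer" missing.
#'
#' @param response Character vector of responses (NA allowed).
#' @return Character vector with values `"yes"` (morning), `"no"` (evening)
#'   or `NA`.
#' @examples
#' classify_chronotype_ukbb("Definitely a 'morning' person")
#' @export
classify_chronotype_ukbb <- function(response) {
  morning <- c("Definitely a 'morning' person",
               "More a 'morning' than 'evening' person")
  evening <- c("More an 'evening' than a 'morning' person",
               "Definitely an 'evening' person")
  other <- c("Do not know", "Prefer not to answer")
  # Accept typographic quotes as they appear in questionnaire exports.
  canon <- function(x) gsub("[‘’]", "'", x)
  response <- canon(response)
  check_vocab(response, c(morning, evening, other), "chronotype")
  tristate(yes = !is.na(response) & response %in% morning,
           no = !is.na(response) & response %in% evening)
}
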