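#' Apply subject exclusion rules
#'
#' Drops subjects who were pregnant and/or lactating, whose dietary recall
#' was incomplete or unreliable, or whose age falls outside 6-18 years.
#' Reasons are tallied with a fixed precedence — pregnancy/lactation first,
#' then unreliable recall, then age — so a subject failing several rules is
#' counted exactly once and the tally sums to the number excluded.
#'
#' @param subjects Subject table (see [read_subjects()]).
#' @return A list with `kept` (the eligible subject tibble) and `tally`, a
#'   named integer vector over reasons `pregnant_or_lactating`,
#'   `unreliable_recall`, `age_out_of_range`.
#' @export
apply_exclusions <- function(subjects) {
  preg <- subjects$pregnant_or_lactating
  unreliable <- !subjects$recall_reliable
  age_bad <- subjects$age_years < 6 | subjects$age_years > 18
  kept <- !preg & !unreliable & !age_bad
  tally <- c(
    pregnant_or_lactating = sum(preg),
    unreliable_recall = sum(unreliable & !preg),
    age_out_of_range = sum(age_bad & !preg & !unreliable)
  )
  list(kept = subjects[kept, , drop = FALSE], tally = tally)
}
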