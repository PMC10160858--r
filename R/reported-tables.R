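#' Published raw prediction counts from the COMSA Mozambique VA analysis
#'
#' Per-algorithm counts of predicted broad causes among the complete-case
#' COMSA verbal-autopsy records (1,589 child deaths aged 1-59 months after
#' excluding 252 with inconclusive expert-algorithm diagnoses out of 1,841;
#' 632 neonatal deaths after excluding 186 out of 818), as published by the
#' study. These counts are inputs for reproducing the raw CSMF tables; the
#' underlying record-level data are not public.
#'
#' @inheritParams builtin_cause_list
#' @return A list with `causes` (the [builtin_cause_list()]), `counts`
#'   (named list of per-algorithm integer count vectors in canonical cause
#'   order), `n` (records after exclusion), `n_total` (before exclusion) and
#'   `n_inconclusive` (excluded records).
#' @export
comsa_raw_counts <- function(age_group = c("child", "neonate")) {
  age_group <- match.arg(age_group)
  causes <- builtin_cause_list(age_group)
  if (age_group == "child") {
    # order: pneumonia, malaria, diarrhea, severe malnutrition, hiv,
    #        other infections, other
    counts <- list(
      insilicova = c(251L, 303L, 399L, 74L, 58L, 376L, 128L),
      eava       = c(342L, 134L, 308L, 98L, 125L, 483L, 99L))
    n_total <- 1841L; n_excl <- 252L
  } else {
    # order: congenital malformation, infection, ipre, prematurity, other
    counts <- list(
      insilicova = c(1L, 290L, 161L, 168L, 12L),
      eava       = c(28L, 333L, 132L, 118L, 21L))
    n_total <- 818L; n_excl <- 186L
  }
  counts <- lapply(counts, function(x) stats::setNames(x, causes$labels))
  n <- sum(counts[[1]])
  stopifnot(n == n_total - n_excl, sum(counts[[2]]) == n)
  list(causes = causes, counts = counts, n = n, n_total = n_total,
       n_inconclusive = n_excl)
}

#' Raw CSMFs implied by the published count tables
#'
#' Convenience wrapper turning [comsa_raw_counts()] into per-algorithm
#' [csmf] objects plus their equally weighted (uncalibrated ensemble)
#' average.
#'
#' @inheritParams builtin_cause_list
#' @return Named list of [csmf]: one per algorithm plus `ensemble`.
#' @export
comsa_raw_csmfs <- function(age_group = c("child", "neonate")) {
  tab <- comsa_raw_counts(age_group)
  out <- lapply(tab$counts, function(ct) {
    csmf(ct / tab$n, tab$causes, counts = ct)
  })
  out$ensemble <- ensemble_uncalibrated(out)
  out
}
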