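#' Ordered list of broad cause-of-death categories
#'
#' A `cause_list` fixes the set of broad causes and, crucially, their order:
#' every CSMF vector and every misclassification matrix in the package indexes
#' causes by this order, so raw estimates, posterior draws and output tables
#' stay column-compatible across runs.
#'
#' @param labels Character vector of distinct, non-empty cause names.
#' @return An object of class `cause_list` with elements `labels` and `C`.
#' @export
cause_list <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) < 2L) {
    stop("a cause list needs at least two causes", call. = FALSE)
  }
  if (anyNA(labels) || any(!nzchar(trimws(labels)))) {
    stop("cause labels must be non-empty strings", call. = FALSE)
  }
  if (anyDuplicated(canonical_label(labels))) {
    stop("cause labels must be unique (case/whitespace-insensitively)",
         call. = FALSE)
  }
  structure(list(labels = labels, C = length(labels)), class = "cause_list")
}

#' @export
print.cause_list <- function(x, ...) {
  cat("Cause list (", x$C, " broad causes):\n  ", sep = "")
  cat(paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.cause_list <- function(x) x$C

# Matching key: causes are compared case-insensitively after trimming.
canonical_label <- function(x) tolower(trimws(x))

#' Built-in broad cause lists for the two supported age groups
#'
#' Children aged 1-59 months use seven broad causes; neonates use five.
#' The order returned here is the canonical index order used everywhere
#' downstream.
#'
#' @param age_group `"child"` (1-59 months) or `"neonate"`.
#' @return A [cause_list].
#' @examples
#' builtin_cause_list("child")
#' builtin_cause_list("neonate")
#' @export
builtin_cause_list <- function(age_group = c("child", "neonate")) {
  if (!is.character(age_group) ||
      !all(age_group %in% c("child", "neonate")) || length(age_group) < 1L) {
    stop("unknown age_group; supported values are \"child\" and \"neonate\"",
         call. = FALSE)
  }
  age_group <- match.arg(age_group)
  switch(age_group,
    child = cause_list(c("pneumonia", "malaria", "diarrhea",
                         "severe malnutrition", "hiv",
                         "other infections", "other")),
    neonate = cause_list(c("congenital malformation", "infection", "ipre",
                           "prematurity", "other"))
  )
}

#' Fine-to-broad cause map
#'
#' Maps fine-grained cause names (the vocabulary of a CCVA algorithm) onto a
#' broad [cause_list]. Matching of both fine and broad names is
#' case-insensitive after whitespace trimming.
#'
#' @param entries Named character vector: names are fine causes, values are
#'   broad causes that must all belong to `target`.
#' @param target The broad [cause_list] mapped into.
#' @return An object of class `cause_map`.
#' @export
cause_map <- function(entries, target) {
  stopifnot(inherits(target, "cause_list"))
  if (is.null(names(entries)) || any(!nzchar(names(entries)))) {
    stop("`entries` must be a named character vector (fine -> broad)",
         call. = FALSE)
  }
  broad <- match_cause(unname(entries), target, context = "cause map value")
  ent <- stats::setNames(target$labels[broad], canonical_label(names(entries)))
  if (anyDuplicated(names(ent))) {
    stop("duplicate fine-cause entries in map", call. = FALSE)
  }
  structure(list(entries = ent, target = target), class = "cause_map")
}

# Resolve labels against a cause list; returns integer indices.
# Unmatched labels -> error listing them (prefixed by `context`).
match_cause <- function(labels, causes, context = "cause label") {
  idx <- match(canonical_label(labels), canonical_label(causes$labels))
  if (anyNA(idx)) {
    bad <- unique(labels[is.na(idx)])
    stop(sprintf("%s(s) not in cause list: %s", context,
                 paste(shQuote(bad), collapse = ", ")), call. = FALSE)
  }
  idx
}

#' Default fine-to-broad maps for the built-in cause lists
#'
#' Covers the broad labels themselves (identity) plus the fine causes the
#' study names for each broad category: for children, meningitis, typhoid
#' fever and hepatitis fold into "other infections" and cancer, injury and
#' congenital malformation into "other"; for neonates, neonatal tetanus,
#' meningitis and encephalitis, diarrhea, pneumonia and sepsis fold into
#' "infection" and injury into "other". CCVA vocabularies are larger than
#' this; extend via [read_cause_map()] for real outputs.
#'
#' @inheritParams builtin_cause_list
#' @return A [cause_map] onto [builtin_cause_list()] for the age group.
#' @export
default_cause_map <- function(age_group = c("child", "neonate")) {
  age_group <- match.arg(age_group)
  target <- builtin_cause_list(age_group)
  identity <- stats::setNames(target$labels, target$labels)
  extra <- switch(age_group,
    child = c("meningitis"              = "other infections",
              "typhoid fever"           = "other infections",
              "hepatitis"               = "other infections",
              "cancer"                  = "other",
              "injury"                  = "other",
              "congenital malformation" = "other"),
    neonate = c("neonatal tetanus"          = "infection",
                "meningitis and encephalitis" = "infection",
                "diarrhea"                  = "infection",
                "pneumonia"                 = "infection",
                "sepsis"                    = "infection",
                "injury"                    = "other")
  )
  cause_map(c(identity, extra), target)
}

#' Apply a cause map to a vector of fine cause labels
#'
#' @param labels Character vector of fine cause names; `NA` entries pass
#'   through as `NA` (missing predictions stay missing).
#' @param map A [cause_map].
#' @return Character vector of broad cause names, same length and order.
#' @export
apply_cause_map <- function(labels, map) {
  stopifnot(inherits(map, "cause_map"))
  out <- rep(NA_character_, length(labels))
  live <- !is.na(labels)
  key <- canonical_label(labels[live])
  hit <- match(key, names(map$entries))
  if (anyNA(hit)) {
    bad <- unique(labels[live][is.na(hit)])
    stop("fine cause(s) without a map entry: ",
         paste(shQuote(bad), collapse = ", "), call. = FALSE)
  }
  out[live] <- unname(map$entries[hit])
  out
}

#' Read a fine-to-broad cause map from a two-column CSV
#'
#' Expected columns: `fine_cause`, `broad_cause` (header mandatory).
#'
#' @param path CSV path.
#' @param target Broad [cause_list] the map must land in.
#' @return A [cause_map].
#' @export
read_cause_map <- function(path, target) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("fine_cause", "broad_cause")
  if (!all(need %in% names(df))) {
    stop("cause map file must have columns fine_cause, broad_cause",
         call. = FALSE)
  }
  cause_map(stats::setNames(df$broad_cause, df$fine_cause), target)
}
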