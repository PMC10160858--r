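#' Unpaired verbal-autopsy dataset (surveillance role)
#'
#' One row per death with a predicted broad cause per CCVA algorithm and no
#' reference cause. Missing predictions (an algorithm's "inconclusive"
#' outcome) are `NA`.
#'
#' @param death_id Character vector of unique record identifiers.
#' @param predictions Data frame (or list coercible to one) with one column
#'   per algorithm; entries are broad cause names or `NA`.
#' @param algorithms Character vector naming the prediction columns, in order.
#' @param causes The [cause_list] predictions are validated against.
#' @return An object of class `va_unpaired` (and `va_dataset`).
#' @export
unpaired_dataset <- function(death_id, predictions, algorithms, causes) {
  new_va_dataset(death_id, predictions, algorithms, causes,
                 reference = NULL, class = "va_unpaired")
}

#' Paired verbal-autopsy dataset (reference-standard role)
#'
#' Like [unpaired_dataset()] but every record additionally carries a
#' never-missing reference cause (e.g. a MITS-determined cause of death).
#'
#' @inheritParams unpaired_dataset
#' @param reference_cause Character vector of broad reference causes, one per
#'   record, no missing values.
#' @return An object of class `va_paired` (and `va_dataset`).
#' @export
paired_dataset <- function(death_id, reference_cause, predictions, algorithms,
                           causes) {
  new_va_dataset(death_id, predictions, algorithms, causes,
                 reference = reference_cause, class = "va_paired")
}

new_va_dataset <- function(death_id, predictions, algorithms, causes,
                           reference, class) {
  stopifnot(inherits(causes, "cause_list"))
  algorithms <- as.character(algorithms)
  if (length(algorithms) < 1L || anyDuplicated(algorithms)) {
    stop("need at least one uniquely named algorithm", call. = FALSE)
  }
  death_id <- as.character(death_id)
  if (anyNA(death_id) || anyDuplicated(death_id)) {
    dup <- unique(death_id[duplicated(death_id)])
    stop("death_id values must be unique and non-missing",
         if (length(dup)) paste0(": duplicated ", paste(shQuote(dup),
                                                        collapse = ", ")),
         call. = FALSE)
  }
  predictions <- as.data.frame(predictions, stringsAsFactors = FALSE)
  if (!all(algorithms %in% names(predictions))) {
    stop("predictions lack a column for algorithm(s): ",
         paste(shQuote(setdiff(algorithms, names(predictions))),
               collapse = ", "), call. = FALSE)
  }
  predictions <- predictions[algorithms]
  if (nrow(predictions) != length(death_id)) {
    stop("death_id and predictions disagree on record count", call. = FALSE)
  }
  for (alg in algorithms) {
    predictions[[alg]] <- validate_labels(predictions[[alg]], causes,
                                          what = sprintf("prediction (%s)", alg),
                                          allow_missing = TRUE)
  }
  x <- list(death_id = death_id, predictions = predictions,
            algorithms = algorithms, causes = causes)
  if (!is.null(reference)) {
    x$reference_cause <- validate_labels(as.character(reference), causes,
                                         what = "reference_cause",
                                         allow_missing = FALSE)
    if (length(x$reference_cause) != length(death_id)) {
      stop("reference_cause and death_id disagree on record count",
           call. = FALSE)
    }
  }
  structure(x, class = c(class, "va_dataset"))
}

# Validate labels against a cause list, normalising to the canonical
# spelling. Errors name the offending 1-based row numbers.
validate_labels <- function(x, causes, what, allow_missing) {
  miss <- is.na(x) | !nzchar(trimws(ifelse(is.na(x), "", x)))
  if (any(miss) && !allow_missing) {
    stop(sprintf("%s is missing in row(s) %s", what,
                 paste(which(miss), collapse = ", ")), call. = FALSE)
  }
  out <- rep(NA_character_, length(x))
  if (any(!miss)) {
    idx <- match(canonical_label(x[!miss]), canonical_label(causes$labels))
    if (anyNA(idx)) {
      rows <- which(!miss)[is.na(idx)]
      stop(sprintf("unknown %s label(s) %s in row(s) %s", what,
                   paste(shQuote(unique(x[rows])), collapse = ", "),
                   paste(rows, collapse = ", ")), call. = FALSE)
    }
    out[!miss] <- causes$labels[idx]
  }
  out
}

#' @export
print.va_dataset <- function(x, ...) {
  cat(sprintf("%s dataset: %d records, %d algorithms (%s), %d causes\n",
              if (inherits(x, "va_paired")) "Paired" else "Unpaired",
              n_records(x), length(x$algorithms),
              paste(x$algorithms, collapse = ", "), x$causes$C))
  miss <- vapply(x$predictions, function(p) sum(is.na(p)), integer(1))
  if (any(miss > 0)) {
    cat("  missing predictions:",
        paste(sprintf("%s=%d", names(miss), miss), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of death records in a dataset
#' @param x A `va_dataset`.
#' @return Integer record count.
#' @export
n_records <- function(x) length(x$death_id)

# Missing cells come in as "" or the literal "NA" in either case.
read_va_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  na.strings = c("", "NA", "na"), fileEncoding = "UTF-8")
}

#' Read an unpaired dataset from CSV
#'
#' Expected columns: `death_id`, then one column per algorithm. Empty cells
#' and the literal token `NA` are read as missing predictions.
#'
#' @param path CSV path (UTF-8, comma-separated, header row).
#' @param causes [cause_list] the labels must belong to.
#' @param algorithms Algorithm column names, in the order they should be kept.
#' @return A [unpaired_dataset()].
#' @export
read_unpaired <- function(path, causes, algorithms) {
  df <- read_va_csv(path)
  require_columns(df, c("death_id", algorithms), path)
  unpaired_dataset(df$death_id, df[algorithms], algorithms, causes)
}

#' Read a paired dataset from CSV
#'
#' Expected columns: `death_id`, `reference_cause`, then one column per
#' algorithm. The reference cause must never be missing.
#'
#' @inheritParams read_unpaired
#' @return A [paired_dataset()].
#' @export
read_paired <- function(path, causes, algorithms) {
  df <- read_va_csv(path)
  require_columns(df, c("death_id", "reference_cause", algorithms), path)
  paired_dataset(df$death_id, df$reference_cause, df[algorithms],
                 algorithms, causes)
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s lacks required column(s): %s", path,
                 paste(shQuote(missing), collapse = ", ")), call. = FALSE)
  }
}

#' Write a dataset back to the CSV dialect the readers accept
#'
#' @param x A `va_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(x, path) {
  df <- as.data.frame(x)
  utf8_write_csv(df, path)
  invisible(path)
}

utf8_write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8", quote = FALSE)
}

#' @export
as.data.frame.va_dataset <- function(x, ...) {
  df <- data.frame(death_id = x$death_id, stringsAsFactors = FALSE)
  if (!is.null(x$reference_cause)) df$reference_cause <- x$reference_cause
  cbind(df, x$predictions)
}

#' Complete-case filter: drop records with inconclusive predictions
#'
#' Keeps exactly the records for which every required algorithm produced a
#' (non-missing) prediction, mirroring the exclusion of deaths with
#' inconclusive diagnoses from the analysis. The same records are dropped for
#' all algorithms so that single-algorithm and ensemble estimates remain
#' comparable.
#'
#' @param x A `va_dataset`.
#' @param algorithms_required Algorithms whose predictions must be present;
#'   defaults to all algorithms in the dataset.
#' @return A list with `dataset` (the filtered dataset, same class) and
#'   `n_excluded` (records dropped).
#' @examples
#' causes <- builtin_cause_list("neonate")
#' d <- unpaired_dataset(c("a", "b"),
#'   data.frame(eava = c("infection", NA)), "eava", causes)
#' complete_case_filter(d)$n_excluded  # 1
#' @export
complete_case_filter <- function(x, algorithms_required = x$algorithms) {
  stopifnot(inherits(x, "va_dataset"))
  if (!all(algorithms_required %in% x$algorithms)) {
    stop("algorithms_required must be a subset of the dataset's algorithms",
         call. = FALSE)
  }
  keep <- rep(TRUE, n_records(x))
  for (alg in algorithms_required) keep <- keep & !is.na(x$predictions[[alg]])
  out <- subset_records(x, keep)
  if (n_records(out) == 0L) {
    warning("complete-case filter removed every record", call. = FALSE)
  }
  list(dataset = out, n_excluded = sum(!keep))
}

subset_records <- function(x, keep) {
  x$death_id <- x$death_id[keep]
  x$predictions <- x$predictions[keep, , drop = FALSE]
  rownames(x$predictions) <- NULL
  if (!is.null(x$reference_cause)) x$reference_cause <- x$reference_cause[keep]
  x
}
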