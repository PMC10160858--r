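#' Cause-specific mortality fraction vector
#'
#' A point on the probability simplex indexed by a [cause_list]. Fractions
#' must lie in [0, 1] and sum to 1 within 1e-9.
#'
#' @param p Numeric vector of fractions, one per cause.
#' @param causes The [cause_list] giving names and order.
#' @param counts Optional integer counts behind the fractions (for reporting).
#' @return An object of class `csmf`.
#' @export
csmf <- function(p, causes, counts = NULL) {
  stopifnot(inherits(causes, "cause_list"))
  p <- as.numeric(p)
  if (length(p) != causes$C) stop("p and cause list disagree on length",
                                  call. = FALSE)
  if (any(p < -1e-12) || any(p > 1 + 1e-12) || abs(sum(p) - 1) > 1e-9) {
    stop("CSMF entries must lie in [0, 1] and sum to 1 (within 1e-9)",
         call. = FALSE)
  }
  p <- pmin(pmax(p, 0), 1)
  names(p) <- causes$labels
  structure(list(p = p, causes = causes, counts = counts), class = "csmf")
}

#' @export
print.csmf <- function(x, digits = 1, ...) {
  cat("CSMF over", x$causes$C, "causes:\n")
  print(round(100 * x$p, digits))
  invisible(x)
}

#' Format a CSMF as percentages the way study tables print them
#'
#' Internal computation is full precision; only reporting rounds.
#'
#' @param x A [csmf].
#' @param digits Decimal places on the percentage scale (default 1).
#' @return Named numeric vector of percentages.
#' @export
as_percent <- function(x, digits = 1) {
  stopifnot(inherits(x, "csmf"))
  round(100 * x$p, digits)
}

#' Raw (uncalibrated) CSMF from predicted causes
#'
#' The raw CSMF for cause j is simply the share of records whose predicted
#' cause is j: count(prediction == j) / N. Missing predictions are not
#' accepted; apply [complete_case_filter()] first.
#'
#' @param predictions Character vector of predicted broad causes.
#' @param causes [cause_list] the labels belong to.
#' @return A [csmf] with per-cause `counts` retained.
#' @examples
#' cl <- cause_list(c("a", "b", "c"))
#' raw_csmf(rep(c("a", "b", "c"), c(2, 3, 5)), cl)$p  # 0.2 0.3 0.5
#' @export
raw_csmf <- function(predictions, causes) {
  if (length(predictions) == 0L) {
    stop("cannot estimate a CSMF from zero records", call. = FALSE)
  }
  if (anyNA(predictions)) {
    stop("missing predictions; run complete_case_filter() first",
         call. = FALSE)
  }
  idx <- match_cause(predictions, causes, context = "prediction")
  counts <- tabulate(idx, nbins = causes$C)
  names(counts) <- causes$labels
  csmf(counts / length(predictions), causes, counts = counts)
}

#' Raw CSMFs for every algorithm in a dataset
#'
#' @param x A `va_dataset` with no missing predictions for the requested
#'   algorithms.
#' @param algorithms Algorithms to tabulate (default all).
#' @return Named list of [csmf], one per algorithm.
#' @export
raw_csmf_by_algorithm <- function(x, algorithms = x$algorithms) {
  stats::setNames(
    lapply(algorithms, function(a) raw_csmf(x$predictions[[a]], x$causes)),
    algorithms)
}

#' Row-stochastic misclassification matrix
#'
#' Entry (i, j) is the probability that the CCVA algorithm predicts cause j
#' for a death whose reference cause is i; the diagonal holds the
#' cause-specific sensitivities. `row_counts` records how many paired deaths
#' informed each row; rows with zero records carry a uniform placeholder
#' distribution and `row_counts == 0` flags them.
#'
#' @param M Numeric C x C matrix, rows summing to 1 (within 1e-9) wherever
#'   `row_counts > 0`.
#' @param causes The shared [cause_list].
#' @param row_counts Integer vector of per-reference-cause record counts.
#' @return An object of class `misclassification_matrix`.
#' @export
misclassification_matrix <- function(M, causes,
                                     row_counts = rep(NA_integer_, causes$C)) {
  stopifnot(inherits(causes, "cause_list"))
  M <- as.matrix(M)
  if (!all(dim(M) == causes$C)) stop("M must be C x C", call. = FALSE)
  if (any(M < -1e-12) || any(M > 1 + 1e-12)) {
    stop("misclassification rates must lie in [0, 1]", call. = FALSE)
  }
  informative <- is.na(row_counts) | row_counts > 0
  if (any(abs(rowSums(M)[informative] - 1) > 1e-9)) {
    stop("rows of M must sum to 1 (within 1e-9)", call. = FALSE)
  }
  dimnames(M) <- list(causes$labels, causes$labels)
  structure(list(M = M, causes = causes, row_counts = row_counts),
            class = "misclassification_matrix")
}

#' @export
print.misclassification_matrix <- function(x, digits = 2, ...) {
  cat("Misclassification matrix (rows = reference cause):\n")
  print(round(x$M, digits))
  if (!all(is.na(x$row_counts))) {
    cat("row counts:", paste(x$row_counts, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Estimate an algorithm's misclassification matrix from paired data
#'
#' Row i is the empirical distribution of the algorithm's predicted causes
#' among paired deaths with reference cause i. Records where the algorithm's
#' prediction is missing are dropped. Reference causes with no informative
#' record get a uniform row, flagged by `row_counts == 0` (the Bayesian
#' module instead resolves such rows through its prior).
#'
#' @param paired A [paired_dataset()].
#' @param algorithm Name of the algorithm column to tabulate.
#' @return A [misclassification_matrix].
#' @export
estimate_misclassification <- function(paired, algorithm) {
  stopifnot(inherits(paired, "va_paired"))
  if (!algorithm %in% paired$algorithms) {
    stop(sprintf("algorithm %s not in dataset (has: %s)", shQuote(algorithm),
                 paste(paired$algorithms, collapse = ", ")), call. = FALSE)
  }
  pred <- paired$predictions[[algorithm]]
  keep <- !is.na(pred)
  if (!any(keep)) {
    stop("no paired record has a prediction for this algorithm",
         call. = FALSE)
  }
  counts <- paired_crosstab(paired, algorithm)
  row_counts <- rowSums(counts)
  M <- counts / ifelse(row_counts > 0, row_counts, 1)
  M[row_counts == 0, ] <- 1 / paired$causes$C
  misclassification_matrix(M, paired$causes,
                           row_counts = as.integer(row_counts))
}

# Reference-by-predicted cross-tabulation (counts), dropping records whose
# prediction for `algorithm` is missing.
paired_crosstab <- function(paired, algorithm) {
  causes <- paired$causes
  pred <- paired$predictions[[algorithm]]
  keep <- !is.na(pred)
  ref_i <- match_cause(paired$reference_cause[keep], causes, "reference_cause")
  prd_j <- match_cause(pred[keep], causes, "prediction")
  counts <- matrix(0, causes$C, causes$C,
                   dimnames = list(causes$labels, causes$labels))
  for (r in seq_along(ref_i)) {
    counts[ref_i[r], prd_j[r]] <- counts[ref_i[r], prd_j[r]] + 1
  }
  counts
}

check_same_causes <- function(a, b) {
  if (!identical(canonical_label(a$labels), canonical_label(b$labels))) {
    stop("cause lists do not match", call. = FALSE)
  }
}

#' Forward marginal: predicted-cause distribution implied by a true CSMF
#'
#' q_j = sum_i p_i * M_ij — the distribution of predicted causes when deaths
#' with true CSMF `p` are classified by an algorithm with misclassification
#' matrix `M`. For a row-stochastic M this maps the simplex to itself.
#'
#' @param p A [csmf] (the true/calibrated CSMF).
#' @param M A [misclassification_matrix] on the same cause list.
#' @return A [csmf] of predicted-cause fractions.
#' @export
forward_marginal <- function(p, M) {
  stopifnot(inherits(p, "csmf"), inherits(M, "misclassification_matrix"))
  check_same_causes(p$causes, M$causes)
  q <- as.numeric(p$p %*% M$M)
  csmf(q / sum(q), p$causes)
}

#' Back-solve a predicted-cause distribution for the true CSMF
#'
#' Solves q = M^T p for p. With two causes and sensitivities (0.95, 0.65),
#' observed fractions (0.53, 0.47) back-solve to (0.30, 0.70). With more
#' causes the solution may leave the simplex ("absurd" negative or >100%
#' fractions); such results are returned unclipped with `feasible = FALSE` —
#' they are the motivation for the Bayesian calibration model, which keeps
#' estimates on the simplex by construction.
#'
#' @param q A [csmf] of observed predicted-cause fractions.
#' @param M A [misclassification_matrix] on the same cause list.
#' @param max_condition Condition-number bound above which the system is
#'   declared ill-conditioned (default 1e8).
#' @return A list with `p` (numeric solution, named by cause), `feasible`
#'   (TRUE iff every entry lies in [0, 1]), and `csmf` (a [csmf] when
#'   feasible, else NULL).
#' @export
backsolve_csmf <- function(q, M, max_condition = 1e8) {
  stopifnot(inherits(q, "csmf"), inherits(M, "misclassification_matrix"))
  check_same_causes(q$causes, M$causes)
  A <- t(M$M)
  if (!all(is.finite(A)) || kappa(A, exact = TRUE) > max_condition) {
    stop("misclassification matrix is singular or ill-conditioned; ",
         "use the Bayesian calibration instead", call. = FALSE)
  }
  p <- as.numeric(solve(A, q$p))
  names(p) <- q$causes$labels
  feasible <- all(p >= -1e-12) && all(p <= 1 + 1e-12)
  list(p = p, feasible = feasible,
       csmf = if (feasible) csmf(p / sum(p), q$causes) else NULL)
}

#' Equally weighted (uncalibrated) ensemble CSMF
#'
#' The entrywise mean of the per-algorithm raw CSMFs — the uncalibrated
#' ensemble estimate against which the calibrated ensemble is compared.
#'
#' @param csmfs List of [csmf] objects sharing one cause list.
#' @return A [csmf].
#' @export
ensemble_uncalibrated <- function(csmfs) {
  if (length(csmfs) < 1L) stop("need at least one CSMF", call. = FALSE)
  stopifnot(all(vapply(csmfs, inherits, logical(1), "csmf")))
  for (x in csmfs[-1]) check_same_causes(csmfs[[1]]$causes, x$causes)
  csmf(rowMeans(vapply(csmfs, function(x) x$p,
                       numeric(csmfs[[1]]$causes$C))),
       csmfs[[1]]$causes)
}

#' Write a CSMF (or several) to CSV
#'
#' Columns: cause, estimate, and count where counts are available; with a
#' named list, an extra leading `model` column.
#'
#' @param x A [csmf] or named list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_csmf <- function(x, path) {
  if (inherits(x, "csmf")) x <- list(estimate = x)
  rows <- lapply(names(x), function(nm) {
    est <- x[[nm]]
    data.frame(model = nm, cause = est$causes$labels,
               estimate = unname(est$p),
               count = if (is.null(est$counts)) NA_integer_ else
                 unname(est$counts),
               stringsAsFactors = FALSE)
  })
  utf8_write_csv(do.call(rbind, rows), path)
  invisible(path)
}

#' Write a misclassification matrix to CSV
#'
#' Columns: reference_cause, one column per predicted cause, row_count.
#'
#' @param x A [misclassification_matrix].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_misclassification <- function(x, path) {
  df <- data.frame(reference_cause = x$causes$labels, x$M,
                   row_count = x$row_counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utf8_write_csv(df, path)
  invisible(path)
}
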