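#' Configuration of the Bayesian calibration sampler
#'
#' @param n_chains Number of independent MCMC chains (>= 1).
#' @param n_iter Gibbs iterations per chain.
#' @param n_burnin Iterations discarded from the start of each chain
#'   (must be < `n_iter`).
#' @param seed Integer seed; the sampler is reproducible given the seed and
#'   config on one platform.
#' @param p_prior Dirichlet concentration for the CSMF prior; a scalar is
#'   recycled across causes. Default 1 (flat on the simplex).
#' @param M_prior_diag,M_prior_offdiag Dirichlet concentrations for each
#'   misclassification-matrix row: `M_prior_diag` on the diagonal entry,
#'   `M_prior_offdiag` elsewhere. The default (5, 0.5) shrinks rows toward
#'   the identity, so reference causes with few paired deaths default toward
#'   "the algorithm is right"; set both to 1 for a flat row prior.
#' @param credible_level Equal-tailed credible-interval level, in (0, 1).
#' @return An object of class `calibration_config`.
#' @export
calibration_config <- function(n_chains = 4L, n_iter = 10000L,
                               n_burnin = 5000L, seed = 1L,
                               p_prior = 1, M_prior_diag = 5,
                               M_prior_offdiag = 0.5,
                               credible_level = 0.95) {
  stopifnot(n_chains >= 1, n_iter >= 2, n_burnin >= 0, n_burnin < n_iter,
            all(p_prior > 0), M_prior_diag > 0, M_prior_offdiag > 0,
            credible_level > 0, credible_level < 1)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin), seed = as.integer(seed),
                 p_prior = p_prior, M_prior_diag = M_prior_diag,
                 M_prior_offdiag = M_prior_offdiag,
                 credible_level = credible_level),
            class = "calibration_config")
}

# One Dirichlet draw per row of the shape matrix (via independent gammas).
rdirichlet_rows <- function(shape) {
  g <- matrix(stats::rgamma(length(shape), shape = shape),
              nrow = nrow(shape))
  s <- rowSums(g)
  bad <- s <= 0                       # gamma underflow at tiny shapes
  if (any(bad)) {
    g[bad, ] <- 1
    s[bad] <- ncol(shape)
  }
  g / s
}

# Unique prediction patterns of a complete-case dataset.
# Returns list(A = P x K matrix of cause indices, n = counts,
#              record_pattern = per-record pattern index).
prediction_patterns <- function(x, algorithms) {
  causes <- x$causes
  idx <- vapply(algorithms,
                function(a) match_cause(x$predictions[[a]], causes,
                                        "prediction"),
                integer(n_records(x)))
  idx <- matrix(idx, nrow = n_records(x))
  key <- apply(idx, 1, paste, collapse = "\r")
  first <- !duplicated(key)
  A <- idx[first, , drop = FALSE]
  pat_of <- match(key, key[first])
  list(A = A, n = as.integer(tabulate(pat_of, nbins = sum(first))),
       record_pattern = pat_of)
}

#' Bayesian calibration of CSMFs for CCVA misclassification
#'
#' Jointly estimates the calibrated CSMF and each algorithm's
#' misclassification matrix from unpaired (predictions only) and paired
#' (reference cause + predictions) data. The generative model: each unpaired
#' death has a latent true cause z ~ Categorical(p); algorithm k's prediction
#' given z = i follows row i of its misclassification matrix M^(k),
#' conditionally independently across algorithms; paired deaths contribute
#' the same per-algorithm categorical likelihood with the reference cause in
#' place of z. Priors are Dirichlet on p and on each M row (see
#' [calibration_config()]). Fitting is a data-augmented Gibbs sampler with
#' conjugate categorical/Dirichlet updates; records sharing a prediction
#' pattern are updated jointly via multinomial draws, so cost scales with the
#' number of distinct patterns, not deaths.
#'
#' With one algorithm this is single-algorithm calibration; with several it
#' is the ensemble, which back-solves for the one CSMF that best agrees with
#' all algorithms' raw CSMFs and misclassification rates, implicitly
#' weighting the more accurate algorithms favorably.
#'
#' @param unpaired An [unpaired_dataset()]; complete cases only for the
#'   requested algorithms (run [complete_case_filter()] first).
#' @param paired A [paired_dataset()] on the same cause list; complete cases
#'   only.
#' @param algorithms Algorithms to calibrate with (default: all shared by the
#'   two datasets, in the unpaired dataset's order).
#' @param config A [calibration_config()].
#' @param fixed_p Optional CSMF (numeric vector or [csmf]) at which p is held
#'   fixed instead of being sampled — the "uncalibrated" comparator used for
#'   model comparison; M is still sampled.
#' @return A `csmf_posterior`: pooled post-burn-in draws of p (`draws`,
#'   S x C), per-algorithm M draws (`M_draws`, S x C x C arrays), posterior
#'   mean (`point`), equal-tailed credible bounds (`interval`), chain and
#'   iteration indices, and bookkeeping (`algorithms`, `config`,
#'   `prior_driven` flags).
#' @export
run_calibration <- function(unpaired, paired,
                            algorithms = intersect(unpaired$algorithms,
                                                   paired$algorithms),
                            config = calibration_config(),
                            fixed_p = NULL) {
  stopifnot(inherits(unpaired, "va_unpaired"), inherits(paired, "va_paired"),
            inherits(config, "calibration_config"))
  check_same_causes(unpaired$causes, paired$causes)
  if (length(algorithms) < 1L) stop("no algorithm requested", call. = FALSE)
  for (d in list(unpaired, paired)) {
    if (!all(algorithms %in% d$algorithms)) {
      stop("algorithm(s) absent from a dataset: ",
           paste(shQuote(setdiff(algorithms, d$algorithms)), collapse = ", "),
           call. = FALSE)
    }
    if (any(vapply(d$predictions[algorithms], anyNA, logical(1)))) {
      stop("datasets must be complete cases for the requested algorithms; ",
           "run complete_case_filter() first", call. = FALSE)
    }
  }
  causes <- unpaired$causes
  C <- causes$C
  K <- length(algorithms)

  pat <- prediction_patterns(unpaired, algorithms)
  P <- nrow(pat$A)
  # P x C pattern-to-predicted-cause indicators, one per algorithm
  ind <- lapply(seq_len(K), function(k) {
    m <- matrix(0, P, C)
    m[cbind(seq_len(P), pat$A[, k])] <- 1
    m
  })
  paired_ct <- lapply(algorithms, function(a) paired_crosstab(paired, a))
  names(paired_ct) <- algorithms

  # causes never seen in any role are identified only through the prior
  seen <- Reduce(`|`, c(
    lapply(seq_len(K), function(k) tabulate(pat$A[, k], C) > 0),
    lapply(paired_ct, function(ct) rowSums(ct) > 0 | colSums(ct) > 0)))
  if (any(!seen)) {
    warning("cause(s) with no evidence in either dataset (posterior is ",
            "prior-driven): ", paste(causes$labels[!seen], collapse = ", "),
            call. = FALSE)
  }

  p_prior <- rep_len(config$p_prior, C)
  M_prior <- matrix(config$M_prior_offdiag, C, C)
  diag(M_prior) <- config$M_prior_diag

  if (!is.null(fixed_p)) {
    fixed_p <- if (inherits(fixed_p, "csmf")) fixed_p$p else as.numeric(fixed_p)
    stopifnot(length(fixed_p) == C, abs(sum(fixed_p) - 1) < 1e-9)
  }

  n_keep <- config$n_iter - config$n_burnin
  S <- n_keep * config$n_chains
  p_draws <- matrix(NA_real_, S, C, dimnames = list(NULL, causes$labels))
  M_draws <- stats::setNames(
    lapply(seq_len(K), function(k) array(NA_real_, c(S, C, C))), algorithms)
  chain_id <- rep(seq_len(config$n_chains), each = n_keep)
  iter_id <- rep(config$n_burnin + seq_len(n_keep), config$n_chains)

  set.seed(config$seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, config$n_chains)

  for (ch in seq_len(config$n_chains)) {
    set.seed(chain_seeds[ch])
    # warm start: latent causes at algorithm 1's predictions
    Zc <- matrix(0, C, P)
    Zc[cbind(pat$A[, 1], seq_len(P))] <- pat$n
    p_cur <- if (is.null(fixed_p)) as.numeric(rdirichlet_rows(
      matrix(p_prior + rowSums(Zc), 1))) else fixed_p
    M_cur <- vector("list", K)
    for (it in seq_len(config$n_iter)) {
      # M^(k) rows | z: Dirichlet(prior + paired cross-tab + unpaired counts)
      for (k in seq_len(K)) {
        M_cur[[k]] <- rdirichlet_rows(M_prior + paired_ct[[k]] +
                                        Zc %*% ind[[k]])
      }
      # z | p, M per pattern: categorical weights p_i * prod_k M^(k)[i, a_k]
      W <- matrix(p_cur, P, C, byrow = TRUE)
      for (k in seq_len(K)) W <- W * t(M_cur[[k]])[pat$A[, k], , drop = FALSE]
      ws <- rowSums(W)
      zero <- ws <= 0
      if (any(zero)) {                 # total underflow: fall back to p
        W[zero, ] <- matrix(p_cur, sum(zero), C, byrow = TRUE)
        ws[zero] <- 1
      }
      W <- W / ws
      Zc <- vapply(seq_len(P),
                   function(pp) stats::rmultinom(1, pat$n[pp], W[pp, ])[, 1],
                   numeric(C))
      # p | z: Dirichlet(prior + latent-cause counts)
      if (is.null(fixed_p)) {
        p_cur <- as.numeric(rdirichlet_rows(
          matrix(p_prior + rowSums(Zc), 1)))
      }
      if (it > config$n_burnin) {
        s <- (ch - 1L) * n_keep + (it - config$n_burnin)
        p_draws[s, ] <- p_cur
        for (k in seq_len(K)) M_draws[[k]][s, , ] <- M_cur[[k]]
      }
    }
  }

  point <- colMeans(p_draws)
  alpha <- (1 - config$credible_level) / 2
  interval <- apply(p_draws, 2, stats::quantile, probs = c(alpha, 1 - alpha),
                    names = FALSE)
  rownames(interval) <- c("lower", "upper")
  structure(list(causes = causes, draws = p_draws, M_draws = M_draws,
                 algorithms = algorithms, point = point, interval = interval,
                 chain = chain_id, iteration = iter_id, config = config,
                 fixed_p = fixed_p, prior_driven = !seen,
                 n_unpaired = n_records(unpaired),
                 n_paired = n_records(paired)),
            class = "csmf_posterior")
}

#' @export
print.csmf_posterior <- function(x, ...) {
  cat(sprintf(paste0("Calibrated CSMF posterior (%s; %d draws, %d chains",
                     "%s)\n"),
              paste(x$algorithms, collapse = " + "), nrow(x$draws),
              x$config$n_chains,
              if (!is.null(x$fixed_p)) "; p fixed" else ""))
  print(summarize_posterior(x), digits = 3)
  invisible(x)
}

#' Posterior summary table for a calibrated CSMF
#'
#' @param posterior A `csmf_posterior` from [run_calibration()].
#' @param level Equal-tailed credible level in (0, 1); defaults to the level
#'   the sampler was configured with.
#' @return Data frame with columns cause, mean, lower, upper.
#' @export
summarize_posterior <- function(posterior, level = NULL) {
  stopifnot(inherits(posterior, "csmf_posterior"))
  if (is.null(level)) level <- posterior$config$credible_level
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    stop("level must lie strictly between 0 and 1", call. = FALSE)
  }
  if (nrow(posterior$draws) == 0L) stop("no posterior draws", call. = FALSE)
  a <- (1 - level) / 2
  qs <- apply(posterior$draws, 2, stats::quantile, probs = c(a, 1 - a),
              names = FALSE)
  data.frame(cause = posterior$causes$labels,
             mean = unname(colMeans(posterior$draws)),
             lower = qs[1, ], upper = qs[2, ],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Split-chain convergence diagnostics for the CSMF coordinates
#'
#' Split-chain potential-scale-reduction factors (rank-free, classic form on
#' half-chains) and a monotone-pairs effective-sample-size estimate per CSMF
#' coordinate. Values of the scale-reduction factor above 1.01 are flagged.
#'
#' @param posterior A `csmf_posterior`.
#' @return Data frame with columns cause, rhat, ess; `rhat` is `NA` (with a
#'   message) when only one chain was run.
#' @export
convergence_diagnostics <- function(posterior) {
  stopifnot(inherits(posterior, "csmf_posterior"))
  C <- posterior$causes$C
  chains <- split(seq_len(nrow(posterior$draws)), posterior$chain)
  rhat <- rep(NA_real_, C)
  ess <- numeric(C)
  for (j in seq_len(C)) {
    per_chain <- lapply(chains, function(i) posterior$draws[i, j])
    ess[j] <- sum(vapply(per_chain, ess_one, numeric(1)))
    if (length(per_chain) >= 2L) rhat[j] <- split_rhat(per_chain)
  }
  if (length(chains) < 2L) {
    message("single chain: split-Rhat omitted (need n_chains >= 2)")
  } else if (any(rhat > 1.01, na.rm = TRUE)) {
    warning("split-Rhat > 1.01 for cause(s): ",
            paste(posterior$causes$labels[which(rhat > 1.01)],
                  collapse = ", "), call. = FALSE)
  }
  data.frame(cause = posterior$causes$labels, rhat = rhat, ess = ess,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Classic split-chain Rhat: halve every chain, compare between/within.
split_rhat <- function(per_chain) {
  halves <- unlist(lapply(per_chain, function(x) {
    n <- length(x) %/% 2L
    list(x[seq_len(n)], x[n + seq_len(n)])
  }), recursive = FALSE)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W <= 0) return(if (B <= 1e-24) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# ESS via initial-positive-sequence (Geyer) pairing of autocorrelations.
ess_one <- function(x) {
  n <- length(x)
  if (stats::var(x) == 0 || n < 4L) return(n)
  lag_max <- min(n - 1L, 10L * floor(sqrt(n)))
  rho <- stats::acf(x, lag.max = lag_max, plot = FALSE,
                    demean = TRUE)$acf[-1]
  s <- 0
  t <- 1L
  while (t + 1L <= length(rho)) {
    pair <- rho[t] + rho[t + 1L]
    if (pair < 0) break
    s <- s + pair
    t <- t + 2L
  }
  max(1, n / (1 + 2 * s))
}

#' Persist posterior draws to CSV (long format)
#'
#' Columns: chain, iteration, cause, value — suitable for external
#' diagnostics tooling.
#'
#' @param posterior A `csmf_posterior`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(posterior, path) {
  C <- posterior$causes$C
  S <- nrow(posterior$draws)
  df <- data.frame(chain = rep(posterior$chain, C),
                   iteration = rep(posterior$iteration, C),
                   cause = rep(posterior$causes$labels, each = S),
                   value = as.vector(posterior$draws),
                   stringsAsFactors = FALSE)
  utf8_write_csv(df, path)
  invisible(path)
}
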