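# Shared fixtures: tiny cause lists and datasets built in code.

cl2 <- cause_list(c("cause_a", "cause_b"))
cl3 <- cause_list(c("x", "y", "z"))

# The textbook two-cause misclassification matrix: sensitivities 95% / 65%.
M2x2 <- matrix(c(0.95, 0.05,
                 0.35, 0.65), 2, 2, byrow = TRUE)

# A small paired dataset from explicit reference/prediction label vectors.
make_paired <- function(ref, pred, causes, algorithm = "alg") {
  df <- stats::setNames(data.frame(pred, stringsAsFactors = FALSE), algorithm)
  paired_dataset(sprintf("d%03d", seq_along(ref)), ref, df, algorithm, causes)
}

make_unpaired <- function(pred, causes, algorithm = "alg") {
  df <- stats::setNames(data.frame(pred, stringsAsFactors = FALSE), algorithm)
  unpaired_dataset(sprintf("d%03d", seq_along(pred)), df, algorithm, causes)
}

# Independent oracle: reference-by-predicted cross-tab by exhaustive double
# loop over records and cause pairs (deliberately naive).
brute_crosstab <- function(ref, pred, causes) {
  C <- length(causes$labels)
  out <- matrix(0, C, C, dimnames = list(causes$labels, causes$labels))
  for (i in seq_len(C)) for (j in seq_len(C)) {
    for (r in seq_along(ref)) {
      if (!is.na(pred[r]) && ref[r] == causes$labels[i] &&
          pred[r] == causes$labels[j]) {
        out[i, j] <- out[i, j] + 1
      }
    }
  }
  out
}

# Independent oracle: per-draw log density of one unpaired record by
# enumerating every latent cause.
brute_unpaired_logdens <- function(p_draw, M_draws_s, a_idx) {
  p_draw <- unname(p_draw)
  a_idx <- unname(a_idx)
  total <- 0
  for (i in seq_along(p_draw)) {
    term <- p_draw[i]
    for (k in seq_along(M_draws_s)) term <- term * M_draws_s[[k]][i, a_idx[k]]
    total <- total + term
  }
  log(total)
}

# Random point in the simplex interior.
rsimplex <- function(C) {
  g <- stats::rgamma(C, shape = 1) + 0.05
  g / sum(g)
}

# Random diagonally dominant row-stochastic matrix.
rdiagdom <- function(C) {
  M <- matrix(stats::runif(C * C, 0.01, 0.2), C, C)
  diag(M) <- diag(M) + 2
  M / rowSums(M)
}

# Minimal hand-built posterior object for summary/diagnostic tests.
fake_posterior <- function(draws, causes, chain = rep(1L, nrow(draws)),
                           level = 0.95) {
  structure(list(causes = causes, draws = draws, chain = chain,
                 iteration = stats::ave(seq_len(nrow(draws)), chain,
                                        FUN = seq_along),
                 config = calibration_config(n_chains = length(unique(chain)),
                                             n_iter = 10, n_burnin = 1,
                                             credible_level = level)),
            class = "csmf_posterior")
}
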