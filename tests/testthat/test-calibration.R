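# Small-but-real MCMC runs; configs are sized for test runtime and the
# tolerances below account for Monte-Carlo error at those sizes.

quick_cfg <- function(seed, ...) {
  calibration_config(n_chains = 2, n_iter = 1500, n_burnin = 500,
                     seed = seed, ...)
}

test_that("calibration is reproducible and draws stay on their simplices", {
  g <- generate(preset_scenario("two_cause_worked_example"))
  cfg <- quick_cfg(301)
  fit1 <- run_calibration(g$unpaired, g$paired, config = cfg)
  fit2 <- run_calibration(g$unpaired, g$paired, config = cfg)
  expect_identical(fit1$draws, fit2$draws)
  expect_identical(fit1$M_draws, fit2$M_draws)

  expect_true(all(fit1$draws >= 0))
  expect_equal(rowSums(fit1$draws), rep(1, nrow(fit1$draws)),
               tolerance = 1e-12)
  Mrows <- apply(fit1$M_draws[[1]], c(1, 2), sum)   # S x C row sums
  expect_equal(as.vector(Mrows), rep(1, length(Mrows)), tolerance = 1e-12)
  # equal-tailed interval brackets the posterior mean
  expect_true(all(fit1$interval["lower", ] <= fit1$point &
                    fit1$point <= fit1$interval["upper", ]))
})

test_that("with no misclassification the calibrated CSMF matches the raw CSMF", {
  set.seed(302)
  labs <- cl3$labels
  up <- make_unpaired(sample(labs, 600, TRUE, prob = c(0.5, 0.3, 0.2)), cl3)
  ref <- rep(labs, each = 40)
  pa <- make_paired(ref, ref, cl3)       # predictions identical to reference
  fit <- run_calibration(up, pa, config = quick_cfg(303))
  raw <- raw_csmf(up$predictions$alg, cl3)
  expect_equal(unname(fit$point), unname(raw$p), tolerance = 0.02)
})

test_that("posterior mean converges to truth as both samples grow", {
  sc <- preset_scenario("two_cause_worked_example")
  err <- sapply(c(small = 1000L, large = 50000L), function(n) {
    sc$n_unpaired <- n
    sc$paired_per_cause <- rep(max(40L, n %/% 25L), 2)
    sc$seed <- 304L
    g <- generate(sc)
    fit <- run_calibration(g$unpaired, g$paired, config = quick_cfg(305))
    sum(abs(fit$point - sc$p_true$p))
  })
  expect_lt(err["large"], err["small"])
  expect_lt(err["large"], 0.03)
})

test_that("ensemble favours the accurate algorithm over a near-uniform one", {
  C <- 4
  cl <- cause_list(paste0("c", 1:C))
  p_star <- c(0.4, 0.3, 0.2, 0.1)
  near_uniform <- matrix(1 / C, C, C) + diag(rep(0.04, C)) -
    0.04 / C
  sc <- synthetic_scenario(
    cl, p_star,
    M_true = list(good = diag(C), bad = near_uniform / rowSums(near_uniform)),
    n_unpaired = 1200, paired_per_cause = 60, seed = 306)
  g <- generate(sc)
  ens <- run_calibration(g$unpaired, g$paired, config = quick_cfg(307))
  bad_only <- run_calibration(g$unpaired, g$paired, algorithms = "bad",
                              config = quick_cfg(307))
  l1 <- function(fit) sum(abs(fit$point - p_star))
  expect_lt(l1(ens), l1(bad_only))
})

test_that("causes with no evidence are flagged as prior-driven", {
  labs <- cl3$labels
  up <- make_unpaired(rep(labs[1:2], 50), cl3)
  pa <- make_paired(rep(labs[1:2], 10), rep(labs[1:2], 10), cl3)
  expect_warning(
    fit <- run_calibration(up, pa,
                           config = quick_cfg(308, M_prior_diag = 1,
                                              M_prior_offdiag = 1)),
    "prior-driven")
  expect_equal(fit$prior_driven, c(x = FALSE, y = FALSE, z = TRUE))
})

test_that("run_calibration rejects incomplete cases and foreign algorithms", {
  up <- make_unpaired(c("x", NA, "y"), cl3)
  pa <- make_paired(c("x", "y"), c("x", "y"), cl3)
  expect_error(run_calibration(up, pa, config = quick_cfg(1)),
               "complete_case_filter")
  expect_error(run_calibration(make_unpaired(c("x", "y"), cl3), pa,
                               algorithms = "other_alg",
                               config = quick_cfg(1)),
               "absent")
})

test_that("summarize_posterior gives equal-tailed intervals with nesting", {
  const <- fake_posterior(matrix(rep(c(0.25, 0.75), each = 50), 50), cl2)
  s <- summarize_posterior(const)
  expect_equal(s$mean, c(0.25, 0.75))
  expect_equal(s$lower, s$upper)

  set.seed(309)
  g <- rgamma(2e5, 1)
  draws <- cbind(g, rgamma(2e5, 1))
  draws <- draws / rowSums(draws)      # Dirichlet(1, 1)
  dir <- fake_posterior(draws, cl2)
  expect_equal(summarize_posterior(dir)$mean, c(0.5, 0.5), tolerance = 0.01)

  narrow <- summarize_posterior(dir, level = 0.5)
  wide <- summarize_posterior(dir, level = 0.95)
  expect_true(all(wide$lower <= narrow$lower & narrow$upper <= wide$upper))
  expect_error(summarize_posterior(dir, level = 1.2), "between 0 and 1")
})

test_that("convergence diagnostics behave on agreeing, iid, and stuck chains", {
  S <- 600
  same <- fake_posterior(matrix(rep(c(0.3, 0.7), each = S), S), cl2,
                         chain = rep(1:2, each = S / 2))
  d <- convergence_diagnostics(same)
  expect_equal(d$rhat, c(1, 1))

  set.seed(310)
  iid <- matrix(rgamma(2 * 4000, 1), ncol = 2)
  iid <- iid / rowSums(iid)
  ok <- convergence_diagnostics(fake_posterior(iid, cl2,
                                               chain = rep(1:2, each = 2000)))
  expect_true(all(ok$rhat < 1.01))
  expect_gt(min(ok$ess), 1000)

  stuck <- fake_posterior(
    rbind(matrix(rep(c(0.2, 0.8), each = S / 2), S / 2),
          matrix(rep(c(0.8, 0.2), each = S / 2), S / 2)),
    cl2, chain = rep(1:2, each = S / 2))
  expect_warning(dd <- convergence_diagnostics(stuck), "split-Rhat")
  expect_gt(max(dd$rhat), 10)

  single <- fake_posterior(iid, cl2)
  expect_message(ds <- convergence_diagnostics(single), "single chain")
  expect_true(all(is.na(ds$rhat)))
})

test_that("posterior draws persist to the long CSV format", {
  g <- generate(preset_scenario("two_cause_worked_example"))
  fit <- run_calibration(g$unpaired, g$paired,
                         config = calibration_config(n_chains = 2,
                                                     n_iter = 60,
                                                     n_burnin = 10,
                                                     seed = 311))
  path <- withr::local_tempfile(fileext = ".csv")
  write_draws(fit, path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  expect_equal(names(df), c("chain", "iteration", "cause", "value"))
  expect_equal(nrow(df), nrow(fit$draws) * 2)
  back <- matrix(df$value, ncol = 2)
  expect_equal(unname(back), unname(fit$draws))
})
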