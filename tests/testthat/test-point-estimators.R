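test_that("raw_csmf is the empirical share of predicted causes", {
  p <- raw_csmf(rep(c("x", "y", "z"), c(2, 3, 5)), cl3)
  expect_equal(unname(p$p), c(0.2, 0.3, 0.5))
  expect_equal(unname(p$counts), c(2, 3, 5))

  only_y <- raw_csmf(rep("y", 8), cl3)
  expect_equal(unname(only_y$p), c(0, 1, 0))

  expect_error(raw_csmf(character(0), cl3), "zero records")
  expect_error(raw_csmf(c("x", NA), cl3), "complete_case_filter")
  expect_error(raw_csmf(c("x", "w"), cl3), "'w'")
})

test_that("estimate_misclassification row-normalises the paired cross-tab", {
  # 2x2: 19/20 of reference-a predicted a; 13/20 of reference-b predicted b
  ref <- rep(c("cause_a", "cause_b"), each = 20)
  pred <- c(rep(c("cause_a", "cause_b"), c(19, 1)),
            rep(c("cause_a", "cause_b"), c(7, 13)))
  M <- estimate_misclassification(make_paired(ref, pred, cl2), "alg")
  expect_equal(unname(M$M), matrix(c(0.95, 0.05, 0.35, 0.65), 2,
                                   byrow = TRUE))
  expect_equal(M$row_counts, c(20L, 20L))

  perfect <- make_paired(rep(cl3$labels, 4), rep(cl3$labels, 4), cl3)
  expect_equal(unname(estimate_misclassification(perfect, "alg")$M), diag(3))

  counts <- make_paired(rep(c("cause_a", "cause_b"), c(10, 10)),
                        rep(c("cause_a", "cause_b", "cause_a", "cause_b"),
                            c(8, 2, 1, 9)), cl2)
  expect_equal(unname(estimate_misclassification(counts, "alg")$M),
               matrix(c(0.8, 0.2, 0.1, 0.9), 2, byrow = TRUE))
  expect_error(estimate_misclassification(counts, "nope"), "not in dataset")
})

test_that("zero-count reference rows become flagged uniform rows", {
  d <- make_paired(rep("x", 6), rep(c("x", "y"), 3), cl3)
  M <- estimate_misclassification(d, "alg")
  expect_equal(M$row_counts, c(6L, 0L, 0L))
  expect_equal(unname(M$M[2, ]), rep(1 / 3, 3))
  expect_equal(unname(M$M[3, ]), rep(1 / 3, 3))
})

test_that("estimate_misclassification matches the brute-force cross-tab oracle", {
  set.seed(401)
  for (rep in 1:10) {
    C <- sample(2:5, 1)
    cl <- cause_list(paste0("c", seq_len(C)))
    n <- sample(5:40, 1)
    ref <- sample(cl$labels, n, replace = TRUE)
    pred <- replace(sample(cl$labels, n, replace = TRUE),
                    stats::runif(n) < 0.1, NA)
    d <- make_paired(ref, pred, cl)
    if (all(is.na(pred))) next
    got <- estimate_misclassification(d, "alg")
    want <- brute_crosstab(ref, pred, cl)
    rc <- rowSums(want)
    expect_equal(got$row_counts, as.integer(rc))
    for (i in which(rc > 0)) {
      expect_equal(got$M[i, ], want[i, ] / rc[i])
    }
  }
})

test_that("forward_marginal reproduces the two-cause example and simplex cases", {
  M <- misclassification_matrix(M2x2, cl2)
  q <- forward_marginal(csmf(c(0.30, 0.70), cl2), M)
  expect_equal(unname(q$p), c(0.53, 0.47))

  I3 <- misclassification_matrix(diag(3), cl3)
  p <- csmf(c(0.2, 0.5, 0.3), cl3)
  expect_equal(forward_marginal(p, I3)$p, p$p)

  set.seed(402)
  Mr <- misclassification_matrix(rdiagdom(3), cl3)
  degenerate <- csmf(c(0, 1, 0), cl3)
  expect_equal(unname(forward_marginal(degenerate, Mr)$p), unname(Mr$M[2, ]))
  expect_error(forward_marginal(csmf(c(0.5, 0.5), cl2), Mr), "not match")
})

test_that("forward_marginal preserves the simplex for random inputs", {
  set.seed(403)
  for (rep in 1:25) {
    C <- sample(2:8, 1)
    cl <- cause_list(paste0("c", seq_len(C)))
    q <- forward_marginal(csmf(rsimplex(C), cl),
                          misclassification_matrix(rdiagdom(C), cl))
    expect_true(all(q$p >= 0))
    expect_equal(sum(q$p), 1, tolerance = 1e-9)
  }
})

test_that("backsolve_csmf inverts the textbook system and flags infeasibility", {
  M <- misclassification_matrix(M2x2, cl2)
  sol <- backsolve_csmf(csmf(c(0.53, 0.47), cl2), M)
  expect_true(sol$feasible)
  expect_equal(unname(sol$p), c(0.30, 0.70))

  ident <- backsolve_csmf(csmf(c(0.4, 0.6), cl2),
                          misclassification_matrix(diag(2), cl2))
  expect_equal(unname(ident$p), c(0.4, 0.6))

  # q = (1, 0) cannot arise from sensitivities (0.95, 0.65): p_a > 1
  infeas <- backsolve_csmf(csmf(c(1, 0), cl2), M)
  expect_false(infeas$feasible)
  expect_null(infeas$csmf)
  expect_gt(infeas$p[1], 1)          # reported unclipped

  singular <- misclassification_matrix(matrix(0.5, 2, 2), cl2)
  expect_error(backsolve_csmf(csmf(c(0.5, 0.5), cl2), singular),
               "Bayesian calibration")
})

test_that("backsolve after forward recovers random simplex points to 1e-8", {
  set.seed(404)
  for (rep in 1:25) {
    C <- sample(2:7, 1)
    cl <- cause_list(paste0("c", seq_len(C)))
    p_star <- rsimplex(C)
    M <- misclassification_matrix(rdiagdom(C), cl)
    q <- forward_marginal(csmf(p_star, cl), M)
    sol <- backsolve_csmf(q, M)
    expect_true(sol$feasible)
    expect_equal(unname(sol$p), p_star, tolerance = 1e-8)
  }
})

test_that("ensemble_uncalibrated averages and is permutation-invariant", {
  a <- csmf(c(0.2, 0.8), cl2)
  b <- csmf(c(0.6, 0.4), cl2)
  expect_equal(unname(ensemble_uncalibrated(list(a, b))$p), c(0.4, 0.6))
  expect_equal(ensemble_uncalibrated(list(b, a))$p,
               ensemble_uncalibrated(list(a, b))$p)
  expect_equal(ensemble_uncalibrated(list(a))$p, a$p)
  expect_error(ensemble_uncalibrated(list()), "at least one")
  expect_error(ensemble_uncalibrated(list(a, csmf(rep(1 / 3, 3), cl3))),
               "not match")
})

test_that("published count tables reproduce the printed raw and ensemble CSMFs", {
  child <- comsa_raw_csmfs("child")
  expect_equal(as_percent(child$eava)[["pneumonia"]], 21.5)
  expect_equal(as_percent(child$eava)[["diarrhea"]], 19.4)
  expect_equal(round(100 * child$ensemble$p[["malaria"]]), 14)

  neonate <- comsa_raw_csmfs("neonate")
  expect_equal(as_percent(neonate$insilicova)[["infection"]], 45.9)
  expect_equal(round(100 * neonate$ensemble$p[["infection"]]), 49)
  expect_equal(round(100 * neonate$ensemble$p[["prematurity"]]), 23)
})

test_that("CSMF and misclassification CSV writers emit the documented schemas", {
  path <- withr::local_tempfile(fileext = ".csv")
  est <- raw_csmf(rep(c("x", "y", "z"), c(1, 2, 2)), cl3)
  write_csmf(list(raw = est), path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  expect_equal(names(df), c("model", "cause", "estimate", "count"))
  expect_equal(df$estimate, c(0.2, 0.4, 0.4))

  M <- estimate_misclassification(
    make_paired(rep(cl2$labels, each = 2),
                c("cause_a", "cause_a", "cause_a", "cause_b"), cl2), "alg")
  write_misclassification(M, path)
  dm <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  expect_equal(dm$reference_cause, cl2$labels)
  expect_equal(dm$row_count, c(2L, 2L))
  expect_equal(dm[["cause_a"]], c(1, 0.5))
})
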