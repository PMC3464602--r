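test_that("maximum likelihood recovers parameters from expected counts", {
  # counts proportional to the model's own cell probabilities are a
  # fixed point of the estimator
  rp <- risk_params(R1 = 1.5, R2 = 2.25, S2 = 1.8)
  sp <- strat_params("HWE", q = 0.3)
  N <- 2e5
  tabs <- list(
    count_table("case_parent_trio",
                round(N * case_trio_cell_probs(rp, sp))),
    count_table("control_parental_mating",
                round(N * vapply(collapse_map("control_parental_mating")$cells,
                                 function(i) sum(control_trio_cell_probs(sp)[i]),
                                 numeric(1)))))
  spec <- model_spec("HWE", free_risk = c("R1", "R2", "S2"), q_start = 0.5)
  fit <- fit_model(tabs, spec)
  expect_true(fit$converged)
  expect_equal(fit$free[["R1"]], 1.5, tolerance = 1e-2)
  expect_equal(fit$free[["R2"]], 2.25, tolerance = 1e-2)
  expect_equal(fit$free[["S2"]], 1.8, tolerance = 1e-2)
  expect_equal(fit$free[["q"]], 0.3, tolerance = 1e-2)
  # standard errors exist and shrink with N on this well-conditioned fit
  expect_true(all(is.finite(fit$se)))
  expect_lt(fit$se[["R1"]], 0.05)
})

test_that("the null HWE fit on a trio table has the closed-form optimum", {
  # under the null, q enters only through the parental genotypes, so the
  # ML allele frequency is the parental allele count proportion
  set.seed(5)
  tab <- simulate_unit_tables(sim_design(c(case_parent_trio = 300),
                                         rp = risk_params(), q = 0.37,
                                         seed = 8))[[1]][[1]]
  tc <- trio_cells()
  n <- tab$counts
  qhat <- sum(n * (tc$gm + tc$gf)) / (4 * sum(n))
  ll_closed <- sum(n * log(dbinom(tc$gm, 2, qhat) * dbinom(tc$gf, 2, qhat) *
                           tc$weight))
  fit <- fit_model(list(tab), model_spec("HWE", q_start = 0.5))
  expect_equal(fit$loglik, ll_closed, tolerance = 1e-8)
  expect_equal(fit$free[["q"]], qhat, tolerance = 1e-5)
})

test_that("constrained fits never beat their unconstrained parents", {
  tabs <- simulate_unit_tables(mixed_unit_design(risk_params(R2 = 2),
                                                 n = 80), seed = 31)[[1]]
  free <- fit_model(tabs, model_spec("HWE", c("R1", "R2"), q_start = 0.3))
  constrained <- fit_model(tabs, model_spec("HWE", "R1",
                                            constraints = "child_multiplicative",
                                            q_start = 0.3))
  expect_lte(constrained$loglik, free$loglik + 1e-8)
  expect_equal(constrained$estimates$rp[["R2"]],
               constrained$estimates$rp[["R1"]]^2)
})

test_that("likelihood-ratio tests follow the chi-squared calibration", {
  mk_fit <- function(ll, spec) structure(
    list(loglik = ll, n_free = spec$n_free, spec = spec,
         converged = TRUE), class = "trio_fit")
  s0 <- model_spec("HWE")
  s1 <- model_spec("HWE", "R2")
  s2 <- model_spec("HWE", c("R1", "R2"))
  t1 <- lrt(mk_fit(-100, s0), mk_fit(-98.08, s1))
  expect_equal(t1$lrt_stat, 3.84, tolerance = 1e-12)
  expect_equal(t1$df, 1)
  expect_equal(t1$p_value, pchisq(3.84, 1, lower.tail = FALSE))
  expect_lt(abs(t1$p_value - 0.05), 1e-3)
  # equal likelihoods: stat clipped at zero, p = 1
  t0 <- lrt(mk_fit(-100, s0), mk_fit(-100, s1))
  expect_equal(t0$lrt_stat, 0)
  expect_equal(t0$p_value, 1)
  expect_equal(lrt(mk_fit(-100, s0), mk_fit(-99, s2))$df, 2)
  expect_error(lrt(mk_fit(-100, s1), mk_fit(-99, mk <- model_spec("HWE", "S1"))),
               "not nested")
  expect_error(lrt(mk_fit(-100, model_spec("CEPG")), mk_fit(-99, s1)),
               "not nested")
})

test_that("null likelihood-ratio p-values are uniform", {
  des <- sim_design(c(case_parent_trio = 150, control_parental_mating = 150),
                    rp = risk_params(), q = 0.3)
  null_spec <- model_spec("HWE", q_start = 0.3)
  alt_spec <- model_spec("HWE", c("R1", "R2"), q_start = 0.3)
  set.seed(2024)
  pvals <- replicate(2000, {
    tabs <- simulate_unit_tables(des, seed = sample.int(2^31 - 1, 1))[[1]]
    lrt(fit_model(tabs, null_spec), fit_model(tabs, alt_spec))$p_value
  })
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.001)
  # empirical size at the 5% level within Monte-Carlo error
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
})

test_that("fits are invariant to the starting point on regular data", {
  tabs <- simulate_unit_tables(mixed_unit_design(risk_params(S2 = 2),
                                                 n = 100), seed = 55)[[1]]
  spec <- model_spec("HWE", c("R1", "R2", "S1", "S2"), q_start = 0.3)
  f1 <- fit_model(tabs, spec)
  set.seed(9)
  for (k in 1:3) {
    start <- setNames(c(exp(rnorm(4, 0, 0.3)), runif(1, 0.15, 0.6)),
                      c("R1", "R2", "S1", "S2", "q"))
    f2 <- fit_model(tabs, spec, start = start)
    expect_equal(f2$loglik, f1$loglik, tolerance = 1e-7)
  }
})

test_that("seven risk parameters are identifiable from full trio data", {
  expect_equal(max_estimable_risk_params(), 7L)
  # a single free risk parameter is always identifiable
  expect_equal(max_estimable_risk_params(menu = "R1"), 1L)
  expect_equal(max_estimable_risk_params(menu = c("R1", "R2")), 2L)
  # the count is stable across generic evaluation points
  expect_equal(max_estimable_risk_params(seed = 99L), 7L)
})

test_that("analyse_snps reports per-SNP results, batches and skips", {
  des <- sim_design(c(case_parent_trio = 80, control_parental_mating = 80),
                    rp = risk_params(R2 = 2), q = 0.3, n_snps = 3,
                    causal = 2, seed = 17)
  tabs <- simulate_unit_tables(des)
  null_spec <- model_spec("HWE", q_start = 0.3)
  alt_spec <- model_spec("HWE", c("R1", "R2"), q_start = 0.3)
  res <- analyse_snps(tabs, null_spec, alt_spec)
  expect_equal(res$snp, c("snp1", "snp2", "snp3"))
  expect_true(all(res$status == "ok"))
  expect_true(all(res$df == 2))
  # the causal SNP carries the strongest signal
  expect_equal(which.min(res$p), 2L)
  # batch halves concatenate to the full run
  res_split <- rbind(analyse_snps(tabs, null_spec, alt_spec, batch = c(1, 2)),
                     analyse_snps(tabs, null_spec, alt_spec, batch = c(3, 3)))
  expect_equal(res_split, res)
  expect_error(analyse_snps(tabs, null_spec, alt_spec, batch = c(2, 9)),
               "in-range")
  # monomorphic SNPs are skipped with a reason, not dropped
  markers <- data.frame(snp = c("snp1", "snp2", "snp3"),
                        risk_allele = c("A", "A", NA),
                        freq = c(0.3, 0.3, NA), monomorphic = c(FALSE, FALSE, TRUE))
  res_m <- analyse_snps(tabs, null_spec, alt_spec, markers = markers)
  expect_equal(nrow(res_m), 3)
  expect_match(res_m$status[3], "skipped: monomorphic")
  expect_true(is.na(res_m$p[3]))
})

test_that("results tables round-trip through the tab-separated format", {
  des <- sim_design(c(case_parent_trio = 60), rp = risk_params(), q = 0.3,
                    n_snps = 2, seed = 4)
  tabs <- simulate_unit_tables(des)
  res <- analyse_snps(tabs, model_spec("HWE", q_start = 0.3),
                      model_spec("HWE", "R2", q_start = 0.3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results(res, path)
  back <- read.delim(path, stringsAsFactors = FALSE)
  expect_equal(names(back), names(res))
  expect_equal(back$loglik_alt, res$loglik_alt, tolerance = 1e-12)
})

test_that("degenerate inputs are rejected or skipped with reasons", {
  empty <- list(count_table("case_parent_trio", rep(0L, 15)))
  expect_error(fit_model(empty, model_spec("HWE")), "non-zero")
  res <- analyse_snps(list(snpX = empty), model_spec("HWE"),
                      model_spec("HWE", "R1"))
  expect_match(res$status, "skipped: no data")
})
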