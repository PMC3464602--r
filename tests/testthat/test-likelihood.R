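test_that("penetrance multipliers compose the published factors", {
  rp <- risk_params(R1 = 1.3, R2 = 1.9, S1 = 1.1, S2 = 2.2, Im = 1.5,
                    Ip = 0.8, gamma21 = 1.4, gamma11 = 1.2)
  # mother homozygous risk, father reference, het child: allele is maternal
  expect_equal(penetrance_multiplier(2, 0, 1, "maternal", rp),
               1.3 * 2.2 * 1.5 * 1.4)
  expect_equal(penetrance_multiplier(1, 1, 1, "paternal", rp),
               1.3 * 1.1 * 0.8 * 1.2)
  # identity parameters give multiplier 1 for every cell
  tc <- trio_cells()
  for (i in seq_len(15)) {
    ph <- switch(tc$phase[i], none = "none", maternal = "maternal",
                 paternal = "paternal", both = "maternal")
    expect_equal(penetrance_multiplier(tc$gm[i], tc$gf[i], tc$gc[i], ph,
                                       risk_params()), 1)
  }
})

test_that("impossible phases are rejected", {
  expect_error(penetrance_multiplier(2, 0, 1, "paternal"), "impossible")
  expect_error(penetrance_multiplier(0, 2, 1, "maternal"), "impossible")
  expect_error(penetrance_multiplier(2, 2, 2, "maternal"), "heterozygous")
  expect_error(penetrance_multiplier(1, 1, 1, "none"), "requires phase")
  expect_error(penetrance_multiplier(0, 0, 1, "maternal"), "inconsistent")
})

test_that("cell probabilities normalise and reduce to the null", {
  sp <- strat_params("HWE", q = 0.5)
  expect_equal(sum(case_trio_cell_probs(risk_params(R2 = 3, Im = 2), sp)), 1)
  expect_equal(case_trio_cell_probs(risk_params(), sp),
               control_trio_cell_probs(sp))
  # het x het -> het under HWE at q = 1/2: 0.5 * 0.5 * 0.5
  expect_equal(case_trio_cell_probs(risk_params(), sp)[9], 0.125)
  # all-reference control trio: (1-q)^2 per parent
  expect_equal(control_trio_cell_probs(strat_params("HWE", q = 0.3))[15],
               0.7^4)
})

test_that("case probabilities equal the brute-force phased enumeration", {
  set.seed(421)
  for (assumption in c("HWE", "CEPG", "CPG")) {
    for (k in 1:10) {
      rp <- random_risk_params()
      sp <- random_strat_params(assumption)
      expect_equal(case_trio_cell_probs(rp, sp), oracle_case_probs(rp, sp),
                   tolerance = 1e-13)
    }
  }
})

test_that("exchangeable strata with HWE masses reproduce the HWE model", {
  rp <- risk_params(R1 = 1.4, R2 = 2, S2 = 1.7, Im = 1.3, gamma11 = 1.2)
  for (q in c(0.1, 0.3, 0.5, 0.8)) {
    expect_equal(case_trio_cell_probs(rp, strat_params("CEPG",
                                                 mu = hwe_mating_mu(q))),
                 case_trio_cell_probs(rp, strat_params("HWE", q = q)),
                 tolerance = 1e-14)
  }
})

test_that("mating symmetry holds under CEPG without parent-specific effects", {
  tc <- trio_cells()
  swap <- vapply(seq_len(15), function(i)
    tc$index[tc$gm == tc$gf[i] & tc$gf == tc$gm[i] & tc$gc == tc$gc[i]],
    integer(1))
  rp <- risk_params(R1 = 1.5, R2 = 2.5, Im = 1.4, Ip = 1.4,
                    gamma01 = 1, gamma11 = 1)
  p <- case_trio_cell_probs(rp, strat_params("CEPG",
                                             mu = exp(rnorm(6, 0, 0.3))))
  expect_equal(p[swap], p, tolerance = 1e-14)
})

test_that("collapsed probabilities conserve mass cell-for-cell", {
  set.seed(7)
  p <- case_trio_cell_probs(random_risk_params(), random_strat_params("CPG"))
  for (k in unit_kinds()) {
    cm <- collapse_map(k)
    collapsed <- vapply(cm$cells, function(i) sum(p[i]), numeric(1))
    expect_equal(sum(collapsed), 1, tolerance = 1e-14)
  }
})

test_that("raising one risk multiplier raises the mass of its cells", {
  tc <- trio_cells()
  sp <- strat_params("HWE", q = 0.4)
  carriers <- list(R2 = tc$gc == 2, S1 = tc$gm == 1,
                   Im = tc$phase %in% c("maternal", "both"),
                   gamma11 = tc$gm == 1 & tc$gc == 1)
  for (nm in names(carriers)) {
    lo <- case_trio_cell_probs(do.call(risk_params, setNames(list(1), nm)),
                               sp)
    hi <- case_trio_cell_probs(do.call(risk_params, setNames(list(2), nm)),
                               sp)
    expect_gt(sum(hi[carriers[[nm]]]), sum(lo[carriers[[nm]]]))
  }
})

test_that("unit log-likelihood collapses and flags zero cells", {
  sp <- strat_params("HWE", q = 0.3)
  rp <- risk_params(S2 = 2)
  p <- case_trio_cell_probs(rp, sp)
  trio <- count_table("case_parent_trio", rep(2L, 15))
  expect_equal(unit_log_likelihood(trio, p), sum(2 * log(p)))
  # empty table contributes exactly zero
  expect_equal(unit_log_likelihood(count_table("case", c(0, 0, 0)), p), 0)
  # duo combination 4 pools cells 5, 9, 11
  duo <- count_table("case_mother_duo", c(0, 0, 0, 3, 0, 0, 0))
  expect_equal(unit_log_likelihood(duo, p), 3 * log(p[5] + p[9] + p[11]))
  # positive count on an impossible combination
  p0 <- p; p0[c(5, 9, 11)] <- 0; p0 <- p0 / sum(p0)
  ll <- unit_log_likelihood(duo, p0)
  expect_identical(as.numeric(ll), -Inf)
  expect_true(attr(ll, "zero_cell"))
})

test_that("the total log-likelihood sums case and control tables", {
  rp <- risk_params(R1 = 1.5, R2 = 2.25)
  sp <- strat_params("HWE", q = 0.3)
  tabs <- simulate_unit_tables(
    sim_design(c(case_parent_trio = 40, control_mother_duo = 30,
                 control = 20), rp = rp, q = 0.3, seed = 3))[[1]]
  expect_equal(total_log_likelihood(list(), rp, sp), 0)
  expect_equal(total_log_likelihood(tabs, rp, sp),
               sum(vapply(tabs, function(tab) unit_log_likelihood(tab,
                 if (is_case_unit(tab$kind)) case_trio_cell_probs(rp, sp)
                 else control_trio_cell_probs(sp)), numeric(1))))
})

test_that("splitting trios into duos preserves no more than the full info", {
  # the duo likelihood of collapsed data equals the collapsed trio
  # likelihood computed by direct Bayes enumeration
  set.seed(12)
  rp <- random_risk_params(0.3)
  sp <- random_strat_params("HWE")
  p_full <- oracle_case_probs(rp, sp)
  cm <- collapse_map("case_mother_duo")
  duo_counts <- c(4L, 1L, 3L, 7L, 2L, 5L, 6L)
  tab <- count_table("case_mother_duo", duo_counts)
  expect_equal(unit_log_likelihood(tab, case_trio_cell_probs(rp, sp)),
               sum(duo_counts * log(vapply(cm$cells, function(i)
                 sum(p_full[i]), numeric(1)))))
})

test_that("parameter constraints expand as documented", {
  s <- model_spec("HWE", free_risk = "R1",
                  constraints = "child_multiplicative", q_start = 0.3)
  pa <- apply_constraints(s, c(1.5, 0.3))
  expect_equal(pa$rp[["R2"]], 2.25)
  expect_equal(pa$sp$q, 0.3)
  s2 <- model_spec("PAE")
  pa2 <- apply_constraints(s2, c(1.1, 1.2, 0.7, 0.9))
  expect_equal(pa2$sp$mu, c(1.1, 1.2, 0.7, 0.7, 0.9, 1))
  # identity embedding without constraints
  s3 <- model_spec("CEPG", free_risk = c("S1", "S2"))
  pa3 <- apply_constraints(s3, c(2, 3, rep(1, 5)))
  expect_equal(pa3$rp[["S1"]], 2)
  expect_equal(pa3$rp[["S2"]], 3)
  expect_error(apply_constraints(s3, 1:3), "expected 7")
  expect_error(model_spec("HWE", free_risk = c("R1", "R2"),
                          constraints = "child_multiplicative"),
               "cannot be free")
  expect_error(model_spec("HWE", free_risk = "gamma20"), "not estimable")
})
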