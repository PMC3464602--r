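map3 <- c("1 snp1 0 1", "1 snp2 0 2", "1 snp3 0 3")

# one complete case/parent trio family with configurable genotypes
trio_lines <- function(fid, gm, gf, gc) {
  g <- function(x) c("G G", "A G", "A A")[x + 1]
  c(sprintf("%s 1 0 0 1 1 %s", fid, paste(rep(g(gf), 3), collapse = " ")),
    sprintf("%s 2 0 0 2 1 %s", fid, paste(rep(g(gm), 3), collapse = " ")),
    sprintf("%s 3 1 2 1 2 %s", fid, paste(rep(g(gc), 3), collapse = " ")))
}

test_that("extraction follows the unit preference order per SNP", {
  lines <- c(
    # family A: complete trio at snp1/3, father missing at snp2
    "A 1 0 0 1 1 A G 0 0 A G",
    "A 2 0 0 2 1 A A A A A A",
    "A 3 1 2 1 2 A A A A A A",
    # family B: child ungenotyped -> parental mating
    "B 1 0 0 1 1 A G A G A G",
    "B 2 0 0 2 1 G G G G G G",
    "B 3 1 2 1 2 0 0 0 0 0 0",
    # family C: only the affected child genotyped -> singleton case
    "C 3 0 0 1 2 A G A G A G",
    # family D: unaffected child with both parents -> control mating
    "D 1 0 0 1 1 A G A G A G",
    "D 2 0 0 2 1 A G A G A G",
    "D 3 1 2 1 1 A A A A A A",
    # family E: lone control
    "E 1 0 0 2 1 G G G G G G")
  fx <- write_ped_fixture(lines, map3)
  pd <- read_pedigrees(fx$ped, fx$map)
  ex <- extract_count_tables(pd)
  totals <- sapply(ex$tables, function(tt) vapply(tt, function(t)
    sum(t$counts), numeric(1)))
  expect_equal(totals["case_parent_trio", ], c(snp1 = 1, snp2 = 0, snp3 = 1))
  expect_equal(totals["case_mother_duo", ], c(snp1 = 0, snp2 = 1, snp3 = 0))
  expect_equal(unname(totals["case_parental_mating", ]), c(1, 1, 1))
  expect_equal(unname(totals["case", ]), c(1, 1, 1))
  expect_equal(unname(totals["control_parental_mating", ]), c(1, 1, 1))
  expect_equal(unname(totals["control", ]), c(1, 1, 1))
  # at most one unit per family per SNP
  expect_true(all(colSums(totals) <= length(unique(pd$fam$fid))))
})

test_that("Mendelian-inconsistent units are dropped at that SNP and logged", {
  lines <- c(
    # trio inconsistent at snp2 only (child A A from G G father)
    "A 1 0 0 1 1 A G G G A G",
    "A 2 0 0 2 1 A A A A A A",
    "A 3 1 2 1 2 A A A A A A",
    # mother-duo inconsistent everywhere (mother A A, child G G)
    "B 2 0 0 2 1 A A A A A A",
    "B 3 0 2 1 2 G G G G G G")
  fx <- write_ped_fixture(lines, map3)
  ex <- extract_count_tables(read_pedigrees(fx$ped, fx$map))
  trio_totals <- vapply(ex$tables, function(tt)
    if (is.null(tt$case_parent_trio)) 0 else sum(tt$case_parent_trio$counts),
    numeric(1))
  expect_equal(unname(trio_totals), c(1, 0, 1))
  expect_equal(sum(ex$log$reason == "mendelian_inconsistent_trio"), 1)
  expect_equal(ex$log$snp[ex$log$reason == "mendelian_inconsistent_trio"],
               "snp2")
  expect_equal(sum(ex$log$reason == "mendelian_inconsistent_duo"), 3)
})

test_that("probands and the multiple-unit option steer case selection", {
  # two affected sibs; sib 4 has no genotype, sib 3 does
  lines <- c(
    "A 1 0 0 1 1 A G A G A G",
    "A 2 0 0 2 1 A G A G A G",
    "A 3 1 2 1 2 A A A A A A",
    "A 4 1 2 2 2 0 0 0 0 0 0")
  fx <- write_ped_fixture(lines, map3)
  pd <- read_pedigrees(fx$ped, fx$map)
  # default: first affected in file order anchors a trio
  ex <- extract_count_tables(pd)
  expect_equal(sum(ex$tables$snp1$case_parent_trio$counts), 1)
  # proband forces the ungenotyped sib: parents-only unit
  exp_ <- extract_count_tables(pd, proband = c(A = "4"))
  expect_equal(sum(exp_$tables$snp1$case_parental_mating$counts), 1)
  expect_null(exp_$tables$snp1$case_parent_trio)
  expect_error(extract_count_tables(pd, proband = c(A = "9")), "proband")
  # multiple units: both genotyped affected sibs yield trios
  lines2 <- c(lines[1:3], "A 4 1 2 2 2 A G A G A G")
  fx2 <- write_ped_fixture(lines2, map3)
  ex2 <- extract_count_tables(read_pedigrees(fx2$ped, fx2$map),
                              multiple_units = TRUE)
  expect_equal(sum(ex2$tables$snp1$case_parent_trio$counts), 2)
})

test_that("unknown phenotypes are controls only under the explicit flag", {
  lines <- c("A 1 0 0 1 0 A G A G A G",
             "B 1 0 0 1 1 A G A G G G")
  fx <- write_ped_fixture(lines, map3)
  pd <- read_pedigrees(fx$ped, fx$map)
  ex <- extract_count_tables(pd)
  expect_equal(sum(ex$tables$snp1$control$counts), 1)
  ex2 <- extract_count_tables(pd, unknown_as_control = TRUE)
  expect_equal(sum(ex2$tables$snp1$control$counts), 2)
})

test_that("extraction totals never exceed the family count", {
  des <- sim_design(c(case_parent_trio = 60, control = 20),
                    rp = risk_params(R2 = 2), q = 0.3, n_snps = 2,
                    missingness = 0.25, seed = 14)
  pd <- triomult:::.simulate_ped_data(des)
  ex <- extract_count_tables(pd)
  nfam <- length(unique(pd$fam$fid))
  for (s in names(ex$tables))
    expect_lte(sum(vapply(ex$tables[[s]], function(t) sum(t$counts),
                          numeric(1))), nfam)
})

test_that("allele recoding leaves reversal-closed fits invariant", {
  des <- sim_design(c(case_parent_trio = 120, control_parental_mating = 120),
                    rp = risk_params(R1 = 1.4, R2 = 2.1, S2 = 1.5), q = 0.3,
                    seed = 23)
  dir <- withr::local_tempdir()
  simulate_ped_files(des, dir)
  pd <- read_pedigrees(file.path(dir, "sim.ped"), file.path(dir, "sim.map"))
  ex1 <- extract_count_tables(pd)
  other <- ex1$info$allele2[1]
  ex2 <- extract_count_tables(pd, info = marker_info(pd,
    overrides = setNames(other, "snp1")))
  spec1 <- model_spec("HWE", c("R1", "R2", "S1", "S2"),
                      q_start = ex1$info$freq[1])
  spec2 <- model_spec("HWE", c("R1", "R2", "S1", "S2"),
                      q_start = 1 - ex1$info$freq[1])
  f1 <- fit_model(ex1$tables$snp1, spec1)
  f2 <- fit_model(ex2$tables$snp1, spec2)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  # and the swapped-coding count tables are the cell-permuted originals
  expect_equal(ex2$tables$snp1$case_parent_trio$counts,
               swap_risk_allele(ex1$tables$snp1$case_parent_trio)$counts)
})
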