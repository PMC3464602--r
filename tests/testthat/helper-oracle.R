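# Independent brute-force oracle for the case-trio cell distribution:
# enumerate ordered parental genotype pairs with their stratum weights and
# all phased child transmissions, apply the penetrance factors directly,
# and normalise.  Kept deliberately separate from the package's vectorised
# construction.

# mating-type indices of the ordered parental pair (gm, gf), as fixed by
# the canonical cell table
.pair_types <- data.frame(
  gm   = c(2, 2, 1, 2, 0, 1, 1, 0, 0),
  gf   = c(2, 1, 2, 0, 2, 1, 0, 1, 0),
  cepg = c(1, 2, 2, 3, 3, 4, 5, 5, 6),
  cpg  = c(1, 2, 3, 4, 5, 6, 7, 8, 9)
)

oracle_case_probs <- function(rp, sp) {
  cells <- trio_cells()
  # mating weight per ordered parental genotype pair.  The stratification
  # parameters are per allele arrangement, so a heterozygous parent
  # contributes its two arrangements (factor 2); HWE genotype
  # probabilities carry that multiplicity already.
  pair_weight <- function(gm, gf) {
    if (sp$assumption == "HWE")
      return(dbinom(gm, 2, sp$q) * dbinom(gf, 2, sp$q))
    row <- .pair_types$gm == gm & .pair_types$gf == gf
    mult <- 2^((gm == 1) + (gf == 1))
    mult * if (sp$assumption == "CPG") sp$mu[.pair_types$cpg[row]]
           else sp$mu[.pair_types$cepg[row]]
  }
  out <- numeric(15)
  for (gm in 0:2) for (gf in 0:2) {
    pm <- gm / 2; pf <- gf / 2
    for (tm in 0:1) for (tf in 0:1) {
      pt <- (if (tm == 1) pm else 1 - pm) * (if (tf == 1) pf else 1 - pf)
      if (pt == 0) next
      gc <- tm + tf
      w <- c(1, rp[["R1"]], rp[["R2"]])[gc + 1] *
           c(1, rp[["S1"]], rp[["S2"]])[gm + 1]
      nm <- sprintf("gamma%d%d", gm, gc)
      if (nm != "gamma00") w <- w * rp[[nm]]
      if (gc == 1) w <- w * (if (tm == 1) rp[["Im"]] else rp[["Ip"]])
      i <- which(cells$gm == gm & cells$gf == gf & cells$gc == gc)
      out[i] <- out[i] + pair_weight(gm, gf) * pt * w
    }
  }
  out / sum(out)
}

# a generic random parameter draw (all estimable parameters perturbed)
random_risk_params <- function(sd = 0.4) {
  nm <- c("R1", "R2", "S1", "S2", "Im", "Ip", "gamma01", "gamma10",
          "gamma11", "gamma12", "gamma21", "gamma22")
  do.call(risk_params, as.list(setNames(exp(rnorm(length(nm), 0, sd)), nm)))
}

random_strat_params <- function(assumption) {
  switch(assumption,
    HWE  = strat_params("HWE", q = runif(1, 0.1, 0.9)),
    PAE  = { m <- exp(rnorm(6, 0, 0.4)); m[4] <- m[3]
             strat_params("PAE", mu = m) },
    CEPG = strat_params("CEPG", mu = exp(rnorm(6, 0, 0.4))),
    CPG  = strat_params("CPG", mu = exp(rnorm(9, 0, 0.4))))
}

# the six-unit mixed design of the likelihood-comparison experiments
mixed_unit_design <- function(rp, q = 0.3, n = 50) {
  sim_design(c(case_parent_trio = n, case_mother_duo = n,
               case_father_duo = n, control_parental_mating = n,
               control_mother_duo = n, control_father_duo = n),
             rp = rp, q = q)
}

# write a tiny ped/map fixture from a matrix of row strings
write_ped_fixture <- function(ped_lines, map_lines,
                              dir = withr::local_tempdir(
                                .local_envir = parent.frame())) {
  ped <- file.path(dir, "fix.ped")
  map <- file.path(dir, "fix.map")
  writeLines(ped_lines, ped)
  writeLines(map_lines, map)
  list(ped = ped, map = map)
}
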