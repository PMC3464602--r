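# Stratification (nuisance) parameters and the multinomial cell
# probabilities for case and control units.

.assumptions <- c("HWE", "PAE", "CEPG", "CPG")

#' Mating-type stratification parameters
#'
#' Nuisance parameters describing the population distribution of parental
#' mating types.  Under `CEPG` (exchangeable parental genotypes, the
#' default) there are six strata; `PAE` (parental allelic exchangeability)
#' is CEPG with the constraint `mu[4] == mu[3]`; `CPG` (conditional on
#' parental genotypes) distinguishes the ordered parental pair with nine
#' strata; `HWE` replaces the strata by a single risk-allele frequency `q`
#' under Hardy-Weinberg equilibrium and random mating.
#'
#' The mu vector is defined up to an overall scale (the multinomial
#' normalisation absorbs it); during fitting the all-reference stratum
#' (mu6 for CEPG/PAE, mu9 for CPG) is held at 1.
#'
#' @param assumption one of "HWE", "PAE", "CEPG", "CPG".
#' @param mu positive stratification parameters (length 6 for CEPG/PAE,
#'   9 for CPG; ignored under HWE).  Default: all 1.
#' @param q risk-allele frequency in (0,1); used under HWE only.
#' @return An object of class `strat_params`.
#' @examples
#' strat_params("HWE", q = 0.3)
#' strat_params("CEPG", mu = hwe_mating_mu(0.3))
#' @export
strat_params <- function(assumption = c("CEPG", "HWE", "PAE", "CPG"),
                         mu = NULL, q = 0.5) {
  assumption <- match.arg(assumption)
  n_mu <- switch(assumption, HWE = 0L, CPG = 9L, 6L)
  if (is.null(mu)) mu <- rep(1, n_mu)
  if (assumption == "HWE") {
    mu <- numeric(0)
    if (!is.finite(q) || q <= 0 || q >= 1)
      stop("q must lie strictly in (0, 1)")
  } else {
    if (length(mu) != n_mu)
      stop(sprintf("%s requires %d stratification parameters, got %d",
                   assumption, n_mu, length(mu)))
    if (anyNA(mu) || any(!is.finite(mu)) || any(mu <= 0))
      stop("mu entries must be finite and > 0")
    if (assumption == "PAE" &&
        abs(mu[4] - mu[3]) > 1e-12 * max(mu[3], mu[4]))
      stop("PAE requires mu[4] == mu[3]")
  }
  structure(list(assumption = assumption, mu = unname(mu), q = q),
            class = "strat_params")
}

#' Exchangeable mating-type strata induced by Hardy-Weinberg equilibrium
#'
#' The six CEPG stratification parameters that make the exchangeable-mating
#' model coincide cell-for-cell with the HWE model at allele frequency `q`
#' (each stratum carries the HWE probability of one ordered parental
#' genotype pair of that mating type).
#'
#' Because strata are parameterised per ordered parental allele
#' arrangement (the heterozygote multiplicity is a fixed cell
#' coefficient), the induced values satisfy the allelic-exchangeability
#' constraint `mu[4] == mu[3]`: the assumption hierarchy is
#' HWE within PAE within CEPG within CPG.
#'
#' @param q risk-allele frequency in (0,1).
#' @return Numeric vector of length 6, `q^a * (1-q)^(4-a)` with `a` the
#'   parental risk-allele total of the mating type.
#' @export
hwe_mating_mu <- function(q) {
  stopifnot(is.finite(q), q > 0, q < 1)
  p <- 1 - q
  c(q^4, q^3 * p, q^2 * p^2, q^2 * p^2, q * p^3, p^4)
}

# base(i) = stratum mass x allele-arrangement multiplicity x Mendelian
# weight, common to cases and controls.  Under HWE the genotype
# probabilities dbinom(g, 2, q) already carry the heterozygote
# multiplicity.
cell_base <- function(sp) {
  stopifnot(inherits(sp, "strat_params"))
  tc <- trio_cells()
  switch(sp$assumption,
    HWE = stats::dbinom(tc$gm, 2, sp$q) * stats::dbinom(tc$gf, 2, sp$q) *
          tc$weight,
    CPG = sp$mu[tc$cpg] * tc$pairs * tc$weight,
    sp$mu[tc$cepg] * tc$pairs * tc$weight)   # CEPG and PAE
}

#' Trio cell probabilities for case and control units
#'
#' `case_trio_cell_probs()` returns P(gm, gf, gc | child affected) for the
#' 15 Mendelian cells in canonical order: proportional to the mating-type
#' stratum mass times the Mendelian segregation weight times the penetrance
#' multiplier of the cell (phase-averaged for the ambiguous het x het ->
#' het cell).  `control_trio_cell_probs()` is the same construction with
#' all penetrance multipliers equal to 1, i.e. the general-population
#' distribution of genotype configurations (a rare-disease assumption when
#' controls are genuinely unaffected).
#'
#' @param rp a [risk_params()] object.
#' @param sp a [strat_params()] object (shared between the case and
#'   control sides of one analysis).
#' @return Numeric probability vector of length 15 summing to 1.
#' @examples
#' p <- case_trio_cell_probs(risk_params(R2 = 2), strat_params("HWE", q = .3))
#' stopifnot(abs(sum(p) - 1) < 1e-12)
#' @export
case_trio_cell_probs <- function(rp, sp) {
  v <- cell_base(sp) * cell_multipliers(rp)
  v / sum(v)
}

#' @rdname case_trio_cell_probs
#' @export
control_trio_cell_probs <- function(sp) {
  v <- cell_base(sp)
  v / sum(v)
}

#' Log-likelihood of one unit-type count table
#'
#' Collapses a 15-cell trio probability vector to the observable
#' combinations of the table's unit type and returns the multinomial
#' log-likelihood contribution `sum(counts * log(collapsed probs))`.
#' Pass the case probability vector for case units and the control vector
#' for control units.
#'
#' @param table a [count_table()].
#' @param trio_probs probability vector of length 15 (canonical order).
#' @return The log-likelihood; `-Inf` (with attribute `zero_cell = TRUE`)
#'   if a positive count sits on a zero-probability combination.
#' @export
unit_log_likelihood <- function(table, trio_probs) {
  stopifnot(inherits(table, "count_table"), length(trio_probs) == 15)
  cm <- collapse_map(table$kind)
  p <- vapply(cm$cells, function(i) sum(trio_probs[i]), numeric(1))
  p <- p / sum(p)
  nz <- table$counts > 0
  if (any(nz & p == 0))
    return(structure(-Inf, zero_cell = TRUE))
  sum(table$counts[nz] * log(p[nz]))
}

#' Total log-likelihood over a collection of unit tables
#'
#' Sums [unit_log_likelihood()] over all tables for one SNP, using the case
#' cell probabilities for case units and the control probabilities for
#' control units, with a single shared set of stratification parameters.
#'
#' @param tables list of [count_table()] objects (one SNP).
#' @inheritParams case_trio_cell_probs
#' @return The total log-likelihood (0 for an empty collection).
#' @export
total_log_likelihood <- function(tables, rp, sp) {
  if (!length(tables)) return(0)
  pc <- case_trio_cell_probs(rp, sp)
  p0 <- control_trio_cell_probs(sp)
  ll <- 0
  zero <- FALSE
  for (tab in tables) {
    li <- unit_log_likelihood(tab, if (is_case_unit(tab$kind)) pc else p0)
    zero <- zero || isTRUE(attr(li, "zero_cell"))
    ll <- ll + li
  }
  if (zero) structure(as.numeric(ll), zero_cell = TRUE) else as.numeric(ll)
}
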