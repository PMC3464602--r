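# Model specification: which risk parameters are free, which likelihood
# assumption stratifies the matings, and which multiplicative constraints
# tie parameters together.

.constraint_names <- c("child_multiplicative", "maternal_multiplicative")

#' Specify a model to be fitted
#'
#' @param assumption likelihood assumption: "HWE", "PAE", "CEPG" or "CPG"
#'   (see [strat_params()]).
#' @param free_risk character vector of relative-risk parameters to
#'   estimate (subset of R1, R2, S1, S2, Im, Ip, gamma01, gamma10, gamma11,
#'   gamma12, gamma21, gamma22).  Parameters not listed are held at 1.
#' @param constraints optional multiplicative constraints:
#'   `"child_multiplicative"` imposes R2 = R1^2, `"maternal_multiplicative"`
#'   imposes S2 = S1^2.  A constrained parameter cannot also be free.
#' @param q_start starting value for the allele frequency under HWE
#'   (typically the marker-file estimate).
#' @return An object of class `model_spec`, with `n_free` counting the free
#'   risk parameters plus the free stratification parameters (1 under HWE,
#'   4 under PAE, 5 under CEPG, 8 under CPG; one stratum is the fixed
#'   reference).
#' @examples
#' model_spec("HWE", free_risk = c("R1", "R2"), q_start = 0.3)
#' @export
model_spec <- function(assumption = c("CEPG", "HWE", "PAE", "CPG"),
                       free_risk = character(),
                       constraints = character(),
                       q_start = 0.5) {
  assumption <- match.arg(assumption)
  free_risk <- as.character(free_risk)
  bad <- setdiff(free_risk, .free_risk_menu)
  if (length(bad))
    stop("not estimable risk parameter(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(free_risk))
    stop("duplicated free risk parameters")
  constraints <- as.character(constraints)
  bad <- setdiff(constraints, .constraint_names)
  if (length(bad))
    stop("unknown constraint(s): ", paste(bad, collapse = ", "))
  if ("child_multiplicative" %in% constraints && "R2" %in% free_risk)
    stop("R2 cannot be free under the child_multiplicative constraint")
  if ("maternal_multiplicative" %in% constraints && "S2" %in% free_risk)
    stop("S2 cannot be free under the maternal_multiplicative constraint")
  if (!is.finite(q_start) || q_start <= 0 || q_start >= 1)
    stop("q_start must lie strictly in (0, 1)")
  n_strat <- switch(assumption, HWE = 1L, PAE = 4L, CEPG = 5L, CPG = 8L)
  structure(list(assumption = assumption, free_risk = free_risk,
                 constraints = constraints, q_start = q_start,
                 n_strat = n_strat,
                 n_free = length(free_risk) + n_strat),
            class = "model_spec")
}

# names of the free parameter vector, risk first then stratification
free_param_names <- function(spec) {
  strat <- switch(spec$assumption,
    HWE  = "q",
    PAE  = paste0("mu", c(1, 2, 3, 5)),
    CEPG = paste0("mu", 1:5),
    CPG  = paste0("mu", 1:8))
  c(spec$free_risk, strat)
}

#' Expand a free-parameter vector into full parameter objects
#'
#' Maps the free values of a [model_spec()] (natural scale, in the order
#' given by the spec: free risk parameters first, then stratification
#' parameters) to a complete ([risk_params()], [strat_params()]) pair,
#' applying the multiplicative constraints (R2 = R1^2, S2 = S1^2), the
#' parental-allelic-exchangeability tie mu4 = mu3, and the reference values
#' (1) for everything not free.
#'
#' @param spec a [model_spec()].
#' @param free_values numeric vector of length `spec$n_free`.
#' @return A list with components `rp` and `sp`.
#' @examples
#' s <- model_spec("HWE", free_risk = "R1",
#'                 constraints = "child_multiplicative")
#' apply_constraints(s, c(1.5, 0.3))$rp[["R2"]]  # 2.25
#' @export
apply_constraints <- function(spec, free_values) {
  stopifnot(inherits(spec, "model_spec"))
  if (length(free_values) != spec$n_free)
    stop(sprintf("expected %d free values, got %d",
                 spec$n_free, length(free_values)))
  nr <- length(spec$free_risk)
  rp <- risk_params()
  rp[spec$free_risk] <- free_values[seq_len(nr)]
  if ("child_multiplicative" %in% spec$constraints)
    rp[["R2"]] <- rp[["R1"]]^2
  if ("maternal_multiplicative" %in% spec$constraints)
    rp[["S2"]] <- rp[["S1"]]^2
  if (any(unclass(rp) <= 0)) stop("risk parameters must be > 0")
  sv <- free_values[nr + seq_len(length(free_values) - nr)]
  sp <- switch(spec$assumption,
    HWE  = strat_params("HWE", q = sv),
    PAE  = strat_params("PAE", mu = c(sv[1:3], sv[3], sv[4], 1)),
    CEPG = strat_params("CEPG", mu = c(sv, 1)),
    CPG  = strat_params("CPG", mu = c(sv, 1)))
  list(rp = rp, sp = sp)
}
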