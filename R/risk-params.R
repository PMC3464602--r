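# Multiplicative relative-risk parameters and per-cell penetrance
# multipliers.  The baseline penetrance cancels in the conditional
# likelihood, so only the multipliers appear.

.risk_param_names <- c("R1", "R2", "S1", "S2", "Im", "Ip",
                       "gamma01", "gamma02", "gamma10", "gamma11",
                       "gamma12", "gamma20", "gamma21", "gamma22")

# gamma02 / gamma20 multiply no Mendelian-consistent cell; they are kept in
# the grid for completeness but carry no likelihood information.
.free_risk_menu <- setdiff(.risk_param_names, c("gamma02", "gamma20"))

#' Relative-risk parameters
#'
#' The multiplicative genotype relative risks of the penetrance model:
#' `R1`/`R2` for a child carrying one/two risk alleles, `S1`/`S2` for a
#' mother carrying one/two, `Im`/`Ip` for a heterozygous child whose risk
#' allele is maternally/paternally inherited, and an interaction grid
#' `gammaIJ` for a mother with I and child with J risk-allele copies
#' (`gamma00` is the fixed reference).  Parameters default to 1 (no effect).
#'
#' @param ... named parameter values, e.g. `risk_params(R1 = 1.5, R2 = 2.25)`.
#'   Valid names: R1, R2, S1, S2, Im, Ip, gamma01, gamma02, gamma10,
#'   gamma11, gamma12, gamma20, gamma21, gamma22.
#' @return A named numeric vector of class `risk_params`.
#' @export
risk_params <- function(...) {
  v <- stats::setNames(rep(1, length(.risk_param_names)), .risk_param_names)
  args <- list(...)
  if (length(args)) {
    bad <- setdiff(names(args), .risk_param_names)
    if (length(bad) || is.null(names(args)) || any(names(args) == ""))
      stop("unknown risk parameter(s): ",
           paste(if (length(bad)) bad else "<unnamed>", collapse = ", "))
    vals <- unlist(args)
    if (anyNA(vals) || any(!is.finite(vals)) || any(vals <= 0))
      stop("risk parameters must be finite and > 0")
    v[names(args)] <- vals
  }
  structure(v, class = "risk_params")
}

as_risk_params <- function(x) {
  if (inherits(x, "risk_params")) return(x)
  do.call(risk_params, as.list(x))
}

#' Penetrance multiplier of one trio genotype configuration
#'
#' The factor by which the baseline disease risk is multiplied for a child
#' in configuration (`gm`, `gf`, `gc`): the child-genotype factor, the
#' maternal-genotype factor, the mother-child interaction factor, and (for
#' heterozygous children) the imprinting factor keyed to the parental
#' origin of the single risk allele.
#'
#' @param gm,gf,gc risk-allele counts of mother, father, child (must be
#'   Mendelian-consistent).
#' @param phase parental origin of a heterozygous child's risk allele
#'   ("maternal" or "paternal"); must be "none" for homozygous children.
#'   The stated phase must be possible for the configuration.
#' @param rp a [risk_params()] object.
#' @return A positive scalar.
#' @examples
#' rp <- risk_params(R1 = 2, S2 = 3, Im = 1.5, gamma21 = 1.2)
#' penetrance_multiplier(2, 0, 1, "maternal", rp)  # R1 * S2 * Im * gamma21
#' @export
penetrance_multiplier <- function(gm, gf, gc,
                                  phase = c("none", "maternal", "paternal"),
                                  rp = risk_params()) {
  phase <- match.arg(phase)
  rp <- as_risk_params(rp)
  mendelian_weight(gm, gf, gc)  # validates consistency
  if (gc == 1L) {
    mat_possible <- gm > 0 && gf < 2
    pat_possible <- gf > 0 && gm < 2
    if (phase == "none")
      stop("a heterozygous child requires phase 'maternal' or 'paternal'")
    if (phase == "maternal" && !mat_possible)
      stop("maternal origin impossible for this configuration")
    if (phase == "paternal" && !pat_possible)
      stop("paternal origin impossible for this configuration")
  } else if (phase != "none") {
    stop("phase applies only to heterozygous children")
  }
  w <- c(1, rp[["R1"]], rp[["R2"]])[gc + 1] *
       c(1, rp[["S1"]], rp[["S2"]])[gm + 1]
  if (gm > 0L || gc > 0L) w <- w * rp[[sprintf("gamma%d%d", gm, gc)]]
  if (gc == 1L) w <- w * if (phase == "maternal") rp[["Im"]] else rp[["Ip"]]
  unname(w)
}

# Vectorised penetrance multipliers for the 15 cells.  Imprinting factors
# attach to heterozygous children only; the phase-ambiguous het x het ->
# het cell takes the phase average (Im + Ip) / 2.
cell_multipliers <- function(rp) {
  rp <- as_risk_params(rp)
  tc <- trio_cells()
  gidx <- ifelse(tc$gm == 0L & tc$gc == 0L, NA,
                 match(sprintf("gamma%d%d", tc$gm, tc$gc), .risk_param_names))
  g <- ifelse(is.na(gidx), 1, unclass(rp)[gidx])
  im <- rp[["Im"]]; ip <- rp[["Ip"]]
  i <- c(none = 1, maternal = im, paternal = ip,
         both = (im + ip) / 2)[tc$phase]
  unname(c(1, rp[["R1"]], rp[["R2"]])[tc$gc + 1] *
         c(1, rp[["S1"]], rp[["S2"]])[tc$gm + 1] * g * i)
}
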