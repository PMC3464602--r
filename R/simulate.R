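# Seeded simulator of family genotype data of all unit types, both as
# in-memory count tables and as round-trippable PLINK ped/map files.  Both
# output paths consume the same latent trio-cell draws, so with the same
# seed the extracted count tables equal the directly simulated ones.

#' Specify a simulation design
#'
#' @param n_units named vector of unit counts per SNP-independent family
#'   set, e.g. `c(case_parent_trio = 50, control_mother_duo = 50)`; names
#'   must be unit kinds (see [unit_kinds()]).
#' @param rp [risk_params()] applied at causal SNPs (non-causal SNPs use
#'   all-1 risk parameters).
#' @param q risk-allele frequency in (0, 1); parental genotypes are drawn
#'   under Hardy-Weinberg equilibrium and random mating.
#' @param n_snps number of independent SNPs.
#' @param causal indices of causal SNPs (where `rp` applies), or a named
#'   list mapping SNP indices to [risk_params()] for per-SNP effects.
#' @param missingness probability that any single genotype call is missing
#'   in the emitted pedigree files.
#' @param seed default random seed for the simulation functions.
#' @return An object of class `sim_design`.
#' @examples
#' sim_design(c(case_parent_trio = 50), rp = risk_params(R2 = 2), q = 0.3)
#' @export
sim_design <- function(n_units, rp = risk_params(), q = 0.3, n_snps = 1L,
                       causal = seq_len(n_snps), missingness = 0,
                       seed = NULL) {
  bad <- setdiff(names(n_units), unit_kinds())
  if (length(bad) || is.null(names(n_units)))
    stop("n_units must be named by unit kinds; unknown: ",
         paste(bad, collapse = ", "))
  if (any(n_units < 0)) stop("unit counts must be >= 0")
  if (!is.finite(q) || q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  if (missingness < 0 || missingness > 1)
    stop("missingness must lie in [0, 1]")
  if (is.list(causal)) {
    idx <- as.integer(names(causal))
    if (anyNA(idx)) stop("causal list must be named by SNP indices")
    causal_rp <- lapply(causal, as_risk_params)
    names(causal_rp) <- idx
  } else {
    idx <- as.integer(causal)
    causal_rp <- stats::setNames(rep(list(as_risk_params(rp)), length(idx)),
                                 idx)
  }
  if (any(idx < 1 | idx > n_snps)) stop("causal SNP index out of range")
  structure(list(n_units = n_units[n_units > 0], q = q,
                 n_snps = as.integer(n_snps), causal = causal_rp,
                 missingness = missingness, seed = seed),
            class = "sim_design")
}

.design_seed <- function(design, seed) {
  s <- if (is.null(seed)) design$seed else seed
  if (is.null(s)) stop("a seed is required (in the design or as argument)")
  s
}

# latent trio-cell draws: list (per unit kind) of n x n_snps matrices
.draw_latent_cells <- function(design, seed = NULL) {
  set.seed(.design_seed(design, seed))
  kinds <- names(design$n_units)
  cells <- lapply(design$n_units, function(n)
    matrix(NA_integer_, n, design$n_snps))
  sp <- strat_params("HWE", q = design$q)
  p0 <- control_trio_cell_probs(sp)
  for (s in seq_len(design$n_snps)) {
    rp_s <- design$causal[[as.character(s)]]
    pc <- if (is.null(rp_s)) p0 else case_trio_cell_probs(rp_s, sp)
    for (k in kinds) {
      n <- design$n_units[[k]]
      prob <- if (is_case_unit(k)) pc else p0
      cells[[k]][, s] <- sample.int(15L, n, replace = TRUE, prob = prob)
    }
  }
  cells
}

#' Simulate per-SNP unit count tables
#'
#' Draws, for every family unit, a latent complete trio configuration from
#' the case (for case units) or control (for control units) cell
#' probabilities under the design's HWE stratification, then tabulates the
#' observable combinations of each unit type.
#'
#' @param design a [sim_design()].
#' @param seed random seed (defaults to the design's).
#' @return Named per-SNP list of [count_table()] lists, suitable for
#'   [fit_model()] / [analyse_snps()] / [write_count_files()].
#' @export
simulate_unit_tables <- function(design, seed = NULL) {
  stopifnot(inherits(design, "sim_design"))
  cells <- .draw_latent_cells(design, seed)
  kinds <- names(design$n_units)
  comb_of_cell <- lapply(stats::setNames(kinds, kinds), function(k) {
    cm <- collapse_map(k)
    v <- integer(15)
    for (i in seq_along(cm$cells)) v[cm$cells[[i]]] <- i
    v
  })
  snps <- paste0("snp", seq_len(design$n_snps))
  tables <- lapply(seq_len(design$n_snps), function(s)
    lapply(stats::setNames(kinds, kinds), function(k) {
      cm <- collapse_map(k)
      count_table(k, tabulate(comb_of_cell[[k]][cells[[k]][, s]],
                              nbins = length(cm$cells)),
                  snp = snps[s])
    }))
  stats::setNames(tables, snps)
}

# which members are genotyped / present in the emitted pedigree, per kind
.sim_layout <- list(
  case_parent_trio        = list(geno = c("gm", "gf", "gc"), child = "2"),
  case_mother_duo         = list(geno = c("gm", "gc"), child = "2"),
  case_father_duo         = list(geno = c("gf", "gc"), child = "2"),
  case                    = list(geno = "gc", child = "2"),
  case_parental_mating    = list(geno = c("gm", "gf"), child = "2"),
  case_mother             = list(geno = "gm", child = "2"),
  case_father             = list(geno = "gf", child = "2"),
  control_parental_mating = list(geno = c("gm", "gf"), child = "1"),
  control_mother_duo      = list(geno = c("gm", "gc"), child = "1"),
  control_father_duo      = list(geno = c("gf", "gc"), child = "1"),
  control                 = list(geno = "gc", child = "1")
)

#' Simulate PLINK-format pedigree files
#'
#' Emits one nuclear family per simulated unit.  Members whose genotype
#' the unit type does not observe are either absent from the pedigree
#' (missing parents of duos and singletons) or present with a fully
#' missing genotype (ungenotyped children of parental-mating and
#' single-parent units), so that per-SNP extraction with
#' [extract_count_tables()] reproduces the designed unit mix exactly when
#' `missingness = 0`.  The risk allele is written as "A", the other allele
#' as "G"; with `q < 0.5` the default minor-allele assignment recovers the
#' simulated risk allele.
#'
#' @inheritParams simulate_unit_tables
#' @param dir output directory for `sim.ped`, `sim.map` and a `sim.cfg`
#'   design echo.
#' @return Invisibly, the `ped_data` object written.
#' @export
simulate_ped_files <- function(design, dir, seed = NULL) {
  stopifnot(inherits(design, "sim_design"))
  pd <- .simulate_ped_data(design, seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ped_files(pd, file.path(dir, "sim.ped"), file.path(dir, "sim.map"))
  cfg <- c(list(q = design$q, n_snps = design$n_snps,
                missingness = design$missingness,
                seed = .design_seed(design, seed),
                causal = paste(names(design$causal), collapse = ",")),
           stats::setNames(as.list(design$n_units),
                           paste0("n_", names(design$n_units))))
  rp1 <- design$causal[[1]]
  if (!is.null(rp1)) {
    eff <- unclass(rp1)[unclass(rp1) != 1]
    cfg <- c(cfg, as.list(eff))
  }
  write_config(cfg, file.path(dir, "sim.cfg"))
  invisible(pd)
}

.simulate_ped_data <- function(design, seed = NULL) {
  if (design$q >= 0.5)
    warning("q >= 0.5: the simulated risk allele is not the minor allele; ",
            "default extraction will assign the opposite coding")
  cells <- .draw_latent_cells(design, seed)
  tc <- trio_cells()
  kinds <- names(design$n_units)
  gstr <- c("G G", "A G", "A A")   # risk-allele count 0/1/2
  fam <- list(); a1 <- list(); a2 <- list()
  fam_no <- 0L
  for (k in kinds) {
    lay <- .sim_layout[[k]]
    for (i in seq_len(design$n_units[[k]])) {
      fam_no <- fam_no + 1L
      fid <- sprintf("F%05d", fam_no)
      cl <- cells[[k]][i, ]
      with_father <- "gf" %in% lay$geno
      with_mother <- "gm" %in% lay$geno
      g <- function(memb, present)
        if (present) gstr[tc[[memb]][cl] + 1L] else rep("0 0",
                                                        design$n_snps)
      if (with_father) {
        fam[[length(fam) + 1L]] <- c(fid, "1", "0", "0", "1", "0")
        a1[[length(a1) + 1L]] <- g("gf", TRUE)
      }
      if (with_mother) {
        fam[[length(fam) + 1L]] <- c(fid, "2", "0", "0", "2", "0")
        a1[[length(a1) + 1L]] <- g("gm", TRUE)
      }
      fam[[length(fam) + 1L]] <- c(fid, "3",
                                   if (with_father) "1" else "0",
                                   if (with_mother) "2" else "0",
                                   "1", lay$child)
      a1[[length(a1) + 1L]] <- g("gc", "gc" %in% lay$geno)
    }
  }
  fam <- as.data.frame(do.call(rbind, fam), stringsAsFactors = FALSE)
  names(fam) <- c("fid", "iid", "pat", "mat", "sex", "pheno")
  fam$status <- ifelse(fam$pheno == "2", "affected",
                ifelse(fam$pheno == "1", "unaffected", "unknown"))
  gg <- do.call(rbind, a1)
  A1 <- substr(gg, 1, 1)
  A2 <- substr(gg, 3, 3)
  dim(A1) <- dim(A2) <- dim(gg)
  map <- data.frame(chr = "1", snp = paste0("snp", seq_len(design$n_snps)),
                    cm = 0, pos = seq_len(design$n_snps),
                    stringsAsFactors = FALSE)
  colnames(A1) <- colnames(A2) <- map$snp
  pd <- structure(list(fam = fam, map = map, a1 = A1, a2 = A2),
                  class = "ped_data")
  if (design$missingness > 0)
    pd <- apply_missingness(pd, design$missingness)
  pd
}

#' Blank genotype calls at random
#'
#' Independently sets each present genotype call (one individual at one
#' SNP) to missing with probability `p`; downstream extraction then
#' re-derives unit types per SNP from the surviving calls.
#'
#' @param ped_data a `ped_data` object.
#' @param p missingness probability in [0, 1].
#' @param seed optional seed; by default the current RNG stream is used
#'   (so the operation is reproducible as part of a seeded pipeline).
#' @return The thinned `ped_data`.
#' @export
apply_missingness <- function(ped_data, p, seed = NULL) {
  stopifnot(inherits(ped_data, "ped_data"), p >= 0, p <= 1)
  if (!is.null(seed)) set.seed(seed)
  if (p == 0) return(ped_data)
  drop <- matrix(stats::runif(length(ped_data$a1)) < p,
                 nrow(ped_data$a1))
  ped_data$a1[drop] <- "0"
  ped_data$a2[drop] <- "0"
  ped_data
}

#' Rejection-sampling cross-check of the case-trio distribution
#'
#' Samples complete case/parent trios the long way round: draw parental
#' genotypes from the stratification model and a phased child transmission,
#' then accept the trio as a case with probability alpha times the
#' penetrance multiplier.  The accepted-cell distribution equals
#' [case_trio_cell_probs()]; this path exists as an independent oracle for
#' the direct conditional sampler and is far slower.
#'
#' @param n number of accepted case trios required.
#' @param rp,sp model parameters; `alpha` the baseline penetrance (must
#'   keep all penetrances <= 1).
#' @param alpha baseline penetrance.
#' @param seed random seed.
#' @return Integer vector of accepted counts per trio cell (length 15).
#' @export
sample_case_trios_rejection <- function(n, rp, sp, alpha = 0.01,
                                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rp <- as_risk_params(rp)
  w <- cell_multipliers(rp)
  if (alpha * max(w) > 1)
    stop("alpha too large: penetrance exceeds 1")
  p0 <- control_trio_cell_probs(sp)
  tc <- trio_cells()
  counts <- integer(15)
  got <- 0L
  while (got < n) {
    batch <- max(1000L, ceiling((n - got) / (alpha * mean(w))))
    cl <- sample.int(15L, batch, replace = TRUE, prob = p0)
    # phased penetrance: resolve the ambiguous cell by transmission origin
    pen <- numeric(batch)
    amb <- tc$phase[cl] == "both"
    pen[!amb] <- w[cl[!amb]]
    if (any(amb)) {
      base <- w[cl[amb]] * 2 / (rp[["Im"]] + rp[["Ip"]])
      mat <- stats::runif(sum(amb)) < 0.5
      pen[amb] <- base * ifelse(mat, rp[["Im"]], rp[["Ip"]])
    }
    keep <- stats::runif(batch) < alpha * pen
    kept <- cl[keep]
    if (length(kept) > n - got) kept <- kept[seq_len(n - got)]
    counts <- counts + tabulate(kept, nbins = 15L)
    got <- got + length(kept)
  }
  counts
}
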