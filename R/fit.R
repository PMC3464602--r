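# Maximum-likelihood fitting, likelihood-ratio tests and identifiability
# diagnostics.  All positive parameters are optimised on the log scale
# (the allele frequency on the logit scale), with an analytic gradient of
# the collapsed multinomial log-likelihood.

# column of d log(cell mass) / d theta for one free parameter, on the
# internal (log / logit) scale, at the current parameter values
.exp_col <- function(name, tc, rp, sp) {
  if (name == "q") return(tc$gm + tc$gf - 4 * sp$q)
  if (grepl("^mu[0-9]$", name)) {
    t <- as.integer(substring(name, 3))
    if (sp$assumption == "CPG") return(as.numeric(tc$cpg == t))
    if (sp$assumption == "PAE" && t == 3L)
      return(as.numeric(tc$cepg %in% 3:4))
    return(as.numeric(tc$cepg == t))
  }
  im <- rp[["Im"]]; ip <- rp[["Ip"]]
  switch(name,
    R1 = as.numeric(tc$gc == 1L),
    R2 = as.numeric(tc$gc == 2L),
    S1 = as.numeric(tc$gm == 1L),
    S2 = as.numeric(tc$gm == 2L),
    Im = as.numeric(tc$phase == "maternal") +
         (tc$phase == "both") * im / (im + ip),
    Ip = as.numeric(tc$phase == "paternal") +
         (tc$phase == "both") * ip / (im + ip),
    {
      ij <- as.integer(strsplit(substring(name, 6), "")[[1]])
      as.numeric(tc$gm == ij[1] & tc$gc == ij[2])
    })
}

# 15 x p matrix of log-derivative columns; constraint folding for the
# multiplicative models (R2 = R1^2 adds 2 x the R2 column to R1, etc.)
.exp_matrix <- function(names, tc, rp, sp, constraints = character()) {
  E <- vapply(names, .exp_col, numeric(15), tc = tc, rp = rp, sp = sp)
  if ("child_multiplicative" %in% constraints && "R1" %in% names)
    E[, "R1"] <- E[, "R1"] + 2 * .exp_col("R2", tc, rp, sp)
  if ("maternal_multiplicative" %in% constraints && "S1" %in% names)
    E[, "S1"] <- E[, "S1"] + 2 * .exp_col("S2", tc, rp, sp)
  E
}

# internal <-> natural scale for the free vector
.to_internal <- function(spec, natural) {
  nr <- length(spec$free_risk)
  rest <- nr + seq_len(length(natural) - nr)
  c(log(natural[seq_len(nr)]),
    if (spec$assumption == "HWE") stats::qlogis(natural[rest])
    else log(natural[rest]))
}
.to_natural <- function(spec, internal) {
  nr <- length(spec$free_risk)
  rest <- nr + seq_len(length(internal) - nr)
  c(exp(internal[seq_len(nr)]),
    if (spec$assumption == "HWE") stats::plogis(internal[rest])
    else exp(internal[rest]))
}

# objective closures (log-likelihood and analytic gradient) over the
# internal free vector
.make_objective <- function(tables, spec) {
  tc <- trio_cells()
  pn <- free_param_names(spec)
  nr <- length(spec$free_risk)
  prep <- lapply(tables, function(tab) {
    cm <- collapse_map(tab$kind)
    C <- matrix(0, length(cm$cells), 15)
    for (k in seq_along(cm$cells)) C[k, cm$cells[[k]]] <- 1
    list(m = as.numeric(tab$counts), M = sum(tab$counts), C = C,
         case = is_case_unit(tab$kind))
  })
  unpack <- function(par) apply_constraints(spec, .to_natural(spec, par))
  # points the parameterisation cannot represent (overflow of exp, q
  # rounding onto 0/1 during a long line-search step) score -1e12 so the
  # line search backtracks
  unpack_safe <- function(par)
    tryCatch(unpack(par), error = function(e) NULL)
  fn <- function(par) {
    pa <- unpack_safe(par)
    if (is.null(pa)) return(-1e12)
    base <- cell_base(pa$sp)
    u_case <- base * cell_multipliers(pa$rp)
    ll <- 0
    for (tb in prep) {
      u <- if (tb$case) u_case else base
      v <- drop(tb$C %*% u)
      if (anyNA(v) || any(v <= 0 & tb$m > 0)) return(-1e12)
      pos <- tb$m > 0
      ll <- ll + sum(tb$m[pos] * log(v[pos])) - tb$M * log(sum(u))
    }
    ll
  }
  gr <- function(par) {
    pa <- unpack_safe(par)
    if (is.null(pa)) return(numeric(length(pn)))
    base <- cell_base(pa$sp)
    u_case <- base * cell_multipliers(pa$rp)
    E <- .exp_matrix(pn, tc, pa$rp, pa$sp, spec$constraints)
    g <- numeric(length(pn))
    for (tb in prep) {
      u <- if (tb$case) u_case else base
      Et <- E
      if (!tb$case && nr > 0) Et[, seq_len(nr)] <- 0
      v <- drop(tb$C %*% u)
      if (any(v <= 0 & tb$m > 0)) return(g)
      uE <- u * Et
      num <- tb$C %*% uE
      ok <- v > 0
      g <- g + colSums(num[ok, , drop = FALSE] * (tb$m[ok] / v[ok])) -
        tb$M * colSums(uE) / sum(u)
    }
    g
  }
  list(fn = fn, gr = gr, unpack = unpack, names = pn)
}

#' Fit a multinomial relative-risk model by maximum likelihood
#'
#' Maximises [total_log_likelihood()] over the free parameters of a
#' [model_spec()] by quasi-Newton (BFGS) iteration on log-transformed
#' parameters, with an analytic gradient.  Standard errors come from the
#' inverse of the numerically differentiated Hessian at the optimum,
#' delta-method-transformed to the natural scale; on Hessian failure they
#' are reported as `NA`.
#'
#' @param tables list of [count_table()] objects for one SNP.
#' @param spec a [model_spec()].
#' @param start optional named starting values on the natural scale (order
#'   and names as `spec`'s free parameters: free risk parameters, then `q`
#'   or `mu1`, `mu2`, ...).  Defaults: risk parameters 1, mu 1, q from
#'   `spec$q_start`.
#' @return An object of class `trio_fit`: list with `loglik`, `estimates`
#'   (full `rp`/`sp` pair), `free` (named free-parameter estimates, natural
#'   scale), `se` (delta-method standard errors), `n_free`, `converged`,
#'   `iterations`, `boundary` (TRUE when an estimate ran to the edge of the
#'   positive range) and `spec`.
#' @export
fit_model <- function(tables, spec, start = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (!length(tables) || !any(vapply(tables, function(t) sum(t$counts),
                                     numeric(1)) > 0))
    stop("no non-zero count tables to fit")
  obj <- .make_objective(tables, spec)
  pn <- obj$names
  if (is.null(start)) {
    start <- stats::setNames(rep(1, length(pn)), pn)
    # strata start at their random-mating shape at q_start (odds ratio
    # (q/p)^a per parental allele total a), the analogue of seeding the
    # HWE fit with the marker frequency
    odds <- spec$q_start / (1 - spec$q_start)
    a <- switch(spec$assumption,
                HWE = NULL, PAE = c(4, 3, 2, 1), CEPG = c(4, 3, 2, 2, 1),
                CPG = c(4, 3, 3, 2, 2, 2, 1, 1))
    if (spec$assumption == "HWE") start[["q"]] <- spec$q_start
    else start[seq.int(length(spec$free_risk) + 1L, length(pn))] <- odds^a
  } else {
    if (length(start) != length(pn))
      stop(sprintf("start must have %d values (%s)", length(pn),
                   paste(pn, collapse = ", ")))
    start <- stats::setNames(as.numeric(start), pn)
  }
  p0 <- .to_internal(spec, start)
  opt <- stats::optim(p0, obj$fn, obj$gr, method = "BFGS",
                      control = list(fnscale = -1, maxit = 500,
                                     reltol = 1e-12))
  est_nat <- stats::setNames(.to_natural(spec, opt$par), pn)
  se <- rep(NA_real_, length(pn))
  H <- tryCatch(.num_hessian(obj$gr, opt$par), error = function(e) NULL)
  if (!is.null(H)) {
    V <- tryCatch(solve(-(H + t(H)) / 2), error = function(e) NULL)
    if (!is.null(V) && all(diag(V) > 0)) {
      se_int <- sqrt(diag(V))
      # delta method: log scale -> x * se, logit scale -> q(1-q) * se
      scale <- est_nat
      if (spec$assumption == "HWE") {
        q <- est_nat[["q"]]
        scale[length(pn)] <- q * (1 - q)
      }
      se <- se_int * scale
    }
  }
  structure(list(
    loglik = opt$value,
    estimates = obj$unpack(opt$par),
    free = est_nat,
    se = stats::setNames(se, pn),
    n_free = spec$n_free,
    converged = opt$convergence == 0,
    iterations = unname(opt$counts[1]),
    boundary = any(abs(opt$par) > log(1000)),
    spec = spec), class = "trio_fit")
}

# central-difference Jacobian of the gradient
.num_hessian <- function(gr, par, h = 1e-5) {
  p <- length(par)
  H <- matrix(NA_real_, p, p)
  for (j in seq_len(p)) {
    hj <- h * (1 + abs(par[j]))
    up <- par; up[j] <- up[j] + hj
    dn <- par; dn[j] <- dn[j] - hj
    H[, j] <- (gr(up) - gr(dn)) / (2 * hj)
  }
  H
}

#' @export
print.trio_fit <- function(x, ...) {
  cat(sprintf("multinomial relative-risk fit (%s): loglik %.4f, %d free, %s\n",
              x$spec$assumption, x$loglik, x$n_free,
              if (x$converged) "converged" else "NOT converged"))
  print(data.frame(estimate = x$free, se = x$se))
  if (x$boundary) cat("note: estimate(s) at the boundary of the range\n")
  invisible(x)
}

#' Likelihood-ratio test between two nested fits
#'
#' @param null_fit,alt_fit [fit_model()] results under the same assumption
#'   and data, with the null's free risk parameters a subset of the
#'   alternative's.
#' @return An object of class `trio_lrt`: `lrt_stat` (twice the
#'   log-likelihood difference, clipped at 0), `df` (difference in the
#'   number of free parameters) and `p_value` (chi-squared upper tail).
#' @export
lrt <- function(null_fit, alt_fit) {
  stopifnot(inherits(null_fit, "trio_fit"), inherits(alt_fit, "trio_fit"))
  s0 <- null_fit$spec; s1 <- alt_fit$spec
  nested <- s0$assumption == s1$assumption &&
    all(s0$free_risk %in% s1$free_risk) &&
    all(s1$constraints %in% s0$constraints) &&
    s1$n_free > s0$n_free
  if (!nested)
    stop("fits are not nested (same assumption, null free parameters a ",
         "strict subset of the alternative's, required)")
  stat <- max(0, 2 * (alt_fit$loglik - null_fit$loglik))
  df <- s1$n_free - s0$n_free
  structure(list(lrt_stat = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE)),
            class = "trio_lrt")
}

#' @export
print.trio_lrt <- function(x, ...) {
  cat(sprintf("LRT: stat %.4f, df %d, p %.4g\n", x$lrt_stat, x$df,
              x$p_value))
  invisible(x)
}

#' Number of jointly identifiable relative-risk parameters
#'
#' Determines how many relative-risk parameters can be estimated
#' simultaneously from complete case/parent trio data, by greedily adding
#' parameters from the menu to the stratification parameters and accepting
#' an addition only when it increases the numerical rank of the Jacobian of
#' the 15-cell probability map (evaluated analytically at a generic
#' interior parameter point).  The count is a generic-rank (matroid)
#' property, so the greedy order does not affect it.
#'
#' @param assumption stratification assumption (default CEPG).
#' @param menu candidate risk parameters; default: the ten-parameter menu
#'   R1, R2, S1, S2, gamma11, gamma12, gamma21, gamma22, Im, Ip.
#' @param seed seed for the generic evaluation point.
#' @param tol relative singular-value threshold for the numerical rank.
#' @return Integer: the number of accepted risk parameters.
#' @export
max_estimable_risk_params <- function(assumption = "CEPG", menu = NULL,
                                      seed = 1L, tol = 1e-8) {
  if (is.null(menu))
    menu <- c("R1", "R2", "S1", "S2", "gamma11", "gamma12", "gamma21",
              "gamma22", "Im", "Ip")
  stopifnot(all(menu %in% .free_risk_menu))
  spec <- model_spec(assumption, free_risk = menu)
  tc <- trio_cells()
  set.seed(seed)
  vals <- exp(stats::rnorm(spec$n_free, 0, 0.3))
  if (spec$assumption == "HWE") vals[spec$n_free] <- stats::runif(1, .2, .8)
  pa <- apply_constraints(spec, vals)
  pn <- free_param_names(spec)
  E <- .exp_matrix(pn, tc, pa$rp, pa$sp)
  p <- case_trio_cell_probs(pa$rp, pa$sp)
  # d p_i / d theta_j of the normalised probability map
  J <- p * (E - rep(colSums(p * E), each = 15))
  nrank <- function(M) {
    s <- svd(M)$d
    sum(s > tol * s[1])
  }
  strat_cols <- setdiff(pn, menu)
  acc <- J[, strat_cols, drop = FALSE]
  n_accepted <- 0L
  for (m in menu) {
    cand <- cbind(acc, J[, m])
    if (nrank(cand) == ncol(acc) + 1L) {
      acc <- cand
      n_accepted <- n_accepted + 1L
    }
  }
  n_accepted
}
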