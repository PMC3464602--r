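# Per-SNP analysis driver: null/alternative fits and likelihood-ratio
# tests over a collection of SNPs, with batch ranges for parallel runs.

#' Fit and test a null/alternative model pair at every SNP
#'
#' For each SNP, fits `null_spec` and `alt_spec` to that SNP's unit count
#' tables, and reports the likelihood-ratio test together with the
#' alternative model's parameter estimates and standard errors.  SNPs with
#' degenerate data (no non-zero counts, or flagged monomorphic in
#' `markers`) are reported as skipped, not dropped.
#'
#' @param snp_tables named list (one element per SNP, in analysis order) of
#'   lists of [count_table()] objects, as produced by
#'   [extract_count_tables()] / [read_count_files()] or
#'   [simulate_unit_tables()].
#' @param null_spec,alt_spec nested [model_spec()] objects (same
#'   assumption; the null's free risk parameters a subset of the
#'   alternative's).
#' @param markers optional marker data frame (columns `snp`, `risk_allele`,
#'   `freq`, optionally `monomorphic`); `freq` seeds the allele-frequency
#'   start under HWE.
#' @param batch optional integer vector of length 2: the (inclusive) range
#'   of SNP positions (in `snp_tables` order) to analyse, enabling
#'   batch-parallel runs whose concatenated results equal a full run.
#' @return A data frame with one row per analysed SNP: identifiers, risk
#'   allele, unit totals, null/alternative log-likelihoods and
#'   free-parameter counts, the LRT statistic/df/p-value, one
#'   `est_<param>`/`se_<param>` column pair per alternative free parameter,
#'   and a `status` column ("ok" or "skipped: <reason>").
#' @export
analyse_snps <- function(snp_tables, null_spec, alt_spec, markers = NULL,
                         batch = NULL) {
  stopifnot(inherits(null_spec, "model_spec"),
            inherits(alt_spec, "model_spec"))
  snps <- names(snp_tables)
  if (is.null(snps)) snps <- as.character(seq_along(snp_tables))
  idx <- seq_along(snp_tables)
  if (!is.null(batch)) {
    if (length(batch) != 2 || batch[1] < 1 || batch[2] > length(idx) ||
        batch[1] > batch[2])
      stop("batch must be an in-range pair (first, last)")
    idx <- seq.int(batch[1], batch[2])
  }
  est_names <- free_param_names(alt_spec)
  rows <- lapply(idx, function(i) {
    tabs <- snp_tables[[i]]
    row <- list(snp = snps[i], risk_allele = NA_character_,
                n_units = sum(vapply(tabs, function(t) sum(t$counts),
                                     numeric(1))))
    q0 <- NULL
    if (!is.null(markers)) {
      mi <- match(snps[i], markers$snp)
      if (!is.na(mi)) {
        row$risk_allele <- as.character(markers$risk_allele[mi])
        if (isTRUE(markers$monomorphic[mi]))
          return(c(row, .na_fit_cols(est_names),
                   status = "skipped: monomorphic"))
        q0 <- markers$freq[mi]
      }
    }
    if (row$n_units == 0)
      return(c(row, .na_fit_cols(est_names), status = "skipped: no data"))
    ns <- null_spec; as_ <- alt_spec
    if (!is.null(q0) && is.finite(q0) && q0 > 0 && q0 < 1) {
      ns$q_start <- q0
      as_$q_start <- q0
    }
    res <- tryCatch({
      f0 <- fit_model(tabs, ns)
      f1 <- fit_model(tabs, as_)
      tst <- lrt(f0, f1)
      est <- as.list(f1$free)
      names(est) <- paste0("est_", est_names)
      se <- as.list(f1$se)
      names(se) <- paste0("se_", est_names)
      c(row,
        list(loglik_null = f0$loglik, loglik_alt = f1$loglik,
             n_free_null = f0$n_free, n_free_alt = f1$n_free,
             lrt = tst$lrt_stat, df = tst$df, p = tst$p_value),
        est, se,
        status = if (f0$converged && f1$converged) "ok"
                 else "ok: optimizer not converged")
    }, error = function(e)
      c(row, .na_fit_cols(est_names),
        status = paste0("skipped: ", conditionMessage(e))))
    res
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r,
                                                        stringsAsFactors = FALSE)))
}

.na_fit_cols <- function(est_names) {
  out <- list(loglik_null = NA_real_, loglik_alt = NA_real_,
              n_free_null = NA_integer_, n_free_alt = NA_integer_,
              lrt = NA_real_, df = NA_integer_, p = NA_real_)
  for (nm in est_names) {
    out[[paste0("est_", nm)]] <- NA_real_
    out[[paste0("se_", nm)]] <- NA_real_
  }
  out
}

#' Write a per-SNP results table
#'
#' Tab-separated with a mandatory header row; missing values written as
#' "NA".
#'
#' @param results data frame from [analyse_snps()].
#' @param path output file path.
#' @export
write_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
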