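# Pipeline entry points tying extraction, analysis and simulation
# together behind the shared configuration dialect.  These back the
# command-line wrapper in inst/cli/.

.log_msg <- function(verbose, ...) if (verbose) message(sprintf(...))

#' Run the extraction step: pedigree files to count files
#'
#' Config keys: `ped`, `map` (input paths), `out_dir`; optional
#' `proband_file` (lines: family id, individual id), `risk_allele_file`
#' (lines: SNP id, allele), `multiple_units`, `unknown_as_control`
#' (flags).  Writes one count file per unit type, a marker file
#' (`markers.dat`), and an extraction log (`extraction_log.tsv`) recording
#' per-SNP discarded families with reasons.
#'
#' @param config path to a configuration file, or a named list.
#' @param verbose emit progress messages.
#' @return Invisibly, the [extract_count_tables()] result.
#' @export
run_extract <- function(config, verbose = TRUE) {
  cfg <- if (is.character(config)) read_config(config) else config
  out_dir <- cfg_chr(cfg, "out_dir")
  pd <- read_pedigrees(cfg_chr(cfg, "ped"), cfg_chr(cfg, "map"))
  .log_msg(verbose, "read %d individuals, %d SNPs", nrow(pd$fam),
           nrow(pd$map))
  overrides <- NULL
  if (!is.null(cfg$risk_allele_file)) {
    ov <- utils::read.table(cfg$risk_allele_file, header = FALSE,
                            stringsAsFactors = FALSE)
    overrides <- stats::setNames(as.character(ov[[2]]),
                                 as.character(ov[[1]]))
  }
  proband <- NULL
  if (!is.null(cfg$proband_file)) {
    pb <- utils::read.table(cfg$proband_file, header = FALSE,
                            stringsAsFactors = FALSE)
    proband <- stats::setNames(as.character(pb[[2]]),
                               as.character(pb[[1]]))
  }
  info <- marker_info(pd, overrides = overrides)
  ex <- extract_count_tables(pd, info, proband = proband,
                             multiple_units = cfg_flag(cfg,
                                                       "multiple_units"),
                             unknown_as_control = cfg_flag(cfg,
                                                  "unknown_as_control"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_count_files(ex$tables, out_dir)
  write_marker_file(info, file.path(out_dir, "markers.dat"))
  utils::write.table(ex$log, file.path(out_dir, "extraction_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .log_msg(verbose, "wrote count files for %d SNPs to %s (%d drops logged)",
           length(ex$tables), out_dir, nrow(ex$log))
  invisible(ex)
}

#' Run the analysis step: count files to a per-SNP results table
#'
#' Config keys: `count_dir` (from [run_extract()]), `out_file`;
#' `assumption` (HWE/PAE/CEPG/CPG, default CEPG); `free` (comma-separated
#' alternative-model risk parameters), `null_free` (null-model risk
#' parameters, default none), `constraints` (comma-separated), optional
#' `marker_file` and `batch` ("first-last" SNP range).
#'
#' @inheritParams run_extract
#' @return Invisibly, the results data frame.
#' @export
run_analyse <- function(config, verbose = TRUE) {
  cfg <- if (is.character(config)) read_config(config) else config
  tables <- read_count_files(cfg_chr(cfg, "count_dir"))
  markers <- NULL
  mf <- cfg$marker_file
  if (is.null(mf)) {
    cand <- file.path(cfg_chr(cfg, "count_dir"), "markers.dat")
    if (file.exists(cand)) mf <- cand
  }
  if (!is.null(mf)) markers <- read_marker_file(mf)
  assumption <- cfg_chr(cfg, "assumption", "CEPG")
  constraints <- cfg_list(cfg, "constraints")
  alt <- model_spec(assumption, free_risk = cfg_list(cfg, "free"),
                    constraints = constraints)
  null <- model_spec(assumption, free_risk = cfg_list(cfg, "null_free"),
                     constraints = constraints)
  batch <- NULL
  if (!is.null(cfg$batch)) {
    batch <- suppressWarnings(as.integer(strsplit(cfg$batch,
                                                  "-", fixed = TRUE)[[1]]))
    if (length(batch) != 2 || anyNA(batch))
      stop("batch must be of the form 'first-last'")
  }
  res <- analyse_snps(tables, null, alt, markers = markers, batch = batch)
  write_results(res, cfg_chr(cfg, "out_file"))
  .log_msg(verbose, "analysed %d SNPs (%d ok) -> %s", nrow(res),
           sum(res$status == "ok"), cfg_chr(cfg, "out_file"))
  invisible(res)
}

#' Run the simulation step: design to pedigree files
#'
#' Config keys: `out_dir`, `seed`; `q` (allele frequency, default 0.3),
#' `n_snps` (default 1), `missingness` (default 0), `causal`
#' (comma-separated SNP indices, default all), per-unit counts as
#' `n_<unit_kind>` (e.g. `n_case_parent_trio = 50`), and relative-risk
#' values by parameter name (e.g. `R2 = 2`).
#'
#' @inheritParams run_extract
#' @return Invisibly, the simulated `ped_data`.
#' @export
run_simulate <- function(config, verbose = TRUE) {
  cfg <- if (is.character(config)) read_config(config) else config
  nu_keys <- setdiff(grep("^n_", names(cfg), value = TRUE), "n_snps")
  kinds <- sub("^n_", "", nu_keys)
  bad <- setdiff(kinds, unit_kinds())
  if (length(bad)) stop("unknown unit kind(s) in config: ",
                        paste(bad, collapse = ", "))
  if (!length(kinds)) stop("no unit counts given (n_<unit_kind> keys)")
  n_units <- stats::setNames(vapply(nu_keys, function(k) cfg_num(cfg, k),
                                    numeric(1)), kinds)
  rp_keys <- intersect(names(cfg), .risk_param_names)
  rp <- do.call(risk_params,
                stats::setNames(lapply(rp_keys, function(k)
                  cfg_num(cfg, k)), rp_keys))
  n_snps <- as.integer(cfg_num(cfg, "n_snps", 1))
  causal <- as.integer(cfg_list(cfg, "causal", seq_len(n_snps)))
  design <- sim_design(n_units, rp = rp, q = cfg_num(cfg, "q", 0.3),
                       n_snps = n_snps, causal = causal,
                       missingness = cfg_num(cfg, "missingness", 0),
                       seed = as.integer(cfg_num(cfg, "seed")))
  pd <- simulate_ped_files(design, cfg_chr(cfg, "out_dir"))
  .log_msg(verbose, "simulated %d families x %d SNPs -> %s",
           length(unique(pd$fam$fid)), n_snps, cfg_chr(cfg, "out_dir"))
  invisible(pd)
}
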