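# Risk-allele assignment and allele-frequency estimation per SNP, plus
# recoding of allele pairs to risk-allele counts.

#' Assign the risk allele at one SNP
#'
#' By default the minor allele (by sample allele count over all genotyped
#' individuals) is taken as the risk allele; an exact 50/50 tie is broken
#' towards the lexicographically smaller label.  The choice can be
#' overridden with any observed allele.  The risk-allele frequency is
#' estimated from founders (see [estimate_allele_frequency()]).
#'
#' @param ped_data a [read_pedigrees()] object.
#' @param snp SNP id or column index.
#' @param override optional allele label to force as the risk allele.
#' @return One-row data frame: `snp`, `chr`, `pos`, `allele1`, `allele2`
#'   (risk and non-risk labels), `risk_allele`, `freq` (founder estimate),
#'   `monomorphic`.
#' @export
assign_risk_allele <- function(ped_data, snp, override = NULL) {
  j <- .snp_index(ped_data, snp)
  al <- c(ped_data$a1[, j], ped_data$a2[, j])
  counts <- table(al[al != "0"])
  row <- data.frame(snp = ped_data$map$snp[j], chr = ped_data$map$chr[j],
                    pos = ped_data$map$pos[j], allele1 = NA_character_,
                    allele2 = NA_character_, risk_allele = NA_character_,
                    freq = NA_real_, monomorphic = TRUE,
                    stringsAsFactors = FALSE)
  if (length(counts) > 2)
    stop(sprintf("SNP %s has %d alleles; only biallelic markers supported",
                 row$snp, length(counts)))
  if (!is.null(override)) {
    override <- as.character(override)
    if (!override %in% names(counts))
      stop(sprintf("override allele '%s' not observed at SNP %s",
                   override, row$snp))
  }
  if (length(counts) < 2) {
    if (length(counts) == 1) row$allele1 <- names(counts)
    return(row)   # monomorphic (or fully missing): flagged, no risk allele
  }
  counts <- counts[order(counts, names(counts))]  # minor first, ties lexic.
  risk <- if (is.null(override)) names(counts)[1] else override
  row$risk_allele <- risk
  row$allele1 <- risk
  row$allele2 <- setdiff(names(counts), risk)
  row$monomorphic <- FALSE
  row$freq <- estimate_allele_frequency(ped_data, j, risk)
  row
}

#' Marker information for all SNPs
#'
#' Applies [assign_risk_allele()] across the map, honouring optional
#' per-SNP overrides.
#'
#' @inheritParams assign_risk_allele
#' @param overrides optional named character vector (names = SNP ids) of
#'   forced risk alleles.
#' @return Data frame with one row per SNP.
#' @export
marker_info <- function(ped_data, overrides = NULL) {
  rows <- lapply(seq_len(nrow(ped_data$map)), function(j) {
    ov <- if (!is.null(overrides)) overrides[[ped_data$map$snp[j]]]
    assign_risk_allele(ped_data, j, override = ov)
  })
  do.call(rbind, rows)
}

#' Founder-based risk-allele frequency estimate
#'
#' Counts alleles among founders (individuals whose parents are not in the
#' pedigree), avoiding the non-independence induced by transmission.  If no
#' founder is genotyped at the SNP, all individuals are used, with a
#' warning.
#'
#' @inheritParams assign_risk_allele
#' @param allele the allele whose frequency is estimated.
#' @return Frequency in [0, 1].
#' @export
estimate_allele_frequency <- function(ped_data, snp, allele) {
  j <- .snp_index(ped_data, snp)
  founder <- ped_data$fam$pat == "0" & ped_data$fam$mat == "0"
  use <- founder & ped_data$a1[, j] != "0"
  if (!any(use)) {
    warning(sprintf("no genotyped founders at SNP %s; using all individuals",
                    ped_data$map$snp[j]))
    use <- ped_data$a1[, j] != "0"
    if (!any(use)) stop("no genotyped individuals at SNP ",
                        ped_data$map$snp[j])
  }
  al <- c(ped_data$a1[use, j], ped_data$a2[use, j])
  mean(al == allele)
}

.snp_index <- function(ped_data, snp) {
  if (is.numeric(snp)) {
    j <- as.integer(snp)
    if (j < 1 || j > nrow(ped_data$map)) stop("SNP index out of range")
  } else {
    j <- match(as.character(snp), ped_data$map$snp)
    if (is.na(j)) stop("unknown SNP id: ", snp)
  }
  j
}

# risk-allele count matrix (individuals x SNPs), NA = missing; monomorphic
# SNPs give all-NA columns
recode_genotypes <- function(ped_data, info) {
  n <- nrow(ped_data$fam)
  m <- nrow(ped_data$map)
  G <- matrix(NA_integer_, n, m, dimnames = list(NULL, ped_data$map$snp))
  for (j in seq_len(m)) {
    risk <- info$risk_allele[j]
    if (is.na(risk)) next
    ok <- ped_data$a1[, j] != "0"
    G[ok, j] <- (ped_data$a1[ok, j] == risk) + (ped_data$a2[ok, j] == risk)
  }
  G
}
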