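# PLINK-format text pedigree input and output.  Genotypes are stored as
# allele-label pairs here; translation to risk-allele counts happens in
# the recoding layer once a risk allele is assigned per SNP.

#' Read PLINK-format text pedigree files
#'
#' Parses a whitespace-delimited `.ped` file (six leading columns: family
#' id, individual id, father id, mother id, sex, phenotype; then two
#' allele columns per SNP) together with its `.map` file (3 or 4 columns:
#' chromosome, SNP id, optional genetic distance, position).  Phenotype
#' coding: 2 = affected, 1 = unaffected, 0 or -9 = unknown.  A genotype
#' with either allele coded "0" is treated as wholly missing.
#'
#' @param ped,map file paths.
#' @return An object of class `ped_data`: list with `fam` (data frame:
#'   fid, iid, pat, mat, sex, pheno, status), `map` (data frame: chr, snp,
#'   cm, pos), and character matrices `a1`, `a2` (individuals x SNPs,
#'   "0" = missing).
#' @export
read_pedigrees <- function(ped, map) {
  mp <- read_map(map)
  m <- nrow(mp)
  lines <- readLines(ped)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("ped file is empty: ", ped)
  fields <- strsplit(trimws(lines), "[ \t]+")
  want <- 6L + 2L * m
  nf <- lengths(fields)
  if (any(nf != want))
    stop(sprintf("ped line %d has %d fields, expected %d (6 + 2 x %d SNPs)",
                 which(nf != want)[1], nf[nf != want][1], want, m))
  M <- do.call(rbind, fields)
  fam <- data.frame(fid = M[, 1], iid = M[, 2], pat = M[, 3], mat = M[, 4],
                    sex = M[, 5], pheno = M[, 6],
                    stringsAsFactors = FALSE)
  dup <- duplicated(paste(fam$fid, fam$iid))
  if (any(dup))
    stop(sprintf("duplicate individual id at ped line %d: %s %s",
                 which(dup)[1], fam$fid[dup][1], fam$iid[dup][1]))
  fam$status <- ifelse(fam$pheno == "2", "affected",
                ifelse(fam$pheno == "1", "unaffected", "unknown"))
  a1 <- M[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
  a2 <- M[, 6L + 2L * seq_len(m), drop = FALSE]
  half <- (a1 == "0") != (a2 == "0")
  a1[half] <- "0"
  a2[half] <- "0"
  colnames(a1) <- colnames(a2) <- mp$snp
  structure(list(fam = fam, map = mp, a1 = a1, a2 = a2),
            class = "ped_data")
}

#' @rdname read_pedigrees
#' @export
read_map <- function(map) {
  lines <- readLines(map)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("map file is empty: ", map)
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (!all(nf %in% c(3L, 4L)))
    stop(sprintf("map line %d has %d fields, expected 3 or 4",
                 which(!nf %in% c(3L, 4L))[1], nf[!nf %in% c(3L, 4L)][1]))
  if (length(unique(nf)) != 1) stop("map file mixes 3- and 4-column rows")
  M <- do.call(rbind, fields)
  mp <- if (ncol(M) == 4L)
    data.frame(chr = M[, 1], snp = M[, 2], cm = as.numeric(M[, 3]),
               pos = as.numeric(M[, 4]), stringsAsFactors = FALSE)
  else
    data.frame(chr = M[, 1], snp = M[, 2], cm = 0,
               pos = as.numeric(M[, 3]), stringsAsFactors = FALSE)
  if (anyDuplicated(mp$snp))
    stop("duplicate SNP id in map: ", mp$snp[duplicated(mp$snp)][1])
  mp
}

#' @export
print.ped_data <- function(x, ...) {
  cat(sprintf("ped data: %d individuals in %d families, %d SNPs\n",
              nrow(x$fam), length(unique(x$fam$fid)), nrow(x$map)))
  cat(sprintf("  affected %d / unaffected %d / unknown %d\n",
              sum(x$fam$status == "affected"),
              sum(x$fam$status == "unaffected"),
              sum(x$fam$status == "unknown")))
  invisible(x)
}

#' Write a `ped_data` object back to PLINK text files
#'
#' @param ped_data a `ped_data` object.
#' @param ped,map output file paths.
#' @export
write_ped_files <- function(ped_data, ped, map) {
  stopifnot(inherits(ped_data, "ped_data"))
  m <- nrow(ped_data$map)
  geno <- matrix("", nrow(ped_data$fam), 2L * m)
  geno[, 2L * seq_len(m) - 1L] <- ped_data$a1
  geno[, 2L * seq_len(m)] <- ped_data$a2
  lines <- do.call(paste, c(ped_data$fam[c("fid", "iid", "pat", "mat",
                                           "sex", "pheno")],
                            as.data.frame(geno, stringsAsFactors = FALSE)))
  writeLines(lines, ped)
  writeLines(do.call(paste, ped_data$map[c("chr", "snp", "cm", "pos")]), map)
  invisible(ped_data)
}
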