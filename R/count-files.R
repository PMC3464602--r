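# Canonical on-disk representation of extracted genotype-combination
# counts: one tab-separated file per unit type, one row per SNP, columns
# in the frozen combination order of the collapse maps.

.count_file_name <- function(kind) paste0(kind, ".dat")

#' Write per-SNP unit count tables to canonical count files
#'
#' One file `<unit_kind>.dat` per unit type present in `tables`, with
#' header comments naming the unit type and the column order (observed
#' members and their risk-allele counts), then one row per SNP: the SNP id
#' followed by the counts, tab-separated.
#'
#' @param tables named per-SNP list of [count_table()] lists, as returned
#'   in the `tables` element of [extract_count_tables()] or by
#'   [simulate_unit_tables()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_count_files <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  snps <- names(tables)
  kinds <- unique(unlist(lapply(tables, names)))
  paths <- character(0)
  for (k in kinds) {
    cm <- collapse_map(k)
    lab <- apply(cm$key, 1, paste, collapse = "")
    path <- file.path(dir, .count_file_name(k))
    hdr <- c(sprintf("# unit_type: %s", k),
             sprintf("# columns: snp %s",
                     paste0(paste(cm$members, collapse = ""), "_", lab,
                            collapse = " ")))
    rows <- vapply(seq_along(tables), function(s) {
      tab <- tables[[s]][[k]]
      cnt <- if (is.null(tab)) rep(0L, length(cm$cells)) else tab$counts
      paste(c(snps[s], cnt), collapse = "\t")
    }, character(1))
    writeLines(c(hdr, rows), path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read canonical count files back into per-SNP tables
#'
#' @param dir directory holding `<unit_kind>.dat` files written by
#'   [write_count_files()].
#' @return Named per-SNP list of [count_table()] lists.
#' @export
read_count_files <- function(dir) {
  files <- list.files(dir, pattern = "\\.dat$", full.names = TRUE)
  files <- files[basename(files) %in% .count_file_name(unit_kinds())]
  if (!length(files)) stop("no count files found in ", dir)
  per_kind <- list()
  snps <- NULL
  for (path in files) {
    kind <- sub("\\.dat$", "", basename(path))
    cm <- collapse_map(kind)
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf != length(cm$cells) + 1L))
      stop(sprintf("%s row %d has %d fields, expected %d",
                   basename(path), which(nf != length(cm$cells) + 1L)[1],
                   nf[nf != length(cm$cells) + 1L][1],
                   length(cm$cells) + 1L))
    ids <- vapply(parts, `[[`, character(1), 1L)
    if (is.null(snps)) snps <- ids
    else if (!identical(snps, ids))
      stop("count files disagree on SNP ids/order: ", basename(path))
    per_kind[[kind]] <- lapply(parts, function(p) {
      cnt <- suppressWarnings(as.integer(p[-1]))
      if (anyNA(cnt)) stop("non-integer count in ", basename(path))
      cnt
    })
  }
  per_kind <- per_kind[order(match(names(per_kind), unit_kinds()))]
  tables <- lapply(seq_along(snps), function(s)
    lapply(per_kind, function(rows) NULL))
  tables <- stats::setNames(tables, snps)
  for (s in seq_along(snps))
    for (kind in names(per_kind))
      tables[[s]][[kind]] <- count_table(kind, per_kind[[kind]][[s]],
                                         snp = snps[s])
  tables
}

#' Write / read the per-SNP marker file
#'
#' Tab-separated: SNP id, risk allele, risk-allele frequency (the
#' frequency seeds the allele-frequency parameter of HWE fits).
#'
#' @param info marker data frame (from [marker_info()], or any data frame
#'   with columns `snp`, `risk_allele`, `freq`).
#' @param path file path.
#' @export
write_marker_file <- function(info, path) {
  utils::write.table(info[c("snp", "risk_allele", "freq")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_marker_file
#' @export
read_marker_file <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "character",
                                         "numeric"))
  df$monomorphic <- is.na(df$risk_allele)
  df
}
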