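# Per-SNP extraction of the most informative child-parent sub-unit from
# each pedigree, following the fixed unit-type preference order.

# combination lookup arrays (genotype count + 1 indexed), built per kind
.combo_lookup <- function(kind) {
  cached <- .triomult_cache$lookup[[kind]]
  if (!is.null(cached)) return(cached)
  cm <- collapse_map(kind)
  dims <- rep(3L, length(cm$members))
  arr <- array(NA_integer_, dim = dims)
  key <- as.matrix(cm$key) + 1L
  arr[key] <- seq_along(cm$cells)
  if (is.null(.triomult_cache$lookup)) .triomult_cache$lookup <- list()
  .triomult_cache$lookup[[kind]] <- arr
  arr
}

#' Extract per-SNP unit count tables from pedigree data
#'
#' For each SNP and each pedigree, selects the highest-preference family
#' sub-unit constructible from members with non-missing genotypes at that
#' SNP (see [unit_kinds()] for the preference order).  The case anchoring
#' the unit is the stated proband, or else the first affected individual
#' in file order, with individuals that have parent links taking
#' precedence (an affected child outranks an affected founder); when no
#' case unit is constructible, control units are anchored on the first
#' control individual under the same child-first ordering.  Extraction is
#' per-SNP, so a family may contribute a trio at one SNP and a duo at
#' another, driven only by missingness.  Mendelian-inconsistent trios and
#' duos are discarded at the offending SNP only, and tallied in the log.
#'
#' @param ped_data a [read_pedigrees()] object.
#' @param info marker information from [marker_info()] (computed if
#'   omitted); its risk-allele assignment drives all genotype recoding.
#' @param proband optional named character vector (names = family ids)
#'   designating the affected individual to anchor extraction.
#' @param multiple_units if `TRUE`, emit every constructible case/parent
#'   trio (or, failing that, every control parental mating) from each
#'   family instead of a single unit.
#' @param unknown_as_control treat unknown-phenotype individuals as
#'   population-based controls.
#' @return A list with `tables` (named list per SNP of [count_table()]s,
#'   covering every unit kind observed at any SNP), `log` (data frame of
#'   per-SNP discarded families with reasons) and `info`.
#' @export
extract_count_tables <- function(ped_data, info = NULL, proband = NULL,
                                 multiple_units = FALSE,
                                 unknown_as_control = FALSE) {
  stopifnot(inherits(ped_data, "ped_data"))
  if (is.null(info)) info <- marker_info(ped_data)
  G <- recode_genotypes(ped_data, info)
  fam <- ped_data$fam
  kinds <- unit_kinds()
  lookups <- lapply(stats::setNames(kinds, kinds), .combo_lookup)
  ncomb <- vapply(lookups, function(a) max(a, na.rm = TRUE), numeric(1))
  nsnp <- nrow(ped_data$map)
  counts <- lapply(stats::setNames(kinds, kinds),
                   function(k) matrix(0L, ncomb[[k]], nsnp))
  log_rows <- list()

  fam_split <- split(seq_len(nrow(fam)), fam$fid)
  is_control <- fam$status == "unaffected" |
    (unknown_as_control & fam$status == "unknown")

  # per-family structure: candidate rows and their parent row indices
  fam_info <- lapply(fam_split, function(rows) {
    ids <- fam$iid[rows]
    fid <- fam$fid[rows[1]]
    parent_row <- function(pid) {
      if (pid == "0") return(NA_integer_)
      r <- rows[match(pid, ids)]
      if (is.na(r)) NA_integer_ else r
    }
    # candidate anchors: individuals with parent links in the pedigree
    # (children) first, then the rest, each group in file order
    has_parents <- fam$mat[rows] != "0" | fam$pat[rows] != "0"
    prefer_children <- function(r) r[order(!has_parents[match(r, rows)])]
    cases <- prefer_children(rows[fam$status[rows] == "affected"])
    case <- if (!is.null(proband) && !is.na(proband[fid])) {
      r <- rows[match(proband[[fid]], ids)]
      if (is.na(r)) stop(sprintf("proband %s not found in family %s",
                                 proband[[fid]], fid))
      r
    } else if (length(cases)) cases[1] else NA_integer_
    ctrls <- prefer_children(rows[is_control[rows]])
    list(fid = fid, case = case, cases = cases,
         ctrl = if (length(ctrls)) ctrls[1] else NA_integer_, ctrls = ctrls,
         mother = vapply(rows, function(r) parent_row(fam$mat[r]),
                         integer(1)),
         father = vapply(rows, function(r) parent_row(fam$pat[r]),
                         integer(1)),
         rows = rows)
  })

  geno <- function(r, s) if (is.na(r)) NA_integer_ else G[r, s]

  # classify one anchored individual at one SNP; returns list(kind, combo)
  # or list(reason) when a Mendelian inconsistency discards the family
  classify_case <- function(fi, anchor, s) {
    ai <- match(anchor, fi$rows)
    gc <- geno(anchor, s)
    gm <- geno(fi$mother[ai], s)
    gf <- geno(fi$father[ai], s)
    if (!is.na(gc) && !is.na(gm) && !is.na(gf)) {
      cell <- .combo_lookup("case_parent_trio")[gm + 1, gf + 1, gc + 1]
      if (is.na(cell)) return(list(reason = "mendelian_inconsistent_trio"))
      return(list(kind = "case_parent_trio", combo = cell))
    }
    if (!is.na(gc) && !is.na(gm)) {
      cb <- .combo_lookup("case_mother_duo")[gm + 1, gc + 1]
      if (is.na(cb)) return(list(reason = "mendelian_inconsistent_duo"))
      return(list(kind = "case_mother_duo", combo = cb))
    }
    if (!is.na(gc) && !is.na(gf)) {
      cb <- .combo_lookup("case_father_duo")[gf + 1, gc + 1]
      if (is.na(cb)) return(list(reason = "mendelian_inconsistent_duo"))
      return(list(kind = "case_father_duo", combo = cb))
    }
    if (!is.na(gc))
      return(list(kind = "case", combo = .combo_lookup("case")[gc + 1]))
    if (!is.na(gm) && !is.na(gf))
      return(list(kind = "case_parental_mating",
                  combo = .combo_lookup("case_parental_mating")[gm + 1,
                                                                gf + 1]))
    if (!is.na(gm))
      return(list(kind = "case_mother",
                  combo = .combo_lookup("case_mother")[gm + 1]))
    if (!is.na(gf))
      return(list(kind = "case_father",
                  combo = .combo_lookup("case_father")[gf + 1]))
    NULL
  }
  classify_control <- function(fi, anchor, s) {
    ai <- match(anchor, fi$rows)
    gc <- geno(anchor, s)
    gm <- geno(fi$mother[ai], s)
    gf <- geno(fi$father[ai], s)
    if (!is.na(gm) && !is.na(gf))
      return(list(kind = "control_parental_mating",
                  combo = .combo_lookup("control_parental_mating")[gm + 1,
                                                                   gf + 1]))
    if (!is.na(gc) && !is.na(gm)) {
      cb <- .combo_lookup("control_mother_duo")[gm + 1, gc + 1]
      if (is.na(cb)) return(list(reason = "mendelian_inconsistent_duo"))
      return(list(kind = "control_mother_duo", combo = cb))
    }
    if (!is.na(gc) && !is.na(gf)) {
      cb <- .combo_lookup("control_father_duo")[gf + 1, gc + 1]
      if (is.na(cb)) return(list(reason = "mendelian_inconsistent_duo"))
      return(list(kind = "control_father_duo", combo = cb))
    }
    if (!is.na(gc))
      return(list(kind = "control", combo = .combo_lookup("control")[gc + 1]))
    NULL
  }
  add <- function(res, s) counts[[res$kind]][res$combo, s] <<-
    counts[[res$kind]][res$combo, s] + 1L
  drop_log <- function(fid, s, reason) log_rows[[length(log_rows) + 1L]] <<-
    data.frame(snp = ped_data$map$snp[s], fid = fid, reason = reason,
               stringsAsFactors = FALSE)

  for (fi in fam_info) {
    for (s in seq_len(nsnp)) {
      if (info$monomorphic[s]) next
      if (multiple_units) {
        trio_res <- list()
        bad <- FALSE
        for (a in fi$cases) {
          r <- classify_case(fi, a, s)
          if (!is.null(r) && !is.null(r$reason)) bad <- TRUE
          else if (!is.null(r) && r$kind == "case_parent_trio")
            trio_res[[length(trio_res) + 1L]] <- r
        }
        if (bad) { drop_log(fi$fid, s, "mendelian_inconsistent_trio"); next }
        if (length(trio_res)) {
          for (r in trio_res) add(r, s)
          next
        }
        if (is.na(fi$case) && length(fi$ctrls)) {
          mat_res <- list()
          for (a in fi$ctrls) {
            r <- classify_control(fi, a, s)
            if (!is.null(r) && is.null(r$reason) &&
                r$kind == "control_parental_mating")
              mat_res[[length(mat_res) + 1L]] <- r
          }
          if (length(mat_res)) {
            for (r in mat_res) add(r, s)
            next
          }
        }
        # fall through to single-unit logic
      }
      res <- if (!is.na(fi$case)) classify_case(fi, fi$case, s)
      if (is.null(res) && !is.na(fi$ctrl))
        res <- classify_control(fi, fi$ctrl, s)
      if (is.null(res)) next
      if (!is.null(res$reason)) drop_log(fi$fid, s, res$reason)
      else add(res, s)
    }
  }

  used <- kinds[vapply(counts, function(M) any(M > 0), logical(1))]
  tables <- lapply(seq_len(nsnp), function(s)
    lapply(stats::setNames(used, used), function(k)
      count_table(k, counts[[k]][, s], snp = ped_data$map$snp[s])))
  names(tables) <- ped_data$map$snp
  list(tables = tables,
       log = if (length(log_rows)) do.call(rbind, log_rows)
             else data.frame(snp = character(), fid = character(),
                             reason = character(), stringsAsFactors = FALSE),
       info = info)
}
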