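# Enumeration of the Mendelian-consistent trio genotype configurations and
# the collapsing maps for partially observed family units.  Genotypes are
# risk-allele counts (0, 1, 2) throughout; allele labels are resolved once,
# in the pedigree I/O layer.

.triomult_cache <- new.env(parent = emptyenv())

# Frozen canonical order of the 15 cells.  Column `cepg` indexes the
# unordered (exchangeable) parental mating type, `cpg` the ordered one.
.trio_cells_raw <- data.frame(
  index = 1:15,
  gm = c(2L, 2L, 2L, 1L, 1L, 2L, 0L, 1L, 1L, 1L, 1L, 1L, 0L, 0L, 0L),
  gf = c(2L, 1L, 1L, 2L, 2L, 0L, 2L, 1L, 1L, 1L, 0L, 0L, 1L, 1L, 0L),
  gc = c(2L, 2L, 1L, 2L, 1L, 1L, 1L, 2L, 1L, 0L, 1L, 0L, 1L, 0L, 0L),
  cepg = c(1L, 2L, 2L, 2L, 2L, 3L, 3L, 4L, 4L, 4L, 5L, 5L, 5L, 5L, 6L),
  cpg  = c(1L, 2L, 2L, 3L, 3L, 4L, 5L, 6L, 6L, 6L, 7L, 7L, 8L, 8L, 9L)
)

#' The 15 Mendelian-consistent trio genotype configurations
#'
#' Enumerates every (mother, father, child) genotype configuration that is
#' consistent with Mendelian transmission at a biallelic autosomal locus,
#' in the frozen canonical order used by all count files and probability
#' vectors in this package.  Genotypes are risk-allele counts.
#'
#' @return A 15-row data frame with columns:
#' \describe{
#'   \item{index}{cell index 1--15 (canonical order).}
#'   \item{gm, gf, gc}{risk-allele counts of mother, father, child.}
#'   \item{cepg}{mating-type index (1--6) under parental exchangeability;
#'     symmetric in (gm, gf).}
#'   \item{cpg}{mating-type index (1--9) for the ordered parental pair.}
#'   \item{weight}{Mendelian segregation probability P(gc | gm, gf), one of
#'     1, 1/2, 1/4; weights sum to 1 within each mating type.}
#'   \item{pairs}{number of ordered parental allele arrangements carrying
#'     the genotype pair: 2 per heterozygous parent.  Mating strata are
#'     parameterised per allele arrangement, so this multiplicity is a
#'     fixed cell coefficient; it is what makes the allelic-exchangeability
#'     constraint mu4 = mu3 contain the Hardy-Weinberg model.}
#'   \item{phase}{parental origin of the risk allele for heterozygous
#'     children: "maternal", "paternal", "both" (ambiguous, het x het
#'     mating), or "none" for homozygous children.}
#' }
#' @examples
#' tc <- trio_cells()
#' # segregation weights sum to 1 within each ordered parental mating
#' stopifnot(nrow(tc) == 15,
#'           all(tapply(tc$weight, paste(tc$gm, tc$gf), sum) == 1))
#' @export
trio_cells <- function() {
  if (!is.null(.triomult_cache$cells)) return(.triomult_cache$cells)
  tc <- .trio_cells_raw
  tc$weight <- mapply(mendelian_weight, tc$gm, tc$gf, tc$gc)
  tc$pairs <- 2L^((tc$gm == 1L) + (tc$gf == 1L))
  tc$phase <- mapply(function(gm, gf, gc) {
    if (gc != 1L) return("none")
    mat <- (gm / 2) * (1 - gf / 2)   # risk from mother, not from father
    pat <- (1 - gm / 2) * (gf / 2)
    if (mat > 0 && pat > 0) "both" else if (mat > 0) "maternal" else "paternal"
  }, tc$gm, tc$gf, tc$gc)
  .triomult_cache$cells <- tc
  tc
}

#' Mendelian segregation probability of a child genotype
#'
#' P(child carries `gc` risk alleles | parental counts `gm`, `gf`) under
#' random transmission of one allele per parent.
#'
#' @param gm,gf,gc risk-allele counts (0, 1 or 2) of mother, father, child.
#' @return A probability in \{1, 1/2, 1/4\}.  Configurations with zero
#'   transmission probability are Mendelian-inconsistent and raise an error.
#' @examples
#' mendelian_weight(1, 1, 2)  # 1/4
#' @export
mendelian_weight <- function(gm, gf, gc) {
  stopifnot(length(gm) == 1, length(gf) == 1, length(gc) == 1)
  if (anyNA(c(gm, gf, gc)) || !all(c(gm, gf, gc) %in% 0:2))
    stop("genotypes must be risk-allele counts in {0, 1, 2}")
  pm <- gm / 2
  pf <- gf / 2
  p <- c((1 - pm) * (1 - pf), pm * (1 - pf) + (1 - pm) * pf, pm * pf)[gc + 1]
  if (p == 0)
    stop(sprintf("Mendelian-inconsistent configuration (gm=%d, gf=%d, gc=%d)",
                 gm, gf, gc))
  p
}

#' Observable family unit types, in extraction preference order
#'
#' The eleven child--parent sub-unit types a pedigree can contribute at a
#' SNP, ordered by extraction preference (most informative first).
#'
#' @return Character vector of length 11.
#' @export
unit_kinds <- function() {
  c("case_parent_trio", "case_mother_duo", "case_father_duo", "case",
    "case_parental_mating", "case_mother", "case_father",
    "control_parental_mating", "control_mother_duo", "control_father_duo",
    "control")
}

#' @rdname unit_kinds
#' @param kind a unit-type name.
#' @return `is_case_unit()`: `TRUE` for units ascertained through an affected
#'   child, `FALSE` for control units.
#' @export
is_case_unit <- function(kind) {
  kind <- match.arg(kind, unit_kinds())
  !startsWith(kind, "control")
}

# which trio members are observed for each unit kind
.unit_members <- list(
  case_parent_trio        = c("gm", "gf", "gc"),
  case_mother_duo         = c("gm", "gc"),
  case_father_duo         = c("gf", "gc"),
  case                    = "gc",
  case_parental_mating    = c("gm", "gf"),
  case_mother             = "gm",
  case_father             = "gf",
  control_parental_mating = c("gm", "gf"),
  control_mother_duo      = c("gm", "gc"),
  control_father_duo      = c("gf", "gc"),
  control                 = "gc"
)

#' Collapsing map from trio cells to the observable combinations of a unit
#'
#' A unit type with missing members cannot distinguish all 15 trio cells;
#' its observable genotype combinations are obtained by marginalising the
#' trio table over the unobserved members.  The map returned here partitions
#' the cell indices \{1..15\} into the observable combinations, ordered by
#' decreasing genotype counts of the observed members (for case/parent trios
#' the map is the identity).  Case and control variants of the same member
#' configuration share the same map.
#'
#' @param kind a unit-type name (see [unit_kinds()]).
#' @return An object of class `collapse_map`: a list with elements `kind`,
#'   `members` (observed trio members), `key` (data frame of observed
#'   genotype counts, one row per combination) and `cells` (list of integer
#'   vectors partitioning 1:15).
#' @examples
#' cm <- collapse_map("case_mother_duo")
#' cm$cells[[4]]  # mother het, child het: cells 5, 9, 11
#' @export
collapse_map <- function(kind) {
  kind <- match.arg(kind, unit_kinds())
  cached <- .triomult_cache$maps[[kind]]
  if (!is.null(cached)) return(cached)
  tc <- trio_cells()
  members <- .unit_members[[kind]]
  key_all <- tc[members]
  id <- do.call(paste, key_all)
  uniq <- !duplicated(id)
  key <- key_all[uniq, , drop = FALSE]
  # canonical combination order: the frozen cell order itself when all
  # members are observed (identity map, in first-appearance order),
  # otherwise decreasing genotype counts with the first observed member
  # varying slowest (reproduces the published duo table ordering)
  ord <- if (length(members) == 3L) seq_len(nrow(key))
         else do.call(order, c(unname(lapply(key, function(x) -x))))
  key <- key[ord, , drop = FALSE]
  rownames(key) <- NULL
  cells <- lapply(do.call(paste, key), function(k) tc$index[id == k])
  map <- structure(
    list(kind = kind, members = members, key = key, cells = cells),
    class = "collapse_map")
  if (is.null(.triomult_cache$maps)) .triomult_cache$maps <- list()
  .triomult_cache$maps[[kind]] <- map
  map
}

#' @export
print.collapse_map <- function(x, ...) {
  cat(sprintf("collapse map for %s: %d observable combinations\n",
              x$kind, length(x$cells)))
  lab <- apply(x$key, 1, paste, collapse = "/")
  for (i in seq_along(x$cells))
    cat(sprintf("  %2d  (%s = %s)  cells {%s}\n", i,
                paste(x$members, collapse = ","), lab[i],
                paste(x$cells[[i]], collapse = ",")))
  invisible(x)
}

#' Cell permutation induced by exchanging the risk-allele label
#'
#' Relabelling the risk allele replaces every risk-allele count g by 2 - g.
#' This maps the 15 Mendelian cells onto themselves; the returned vector
#' `p` satisfies: cell `i` of the original coding is cell `p[i]` of the
#' swapped coding.
#'
#' @return Integer permutation of 1:15.
#' @export
allele_swap_permutation <- function() {
  tc <- trio_cells()
  vapply(seq_len(15), function(i) {
    tc$index[tc$gm == 2L - tc$gm[i] & tc$gf == 2L - tc$gf[i] &
             tc$gc == 2L - tc$gc[i]]
  }, integer(1))
}

#' Observed genotype counts for one unit type at one SNP
#'
#' @param kind unit-type name (see [unit_kinds()]).
#' @param counts non-negative integer vector in the canonical combination
#'   order of [collapse_map()] for this kind.
#' @param snp optional SNP identifier.
#' @return A `count_table` object.
#' @export
count_table <- function(kind, counts, snp = NA_character_) {
  kind <- match.arg(kind, unit_kinds())
  cm <- collapse_map(kind)
  if (length(counts) != length(cm$cells))
    stop(sprintf("unit type %s requires %d counts, got %d",
                 kind, length(cm$cells), length(counts)))
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative")
  structure(list(kind = kind, counts = as.integer(counts),
                 snp = as.character(snp)),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count table: %s%s, %d units\n", x$kind,
              if (is.na(x$snp)) "" else paste0(" @ ", x$snp),
              sum(x$counts)))
  print(stats::setNames(x$counts, apply(collapse_map(x$kind)$key, 1,
                                        paste, collapse = "/")))
  invisible(x)
}

#' Re-express a count table with the opposite risk-allele coding
#'
#' Swapping which allele is "risk" permutes the observable combinations of
#' every unit type.  A dataset recoded this way and fitted with child
#' effects plus the mother-1/child-2 interaction multiplier reproduces the
#' non-inherited maternal antigen (mother-1/child-0) model of the original
#' coding.
#'
#' @param table a [count_table()].
#' @return A `count_table` of the same kind with permuted counts.
#' @export
swap_risk_allele <- function(table) {
  stopifnot(inherits(table, "count_table"))
  cm <- collapse_map(table$kind)
  key <- cm$key
  swapped <- 2L - as.matrix(key)
  idx <- match(do.call(paste, as.data.frame(swapped)), do.call(paste, key))
  out <- integer(length(table$counts))
  out[idx] <- table$counts
  count_table(table$kind, out, table$snp)
}
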