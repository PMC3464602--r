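Package: triomult
Title: Child, Maternal, Imprinting and Mother-Child Interaction Genotype
    Relative Risks from Case/Parent Trios and Related Family Units
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maximum-likelihood estimation of child genotype, maternal
    genotype, parent-of-origin (imprinting) and maternal-fetal interaction
    relative risks from nuclear-family genotype data, using a multinomial
    model over the 15 Mendelian-consistent mother/father/child genotype
    configurations with mating-type stratification.  Supports complete
    case/parent trios as well as partially observed units (case/mother and
    case/father duos, parental matings, single parents, singleton cases and
    controls) via collapsed multinomial cells, under a choice of likelihood
    assumptions: Hardy-Weinberg equilibrium with random mating, parental
    allelic exchangeability, conditioning on exchangeable parental genotypes,
    or conditioning on parental genotypes.  Includes per-SNP extraction of
    the most informative family sub-unit from PLINK-format pedigree files,
    likelihood-ratio testing across SNPs, and a seeded simulator of all unit
    types for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
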