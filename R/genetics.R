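#' @keywords internal
"_PACKAGE"

## Biallelic, generational population genetics: genotype bookkeeping,
## Hardy-Weinberg initialization, Mendelian random mating, allele-frequency
## statistics. Genotypes are unordered at a single autosomal locus; "R" is
## the resistance allele, "S" the susceptibility allele.

GENOTYPES <- c("SS", "RS", "RR")
SPECIES <- c("SF", "HA")

## number of R alleles carried by each genotype
R_DOSE <- c(SS = 0, RS = 1, RR = 2)

#' Hardy-Weinberg genotype frequencies
#'
#' Genotype frequencies at a biallelic autosomal locus under
#' Hardy-Weinberg equilibrium, given the resistance-allele frequency.
#'
#' @param p_R Frequency of the resistance allele R, in `[0, 1]`.
#' @return Named numeric vector `c(SS, RS, RR)` with frequencies
#'   `(1-p)^2`, `2p(1-p)`, `p^2`; sums to 1.
#' @examples
#' hw_genotype_frequencies(0.1)
#' @export
hw_genotype_frequencies <- function(p_R) {
  if (!is.numeric(p_R) || length(p_R) != 1L || is.na(p_R) || p_R < 0 || p_R > 1)
    stop("'p_R' must be a single number in [0, 1]", call. = FALSE)
  c(SS = (1 - p_R)^2, RS = 2 * p_R * (1 - p_R), RR = p_R^2)
}

#' Mendelian cross between two genotypes
#'
#' Offspring genotype distribution for a single-locus cross between two
#' parents of the same species. Inheritance is autosomal and monogenic;
#' the heterozygote is unordered.
#'
#' @param parent_a,parent_b Parent genotypes, each one of `"SS"`, `"RS"`,
#'   `"RR"`.
#' @return Named numeric vector `c(SS, RS, RR)` of offspring
#'   probabilities; sums to 1.
#' @examples
#' cross_genotypes("RS", "RS")  # 1/4 : 1/2 : 1/4
#' cross_genotypes("RR", "SS")  # all heterozygous
#' @export
cross_genotypes <- function(parent_a, parent_b) {
  pa <- .gamete_r(parent_a)
  pb <- .gamete_r(parent_b)
  c(SS = (1 - pa) * (1 - pb),
    RS = pa * (1 - pb) + (1 - pa) * pb,
    RR = pa * pb)
}

## probability that a gamete from this genotype carries R
.gamete_r <- function(genotype) {
  if (!is.character(genotype) || length(genotype) != 1L ||
      !genotype %in% GENOTYPES)
    stop("genotype must be one of ", paste(GENOTYPES, collapse = ", "),
         call. = FALSE)
  unname(R_DOSE[genotype]) / 2
}

.check_counts <- function(counts) {
  if (!is.numeric(counts) || length(counts) != 3L ||
      is.null(names(counts)) || !setequal(names(counts), GENOTYPES))
    stop("'counts' must be a numeric vector with names SS, RS, RR",
         call. = FALSE)
  if (any(is.na(counts)) || any(counts < 0))
    stop("genotype counts must be non-negative", call. = FALSE)
  counts[GENOTYPES]
}

#' Resistance-allele frequency of a genotype-count vector
#'
#' @param counts Named numeric vector `c(SS = , RS = , RR = )` of
#'   individuals of one species.
#' @return `(2 n_RR + n_RS) / (2 total)`, in `[0, 1]`.
#'   An empty pool is an error (the frequency is undefined, not 0).
#' @examples
#' allele_frequency(c(SS = 60, RS = 30, RR = 10))  # 0.25
#' @export
allele_frequency <- function(counts) {
  counts <- .check_counts(counts)
  total <- sum(counts)
  if (total == 0)
    stop(empty_pool_condition("allele frequency undefined for an empty pool"))
  unname((2 * counts[["RR"]] + counts[["RS"]]) / (2 * total))
}

empty_pool_condition <- function(msg) {
  structure(class = c("refugeCA_empty_pool", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

#' Offspring distribution under random mating in a pool
#'
#' Random mating among all adults of one species: the gamete pool carries
#' the R allele at frequency `p_R = (2 n_RR + n_RS) / (2 total)` and
#' offspring genotypes are drawn from the Hardy-Weinberg distribution of
#' that gamete frequency (infinite-gamete approximation; no explicit pair
#' formation, no sexes).
#'
#' @inheritParams allele_frequency
#' @return Named numeric vector `c(SS, RS, RR)` of offspring
#'   probabilities. An empty pool raises a `refugeCA_empty_pool`
#'   condition ("no mating"); callers produce no offspring.
#' @examples
#' pool_mating_offspring(c(SS = 60, RS = 30, RR = 10))
#' @export
pool_mating_offspring <- function(counts) {
  counts <- .check_counts(counts)
  if (sum(counts) == 0)
    stop(empty_pool_condition("no mating: empty adult pool"))
  hw_genotype_frequencies(allele_frequency(counts))
}
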