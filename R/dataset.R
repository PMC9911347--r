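#' Genotype dataset carrier
#'
#' A `pk_dataset` bundles a SNP table, a sample table and a genotype matrix,
#' the common carrier passed between all analysis stages.
#'
#' Genotype codes count the REFERENCE allele: `2` = homozygous reference,
#' `1` = heterozygous, `0` = homozygous alternative, `9` = missing. In
#' `pseudo_haploid` mode a single randomly sampled allele represents each
#' call, so only `{0, 2, 9}` occur (`0` = alt allele drawn, `2` = ref allele
#' drawn). The X chromosome is stored as chromosome 23; male X calls are
#' hemizygous and use the haploid codes `{0, 2, 9}` even in diploid mode.
#'
#' @param snps data.frame with columns `snp_id`, `chrom` (integer, 23 = X),
#'   `gpos` (genetic position in Morgans), `ppos` (1-based physical
#'   position), `ref`, `alt`. Must be sorted by (chrom, ppos) with
#'   non-decreasing `gpos` within a chromosome.
#' @param samples data.frame with columns `sample_id`, `sex` (`"M"`, `"F"`
#'   or `"U"`), `group`; a column `n_covered` is (re)computed from the
#'   genotypes.
#' @param geno integer matrix, `nrow(snps)` x `nrow(samples)`, of genotype
#'   codes as above.
#' @param ploidy `"pseudo_haploid"` or `"diploid"`.
#' @param validate check invariants (sorted SNPs, legal codes)?
#' @return An object of class `pk_dataset`.
#' @export
pk_dataset <- function(snps, samples, geno, ploidy = c("pseudo_haploid", "diploid"),
                       validate = TRUE) {
  ploidy <- match.arg(ploidy)
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (nrow(geno) != nrow(snps))
    stop("genotype matrix has ", nrow(geno), " rows but SNP table has ",
         nrow(snps), " entries")
  if (ncol(geno) != nrow(samples))
    stop("genotype matrix has ", ncol(geno), " columns but sample table has ",
         nrow(samples), " entries")
  colnames(geno) <- samples$sample_id
  samples$n_covered <- if (nrow(snps)) colSums(geno != 9L) else integer(nrow(samples))
  ds <- structure(list(snps = snps, samples = samples, geno = geno,
                       ploidy = ploidy),
                  class = "pk_dataset")
  if (validate) validate_dataset(ds)
  ds
}

validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "pk_dataset"))
  snps <- ds$snps
  if (anyDuplicated(ds$samples$sample_id))
    stop("duplicate sample ids")
  if (nrow(snps)) {
    o <- order(snps$chrom, snps$ppos)
    if (!identical(o, seq_len(nrow(snps))))
      stop("SNP table must be sorted by (chromosome, physical position)")
    if (anyDuplicated(snps[c("chrom", "ppos")]))
      stop("duplicate (chromosome, physical position) in SNP table")
    dg <- unlist(tapply(snps$gpos, snps$chrom, function(g) diff(g) < -1e-12),
                 use.names = FALSE)
    if (any(dg))
      stop("genetic positions must be non-decreasing within a chromosome")
  }
  codes <- unique(as.vector(ds$geno))
  legal <- if (ds$ploidy == "pseudo_haploid") c(0L, 2L, 9L) else c(0L, 1L, 2L, 9L)
  bad <- setdiff(codes, legal)
  if (length(bad))
    stop("illegal genotype code(s) ", paste(bad, collapse = ", "),
         " for ploidy mode '", ds$ploidy, "'")
  invisible(ds)
}

#' @export
print.pk_dataset <- function(x, ...) {
  cat("pk_dataset:", nrow(x$snps), "SNPs x", nrow(x$samples), "samples (",
      x$ploidy, ")\n")
  cat("  chromosomes:", paste(unique(x$snps$chrom), collapse = " "), "\n")
  cat("  groups:", paste(unique(x$samples$group), collapse = ", "), "\n")
  miss <- if (length(x$geno)) mean(x$geno == 9L) else NA_real_
  cat("  missingness:", format(miss, digits = 3), "\n")
  invisible(x)
}

#' @export
`[.pk_dataset` <- function(x, i, j) {
  if (missing(i)) i <- seq_len(nrow(x$snps))
  if (missing(j)) j <- seq_len(nrow(x$samples))
  if (is.character(j)) j <- match(j, x$samples$sample_id)
  pk_dataset(x$snps[i, , drop = FALSE],
             x$samples[j, , drop = FALSE],
             x$geno[i, j, drop = FALSE],
             ploidy = x$ploidy, validate = FALSE)
}

#' Subset a dataset to one or more chromosomes
#' @param ds a [pk_dataset()]
#' @param chroms integer chromosome codes (23 = X)
#' @export
subset_chromosomes <- function(ds, chroms) {
  ds[ds$snps$chrom %in% chroms, ]
}

# run code with a temporary RNG seed, restoring the caller's RNG state
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# derive a child seed < 2^31 from a master seed and a label, stable across runs
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 131L)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629)
}
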