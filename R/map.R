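#' Default genetic map
#'
#' Chromosome lengths in Morgans. The autosomal total (default 35.2 M, a
#' conventional sex-averaged constant) is split over 22 autosomes in
#' proportion to approximate human genetic lengths; the X chromosome
#' (stored as chromosome 23) defaults to 1.8 M.
#'
#' @param total_morgans autosomal total map length in Morgans
#' @param x_morgans X-chromosome length in Morgans
#' @param include_x include the X chromosome?
#' @param n_autosomes number of autosomes (shorter maps keep the longest
#'   chromosomes, useful for desk-scale simulation)
#' @return data.frame with columns `chrom`, `morgans`.
#' @export
default_map <- function(total_morgans = 35.2, x_morgans = 1.8,
                        include_x = FALSE, n_autosomes = 22L) {
  # approximate sex-averaged genetic lengths (cM) of human autosomes 1-22
  rel <- c(286, 269, 223, 214, 204, 192, 187, 168, 166, 181,
           158, 175, 126, 119, 141, 134, 128, 117, 107, 108, 62, 74)
  stopifnot(n_autosomes >= 1L, n_autosomes <= 22L)
  rel <- rel[seq_len(n_autosomes)]
  map <- data.frame(chrom = seq_len(n_autosomes),
                    morgans = total_morgans * rel / sum(rel))
  if (include_x)
    map <- rbind(map, data.frame(chrom = 23L, morgans = x_morgans))
  map
}

#' Build a SNP panel on a genetic map
#'
#' Places `n_snps` sites on the map, allocated to chromosomes in proportion
#' to genetic length, with uniformly distributed genetic positions.
#' Physical positions use a 1 cM per Mb scale.
#'
#' @param n_snps total number of SNPs
#' @param map data.frame as from [default_map()]
#' @param seed integer RNG seed
#' @return A SNP table suitable for [pk_dataset()].
#' @export
make_snp_panel <- function(n_snps, map = default_map(), seed = 1L) {
  local_seed(seed, {
    n_per <- round(n_snps * map$morgans / sum(map$morgans))
    n_per[length(n_per)] <- n_snps - sum(n_per[-length(n_per)])
    parts <- lapply(seq_len(nrow(map)), function(i) {
      g <- sort(stats::runif(n_per[i], 0, map$morgans[i]))
      pp <- as.integer(round(g * 1e8)) + 1L          # 1 Morgan = 100 Mb
      dup <- duplicated(pp)
      while (any(dup)) {                              # nudge physical collisions
        pp[dup] <- pp[dup] + 1L
        o <- order(pp); pp <- pp[o]; g <- g[o]
        dup <- duplicated(pp)
      }
      data.frame(chrom = map$chrom[i], gpos = g, ppos = pp)
    })
    snp <- do.call(rbind, parts)
    alleles <- c("A", "C", "G", "T")
    ra <- sample(alleles, nrow(snp), replace = TRUE)
    aa <- sample(alleles[-1], nrow(snp), replace = TRUE)
    aa <- ifelse(aa == ra, "A", aa)
    data.frame(snp_id = sprintf("snp_%d_%d", snp$chrom, snp$ppos),
               chrom = snp$chrom, gpos = snp$gpos, ppos = snp$ppos,
               ref = ra, alt = ifelse(aa == ra, "T", aa),
               stringsAsFactors = FALSE)
  })
}
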