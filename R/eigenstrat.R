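#' Read an EIGENSTRAT genotype triplet
#'
#' Reads the text dialect of EIGENSTRAT: a `.geno` file with one row of
#' digits per SNP (one digit per individual, no separators), a 6-column
#' `.snp` file (id, chromosome, genetic position in Morgans, physical
#' position, ref allele, alt allele) and a 3-column `.ind` file (id, sex,
#' group label).
#'
#' @param prefix path prefix; `<prefix>.geno`, `<prefix>.snp`,
#'   `<prefix>.ind` are read. Alternatively a named list/vector with
#'   elements `geno`, `snp`, `ind`.
#' @param ploidy declared ploidy mode of the data; a `1` in a file declared
#'   `pseudo_haploid` is an error.
#' @return A [pk_dataset()].
#' @export
read_eigenstrat <- function(prefix, ploidy = c("pseudo_haploid", "diploid")) {
  ploidy <- match.arg(ploidy)
  paths <- eigenstrat_paths(prefix)
  ind <- utils::read.table(paths[["ind"]], header = FALSE,
                           col.names = c("sample_id", "sex", "group"),
                           colClasses = "character")
  snp <- utils::read.table(paths[["snp"]], header = FALSE,
                           col.names = c("snp_id", "chrom", "gpos", "ppos", "ref", "alt"),
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  snp$chrom <- chrom_to_int(snp$chrom)
  lines <- readLines(paths[["geno"]])
  if (length(lines) != nrow(snp))
    stop("dimension mismatch: ", paths[["geno"]], " has ", length(lines),
         " rows but ", paths[["snp"]], " lists ", nrow(snp), " SNPs")
  widths <- nchar(lines)
  if (nrow(snp) && any(widths != nrow(ind)))
    stop("dimension mismatch: ", paths[["geno"]], " row ",
         which(widths != nrow(ind))[1], " has ", widths[widths != nrow(ind)][1],
         " characters but ", paths[["ind"]], " lists ", nrow(ind), " individuals")
  geno <- parse_geno_lines(lines, nrow(ind), paths[["geno"]])
  if (ploidy == "pseudo_haploid" && any(geno == 1L))
    stop("ploidy violation: genotype code 1 found in file declared pseudo_haploid (",
         paths[["geno"]], ", row ", which(rowSums(geno == 1L) > 0)[1], ")")
  pk_dataset(snp, ind, geno, ploidy = ploidy)
}

eigenstrat_paths <- function(prefix) {
  if (is.list(prefix) || length(prefix) == 3L) {
    p <- unlist(prefix)
    stopifnot(all(c("geno", "snp", "ind") %in% names(p)))
    return(p[c("geno", "snp", "ind")])
  }
  c(geno = paste0(prefix, ".geno"), snp = paste0(prefix, ".snp"),
    ind = paste0(prefix, ".ind"))
}

chrom_to_int <- function(x) {
  x <- sub("^chr", "", as.character(x))
  x[x %in% c("X", "x")] <- "23"
  out <- suppressWarnings(as.integer(x))
  if (anyNA(out)) stop("unparseable chromosome label: ", x[is.na(out)][1])
  out
}

parse_geno_lines <- function(lines, n_ind, file) {
  if (!length(lines)) return(matrix(integer(), 0L, n_ind))
  chars <- strsplit(lines, "", fixed = TRUE)
  m <- matrix(match(unlist(chars), c("0", "1", "2", "9")) - 1L,
              nrow = length(lines), ncol = n_ind, byrow = TRUE)
  m[m == 3L] <- 9L
  if (anyNA(m)) {
    bad <- which(rowSums(is.na(m)) > 0)[1]
    stop("parse error: illegal genotype character in ", file, " row ", bad)
  }
  m
}

#' Write a dataset as an EIGENSTRAT triplet
#'
#' Writes the canonical text dialect (see [read_eigenstrat()]); genetic
#' positions are written in Morgans with six decimals.
#'
#' @param ds a [pk_dataset()]
#' @param prefix output path prefix
#' @return The three file paths, invisibly.
#' @export
write_eigenstrat <- function(ds, prefix) {
  paths <- eigenstrat_paths(prefix)
  g <- ds$geno
  lines <- if (nrow(g)) {
    m <- matrix(as.character(g), nrow(g), ncol(g))
    do.call(paste0, c(as.data.frame(m, stringsAsFactors = FALSE), list()))
  } else character()
  if (nrow(g) && ncol(g) == 0L) lines <- rep("", nrow(g))
  writeLines(lines, paths[["geno"]])
  snp <- ds$snps
  chrom_lab <- ifelse(snp$chrom == 23L, "23", as.character(snp$chrom))
  writeLines(sprintf("%s\t%s\t%.6f\t%d\t%s\t%s", snp$snp_id, chrom_lab,
                     snp$gpos, snp$ppos, snp$ref, snp$alt), paths[["snp"]])
  smp <- ds$samples
  writeLines(sprintf("%s\t%s\t%s", smp$sample_id, smp$sex, smp$group),
             paths[["ind"]])
  invisible(paths)
}

#' Merge duplicate libraries of one individual at the genotype level
#'
#' At every SNP, if exactly one input sample has a non-missing call it is
#' taken; if several disagree-or-agree a non-missing call is chosen
#' uniformly at random; if all are missing the merged call is missing.
#'
#' @param ds a [pk_dataset()]
#' @param sample_ids two or more sample ids to merge
#' @param new_id id of the merged sample (default: first id)
#' @param seed integer RNG seed for the random choice among non-missing calls
#' @param drop_inputs remove the input samples from the result?
#' @return A [pk_dataset()] containing the merged sample.
#' @export
merge_samples <- function(ds, sample_ids, new_id = sample_ids[1], seed = 1L,
                          drop_inputs = TRUE) {
  idx <- match(sample_ids, ds$samples$sample_id)
  if (anyNA(idx))
    stop("unknown sample id(s): ",
         paste(sample_ids[is.na(idx)], collapse = ", "))
  if (length(idx) < 2L) stop("need at least two samples to merge")
  g <- ds$geno[, idx, drop = FALSE]
  merged <- local_seed(seed, {
    ok <- g != 9L
    n_ok <- rowSums(ok)
    out <- rep(9L, nrow(g))
    # pick a uniformly random non-missing column per SNP
    pick <- ceiling(stats::runif(nrow(g)) * pmax(n_ok, 1L))
    csum <- ok * 0L
    csum[] <- t(apply(ok, 1L, cumsum))
    for (j in seq_len(ncol(g))) {
      take <- ok[, j] & csum[, j] == pick & out == 9L
      out[take] <- g[take, j]
    }
    out[n_ok == 0L] <- 9L
    out
  })
  keep <- if (drop_inputs) setdiff(seq_len(ncol(ds$geno)), idx) else seq_len(ncol(ds$geno))
  first <- ds$samples[idx[1], , drop = FALSE]
  first$sample_id <- new_id
  samples <- rbind(ds$samples[keep, , drop = FALSE], first)
  geno <- cbind(ds$geno[, keep, drop = FALSE], merged)
  pk_dataset(ds$snps, samples, geno, ploidy = ds$ploidy, validate = FALSE)
}

#' Drop poorly covered individuals
#'
#' Removes samples whose number of covered (non-missing) SNPs falls below
#' `min_snps`. Contamination-based exclusion is an upstream concern and is
#' exposed only as an optional logical mask.
#'
#' @param ds a [pk_dataset()]
#' @param min_snps minimum covered-SNP count; samples strictly below it are
#'   removed (default 20000)
#' @param keep_mask optional logical vector (one per sample); `FALSE`
#'   removes the sample regardless of coverage
#' @return The filtered [pk_dataset()] (possibly with zero samples).
#' @export
filter_individuals <- function(ds, min_snps = 20000L, keep_mask = NULL) {
  stopifnot(min_snps >= 0)
  keep <- ds$samples$n_covered >= min_snps
  if (!is.null(keep_mask)) keep <- keep & keep_mask
  ds[, which(keep)]
}
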