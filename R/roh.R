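#' Call runs of homozygosity with a two-state HMM
#'
#' A frequency-based HMM on sparse diploid calls: along each chromosome
#' the hidden state is ROH (autozygous) or non-ROH; heterozygotes are
#' emitted with probability `2p(1-p)` (scaled by `1 - err`) outside ROH
#' and with probability `err` inside; homozygote emissions follow allele
#' frequency inside ROH and Hardy-Weinberg outside. Transitions use entry
#' rate `theta` per cM and exit rate `1/mean_len_cM`. Viterbi segments
#' are post-filtered to `min_cM` genetic length and `min_snps` covered
#' sites; segment endpoints are placed at the midpoint between the
#' boundary SNP and the adjacent SNP outside (the convention for sparse
#' data). This caller works from genotypes and population frequencies
#' alone - it is not a haplotype-copying reference-panel HMM.
#'
#' @param ds a diploid [pk_dataset()] with a genetic map (`gpos`)
#' @param freqs per-SNP reference-allele frequencies
#' @param samples sample ids to call (default all)
#' @param min_cM minimum reported segment length (default 4)
#' @param min_snps minimum covered SNPs per segment (default 50)
#' @param err genotype/emission error rate (default 0.01)
#' @param theta ROH entry rate per cM (default 0.001, i.e. 0.1 expected
#'   entries per Morgan under outbreeding)
#' @param mean_len_cM prior mean ROH length (default 8)
#' @param min_covered samples covered at fewer autosomal SNPs are skipped
#'   with a warning (default 0.25 x the panel size, emulating the
#'   250k-of-1.1M operating point; pass an absolute count to override)
#' @return data.frame of class `pk_roh`: sample, chrom, start_cM, end_cM,
#'   length_cM, n_snps.
#' @export
call_roh <- function(ds, freqs, samples = NULL, min_cM = 4, min_snps = 50L,
                     err = 0.01, theta = 0.001, mean_len_cM = 8,
                     min_covered = NULL) {
  stopifnot(ds$ploidy == "diploid")
  if (is.null(ds$snps$gpos) || all(ds$snps$gpos == 0))
    stop("no genetic map: cM segment lengths are undefined")
  if (is.null(samples)) samples <- ds$samples$sample_id
  aut <- ds$snps$chrom != 23L
  if (is.null(min_covered)) min_covered <- 0.25 * sum(aut)
  chroms <- setdiff(unique(ds$snps$chrom), 23L)
  out <- list()
  for (sid in samples) {
    j <- match(sid, ds$samples$sample_id)
    g <- ds$geno[, j]
    if (sum(g[aut] != 9L) < min_covered) {
      warning("sample ", sid, " below the covered-SNP floor; skipped")
      next
    }
    for (ch in chroms) {
      idx <- which(ds$snps$chrom == ch & g != 9L)
      if (length(idx) < min_snps) next
      p <- pmin(pmax(freqs[idx], 1e-4), 1 - 1e-4)
      gg <- g[idx]
      q <- 1 - p
      le <- matrix(0, 2L, length(idx))
      het <- gg == 1L
      hom_r <- gg == 2L
      le[1, ] <- log(ifelse(het, 2 * p * q * (1 - err),
                            ifelse(hom_r, p^2 + p * q * err, q^2 + p * q * err)))
      le[2, ] <- log(ifelse(het, err,
                            ifelse(hom_r, p * (1 - err), q * (1 - err))))
      cm <- ds$snps$gpos[idx] * 100
      path <- viterbi_two_state(le, diff(cm), theta, 1 / mean_len_cM)
      if (!any(path == 1L)) next
      r <- rle(path == 1L)
      hi <- cumsum(r$lengths); lo <- hi - r$lengths + 1L
      for (seg in which(r$values)) {
        a <- lo[seg]; b <- hi[seg]
        start <- if (a == 1L) cm[1] else (cm[a - 1L] + cm[a]) / 2
        end <- if (b == length(cm)) cm[length(cm)] else (cm[b] + cm[b + 1L]) / 2
        len <- end - start
        if (len < min_cM || (b - a + 1L) < min_snps) next
        out[[length(out) + 1L]] <-
          data.frame(sample = sid, chrom = ch, start_cM = start, end_cM = end,
                     length_cM = len, n_snps = b - a + 1L,
                     stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(sample = character(), chrom = integer(), start_cM = numeric(),
               end_cM = numeric(), length_cM = numeric(), n_snps = integer())
  class(res) <- c("pk_roh", "data.frame")
  res
}

#' Summarize ROH segments into length-bin profiles
#'
#' Sums segment lengths per sample in the conventional reporting bins
#' `[4,8)`, `[8,12)`, `[12,20)`, `[20,Inf)` cM.
#'
#' @param segments `pk_roh` data.frame from [call_roh()] (or a truth
#'   table with columns `sample`/`id` and `length_cM`)
#' @param samples sample ids to tabulate (default: those present);
#'   samples without segments get all-zero rows
#' @param breaks lower bin edges (last bin open-ended)
#' @return matrix of class `pk_roh_profile`: samples x bins, plus a
#'   `total` column.
#' @export
summarize_roh <- function(segments, samples = NULL, breaks = c(4, 8, 12, 20)) {
  id_col <- if ("sample" %in% names(segments)) "sample" else "id"
  if (is.null(samples)) samples <- unique(segments[[id_col]])
  labs <- paste0("[", breaks, ",", c(breaks[-1], Inf), ")")
  prof <- matrix(0, length(samples), length(breaks) + 1L,
                 dimnames = list(samples, c(labs, "total")))
  if (nrow(segments)) {
    keep <- segments$length_cM >= breaks[1] &
      segments[[id_col]] %in% samples
    seg <- segments[keep, , drop = FALSE]
    if (nrow(seg)) {
      bin <- findInterval(seg$length_cM, breaks)
      for (k in seq_len(nrow(seg))) {
        i <- match(seg[[id_col]][k], samples)
        prof[i, bin[k]] <- prof[i, bin[k]] + seg$length_cM[k]
      }
      prof[, "total"] <- rowSums(prof[, seq_along(breaks), drop = FALSE])
    }
  }
  class(prof) <- c("pk_roh_profile", "matrix", "array")
  prof
}

#' Standard parental-relationship pedigrees
#'
#' Builds the pedigree whose last member (`"proband"`) is the offspring
#' of parents related to the given degree, used for ROH expectation
#' simulations. Supported: `"unrelated"`, `"first_cousins"` (F = 1/16),
#' `"second_cousins"` (1/64), `"half_siblings"` (1/8), `"avuncular"`
#' (1/8), `"double_first_cousins"` (1/8).
#'
#' @param relationship one of the supported labels
#' @return pedigree data.frame for [simulate_pedigree_genotypes()].
#' @export
relationship_pedigree <- function(relationship = c("unrelated", "first_cousins",
                                                   "second_cousins",
                                                   "half_siblings", "avuncular",
                                                   "double_first_cousins")) {
  relationship <- match.arg(relationship)
  P <- function(id, sex, fa = NA, mo = NA)
    data.frame(id = id, sex = sex, father = fa, mother = mo,
               stringsAsFactors = FALSE)
  switch(relationship,
    unrelated = rbind(P("fa", "M"), P("mo", "F"),
                      P("proband", "F", "fa", "mo")),
    first_cousins = rbind(
      P("g1", "M"), P("g2", "F"), P("s1", "M", "g1", "g2"),
      P("s2", "F", "g1", "g2"), P("w1", "F"), P("h2", "M"),
      P("fa", "M", "s1", "w1"), P("mo", "F", "h2", "s2"),
      P("proband", "F", "fa", "mo")),
    second_cousins = rbind(
      P("gg1", "M"), P("gg2", "F"),
      P("a1", "M", "gg1", "gg2"), P("a2", "F", "gg1", "gg2"),
      P("aw", "F"), P("ah", "M"),
      P("b1", "M", "a1", "aw"), P("b2", "F", "ah", "a2"),
      P("bw", "F"), P("bh", "M"),
      P("fa", "M", "b1", "bw"), P("mo", "F", "bh", "b2"),
      P("proband", "F", "fa", "mo")),
    half_siblings = rbind(
      P("g1", "M"), P("w1", "F"), P("w2", "F"),
      P("fa", "M", "g1", "w1"), P("mo", "F", "g1", "w2"),
      P("proband", "F", "fa", "mo")),
    avuncular = rbind(
      P("g1", "M"), P("g2", "F"), P("s1", "M", "g1", "g2"),
      P("mo", "F", "g1", "g2"), P("w1", "F"),
      P("fa", "M", "s1", "w1"),
      P("proband", "F", "fa", "mo")),
    double_first_cousins = rbind(
      P("ga", "M"), P("gb", "F"), P("gc", "M"), P("gd", "F"),
      P("a1", "M", "ga", "gb"), P("a2", "F", "ga", "gb"),
      P("b1", "F", "gc", "gd"), P("b2", "M", "gc", "gd"),
      P("fa", "M", "a1", "b1"), P("mo", "F", "b2", "a2"),
      P("proband", "F", "fa", "mo")))
}

#' Simulated ROH expectations for a parental relationship
#'
#' Simulates `n_sims` offspring of parents with the given relationship
#' (pedigree transmission with Poisson crossovers; truth autozygous
#' segments, no genotype noise) and summarizes each genome's ROH length
#' profile, giving the reference distribution against which observed
#' profiles are matched.
#'
#' @param relationship label understood by [relationship_pedigree()]
#' @param map genetic map (default [default_map()])
#' @param n_sims number of simulated genomes (>= 100 recommended)
#' @param seed integer RNG seed
#' @param breaks bin edges as in [summarize_roh()]
#' @param min_cM segments below this are dropped, matching the caller
#' @return list of class `pk_roh_expectation`: `relationship`, `profiles`
#'   (n_sims x bins), `mean`, `sd`.
#' @export
expected_roh <- function(relationship, map = default_map(), n_sims = 200L,
                         seed = 1L, breaks = c(4, 8, 12, 20), min_cM = 4) {
  ped <- relationship_pedigree(relationship)
  profs <- matrix(0, n_sims, length(breaks) + 1L)
  for (i in seq_len(n_sims)) {
    sim <- simulate_pedigree_genotypes(ped, genotypes = FALSE, map = map,
                                       seed = child_seed(seed, paste0(relationship, i)))
    tr <- sim$roh_truth[sim$roh_truth$id == "proband" &
                          sim$roh_truth$length_cM >= min_cM, , drop = FALSE]
    profs[i, ] <- summarize_roh(tr, samples = "proband", breaks = breaks)[1, ]
  }
  colnames(profs) <- c(paste0("[", breaks, ",", c(breaks[-1], Inf), ")"), "total")
  structure(list(relationship = relationship, profiles = profs,
                 mean = colMeans(profs), sd = apply(profs, 2, stats::sd)),
            class = "pk_roh_expectation")
}

#' Classify parental relatedness from ROH profiles
#'
#' Matches each observed bin profile (or, with `combine = TRUE`, the
#' pooled profile of all samples - the combined-histogram logic) against
#' the simulated distribution of every candidate relationship using a
#' Gaussian-smoothed bin-wise log likelihood (simulated mean and sd per
#' bin, sd floored by `sd_floor` to absorb single-genome recombination
#' noise). The best class is returned with its margin over the runner-up;
#' a sample is flagged consanguineous when the best class is a close-kin
#' union (inbreeding coefficient >= 1/16) and beats "unrelated".
#'
#' @param profiles a `pk_roh_profile` matrix from [summarize_roh()]
#' @param expectations list of `pk_roh_expectation` objects covering the
#'   hypothesis set (must include `"unrelated"`)
#' @param combine pool all rows into one cumulative profile?
#' @param sd_floor minimum per-bin sd in cM (default 10)
#' @return data.frame: sample, best, margin, consanguineous, plus one
#'   log-likelihood column per relationship.
#' @export
classify_parental_relatedness <- function(profiles, expectations,
                                          combine = FALSE, sd_floor = 10) {
  rels <- vapply(expectations, function(e) e$relationship, "")
  names(expectations) <- rels
  if (!"unrelated" %in% rels)
    stop("expectations must include the 'unrelated' hypothesis")
  close_kin <- c("first_cousins", "half_siblings", "avuncular",
                 "double_first_cousins")
  X <- unclass(profiles)
  if (combine) {
    X <- matrix(colSums(X), 1L, ncol(X), dimnames = list("combined", colnames(X)))
    n_pool <- nrow(profiles)
  } else n_pool <- 1L
  nb <- ncol(X) - 1L                       # drop the redundant total column
  ll <- matrix(NA_real_, nrow(X), length(rels),
               dimnames = list(rownames(X), rels))
  for (r in rels) {
    e <- expectations[[r]]
    mu <- n_pool * e$mean[seq_len(nb)]
    sdv <- pmax(sqrt(n_pool) * e$sd[seq_len(nb)], sd_floor)
    ll[, r] <- colSums(stats::dnorm(t(X[, seq_len(nb), drop = FALSE]),
                                    mean = mu, sd = sdv, log = TRUE))
  }
  best <- rels[max.col(ll)]
  margin <- apply(ll, 1L, function(v) {
    s <- sort(v, decreasing = TRUE); s[1] - s[2]
  })
  data.frame(sample = rownames(X), best = best, margin = margin,
             consanguineous = best %in% close_kin &
               ll[cbind(seq_len(nrow(ll)), match(best, rels))] >
                 ll[, "unrelated"],
             ll, stringsAsFactors = FALSE, row.names = NULL)
}

#' Within-individual heterozygosity
#'
#' `h` = heterozygous sites / covered sites, per sample, on diploid
#' calls (autosomes only). Under random mating `h` matches the
#' population's pairwise mismatch rate `P0` of unrelated pseudo-haploid
#' pairs, so a jointly reduced `h` and `P0` indicates a small-population
#' (drifted) gene pool rather than close kin.
#'
#' @param ds a diploid [pk_dataset()]
#' @param samples sample ids (default all)
#' @return named numeric vector of per-sample heterozygosity.
#' @export
heterozygosity <- function(ds, samples = NULL) {
  stopifnot(ds$ploidy == "diploid")
  if (is.null(samples)) samples <- ds$samples$sample_id
  aut <- ds$snps$chrom != 23L
  vapply(samples, function(sid) {
    g <- ds$geno[aut, match(sid, ds$samples$sample_id)]
    sum(g == 1L) / sum(g != 9L)
  }, 0)
}
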