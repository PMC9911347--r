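#' Pairwise mismatch rates (READ-style P0)
#'
#' For every sample pair, `P0` is the fraction of overlapping (both
#' called) SNPs at which the two pseudo-haploid calls differ. `P0` is
#' also computed on non-overlapping physical windows; the reported
#' standard error is the weighted block jackknife over windows (weights =
#' overlapping SNPs per window), robust to sparse windows.
#'
#' @param ds a pseudo-haploid [pk_dataset()]
#' @param pairs optional 2-column matrix/data.frame of sample ids;
#'   default: all pairs
#' @param window_mb window size in megabases (default 1, the original
#'   tool's default)
#' @param min_overlap pairs with fewer overlapping SNPs are skipped (and
#'   recorded with `NA`)
#' @return data.frame of class `pk_mismatch`: id1, id2, n_overlap, P0, se.
#' @export
pairwise_mismatch <- function(ds, pairs = NULL, window_mb = 1,
                              min_overlap = 1000L) {
  stopifnot(ds$ploidy == "pseudo_haploid")
  ids <- ds$samples$sample_id
  if (is.null(pairs)) {
    cb <- utils::combn(ids, 2L)
    pairs <- data.frame(id1 = cb[1, ], id2 = cb[2, ], stringsAsFactors = FALSE)
  } else {
    pairs <- data.frame(id1 = as.character(pairs[[1]]),
                        id2 = as.character(pairs[[2]]), stringsAsFactors = FALSE)
  }
  win <- ds$snps$chrom * 1e7 + floor(ds$snps$ppos / (window_mb * 1e6))
  win <- match(win, unique(win))
  out <- pairs
  out$n_overlap <- NA_integer_; out$P0 <- NA_real_; out$se <- NA_real_
  for (k in seq_len(nrow(pairs))) {
    g1 <- ds$geno[, match(pairs$id1[k], ids)]
    g2 <- ds$geno[, match(pairs$id2[k], ids)]
    ok <- g1 != 9L & g2 != 9L
    n <- sum(ok)
    out$n_overlap[k] <- n
    if (n < min_overlap) next
    mm <- as.numeric(g1 != g2 & ok)
    bs <- rowsum(mm, win)
    bn <- rowsum(as.numeric(ok), win)[, 1]
    jk <- block_jackknife(bs, bn)
    out$P0[k] <- jk$value
    out$se[k] <- jk$se
  }
  class(out) <- c("pk_mismatch", "data.frame")
  out
}

#' Classify relatedness degree from normalized mismatch rates
#'
#' Normalizes each pair's `P0` by `alpha`, the cohort's unrelated-pair
#' baseline (default: the median `P0` over all pairs). Expected
#' normalized values are 1 (unrelated), 0.875 (second degree), 0.75
#' (first degree) and 0.5 (identical individuals/twins: `P0 = alpha/2`);
#' the classification cutoffs 0.90625, 0.8125 and 0.625 are the midpoints
#' between adjacent expectations, with boundaries assigned to the
#' closer-kin class.
#'
#' @param mm result of [pairwise_mismatch()]
#' @param alpha optional normalization constant; default median of the
#'   pair `P0` values (requires >= 3 pairs)
#' @return data.frame of class `pk_kinship`: the mismatch columns plus
#'   `normalized` and `degree_class` (`identical`, `first`, `second`,
#'   `unrelated`); `alpha` as an attribute.
#' @export
classify_read <- function(mm, alpha = NULL) {
  p0 <- mm$P0[!is.na(mm$P0)]
  estimated <- is.null(alpha)
  if (estimated) {
    if (length(p0) < 3L)
      stop("fewer than 3 pairs: supply alpha explicitly")
    alpha <- stats::median(p0)
  }
  if (alpha <= 0) stop("alpha must be positive")
  frac_related <- mean(p0 / alpha <= 0.90625)
  if (estimated && frac_related > 0.3)
    warning(sprintf(paste0("%.0f%% of pairs fall below the second-degree ",
                           "threshold; the median-based alpha is unreliable ",
                           "in relative-dominated cohorts - supply alpha"),
                    100 * frac_related))
  norm <- mm$P0 / alpha
  cls <- cut(norm, c(-Inf, 0.625, 0.8125, 0.90625, Inf),
             labels = c("identical", "first", "second", "unrelated"),
             right = TRUE)
  out <- mm
  out$normalized <- norm
  out$degree_class <- as.character(cls)
  attr(out, "alpha") <- alpha
  class(out) <- c("pk_kinship", "data.frame")
  out
}

# per-site observation probabilities P(obs | true genotype G), G = 0,1,2
# ref alleles. Diploid calls: symmetric error err split over the two
# wrong genotypes. Pseudo-haploid calls: one random allele with call
# error err (note: affine in G, so IBD states are only identified
# through r on this path).
obs_given_geno <- function(g, ploidy, err) {
  n <- length(g)
  E <- matrix(NA_real_, n, 3L)
  if (ploidy == "diploid") {
    for (G in 0:2)
      E[, G + 1L] <- ifelse(g == G, 1 - err, err / 2)
  } else {
    a <- as.integer(g == 2L)        # ref allele drawn?
    for (G in 0:2) {
      pref <- (1 - err) * G / 2 + err * (1 - G / 2)
      E[, G + 1L] <- ifelse(a == 1L, pref, 1 - pref)
    }
  }
  E
}

# likelihood of the observed call pair under IBD state m, given ref
# frequency p and observation matrices E1, E2 (sites x 3)
pair_call_likelihood <- function(E1, E2, p, m) {
  like <- 0
  for (G1 in 0:2) {
    pg1 <- stats::dbinom(G1, 2, p)
    for (G2 in 0:2) {
      jp <- switch(as.character(m),
        "0" = pg1 * stats::dbinom(G2, 2, p),
        "2" = pg1 * as.numeric(G1 == G2),
        "1" = joint_ibd1(G1, G2, p))
      like <- like + jp * E1[, G1 + 1L] * E2[, G2 + 1L]
    }
  }
  like
}

# P(G1, G2 | share exactly one allele IBD): shared allele z ~ Bern(p),
# plus one independent allele each
joint_ibd1 <- function(G1, G2, p) {
  q <- 1 - p
  out <- 0
  for (z in 0:1) {
    pz <- if (z == 1) p else q
    x1 <- G1 - z; x2 <- G2 - z
    ok <- x1 %in% 0:1 & x2 %in% 0:1
    if (!ok) next
    px1 <- if (x1 == 1) p else q
    px2 <- if (x2 == 1) p else q
    out <- out + pz * px1 * px2
  }
  out
}

#' Maximum-likelihood IBD coefficients for a pair
#'
#' Estimates `(k0, k1, k2)` — the probabilities of sharing 0, 1 or 2
#' alleles identical by descent — by maximising, over the probability
#' simplex, the product across SNPs of the likelihood of the observed
#' call pair given the population allele frequency and a symmetric
#' call-error rate. The relatedness coefficient is `r` `= k1/2 + k2`.
#' Parent-offspring pairs have `k0 = 0`; full siblings approximately
#' `(0.25, 0.5, 0.25)`.
#'
#' On diploid calls (including sparse best-call genotypes, the way the
#' method is used on low-coverage data) the full `(k0,k1,k2)` triple is
#' identified. On pseudo-haploid calls only `r` is identified: a single
#' random allele per site makes the per-site likelihood exactly linear
#' along the `k1/2 + k2` ridge, so `k0` from this path is arbitrary and
#' `r` is the quantity to interpret.
#'
#' @param ds a [pk_dataset()] (diploid or pseudo-haploid; see Details)
#' @param id1,id2 sample ids
#' @param freqs per-SNP reference-allele frequencies (true simulation
#'   frequencies or cohort estimates)
#' @param genotype_error symmetric per-call error rate (default 0.01)
#' @param min_overlap minimum overlapping SNPs (default 5000)
#' @param max_iter,tol EM controls
#' @return list: `k0`, `k1`, `k2`, `r`, `n_snps`, `loglik`.
#' @export
estimate_ibd <- function(ds, id1, id2, freqs, genotype_error = 0.01,
                         min_overlap = 5000L, max_iter = 400L, tol = 1e-9) {
  i <- match(id1, ds$samples$sample_id); j <- match(id2, ds$samples$sample_id)
  if (is.na(i) || is.na(j)) stop("unknown sample id")
  aut <- ds$snps$chrom != 23L
  g1 <- ds$geno[, i]; g2 <- ds$geno[, j]
  ok <- aut & g1 != 9L & g2 != 9L
  if (sum(ok) < min_overlap)
    stop("only ", sum(ok), " overlapping SNPs (need ", min_overlap, ")")
  p <- freqs[ok]
  if (max(p) - min(p) < 1e-6)
    stop("degenerate allele frequencies: IBD coefficients unidentifiable")
  E1 <- obs_given_geno(g1[ok], ds$ploidy, genotype_error)
  E2 <- obs_given_geno(g2[ok], ds$ploidy, genotype_error)
  L <- vapply(0:2, function(m) pair_call_likelihood(E1, E2, p, m),
              numeric(sum(ok)))
  k <- c(1, 1, 1) / 3
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    mix <- L %*% k
    post <- sweep(L, 2L, k, "*") / as.vector(mix)
    k <- colMeans(post)
    ll <- sum(log(mix))
    if (ll - ll_old < tol) break
    ll_old <- ll
  }
  list(k0 = k[1], k1 = k[2], k2 = k[3], r = k[2] / 2 + k[3],
       n_snps = sum(ok), loglik = ll)
}

#' Opposing homozygotes for a diploid pair
#'
#' Counts sites where one sample is homozygous reference and the other
#' homozygous alternative — a Mendelian impossibility for error-free
#' parent-offspring pairs, which disambiguates pedigrees with equal IBD
#' expectations (for example half-siblings versus avuncular after
#' imputation). The rate is per overlapping (both-called) site.
#'
#' @param ds a diploid [pk_dataset()]
#' @param id1,id2 sample ids
#' @return list: `count`, `n_overlap`, `rate`.
#' @export
opposing_homozygotes <- function(ds, id1, id2) {
  if (ds$ploidy != "diploid")
    stop("opposing homozygotes require diploid calls; pseudo-haploid input is unsupported")
  i <- match(id1, ds$samples$sample_id); j <- match(id2, ds$samples$sample_id)
  g1 <- ds$geno[, i]; g2 <- ds$geno[, j]
  ok <- g1 != 9L & g2 != 9L & ds$snps$chrom != 23L
  cnt <- sum((g1 == 0L & g2 == 2L | g1 == 2L & g2 == 0L) & ok)
  list(count = cnt, n_overlap = sum(ok), rate = cnt / sum(ok))
}

#' Degree classes from relatedness coefficients
#'
#' Maps an estimated relatedness coefficient `r` to a degree on the
#' half-log2 grid: first degree (`r` near 1/2), second (1/4), third
#' (`1/8`), else unrelated (0). Degrees beyond 3 degrade to unrelated.
#'
#' @param r numeric vector of relatedness coefficients
#' @return integer vector: 1, 2, 3 or 0 (unrelated).
#' @export
degree_from_r <- function(r) {
  out <- integer(length(r))
  out[r >= 2^-1.5] <- 1L
  out[r >= 2^-2.5 & r < 2^-1.5] <- 2L
  out[r >= 2^-3.5 & r < 2^-2.5] <- 3L
  out
}
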