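#' 5 cM block partition of a SNP table
#'
#' Assigns every SNP to a contiguous genetic-map window of `block_morgans`
#' (default 0.05 M = 5 cM). Block edges always fall at chromosome
#' boundaries; the last block of a chromosome may be short and is kept.
#'
#' @param snps SNP table of a [pk_dataset()]
#' @param block_morgans target block size in Morgans
#' @return integer vector of block ids (1-based, contiguous).
#' @export
block_partition <- function(snps, block_morgans = 0.05) {
  local <- floor(snps$gpos / block_morgans)
  key <- snps$chrom * 1e6 + local
  match(key, unique(key))
}

# resolve group spec -> named list of sample indices
resolve_groups <- function(ds, specs) {
  ids <- ds$samples$sample_id
  lab <- ds$samples$group
  lapply(specs, function(s) {
    if (all(s %in% ids)) return(match(s, ids))
    idx <- which(lab %in% s)
    if (!length(idx)) stop("no samples for group '", paste(s, collapse = ","), "'")
    idx
  })
}

#' Per-group allele counts
#'
#' Counts reference alleles and total called alleles per SNP per group.
#' A pseudo-haploid call contributes one allele; a diploid call two; male
#' X calls contribute one allele in either mode.
#'
#' @param ds a [pk_dataset()]
#' @param groups named list, each element a group label (from the sample
#'   table) or a vector of sample ids
#' @return list with matrices `ref` and `tot` (SNPs x groups) and `freq`
#'   (`ref/tot`, `NaN` where uncovered).
#' @export
allele_counts <- function(ds, groups) {
  idxs <- resolve_groups(ds, groups)
  n <- nrow(ds$snps)
  is_x <- ds$snps$chrom == 23L
  ref <- matrix(0, n, length(idxs), dimnames = list(NULL, names(idxs)))
  tot <- ref
  for (k in seq_along(idxs)) {
    G <- ds$geno[, idxs[[k]], drop = FALSE]
    M <- G != 9L
    if (ds$ploidy == "pseudo_haploid") {
      ref[, k] <- rowSums((G == 2L) * M)
      tot[, k] <- rowSums(M)
    } else {
      R <- G * M
      Tt <- 2 * M
      if (any(is_x)) {
        male <- ds$samples$sex[idxs[[k]]] == "M"
        if (any(male)) {
          R[is_x, male] <- R[is_x, male] / 2
          Tt[is_x, male] <- M[is_x, male]
        }
      }
      ref[, k] <- rowSums(R)
      tot[, k] <- rowSums(Tt)
    }
  }
  list(ref = ref, tot = tot, freq = ref / tot)
}

#' Weighted block jackknife of a per-SNP statistic
#'
#' Combines per-block sums with weights equal to the SNPs per block
#' (Busing-style weighted delete-one jackknife), the standard error model
#' used for all f-statistics here.
#'
#' @param block_sums numeric matrix (blocks x statistics) of per-block
#'   sums of the per-SNP statistic
#' @param block_n integer vector of SNPs per block
#' @return list: `value` (overall mean), `se`, `z`, `n_blocks`, `n_snps`,
#'   `loo` (leave-one-block-out values), `cov` (jackknife covariance).
#' @export
block_jackknife <- function(block_sums, block_n) {
  block_sums <- as.matrix(block_sums)
  keep <- block_n > 0
  S <- block_sums[keep, , drop = FALSE]
  m <- block_n[keep]
  nb <- length(m)
  if (nb < 2L) stop("fewer than 2 usable blocks; cannot jackknife")
  M <- sum(m)
  tot <- colSums(S)
  theta <- tot / M
  loo <- sweep(-S, 2L, tot, "+") / (M - m)       # theta_{-j}
  h <- M / m
  tau <- outer(h, theta) - (h - 1) * loo
  theta_j <- nb * theta - colSums((1 - m / M) * loo)
  dev <- sweep(tau, 2L, theta_j)
  cv <- crossprod(dev / sqrt(h - 1)) / nb
  se <- sqrt(diag(cv))
  list(value = theta, se = se, z = ifelse(se > 0, theta / se, NA_real_),
       n_blocks = nb, n_snps = M, loo = loo, cov = cv)
}

# shared driver: per-SNP numerator + mask -> jackknifed estimate
fstat_estimate <- function(num, mask, blocks, stat, groups_used) {
  num[!mask] <- 0
  bs <- rowsum(num, blocks)
  bn <- rowsum(as.numeric(mask), blocks)[, 1]
  jk <- block_jackknife(bs, bn)
  structure(list(stat = stat, groups = groups_used, value = unname(jk$value),
                 se = unname(jk$se), z = unname(jk$z), n_blocks = jk$n_blocks,
                 n_snps = jk$n_snps, loo = as.numeric(jk$loo)),
            class = "pk_jack")
}

#' @export
print.pk_jack <- function(x, ...) {
  cat(sprintf("%s(%s) = %.6g  se %.3g  Z %.2f  (%d SNPs, %d blocks)\n",
              x$stat, paste(names(x$groups), collapse = ", "),
              x$value, x$se, x$z, x$n_snps, x$n_blocks))
  invisible(x)
}

#' f4 statistic with block-jackknife standard error
#'
#' `f4(A,B;C,D)` is the mean over SNPs of `(pA - pB)(pC - pD)`, positive
#' when A shares excess drift with C (equivalently B with D). SNPs are
#' restricted to those covered in all four groups; the estimate, standard
#' error and Z score come from the weighted 5 cM block jackknife.
#'
#' @param ds a [pk_dataset()]
#' @param A,B,C,D group labels or sample-id vectors
#' @param block_morgans jackknife block size in Morgans
#' @param blocks optional precomputed [block_partition()]
#' @return A `pk_jack` estimate (value, se, z, n_blocks, loo).
#' @export
f4 <- function(ds, A, B, C, D, block_morgans = 0.05, blocks = NULL) {
  ac <- allele_counts(ds, list(A = A, B = B, C = C, D = D))
  mask <- rowSums(ac$tot > 0) == 4L
  f <- ac$freq
  num <- (f[, 1] - f[, 2]) * (f[, 3] - f[, 4])
  if (is.null(blocks)) blocks <- block_partition(ds$snps, block_morgans)
  fstat_estimate(num, mask, blocks, "f4", list(A = A, B = B, C = C, D = D))
}

#' f3 statistic (admixture or outgroup form)
#'
#' `f3(A; B, C)` is the mean of `(pA - pB)(pA - pC)`. A significantly
#' negative value (Z <= -3) indicates that A's frequencies are
#' intermediate between B and C, i.e. that A is admixed. With
#' `correct = TRUE` (the admixture-f3 default) the finite-sample
#' heterozygosity bias of the target is removed by subtracting
#' `pA(1-pA)/(nA-1)` per SNP (`nA` = called alleles), which makes the
#' statistic unbiased for pseudo-haploid or small target samples; in
#' outgroup mode the uncorrected statistic is conventional.
#'
#' @inheritParams f4
#' @param correct apply the target heterozygosity correction? Default `TRUE`
#'   unless `outgroup_mode = TRUE`.
#' @param outgroup_mode set `TRUE` when A is a deep outgroup and f3 is used
#'   as a shared-drift measure
#' @return A `pk_jack` estimate.
#' @export
f3 <- function(ds, A, B, C, block_morgans = 0.05, blocks = NULL,
               outgroup_mode = FALSE, correct = !outgroup_mode) {
  ac <- allele_counts(ds, list(A = A, B = B, C = C))
  f <- ac$freq
  num <- (f[, 1] - f[, 2]) * (f[, 1] - f[, 3])
  if (correct) {
    mask <- ac$tot[, 1] >= 2 & ac$tot[, 2] > 0 & ac$tot[, 3] > 0
    num <- num - f[, 1] * (1 - f[, 1]) / (ac$tot[, 1] - 1)
  } else {
    mask <- rowSums(ac$tot > 0) == 3L
  }
  if (is.null(blocks)) blocks <- block_partition(ds$snps, block_morgans)
  fstat_estimate(num, mask, blocks, "f3", list(A = A, B = B, C = C))
}

#' f2 drift distance
#'
#' Mean of `(pA - pB)^2` with the finite-sample corrections
#' `-pA(1-pA)/(nA-1) - pB(1-pB)/(nB-1)`, so the estimate is unbiased and
#' non-negative in expectation.
#'
#' @inheritParams f4
#' @return A `pk_jack` estimate.
#' @export
f2 <- function(ds, A, B, block_morgans = 0.05, blocks = NULL) {
  ac <- allele_counts(ds, list(A = A, B = B))
  f <- ac$freq
  num <- (f[, 1] - f[, 2])^2 -
    f[, 1] * (1 - f[, 1]) / (ac$tot[, 1] - 1) -
    f[, 2] * (1 - f[, 2]) / (ac$tot[, 2] - 1)
  mask <- ac$tot[, 1] >= 2 & ac$tot[, 2] >= 2
  if (is.null(blocks)) blocks <- block_partition(ds$snps, block_morgans)
  fstat_estimate(num, mask, blocks, "f2", list(A = A, B = B))
}

#' PCA of reference samples with least-squares projection of targets
#'
#' Computes principal components from reference samples (per-SNP mean
#' centring, 1/sqrt(p(1-p)) normalisation, mean imputation of the few
#' missing reference calls) and projects each target by least squares
#' using only its non-missing SNPs (the lsqproject approach for sparse
#' ancient samples).
#'
#' @param ds a [pk_dataset()]
#' @param refs,targets sample-id vectors (or group labels)
#' @param n_pcs number of components (>= 2)
#' @param min_overlap targets covered at fewer SNPs are flagged and get
#'   `NA` coordinates
#' @return list with `ref_coords`, `target_coords` (matrices, samples x
#'   PCs), `flagged` (ids withheld), `sdev`.
#' @export
pca_project <- function(ds, refs, targets, n_pcs = 2L, min_overlap = 100L) {
  stopifnot(n_pcs >= 2L)
  ridx <- resolve_groups(ds, list(r = refs))$r
  tidx <- resolve_groups(ds, list(t = targets))$t
  G <- ds$geno
  dose <- function(j) {
    x <- G[, j]
    ifelse(x == 9L, NA_real_, x / 2)
  }
  R <- vapply(ridx, dose, numeric(nrow(G)))
  mu <- rowMeans(R, na.rm = TRUE)
  keep <- !is.na(mu) & mu > 0 & mu < 1
  R <- R[keep, , drop = FALSE]
  mu <- mu[keep]
  sdv <- sqrt(mu * (1 - mu))
  Rc <- (R - mu) / sdv
  Rc[is.na(Rc)] <- 0
  sv <- svd(Rc, nu = 0L, nv = n_pcs)
  V <- sv$v                                   # ref coords (samples x PCs)
  load <- Rc %*% V %*% diag(1 / sv$d[seq_len(n_pcs)], n_pcs)  # SNP loadings
  ref_coords <- V %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  rownames(ref_coords) <- ds$samples$sample_id[ridx]
  flagged <- character()
  target_coords <- matrix(NA_real_, length(tidx), n_pcs,
                          dimnames = list(ds$samples$sample_id[tidx], NULL))
  for (k in seq_along(tidx)) {
    x <- dose(tidx[k])[keep]
    ok <- !is.na(x)
    if (sum(ok) < min_overlap) {
      flagged <- c(flagged, ds$samples$sample_id[tidx[k]])
      next
    }
    xc <- (x[ok] - mu[ok]) / sdv[ok]
    L <- load[ok, , drop = FALSE]
    target_coords[k, ] <- solve(crossprod(L), crossprod(L, xc))
  }
  list(ref_coords = ref_coords, target_coords = target_coords,
       flagged = flagged, sdev = sv$d[seq_len(n_pcs)])
}
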