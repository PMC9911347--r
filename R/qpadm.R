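# f4 matrix machinery shared by qpWave and qpAdm.
#
# For left populations L0..L(l-1) and right populations R0..R(r-1) the
# entry (i, j) is f4(L0, Li; R0, Rj), i = 1..l-1, j = 1..r-1, computed
# complete-case across left+right. Per-block sums over the shared 5 cM
# partition give the weighted-jackknife covariance of all entries
# (vec order: i fastest, then j).
f4_block_matrix <- function(ds, left, right, block_morgans = 0.05) {
  left <- if (is.list(left)) left else as.list(left)
  right <- if (is.list(right)) right else as.list(right)
  stopifnot(length(left) >= 2L, length(right) >= 2L)
  if (length(intersect(vapply(left, source_name, ""),
                       vapply(right, source_name, ""))))
    stop("left and right population sets must be disjoint")
  specs <- c(left, right)
  names(specs) <- c(paste0("L", seq_along(left) - 1L),
                    paste0("R", seq_along(right) - 1L))
  ac <- allele_counts(ds, specs)
  mask <- rowSums(ac$tot > 0) == length(specs)
  f <- ac$freq
  l <- length(left); r <- length(right)
  dl <- f[, 1] - f[, 2:l, drop = FALSE]              # pL0 - pLi
  dr <- f[, l + 1] - f[, (l + 2):(l + r), drop = FALSE]  # pR0 - pRj
  D <- (l - 1L) * (r - 1L)
  num <- matrix(0, nrow(f), D)
  for (j in seq_len(r - 1L))
    num[, (j - 1L) * (l - 1L) + seq_len(l - 1L)] <- dl * dr[, j]
  num[!mask, ] <- 0
  blocks <- block_partition(ds$snps, block_morgans)
  bs <- rowsum(num, blocks)
  bn <- rowsum(as.numeric(mask), blocks)[, 1]
  jk <- block_jackknife(bs, bn)
  list(est = jk$value, cov = jk$cov, loo = jk$loo, block_sums = bs[bn > 0, , drop = FALSE],
       block_n = bn[bn > 0], l = l, r = r, left = left, right = right,
       n_snps = jk$n_snps)
}

# Cholesky-based inverse with ridge conditioning for near-singular
# jackknife covariances.
safe_inverse <- function(C) {
  lam <- 0
  for (k in 0:6) {
    Ck <- C + diag(lam, nrow(C))
    ch <- tryCatch(chol(Ck), error = function(e) NULL)
    if (!is.null(ch)) {
      if (lam > 0)
        warning("covariance conditioned with ridge term ", signif(lam, 3))
      return(chol2inv(ch))
    }
    lam <- if (lam == 0) max(1e-6 * sum(diag(C)) / nrow(C), 1e-12) else lam * 10
  }
  stop("covariance matrix could not be inverted")
}

#' qpWave rank test
#'
#' Tests whether the f4 matrix relating the left (target) populations to
#' the right (reference) populations is consistent with rank `rank`, i.e.
#' whether `rank + 1` independent gene pools suffice to explain the left
#' set. Rank 0 with two left populations is the cladality test: a high p
#' means the pair is indistinguishable to the resolution of the
#' references. The statistic is the covariance-weighted quadratic form of
#' the rank-constrained residual, referred to a chi-square with
#' `(l-1-rank)(r-1-rank)` degrees of freedom (a quadratic-form
#' approximation to the original Wishart likelihood-ratio).
#'
#' @param ds a [pk_dataset()]
#' @param left,right disjoint vectors of group labels (or sample ids);
#'   `length(right) > length(left)` is required for a meaningful test
#' @param rank tested rank (default 0)
#' @param block_morgans jackknife block size
#' @return list: `p_value`, `statistic`, `dof`, `rank`, `n_snps`.
#' @export
qpwave_test <- function(ds, left, right, rank = 0L, block_morgans = 0.05) {
  fb <- f4_block_matrix(ds, left, right, block_morgans)
  qpwave_from_blocks(fb, rank)
}

qpwave_from_blocks <- function(fb, rank = 0L) {
  l <- fb$l; r <- fb$r
  stopifnot(rank >= 0L, rank < min(l - 1L, r - 1L) || rank == 0L)
  Ci <- safe_inverse(fb$cov)
  X <- matrix(fb$est, l - 1L, r - 1L)
  if (rank == 0L) {
    resid <- fb$est
  } else {
    fitted <- rank_fit(X, Ci, rank)
    resid <- fb$est - as.vector(fitted)
  }
  stat <- drop(t(resid) %*% Ci %*% resid)
  dof <- (l - 1L - rank) * (r - 1L - rank)
  list(p_value = stats::pchisq(stat, dof, lower.tail = FALSE),
       statistic = stat, dof = dof, rank = rank, n_snps = fb$n_snps)
}

# alternating GLS fit of a rank-k approximation under covariance Ci
rank_fit <- function(X, Ci, k) {
  sv <- svd(X)
  A <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k)
  B <- sv$v[, seq_len(k), drop = FALSE]
  li <- nrow(X); ri <- ncol(X)
  for (it in 1:30) {
    Z <- diag(ri) %x% A                       # vec(AB') = Z vec(t(B))
    vb <- solve(crossprod(Z, Ci %*% Z), crossprod(Z, Ci %*% as.vector(X)))
    B <- matrix(vb, ri, k, byrow = TRUE)
    Z2 <- B %x% diag(li)                      # vec(AB') = Z2 vec(A)
    va <- solve(crossprod(Z2, Ci %*% Z2), crossprod(Z2, Ci %*% as.vector(X)))
    A <- matrix(va, li, k)
  }
  A %*% t(B)
}

#' qpAdm admixture-coefficient estimation
#'
#' Models the target as a mixture of the source populations: weights `w`
#' (summing to 1) are chosen so that every f4 relationship between the
#' target-minus-mixture residual and the right populations vanishes,
#' minimising the jackknife-covariance-weighted quadratic form. The full
#' model is scored by a chi-square tail probability with `|right| -
#' |sources|` degrees of freedom; each nested model re-fits with one
#' source dropped. Weight standard errors come from leave-one-block-out
#' refits (5 cM blocks). Weights outside `[0,1]` mark the model
#' infeasible.
#'
#' @param ds a [pk_dataset()]
#' @param target group label (or sample ids) of the admixed population
#' @param sources vector of source group labels
#' @param right vector of right (reference) group labels
#' @param block_morgans jackknife block size
#' @param feasibility_tol slack allowed outside `[0,1]`
#' @return An object of class `pk_qpadm`: `weights`, `se`, `p_full`,
#'   `nested` (data.frame: dropped source, p-value), `feasible`, `dof`,
#'   `n_snps`.
#' @export
qpadm_fit <- function(ds, target, sources, right, block_morgans = 0.05,
                      feasibility_tol = 1e-9) {
  sources <- if (is.list(sources)) sources else as.list(sources)
  right <- if (is.list(right)) right else as.list(right)
  n <- length(sources)
  if (n < 1L) stop("need at least one source")
  if (n > length(right) - 1L)
    stop("identifiability error: need |sources| <= |right| - 1")
  fb <- f4_block_matrix(ds, c(list(target), sources), right, block_morgans)
  fit <- qpadm_from_blocks(fb, feasibility_tol)
  nested <- data.frame(dropped = character(), p_value = numeric())
  if (n >= 2L) {
    for (i in seq_len(n)) {
      fbi <- f4_block_matrix(ds, c(list(target), sources[-i]), right,
                             block_morgans)
      nested <- rbind(nested,
                      data.frame(dropped = source_name(sources[[i]]),
                                 p_value = qpadm_from_blocks(fbi, feasibility_tol)$p_full))
    }
  }
  fit$nested <- nested
  fit$target <- source_name(target)
  fit$sources <- vapply(sources, source_name, "")
  names(fit$weights) <- names(fit$se) <- fit$sources
  class(fit) <- "pk_qpadm"
  fit
}

source_name <- function(s) paste(s, collapse = "+")

# core solver on a prepared f4 block matrix whose left set is
# c(target, sources)
qpadm_from_blocks <- function(fb, feasibility_tol = 1e-9) {
  n <- fb$l - 1L
  rr <- fb$r - 1L
  M <- matrix(fb$est, n, rr)        # rows = sources, cols = right contrasts
  C <- fb$cov                       # covariance of vec(M), i fastest
  solve_w <- function(Mm, w0) {
    w <- w0
    for (it in 1:12) {
      Aw <- diag(rr) %x% t(w)                 # e = Aw vec(M)
      Ce <- Aw %*% C %*% t(Aw)
      Cei <- safe_inverse(Ce)
      B <- Mm %*% Cei %*% t(Mm)
      sol <- solve(B + diag(1e-12 * max(diag(B)), n), rep(1, n))
      w_new <- sol / sum(sol)
      if (max(abs(w_new - w)) < 1e-10) { w <- w_new; break }
      w <- w_new
    }
    w
  }
  w <- solve_w(M, rep(1 / n, n))
  Aw <- diag(rr) %x% t(w)
  Ce <- Aw %*% C %*% t(Aw)
  Cei <- safe_inverse(Ce)
  e <- drop(t(M) %*% w)
  stat <- drop(t(e) %*% Cei %*% e)
  dof <- fb$r - n
  p_full <- stats::pchisq(stat, dof, lower.tail = FALSE)
  # leave-one-block-out weights -> weighted jackknife SE
  bs <- fb$block_sums; bn <- fb$block_n
  tot <- colSums(bs); Mtot <- sum(bn)
  nb <- length(bn)
  loo_w <- matrix(NA_real_, nb, n)
  for (b in seq_len(nb)) {
    Mb <- matrix((tot - bs[b, ]) / (Mtot - bn[b]), n, rr)
    loo_w[b, ] <- solve_w(Mb, w)
  }
  h <- Mtot / bn
  tau <- outer(h, w) - (h - 1) * loo_w
  theta_j <- nb * w - colSums((1 - bn / Mtot) * loo_w)
  se <- sqrt(colSums(sweep(tau, 2L, theta_j)^2 / (h - 1)) / nb)
  feasible <- all(w >= -feasibility_tol & w <= 1 + feasibility_tol)
  list(weights = w, se = se, p_full = p_full, statistic = stat, dof = dof,
       feasible = feasible, n_snps = fb$n_snps)
}

#' @export
print.pk_qpadm <- function(x, ...) {
  cat("qpAdm:", x$target, "~", paste(x$sources, collapse = " + "), "\n")
  for (i in seq_along(x$weights))
    cat(sprintf("  %-14s %7.4f (se %.4f)\n", x$sources[i], x$weights[i], x$se[i]))
  cat(sprintf("  p_full = %.4g (dof %d, %d SNPs); feasible: %s\n",
              x$p_full, x$dof, x$n_snps, x$feasible))
  if (nrow(x$nested))
    for (i in seq_len(nrow(x$nested)))
      cat(sprintf("  nested (drop %s): p = %.4g\n",
                  x$nested$dropped[i], x$nested$p_value[i]))
  invisible(x)
}

#' Competing-source rotation protocol
#'
#' For each candidate source set, the remaining candidates are moved into
#' the right population list: if a population placed on the right is a
#' better proxy for a real source than the ones modelled on the left, the
#' model fits poorly (low p). Models with `p < p_cut` are flagged
#' rejected.
#'
#' @param ds a [pk_dataset()]
#' @param target target group
#' @param candidates vector of candidate source groups (>= 2, or 1 for a
#'   plain fit)
#' @param base_right right populations always kept on the right
#' @param n_sources number of sources per model (default 1 uses each
#'   candidate alone; 2 uses every unordered pair, etc.)
#' @param p_cut rejection threshold (default 0.01)
#' @param block_morgans jackknife block size
#' @return data.frame: sources, p_full, weights, feasible, rejected.
#' @export
rotate_competing_sources <- function(ds, target, candidates, base_right,
                                     n_sources = 1L, p_cut = 0.01,
                                     block_morgans = 0.05) {
  stopifnot(length(candidates) >= 1L)
  sets <- utils::combn(length(candidates), min(n_sources, length(candidates)),
                       simplify = FALSE)
  rows <- lapply(sets, function(sel) {
    src <- candidates[sel]
    right <- c(base_right, candidates[-sel])
    fit <- tryCatch(qpadm_fit(ds, target, src, right, block_morgans),
                    error = function(e) e)
    if (inherits(fit, "error"))
      return(data.frame(sources = paste(src, collapse = "+"),
                        p_full = NA_real_, weights = NA_character_,
                        feasible = NA, rejected = NA,
                        error = conditionMessage(fit)))
    data.frame(sources = paste(src, collapse = "+"),
               p_full = fit$p_full,
               weights = paste(sprintf("%.3f", fit$weights), collapse = ","),
               feasible = fit$feasible,
               rejected = fit$p_full < p_cut | !fit$feasible,
               error = NA_character_)
  })
  do.call(rbind, rows)
}

#' Per-chromosome qpAdm coefficients
#'
#' Fits the same qpAdm model separately on each chromosome (each with its
#' own block partition); the X chromosome uses female calls plus male
#' hemizygous calls through the standard allele-count rules.
#'
#' @inheritParams qpadm_fit
#' @param chroms chromosomes to fit (default: all in the dataset)
#' @param source which source's coefficient to tabulate
#' @return data.frame: chrom, coef, se, p_full.
#' @export
qpadm_by_chromosome <- function(ds, target, sources, right,
                                chroms = unique(ds$snps$chrom),
                                source = 1L, block_morgans = 0.05) {
  rows <- lapply(chroms, function(ch) {
    sub <- subset_chromosomes(ds, ch)
    fit <- qpadm_fit(sub, target, sources, right, block_morgans)
    data.frame(chrom = ch, coef = unname(fit$weights[source]),
               se = unname(fit$se[source]), p_full = fit$p_full)
  })
  do.call(rbind, rows)
}

#' Autosome-versus-X admixture-coefficient Z scores
#'
#' For each autosome A, `Z = (coef_A - coef_X) / sqrt(se_A^2 + se_X^2)`;
#' `Z >= 3` flags a significant autosome/X difference, the signature of
#' sex-biased admixture.
#'
#' @param coefs data.frame with columns `chrom`, `coef`, `se` as returned
#'   by [qpadm_by_chromosome()]; the X chromosome is `chrom == 23`.
#' @param z_cut significance threshold (default 3)
#' @return data.frame of per-autosome Z with attribute `n_significant`.
#' @export
sex_bias_z <- function(coefs, z_cut = 3) {
  xi <- which(coefs$chrom == 23L)
  if (length(xi) != 1L) stop("missing (or duplicated) X-chromosome fit")
  aut <- coefs[-xi, , drop = FALSE]
  z <- (aut$coef - coefs$coef[xi]) / sqrt(aut$se^2 + coefs$se[xi]^2)
  out <- data.frame(chrom = aut$chrom, z = z)
  attr(out, "n_significant") <- sum(z >= z_cut - 1e-9, na.rm = TRUE)
  out
}
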