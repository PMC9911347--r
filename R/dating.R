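#' Ancestry-covariance decay curve
#'
#' Computes, for a set of admixed target samples, the covariance of
#' source-informative genotype residuals over SNP pairs binned by genetic
#' distance within chromosomes. Each SNP carries a weight
#' `w = pA - pB` (the source frequency contrast) and a residual
#' `z = dose - (pB + alpha_hat * (pA - pB))` per sample (`dose` =
#' genotype / 2), where `alpha_hat` is the sample's genome-wide ancestry
#' proportion estimated by regressing the doses on the frequency
#' contrast - centring on each sample's own mean ancestry removes the
#' constant offset an unadmixed or unevenly admixed sample would
#' otherwise contribute. The binned ratio estimator
#' `c(d) = sum(z_s w_s z_t w_t) / sum(w_s^2 w_t^2)`
#' is, in expectation, `alpha(1-alpha) exp(-g d)` times an ancestry-
#' ploidy factor (1/2 for diploid or pseudo-haploid targets), so the decay
#' rate in Morgans^-1 equals the number of generations `g` since
#' admixture. Pairs are accumulated on a genetic-distance grid at
#' `binsize` resolution (positions rounded to grid cells; FFT
#' autocorrelation per sample and chromosome), capped at `maxdist` within
#' the same chromosome.
#'
#' @param ds a [pk_dataset()] holding the target samples
#' @param targets sample ids (or a group label) of the admixed targets
#' @param freq_a,freq_b per-SNP allele frequencies of the two sources
#' @param binsize genetic-distance bin width in Morgans (default 0.001)
#' @param maxdist maximum pair distance in Morgans (default 1)
#' @return A `pk_decay_curve`: data.frame (`bin` midpoint in Morgans,
#'   `cov`, `n_pairs`) with per-chromosome accumulators kept as
#'   attributes for the leave-one-chromosome-out fit.
#' @export
ancestry_covariance <- function(ds, targets, freq_a, freq_b,
                                binsize = 0.001, maxdist = 1) {
  tidx <- resolve_groups(ds, list(t = targets))$t
  stopifnot(length(tidx) >= 1L)
  w <- freq_a - freq_b
  pbar <- (freq_a + freq_b) / 2
  chroms <- unique(ds$snps$chrom)
  n_bins <- as.integer(round(maxdist / binsize))
  # genome-wide ancestry proportion per target sample
  alpha_hat <- vapply(tidx, function(j) {
    g <- ds$geno[, j]
    ok <- g != 9L
    a <- 0.5 + sum((g[ok] / 2 - pbar[ok]) * w[ok]) / sum(w[ok]^2)
    min(max(a, 0), 1)
  }, 0)
  num <- den <- npair <- matrix(0, length(chroms), n_bins,
                                dimnames = list(as.character(chroms), NULL))
  for (ci in seq_along(chroms)) {
    idx <- which(ds$snps$chrom == chroms[ci])
    cell <- as.integer(floor(ds$snps$gpos[idx] / binsize)) + 1L
    n_cell <- max(cell)
    pad <- stats::nextn(n_cell + n_bins + 1L, 2)
    for (jj in seq_along(tidx)) {
      j <- tidx[jj]
      g <- ds$geno[idx, j]
      ok <- g != 9L
      if (!any(ok)) next
      dose <- g[ok] / 2
      ww <- w[idx][ok]
      pexp <- pbar[idx][ok] + (alpha_hat[jj] - 0.5) * ww
      u <- (dose - pexp) * ww
      v <- ww^2
      U <- V <- Np <- numeric(pad)
      cu <- cell[ok]
      U[seq_len(n_cell)] <- unname(rowsum(u, cu, reorder = TRUE))[
        match(seq_len(n_cell), sort(unique(cu)))]
      U[is.na(U)] <- 0
      V[seq_len(n_cell)] <- unname(rowsum(v, cu))[
        match(seq_len(n_cell), sort(unique(cu)))]
      V[is.na(V)] <- 0
      Np[seq_len(n_cell)] <- tabulate(cu, n_cell)
      ac <- function(x) {
        f <- stats::fft(x)
        Re(stats::fft(f * Conj(f), inverse = TRUE)) / length(x)
      }
      lagU <- ac(U); lagV <- ac(V); lagN <- ac(Np)
      lag <- seq_len(n_bins)                       # lag b -> distance b*binsize
      num[ci, ] <- num[ci, ] + lagU[lag + 1L]
      den[ci, ] <- den[ci, ] + lagV[lag + 1L]
      npair[ci, ] <- npair[ci, ] + lagN[lag + 1L]
    }
  }
  cov_bin <- colSums(num) / pmax(colSums(den), .Machine$double.eps)
  cov_bin[colSums(npair) < 1] <- NA_real_
  curve <- data.frame(bin = (seq_len(n_bins)) * binsize,
                      cov = cov_bin, n_pairs = round(colSums(npair)))
  structure(curve, class = c("pk_decay_curve", "data.frame"),
            num = num, den = den, npair = npair, binsize = binsize,
            chroms = chroms, n_targets = length(tidx))
}

#' Fit an exponential decay to an ancestry-covariance curve
#'
#' Weighted least squares of `A * exp(-g * d) + c` over bins with
#' `lovalfit <= d <= maxdist` (weights = SNP-pair counts). `g` is the
#' number of generations since admixture. The standard error of `g` comes
#' from a leave-one-chromosome-out jackknife when the curve carries
#' per-chromosome accumulators.
#'
#' @param curve a `pk_decay_curve` from [ancestry_covariance()], or any
#'   data.frame with columns `bin`, `cov` (and optionally `n_pairs`)
#' @param loval,maxdist fit window in Morgans (defaults 0.0045 and 1)
#' @return A `pk_decay_fit`: `A`, `g`, `c`, `g_se`, `significant`
#'   (`|g/g_se| >= 2`), `n_bins`.
#' @export
fit_decay <- function(curve, loval = 0.0045, maxdist = 1) {
  in_win <- curve$bin >= loval & curve$bin <= maxdist
  if (any(in_win & is.na(curve$cov)))
    warning(sum(in_win & is.na(curve$cov)),
            " empty bin(s) inside the fit window excluded")
  sel <- which(in_win & !is.na(curve$cov))
  if (length(sel) < 20L)
    stop("fewer than 20 usable bins in the fit window")
  wgt <- if ("n_pairs" %in% names(curve)) curve$n_pairs[sel] else rep(1, length(sel))
  fit0 <- decay_ls(curve$bin[sel], curve$cov[sel], wgt)
  g_se <- NA_real_
  num <- attr(curve, "num")
  if (!is.null(num) && nrow(num) >= 3L) {
    den <- attr(curve, "den"); npair <- attr(curve, "npair")
    gs <- vapply(seq_len(nrow(num)), function(ci) {
      cb <- colSums(num[-ci, , drop = FALSE]) /
        pmax(colSums(den[-ci, , drop = FALSE]), .Machine$double.eps)
      np <- colSums(npair[-ci, , drop = FALSE])
      ok <- sel[np[sel] > 0]
      out <- tryCatch(decay_ls(curve$bin[ok], cb[ok], np[ok])$g,
                      error = function(e) NA_real_)
      out
    }, 0)
    gs <- gs[!is.na(gs)]
    nb <- length(gs)
    if (nb >= 3L)
      g_se <- sqrt((nb - 1) / nb * sum((gs - mean(gs))^2))
  }
  structure(list(A = fit0$A, g = fit0$g, c = fit0$c, g_se = g_se,
                 significant = is.finite(g_se) && g_se > 0 &&
                   abs(fit0$g / g_se) >= 2,
                 n_bins = length(sel)),
            class = "pk_decay_fit")
}

decay_ls <- function(d, y, wgt) {
  pos <- y > 0
  g0 <- if (sum(pos) >= 5) {
    sl <- stats::coef(stats::lm(log(y[pos]) ~ d[pos], weights = wgt[pos]))[2]
    max(1, min(500, -sl))
  } else 20
  A0 <- max(y[1], 1e-6)
  fit <- minpack.lm::nlsLM(y ~ A * exp(-g * d) + cc,
                           start = list(A = A0, g = g0, cc = 0),
                           weights = wgt,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  if (!is.finite(cf["g"])) stop("decay fit did not converge")
  list(A = unname(cf["A"]), g = unname(cf["g"]), c = unname(cf["cc"]))
}

#' @export
print.pk_decay_fit <- function(x, ...) {
  cat(sprintf("decay fit: g = %.2f generations (se %.2f), A = %.3g, c = %.3g\n",
              x$g, x$g_se, x$A, x$c))
  invisible(x)
}

#' Convert an admixture age in generations to a calendar interval
#'
#' @param g generations since admixture
#' @param g_se standard error of `g`
#' @param mean_sample_date_BC mean calendar date of the sampled
#'   individuals, in years BC (positive = BC)
#' @param generation_years years per generation (default 28, a
#'   conventional ancient-DNA constant)
#' @return list: `date_BC`, `se_years`, `interval_BC` (1 se).
#' @export
generations_to_date <- function(g, g_se = 0, mean_sample_date_BC,
                                generation_years = 28) {
  stopifnot(generation_years > 0)
  date <- mean_sample_date_BC + g * generation_years
  se <- g_se * generation_years
  list(date_BC = date, se_years = se, interval_BC = c(date - se, date + se))
}
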