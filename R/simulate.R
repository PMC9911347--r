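#' Simulate per-population allele frequencies under drift
#'
#' Ancestral frequencies are drawn from `Uniform(ancestral[1], ancestral[2])`
#' (bounded away from 0/1 to avoid rare-allele pathologies in likelihood
#' kinship). Each population drifts from its parent under a
#' Balding-Nichols model: `p_pop ~ Beta(p(1-F)/F, (1-p)(1-F)/F)`, whose
#' variance is `F p (1-p)`. Populations may be nested (a tree of drift
#' steps) by giving a `parent` column.
#'
#' @param panel SNP table (only its length is used) or an integer SNP count
#' @param pops either a named numeric vector of drift (F_ST-like) parameters,
#'   each population drifting independently from the ancestral pool, or a
#'   data.frame with columns `name`, `parent` (`NA` = ancestral), `fst`
#' @param ancestral range of the ancestral frequency spectrum
#' @param seed integer RNG seed
#' @return list with `ancestral` (numeric vector) and `freqs` (matrix,
#'   SNPs x populations, named columns; includes internal tree nodes).
#' @export
simulate_population_freqs <- function(panel, pops, ancestral = c(0.05, 0.95),
                                      seed = 1L) {
  n <- if (is.data.frame(panel)) nrow(panel) else as.integer(panel)
  if (is.numeric(pops) && !is.null(names(pops)))
    pops <- data.frame(name = names(pops), parent = NA_character_,
                       fst = unname(pops), stringsAsFactors = FALSE)
  stopifnot(all(pops$fst >= 0), all(pops$fst < 1))
  local_seed(seed, {
    anc <- stats::runif(n, ancestral[1], ancestral[2])
    freqs <- matrix(NA_real_, n, nrow(pops),
                    dimnames = list(NULL, pops$name))
    remaining <- seq_len(nrow(pops))
    while (length(remaining)) {
      ready <- remaining[is.na(pops$parent[remaining]) |
                           pops$parent[remaining] %in% colnames(freqs)[!is.na(freqs[1, ])]]
      if (!length(ready)) stop("population tree has unresolved parents")
      for (i in ready) {
        base <- if (is.na(pops$parent[i])) anc else freqs[, pops$parent[i]]
        freqs[, i] <- drift_freqs(base, pops$fst[i])
      }
      remaining <- setdiff(remaining, ready)
    }
    list(ancestral = anc, freqs = freqs)
  })
}

drift_freqs <- function(p, fst) {
  if (fst == 0) return(p)
  a <- p * (1 - fst) / fst
  b <- (1 - p) * (1 - fst) / fst
  stats::rbeta(length(p), a, b)
}

#' Simulate a cohort of unadmixed diploid individuals
#'
#' Genotypes are drawn site-independently from each population's allele
#' frequencies (linkage equilibrium within populations). Male X calls are
#' hemizygous (codes 0/2).
#'
#' @param panel SNP table from [make_snp_panel()]
#' @param freqs matrix of per-population allele frequencies (SNPs x pops)
#' @param groups named integer vector: individuals per population; names
#'   must match columns of `freqs`
#' @param seed integer RNG seed
#' @param sexes optional character vector (one per individual) of
#'   `"M"`/`"F"`; default alternates
#' @return A diploid [pk_dataset()].
#' @export
simulate_cohort <- function(panel, freqs, groups, seed = 1L, sexes = NULL) {
  stopifnot(all(names(groups) %in% colnames(freqs)))
  n_ind <- sum(groups)
  pop_of <- rep(names(groups), groups)
  if (is.null(sexes)) sexes <- rep_len(c("M", "F"), n_ind)
  is_x <- panel$chrom == 23L
  local_seed(seed, {
    g <- matrix(9L, nrow(panel), n_ind)
    for (j in seq_len(n_ind)) {
      p <- freqs[, pop_of[j]]
      gj <- stats::rbinom(nrow(panel), 2L, p)
      if (sexes[j] == "M" && any(is_x))
        gj[is_x] <- 2L * stats::rbinom(sum(is_x), 1L, p[is_x])
      g[, j] <- gj
    }
    ids <- sprintf("%s_%02d", pop_of, stats::ave(seq_len(n_ind), pop_of, FUN = seq_along))
    pk_dataset(panel,
               data.frame(sample_id = ids, sex = sexes, group = pop_of,
                          stringsAsFactors = FALSE),
               g, ploidy = "diploid", validate = FALSE)
  })
}

# --- piecewise-constant haplotypes --------------------------------------
# a haplotype on one chromosome: list(end = cumulative endpoints in Morgans
# (last = chromosome length), lab = integer founder-haplotype label per
# segment)

new_hap <- function(len, lab) list(end = len, lab = lab)

# labels at genetic positions
hap_labels_at <- function(h, gpos) {
  h$lab[findInterval(gpos, h$end, left.open = TRUE) + 1L]
}

# recombine two parental haplotypes into a gamete; Poisson crossovers,
# no interference
meiose <- function(h1, h2, len) {
  k <- stats::rpois(1L, len)
  phase <- stats::rbinom(1L, 1L, 0.5)
  if (k == 0L) return(if (phase == 0L) h1 else h2)
  xo <- sort(stats::runif(k, 0, len))
  cuts <- sort(unique(c(xo, h1$end, h2$end)))
  mids <- (c(0, cuts[-length(cuts)]) + cuts) / 2
  use1 <- (findInterval(mids, xo) + phase) %% 2L == 0L
  lab <- ifelse(use1, h1$lab[findInterval(mids, h1$end, left.open = TRUE) + 1L],
                h2$lab[findInterval(mids, h2$end, left.open = TRUE) + 1L])
  keep <- c(lab[-1] != lab[-length(lab)], TRUE)
  list(end = cuts[keep], lab = lab[keep])
}

# intervals where the two haplotypes carry the same founder label
autozygous_segments <- function(h1, h2) {
  cuts <- sort(unique(c(h1$end, h2$end)))
  mids <- (c(0, cuts[-length(cuts)]) + cuts) / 2
  same <- hap_labels_at(h1, mids) == hap_labels_at(h2, mids)
  runs_to_segments(same, c(0, cuts[-length(cuts)]), cuts)
}

runs_to_segments <- function(flag, starts, ends) {
  if (!length(flag) || !any(flag))
    return(data.frame(start = numeric(), end = numeric()))
  r <- rle(flag)
  hi <- cumsum(r$lengths)
  lo <- hi - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[lo[keep]], end = ends[hi[keep]])
}

#' Simulate two-source admixed individuals with local-ancestry truth
#'
#' Each haploid chromosome is a Markov mosaic: segment breakpoints occur at
#' rate `g` per Morgan (the number of generations since the pulse) and each
#' segment's ancestry is drawn independently with probability `alpha` of
#' coming from source A. Segment (truth-track) lengths are therefore
#' Exponential with mean `1/g` Morgans and the marginal ancestry is
#' `alpha`. Genotypes are drawn per site from the segment's source
#' frequency.
#'
#' @param panel SNP table
#' @param freq_a,freq_b per-SNP allele frequencies of the two sources
#' @param alpha proportion of ancestry from source A, in `[0,1]`
#' @param g generations since admixture (>= 1)
#' @param n_ind number of diploid individuals
#' @param seed integer RNG seed
#' @param alpha_x ancestry proportion used on the X chromosome (sex-biased
#'   admixture); defaults to `alpha`
#' @param group group label for the generated samples
#' @param sexes optional sexes, default alternating
#' @return list with `dataset` (diploid [pk_dataset()]) and `tracts`
#'   (data.frame: sample, hap, chrom, start_M, end_M, source).
#' @export
simulate_admixed_individuals <- function(panel, freq_a, freq_b, alpha, g,
                                         n_ind, seed = 1L, alpha_x = alpha,
                                         group = "admixed", sexes = NULL) {
  stopifnot(g >= 1, alpha >= 0, alpha <= 1)
  chroms <- unique(panel$chrom)
  lens <- tapply(panel$gpos, panel$chrom, max)[as.character(chroms)] + 1e-9
  if (is.null(sexes)) sexes <- rep_len(c("M", "F"), n_ind)
  local_seed(seed, {
    geno <- matrix(9L, nrow(panel), n_ind)
    tracts <- vector("list", 0L)
    for (j in seq_len(n_ind)) {
      for (ci in seq_along(chroms)) {
        ch <- chroms[ci]
        idx <- which(panel$chrom == ch)
        a_here <- if (ch == 23L) alpha_x else alpha
        n_hap <- if (ch == 23L && sexes[j] == "M") 1L else 2L
        dose <- integer(length(idx))
        for (h in seq_len(n_hap)) {
          mos <- ancestry_mosaic(lens[ci], g, a_here)
          src <- mos$lab[findInterval(panel$gpos[idx], mos$end,
                                      left.open = TRUE) + 1L]
          p <- ifelse(src == 1L, freq_a[idx], freq_b[idx])
          dose <- dose + stats::rbinom(length(idx), 1L, p)
          tracts[[length(tracts) + 1L]] <-
            data.frame(sample = j, hap = h, chrom = ch,
                       start_M = c(0, mos$end[-length(mos$end)]),
                       end_M = mos$end,
                       source = ifelse(mos$lab == 1L, "A", "B"))
        }
        geno[idx, j] <- if (n_hap == 1L) 2L * dose else dose
      }
    }
    ids <- sprintf("%s_%02d", group, seq_len(n_ind))
    ds <- pk_dataset(panel,
                     data.frame(sample_id = ids, sex = sexes, group = group,
                                stringsAsFactors = FALSE),
                     geno, ploidy = "diploid", validate = FALSE)
    tr <- do.call(rbind, tracts)
    tr$sample <- ids[tr$sample]
    list(dataset = ds, tracts = tr)
  })
}

# breakpoints at rate g/Morgan; each segment ancestry ~ Bernoulli(alpha);
# segments are NOT merged so truth tract lengths are Exponential(mean 1/g)
ancestry_mosaic <- function(len, g, alpha) {
  k <- stats::rpois(1L, g * len)
  ends <- sort(c(stats::runif(k, 0, len), len))
  list(end = ends, lab = ifelse(stats::runif(length(ends)) < alpha, 1L, 2L))
}

#' Simulate genotypes through a pedigree with recombination
#'
#' Founder haplotypes carry unique labels and draw alleles from the founder
#' population's frequencies. Each meiosis applies Poisson crossovers (no
#' interference) at 1 per Morgan. Truth autozygosity (both haplotype
#' labels identical by descent) is returned per individual; the full
#' haplotype label structure is kept so pairwise IBD truth can be computed
#' with [truth_ibd()]. The X chromosome is transmitted with male
#' hemizygosity (fathers pass their single X to daughters unrecombined).
#'
#' @param ped pedigree data.frame with columns `id`, `sex` (`"M"`/`"F"`),
#'   `father`, `mother` (`NA` for founders); parents must precede children
#' @param panel SNP table (ignored when `genotypes = FALSE`)
#' @param freqs founder-population allele frequency vector (one per SNP)
#' @param seed integer RNG seed
#' @param genotypes emit a genotype dataset? `FALSE` returns only the
#'   label structure and truth segments (fast, used by [expected_roh()])
#' @param map genetic map used when `genotypes = FALSE`; defaults to the
#'   panel's chromosome extents
#' @return list with `dataset` (diploid [pk_dataset()] or `NULL`),
#'   `roh_truth` (data.frame: id, chrom, start_M, end_M, length_cM),
#'   `haps` (internal label structure) and `ped`.
#' @export
simulate_pedigree_genotypes <- function(ped, panel = NULL, freqs = NULL,
                                        seed = 1L, genotypes = TRUE,
                                        map = NULL) {
  ped <- as.data.frame(ped, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "sex", "father", "mother") %in% names(ped)))
  ids <- ped$id
  if (anyDuplicated(ids)) stop("duplicate pedigree ids")
  for (i in seq_len(nrow(ped))) {
    for (par in c(ped$father[i], ped$mother[i]))
      if (!is.na(par) && !(par %in% ids[seq_len(i - 1L)]))
        stop("pedigree not topologically ordered (or cyclic): parent '",
             par, "' of '", ids[i], "' does not precede it")
  }
  if (genotypes) {
    stopifnot(!is.null(panel), !is.null(freqs))
    chroms <- unique(panel$chrom)
    lens <- tapply(panel$gpos, panel$chrom, max)[as.character(chroms)] + 1e-9
  } else {
    if (is.null(map)) map <- default_map()
    chroms <- map$chrom
    lens <- map$morgans
  }
  local_seed(seed, {
    n <- nrow(ped)
    founder <- is.na(ped$father) & is.na(ped$mother)
    if (any(is.na(ped$father) != is.na(ped$mother)))
      stop("individuals must have either both parents or none")
    # assign founder haplotype labels
    next_lab <- 1L
    haps <- vector("list", n)      # haps[[i]][[ci]] = list(h1, h2)
    names(haps) <- ids
    for (i in seq_len(n)) {
      haps[[i]] <- vector("list", length(chroms))
      if (founder[i]) {
        for (ci in seq_along(chroms)) {
          hemi <- chroms[ci] == 23L && ped$sex[i] == "M"
          h1 <- new_hap(lens[ci], next_lab)
          h2 <- if (hemi) h1 else new_hap(lens[ci], next_lab + 1L)
          haps[[i]][[ci]] <- list(h1 = h1, h2 = h2)
        }
        next_lab <- next_lab + 2L
      } else {
        fa <- match(ped$father[i], ids)
        mo <- match(ped$mother[i], ids)
        if (ped$sex[fa] != "M" || ped$sex[mo] != "F")
          stop("father of '", ids[i], "' must be M and mother F")
        for (ci in seq_along(chroms)) {
          x <- chroms[ci] == 23L
          mat <- meiose(haps[[mo]][[ci]]$h1, haps[[mo]][[ci]]$h2, lens[ci])
          if (x && ped$sex[i] == "M") {
            haps[[i]][[ci]] <- list(h1 = mat, h2 = mat)   # hemizygous
          } else if (x) {
            haps[[i]][[ci]] <- list(h1 = haps[[fa]][[ci]]$h1, h2 = mat)
          } else {
            pat <- meiose(haps[[fa]][[ci]]$h1, haps[[fa]][[ci]]$h2, lens[ci])
            haps[[i]][[ci]] <- list(h1 = pat, h2 = mat)
          }
        }
      }
    }
    # truth autozygosity on autosomes
    roh <- list()
    for (i in seq_len(n)) {
      for (ci in which(chroms != 23L)) {
        seg <- autozygous_segments(haps[[i]][[ci]]$h1, haps[[i]][[ci]]$h2)
        if (nrow(seg))
          roh[[length(roh) + 1L]] <-
            data.frame(id = ids[i], chrom = chroms[ci], start_M = seg$start,
                       end_M = seg$end,
                       length_cM = 100 * (seg$end - seg$start))
      }
    }
    roh <- if (length(roh)) do.call(rbind, roh) else
      data.frame(id = character(), chrom = integer(), start_M = numeric(),
                 end_M = numeric(), length_cM = numeric())
    ds <- NULL
    if (genotypes) {
      n_haps <- next_lab - 1L
      alleles <- matrix(0L, nrow(panel), n_haps)
      for (h in seq_len(n_haps))
        alleles[, h] <- stats::rbinom(nrow(panel), 1L, freqs)
      geno <- matrix(9L, nrow(panel), n)
      for (i in seq_len(n)) {
        for (ci in seq_along(chroms)) {
          idx <- which(panel$chrom == chroms[ci])
          l1 <- hap_labels_at(haps[[i]][[ci]]$h1, panel$gpos[idx])
          hemi <- chroms[ci] == 23L && ped$sex[i] == "M"
          if (hemi) {
            geno[idx, i] <- 2L * alleles[cbind(idx, l1)]
          } else {
            l2 <- hap_labels_at(haps[[i]][[ci]]$h2, panel$gpos[idx])
            geno[idx, i] <- alleles[cbind(idx, l1)] + alleles[cbind(idx, l2)]
          }
        }
      }
      ds <- pk_dataset(panel,
                       data.frame(sample_id = ids, sex = ped$sex,
                                  group = "pedigree", stringsAsFactors = FALSE),
                       geno, ploidy = "diploid", validate = FALSE)
    }
    list(dataset = ds, roh_truth = roh, haps = haps, ped = ped,
         chroms = chroms, lens = as.numeric(lens))
  })
}

#' Truth IBD sharing fractions for a simulated pair
#'
#' Computes, from the haplotype label structure returned by
#' [simulate_pedigree_genotypes()], the autosomal genome fractions over
#' which a pair shares 0, 1 or 2 alleles identical by descent.
#'
#' @param sim result of [simulate_pedigree_genotypes()]
#' @param id1,id2 pedigree ids
#' @return named numeric vector `k0`, `k1`, `k2`, `r`.
#' @export
truth_ibd <- function(sim, id1, id2) {
  i <- match(id1, sim$ped$id); j <- match(id2, sim$ped$id)
  tot <- 0; shared <- c(0, 0, 0)
  for (ci in which(sim$chroms != 23L)) {
    a <- sim$haps[[i]][[ci]]; b <- sim$haps[[j]][[ci]]
    cuts <- sort(unique(c(a$h1$end, a$h2$end, b$h1$end, b$h2$end)))
    starts <- c(0, cuts[-length(cuts)])
    mids <- (starts + cuts) / 2
    a1 <- hap_labels_at(a$h1, mids); a2 <- hap_labels_at(a$h2, mids)
    b1 <- hap_labels_at(b$h1, mids); b2 <- hap_labels_at(b$h2, mids)
    # size of the bipartite match between {a1,a2} and {b1,b2}
    m11 <- a1 == b1; m12 <- a1 == b2; m21 <- a2 == b1; m22 <- a2 == b2
    two <- (m11 & m22) | (m12 & m21)
    one <- !two & (m11 | m12 | m21 | m22)
    w <- cuts - starts
    shared <- shared + c(sum(w[!one & !two]), sum(w[one]), sum(w[two]))
    tot <- tot + sum(w)
  }
  k <- shared / tot
  c(k0 = k[1], k1 = k[2], k2 = k[3], r = k[2] / 2 + k[3])
}

#' Downsample a diploid dataset to sparse or pseudo-haploid calls
#'
#' In `pseudo_haploid` mode one of the two alleles is drawn uniformly at
#' every covered site (hemizygous male X calls keep their single allele);
#' missingness is applied i.i.d. per (sample, SNP). In `diploid` mode only
#' missingness is applied.
#'
#' @param ds a diploid [pk_dataset()]
#' @param missing_rate per-site probability of no call, in `[0,1]`
#' @param mode `"pseudo_haploid"` or `"diploid"`
#' @param seed integer RNG seed
#' @return A [pk_dataset()] in the requested mode.
#' @export
downsample <- function(ds, missing_rate = 0, mode = c("pseudo_haploid", "diploid"),
                       seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(ds$ploidy == "diploid", missing_rate >= 0, missing_rate <= 1)
  local_seed(seed, {
    g <- ds$geno
    if (mode == "pseudo_haploid") {
      het <- which(g == 1L)
      g[het] <- 2L * stats::rbinom(length(het), 1L, 0.5)
    }
    if (missing_rate > 0) {
      drop <- stats::runif(length(g)) < missing_rate
      g[drop] <- 9L
    }
    pk_dataset(ds$snps, ds$samples, g, ploidy = mode, validate = FALSE)
  })
}
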