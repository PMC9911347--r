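# cohort with a nuclear family, a half-sib, a second cousin and unrelated
# individuals, plus a duplicate sampling of one individual
kin_fixture <- local({
  env <- new.env()
  env$get <- function() {
    if (is.null(env$ph)) {
      panel <- make_snp_panel(60000L, default_map(), seed = 601)
      fr <- simulate_population_freqs(panel, c(P = 0.05), seed = 602)
      ped <- rbind(
        data.frame(id = c("fa", "mo", "w2", "kid", "sib", "half"),
                   sex = c("M", "F", "F", "F", "M", "M"),
                   father = c(NA, NA, NA, "fa", "fa", "fa"),
                   mother = c(NA, NA, NA, "mo", "mo", "w2")))
      fam <- simulate_pedigree_genotypes(ped, panel, fr$freqs[, "P"], seed = 603)
      un <- simulate_cohort(panel, fr$freqs, c(P = 8L), seed = 604)
      dup <- un[, 1]
      dup$samples$sample_id <- "P_01b"
      ds <- pk_dataset(panel, rbind(un$samples, dup$samples, fam$dataset$samples),
                       cbind(un$geno, dup$geno, fam$dataset$geno), "diploid",
                       validate = FALSE)
      env$panel <- panel; env$fr <- fr; env$fam <- fam
      env$dip <- downsample(ds, 0.2, "diploid", seed = 605)
      env$ph <- downsample(ds, 0.3, "pseudo_haploid", seed = 606)
      env$mm <- pairwise_mismatch(env$ph)
      env$kc <- classify_read(env$mm)
    }
    env
  }
  env
})
pair_row <- function(tab, a, b)
  tab[(tab$id1 == a & tab$id2 == b) | (tab$id1 == b & tab$id2 == a), ]

test_that("P0 is symmetric, order-invariant and zero for identical vectors", {
  e <- kin_fixture$get()
  m1 <- pairwise_mismatch(e$ph, pairs = data.frame(id1 = "fa", id2 = "kid"))
  m2 <- pairwise_mismatch(e$ph, pairs = data.frame(id1 = "kid", id2 = "fa"))
  expect_equal(m1$P0, m2$P0)
  perm <- order(e$ph$snps$chrom, -e$ph$snps$ppos)
  shuffled <- pk_dataset(e$ph$snps[order(e$ph$snps$chrom, e$ph$snps$ppos), ],
                         e$ph$samples, e$ph$geno, "pseudo_haploid",
                         validate = FALSE)
  # same data, same windows: identical P0
  expect_equal(pairwise_mismatch(shuffled,
                                 pairs = data.frame("fa", "kid"))$P0, m1$P0)
  # a sample against its own calls mismatches nowhere
  self <- e$ph[, c(1, 1)]
  self$samples$sample_id <- c("x", "y")
  expect_equal(pairwise_mismatch(self)$P0, 0)
})

test_that("two pseudo-haploid samplings of one individual normalize to 1/2", {
  e <- kin_fixture$get()
  r <- pair_row(e$kc, "P_01", "P_01b")
  expect_equal(r$normalized, 0.5, tolerance = 0.04)
  expect_identical(r$degree_class, "identical")
})

test_that("parent-offspring pairs classify first degree near 0.75", {
  e <- kin_fixture$get()
  r <- pair_row(e$kc, "fa", "kid")
  expect_identical(r$degree_class, "first")
  expect_equal(r$normalized, 0.75, tolerance = 0.05)
  h <- pair_row(e$kc, "kid", "half")
  expect_identical(h$degree_class, "second")
  u <- pair_row(e$kc, "P_01", "P_02")
  expect_identical(u$degree_class, "unrelated")
  expect_equal(u$normalized, 1, tolerance = 0.05)
})

test_that("classification cutoffs, boundaries and alpha handling behave", {
  mm <- data.frame(id1 = letters[1:6], id2 = LETTERS[1:6],
                   n_overlap = 10000L,
                   P0 = c(0.30, 0.2975, 0.25, 0.199, 0.1875, 0.14),
                   se = 0.01)
  kc <- classify_read(mm, alpha = 0.3)
  # normalized: 1.0, 0.99167, 0.8333, 0.6633, 0.625 (boundary), 0.4667
  expect_identical(kc$degree_class,
                   c("unrelated", "unrelated", "second", "first",
                     "identical", "identical"))
  expect_error(classify_read(mm, alpha = 0), "positive")
  expect_error(classify_read(mm[1:2, ]), "supply alpha")
  expect_warning(classify_read(within(mm, P0 <- P0 * c(1, .6, .6, .6, .6, .6))),
                 "unreliable")
})

test_that("ML IBD coefficients match pedigree expectations on diploid calls", {
  e <- kin_fixture$get()
  fr <- e$fr$freqs[, "P"]
  po <- estimate_ibd(e$dip, "fa", "kid", fr)
  expect_lte(po$k0, 0.02)
  expect_equal(po$r, 0.5, tolerance = 0.1)
  fs <- estimate_ibd(e$dip, "kid", "sib", fr)
  expect_equal(c(fs$k0, fs$k1, fs$k2), c(0.25, 0.5, 0.25), tolerance = 0.35)
  un <- estimate_ibd(e$dip, "P_01", "P_02", fr)
  expect_gt(un$k0, 0.9)
  expect_lt(un$r, 0.05)
  expect_error(estimate_ibd(e$dip, "fa", "nope", fr), "unknown")
  expect_error(estimate_ibd(e$dip, "fa", "kid", rep(0.5, length(fr)),
                            min_overlap = 1e7), "overlapping")
  expect_error(estimate_ibd(e$dip, "fa", "kid", rep(0.5, length(fr))),
               "degenerate")
})

test_that("pseudo-haploid calls still identify the relatedness coefficient r", {
  e <- kin_fixture$get()
  fr <- e$fr$freqs[, "P"]
  po <- estimate_ibd(e$ph, "fa", "kid", fr)
  expect_equal(po$r, 0.5, tolerance = 0.15)
  un <- estimate_ibd(e$ph, "P_01", "P_02", fr)
  expect_lt(un$r, 0.08)
})

test_that("opposing homozygotes order parent-offspring, siblings, unrelated", {
  e <- kin_fixture$get()
  po <- opposing_homozygotes(e$dip, "fa", "kid")
  fs <- opposing_homozygotes(e$dip, "kid", "sib")
  un <- opposing_homozygotes(e$dip, "P_01", "P_02")
  expect_identical(po$count, 0L)
  expect_gt(fs$rate, 0)
  expect_lt(fs$rate, un$rate)
  expect_error(opposing_homozygotes(e$ph, "fa", "kid"), "unsupported")
  # HWE arithmetic at p = 0.5: rate 2 * 0.25 * 0.25 = 0.125
  panel <- fix$panel_small
  fr5 <- simulate_population_freqs(panel, c(P = 0), ancestral = c(0.5, 0.5),
                                   seed = 607)
  ds5 <- simulate_cohort(panel, fr5$freqs, c(P = 2L), seed = 608)
  expect_equal(opposing_homozygotes(ds5, "P_01", "P_02")$rate, 0.125,
               tolerance = 0.1)
})

test_that("READ degree accuracy holds at 50k overlapping SNPs", {
  panel <- make_snp_panel(55000L, default_map(), seed = 610)
  fr <- simulate_population_freqs(panel, c(P = 0.05), seed = 611)
  n_fam <- 18L
  peds <- lapply(seq_len(n_fam), function(i)
    data.frame(id = paste0(c("fa", "mo", "w2", "kid", "sib", "half"), "_", i),
               sex = c("M", "F", "F", "F", "M", "M"),
               father = c(NA, NA, NA, paste0("fa_", i), paste0("fa_", i),
                          paste0("fa_", i)),
               mother = c(NA, NA, NA, paste0("mo_", i), paste0("mo_", i),
                          paste0("w2_", i))))
  sims <- lapply(seq_len(n_fam), function(i)
    simulate_pedigree_genotypes(peds[[i]], panel, fr$freqs[, "P"],
                                seed = 700 + i)$dataset)
  ds <- pk_dataset(panel, do.call(rbind, lapply(sims, `[[`, "samples")),
                   do.call(cbind, lapply(sims, `[[`, "geno")), "diploid",
                   validate = FALSE)
  ph <- downsample(ds, 0.05, "pseudo_haploid", seed = 612)
  first <- do.call(rbind, lapply(seq_len(n_fam), function(i)
    data.frame(id1 = c(paste0("fa_", i), paste0("kid_", i)),
               id2 = c(paste0("kid_", i), paste0("sib_", i)))))
  second <- do.call(rbind, lapply(seq_len(n_fam), function(i)
    data.frame(id1 = paste0("kid_", i), id2 = paste0("half_", i))))
  unrel <- data.frame(id1 = paste0("fa_", 1:n_fam),
                      id2 = paste0("mo_", c(2:n_fam, 1)))
  mm <- pairwise_mismatch(ph, rbind(first, second, unrel))
  kc <- classify_read(mm, alpha = stats::median(mm$P0[unrel_idx <- seq(nrow(first) +
    nrow(second) + 1, nrow(mm))]))
  acc1 <- mean(kc$degree_class[seq_len(nrow(first))] == "first")
  acc2 <- mean(kc$degree_class[nrow(first) + seq_len(nrow(second))] == "second")
  expect_gte(acc1, 0.9)
  expect_gte(acc2, 0.75)
})

test_that("relatives beyond the third degree degrade to unrelated", {
  panel <- fix$panel_mid
  fr <- simulate_population_freqs(panel, c(P = 0.05), seed = 620)
  ped <- relationship_pedigree("second_cousins")   # parents are second cousins
  sim <- simulate_pedigree_genotypes(ped, panel, fr$freqs[, "P"], seed = 621)
  ph <- downsample(sim$dataset, 0.2, "pseudo_haploid", seed = 622)
  ib <- estimate_ibd(ph, "fa", "mo", fr$freqs[, "P"])   # r = 1/32
  expect_identical(degree_from_r(ib$r), 0L)
})
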