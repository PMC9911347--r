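# dense single-chromosome panel at 1240K-like density (~312 SNPs per cM)
# with sparsity emulating the 250k-400k covered-SNP operating point
roh_fixture <- local({
  env <- new.env()
  env$get <- function() {
    if (is.null(env$panel)) {
      env$panel <- make_snp_panel(46800L, data.frame(chrom = 1L, morgans = 1.5),
                                  seed = 801)
      env$freqs <- simulate_population_freqs(env$panel, c(P = 0),
                                             seed = 802)$freqs[, "P"]
    }
    env
  }
  env
})

plant_genome <- function(len_cM, seed, coverage = 0.27) {
  e <- roh_fixture$get()
  local_seed(seed, {
    g <- stats::rbinom(nrow(e$panel), 2L, e$freqs)
    start <- stats::runif(1, 0.1, 1.5 - len_cM / 100 - 0.1)
    inroh <- e$panel$gpos >= start & e$panel$gpos < start + len_cM / 100
    g[inroh] <- 2L * stats::rbinom(sum(inroh), 1L, e$freqs[inroh])
    g[stats::runif(length(g)) > coverage] <- 9L
    list(ds = pk_dataset(e$panel,
                         data.frame(sample_id = "s", sex = "F", group = "g"),
                         matrix(g, ncol = 1), "diploid", validate = FALSE),
         start_cM = start * 100, end_cM = (start + len_cM / 100) * 100)
  })
}

detected <- function(segs, start_cM, end_cM, min_frac = 0.5) {
  if (!nrow(segs)) return(FALSE)
  ov <- pmin(segs$end_cM, end_cM) - pmax(segs$start_cM, start_cM)
  any(ov >= min_frac * (end_cM - start_cM))
}

test_that("outbred genomes produce almost no ROH calls of 4 cM or longer", {
  e <- roh_fixture$get()
  n_fp <- vapply(1:20, function(i) {
    pg <- plant_genome(0.01, 900 + i)     # negligible plant
    nrow(suppressWarnings(call_roh(pg$ds, e$freqs, min_covered = 0)))
  }, 0L)
  expect_lt(mean(n_fp), 0.05 * 1.5)       # per 1.5 Morgans of genome
})

test_that("a planted 20 cM autozygous tract is recovered with sub-cM boundaries", {
  e <- roh_fixture$get()
  errs <- vapply(1:10, function(i) {
    pg <- plant_genome(20, 920 + i, coverage = 0.7)   # 30% missingness
    segs <- suppressWarnings(call_roh(pg$ds, e$freqs, min_covered = 0))
    expect_true(detected(segs, pg$start_cM, pg$end_cM))
    best <- which.max(pmin(segs$end_cM, pg$end_cM) -
                        pmax(segs$start_cM, pg$start_cM))
    max(abs(segs$start_cM[best] - pg$start_cM),
        abs(segs$end_cM[best] - pg$end_cM))
  }, 0)
  expect_lt(max(errs), 1)
})

test_that("detection power is at least 80% for segments longer than 4 cM", {
  e <- roh_fixture$get()
  hits <- vapply(1:30, function(i) {
    pg <- plant_genome(6, 950 + i)
    detected(suppressWarnings(call_roh(pg$ds, e$freqs, min_covered = 0)),
             pg$start_cM, pg$end_cM)
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})

test_that("calls are robust to threefold changes in the entry-rate prior", {
  e <- roh_fixture$get()
  pg <- plant_genome(8, 990)
  for (th in c(0.001 / 3, 0.001, 0.003)) {
    segs <- suppressWarnings(call_roh(pg$ds, e$freqs, theta = th,
                                      min_covered = 0))
    expect_true(detected(segs, pg$start_cM, pg$end_cM))
  }
  expect_error(call_roh(pk_dataset(within(e$panel, gpos <- 0),
                                   pg$ds$samples, pg$ds$geno, "diploid",
                                   validate = FALSE), e$freqs),
               "genetic map")
})

test_that("segment totals decompose over chromosomes", {
  map <- default_map(n_autosomes = 3L, total_morgans = 4)
  panel <- make_snp_panel(40000L, map, seed = 810)
  fr <- simulate_population_freqs(panel, c(P = 0), seed = 811)$freqs[, "P"]
  ped <- relationship_pedigree("first_cousins")
  sim <- simulate_pedigree_genotypes(ped, panel, fr, seed = 812)
  ds <- sim$dataset[, "proband"]
  full <- suppressWarnings(call_roh(ds, fr, min_covered = 0))
  per_chrom <- sum(vapply(1:3, function(ch) {
    keep <- panel$chrom == ch
    sub <- subset_chromosomes(ds, ch)
    sum(suppressWarnings(call_roh(sub, fr[keep], min_covered = 0))$length_cM)
  }, 0))
  expect_equal(sum(full$length_cM), per_chrom)
})

test_that("profiles bin segment lengths into the conventional classes", {
  segs <- data.frame(sample = "s", chrom = 1L, start_cM = 0, end_cM = 0,
                     length_cM = c(5, 9, 25), n_snps = 100L)
  prof <- summarize_roh(segs)
  expect_equal(unname(prof["s", ]), c(5, 9, 0, 25, 39))
  empty <- summarize_roh(segs[0, ], samples = "s")
  expect_equal(unname(empty["s", ]), rep(0, 5))
})

test_that("simulated expectations follow pedigree inbreeding identities", {
  map <- default_map()
  e_fc <- expected_roh("first_cousins", map, n_sims = 150, seed = 820)
  e_hs <- expected_roh("half_siblings", map, n_sims = 150, seed = 821)
  e_sc <- expected_roh("second_cousins", map, n_sims = 150, seed = 822)
  e_av <- expected_roh("avuncular", map, n_sims = 150, seed = 823)
  e_un <- expected_roh("unrelated", map, n_sims = 30, seed = 824)
  # F = 1/16 of the 3520 cM genome for first-cousin unions
  expect_equal(unname(e_fc$mean["total"]), 3520 / 16, tolerance = 0.1)
  # half-sibling unions (F = 1/8) produce twice the first-cousin total
  expect_equal(unname(e_hs$mean["total"] / e_fc$mean["total"]), 2,
               tolerance = 0.15)
  # first versus second cousins: ratio about 4 (1/16 vs 1/64)
  expect_equal(unname(e_fc$mean["total"] / e_sc$mean["total"]), 4,
               tolerance = 0.25)
  expect_equal(unname(e_un$mean["total"]), 0)
  # mean totals track pedigree F linearly
  Fs <- c(0, 1 / 64, 1 / 16, 1 / 8, 1 / 8)
  tots <- c(e_un$mean["total"], e_sc$mean["total"], e_fc$mean["total"],
            e_av$mean["total"], e_hs$mean["total"])
  expect_gt(stats::cor(Fs, tots), 0.98)
  roh_fixture$exps <- list(e_fc, e_sc, e_hs, e_av, e_un)
})

test_that("profiles drawn from a relationship classify back to it", {
  exps <- roh_fixture$exps
  e_fc <- exps[[1]]
  as_prof <- function(m, ids) structure(m, dimnames = list(ids, colnames(m)),
                                        class = c("pk_roh_profile", "matrix",
                                                  "array"))
  single <- classify_parental_relatedness(
    as_prof(e_fc$profiles[1:40, , drop = FALSE], paste0("s", 1:40)), exps)
  expect_gte(mean(single$best == "first_cousins"), 0.7)
  expect_gte(mean(single$consanguineous), 0.7)
  combined_correct <- vapply(0:9, function(b) {
    rows <- 41 + b * 10 + 0:9
    cmb <- classify_parental_relatedness(
      as_prof(e_fc$profiles[rows, , drop = FALSE], paste0("c", 1:10)),
      exps, combine = TRUE)
    cmb$best == "first_cousins"
  }, TRUE)
  expect_gte(mean(combined_correct), 0.95)
  zero <- classify_parental_relatedness(
    as_prof(matrix(0, 1, 5), "z"), exps)
  expect_identical(zero$best, "unrelated")
  expect_false(zero$consanguineous)
})

test_that("heterozygosity matches HWE, autozygosity and the P0 identity", {
  panel <- fix$panel_small
  fr5 <- simulate_population_freqs(panel, c(P = 0), ancestral = c(0.5, 0.5),
                                   seed = 830)
  ds5 <- simulate_cohort(panel, fr5$freqs, c(P = 4L), seed = 831)
  h <- heterozygosity(ds5)
  expect_equal(unname(h), rep(0.5, 4), tolerance = 0.05)
  # a fully autozygous genome has no heterozygotes
  g <- ds5$geno
  g[g == 1L] <- 0L
  expect_equal(unname(heterozygosity(pk_dataset(panel, ds5$samples, g,
                                                "diploid", validate = FALSE))[1]),
               0)
  # random-mating identity: h of individuals matches P0 of unrelated
  # pseudo-haploid pairs from the same population
  panel2 <- fix$panel_mid
  fr <- simulate_population_freqs(panel2, c(P = 0.05), seed = 832)
  ds <- simulate_cohort(panel2, fr$freqs, c(P = 8L), seed = 833)
  hbar <- mean(heterozygosity(ds))
  ph <- downsample(ds, 0.2, "pseudo_haploid", seed = 834)
  p0 <- stats::median(pairwise_mismatch(ph)$P0)
  expect_equal(hbar, p0, tolerance = 0.1)
})
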