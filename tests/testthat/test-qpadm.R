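# shared qpAdm world: target = 0.7 S1 + 0.3 S2 admixture 30 generations ago,
# sister references R1/R2 plus deeper outgroups, all pseudo-haploid
qp_fixture <- local({
  env <- new.env()
  env$get <- function() {
    if (is.null(env$ph)) {
      panel <- make_snp_panel(100000L, default_map(), seed = 401)
      fr <- simulate_population_freqs(panel, qpadm_tree(), seed = 402)
      ds <- simulate_cohort(panel, fr$freqs,
                            c(S1 = 12L, S2 = 12L, R0 = 12L, R1 = 12L,
                              R2 = 12L, R3 = 12L, R4 = 12L), seed = 403)
      adm <- simulate_admixed_individuals(panel, fr$freqs[, "S1"],
                                          fr$freqs[, "S2"], alpha = 0.7,
                                          g = 30, n_ind = 10L, seed = 404,
                                          group = "T")
      full <- pk_dataset(panel, rbind(ds$samples, adm$dataset$samples),
                         cbind(ds$geno, adm$dataset$geno), "diploid",
                         validate = FALSE)
      env$panel <- panel
      env$fr <- fr
      env$ph <- downsample(full, 0.1, "pseudo_haploid", seed = 405)
    }
    list(ph = env$ph, fr = env$fr, panel = env$panel)
  }
  env
})
qp_rights <- c("R0", "R1", "R2", "R3", "R4")

test_that("a duplicated left population gives a rank-0 statistic of zero", {
  ph <- qp_fixture$get()$ph
  id <- ph$samples$sample_id[ph$samples$group == "S1"][1]
  # the degenerate covariance triggers the documented ridge conditioning
  expect_warning(qw <- qpwave_test(ph, list(id, id), as.list(qp_rights)),
                 "ridge")
  expect_lt(qw$statistic, 1e-9)
  expect_equal(qw$p_value, 1)
  expect_equal(qw$dof, 4L)
})

test_that("lefts with different mixture proportions reject rank 0", {
  fxt <- qp_fixture$get()
  adm2 <- simulate_admixed_individuals(fxt$panel, fxt$fr$freqs[, "S1"],
                                       fxt$fr$freqs[, "S2"], alpha = 0.2,
                                       g = 30, n_ind = 10L, seed = 406,
                                       group = "T2")
  ds <- pk_dataset(fxt$panel, rbind(fxt$ph$samples, adm2$dataset$samples),
                   cbind(fxt$ph$geno,
                         downsample(adm2$dataset, 0.1, "pseudo_haploid",
                                    seed = 407)$geno),
                   "pseudo_haploid", validate = FALSE)
  qw <- qpwave_test(ds, c("T", "T2"), qp_rights)
  expect_lt(qw$p_value, 0.01)
  # but the same two-source structure is consistent with rank 1
  qw1 <- qpwave_test(ds, c("T", "T2", "S1"), qp_rights, rank = 1L)
  expect_gt(qw1$p_value, 0.001)
})

test_that("qpAdm recovers a 70/30 mixture within 2 SE with a feasible model", {
  ph <- qp_fixture$get()$ph
  fit <- qpadm_fit(ph, "T", c("S1", "S2"), qp_rights)
  expect_true(fit$feasible)
  expect_lt(abs(fit$weights["S1"] - 0.7), 2 * fit$se["S1"])
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  expect_gt(fit$p_full, 0.01)
  expect_equal(fit$dof, 3L)
  # both nested single-source models are strongly rejected
  expect_true(all(fit$nested$p_value < 0.01))
})

test_that("replacing a true source by an outgroup breaks the model", {
  ph <- qp_fixture$get()$ph
  fit <- qpadm_fit(ph, "T", c("S1", "R4"), c("R0", "R1", "R2", "R3"))
  expect_true(fit$p_full < 0.01 || !fit$feasible)
})

test_that("a single source equal to the target's own population fits with weight 1", {
  ph <- qp_fixture$get()$ph
  s1 <- ph$samples$sample_id[ph$samples$group == "S1"]
  fit <- qpadm_fit(ph, s1[1:6], list(s1[7:12]), qp_rights)
  expect_equal(unname(fit$weights), 1)
  expect_gt(fit$p_full, 0.01)
  # and reproduces the qpWave rank-0 p for the same left set
  qw <- qpwave_test(ph, list(s1[1:6], s1[7:12]), as.list(qp_rights))
  expect_equal(fit$p_full, qw$p_value, tolerance = 1e-6)
})

test_that("weights are invariant to permuting the right populations", {
  ph <- qp_fixture$get()$ph
  f1 <- qpadm_fit(ph, "T", c("S1", "S2"), qp_rights)
  f2 <- qpadm_fit(ph, "T", c("S1", "S2"), rev(qp_rights))
  expect_lt(abs(f1$weights["S1"] - f2$weights["S1"]), f1$se["S1"])
})

test_that("more sources than rights minus one is an identifiability error", {
  ph <- qp_fixture$get()$ph
  expect_error(qpadm_fit(ph, "T", c("S1", "S2", "R3"), c("R0", "R1", "R2")),
               "identifiability")
})

test_that("the competing-source rotation rejects models missing a real source", {
  ph <- qp_fixture$get()$ph
  tab <- rotate_competing_sources(ph, "T", c("S1", "S2", "R3"),
                                  c("R0", "R1", "R2", "R4"), n_sources = 2L)
  expect_equal(nrow(tab), 3L)
  with_both <- tab$sources == "S1+S2"
  expect_false(tab$rejected[with_both])
  expect_true(all(tab$rejected[!with_both]))
  # a single candidate degenerates to a plain fit
  one <- rotate_competing_sources(ph, "T", "S1", qp_rights)
  direct <- qpadm_fit(ph, "T", "S1", qp_rights)
  expect_equal(one$p_full, direct$p_full)
})

test_that("two sister proxies of one source both pass the rotation", {
  # the target descends from the internal node N1; S1 and R1 are two
  # equally drifted daughters, hence interchangeable proxies: with either
  # proxy on the right, the other still fits
  fxt <- qp_fixture$get()
  tp <- simulate_cohort(fxt$panel, fxt$fr$freqs, c(N1 = 10L), seed = 408)
  ds <- pk_dataset(fxt$panel, rbind(fxt$ph$samples, tp$samples),
                   cbind(fxt$ph$geno,
                         downsample(tp, 0.1, "pseudo_haploid", seed = 409)$geno),
                   "pseudo_haploid", validate = FALSE)
  tab <- rotate_competing_sources(ds, "N1", c("S1", "R1"),
                                  c("R0", "R2", "R3", "R4"), n_sources = 1L)
  expect_true(all(!tab$rejected))
})

test_that("qpAdm p-values are calibrated under a correctly specified model", {
  # small correct models on fresh cladal draws; the full-model p should be
  # roughly uniform (here: not enriched near zero)
  fxt <- qp_fixture$get()
  panel <- fix$panel_mid
  fr <- simulate_population_freqs(panel, qpadm_tree(), seed = 410)
  ps <- vapply(1:30, function(i) {
    ds <- simulate_cohort(panel, fr$freqs,
                          c(S1 = 6L, R0 = 6L, R1 = 6L, R2 = 6L, R3 = 6L),
                          seed = 5000 + i)
    s1 <- ds$samples$sample_id[ds$samples$group == "S1"]
    qpadm_fit(ds, s1[1:3], list(s1[4:6]), c("R0", "R1", "R2", "R3"))$p_full
  }, 0)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("sex-biased admixture yields large autosome-versus-X Z scores", {
  # Z arithmetic first
  z <- sex_bias_z(data.frame(chrom = c(1L, 2L, 23L),
                             coef = c(0.25, 0.10, 0.10),
                             se = c(0.03, 0.04, 0.04)))
  expect_equal(z$z, c(0.15 / sqrt(0.03^2 + 0.04^2), 0))
  expect_equal(attr(z, "n_significant"), 1L)
  expect_error(sex_bias_z(data.frame(chrom = 1:2, coef = c(1, 1), se = c(1, 1))),
               "X-chromosome")
  # simulated male-biased admixture: autosomal alpha 0.3, X alpha 0.05
  map <- default_map(n_autosomes = 3L, total_morgans = 6, include_x = TRUE)
  panel <- make_snp_panel(90000L, map, seed = 411)
  fr <- simulate_population_freqs(panel, qpadm_tree(), seed = 412)
  ds <- simulate_cohort(panel, fr$freqs,
                        c(S1 = 12L, S2 = 12L, R0 = 12L, R1 = 12L, R2 = 12L,
                          R3 = 12L, R4 = 12L), seed = 413)
  adm <- simulate_admixed_individuals(panel, fr$freqs[, "S1"], fr$freqs[, "S2"],
                                      alpha = 0.3, g = 20, n_ind = 12L,
                                      seed = 414, alpha_x = 0.05, group = "T",
                                      sexes = rep("F", 12L))
  full <- pk_dataset(panel, rbind(ds$samples, adm$dataset$samples),
                     cbind(ds$geno, adm$dataset$geno), "diploid",
                     validate = FALSE)
  coefs <- qpadm_by_chromosome(full, "T", c("S1", "S2"), qp_rights,
                               source = "S1")
  zz <- sex_bias_z(coefs)
  expect_gte(attr(zz, "n_significant"), 2L)
})
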