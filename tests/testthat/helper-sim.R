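# Shared small fixtures, built once per test run. Sizes are desk-scale:
# enough SNPs for the statistics to separate signal from noise, small
# enough to keep the whole suite fast.

fix <- local({
  env <- new.env()
  env$panel_small <- make_snp_panel(2000L, default_map(n_autosomes = 4L), seed = 101)
  env$panel_mid <- make_snp_panel(50000L, default_map(), seed = 102)
  env$freqs_small <- simulate_population_freqs(env$panel_small,
                                               c(A = 0.05, B = 0.05), seed = 103)
  env
})

# a tiny hand-built pseudo-haploid dataset for IO tests
tiny_dataset <- function() {
  snps <- data.frame(snp_id = c("s1", "s2", "s3"), chrom = c(1L, 1L, 2L),
                     gpos = c(0.01, 0.52, 0.1), ppos = c(100L, 5200L, 900L),
                     ref = c("A", "C", "G"), alt = c("G", "T", "A"),
                     stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = c("ind1", "ind2"), sex = c("M", "F"),
                        group = c("g1", "g1"), stringsAsFactors = FALSE)
  geno <- matrix(c(0L, 2L,
                   9L, 0L,
                   2L, 9L), nrow = 3, byrow = TRUE)
  pk_dataset(snps, samples, geno, ploidy = "pseudo_haploid")
}

# extended-family truth used by the burial-reconstruction tests: a
# founding couple (gf x gm) with two genotyped infant children (c1, c2)
# and two ungenotyped adult sons (a1, a2); a1's daughter g1, a2's
# children g2-g4; k7 is g1's maternal first cousin (through sisters s1m
# and s1b), unrelated to the couple. The seven genotyped samples are all
# perinatal infants, i.e. leaves.
burial_pedigree <- function() {
  data.frame(
    id = c("p1", "p2", "s1m", "s1b", "gf", "gm", "s2", "s3", "a1", "a2",
           "c1", "c2", "g1", "g2", "g3", "g4", "k7"),
    sex = c("M", "F", "F", "F", "M", "F", "F", "M", "M", "M",
            "F", "M", "F", "M", "F", "M", "F"),
    father = c(NA, NA, "p1", "p1", NA, NA, NA, NA, "gf", "gf",
               "gf", "gf", "a1", "a2", "a2", "a2", "s3"),
    mother = c(NA, NA, "p2", "p2", NA, NA, NA, NA, "gm", "gm",
               "gm", "gm", "s1m", "s2", "s2", "s2", "s1b"),
    stringsAsFactors = FALSE)
}
burial_infants <- c("c1", "c2", "g1", "g2", "g3", "g4", "k7")
burial_matriline <- c(c1 = "gm", c2 = "gm", g1 = "p2", g2 = "s2", g3 = "s2",
                      g4 = "s2", k7 = "p2")
burial_yline <- c(c2 = "gf", g2 = "gf", g4 = "gf")

# population tree used by the qpAdm tests: two sources with sister
# reference populations plus deeper outgroups
qpadm_tree <- function() {
  data.frame(name = c("N1", "N2", "S1", "R1", "S2", "R2", "R0", "R3", "R4"),
             parent = c(NA, NA, "N1", "N1", "N2", "N2", NA, NA, NA),
             fst = c(.05, .05, .05, .05, .05, .05, .08, .12, .15),
             stringsAsFactors = FALSE)
}
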