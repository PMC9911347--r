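#' Run a staged analysis pipeline on a dataset or simulation scenario
#'
#' Orchestrates the analysis stages in dependency order and writes
#' per-stage TSVs plus a combined JSON summary to `out_dir`. A single
#' master seed fans out to stable per-stage child seeds (hash of the
#' stage name), so adding a stage never perturbs another stage's
#' randomness; every output records the seed.
#'
#' @param config a list with elements:
#'   \describe{
#'     \item{dataset}{a [pk_dataset()], or `NULL` when `scenario` is given}
#'     \item{scenario}{optional built-in simulation scenario name
#'       (currently `"aegean_demo"`: three drifted populations, one
#'       admixture event, one three-generation family, one first-cousin
#'       union)}
#'     \item{stages}{character vector from `"fstats"`, `"qpadm"`,
#'       `"dating"`, `"kinship"`, `"roh"`; must be non-empty}
#'     \item{seed}{master integer seed}
#'     \item{params}{optional per-stage parameter lists}
#'   }
#' @param out_dir output directory (created if needed); `NULL` skips
#'   file output
#' @return list of per-stage results (also serialized to
#'   `summary.json`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(is.list(config))
  stages <- config$stages
  if (is.null(stages) || !length(stages))
    stop("config validation error: empty stage list")
  bad <- setdiff(stages, c("fstats", "qpadm", "dating", "kinship", "roh"))
  if (length(bad)) stop("config validation error: unknown stage(s) ",
                        paste(bad, collapse = ", "))
  seed <- config$seed %||% 1L
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scen <- NULL
  if (!is.null(config$scenario)) {
    scen <- build_scenario(config$scenario, child_seed(seed, "scenario"))
    ds <- scen$dataset
  } else ds <- config$dataset
  if (is.null(ds)) stop("config validation error: no dataset or scenario")
  results <- list(seed = seed,
                  n_snps = nrow(ds$snps), n_samples = nrow(ds$samples))
  log_line <- function(...) message("[popkin] ", ...)
  emit <- function(name, df) {
    if (!is.null(out_dir) && is.data.frame(df)) {
      path <- file.path(out_dir, paste0(name, ".tsv"))
      con <- file(path, "w")
      writeLines(paste0("# seed=", seed, " stage=", name), con)
      utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
      close(con)
    }
  }
  groups <- unique(ds$samples$group)
  for (stage in stages) {
    log_line("stage ", stage)
    res <- switch(stage,
      fstats = {
        if (length(groups) < 3L) stop("fstats stage needs >= 3 groups")
        combos <- utils::combn(groups, 3L, simplify = FALSE)
        tab <- do.call(rbind, lapply(combos, function(g3) {
          est <- f3(ds, g3[1], g3[2], g3[3])
          data.frame(A = g3[1], B = g3[2], C = g3[3], value = est$value,
                     se = est$se, z = est$z, n_snps = est$n_snps)
        }))
        emit("fstats", tab); tab
      },
      qpadm = {
        p <- config$params$qpadm
        if (is.null(p)) stop("qpadm stage needs params$qpadm (target, sources, right)")
        fit <- qpadm_fit(ds, p$target, p$sources, p$right)
        tab <- data.frame(target = fit$target, source = fit$sources,
                          weight = fit$weights, se = fit$se,
                          p_full = fit$p_full, feasible = fit$feasible)
        emit("qpadm", tab); fit
      },
      dating = {
        p <- config$params$dating
        if (is.null(p)) stop("dating stage needs params$dating (targets, freq_a, freq_b)")
        curve <- ancestry_covariance(ds, p$targets, p$freq_a, p$freq_b)
        fit <- fit_decay(curve)
        emit("dating_curve", as.data.frame(curve))
        fit
      },
      kinship = {
        mm <- pairwise_mismatch(ds_pseudo(ds, seed),
                                min_overlap = config$params$kinship$min_overlap %||% 1000L)
        kc <- classify_read(mm)
        emit("kinship", as.data.frame(kc)); kc
      },
      roh = {
        p <- config$params$roh
        freqs <- p$freqs %||% allele_counts(ds, list(all = ds$samples$sample_id))$freq[, 1]
        segs <- call_roh(ds, freqs, min_covered = p$min_covered %||% 0)
        emit("roh_segments", as.data.frame(segs))
        prof <- summarize_roh(segs, samples = ds$samples$sample_id)
        list(segments = segs, profile = prof)
      })
    results[[stage]] <- res
  }
  if (!is.null(scen)) results$truth <- scen$truth
  if (!is.null(out_dir)) {
    summarizable <- results[!vapply(results, is.function, TRUE)]
    jsonlite::write_json(serialize_results(summarizable),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  results
}

ds_pseudo <- function(ds, seed) {
  if (ds$ploidy == "pseudo_haploid") ds
  else downsample(ds, 0, mode = "pseudo_haploid", seed = child_seed(seed, "ph"))
}

serialize_results <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.matrix(x)) return(as.data.frame(x))
  if (is.list(x)) return(lapply(x, serialize_results))
  x
}

# a small end-to-end demonstration scenario: three drifted populations,
# an admixture event 20 generations ago, a nuclear family and one
# first-cousin-union offspring
build_scenario <- function(name, seed) {
  if (name != "aegean_demo") stop("unknown scenario '", name, "'")
  panel <- make_snp_panel(40000L, default_map(n_autosomes = 8L),
                          seed = child_seed(seed, "panel"))
  fr <- simulate_population_freqs(panel, c(popA = 0.05, popB = 0.08, popO = 0.15),
                                  seed = child_seed(seed, "freqs"))
  cohort <- simulate_cohort(panel, fr$freqs, c(popA = 6L, popB = 6L, popO = 6L),
                            seed = child_seed(seed, "cohort"))
  adm <- simulate_admixed_individuals(panel, fr$freqs[, "popA"], fr$freqs[, "popB"],
                                      alpha = 0.5, g = 20, n_ind = 6L,
                                      seed = child_seed(seed, "admix"))
  fam <- rbind(relationship_pedigree("first_cousins"),
               data.frame(id = "sib", sex = "M", father = "fa", mother = "mo"))
  ped <- simulate_pedigree_genotypes(fam, panel, fr$freqs[, "popA"],
                                     seed = child_seed(seed, "ped"))
  keep <- c("fa", "mo", "proband", "sib")
  pd <- ped$dataset[, keep]
  pd$samples$group <- "family"
  ds <- pk_dataset(panel,
                   rbind(cohort$samples, adm$dataset$samples, pd$samples),
                   cbind(cohort$geno, adm$dataset$geno, pd$geno),
                   ploidy = "diploid", validate = FALSE)
  list(dataset = ds,
       truth = list(admixture = list(alpha = 0.5, g = 20),
                    family = fam,
                    roh = ped$roh_truth[ped$roh_truth$id %in% keep, ]))
}
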