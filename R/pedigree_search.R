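# Constraint-based pedigree reconstruction.
#
# A pedigree hypothesis is grown by attaching genotyped samples one at a
# time to a structure that may contain ungenotyped placeholder
# individuals, created on demand (new founders, new siblings of existing
# individuals, new intermediate parents). Kinship coefficients are
# maintained incrementally, so every partial hypothesis can be scored
# against the called pairwise degrees and pruned; iterative deepening on
# the number of tolerated violations returns all maximal-score
# hypotheses. Hypotheses identical at the level of pairwise (k0,k1,k2)
# among the genotyped samples are collapsed into one ambiguity class.

new_state <- function() {
  list(id = character(), sex = character(), father = integer(),
       mother = integer(), genotyped = logical(), gen = integer(),
       matri = integer(), patri = integer(),
       K = matrix(numeric(), 0, 0))
}

st_add_founder <- function(st, sex, genotyped, id, gen = 0L) {
  n <- length(st$id) + 1L
  st$id[n] <- id; st$sex[n] <- sex; st$father[n] <- 0L; st$mother[n] <- 0L
  st$genotyped[n] <- genotyped; st$gen[n] <- gen
  st$matri[n] <- n; st$patri[n] <- n
  K <- matrix(0, n, n); if (n > 1L) K[-n, -n] <- st$K
  K[n, n] <- 0.5
  st$K <- K
  st
}

st_add_child <- function(st, f, m, sex, genotyped, id) {
  n <- length(st$id) + 1L
  st$id[n] <- id; st$sex[n] <- sex; st$father[n] <- f; st$mother[n] <- m
  st$genotyped[n] <- genotyped
  st$gen[n] <- max(st$gen[f], st$gen[m]) + 1L
  st$matri[n] <- st$matri[m]; st$patri[n] <- st$patri[f]
  K <- matrix(0, n, n); K[-n, -n] <- st$K
  K[n, -n] <- K[-n, n] <- (st$K[f, ] + st$K[m, ]) / 2
  K[n, n] <- 0.5 * (1 + st$K[f, m])
  st$K <- K
  st
}

# give a parentless individual z two new founder parents; all existing
# kinship to the new founders flows through z
st_ensure_parents <- function(st, z) {
  if (st$father[z] != 0L) return(st)
  for (sex in c("M", "F")) {
    n <- length(st$id) + 1L
    st$id[n] <- paste0("U", n); st$sex[n] <- sex
    st$father[n] <- 0L; st$mother[n] <- 0L
    st$genotyped[n] <- FALSE; st$gen[n] <- st$gen[z] - 1L
    st$matri[n] <- n; st$patri[n] <- n
    K <- matrix(0, n, n); K[-n, -n] <- st$K
    K[n, -n] <- K[-n, n] <- st$K[z, ] / 2
    K[n, n] <- 0.5
    st$K <- K
    if (sex == "M") {
      st$father[z] <- n
      old <- st$patri[z]
      st$patri[st$patri == old] <- n
    } else {
      st$mother[z] <- n
      old <- st$matri[z]
      st$matri[st$matri == old] <- n
    }
  }
  st
}

# implied IBD2 probability for an outbred pair from parental kinships
st_k2 <- function(st, i, j) {
  if (i == j) return(1)
  fi <- st$father[i]; fj <- st$father[j]
  if (fi == 0L || fj == 0L) return(0)
  mi <- st$mother[i]; mj <- st$mother[j]
  st$K[fi, fj] * st$K[mi, mj] + st$K[fi, mj] * st$K[mi, fj]
}

st_degree <- function(st, i, j) degree_from_r(2 * st$K[i, j])

#' Reconstruct pedigrees consistent with pairwise degree calls
#'
#' Enumerates pedigree hypotheses over the genotyped samples plus
#' ungenotyped placeholder individuals (created on demand), scoring each
#' by agreement between the degrees its structure implies (from pairwise
#' kinship coefficients) and the called degrees, plus optional
#' mitochondrial / Y-chromosome line constraints. A branch-and-bound
#' search with iterative deepening on the number of tolerated violations
#' returns every maximal-score hypothesis; hypotheses with identical
#' pairwise (k0,k1,k2) among the genotyped samples are one ambiguity
#' class and reported once (so, for example, a parent-offspring versus
#' full-sibling orientation is only split when the calls constrain k2).
#'
#' @param degrees square matrix of called degrees with sample ids as
#'   dimnames; entries 1, 2, 3, 0 (unrelated) or `NA` (no call)
#' @param sexes named character vector (`"M"`/`"F"`) per sample
#' @param mito,y_hap optional named vectors of uniparental haplogroup
#'   labels; samples on one implied maternal (paternal) line must share
#'   them
#' @param leaves sample ids known to have left no offspring (for example
#'   perinatal infants); they are never placed as parents. Age evidence
#'   of this kind is what resolves parent-offspring versus sibling
#'   orientations
#' @param max_individuals cap on total pedigree size (genotyped +
#'   placeholders)
#' @param max_generations cap on the generation span of the hypothesis
#' @param max_violations deepest violation level tried before giving up
#' @param node_budget search-node cap; the search stops early (with a
#'   warning) if exhausted
#' @param max_solutions cap on distinct hypotheses returned
#' @return list of hypotheses, each with `ped` (data.frame: id, sex,
#'   father, mother, genotyped), `violations`, `score`, `degrees`
#'   (implied matrix) and `kinship` (2 * kinship coefficients); attribute
#'   `complete` says whether the search ran to completion.
#' @export
reconstruct_pedigree <- function(degrees, sexes, mito = NULL, y_hap = NULL,
                                 leaves = NULL,
                                 max_individuals = 24L, max_generations = 4L,
                                 max_violations = 3L, node_budget = 2e5,
                                 max_solutions = 64L) {
  ids <- rownames(degrees)
  stopifnot(!is.null(ids), identical(ids, colnames(degrees)),
            all(ids %in% names(sexes)))
  if (length(ids) > 12L)
    stop("exhaustive search is bounded at 12 genotyped samples")
  if (!all(degrees[!is.na(degrees)] %in% 0:3))
    stop("degrees must be 0 (unrelated), 1, 2, 3 or NA")
  links <- rowSums(!is.na(degrees) & degrees > 0, na.rm = TRUE)
  order_ids <- ids[order(-links)]
  env <- new.env(parent = emptyenv())
  env$ids <- ids
  max_extra <- max(0L, max_individuals - length(ids))
  # iterative deepening: first on tolerated violations, then on the
  # number of ungenotyped placeholders, so the hypotheses returned are
  # the most parsimonious pedigrees at the best attainable score
  for (v in 0:max_violations) {
    done <- FALSE
    for (m in 0:max_extra) {
      env$solutions <- list()
      env$keys <- character()
      env$nodes <- 0L
      env$exhausted <- FALSE
      search_attach(new_state(), order_ids, 1L, v, degrees, sexes, mito, y_hap,
                    leaves, length(ids) + m, max_generations, node_budget,
                    max_solutions, env)
      if (length(env$solutions)) { done <- TRUE; break }
    }
    if (done) break
  }
  if (env$exhausted)
    warning("node budget exhausted; hypothesis list may be incomplete")
  sols <- env$solutions
  n_called <- sum(!is.na(degrees[upper.tri(degrees)]))
  out <- lapply(sols, function(s) {
    gi <- which(s$genotyped)
    gi <- gi[match(ids, s$id[gi])]
    dmat <- outer(gi, gi, Vectorize(function(a, b) st_degree(s, a, b)))
    diag(dmat) <- NA_integer_
    dimnames(dmat) <- list(ids, ids)
    kin <- 2 * s$K[gi, gi]
    dimnames(kin) <- list(ids, ids)
    list(ped = data.frame(id = s$id, sex = s$sex,
                          father = ifelse(s$father == 0L, NA, s$id[pmax(s$father, 1L)]),
                          mother = ifelse(s$mother == 0L, NA, s$id[pmax(s$mother, 1L)]),
                          genotyped = s$genotyped, stringsAsFactors = FALSE),
         violations = s$violations,
         score = n_called - 2L * s$violations,
         degrees = dmat, kinship = kin)
  })
  structure(out, complete = !env$exhausted)
}

search_attach <- function(st, order_ids, k, budget, degrees, sexes, mito,
                          y_hap, leaves, max_ind, max_gen, node_budget,
                          max_solutions, env) {
  if (env$exhausted || length(env$solutions) >= max_solutions) return()
  env$nodes <- env$nodes + 1L
  if (env$nodes > node_budget) { env$exhausted <- TRUE; return() }
  if (k > length(order_ids)) {
    st$violations <- st$v_used
    gi <- which(st$genotyped)
    gi <- gi[match(env$ids, st$id[gi])]
    key <- paste(round(c(st$K[gi, gi],
                         outer(gi, gi, Vectorize(function(a, b) st_k2(st, a, b)))),
                       5), collapse = ",")
    if (!(key %in% env$keys)) {
      env$keys <- c(env$keys, key)
      env$solutions[[length(env$solutions) + 1L]] <- st
    }
    return()
  }
  sid <- order_ids[k]
  sx <- sexes[[sid]]
  if (is.null(st$v_used)) st$v_used <- 0L
  recurse <- function(st2, v) {
    st2$v_used <- st$v_used + v
    search_attach(st2, order_ids, k + 1L, budget, degrees, sexes, mito,
                  y_hap, leaves, max_ind, max_gen, node_budget, max_solutions,
                  env)
  }
  is_leaf <- function(id) !is.null(leaves) && id %in% leaves
  n0 <- length(st$id)
  gi <- which(st$genotyped)
  called <- if (length(gi)) degrees[sid, st$id[gi]] else integer()
  # cheap violation pre-check from the would-be kinship vector of the new
  # sample to the placed genotyped samples, plus uniparental-line classes
  pre_violations <- function(kvec_g, mclass, pclass) {
    v <- sum(degree_from_r(2 * kvec_g) != called, na.rm = TRUE)
    if (!is.null(mito) && !is.na(mclass)) {
      a <- mito[sid]
      if (!is.na(a))
        v <- v + sum(st$matri[gi] == mclass & !is.na(mito[st$id[gi]]) &
                       mito[st$id[gi]] != a)
    }
    if (!is.null(y_hap) && sx == "M" && !is.na(pclass)) {
      a <- y_hap[sid]
      if (!is.na(a))
        v <- v + sum(st$patri[gi] == pclass & st$sex[gi] == "M" &
                       !is.na(y_hap[st$id[gi]]) & y_hap[st$id[gi]] != a)
    }
    v
  }
  # option 1: isolated founder (kinship zero to everyone)
  v1 <- pre_violations(rep(0, length(gi)), NA, NA)
  if (st$v_used + v1 <= budget)
    recurse(st_add_founder(st, sx, TRUE, sid,
                           gen = if (n0) min(st$gen) else 0L), v1)
  if (n0 == 0L) return()
  # parent-slot candidates: existing individual, new founder, or new
  # sibling of an existing individual. Placeholder siblings may only be
  # created for genotyped individuals or for parents of genotyped ones
  # (keeps the placeholder scaffold anchored to observed samples). Each
  # option carries the kinship vector (over existing individuals) and the
  # extra-individual cost, so candidates are screened before any state is
  # materialized.
  anchored <- st$genotyped
  anchored[st$father[st$genotyped]] <- TRUE
  anchored[st$mother[st$genotyped]] <- TRUE
  slot_opts <- function(sex) {
    ex <- which(st$sex == sex &
                  !(st$genotyped & vapply(st$id, is_leaf, TRUE)))
    c(lapply(ex, function(i)
        list(type = "ex", i = i, kvec = st$K[i, ], cost = 0L,
             mclass = st$matri[i], pclass = st$patri[i])),
      list(list(type = "newf", kvec = rep(0, n0), cost = 1L,
                mclass = NA_integer_, pclass = NA_integer_)),
      lapply(which(anchored), function(z) {
        parentless <- st$father[z] == 0L
        kv <- if (parentless) st$K[z, ] / 2 else
          (st$K[st$father[z], ] + st$K[st$mother[z], ]) / 2
        list(type = "sib", z = z, kvec = kv,
             cost = if (parentless) 3L else 1L,
             mclass = st$matri[z], pclass = st$patri[z])
      }))
  }
  # kinship between the two slot parents (for the outbred-union rule)
  slot_phi <- function(of, om) {
    if (of$type == "newf" || om$type == "newf") return(0)
    if (om$type == "ex") return(of$kvec[om$i])
    if (om$z <= length(of$kvec) && st$father[om$z] == 0L)
      return(of$kvec[om$z] / 2)
    (of$kvec[st$father[om$z]] + of$kvec[st$mother[om$z]]) / 2
  }
  mk_parent <- function(stx, opt, sex, gen0) {
    if (opt$type == "ex") return(list(st = stx, i = opt$i))
    if (opt$type == "newf") {
      stx <- st_add_founder(stx, sex, FALSE, paste0("U", length(stx$id) + 1L),
                            gen = gen0)
      return(list(st = stx, i = length(stx$id)))
    }
    stx <- st_ensure_parents(stx, opt$z)
    stx <- st_add_child(stx, stx$father[opt$z], stx$mother[opt$z], sex,
                        FALSE, paste0("U", length(stx$id) + 1L))
    list(st = stx, i = length(stx$id))
  }
  # option 2: child of a parent pair; unions between related individuals
  # are excluded (the hypothesis space is outbred)
  opts_m <- slot_opts("M"); opts_f <- slot_opts("F")
  for (of in opts_m) {
    for (om in opts_f) {
      if (of$type == "newf" && om$type == "newf") next
      if (of$type == "sib" && om$type == "sib" && of$z == om$z) next
      if (n0 + of$cost + om$cost + 1L > max_ind) next
      if (slot_phi(of, om) > 1e-9) next
      kg <- (of$kvec[gi] + om$kvec[gi]) / 2
      v <- pre_violations(kg, om$mclass %||% NA, of$pclass %||% NA)
      if (st$v_used + v > budget) next
      stx <- st
      pf <- mk_parent(stx, of, "M", if (om$type == "ex") st$gen[om$i] else 0L)
      stx <- pf$st
      pm <- mk_parent(stx, om, "F", stx$gen[pf$i])
      stx <- pm$st
      stx <- st_add_child(stx, pf$i, pm$i, sx, TRUE, sid)
      if (length(stx$id) > max_ind) next
      if (diff(range(stx$gen)) + 1L > max_gen) next
      recurse(stx, v)
    }
  }
  # option 3: become a parent of a parentless existing individual
  for (z in seq_len(n0)) {
    if (is_leaf(sid)) break
    if (st$father[z] != 0L) next
    kg <- st$K[z, gi] / 2
    v <- pre_violations(kg, if (sx == "F") st$matri[z] else NA,
                        if (sx == "M") st$patri[z] else NA)
    if (st$v_used + v > budget) next
    if (n0 + 2L > max_ind) next
    stx <- st_ensure_parents(st, z)
    if (diff(range(stx$gen)) + 1L > max_gen) next
    ph <- if (sx == "M") stx$father[z] else stx$mother[z]
    recurse(st_substitute(stx, ph, sid), v)
  }
  # option 4: substitute an ungenotyped placeholder of the same sex
  for (p in which(!st$genotyped & st$sex == sx)) {
    if (is_leaf(sid) && any(st$father == p | st$mother == p)) next
    v <- pre_violations(st$K[p, gi], st$matri[p], st$patri[p])
    if (st$v_used + v > budget) next
    recurse(st_substitute(st, p, sid), v)
  }
  # option 5: aunt/uncle of a parentless individual - sibling of a newly
  # created parent of z (the two-level attachment needed when every
  # genotyped sample is a leaf, e.g. the infants of one extended family)
  for (z in which(anchored)) {
    if (st$father[z] != 0L) next
    if (n0 + 4L + 1L > max_ind) next           # 4 new placeholders + sample
    for (sp in c("M", "F")) {
      kg <- st$K[z, gi] / 4
      v <- pre_violations(kg, if (sp == "F") st$matri[z] else NA,
                          if (sp == "M") st$patri[z] else NA)
      if (st$v_used + v > budget) next
      stx <- st_ensure_parents(st, z)
      P <- if (sp == "M") stx$father[z] else stx$mother[z]
      stx <- st_ensure_parents(stx, P)
      stx <- st_add_child(stx, stx$father[P], stx$mother[P], sx, TRUE, sid)
      if (length(stx$id) > max_ind) next
      if (diff(range(stx$gen)) + 1L > max_gen) next
      recurse(stx, v)
    }
  }
}

# a genotyped sample takes the place of an ungenotyped placeholder;
# kinship structure is unchanged, only identity changes
st_substitute <- function(st, p, sid) {
  st$id[p] <- sid
  st$genotyped[p] <- TRUE
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Descendants of an individual in a pedigree table
#' @param ped pedigree data.frame (`id`, `father`, `mother`)
#' @param id ancestor id
#' @return character vector of descendant ids (excluding `id`).
#' @export
ped_descendants <- function(ped, id) {
  out <- character()
  frontier <- id
  while (length(frontier)) {
    kids <- ped$id[!is.na(ped$father) & ped$father %in% frontier |
                     !is.na(ped$mother) & ped$mother %in% frontier]
    kids <- setdiff(kids, out)
    out <- c(out, kids)
    frontier <- kids
  }
  out
}
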