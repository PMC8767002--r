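#' Observed pairwise similarity
#'
#' The observed similarity is the complement of Bray-Curtis
#' dissimilarity, `S_obs = 1 - D_obs`, computed on per-sample relative
#' abundances.
#'
#' @param x an `otu_table`
#' @return list with `d_obs` and `s_obs` (symmetric matrices) and
#'   `pairs` (long data.frame `sample_i`, `sample_j`, `d_obs`, `s_obs`)
#' @export
observed_similarity <- function(x) {
  d <- distance_matrix(x, "bray_curtis")
  s <- 1 - d
  diag(s) <- 1
  pr <- pair_frame(d)
  pr$d_obs <- pr$value; pr$value <- NULL
  pr$s_obs <- 1 - pr$d_obs
  list(d_obs = d, s_obs = s, pairs = pr)
}

# one null community table: every sample keeps its observed richness and
# total; membership drawn weighted by occurrence frequency, individuals
# filled weighted by regional relative abundance (one guaranteed
# individual per drawn taxon keeps richness exact)
null_community_table <- function(counts, occ_freq, regional) {
  S <- nrow(counts)
  out <- matrix(0, S, ncol(counts), dimnames = dimnames(counts))
  observed <- which(occ_freq > 0)
  for (s in seq_len(S)) {
    rich <- sum(counts[s, ] > 0)
    total <- sum(counts[s, ])
    taxa <- if (rich >= length(observed)) observed
            else observed[sample.int(length(observed), rich,
                                     prob = occ_freq[observed])]
    fill <- total - length(taxa)
    cnt <- rep(1L, length(taxa))
    if (fill > 0) {
      p <- regional[taxa]
      if (sum(p) == 0) p <- rep(1, length(taxa))
      cnt <- cnt + stats::rmultinom(1, fill, prob = p)[, 1]
    }
    out[s, taxa] <- cnt
  }
  out
}

# pairs x reps matrix of null Bray-Curtis dissimilarities
null_bray_reps <- function(x, n_reps, seed) {
  counts <- x$counts
  occ_freq <- colSums(counts > 0)
  regional <- colSums(counts) / sum(counts)
  npair <- nrow(counts) * (nrow(counts) - 1) / 2
  reps <- with_seed(seed, {
    vapply(seq_len(n_reps), function(r) {
      nc <- null_community_table(counts, occ_freq, regional)
      rel <- nc / rowSums(nc)
      dm <- as.matrix(vegan::vegdist(rel, method = "bray"))
      dm[upper.tri(dm)]   # same pair order as pair_frame()
    }, numeric(npair))
  })
  matrix(reps, nrow = npair)   # stays a matrix even for a single pair
}

#' Null-model expected similarity
#'
#' For each replicate, every null sample keeps its observed richness and
#' total abundance; taxa membership is drawn with probability
#' proportional to occurrence frequency across samples and individuals
#' are filled in proportion to regional relative abundance. The expected
#' similarity `E_exp` is the per-pair mean of `1 - Bray-Curtis` over
#' replicates.
#'
#' @param x an `otu_table` (true counts required)
#' @param n_reps null replicates (default 999; fewer than 99 triggers a
#'   resolution warning)
#' @param seed integer RNG seed
#' @return list with `pairs` (long data.frame `sample_i`, `sample_j`,
#'   `d_obs`, `s_obs`, `e_exp`), `null_sim` (pairs x reps matrix of null
#'   similarities), `n_reps`, `seed`
#' @export
null_expected_similarity <- function(x, n_reps = 999, seed = 1) {
  stopifnot(inherits(x, "otu_table"))
  if (isTRUE(attr(x, "relative")))
    stop("null models need true counts, not relative abundances")
  if (n_reps < 2) stop("n_reps must be >= 2")
  if (n_reps < 99)
    warning("fewer than 99 null replicates gives poor resolution")
  obs <- observed_similarity(x)
  nulls <- null_bray_reps(x, n_reps, seed)
  pr <- obs$pairs
  pr$e_exp <- rowMeans(1 - nulls)
  list(pairs = pr, null_sim = 1 - nulls, n_reps = n_reps, seed = seed)
}

#' Permutation test of observed vs null-expected similarity
#'
#' One-way permutational ANOVA comparing the observed pairwise
#' similarities against the null similarities: the usual F statistic is
#' computed on the pooled values and its null distribution is obtained
#' by permuting the observed/null group labels. A community whose
#' observed similarity significantly exceeds the null expectation is
#' called determinism-dominant.
#'
#' @param s_obs numeric vector of observed pairwise similarities
#' @param null_sim matrix (pairs x reps) or vector of null similarities
#' @param n_perm label permutations (default 999)
#' @param seed integer RNG seed
#' @return one-row data.frame `F`, `p_value`, `mean_obs`, `mean_null`,
#'   `verdict` (`"determinism-dominant"`, `"below-null"` or
#'   `"indistinguishable"`), `n_perm`, `seed`
#' @export
determinism_test <- function(s_obs, null_sim, n_perm = 999, seed = 1) {
  v_null <- as.vector(null_sim)
  if (!length(s_obs) || !length(v_null)) stop("empty similarity sets")
  if (is.matrix(null_sim) && nrow(null_sim) != length(s_obs))
    stop("observed and null similarity sets cover different pair sets")
  v <- c(s_obs, v_null)
  n1 <- length(s_obs); n <- length(v)
  f_stat <- function(sum1) {
    m1 <- sum1 / n1
    m2 <- (tot - sum1) / (n - n1)
    ssb <- n1 * (m1 - gm)^2 + (n - n1) * (m2 - gm)^2
    ssw <- sst - ssb
    if (ssw <= 0) return(Inf)
    ssb / (ssw / (n - 2))
  }
  tot <- sum(v); gm <- tot / n
  sst <- sum((v - gm)^2)
  f_obs <- f_stat(sum(s_obs))
  dir_obs <- mean(s_obs) - mean(v_null)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      f_stat(sum(v[sample.int(n, n1)])) >= f_obs
    }, logical(1)))
  })
  p <- (exceed + 1) / (n_perm + 1)
  verdict <- if (p >= 0.05) "indistinguishable"
             else if (dir_obs > 0) "determinism-dominant" else "below-null"
  data.frame(F = f_obs, p_value = p, mean_obs = mean(s_obs),
             mean_null = mean(v_null), verdict = verdict,
             n_perm = n_perm, seed = seed, stringsAsFactors = FALSE)
}

#' Beta mean nearest-taxon distance
#'
#' For communities k and m, `0.5 * (sum_i p_ik min_j d(i, j) +
#' sum_j p_jm min_i d(j, i))` where the minima run over taxa present in
#' the other community and `d` is patristic distance. Abundance-weighted
#' by default (`p` = relative abundances); the unweighted variant uses
#' equal weights over present taxa.
#'
#' @param x an `otu_table`
#' @param tree [ape::phylo] covering the observed OTUs (reconciled via
#'   [match_tree_table()])
#' @param abundance_weighted logical (default `TRUE`)
#' @return symmetric matrix of betaMNTD values, zero diagonal
#' @export
beta_mntd <- function(x, tree, abundance_weighted = TRUE) {
  prep <- bmntd_prepare(x, tree, abundance_weighted)
  obs <- bmntd_perms(prep$D, prep$P,
                     matrix(seq_len(ncol(prep$P)), nrow = 1))
  m <- matrix(0, nrow(prep$P), nrow(prep$P),
              dimnames = list(rownames(prep$P), rownames(prep$P)))
  m[upper.tri(m)] <- obs[1, ]
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

bmntd_prepare <- function(x, tree, abundance_weighted = TRUE) {
  stopifnot(inherits(x, "otu_table"))
  mt <- match_tree_table(x, tree)
  counts <- mt$table$counts
  D <- ape::cophenetic.phylo(mt$tree)
  D <- D[colnames(counts), colnames(counts)]
  P <- counts / rowSums(counts)
  if (!abundance_weighted) {
    pres <- counts > 0
    P <- pres / rowSums(pres)
  }
  list(D = unname(D), P = P, table = mt$table, tree = mt$tree)
}

#' Beta nearest-taxon index
#'
#' z-score of the observed betaMNTD against a null distribution obtained
#' by shuffling OTU labels across the tree tips (taxa-shuffle null),
#' per pair of samples: `(bMNTD_obs - mean_null) / sd_null`. Values
#' below -2 indicate homogeneous selection, above +2 heterogeneous
#' selection.
#'
#' @inheritParams beta_mntd
#' @param n_null tip shuffles (default 999)
#' @param seed integer RNG seed
#' @return symmetric matrix of betaNTI z-scores (diagonal `NA`), with
#'   attribute `bmntd_obs`
#' @export
beta_nti <- function(x, tree, n_null = 999, seed = 1,
                     abundance_weighted = TRUE) {
  prep <- bmntd_prepare(x, tree, abundance_weighted)
  N <- ncol(prep$P); S <- nrow(prep$P)
  perms <- with_seed(seed, {
    t(vapply(seq_len(n_null), function(i) sample.int(N), integer(N)))
  })
  all_perms <- rbind(seq_len(N), perms)
  vals <- bmntd_perms(prep$D, prep$P, all_perms)
  obs <- vals[1, ]
  nulls <- vals[-1, , drop = FALSE]
  mu <- colMeans(nulls)
  sdv <- apply(nulls, 2, stats::sd)
  degen <- sdv < 1e-12
  if (all(degen))
    stop("null betaMNTD has zero spread for every pair (degenerate tree ",
         "or table, e.g. a star phylogeny); betaNTI is undefined")
  if (any(degen & abs(obs - mu) > 1e-12))
    stop("null betaMNTD has zero spread for a pair whose observed value ",
         "differs from the null; betaNTI is undefined")
  z <- ifelse(degen, 0, (obs - mu) / ifelse(degen, 1, sdv))
  m <- matrix(NA_real_, S, S, dimnames = list(rownames(prep$P),
                                              rownames(prep$P)))
  m[upper.tri(m)] <- z
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  ob <- matrix(0, S, S, dimnames = dimnames(m))
  ob[upper.tri(ob)] <- obs
  ob[lower.tri(ob)] <- t(ob)[lower.tri(ob)]
  attr(m, "bmntd_obs") <- ob
  m
}

#' Modified Raup-Crick index on Bray-Curtis
#'
#' Compares each pair's observed Bray-Curtis dissimilarity with the
#' null distribution generated by the same null model as
#' [null_expected_similarity()]:
#' `RC_raw = (n_less + 0.5 n_ties) / n_null`, rescaled to
#' `RC_bray = 2 (RC_raw - 0.5)` in `[-1, +1]`. Values near +1 mean the
#' pair is more dissimilar than expected by chance (dispersal
#' limitation, under the standard direction convention), near -1 less
#' dissimilar (homogenizing dispersal).
#'
#' @param x an `otu_table`
#' @param n_null null replicates (default 999)
#' @param seed integer RNG seed
#' @return symmetric matrix of RC values in `[-1, 1]` (diagonal `NA`)
#' @export
rc_bray <- function(x, n_null = 999, seed = 1) {
  stopifnot(inherits(x, "otu_table"))
  obs <- observed_similarity(x)
  d_obs <- obs$pairs$d_obs
  nulls <- null_bray_reps(x, n_null, seed)   # pairs x reps dissimilarity
  less <- rowSums(nulls < d_obs - 1e-12)
  ties <- rowSums(abs(nulls - d_obs) <= 1e-12)
  rc <- 2 * ((less + 0.5 * ties) / n_null - 0.5)
  S <- n_samples(x)
  m <- matrix(NA_real_, S, S,
              dimnames = list(rownames(x$counts), rownames(x$counts)))
  m[upper.tri(m)] <- rc
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

#' Classify ecological assembly processes from betaNTI and RC-bray
#'
#' Per pair: `betaNTI > +2` gives heterogeneous selection and
#' `betaNTI < -2` homogeneous selection; otherwise the pair falls to the
#' dispersal tier where `RC > +0.95` gives dispersal limitation,
#' `RC < -0.95` homogenizing dispersal and `|RC| <= 0.95` undominated.
#' All comparisons are strict, so values exactly at a threshold fall to
#' the next tier. The published direction of the RC tier is followed
#' (high RC = more turnover than the null = dispersal limitation);
#' `flip_rc_convention = TRUE` swaps the two dispersal labels.
#'
#' @param bnti betaNTI values: matrix or vector
#' @param rc RC-bray values, same shape
#' @param flip_rc_convention swap the dispersal-tier direction
#' @return character labels, same shape as the input
#' @export
classify_process_pair <- function(bnti, rc, flip_rc_convention = FALSE) {
  if (length(bnti) != length(rc))
    stop("betaNTI and RC inputs differ in length")
  if (any(is.nan(bnti)) || any(is.nan(rc)) ||
      any(is.infinite(bnti)) || any(is.infinite(rc)))
    stop("non-finite betaNTI or RC values")
  if (any(is.na(bnti) != is.na(rc)))
    stop("betaNTI and RC have mismatched missing values")
  if (any(abs(rc) > 1 + 1e-9, na.rm = TRUE)) stop("|RC| must not exceed 1")
  disp_hi <- if (flip_rc_convention) "homogenizing_dispersal" else "dispersal_limitation"
  disp_lo <- if (flip_rc_convention) "dispersal_limitation" else "homogenizing_dispersal"
  out <- ifelse(bnti > 2, "heterogeneous_selection",
         ifelse(bnti < -2, "homogeneous_selection",
         ifelse(rc > 0.95, disp_hi,
         ifelse(rc < -0.95, disp_lo, "undominated"))))
  if (is.matrix(bnti)) out <- matrix(out, nrow(bnti), dimnames = dimnames(bnti))
  out
}

#' Per-pair process labels with per-group aggregation
#'
#' @param bnti symmetric betaNTI matrix (as from [beta_nti()])
#' @param rc symmetric RC-bray matrix over the same samples
#' @param grouping optional named vector `sample -> group`; when given,
#'   within-group pairs are aggregated per group
#' @param flip_rc_convention see [classify_process_pair()]
#' @return list with `pairs` (long data.frame `sample_i`, `sample_j`,
#'   `bnti`, `rc`, `process`) and, when `grouping` is given, `groups`
#'   (per-group mean betaNTI and RC, the process implied by the means,
#'   the modal per-pair label, and the determinism/stochasticity verdict)
#' @export
classify_processes <- function(bnti, rc, grouping = NULL,
                               flip_rc_convention = FALSE) {
  bnti <- as.matrix(bnti); rc <- as.matrix(rc)
  if (!identical(dim(bnti), dim(rc)))
    stop("betaNTI and RC matrices differ in shape")
  if (!is.null(rownames(bnti)) && !is.null(rownames(rc)) &&
      !identical(rownames(bnti), rownames(rc)))
    rc <- rc[rownames(bnti), rownames(bnti)]
  pr <- pair_frame(bnti); names(pr)[3] <- "bnti"
  pr$rc <- rc[upper.tri(rc)]
  pr$process <- classify_process_pair(pr$bnti, pr$rc, flip_rc_convention)
  out <- list(pairs = pr)
  if (!is.null(grouping)) {
    gi <- grouping[pr$sample_i]; gj <- grouping[pr$sample_j]
    within <- !is.na(gi) & !is.na(gj) & gi == gj
    w <- pr[within, ]; w$group <- gi[within]
    out$groups <- do.call(rbind, lapply(split(w, w$group), function(d) {
      mb <- mean(d$bnti); mr <- mean(d$rc)
      proc <- classify_process_pair(mb, mr, flip_rc_convention)
      tab <- sort(table(d$process), decreasing = TRUE)
      data.frame(group = d$group[1], n_pairs = nrow(d),
                 mean_bnti = mb, mean_rc = mr, process = proc,
                 modal_process = names(tab)[1],
                 verdict = if (grepl("selection", proc)) "determinism"
                           else "stochasticity",
                 stringsAsFactors = FALSE)
    }))
    rownames(out$groups) <- NULL
  }
  out
}

#' Full assembly-process analysis per group
#'
#' Runs, for every group of the table separately (each group acting as
#' its own species pool): observed vs null-expected similarity with its
#' permutation test, betaNTI, RC-bray, and the process classification of
#' the group means.
#'
#' @param x an `otu_table` with a grouping column in its metadata
#' @param tree [ape::phylo] covering the OTUs
#' @param group metadata column (default `"group"`)
#' @param n_null null replicates / tip shuffles (default 999)
#' @param seed master seed; per-group seeds are derived from it
#' @param flip_rc_convention see [classify_process_pair()]
#' @return list with `summary` (one row per group: `group`, `mean_s_obs`,
#'   `mean_e_exp`, `F`, `p_value`, `bnti`, `rc_bray`, `process`,
#'   `verdict`) and `pairs` (per-pair long data.frame)
#' @export
assembly_analysis <- function(x, tree, group = "group", n_null = 999,
                              seed = 1, flip_rc_convention = FALSE) {
  stopifnot(inherits(x, "otu_table"))
  g <- as.character(x$metadata[[group]])
  rows <- list(); pairs <- list()
  for (k in seq_along(unique(g))) {
    lev <- unique(g)[k]
    sub <- subset_samples(x, g == lev, drop_empty_otus = TRUE)
    sd1 <- derive_seed(seed, 100 + k)
    nes <- null_expected_similarity(sub, n_reps = n_null, seed = sd1)
    det <- determinism_test(nes$pairs$s_obs, nes$null_sim,
                            n_perm = n_null, seed = derive_seed(seed, 200 + k))
    bnti <- beta_nti(sub, tree, n_null = n_null,
                     seed = derive_seed(seed, 300 + k))
    rc <- rc_bray(sub, n_null = n_null, seed = sd1)
    cl <- classify_processes(bnti, rc,
                             grouping = stats::setNames(rep(lev, n_samples(sub)),
                                                        rownames(sub$counts)),
                             flip_rc_convention = flip_rc_convention)
    p <- cl$pairs; p$group <- lev
    p$s_obs <- nes$pairs$s_obs; p$e_exp <- nes$pairs$e_exp
    p$bmntd <- attr(bnti, "bmntd_obs")[upper.tri(bnti)]
    pairs[[lev]] <- p
    rows[[lev]] <- data.frame(
      group = lev,
      mean_s_obs = mean(nes$pairs$s_obs),
      mean_e_exp = mean(nes$pairs$e_exp),
      F = det$F, p_value = det$p_value,
      bnti = cl$groups$mean_bnti, rc_bray = cl$groups$mean_rc,
      process = cl$groups$process, verdict = cl$groups$verdict,
      stringsAsFactors = FALSE)
  }
  list(summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       pairs = do.call(rbind, c(pairs, list(make.row.names = FALSE))))
}
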