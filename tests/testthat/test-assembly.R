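test_that("observed similarity is the exact complement of Bray-Curtis", {
  same <- otu_table(rbind(s1 = c(a = 3, b = 7), s2 = c(a = 3, b = 7)))
  expect_equal(observed_similarity(same)$s_obs["s1", "s2"], 1)
  disj <- otu_table(rbind(s1 = c(a = 3, b = 0), s2 = c(a = 0, b = 5)))
  expect_equal(observed_similarity(disj)$s_obs["s1", "s2"], 0)
  tab <- random_table(8, 60, seed = 21)
  o <- observed_similarity(tab)
  expect_equal(o$s_obs + o$d_obs,
               matrix(1, 8, 8, dimnames = dimnames(o$d_obs)),
               ignore_attr = TRUE)
  expect_equal(o$pairs$s_obs, 1 - o$pairs$d_obs)
})

test_that("null expected similarity behaves on degenerate and shuffled pools", {
  # single-OTU metacommunity: every null community identical
  one <- otu_table(rbind(s1 = c(a = 50), s2 = c(a = 80)))
  n1 <- null_expected_similarity(one, n_reps = 99, seed = 1)
  expect_equal(n1$pairs$e_exp, 1)
  expect_warning(null_expected_similarity(one, n_reps = 50, seed = 1),
                 "resolution")
  expect_error(null_expected_similarity(one, n_reps = 1, seed = 1), ">= 2")

  # samples that are permutations of one composition: identity broken
  comp <- c(40, 25, 20, 10, 5)
  counts <- rbind(s1 = comp, s2 = comp[c(2, 1, 4, 3, 5)],
                  s3 = comp[c(5, 4, 3, 2, 1)])
  colnames(counts) <- paste0("o", 1:5)
  perm <- otu_table(counts)
  n2 <- null_expected_similarity(perm, n_reps = 199, seed = 2)
  expect_true(all(n2$pairs$e_exp < 1))

  # null means stabilize across seeds
  tab <- random_table(6, 80, seed = 23, lambda = 3)
  a <- null_expected_similarity(tab, n_reps = 999, seed = 10)
  b <- null_expected_similarity(tab, n_reps = 999, seed = 20)
  expect_true(all(abs(a$pairs$e_exp - b$pairs$e_exp) < 0.02))
  # null samples preserve richness and totals
  occ <- colSums(tab$counts > 0)
  reg <- colSums(tab$counts) / sum(tab$counts)
  set.seed(1)
  nc <- miceco:::null_community_table(tab$counts, occ, reg)
  expect_equal(rowSums(nc > 0), rowSums(tab$counts > 0))
  expect_equal(rowSums(nc), rowSums(tab$counts))
})

test_that("observed-vs-null similarity test separates shifted distributions", {
  set.seed(3)
  null_sim <- matrix(stats::runif(15 * 200, 0.2, 0.4), 15, 200)
  shifted <- rowMeans(null_sim) + 0.4
  r <- determinism_test(shifted, null_sim, n_perm = 999, seed = 1)
  expect_equal(r$p_value, 1 / 1000)
  expect_equal(r$verdict, "determinism-dominant")
  expect_error(determinism_test(shifted[1:10], null_sim), "different pair")
})

test_that("observed-vs-null similarity test is calibrated under the null", {
  set.seed(4)
  rej <- 0
  for (i in 1:100) {
    null_sim <- matrix(stats::rbeta(10 * 99, 2, 4), 10, 99)
    pseudo_obs <- stats::rbeta(10, 2, 4)
    p <- determinism_test(pseudo_obs, null_sim, n_perm = 199,
                          seed = i)$p_value
    rej <- rej + (p <= 0.05)
  }
  expect_gte(rej / 100, 0.005)
  expect_lte(rej / 100, 0.12)
})

test_that("betaMNTD matches hand values and a brute-force double loop", {
  tr <- toy_tree()
  ab <- otu_table(rbind(s1 = c(A = 10, B = 0, C = 0),
                        s2 = c(A = 0, B = 7, C = 0)))
  expect_equal(beta_mntd(ab, tr)["s1", "s2"], 2)
  same <- otu_table(rbind(s1 = c(A = 5, B = 5, C = 2),
                          s2 = c(A = 5, B = 5, C = 2)))
  expect_equal(beta_mntd(same, tr)["s1", "s2"], 0)

  tab <- random_table(5, 20, seed = 31, lambda = 2)
  tr2 <- simulate_tree(20, seed = 32, tip_prefix = "o")
  got <- beta_mntd(tab, tr2)
  D <- ape::cophenetic.phylo(tr2)[colnames(tab$counts), colnames(tab$counts)]
  rel <- tab$counts / rowSums(tab$counts)
  for (k in 1:4) for (m in (k + 1):5) {
    ik <- which(tab$counts[k, ] > 0); im <- which(tab$counts[m, ] > 0)
    ref <- 0.5 * (sum(rel[k, ik] * apply(D[ik, im, drop = FALSE], 1, min)) +
                  sum(rel[m, im] * apply(D[im, ik, drop = FALSE], 1, min)))
    expect_equal(got[k, m], ref)
  }
})

test_that("betaMNTD agrees with the independent picante implementation", {
  tab <- random_table(6, 40, seed = 33, lambda = 1.5)
  tr <- simulate_tree(40, seed = 34, tip_prefix = "o")
  D <- ape::cophenetic.phylo(tr)
  got <- beta_mntd(tab, tr, abundance_weighted = TRUE)
  ref <- as.matrix(picante::comdistnt(tab$counts, D,
                                      abundance.weighted = TRUE))
  expect_equal(got[rownames(ref), colnames(ref)], ref,
               tolerance = 1e-10, ignore_attr = TRUE)
  # unweighted variant: equal weights per community (the average of the
  # two per-community means, not picante's pooled mean)
  gotu <- beta_mntd(tab, tr, abundance_weighted = FALSE)
  Dm <- D[colnames(tab$counts), colnames(tab$counts)]
  for (k in 1:3) for (m in (k + 1):4) {
    ik <- which(tab$counts[k, ] > 0); im <- which(tab$counts[m, ] > 0)
    ref_u <- 0.5 * (mean(apply(Dm[ik, im, drop = FALSE], 1, min)) +
                    mean(apply(Dm[im, ik, drop = FALSE], 1, min)))
    expect_equal(gotu[k, m], ref_u)
  }
})

test_that("betaNTI flags degenerate phylogenies and keeps its structure", {
  tab <- otu_table(rbind(s1 = c(A = 5, B = 2, C = 0, D = 0),
                         s2 = c(A = 0, B = 0, C = 4, D = 3)))
  expect_error(beta_nti(tab, star_tree(4), n_null = 49, seed = 1),
               "degenerate")
  tr <- simulate_tree(60, seed = 35, tip_prefix = "o")
  tab2 <- random_table(5, 60, seed = 36, lambda = 1)
  z <- beta_nti(tab2, tr, n_null = 199, seed = 2)
  expect_equal(z, t(z))
  expect_true(all(is.na(diag(z))))
  z2 <- beta_nti(tab2, tr, n_null = 199, seed = 2)
  expect_identical(unclass(z), unclass(z2))
})

test_that("betaNTI sign tracks phylogenetic clustering of turnover", {
  tree <- simulate_tree(300, seed = 5)
  D <- ape::cophenetic.phylo(tree)
  set.seed(6)
  pool <- exp(stats::rnorm(300, 0, 2)); pool <- pool / sum(pool)
  names(pool) <- tree$tip.label
  clade <- names(sort(D["OTU1", ]))[1:30]    # tight clade around OTU1
  far <- names(sort(D["OTU1", ], decreasing = TRUE))[1:30]
  counts <- matrix(0, 3, 300, dimnames = list(c("c1", "c2", "f1"),
                                              tree$tip.label))
  counts["c1", clade[seq(1, 30, 2)]] <- 100   # disjoint halves of the clade
  counts["c2", clade[seq(2, 30, 2)]] <- 100
  counts["f1", far] <- 100
  tab <- otu_table(counts)
  z <- beta_nti(tab, tree, n_null = 499, seed = 7)
  expect_lt(z["c1", "c2"], -1)   # within-clade turnover: clustered
  expect_gt(z["c1", "f1"], 1)    # across-tree turnover: overdispersed
})

test_that("RC-bray hits its definitional floor, ceiling and tie point", {
  same <- otu_table(rbind(s1 = c(a = 30, b = 20, c = 10, d = 5),
                          s2 = c(a = 30, b = 20, c = 10, d = 5)))
  expect_equal(rc_bray(same, n_null = 99, seed = 1)["s1", "s2"], -1)
  dis_counts <- rbind(s1 = c(rep(10L, 20), rep(0L, 20)),
                      s2 = c(rep(0L, 20), rep(10L, 20)))
  colnames(dis_counts) <- paste0("o", 1:40)
  disj <- otu_table(dis_counts)
  expect_equal(rc_bray(disj, n_null = 99, seed = 1)["s1", "s2"], 1)
  one <- otu_table(rbind(s1 = c(a = 50), s2 = c(a = 70)))
  expect_equal(rc_bray(one, n_null = 99, seed = 1)["s1", "s2"], 0)
  tab <- random_table(6, 50, seed = 41)
  rc <- rc_bray(tab, n_null = 199, seed = 2)
  expect_true(all(abs(rc[upper.tri(rc)]) <= 1))
})

test_that("RC-bray is centered when the observation is itself a null draw", {
  per_table <- vapply(c(43, 101, 202), function(bseed) {
    tab <- random_table(8, 60, seed = bseed, lambda = 2)
    a <- miceco:::null_bray_reps(tab, 100, seed = 51)  # pseudo-observations
    b <- miceco:::null_bray_reps(tab, 999, seed = 52)  # null distribution
    rcs <- vapply(seq_len(ncol(a)), function(r) {
      less <- rowSums(b < a[, r] - 1e-12)
      ties <- rowSums(abs(b - a[, r]) <= 1e-12)
      mean(2 * ((less + 0.5 * ties) / ncol(b) - 0.5))
    }, numeric(1))
    mean(rcs)
  }, numeric(1))
  expect_lt(abs(mean(per_table)), 0.05)
})

test_that("process classification is exhaustive at every threshold boundary", {
  eps <- 1e-9
  bv <- c(-2 - eps, -2, 0, 2, 2 + eps)
  rv <- c(-0.95 - eps, -0.95, 0, 0.95, 0.95 + eps)
  grid <- expand.grid(bnti = bv, rc = rv)
  ref <- function(b, r) {
    if (b > 2) return("heterogeneous_selection")
    if (b < -2) return("homogeneous_selection")
    if (r > 0.95) return("dispersal_limitation")
    if (r < -0.95) return("homogenizing_dispersal")
    "undominated"
  }
  got <- classify_process_pair(grid$bnti, grid$rc)
  expect_equal(got, mapply(ref, grid$bnti, grid$rc), ignore_attr = TRUE)
  flipped <- classify_process_pair(grid$bnti, grid$rc,
                                   flip_rc_convention = TRUE)
  swap <- got
  swap[got == "dispersal_limitation"] <- "homogenizing_dispersal"
  swap[got == "homogenizing_dispersal"] <- "dispersal_limitation"
  expect_equal(flipped, swap)
  expect_error(classify_process_pair(NaN, 0.5), "non-finite")
  expect_error(classify_process_pair(0, 1.2), "exceed")
})

test_that("group aggregation reports means, modal labels and verdicts", {
  b <- matrix(c(NA, 3, 4, 3, NA, 5, 4, 5, NA), 3,
              dimnames = list(c("x1", "x2", "x3"), c("x1", "x2", "x3")))
  r <- matrix(0.2, 3, 3, dimnames = dimnames(b)); diag(r) <- NA
  cl <- classify_processes(b, r, grouping = c(x1 = "G", x2 = "G", x3 = "G"))
  expect_equal(cl$groups$process, "heterogeneous_selection")
  expect_equal(cl$groups$verdict, "determinism")
  expect_equal(cl$groups$mean_bnti, 4)
  expect_equal(cl$groups$modal_process, "heterogeneous_selection")
  b2 <- b; b2[upper.tri(b2)] <- 0; b2[lower.tri(b2)] <- 0
  r2 <- r; r2[upper.tri(r2)] <- 0.99; r2[lower.tri(r2)] <- 0.99
  cl2 <- classify_processes(b2, r2, grouping = c(x1 = "G", x2 = "G", x3 = "G"))
  expect_equal(cl2$groups$process, "dispersal_limitation")
  expect_equal(cl2$groups$verdict, "stochasticity")
})
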