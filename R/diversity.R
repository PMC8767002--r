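#' Per-sample alpha diversity
#'
#' Four metrics are supported:
#' \describe{
#'   \item{observed_species}{number of OTUs with positive count}
#'   \item{chao1}{bias-corrected Chao1 richness,
#'     `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` with `F1` singletons and `F2`
#'     doubletons; defined even when a sample has no doubletons}
#'   \item{shannon}{`-sum p_i log(p_i)` over OTUs with positive
#'     abundance; base-2 logarithm by default (bits)}
#'   \item{faith_pd}{Faith's phylogenetic diversity: total branch length
#'     of the minimal rooted subtree spanning the sample's OTUs}
#' }
#'
#' @param x an `otu_table`
#' @param metric one of `"observed_species"`, `"chao1"`, `"shannon"`,
#'   `"faith_pd"`, or `"all"`
#' @param tree [ape::phylo], required for `faith_pd`
#' @param base logarithm base for Shannon (default 2)
#' @return data.frame with `sample_id` and one column per requested metric
#' @export
alpha_diversity <- function(x, metric = "all", tree = NULL, base = 2) {
  stopifnot(inherits(x, "otu_table"))
  metrics <- c("observed_species", "chao1", "shannon", "faith_pd")
  metric <- match.arg(metric, c(metrics, "all"))
  want <- if (metric == "all") {
    if (is.null(tree)) metrics[1:3] else metrics
  } else metric
  if ("faith_pd" %in% want && is.null(tree))
    stop("faith_pd requires a phylogeny")
  counts <- x$counts
  out <- data.frame(sample_id = rownames(counts), stringsAsFactors = FALSE)
  if ("observed_species" %in% want)
    out$observed_species <- rowSums(counts > 0)
  if ("chao1" %in% want)
    out$chao1 <- apply(counts, 1, chao1)
  if ("shannon" %in% want)
    out$shannon <- apply(counts, 1, shannon, base = base)
  if ("faith_pd" %in% want) {
    m <- match_tree_table(x, tree)
    pd <- apply(m$table$counts, 1, function(cnt)
      faith_pd(colnames(m$table$counts)[cnt > 0], m$tree))
    out$faith_pd <- pd[match(out$sample_id, rownames(m$table$counts))]
  }
  rownames(out) <- NULL
  out
}

#' Bias-corrected Chao1 estimator for one sample
#' @param counts integer vector of OTU counts
#' @return estimated richness (>= observed richness)
#' @export
chao1 <- function(counts) {
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Shannon index for one sample
#' @param counts numeric vector of counts or proportions
#' @param base logarithm base (default 2)
#' @return Shannon entropy
#' @export
shannon <- function(counts, base = 2) {
  p <- counts[counts > 0]
  p <- p / sum(p)
  -sum(p * log(p, base = base))
}

#' Faith's phylogenetic diversity of a taxon set
#'
#' Total branch length of the minimal subtree connecting the given tips
#' to the root (root-inclusive, the QIIME convention: a single-tip
#' community has PD equal to its root-to-tip distance).
#'
#' @param tips character vector of tip labels present in the community
#' @param tree [ape::phylo]
#' @return summed branch length
#' @export
faith_pd <- function(tips, tree) {
  validate_tree(tree)
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx))
    stop("tips absent from tree: ",
         paste(tips[is.na(idx)], collapse = ", "))
  if (!length(idx)) return(0)
  # walk from each tip to the root, marking edges on the way
  parent <- tree$edge[, 1]; child <- tree$edge[, 2]
  up <- integer(max(tree$edge))        # edge index leading into each node
  up[child] <- seq_along(child)
  on_path <- logical(nrow(tree$edge))
  for (node in idx) {
    while (node != ape::Ntip(tree) + 1L) {   # root node id
      e <- up[node]
      if (e == 0L || on_path[e]) break
      on_path[e] <- TRUE
      node <- parent[e]
    }
  }
  sum(tree$edge.length[on_path])
}

#' Pairwise community distance matrix
#'
#' Bray-Curtis is computed on per-sample relative abundances
#' (`sum |p - q| / sum (p + q)`); Jaccard on presence/absence
#' (`1 - |intersection| / |union|`).
#'
#' @param x an `otu_table`
#' @param metric `"bray_curtis"` or `"jaccard"`
#' @return symmetric matrix with zero diagonal, entries in `[0, 1]`,
#'   attribute `metric` set; sample ids as dimnames
#' @export
distance_matrix <- function(x, metric = c("bray_curtis", "jaccard")) {
  stopifnot(inherits(x, "otu_table"))
  metric <- match.arg(metric)
  if (nrow(x$counts) < 2) stop("need at least 2 samples")
  d <- if (metric == "bray_curtis") {
    rel <- to_relative_abundance(x)
    vegan::vegdist(unclass(rel), method = "bray")
  } else {
    vegan::vegdist(x$counts > 0, method = "jaccard", binary = TRUE)
  }
  m <- as.matrix(d)
  diag(m) <- 0
  attr(m, "metric") <- metric
  m
}

#' Non-metric multidimensional scaling of a distance matrix
#'
#' Kruskal stress-1 NMDS with multiple random restarts; the best
#' configuration is returned. Deterministic for a fixed seed.
#'
#' @param d symmetric distance matrix
#' @param k target dimension (default 2)
#' @param seed integer RNG seed
#' @param trymax random restarts
#' @return list with `points` (n x k coordinates) and `stress`
#'   (Kruskal stress-1, fraction in `[0, 1]`)
#' @export
nmds <- function(d, k = 2, seed = 1, trymax = 20) {
  d <- as.matrix(d)
  if (nrow(d) < k + 2) stop("need at least k + 2 samples")
  if (all(d == 0)) stop("degenerate (all-zero) distance matrix")
  fit <- with_seed(seed, suppressWarnings(
    vegan::metaMDS(stats::as.dist(d), k = k, trymax = trymax, trace = 0,
                   autotransform = FALSE, wascores = FALSE)))
  list(points = fit$points, stress = fit$stress)
}

#' PERMANOVA on a distance matrix
#'
#' Distance-based pseudo-F partition with free permutation of raw sample
#' labels. With two factors the crossed model `d ~ a * b` is fitted and
#' main effects plus the interaction are reported term by term.
#'
#' @param d symmetric distance matrix with sample ids as dimnames
#' @param metadata data.frame with `sample_id` and the factor columns
#' @param factors character vector of one or two metadata columns
#' @param n_perm permutations (default 999)
#' @param seed integer RNG seed
#' @return data.frame with columns `term`, `statistic` (pseudo-F),
#'   `p_value`, `n_perm`, `seed`
#' @export
permanova <- function(d, metadata, factors, n_perm = 999, seed = 1) {
  d <- as.matrix(d)
  md <- metadata[match(rownames(d), metadata$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id)) stop("metadata does not cover all samples in d")
  for (f in factors) {
    lv <- table(md[[f]])
    if (any(lv < 2))
      stop("factor '", f, "' has singleton level(s): ",
           paste(names(lv)[lv < 2], collapse = ", "))
  }
  rhs <- paste(factors, collapse = " * ")
  form <- stats::as.formula(paste("stats::as.dist(d) ~", rhs))
  dat <- md
  fit <- with_seed(seed,
    vegan::adonis2(form, data = dat, permutations = n_perm, by = "terms"))
  terms <- rownames(fit)
  keep <- !terms %in% c("Residual", "Total")
  data.frame(term = terms[keep],
             statistic = fit$F[keep],
             p_value = fit$`Pr(>F)`[keep],
             n_perm = n_perm, seed = seed,
             stringsAsFactors = FALSE)
}

#' ANOSIM on a distance matrix
#'
#' R statistic `(mean between-group rank - mean within-group rank) /
#' (n(n-1)/4)` with a label-permutation p-value.
#'
#' @inheritParams permanova
#' @param grouping metadata column (or a vector of labels aligned with
#'   the rows of `d`)
#' @return one-row data.frame `term`, `statistic` (R), `p_value`,
#'   `n_perm`, `seed`
#' @export
anosim <- function(d, grouping, metadata = NULL, n_perm = 999, seed = 1) {
  d <- as.matrix(d)
  g <- if (length(grouping) == 1 && !is.null(metadata))
    metadata[[grouping]][match(rownames(d), metadata$sample_id)]
  else grouping
  tab <- table(g)
  if (length(tab) < 2 || any(tab < 2))
    stop("anosim needs >= 2 groups with >= 2 samples each")
  fit <- with_seed(seed, vegan::anosim(stats::as.dist(d), grouping = factor(g),
                                       permutations = n_perm))
  data.frame(term = "grouping", statistic = unname(fit$statistic),
             p_value = fit$signif, n_perm = n_perm, seed = seed,
             stringsAsFactors = FALSE)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal entries with significance by
#' simultaneous row/column permutation of one matrix.
#'
#' @param d1,d2 symmetric distance matrices over the same samples
#' @param n_perm permutations
#' @param seed integer RNG seed
#' @return one-row data.frame `term`, `statistic` (r), `p_value`,
#'   `n_perm`, `seed`
#' @export
mantel <- function(d1, d2, n_perm = 999, seed = 1) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (!identical(dim(d1), dim(d2)))
    stop("distance matrices differ in size")
  if (!is.null(rownames(d1)) && !is.null(rownames(d2))) {
    if (!setequal(rownames(d1), rownames(d2)))
      stop("distance matrices cover different samples")
    d2 <- d2[rownames(d1), rownames(d1)]
  }
  fit <- with_seed(seed, vegan::mantel(stats::as.dist(d1), stats::as.dist(d2),
                                       method = "pearson", permutations = n_perm))
  data.frame(term = "mantel", statistic = unname(fit$statistic),
             p_value = fit$signif, n_perm = n_perm, seed = seed,
             stringsAsFactors = FALSE)
}
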