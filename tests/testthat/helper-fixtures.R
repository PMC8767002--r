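# shared fixture builders; everything is generated in code at test time

toy_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

star_tree <- function(n = 4) {
  ape::read.tree(text = paste0("(", paste0(LETTERS[1:n], ":1",
                                           collapse = ","), ");"))
}

toy_table <- function(counts = NULL, groups = NULL) {
  if (is.null(counts)) {
    counts <- rbind(s1 = c(A = 5, B = 3, C = 2),
                    s2 = c(A = 1, B = 6, C = 3))
  }
  md <- data.frame(sample_id = rownames(counts),
                   group = if (is.null(groups)) "all" else groups,
                   stringsAsFactors = FALSE)
  otu_table(counts, md)
}

random_table <- function(n_samples, n_otus, seed = 1, lambda = 5,
                         groups = NULL) {
  set.seed(seed)
  counts <- matrix(stats::rpois(n_samples * n_otus, lambda), n_samples,
                   dimnames = list(paste0("s", seq_len(n_samples)),
                                   paste0("o", seq_len(n_otus))))
  counts[rowSums(counts) == 0, 1] <- 1
  md <- data.frame(sample_id = rownames(counts),
                   group = if (is.null(groups)) "all" else groups,
                   stringsAsFactors = FALSE)
  otu_table(counts, md)
}

# memoized medium study bundle shared by slower tests
.fixture_env <- new.env(parent = emptyenv())
cached_study <- function() {
  if (is.null(.fixture_env$study))
    .fixture_env$study <- simulate_study(n_otus = 400, n_replicates = 4,
                                         depth = 5000, seed = 42)
  .fixture_env$study
}

# graded block-structured correlation matrix for the RMT scan:
# three blocks whose internal correlations range over (lo, hi) on a
# weak noisy background, so the adjacency evolves along the scan
block_correlation <- function(seed = 1, n_blocks = 3, bsize = 30,
                              bg_sd = 0.12, lo = 0.5, hi = 0.95) {
  set.seed(seed)
  n <- n_blocks * bsize
  corr <- matrix(stats::rnorm(n * n, 0, bg_sd), n, n)
  for (b in seq_len(n_blocks) - 1) {
    i <- b * bsize + seq_len(bsize)
    corr[i, i] <- matrix(stats::runif(bsize^2, lo, hi), bsize, bsize)
  }
  corr <- (corr + t(corr)) / 2
  corr <- pmin(pmax(corr, -0.999), 0.999)
  diag(corr) <- 1
  dimnames(corr) <- list(paste0("O", 1:n), paste0("O", 1:n))
  corr
}
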