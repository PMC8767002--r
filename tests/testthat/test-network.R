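test_that("prevalence filter and zero fill follow the stated policy", {
  counts <- matrix(0L, 8, 3, dimnames = list(paste0("s", 1:8),
                                             c("rare", "mid", "common")))
  counts[1:2, "rare"] <- 5L
  counts[1:4, "mid"] <- 5L
  counts[, "common"] <- 10L
  tab <- otu_table(counts)
  m <- prepare_abundance_matrix(tab, min_prevalence = 0.5)
  expect_setequal(colnames(m), c("mid", "common"))   # 2/8 dropped
  m0 <- prepare_abundance_matrix(tab, min_prevalence = 0)
  expect_setequal(colnames(m0), c("rare", "mid", "common"))
  expect_error(prepare_abundance_matrix(tab, min_prevalence = 1.01),
               "no OTU")
  # zeros filled below the smallest observed value, then log10
  expect_true(all(is.finite(m)))
  tab2 <- random_table(8, 50, seed = 3, lambda = 1)
  keep_ref <- colnames(tab2$counts)[colMeans(tab2$counts > 0) >= 0.5]
  expect_setequal(colnames(prepare_abundance_matrix(tab2, 0.5)), keep_ref)
})

test_that("correlation matrix matches the textbook formula", {
  x <- c(1, 2, 4); y <- c(2, 1, 7); z <- c(1, 5, 9)
  mat <- cbind(o1 = x, o2 = y, o3 = z)
  cm <- correlation_matrix(mat)
  pearson <- function(a, b)
    sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(cm["o1", "o2"], pearson(x, y))
  expect_equal(cm["o1", "o3"], pearson(x, z))
  expect_equal(diag(cm), c(o1 = 1, o2 = 1, o3 = 1))
  expect_equal(correlation_matrix(cbind(a = x, b = -x))["a", "b"], -1)
  expect_warning(correlation_matrix(cbind(a = x, flat = c(1, 1, 1))),
                 "zero-variance")
})

test_that("RMT scan separates planted blocks and idles on noise", {
  corr <- block_correlation(seed = 1)
  r <- rmt_threshold(corr)
  bg_max <- max(abs(corr[1:30, 31:90]))
  expect_gt(r$st, bg_max)         # above every background correlation
  expect_lt(r$st, 0.95)           # below the strongest block links
  # stability rule: accepted threshold starts >= 3 consecutive fits
  i <- match(r$st, r$trace$threshold)
  expect_true(all(r$trace$poisson_fit[i:(i + 2)]))

  set.seed(2)
  noise <- correlation_matrix(matrix(stats::rnorm(50 * 80), 50, 80,
    dimnames = list(NULL, paste0("O", 1:80))))
  rn <- rmt_threshold(noise)
  expect_lte(rn$st, 0.35)         # i.i.d. data: Poisson near scan start
  expect_error(rmt_threshold(corr, start = 0, end = 1), "within")
})

test_that("network construction keeps signs and exact edge counts", {
  corr <- matrix(c(1, 0.9, -0.9, 0.1,
                   0.9, 1, 0.2, 0.05,
                   -0.9, 0.2, 1, 0.3,
                   0.1, 0.05, 0.3, 1), 4, 4,
                 dimnames = list(paste0("O", 1:4), paste0("O", 1:4)))
  net <- build_network(corr, 0.8)
  g <- net$graph
  expect_equal(igraph::ecount(g), 2)
  e12 <- igraph::E(g)[igraph::V(g)["O1"] %--% igraph::V(g)["O2"]]
  e13 <- igraph::E(g)[igraph::V(g)["O1"] %--% igraph::V(g)["O3"]]
  expect_equal(e12$sign, 1)
  expect_equal(e13$sign, -1)
  expect_false("O4" %in% igraph::V(g)$name)   # isolated node dropped
  expect_error(build_network(corr, 0.99), "empty edge set")

  corr2 <- block_correlation(seed = 5)
  net2 <- build_network(corr2, 0.6)
  ref_edges <- sum(abs(corr2[upper.tri(corr2)]) >= 0.6)
  expect_equal(igraph::ecount(net2$graph), ref_edges)
})

test_that("fast-greedy modules recover planted cliques; modularity by hand", {
  g <- igraph::make_full_graph(5) + igraph::make_full_graph(5)
  g <- igraph::add_edges(g, c(1, 6))
  igraph::V(g)$name <- paste0("O", 1:10)
  net <- structure(list(graph = g, st = 0.5), class = "eco_network")
  mod <- detect_modules(net)
  expect_equal(mod$n_modules, 2)
  expect_equal(unname(mod$membership[1:5]), rep(mod$membership[["O1"]], 5))
  expect_equal(unname(mod$membership[6:10]), rep(mod$membership[["O6"]], 5))
  # hand evaluation of M = sum(e_ii - a_i^2)
  m_edges <- igraph::ecount(g)
  e_in <- c(10, 10) / m_edges
  a <- c(21, 21) / (2 * m_edges)     # summed degrees per module
  expect_equal(mod$modularity, sum(e_in - a^2))

  full <- igraph::make_full_graph(8)
  igraph::V(full)$name <- paste0("O", 1:8)
  mfull <- detect_modules(structure(list(graph = full, st = 0.5),
                                    class = "eco_network"))
  expect_lte(mfull$modularity, 0.05)
  expect_error(detect_modules(structure(
    list(graph = igraph::make_empty_graph(1), st = 0.5),
    class = "eco_network")), "fewer than 2")
})

test_that("topology indices match closed forms on rings, stars and power laws", {
  ring <- igraph::make_ring(10)
  igraph::V(ring)$name <- paste0("O", 1:10)
  t_ring <- topology_indices(structure(list(graph = ring, st = 0.5),
                                       class = "eco_network"))
  expect_equal(t_ring$avg_k, 2)
  expect_equal(t_ring$avg_cc, 0)
  expect_equal(t_ring$edges * 2 / t_ring$nodes, t_ring$avg_k)

  n <- 9
  star <- igraph::make_star(n, mode = "undirected")
  igraph::V(star)$name <- paste0("O", 1:n)
  t_star <- topology_indices(structure(list(graph = star, st = 0.5),
                                       class = "eco_network"))
  # closed form: (n-1) centre-leaf pairs at 1, C(n-1,2) leaf pairs at 2
  ref <- ((n - 1) + 2 * choose(n - 1, 2)) / choose(n, 2)
  expect_equal(t_star$avg_path, ref)
  expect_equal(t_star$avg_cc, 0)

  # exact power-law degree histogram: R^2 = 1
  degs <- rep(c(1, 2, 4, 8), times = c(64, 16, 4, 1))
  expect_equal(miceco:::power_law_r2(degs), 1, tolerance = 1e-9)
})

test_that("rewired baselines preserve the degree multiset exactly", {
  corr <- block_correlation(seed = 7)
  net <- build_network(corr, 0.6)
  rb <- random_network_baseline(net, n_random = 20, seed = 1)
  expect_setequal(rb$index, c("avg_cc", "avg_path", "modularity",
                              "power_law_r2"))
  expect_true(all(is.finite(rb$random_mean)))
  # modular planted structure stands out from its degree-preserving null
  m <- rb[rb$index == "modularity", ]
  expect_gt(m$observed, m$random_mean + 2 * m$random_sd)

  clique <- igraph::make_full_graph(6)
  igraph::V(clique)$name <- paste0("O", 1:6)
  cnet <- structure(list(graph = clique, st = 0.5), class = "eco_network")
  rb2 <- random_network_baseline(cnet, n_random = 5, seed = 2)
  expect_true(all(rb2$random_sd[rb2$index != "power_law_r2"] == 0))
})

test_that("Zi-Pi roles follow the quadrant rule with strict boundaries", {
  eps <- 1e-9
  grid <- expand.grid(zi = c(2.5 - eps, 2.5, 2.5 + eps),
                      pi = c(0.6 - eps, 0.6, 0.6 + eps))
  ref <- function(z, p) {
    if (z > 2.5 && p > 0.6) return("network_hub")
    if (z > 2.5) return("module_hub")
    if (p > 0.6) return("connector")
    "peripheral"
  }
  expect_equal(role_from_zp(grid$zi, grid$pi),
               mapply(ref, grid$zi, grid$pi), ignore_attr = TRUE)
})

test_that("Zi and Pi come out right on constructed graphs", {
  # centre node linked once into each of four triangles: Pi = 0.75
  g <- igraph::make_full_graph(3) + igraph::make_full_graph(3) +
       igraph::make_full_graph(3) + igraph::make_full_graph(3)
  g <- igraph::add_vertices(g, 1)
  g <- igraph::add_edges(g, c(13, 1, 13, 4, 13, 7, 13, 10))
  igraph::V(g)$name <- paste0("O", 1:13)
  net <- structure(list(graph = g, st = 0.5), class = "eco_network")
  memb <- c(rep(1:4, each = 3), 5)
  names(memb) <- igraph::V(g)$name
  roles <- node_roles(net, modules = list(membership = memb))
  centre <- roles[roles$node == "O13", ]
  expect_equal(centre$pi, 1 - 4 * (1 / 16))
  expect_equal(centre$zi, 0)    # single-node module: sd undefined -> 0
  expect_equal(centre$role, "connector")
  inner <- roles[roles$node == "O2", ]   # all links inside its module
  expect_equal(inner$pi, 0)
  expect_equal(inner$role, "peripheral")

  # star hub inside one module: Zi large, Pi = 0 -> module hub
  star <- igraph::make_star(9, mode = "undirected", center = 1)
  star <- star + igraph::make_full_graph(3)
  igraph::V(star)$name <- paste0("O", 1:12)
  net2 <- structure(list(graph = star, st = 0.5), class = "eco_network")
  memb2 <- c(rep(1, 9), rep(2, 3)); names(memb2) <- igraph::V(star)$name
  roles2 <- node_roles(net2, modules = list(membership = memb2))
  hub <- roles2[roles2$node == "O1", ]
  expect_gt(hub$zi, 2.5)
  expect_equal(hub$pi, 0)
  expect_equal(hub$role, "module_hub")
})

test_that("network composition tallies phyla and edge signs exactly", {
  corr <- block_correlation(seed = 9)
  net <- build_network(corr, 0.6)
  tax <- data.frame(otu_id = paste0("O", 1:90),
                    phylum = rep(c("Ph_A", "Ph_B", "Ph_C"), each = 30))
  comp <- network_composition(net, tax)
  expect_equal(sum(comp$phyla$fraction), 1)
  sgn <- igraph::E(net$graph)$sign
  expect_equal(comp$edges$n_positive, sum(sgn > 0))
  expect_equal(comp$edges$n_negative, sum(sgn < 0))
  one <- network_composition(net, transform(tax, phylum = "OnlyOne"))
  expect_equal(one$phyla$fraction, 1)
  # unmapped nodes fall back to Unclassified
  comp2 <- network_composition(net, tax[1:10, ])
  expect_true("Unclassified" %in% comp2$phyla$phylum)
})

test_that("network export writes edge list, node table and GraphML", {
  corr <- block_correlation(seed = 11)
  net <- build_network(corr, 0.6)
  dir <- tempfile("net_")
  paths <- export_network(net, dir,
                          taxonomy = data.frame(otu_id = paste0("O", 1:90),
                                                phylum = "P"))
  expect_true(all(file.exists(paths)))
  el <- utils::read.table(paths["edges"], header = TRUE, sep = "\t")
  expect_equal(nrow(el), igraph::ecount(net$graph))
  nt <- utils::read.table(paths["nodes"], header = TRUE, sep = "\t")
  expect_setequal(nt$node, igraph::V(net$graph)$name)
})
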