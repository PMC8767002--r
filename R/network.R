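#' Prevalence-filter and log-transform abundances for network inference
#'
#' Keeps OTUs present in at least `min_prevalence` of the samples,
#' converts to relative abundance, fills zeros with a small value
#' (`zero_fill` times the smallest retained nonzero relative abundance)
#' and log10-transforms — the preprocessing conventionally applied
#' before correlation-based ecological network construction.
#'
#' @param x an `otu_table` (one group's samples; at least 5 recommended)
#' @param min_prevalence fraction of samples an OTU must appear in
#'   (default 0.5)
#' @param zero_fill multiplier for the zero replacement (default 0.01)
#' @return samples x OTUs matrix of log10 relative abundances
#' @export
prepare_abundance_matrix <- function(x, min_prevalence = 0.5,
                                     zero_fill = 0.01) {
  stopifnot(inherits(x, "otu_table"))
  rel <- unclass(to_relative_abundance(x))
  prev <- colMeans(rel > 0)
  keep <- prev >= min_prevalence & prev > 0
  if (!any(keep)) stop("no OTU passes the prevalence filter")
  rel <- rel[, keep, drop = FALSE]
  tiny <- zero_fill * min(rel[rel > 0])
  rel[rel == 0] <- tiny
  log10(rel)
}

#' Pearson correlation matrix between OTUs
#'
#' @param mat prepared abundance matrix (samples x OTUs), e.g. from
#'   [prepare_abundance_matrix()]
#' @return symmetric correlation matrix with unit diagonal;
#'   zero-variance OTUs are dropped with a warning
#' @export
correlation_matrix <- function(mat) {
  if (nrow(mat) < 3) stop("need at least 3 samples for correlations")
  v <- apply(mat, 2, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance OTU(s) dropped")
    mat <- mat[, v > 0, drop = FALSE]
  }
  stats::cor(mat)
}

# nearest-neighbour spacing distribution of the adjacency spectrum at one
# threshold; returns the chi-square GOF p-value against the Poisson form
# exp(-s), or NA when the spectrum is too small to test
nnsd_poisson_p <- function(adj, n_bins = 20, s_max = 3, min_eigen = 20) {
  ev <- eigen(adj, symmetric = TRUE, only.values = TRUE)$values
  ev <- sort(ev)
  ev <- ev[c(TRUE, diff(ev) > 1e-8)]          # drop degenerate eigenvalues
  n <- length(ev)
  if (n < min_eigen) return(NA_real_)
  # spectral unfolding: smooth the cumulative density, map eigenvalues to
  # uniform mean spacing 1
  cum <- (seq_len(n) - 0.5) / n
  sm <- stats::smooth.spline(ev, cum, df = min(10, max(4, n / 10)))
  unfolded <- n * stats::predict(sm, ev)$y
  sp <- diff(unfolded)
  sp <- sp[sp >= 0]
  if (length(sp) < n_bins) return(NA_real_)
  sp <- sp / mean(sp)
  sp <- sp[sp <= s_max]
  if (length(sp) < n_bins) return(NA_real_)
  breaks <- seq(0, s_max, length.out = n_bins + 1)
  obs_cnt <- tabulate(cut(sp, breaks, include.lowest = TRUE), nbins = n_bins)
  p_bin <- diff(-exp(-breaks))                # integral of e^-s per bin
  p_bin <- p_bin / sum(p_bin)
  exp_cnt <- length(sp) * p_bin
  keep <- exp_cnt > 0
  stat <- sum((obs_cnt[keep] - exp_cnt[keep])^2 / exp_cnt[keep])
  stats::pchisq(stat, df = sum(keep) - 1, lower.tail = FALSE)
}

#' Random-matrix-theory threshold scan
#'
#' For each candidate threshold the binary adjacency (`|corr| >=
#' threshold`) is built and the nearest-neighbour spacing distribution
#' of its eigenvalues, after spectral unfolding, is tested against the
#' Poisson form `exp(-s)` (chi-square goodness of fit). Random noise
#' produces Wigner-Dyson (GOE) spacing; modular biological signal
#' produces Poisson spacing, so the chosen threshold `st` is the
#' smallest at which the Poisson fit (p > 0.05) is achieved and persists
#' for `persist` consecutive thresholds.
#'
#' @param corr correlation matrix
#' @param start,end,step scan grid over `(0, 1)` (defaults 0.30 to 0.95
#'   by 0.01)
#' @param persist consecutive Poisson-fitting thresholds required before
#'   accepting (default 3)
#' @param p_cut goodness-of-fit cutoff (default 0.05)
#' @return list with `st` (selected threshold) and `trace` (data.frame
#'   `threshold`, `n_edges`, `p_poisson`, `poisson_fit`)
#' @export
rmt_threshold <- function(corr, start = 0.30, end = 0.95, step = 0.01,
                          persist = 3, p_cut = 0.05) {
  if (start <= 0 || end >= 1 || start >= end) stop("scan range must be within (0, 1)")
  grid <- seq(start, end, by = step)
  ac <- abs(corr); diag(ac) <- 0
  trace <- data.frame(threshold = grid, n_edges = NA_integer_,
                      p_poisson = NA_real_, poisson_fit = FALSE)
  run <- 0L; st <- NA_real_
  for (i in seq_along(grid)) {
    adj <- (ac >= grid[i]) * 1
    trace$n_edges[i] <- sum(adj) / 2
    p <- nnsd_poisson_p(adj)
    trace$p_poisson[i] <- p
    fit <- !is.na(p) && p > p_cut
    trace$poisson_fit[i] <- fit
    run <- if (fit) run + 1L else 0L
    if (is.na(st) && run >= persist) {
      st <- grid[i - persist + 1L]
      break
    }
  }
  if (is.na(st))
    stop("no threshold in [", start, ", ", end,
         "] reaches a stable Poisson spacing fit; widen the scan range")
  list(st = st, trace = trace[!is.na(trace$n_edges), , drop = FALSE])
}

#' Build a signed co-occurrence network from a correlation matrix
#'
#' An edge joins two OTUs when `|corr| >= st`; the edge sign is the sign
#' of the correlation. Isolated nodes are dropped.
#'
#' @param corr correlation matrix with OTU dimnames
#' @param st threshold in `(0, 1)`
#' @return an `eco_network`: list with `graph` (an [igraph] graph with
#'   edge attributes `weight` = correlation and `sign`) and `st`
#' @export
build_network <- function(corr, st) {
  if (!(st > 0 && st < 1)) stop("st must be in (0, 1)")
  ac <- abs(corr); diag(ac) <- 0
  adj <- (ac >= st) * 1
  if (!any(adj > 0)) stop("empty edge set at threshold ", st)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  ends <- igraph::as_edgelist(g)
  w <- corr[cbind(ends[, 1], ends[, 2])]
  igraph::E(g)$weight <- w
  igraph::E(g)$sign <- ifelse(w >= 0, 1L, -1L)
  g <- igraph::delete_vertices(g, igraph::degree(g) == 0)
  structure(list(graph = g, st = st), class = "eco_network")
}

#' @export
print.eco_network <- function(x, ...) {
  cat(sprintf("eco_network: %d nodes, %d edges (st = %.2f)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph), x$st))
  invisible(x)
}

#' Fast-greedy module detection
#'
#' Agglomerative modularity maximization on the unsigned skeleton of the
#' network. Components are handled natively; the returned modularity is
#' that of the final partition.
#'
#' @param net an `eco_network`
#' @return list with `membership` (named integer vector),
#'   `modularity`, `n_modules`, `sizes`
#' @export
detect_modules <- function(net) {
  g <- net$graph
  if (igraph::vcount(g) < 2) stop("network has fewer than 2 nodes")
  gu <- if ("weight" %in% igraph::edge_attr_names(g))
    igraph::delete_edge_attr(g, "weight") else g   # unsigned, unweighted
  cm <- igraph::cluster_fast_greedy(gu)
  memb <- igraph::membership(cm)
  list(membership = stats::setNames(as.integer(memb), names(memb)),
       modularity = igraph::modularity(gu, memb),
       n_modules = length(unique(memb)),
       sizes = as.integer(sort(table(memb), decreasing = TRUE)))
}

# least-squares R^2 of log10 frequency on log10 degree
power_law_r2 <- function(degrees) {
  tab <- table(degrees[degrees >= 1])
  if (length(tab) < 3) return(NA_real_)
  xd <- log10(as.numeric(names(tab)))
  yd <- log10(as.numeric(tab))
  fit <- stats::lm(yd ~ xd)
  suppressWarnings(summary(fit)$r.squared)   # exact fits are legitimate here
}

#' Topology indices of a network
#'
#' @param net an `eco_network`
#' @param modules optional result of [detect_modules()] (computed when
#'   missing)
#' @return one-row data.frame: `nodes`, `edges`, `avg_k` (= 2E/N),
#'   `power_law_r2` (log-log degree-distribution fit), `avg_cc` (mean
#'   local clustering coefficient), `avg_path` (mean geodesic over the
#'   largest connected component), `modularity`, `n_modules`,
#'   `largest_module`
#' @export
topology_indices <- function(net, modules = NULL) {
  g <- net$graph
  n <- igraph::vcount(g); e <- igraph::ecount(g)
  if (n == 0) stop("empty network")
  if (is.null(modules)) modules <- detect_modules(net)
  comp <- igraph::components(g)
  big <- igraph::induced_subgraph(g, which(comp$membership ==
                                             which.max(comp$csize)))
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  data.frame(nodes = n, edges = e, avg_k = 2 * e / n,
             power_law_r2 = power_law_r2(igraph::degree(g)),
             avg_cc = mean(cc),
             avg_path = igraph::mean_distance(big, directed = FALSE,
                                              weights = NA),
             modularity = modules$modularity,
             n_modules = modules$n_modules,
             largest_module = modules$sizes[1])
}

#' Degree-preserving random-network baseline
#'
#' Rewires the network with Maslov-Sneppen double-edge swaps (at least
#' `10 * E` swap attempts per replicate; the degree sequence is
#' preserved exactly and asserted on every replicate), recomputes the
#' topology indices, and reports their null mean, sd and the z-score of
#' the empirical value.
#'
#' @param net an `eco_network`
#' @param n_random replicates (default 100)
#' @param seed integer RNG seed
#' @param swap_factor swap attempts per edge (default 10)
#' @return data.frame with one row per index: `index`, `observed`,
#'   `random_mean`, `random_sd`, `z`
#' @export
random_network_baseline <- function(net, n_random = 100, seed = 1,
                                    swap_factor = 10) {
  g <- net$graph
  if (igraph::ecount(g) < 2) stop("graph too sparse to rewire")
  deg0 <- sort(igraph::degree(g))
  idx <- c("avg_cc", "avg_path", "modularity", "power_law_r2")
  obs <- topology_indices(net)
  vals <- with_seed(seed, {
    vapply(seq_len(n_random), function(r) {
      gr <- igraph::rewire(g, igraph::keeping_degseq(
        niter = swap_factor * igraph::ecount(g)))
      stopifnot(identical(sort(igraph::degree(gr)), deg0))
      ti <- topology_indices(structure(list(graph = gr, st = net$st),
                                       class = "eco_network"))
      unlist(ti[idx])
    }, numeric(length(idx)))
  })
  mu <- rowMeans(vals); sdv <- apply(vals, 1, stats::sd)
  data.frame(index = idx, observed = unlist(obs[idx]),
             random_mean = mu, random_sd = sdv,
             z = (unlist(obs[idx]) - mu) / ifelse(sdv == 0, NA, sdv),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Zi-Pi node roles
#'
#' `Zi` is the within-module degree z-score, `Pi = 1 - sum_s
#' (k_is / k_i)^2` the among-module connectivity. Roles: peripheral
#' (`Zi < 2.5, Pi < 0.6`), module hub (`Zi > 2.5, Pi < 0.6`), connector
#' (`Zi < 2.5, Pi > 0.6`), network hub (`Zi > 2.5, Pi > 0.6`). Values
#' exactly at a threshold take the lower tier (strict inequalities).
#'
#' @param net an `eco_network`
#' @param modules result of [detect_modules()] (computed when missing)
#' @return data.frame `node`, `module`, `degree`, `zi`, `pi`, `role`
#' @export
node_roles <- function(net, modules = NULL) {
  g <- net$graph
  if (is.null(modules)) modules <- detect_modules(net)
  memb <- modules$membership[igraph::V(g)$name]
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  k <- rowSums(adj)
  mods <- sort(unique(memb))
  k_by_mod <- vapply(mods, function(m)
    rowSums(adj[, memb == m, drop = FALSE]), numeric(length(k)))
  colnames(k_by_mod) <- mods
  k_within <- k_by_mod[cbind(seq_along(k), match(memb, mods))]
  zi <- numeric(length(k))
  for (m in mods) {
    in_m <- memb == m
    mu <- mean(k_within[in_m]); sdv <- stats::sd(k_within[in_m])
    zi[in_m] <- if (is.na(sdv) || sdv == 0) 0 else (k_within[in_m] - mu) / sdv
  }
  pi <- 1 - rowSums((k_by_mod / k)^2)
  role <- role_from_zp(zi, pi)
  data.frame(node = igraph::V(g)$name, module = unname(memb),
             degree = unname(k), zi = unname(zi), pi = unname(pi),
             role = role, row.names = NULL, stringsAsFactors = FALSE)
}

#' Node role from Zi and Pi
#'
#' The four-quadrant rule with strict inequalities at `Zi = 2.5` and
#' `Pi = 0.6`; a value exactly on a threshold takes the lower tier.
#'
#' @param zi within-module degree z-score(s)
#' @param pi among-module connectivity value(s) in `[0, 1]`
#' @return character vector of roles
#' @export
role_from_zp <- function(zi, pi) {
  ifelse(zi > 2.5 & pi > 0.6, "network_hub",
  ifelse(zi > 2.5, "module_hub",
  ifelse(pi > 0.6, "connector", "peripheral")))
}

#' Phylum composition and edge-sign tally of a network
#'
#' @param net an `eco_network`
#' @param taxonomy data.frame `otu_id`, `phylum` (nodes missing from the
#'   map are reported as `"Unclassified"`)
#' @param modules optional [detect_modules()] result for the
#'   largest-module breakdown
#' @return list with `phyla` (data.frame `phylum`, `n_nodes`,
#'   `fraction`), `edges` (`n_positive`, `n_negative`,
#'   `prop_negative`), and `largest_module_phyla`
#' @export
network_composition <- function(net, taxonomy, modules = NULL) {
  g <- net$graph
  nodes <- igraph::V(g)$name
  ph <- taxonomy$phylum[match(nodes, taxonomy$otu_id)]
  ph[is.na(ph)] <- "Unclassified"
  tab <- sort(table(ph), decreasing = TRUE)
  phyla <- data.frame(phylum = names(tab), n_nodes = as.integer(tab),
                      fraction = as.integer(tab) / length(nodes),
                      stringsAsFactors = FALSE)
  sgn <- igraph::E(g)$sign
  edges <- data.frame(n_positive = sum(sgn > 0), n_negative = sum(sgn < 0))
  edges$prop_negative <- edges$n_negative / (edges$n_positive + edges$n_negative)
  if (is.null(modules)) modules <- detect_modules(net)
  big_mod <- names(sort(table(modules$membership), decreasing = TRUE))[1]
  in_big <- nodes[modules$membership[nodes] == as.integer(big_mod)]
  phb <- taxonomy$phylum[match(in_big, taxonomy$otu_id)]
  phb[is.na(phb)] <- "Unclassified"
  tb <- sort(table(phb), decreasing = TRUE)
  list(phyla = phyla, edges = edges,
       largest_module_phyla = data.frame(
         phylum = names(tb), n_nodes = as.integer(tb),
         fraction = as.integer(tb) / length(in_big),
         stringsAsFactors = FALSE))
}

#' Export a network as a signed edge list and node table
#'
#' @param net an `eco_network`
#' @param dir output directory
#' @param taxonomy optional taxonomy for the node table
#' @param prefix file-name prefix
#' @return named vector of written paths (edge list TSV, node TSV,
#'   GraphML)
#' @export
export_network <- function(net, dir, taxonomy = NULL, prefix = "network") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- net$graph
  ends <- igraph::as_edgelist(g)
  el <- data.frame(source = ends[, 1], target = ends[, 2],
                   correlation = igraph::E(g)$weight,
                   sign = igraph::E(g)$sign, stringsAsFactors = FALSE)
  modules <- detect_modules(net)
  roles <- node_roles(net, modules)
  if (!is.null(taxonomy))
    roles$phylum <- {
      p <- taxonomy$phylum[match(roles$node, taxonomy$otu_id)]
      ifelse(is.na(p), "Unclassified", p)
    }
  paths <- c(edges = file.path(dir, paste0(prefix, "_edges.tsv")),
             nodes = file.path(dir, paste0(prefix, "_nodes.tsv")),
             graphml = file.path(dir, paste0(prefix, ".graphml")))
  utils::write.table(el, paths["edges"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(roles, paths["nodes"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  igraph::write_graph(g, paths["graphml"], format = "graphml")
  paths
}
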