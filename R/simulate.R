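#' Simulate an ultrametric pure-birth phylogeny
#'
#' @param n_tips number of tips (>= 3)
#' @param seed integer RNG seed; identical seeds give identical trees
#' @param tip_prefix label prefix, tips are `OTU1 ... OTUn`
#' @return rooted ultrametric [ape::phylo] with positive branch lengths
#' @export
simulate_tree <- function(n_tips, seed = 1, tip_prefix = "OTU") {
  if (n_tips < 3) stop("n_tips must be >= 3")
  tr <- with_seed(seed, ape::rphylo(n_tips, birth = 1, death = 0))
  tr$tip.label <- paste0(tip_prefix, seq_len(n_tips))
  tr
}

#' Evolve a continuous habitat trait on a tree by Brownian motion
#'
#' @param tree [ape::phylo]
#' @param seed integer RNG seed
#' @param rate Brownian rate (variance per unit branch length)
#' @return named numeric vector of tip trait values
#' @export
simulate_trait <- function(tree, seed = 1, rate = 1) {
  with_seed(seed, ape::rTraitCont(tree, model = "BM", sigma = sqrt(rate)))
}

#' Build a metacommunity model
#'
#' The regional species pool has long-tailed log-normal abundances
#' (`exp(N(0, pool_sigma^2))`, normalized) and a Brownian habitat trait
#' per OTU; Gaussian environmental filtering on that trait is what the
#' selection scenarios act on.
#'
#' @param tree [ape::phylo] (e.g. from [simulate_tree()])
#' @param seed integer RNG seed
#' @param pool_sigma log-scale sd of the pool abundances (default 2,
#'   which spans the rare/abundant categorization thresholds)
#' @param trait_rate Brownian rate of the habitat trait (default 1)
#' @return list of class `metacommunity_model` with `tree`, `pool`
#'   (named, sums to 1), `trait` (named)
#' @export
metacommunity_model <- function(tree, seed = 1, pool_sigma = 2,
                                trait_rate = 1) {
  validate_tree(tree)
  n <- ape::Ntip(tree)
  pool <- with_seed(derive_seed(seed, 1),
                    exp(stats::rnorm(n, 0, pool_sigma)))
  pool <- pool / sum(pool)
  names(pool) <- tree$tip.label
  trait <- simulate_trait(tree, seed = derive_seed(seed, 2),
                          rate = trait_rate)
  structure(list(tree = tree, pool = pool, trait = trait),
            class = "metacommunity_model")
}

assembly_processes_vocab <- function() {
  c("homogeneous_selection", "heterogeneous_selection", "neutral_drift",
    "dispersal_limitation", "homogenizing_dispersal")
}

#' Classification label expected for a simulated scenario
#'
#' Maps a generator scenario label onto the label the betaNTI / RC-bray
#' classification should assign when it recovers the scenario. All
#' labels map to themselves except `neutral_drift`, whose signature is
#' the `undominated` tier (drift is one of its constituents: neither
#' selection nor dispersal signal exceeds the thresholds).
#'
#' @param process a scenario label (see [assembly_scenario()])
#' @return the corresponding classification label
#' @export
expected_process_label <- function(process) {
  if (!all(process %in% assembly_processes_vocab()))
    stop("unknown assembly process")
  ifelse(process == "neutral_drift", "undominated", process)
}

#' Describe an assembly scenario
#'
#' @param process one of `homogeneous_selection`,
#'   `heterogeneous_selection`, `neutral_drift`, `dispersal_limitation`,
#'   `homogenizing_dispersal`
#' @param n_samples samples to draw (default 12)
#' @param depth sequencing depth per sample (default 20000)
#' @param seed integer RNG seed
#' @param selection_sigma width (patristic-distance units) of the
#'   Gaussian phylogenetic habitat filter used by the selection
#'   scenarios. Default is process-specific: 0.5 for homogeneous
#'   selection (a tight clade every sample is filtered toward) and 1.5
#'   for heterogeneous selection (coarser habitat patches). `Inf`
#'   recovers neutral drift in expectation.
#' @param drift_sigma log-scale sd of per-sample compositional drift in
#'   the selection and dispersal-limitation scenarios (default 2)
#' @param neutral_sigma log-scale sd of the weak drift of
#'   `neutral_drift` (default 0.15)
#' @param retention per-sample colonization (Bernoulli retention)
#'   probability in the selection scenarios; members of the selected
#'   clade enter each sample as a lottery, so replicate communities
#'   share a clade but not a membership. Default is process-specific:
#'   0.5 for homogeneous selection, 1 (no lottery) otherwise.
#' @param migration migration strength of `homogenizing_dispersal` in
#'   `[0, 1]`; residual drift is `drift_sigma * (1 - migration)`
#'   (default 0.98; 1 gives identical expected compositions)
#' @return list of class `assembly_scenario`
#' @export
assembly_scenario <- function(process, n_samples = 12, depth = 20000,
                              seed = 1, selection_sigma = NULL,
                              drift_sigma = 2, neutral_sigma = 0.15,
                              retention = NULL, migration = 0.98) {
  if (!process %in% assembly_processes_vocab())
    stop("unknown assembly process: ", process, "; expected one of ",
         paste(assembly_processes_vocab(), collapse = ", "))
  if (depth <= 0) stop("sequencing depth must be positive")
  if (n_samples < 2) stop("need at least 2 samples")
  if (is.null(selection_sigma))
    selection_sigma <- if (process == "heterogeneous_selection") 1.5 else 0.5
  if (is.null(retention))
    retention <- if (process == "homogeneous_selection") 0.5 else 1
  structure(list(process = process, n_samples = n_samples, depth = depth,
                 seed = seed, selection_sigma = selection_sigma,
                 drift_sigma = drift_sigma, neutral_sigma = neutral_sigma,
                 retention = retention, migration = migration),
            class = "assembly_scenario")
}

# greedy farthest-point spread of k anchor tips over the tree
spread_anchors <- function(D, k, first) {
  anchors <- first
  while (length(anchors) < k) {
    dmin <- apply(D[, anchors, drop = FALSE], 1, min)
    dmin[anchors] <- -1
    anchors <- c(anchors, which.max(dmin))
  }
  anchors
}

# expected per-sample compositions (rows sum to 1) under a scenario.
# Selection filters on patristic distance to an anchor taxon (a
# phylogenetically conserved niche), with a colonization lottery plus
# log-normal drift creating within-clade turnover between replicates.
scenario_compositions <- function(model, scenario) {
  pool <- model$pool
  N <- length(pool)
  n <- scenario$n_samples
  sig <- scenario$selection_sigma
  drift <- function(sd) exp(stats::rnorm(N, 0, sd))
  lottery <- function() stats::rbinom(N, 1, scenario$retention)
  selected <- function(anchor_dist) {
    w <- pool * exp(-anchor_dist^2 / (2 * sig^2)) *
      lottery() * drift(scenario$drift_sigma)
    if (sum(w) == 0)   # lottery emptied the clade: keep the filter only
      w <- pool * exp(-anchor_dist^2 / (2 * sig^2))
    w / sum(w)
  }
  needs_tree <- scenario$process %in% c("homogeneous_selection",
                                        "heterogeneous_selection")
  D <- if (needs_tree) ape::cophenetic.phylo(model$tree)[names(pool),
                                                         names(pool)]
  q <- with_seed(derive_seed(scenario$seed, 11), switch(scenario$process,
    homogeneous_selection = {
      anchor <- sample.int(N, 1)
      do.call(rbind, replicate(n, selected(D[anchor, ]), simplify = FALSE))
    },
    heterogeneous_selection = {
      anchors <- spread_anchors(D, n, sample.int(N, 1))
      do.call(rbind, lapply(anchors, function(a) selected(D[a, ])))
    },
    neutral_drift = {
      do.call(rbind, replicate(n, {
        w <- pool * drift(scenario$neutral_sigma)
        w / sum(w)
      }, simplify = FALSE))
    },
    dispersal_limitation = {
      do.call(rbind, replicate(n, {
        w <- pool * drift(scenario$drift_sigma)
        w / sum(w)
      }, simplify = FALSE))
    },
    homogenizing_dispersal = {
      common <- pool * drift(scenario$drift_sigma)
      common <- common / sum(common)
      resid <- scenario$drift_sigma * (1 - scenario$migration)
      do.call(rbind, replicate(n, {
        w <- common * drift(resid)
        w / sum(w)
      }, simplify = FALSE))
    }))
  colnames(q) <- names(pool)
  q
}

#' Draw grouped samples under an assembly scenario
#'
#' Counts are multinomial draws of `depth` reads from per-sample expected
#' compositions built from the metacommunity model: selection scenarios
#' weight the pool by a Gaussian filter on patristic distance to a
#' habitat-anchor taxon (one shared anchor for homogeneous selection,
#' maximally spread per-sample anchors for heterogeneous selection),
#' with a colonization lottery and log-normal drift supplying
#' within-clade turnover; neutral drift perturbs the shared pool weakly;
#' dispersal limitation gives every sample an isolated, independently
#' drifted sub-pool; homogenizing dispersal mixes samples toward one
#' common drifted composition.
#'
#' @param model a `metacommunity_model`
#' @param scenario an `assembly_scenario`
#' @param group group label stored in the metadata (default the process
#'   name)
#' @param sample_prefix prefix for sample ids
#' @return an `otu_table`; every sample total equals `scenario$depth`
#' @export
simulate_samples <- function(model, scenario, group = scenario$process,
                             sample_prefix = group) {
  stopifnot(inherits(model, "metacommunity_model"),
            inherits(scenario, "assembly_scenario"))
  q <- scenario_compositions(model, scenario)
  counts <- with_seed(derive_seed(scenario$seed, 12),
    t(apply(q, 1, function(p)
      stats::rmultinom(1, size = scenario$depth, prob = p)[, 1])))
  rownames(counts) <- paste0(sample_prefix, "_", seq_len(nrow(counts)))
  colnames(counts) <- names(model$pool)
  md <- data.frame(sample_id = rownames(counts), group = group,
                   process = scenario$process, stringsAsFactors = FALSE)
  otu_table(counts, md)
}

default_study_design <- function() {
  data.frame(
    group  = c("CS", "CW", "XS", "XW", "QS", "QW"),
    sex    = c("female", "female", "male", "male", "all-female", "all-female"),
    season = c("summer", "winter", "summer", "winter", "summer", "winter"),
    process = c("heterogeneous_selection", "homogeneous_selection",
                "neutral_drift", "dispersal_limitation",
                "homogenizing_dispersal", "neutral_drift"),
    stringsAsFactors = FALSE)
}

#' Simulate a full grouped study bundle
#'
#' Generates one shared phylogeny and metacommunity, then a grouped OTU
#' table for a 6-group (sex x season) design with a per-group assembly
#' scenario, a pseudo-taxonomy obtained by clading the tree, and per-fish
#' growth records with a configurable sex effect on final weight.
#'
#' @param n_otus OTUs in the regional pool (default 1000)
#' @param n_replicates samples per group (default 4; the default design
#'   therefore yields 24 samples)
#' @param depth sequencing depth per sample (default 20000)
#' @param design data.frame with columns `group`, `sex`, `season`,
#'   `process` (default [default_study_design()])
#' @param seed master seed; all stage seeds are derived from it
#' @param season_sigma log-scale sd of the winter shift applied to the
#'   pool (default 0.5)
#' @param ... passed to [assembly_scenario()] (e.g. `selection_sigma`)
#' @return list with elements `table` (`otu_table`), `tree`, `taxonomy`
#'   (data.frame `otu_id`, `phylum`, `class`, `genus`), `growth`
#'   (per-fish records), `model`, `design`
#' @export
simulate_study <- function(n_otus = 1000, n_replicates = 4, depth = 20000,
                           design = default_study_design(), seed = 1,
                           season_sigma = 0.5, ...) {
  if (n_replicates < 3) stop("need at least 3 replicates per group")
  need <- setdiff(c("group", "sex", "season", "process"), names(design))
  if (length(need))
    stop("design lacks column(s): ", paste(need, collapse = ", "))
  bad <- setdiff(design$process, assembly_processes_vocab())
  if (length(bad)) stop("unknown scenario label(s): ",
                        paste(bad, collapse = ", "))
  tree <- simulate_tree(n_otus, seed = derive_seed(seed, 21))
  model <- metacommunity_model(tree, seed = derive_seed(seed, 22))
  season_shift <- with_seed(derive_seed(seed, 23),
                            exp(stats::rnorm(n_otus, 0, season_sigma)))
  tabs <- lapply(seq_len(nrow(design)), function(i) {
    m <- model
    if (design$season[i] == "winter") {
      m$pool <- m$pool * season_shift
      m$pool <- m$pool / sum(m$pool)
    }
    sc <- assembly_scenario(design$process[i], n_samples = n_replicates,
                            depth = depth,
                            seed = derive_seed(seed, 30 + i), ...)
    tab <- simulate_samples(m, sc, group = design$group[i])
    tab$metadata$sex <- design$sex[i]
    tab$metadata$season <- design$season[i]
    tab
  })
  counts <- do.call(rbind, lapply(tabs, function(t) t$counts))
  md <- do.call(rbind, lapply(tabs, function(t) t$metadata))
  table <- otu_table(counts, md)
  taxonomy <- clade_taxonomy(tree)
  growth <- simulate_growth(design, seed = derive_seed(seed, 40))
  list(table = table, tree = tree, taxonomy = taxonomy, growth = growth,
       model = model, design = design)
}

#' Pseudo-taxonomy by clading a tree
#'
#' Cuts the ultrametric tree at increasing depths into nested clades and
#' names them as pseudo-phyla/classes/genera, giving downstream
#' composition summaries a realistic lineage structure.
#'
#' @param tree ultrametric [ape::phylo]
#' @param n_phyla,n_classes,n_genera clade counts at the three ranks
#' @return data.frame `otu_id`, `phylum`, `class`, `genus`
#' @export
clade_taxonomy <- function(tree, n_phyla = 8, n_classes = 20, n_genera = 60) {
  n <- ape::Ntip(tree)
  h <- stats::as.hclust(ape::multi2di(tree))
  cut_safe <- function(k) stats::cutree(h, k = min(k, n))
  data.frame(
    otu_id = tree$tip.label,
    phylum = paste0("Phylum_", cut_safe(n_phyla)[tree$tip.label]),
    class  = paste0("Class_", cut_safe(n_classes)[tree$tip.label]),
    genus  = paste0("Genus_", cut_safe(n_genera)[tree$tip.label]),
    stringsAsFactors = FALSE)
}

#' Simulate per-fish growth records with a sex effect
#'
#' Final body weights are log-normal with a sex-specific mean (females
#' and all-females heavier than males), initial weights are shared, so
#' the daily growth coefficient differs by sex by construction; body
#' length is back-computed from a plausible condition factor.
#'
#' @param design study design (needs columns `group`, `sex`)
#' @param n_fish fish per group (default 30)
#' @param seed integer RNG seed
#' @param bw_final named mean final weights (g) per sex
#' @param t elapsed days between weighings (default 344)
#' @return data.frame `group`, `sex`, `bw` (g), `bl` (cm), `bw_i` (g),
#'   `t` (days)
#' @export
simulate_growth <- function(design, n_fish = 30, seed = 1,
                            bw_final = c(male = 450, female = 560,
                                         `all-female` = 600),
                            t = 344) {
  with_seed(seed, {
    recs <- lapply(seq_len(nrow(design)), function(i) {
      sex <- design$sex[i]
      mu <- bw_final[[sex]]
      bw <- stats::rlnorm(n_fish, log(mu), 0.12)
      bw_i <- pmax(stats::rnorm(n_fish, 26.5, 1.1), 5)
      k <- stats::rnorm(n_fish, 19, 1)
      bl <- (1000 * bw / k)^(1 / 3)
      data.frame(group = design$group[i], sex = sex, bw = bw, bl = bl,
                 bw_i = bw_i, t = t, stringsAsFactors = FALSE)
    })
    do.call(rbind, recs)
  })
}

#' End-to-end ground-truth recovery for one assembly scenario
#'
#' Simulates one group of samples under a scenario, runs the betaNTI and
#' RC-bray null models, classifies every within-group pair, and reports
#' whether the modal label matches the label the scenario should produce
#' (see [expected_process_label()]).
#'
#' @param process scenario label
#' @param seed master seed (tree, pool and sampling seeds are derived)
#' @param n_otus regional pool size (default 300)
#' @param n_samples samples in the group (default 12)
#' @param depth sequencing depth (default 20000)
#' @param n_null null replicates / tip shuffles (default 999)
#' @return one-row data.frame: `process`, `seed`, `mean_bnti`, `mean_rc`,
#'   `modal_process`, `expected`, `recovered`
#' @export
recover_scenario <- function(process, seed, n_otus = 300, n_samples = 12,
                             depth = 20000, n_null = 999) {
  tree <- simulate_tree(n_otus, seed = derive_seed(seed, 61))
  model <- metacommunity_model(tree, seed = derive_seed(seed, 62))
  sc <- assembly_scenario(process, n_samples = n_samples, depth = depth,
                          seed = derive_seed(seed, 63))
  tab <- simulate_samples(model, sc)
  bnti <- beta_nti(tab, tree, n_null = n_null,
                   seed = derive_seed(seed, 64))
  rc <- rc_bray(tab, n_null = n_null, seed = derive_seed(seed, 65))
  grouping <- stats::setNames(rep("G", n_samples), rownames(tab$counts))
  cl <- classify_processes(bnti, rc, grouping = grouping)
  expected <- expected_process_label(process)
  data.frame(process = process, seed = seed,
             mean_bnti = cl$groups$mean_bnti, mean_rc = cl$groups$mean_rc,
             modal_process = cl$groups$modal_process, expected = expected,
             recovered = cl$groups$modal_process == expected,
             stringsAsFactors = FALSE)
}

#' Write a simulated study bundle through the package's public formats
#'
#' Emits the OTU TSV, metadata TSV, Newick tree, taxonomy TSV and growth
#' TSV that the loaders in this package read back, so the pipeline can be
#' exercised end-to-end through its I/O surface.
#'
#' @param bundle result of [simulate_study()]
#' @param dir output directory (created if needed)
#' @return named character vector of file paths
#' @export
write_study <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(otu = file.path(dir, "otu_table.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             tree = file.path(dir, "tree.nwk"),
             taxonomy = file.path(dir, "taxonomy.tsv"),
             growth = file.path(dir, "growth.tsv"))
  write_otu_table(bundle$table, paths["otu"], paths["metadata"])
  ape::write.tree(bundle$tree, paths["tree"])
  utils::write.table(bundle$taxonomy, paths["taxonomy"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$growth, paths["growth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths
}

#' Read an assembly-scenario configuration file
#'
#' YAML or JSON file mirroring the [assembly_scenario()] fields.
#'
#' @param path config file (`.yaml`/`.yml` or `.json`)
#' @return an `assembly_scenario`
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(assembly_scenario, cfg)
}
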