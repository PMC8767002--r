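#' Assemble a pipeline configuration
#'
#' Either `input` (paths to OTU/metadata/tree/taxonomy/growth files) or
#' `scenario` (arguments for [simulate_study()]) must be given. Every
#' stochastic stage receives a seed derived from the single master seed,
#' so a config fully determines the outputs.
#'
#' @param input named list of paths: `otu`, `metadata`, `tree`, optional
#'   `taxonomy`, `growth`
#' @param scenario named list of [simulate_study()] arguments (used when
#'   `input` is `NULL`)
#' @param group metadata column defining groups
#' @param n_perm permutations for PERMANOVA/ANOSIM/Mantel
#' @param n_null null replicates / tip shuffles for the assembly stage
#' @param thresholds abundance-category thresholds
#'   ([category_thresholds()])
#' @param min_prevalence network prevalence filter
#' @param rmt_scan `c(start, end, step)` for [rmt_threshold()]; set
#'   `st` instead to skip the scan
#' @param st fixed correlation threshold (disables the RMT scan)
#' @param n_random random-network replicates
#' @param run_networks set `FALSE` to skip the network stage
#' @param seed master seed
#' @param outdir output directory
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(input = NULL, scenario = list(), group = "group",
                            n_perm = 999, n_null = 999,
                            thresholds = category_thresholds(),
                            min_prevalence = 0.5,
                            rmt_scan = c(0.30, 0.95, 0.01), st = NULL,
                            n_random = 30, run_networks = TRUE,
                            seed = 1, outdir = tempfile("miceco_run_")) {
  if (is.null(input) && is.null(scenario))
    stop("either input paths or a synthetic scenario must be given")
  structure(list(input = input, scenario = scenario, group = group,
                 n_perm = n_perm, n_null = n_null, thresholds = thresholds,
                 min_prevalence = min_prevalence, rmt_scan = rmt_scan,
                 st = st, n_random = n_random, run_networks = run_networks,
                 seed = seed, outdir = outdir),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  message(sprintf("[miceco] stage %-12s done in %.1fs", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full analysis pipeline
#'
#' Loads (or simulates) the study bundle, then runs: alpha diversity,
#' Bray-Curtis/Jaccard distances with NMDS and PERMANOVA/ANOSIM,
#' abundance-category classification, per-group assembly-process
#' inference, per-group co-occurrence networks, and growth summaries.
#' Every table is written as TSV with a JSON mirror, plus a run manifest
#' recording the configuration, seeds and output checksums.
#'
#' @param config a [pipeline_config()]
#' @return (invisibly) list of all results, with `$files` naming the
#'   written outputs
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  bundle <- stage("load", {
    if (!is.null(config$input)) {
      inp <- config$input
      list(table = load_otu_table(inp$otu, inp$metadata),
           tree = load_tree(inp$tree),
           taxonomy = if (!is.null(inp$taxonomy)) load_taxonomy(inp$taxonomy),
           growth = if (!is.null(inp$growth))
             utils::read.table(inp$growth, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE))
    } else {
      do.call(simulate_study,
              c(config$scenario,
                list(seed = derive_seed(config$seed, 1))))
    }
  })
  x <- bundle$table
  g <- config$group

  alpha <- stage("alpha", alpha_diversity(x, "all", tree = bundle$tree))

  dists <- stage("distance", list(
    bray_curtis = distance_matrix(x, "bray_curtis"),
    jaccard = distance_matrix(x, "jaccard")))

  ord <- stage("nmds", nmds(dists$jaccard, k = 2,
                            seed = derive_seed(config$seed, 2)))

  perm <- stage("permanova", {
    factors <- if (all(c("sex", "season") %in% names(x$metadata)) &&
                   length(unique(x$metadata$season)) > 1)
      c("sex", "season") else g
    do.call(rbind, lapply(names(dists), function(m) {
      r <- permanova(dists[[m]], x$metadata, factors,
                     n_perm = config$n_perm,
                     seed = derive_seed(config$seed, 3))
      r$metric <- m
      r
    }))
  })

  anos <- stage("anosim",
    anosim(dists$jaccard, g, metadata = x$metadata,
           n_perm = config$n_perm, seed = derive_seed(config$seed, 4)))

  categ <- stage("categories", {
    assign <- classify_taxa_groups(x, group = g,
                                   thresholds = config$thresholds)
    summ <- category_summary(assign)
    list(assignments = assign, summary = summ,
         report = category_report(summ))
  })

  assem <- stage("assembly",
    assembly_analysis(x, bundle$tree, group = g, n_null = config$n_null,
                      seed = derive_seed(config$seed, 5)))

  nets <- if (isTRUE(config$run_networks)) stage("networks", {
    lev <- unique(as.character(x$metadata[[g]]))
    out <- list()
    for (k in seq_along(lev)) {
      sub <- subset_samples(x, x$metadata[[g]] == lev[k],
                            drop_empty_otus = TRUE)
      if (n_samples(sub) < 6)
        warning("group ", lev[k], " has fewer than 6 samples; ",
                "correlations will be noisy")
      grp_net <- tryCatch({
        mat <- prepare_abundance_matrix(sub, config$min_prevalence)
        corr <- correlation_matrix(mat)
        st <- if (!is.null(config$st)) config$st
              else rmt_threshold(corr, config$rmt_scan[1],
                                 config$rmt_scan[2], config$rmt_scan[3])$st
        net <- build_network(corr, st)
        modules <- detect_modules(net)
        topo <- topology_indices(net, modules)
        rand <- random_network_baseline(net, n_random = config$n_random,
                                        seed = derive_seed(config$seed,
                                                           50 + k))
        roles <- node_roles(net, modules)
        comp <- if (!is.null(bundle$taxonomy))
          network_composition(net, bundle$taxonomy, modules)
        list(network = net, modules = modules, topology = topo,
             random = rand, roles = roles, composition = comp)
      }, error = function(e) {
        warning("network for group ", lev[k], " skipped: ",
                conditionMessage(e))
        NULL
      })
      if (!is.null(grp_net)) out[[lev[k]]] <- grp_net
    }
    out
  }) else NULL

  growth <- if (!is.null(bundle$growth))
    stage("growth", growth_summary(bundle$growth))

  results <- list(alpha = alpha, distances = dists, nmds = ord,
                  permanova = perm, anosim = anos, categories = categ,
                  assembly = assem, networks = nets, growth = growth,
                  table = x, config = config)
  results$files <- stage("report", write_report(results, outdir,
                                                taxonomy = bundle$taxonomy))
  invisible(results)
}

write_tsv_json <- function(df, dir, name) {
  if (is.null(df) || !nrow(as.data.frame(df)))
    stop("refusing to write empty result '", name, "'")
  tsv <- file.path(dir, paste0(name, ".tsv"))
  jsn <- file.path(dir, paste0(name, ".json"))
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(df, jsn, dataframe = "rows", digits = NA,
                       pretty = TRUE)
  c(tsv, jsn)
}

#' Write the pipeline report bundle
#'
#' @param results result list from [run_pipeline()]
#' @param outdir output directory
#' @param taxonomy optional taxonomy for network node tables
#' @return named character vector of written files (also includes the
#'   run manifest)
#' @export
write_report <- function(results, outdir, taxonomy = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  files <- c(files, write_tsv_json(results$alpha, outdir, "alpha_diversity"))
  for (m in names(results$distances)) {
    p <- file.path(outdir, paste0("distance_", m, ".tsv"))
    utils::write.table(results$distances[[m]], p, sep = "\t", quote = FALSE)
    files <- c(files, p)
  }
  nm <- data.frame(sample_id = rownames(results$nmds$points),
                   results$nmds$points, stress = results$nmds$stress)
  files <- c(files, write_tsv_json(nm, outdir, "nmds"))
  files <- c(files, write_tsv_json(results$permanova, outdir, "permanova"))
  files <- c(files, write_tsv_json(results$anosim, outdir, "anosim"))
  files <- c(files, write_tsv_json(results$categories$summary, outdir,
                                   "category_summary"))
  files <- c(files, write_tsv_json(results$categories$report, outdir,
                                   "category_report"))
  files <- c(files, write_tsv_json(results$assembly$summary, outdir,
                                   "assembly_summary"))
  files <- c(files, write_tsv_json(results$assembly$pairs, outdir,
                                   "assembly_pairs"))
  if (!is.null(results$networks) && length(results$networks)) {
    topo <- do.call(rbind, lapply(names(results$networks), function(gr) {
      data.frame(group = gr, results$networks[[gr]]$topology)
    }))
    files <- c(files, write_tsv_json(topo, outdir, "network_topology"))
    for (gr in names(results$networks)) {
      files <- c(files, export_network(results$networks[[gr]]$network,
                                       outdir, taxonomy = taxonomy,
                                       prefix = paste0("network_", gr)))
      files <- c(files, write_tsv_json(results$networks[[gr]]$roles, outdir,
                                       paste0("node_roles_", gr)))
      files <- c(files, write_tsv_json(results$networks[[gr]]$random, outdir,
                                       paste0("network_random_", gr)))
    }
  }
  if (!is.null(results$growth))
    files <- c(files, write_tsv_json(results$growth, outdir, "growth_summary"))

  cfg <- results$config
  cfg_json <- jsonlite::toJSON(cfg[setdiff(names(cfg), "input")],
                               auto_unbox = TRUE, digits = NA, force = TRUE)
  manifest <- list(
    package = "miceco",
    package_version = as.character(utils::packageVersion("miceco")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    config = jsonlite::fromJSON(cfg_json),
    config_hash = fnv1a(cfg_json),
    files = stats::setNames(as.vector(tools::md5sum(files)),
                            basename(files)))
  mp <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  c(files, mp)
}

# tiny FNV-1a hash for config fingerprinting (no external digest dep)
fnv1a <- function(s) {
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}
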