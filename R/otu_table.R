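#' Construct and validate an OTU count table
#'
#' An `otu_table` couples a non-negative integer count matrix (samples in
#' rows, OTUs in columns) with a per-sample metadata frame. It is the
#' universal input of the package: diversity, categorization, assembly
#' null models and network construction all start from it.
#'
#' @param counts numeric matrix, samples x OTUs. Must be non-negative and
#'   (unless `relative = TRUE`) integer-valued. Row and column names are
#'   taken as sample and OTU identifiers and must be unique.
#' @param metadata data.frame with one row per sample. Must contain a
#'   `sample_id` column matching `rownames(counts)` (order is reconciled),
#'   and a `group` column; `sex` and `season` columns are carried along
#'   when present.
#' @param relative set `TRUE` to accept a relative-abundance matrix
#'   (rows summing to 1 within 1e-6) instead of counts. Assembly null
#'   models require true counts and will refuse such tables.
#' @return an object of class `otu_table`: a list with elements `counts`
#'   (matrix) and `metadata` (data.frame, rows aligned with the matrix),
#'   plus attribute `relative`.
#' @export
otu_table <- function(counts, metadata = NULL, relative = FALSE) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("sample", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("OTU", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample identifiers: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate OTU identifiers: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  if (!is.numeric(counts))
    stop("counts must be numeric")
  bad <- which(!is.finite(counts) | counts < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("negative or non-finite count at sample '%s', OTU '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  if (!relative) {
    off <- which(abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)
    if (nrow(off))
      stop(sprintf(
        "non-integer count at sample '%s', OTU '%s' (use relative = TRUE for proportions)",
        rownames(counts)[off[1, 1]], colnames(counts)[off[1, 2]]))
    counts <- round(counts)
  } else {
    rs <- rowSums(counts)
    if (any(abs(rs - 1) > 1e-6))
      stop("relative = TRUE but row sums deviate from 1 by more than 1e-6")
  }
  zero <- rownames(counts)[rowSums(counts) == 0]
  if (length(zero))
    stop("samples with zero total count: ", paste(zero, collapse = ", "))

  if (is.null(metadata)) {
    metadata <- data.frame(sample_id = rownames(counts),
                           group = "all", stringsAsFactors = FALSE)
  }
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(metadata)) {
    if (!is.null(rownames(metadata)) &&
        setequal(rownames(metadata), rownames(counts))) {
      metadata$sample_id <- rownames(metadata)
    } else {
      stop("metadata must contain a 'sample_id' column")
    }
  }
  if (anyDuplicated(metadata$sample_id))
    stop("duplicate sample_id in metadata")
  missing_md <- setdiff(rownames(counts), metadata$sample_id)
  missing_ct <- setdiff(metadata$sample_id, rownames(counts))
  if (length(missing_md) || length(missing_ct))
    stop("metadata/sample mismatch; missing from metadata: [",
         paste(missing_md, collapse = ", "), "]; missing from counts: [",
         paste(missing_ct, collapse = ", "), "]")
  metadata <- metadata[match(rownames(counts), metadata$sample_id), ,
                       drop = FALSE]
  rownames(metadata) <- metadata$sample_id
  if (!"group" %in% names(metadata)) metadata$group <- "all"

  structure(list(counts = counts, metadata = metadata),
            relative = relative, class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d OTUs\n",
              nrow(x$counts), ncol(x$counts)))
  cat("groups:", paste(sprintf("%s(%d)", names(table(x$metadata$group)),
                               table(x$metadata$group)), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Number of samples / OTUs in a table
#' @param x an `otu_table`
#' @return integer count
#' @export
n_samples <- function(x) nrow(x$counts)

#' @rdname n_samples
#' @export
n_otus <- function(x) ncol(x$counts)

#' Subset an otu_table by samples
#'
#' @param x an `otu_table`
#' @param samples character vector of sample ids or logical/integer index
#' @param drop_empty_otus drop OTUs with zero total in the subset
#' @return an `otu_table`
#' @export
subset_samples <- function(x, samples, drop_empty_otus = FALSE) {
  stopifnot(inherits(x, "otu_table"))
  counts <- x$counts[samples, , drop = FALSE]
  if (drop_empty_otus) counts <- counts[, colSums(counts) > 0, drop = FALSE]
  otu_table(counts, x$metadata[rownames(counts), , drop = FALSE],
            relative = isTRUE(attr(x, "relative")))
}

#' Read an OTU count table and its sample sheet
#'
#' Expects a tab-separated file with sample ids in the first column and
#' OTUs as the remaining columns, and a tab-separated metadata sheet with
#' mandatory columns `sample_id` and `group` (optional `sex`, `season`).
#'
#' @param path counts file
#' @param metadata_path sample sheet; `NULL` gives a single "all" group
#' @param relative see [otu_table()]
#' @return an `otu_table`
#' @export
load_otu_table <- function(path, metadata_path = NULL, relative = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           row.names = NULL)
  ids <- raw[[1]]
  mat <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(mat), nrow = nrow(mat),
                                 dimnames = list(ids, colnames(mat))))
  bad <- which(is.na(num) & !is.na(mat), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("cannot parse count at row '%s', column '%s': '%s'",
                 ids[bad[1, 1]], colnames(mat)[bad[1, 2]],
                 mat[bad[1, 1], bad[1, 2]]))
  md <- if (is.null(metadata_path)) NULL else load_metadata(metadata_path)
  otu_table(num, md, relative = relative)
}

#' Read a tab-separated sample sheet
#' @param path file with columns `sample_id`, `group`, optional `sex`, `season`
#' @return data.frame
#' @export
load_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  md <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- setdiff(c("sample_id", "group"), names(md))
  if (length(need))
    stop("metadata lacks mandatory column(s): ", paste(need, collapse = ", "))
  md
}

#' Write an otu_table (and optionally its metadata) to tab-separated files
#' @param x an `otu_table`
#' @param path counts file to write
#' @param metadata_path optional sample sheet to write
#' @return `path`, invisibly
#' @export
write_otu_table <- function(x, path, metadata_path = NULL) {
  stopifnot(inherits(x, "otu_table"))
  df <- data.frame(sample_id = rownames(x$counts), x$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata_path))
    utils::write.table(x$metadata, metadata_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' Convert counts to relative abundances
#'
#' @param x an `otu_table` (all sample totals must be positive, which the
#'   constructor guarantees)
#' @return a numeric matrix of class `rel_abundance`, same dimnames as the
#'   counts, each row summing to 1
#' @export
to_relative_abundance <- function(x) {
  stopifnot(inherits(x, "otu_table"))
  tot <- rowSums(x$counts)
  if (any(tot == 0)) stop("zero-total sample; filter upstream")
  structure(sweep(x$counts, 1, tot, "/"),
            class = c("rel_abundance", class(x$counts)))
}

#' Shared-OTU intersection sizes across groups (UpSet semantics)
#'
#' An OTU is "present" in a group when its summed count over that group's
#' samples is positive. Every observed OTU is assigned to exactly one
#' combination: the full set of groups containing it, so the combination
#' sizes partition the observed OTUs.
#'
#' @param x an `otu_table`
#' @param group metadata column used for grouping (default `"group"`)
#' @return data.frame with columns `combination` (group names joined by
#'   `&`, in the group order of the metadata), `degree` (number of groups
#'   in the combination) and `n_otus`; only non-empty combinations are
#'   returned.
#' @export
shared_otu_counts <- function(x, group = "group") {
  stopifnot(inherits(x, "otu_table"))
  g <- as.character(x$metadata[[group]])
  lev <- unique(g)
  if (length(lev) < 2)
    stop("shared_otu_counts needs at least 2 groups")
  pres <- vapply(lev, function(l)
    colSums(x$counts[g == l, , drop = FALSE]) > 0,
    logical(ncol(x$counts)))
  pres <- matrix(pres, ncol = length(lev), dimnames = list(colnames(x$counts), lev))
  observed <- rowSums(pres) > 0
  pres <- pres[observed, , drop = FALSE]
  key <- apply(pres, 1, function(r) paste(lev[r], collapse = "&"))
  tab <- table(key)
  out <- data.frame(combination = names(tab),
                    degree = vapply(strsplit(names(tab), "&", fixed = TRUE),
                                    length, integer(1)),
                    n_otus = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$degree, out$combination), , drop = FALSE]
}

#' Read a rooted phylogeny from a Newick file
#'
#' Branch lengths are mandatory: Faith's PD and nearest-taxon distances
#' are undefined without them.
#'
#' @param path Newick file
#' @return an [ape::phylo] tree
#' @export
load_tree <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("cannot parse Newick: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("cannot parse Newick file: ", path)
  validate_tree(tr)
}

validate_tree <- function(tr) {
  if (is.null(tr$edge.length))
    stop("tree has no branch lengths; PD and nearest-taxon distances are undefined")
  if (any(tr$edge.length < 0)) stop("negative branch lengths")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  tr
}

#' Reconcile an otu_table with a phylogeny
#'
#' OTUs absent from the tree are dropped from the table, and tips absent
#' from the table are pruned from the tree, both with a warning. If fewer
#' than half of the table's OTUs are on the tree the mismatch is treated
#' as a hard error (it almost certainly indicates mismatched inputs).
#'
#' @param x an `otu_table`
#' @param tree an [ape::phylo] tree
#' @return list with elements `table` and `tree`, label sets identical
#' @export
match_tree_table <- function(x, tree) {
  stopifnot(inherits(x, "otu_table"))
  validate_tree(tree)
  shared <- intersect(colnames(x$counts), tree$tip.label)
  frac <- length(shared) / ncol(x$counts)
  if (frac < 0.5)
    stop(sprintf("only %.0f%% of table OTUs are on the tree; inputs look mismatched",
                 100 * frac))
  drop_tab <- setdiff(colnames(x$counts), shared)
  drop_tip <- setdiff(tree$tip.label, shared)
  if (length(drop_tab))
    warning(length(drop_tab), " OTU(s) absent from tree dropped from table")
  if (length(drop_tip))
    warning(length(drop_tip), " tip(s) absent from table pruned from tree")
  if (length(drop_tip))
    tree <- ape::drop.tip(tree, drop_tip)
  if (length(drop_tab)) {
    counts <- x$counts[, shared, drop = FALSE]
    keep <- rowSums(counts) > 0
    if (!all(keep))
      warning(sum(!keep), " sample(s) emptied by pruning were removed")
    x <- otu_table(counts[keep, , drop = FALSE],
                   x$metadata[keep, , drop = FALSE],
                   relative = isTRUE(attr(x, "relative")))
  }
  list(table = x, tree = tree)
}

#' Read an OTU-to-lineage taxonomy map
#'
#' Accepts two-column tab-separated input (`otu_id`, semicolon-delimited
#' lineage, with or without the `p__`/`c__`/`g__` rank prefixes) or an
#' already-split table with columns `otu_id`, `phylum`, `class`, `genus`.
#'
#' @param path taxonomy file
#' @return data.frame with columns `otu_id`, `phylum`, `class`, `genus`
#' @export
load_taxonomy <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tx <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "")
  if (!"otu_id" %in% names(tx)) names(tx)[1] <- "otu_id"
  if (anyDuplicated(tx$otu_id))
    stop("duplicate otu_id in taxonomy: ",
         paste(unique(tx$otu_id[duplicated(tx$otu_id)]), collapse = ", "))
  if (all(c("phylum", "class", "genus") %in% names(tx)))
    return(tx[, c("otu_id", "phylum", "class", "genus")])
  lineage_col <- setdiff(names(tx), "otu_id")[1]
  parts <- strsplit(tx[[lineage_col]], ";", fixed = TRUE)
  pick <- function(p, prefix, pos) {
    hit <- grep(paste0("^\\s*", prefix, "__"), p, value = TRUE)
    val <- if (length(hit)) sub(paste0("^\\s*", prefix, "__"), "", hit[1])
           else if (length(p) >= pos) trimws(p[[pos]]) else ""
    if (!nzchar(val)) "Unclassified" else trimws(val)
  }
  data.frame(otu_id = tx$otu_id,
             phylum = vapply(parts, pick, character(1), prefix = "p", pos = 1),
             class  = vapply(parts, pick, character(1), prefix = "c", pos = 2),
             genus  = vapply(parts, pick, character(1), prefix = "g", pos = 3),
             stringsAsFactors = FALSE)
}
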