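#' Abundance-category thresholds
#'
#' The six-category scheme splits OTUs by their per-sample relative
#' abundance range within a group of samples: rare below `rare_cutoff`
#' (default 0.1\%), abundant above `abundant_cutoff` (default 1\%).
#'
#' @param rare_cutoff relative abundance at or below which an OTU counts
#'   as rare in a sample (default 0.001)
#' @param abundant_cutoff relative abundance at or above which an OTU
#'   counts as abundant in a sample (default 0.01)
#' @return a named list of validated thresholds
#' @export
category_thresholds <- function(rare_cutoff = 0.001, abundant_cutoff = 0.01) {
  if (!(rare_cutoff > 0 && rare_cutoff < abundant_cutoff && abundant_cutoff < 1))
    stop("thresholds must satisfy 0 < rare_cutoff < abundant_cutoff < 1")
  list(rare_cutoff = rare_cutoff, abundant_cutoff = abundant_cutoff)
}

#' Classify OTUs into the six abundance categories
#'
#' Categories are decided by the minimum (`a_min`) and maximum (`a_max`)
#' per-sample relative abundance of each OTU across the supplied samples:
#' \describe{
#'   \item{RT}{rare taxa: `a_max <= rare_cutoff` (rare in all samples)}
#'   \item{AT}{abundant taxa: `a_min >= abundant_cutoff` (abundant in all)}
#'   \item{MT}{moderate taxa: strictly between the cutoffs in all samples}
#'   \item{CRT}{conditionally rare: below the abundant cutoff everywhere,
#'     rare in some but not all samples}
#'   \item{CAT}{conditionally abundant: never rare, abundant in some but
#'     not all samples}
#'   \item{CRAT}{conditionally rare or abundant: spans rare in some
#'     samples to abundant in others}
#' }
#' The six predicates partition the observed OTUs (every OTU with a
#' positive count in at least one sample receives exactly one label).
#'
#' @param rel a `rel_abundance` matrix (samples x OTUs), typically
#'   restricted to one group's samples, or an `otu_table` (converted
#'   internally)
#' @param thresholds see [category_thresholds()]
#' @return named factor over observed OTUs with levels
#'   `RT, AT, MT, CRT, CAT, CRAT`
#' @export
classify_taxa <- function(rel, thresholds = category_thresholds()) {
  if (inherits(rel, "otu_table")) rel <- to_relative_abundance(rel)
  rel <- unclass(as.matrix(rel))
  r <- thresholds$rare_cutoff
  a <- thresholds$abundant_cutoff
  observed <- colSums(rel) > 0
  rel <- rel[, observed, drop = FALSE]
  a_min <- apply(rel, 2, min)
  a_max <- apply(rel, 2, max)
  lab <- classify_abundance_range(a_min, a_max, r, a)
  names(lab) <- colnames(rel)
  factor(lab, levels = category_levels())
}

category_levels <- function() c("RT", "AT", "MT", "CRT", "CAT", "CRAT")

# vectorized predicate core; exported for range-level use and testing
#' Classify abundance ranges directly
#'
#' Lower-level interface to the six-category predicates, taking the
#' per-group minimum and maximum per-sample relative abundances.
#'
#' @param a_min,a_max minimum and maximum per-sample relative abundance
#' @param rare_cutoff,abundant_cutoff see [category_thresholds()]
#' @return character vector of labels
#' @export
classify_abundance_range <- function(a_min, a_max,
                                     rare_cutoff = 0.001,
                                     abundant_cutoff = 0.01) {
  th <- category_thresholds(rare_cutoff, abundant_cutoff)
  r <- th$rare_cutoff; a <- th$abundant_cutoff
  if (any(a_max < a_min)) stop("a_max below a_min")
  ifelse(a_max <= r, "RT",
  ifelse(a_min >= a, "AT",
  ifelse(a_min > r & a_max < a, "MT",
  ifelse(a_min <= r & a_max < a, "CRT",
  ifelse(a_min > r & a_max >= a, "CAT",
         "CRAT")))))
}

#' Classify every group of an otu_table
#'
#' Relative abundances are computed per sample on the full table; each
#' group is then classified over its own samples, restricted to the OTUs
#' observed in that group (group denominators therefore differ).
#'
#' @param x an `otu_table`
#' @param group metadata column defining groups
#' @param thresholds see [category_thresholds()]
#' @return long data.frame with columns `group`, `otu_id`, `category`
#' @export
classify_taxa_groups <- function(x, group = "group",
                                 thresholds = category_thresholds()) {
  stopifnot(inherits(x, "otu_table"))
  rel <- to_relative_abundance(x)
  g <- as.character(x$metadata[[group]])
  out <- lapply(unique(g), function(l) {
    lab <- classify_taxa(rel[g == l, , drop = FALSE], thresholds)
    data.frame(group = l, otu_id = names(lab),
               category = as.character(lab), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Summarize category assignments per group
#'
#' @param assignments long data.frame as returned by
#'   [classify_taxa_groups()] (columns `group`, `category`; one row per
#'   observed OTU per group)
#' @return data.frame with one row per group x category: `group`,
#'   `category`, `count`, `total` (observed OTUs in group) and `percent`
#'   (100 * count / total, rounded to 2 decimals)
#' @export
category_summary <- function(assignments) {
  need <- setdiff(c("group", "category"), names(assignments))
  if (length(need))
    stop("assignments lack column(s): ", paste(need, collapse = ", "))
  groups <- unique(assignments$group)
  out <- do.call(rbind, lapply(groups, function(gr) {
    cat_g <- assignments$category[assignments$group == gr]
    tot <- length(cat_g)
    cnt <- table(factor(cat_g, levels = category_levels()))
    data.frame(group = gr, category = category_levels(),
               count = as.integer(cnt), total = tot,
               percent = round(100 * as.integer(cnt) / tot, 2),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Format a category summary as a category x group report
#'
#' @param summary long summary from [category_summary()]
#' @return data.frame, rows = categories, columns = groups, cells
#'   `"percent (count)"`
#' @export
category_report <- function(summary) {
  groups <- unique(summary$group)
  out <- data.frame(category = category_levels(), stringsAsFactors = FALSE)
  for (gr in groups) {
    s <- summary[summary$group == gr, ]
    s <- s[match(category_levels(), s$category), ]
    out[[gr]] <- sprintf("%.2f (%d)", s$percent, s$count)
  }
  out
}
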