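#' Fulton's body condition factor K
#'
#' K = 1000 * BW / BL^3 with body weight in grams and body length in cm.
#' The 10^3 scaling puts typical fish near K ~ 10-25.
#'
#' @param bw body weight (g), positive
#' @param bl body length (cm), positive
#' @return K, unitless; vectorized over inputs
#' @export
fulton_k <- function(bw, bl) {
  if (any(!is.finite(bw)) || any(!is.finite(bl)) || any(bw <= 0) || any(bl <= 0))
    stop("fulton_k requires positive body weight and length")
  1000 * bw / bl^3
}

#' Daily growth coefficient (DGC)
#'
#' DGC = (BW_f^(1/3) - BW_i^(1/3)) / t * 100, in percent per day. The
#' cube-root scale makes the coefficient approximately constant over
#' ontogeny for isometric growth.
#'
#' @param bw_f final body weight (g), positive
#' @param bw_i initial body weight (g), positive
#' @param t elapsed time (days), positive
#' @return DGC (\% per day); vectorized. A final weight below the initial
#'   weight yields a negative DGC with a warning.
#' @export
dgc <- function(bw_f, bw_i, t) {
  if (any(!is.finite(bw_f)) || any(!is.finite(bw_i)) ||
      any(bw_f <= 0) || any(bw_i <= 0))
    stop("dgc requires positive body weights")
  if (any(t <= 0)) stop("dgc requires elapsed time t > 0")
  if (any(bw_f < bw_i)) warning("final weight below initial weight; negative DGC")
  (bw_f^(1 / 3) - bw_i^(1 / 3)) / t * 100
}

#' Group summaries of growth indices
#'
#' Computes per-fish Fulton's K and DGC from a tidy record table and
#' summarizes them as mean and standard error per group.
#'
#' @param records data.frame with columns `group`, `bw` (g), `bl` (cm),
#'   `bw_i` (g), `t` (days); extra columns are ignored
#' @return data.frame with one row per group: `group`, `n`, `dgc_mean`,
#'   `dgc_se`, `k_mean`, `k_se`
#' @export
growth_summary <- function(records) {
  need <- setdiff(c("group", "bw", "bl", "bw_i", "t"), names(records))
  if (length(need))
    stop("records lack column(s): ", paste(need, collapse = ", "))
  k <- fulton_k(records$bw, records$bl)
  g <- dgc(records$bw, records$bw_i, records$t)
  se <- function(v) stats::sd(v) / sqrt(length(v))
  out <- do.call(rbind, lapply(split(seq_len(nrow(records)), records$group),
    function(i) data.frame(
      n = length(i),
      dgc_mean = mean(g[i]), dgc_se = se(g[i]),
      k_mean = mean(k[i]), k_se = se(k[i]))))
  out <- data.frame(group = rownames(out), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  out
}
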