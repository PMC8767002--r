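# internal helpers shared across modules

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  code
}

# counter-based seed fan-out: one master seed, independent child streams.
# Keeps results stable when a new consumer is added, and stays < 2^31.
derive_seed <- function(seed, counter) {
  s <- (as.double(seed) %% 2147483647) + 1
  for (k in c(counter + 1, 97)) {
    s <- (s * 48271 + k) %% 2147483647
  }
  as.integer(s)
}

# off-diagonal upper-triangle pairs of a symmetric matrix as a long frame
pair_frame <- function(m) {
  ids <- rownames(m)
  ij <- which(upper.tri(m), arr.ind = TRUE)
  data.frame(sample_i = ids[ij[, 1]], sample_j = ids[ij[, 2]],
             value = m[ij], stringsAsFactors = FALSE)
}
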