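# data.table is used via importFrom; mark the namespace as aware so [.data.table
# dispatches correctly inside the package.
.datatable.aware <- TRUE

# Deterministic per-stage / per-iteration seed derivation. Every consumer of
# randomness in the package seeds its own stream from (user seed, stream id),
# so results are reproducible and, for the bootstrap, independent of how
# iterations are scheduled across workers. Arithmetic stays in doubles (exact
# below 2^53) and the result stays below 2^31 - 1.
.derive_seed <- function(seed, stream) {
  s <- abs(as.numeric(seed)) %% 2147483647
  as.integer((s + as.numeric(stream) * 1000003) %% 2147483647)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
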