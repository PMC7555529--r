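## Internal helpers: seeding and small shared utilities.

# Run fn() under a fixed seed without disturbing the caller's RNG state.
# seed = NULL means "use the current RNG stream".
.with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  withr::with_seed(as.integer(seed), fn())
}

# Deterministically derive a sub-seed from a root seed and an index.
# Kept below 2^31 so it is always a valid R integer seed.
.split_seed <- function(seed, index) {
  as.integer((as.double(seed) %% 2147483629 * 7919 +
                as.double(index) * 104729 + 12345) %% 2147483629)
}

.stopifnot_scalar_chrom <- function(chromosome) {
  chromosome <- as.character(chromosome)
  if (length(chromosome) != 1 || is.na(.chrom_order(chromosome)))
    stop("'chromosome' must be a single valid chromosome label")
  chromosome
}

# Atomic write: write via a temp file in the same directory, then rename.
.write_atomic <- function(write_fn, path) {
  tmp <- paste0(path, ".tmp")
  write_fn(tmp)
  if (!file.rename(tmp, path)) stop("could not write ", path)
  invisible(path)
}
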