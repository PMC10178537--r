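# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# 32-bit FNV-1a hash of a character scalar, as 8 hex digits. Used to stamp
# output files with a provenance hash of the configuration; not
# cryptographic.
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- as.integer(charToRaw(x))
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte; arithmetic kept in doubles below 2^53
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- ((hi * 16777619) %% 65536) * 65536 + lo * 16777619
    h <- h %% 4294967296
  }
  sprintf("%08x", h)
}

# index (1-based, possibly fractional) -> physical position in um
vox_to_um <- function(i, voxel_size) (i - 1) * voxel_size

# physical position in um -> 1-based fractional voxel index
um_to_vox <- function(p, voxel_size) p / voxel_size + 1

`%||%` <- function(a, b) if (is.null(a)) b else a
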