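# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so library calls never perturb user-level randomness.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic fan-out of a master seed into per-task seeds, kept below
# 2^31 so they remain valid R integer seeds.
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + as.double(index) * 16807) %% 2147483647)
}

stop_if_not_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) {
    stop(sprintf("%s contains non-finite values", what), call. = FALSE)
  }
  invisible(TRUE)
}

# 32-bit helpers on doubles (R integers are signed 32-bit, too narrow for
# unsigned hash arithmetic).
xor32 <- function(a, b) {
  a_lo <- a %% 65536; a_hi <- (a - a_lo) / 65536
  b_lo <- b %% 65536; b_hi <- (b - b_lo) / 65536
  bitwXor(as.integer(a_hi), as.integer(b_hi)) * 65536 +
    bitwXor(as.integer(a_lo), as.integer(b_lo))
}

mul32 <- function(a, b) {
  a_lo <- a %% 65536
  a_hi <- (a - a_lo) / 65536
  (((a_hi * b) %% 65536) * 65536 + a_lo * b) %% 4294967296
}

# FNV-1a 32-bit hash of a character scalar, in pure R (no hashing package
# is available in the environment). Used to fingerprint phantom specs in
# dataset manifests.
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  for (b in bytes) {
    h <- xor32(h, b)
    h <- mul32(h, 16777619)
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

# Atomic file write: write to a sibling temp file, then rename.
atomic_write <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = paste0(".tmp_", basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
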