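# internal helpers shared across modules

# codes accepted as missing in genotype/phenotype tables
.MISSING_CODES <- c("NA", "", "-")

# run expr with a temporarily seeded RNG, restoring the caller's stream
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# FNV-1a hash of a character scalar, returned as 8 hex digits.
# Used only to fingerprint pipeline configurations in the run manifest.
fnv1a_hash <- function(x) {
  stopifnot(is.character(x))
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483648), b) + (h >= 2147483648) * 2147483648
    # exact 32-bit modular multiply in doubles (split into 16-bit halves)
    lo <- h %% 65536; hi <- (h - lo) / 65536
    h <- (lo * prime + ((hi * prime) %% 65536) * 65536) %% 4294967296
  }
  lo <- h %% 65536; hi <- (h - lo) / 65536
  sprintf("%04x%04x", as.integer(hi), as.integer(lo))
}

# column medians of a numeric matrix (no NAs), avoiding per-column dispatch
col_medians <- function(x) {
  n <- nrow(x)
  if (n == 1L) return(x[1L, ])
  s <- apply(x, 2L, sort.int, method = "quick")
  if (n %% 2L == 1L) s[(n + 1L) %/% 2L, ] else (s[n %/% 2L, ] + s[n %/% 2L + 1L, ]) / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a

vq_message <- function(..., verbose = getOption("vqtlscan.verbose", TRUE)) {
  if (isTRUE(verbose)) message(...)
}
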