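# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @importFrom data.table := .N .SD data.table as.data.table fread fwrite setorder setorderv setnames setcolorder copy rbindlist
NULL

# Classed conditions so callers (and the CLI) can distinguish configuration,
# schema, domain, I/O and usage failures.
stop_with <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(paste0("sepsiscues_", class, "_error"),
                                "sepsiscues_error")))
}
config_error <- function(msg, ...) stop_with("config", msg, ...)
schema_error <- function(msg, ...) stop_with("schema", msg, ...)
domain_error <- function(msg, ...) stop_with("domain", msg, ...)
io_error     <- function(msg, ...) stop_with("io", msg, ...)
usage_error  <- function(msg, ...) stop_with("usage", msg, ...)

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# FNV-1a 32-bit hash of a canonical JSON rendering; used only to stamp cue
# payloads with a digest of their inputs.
fnv1a_hex <- function(x) {
  bytes <- as.integer(charToRaw(canonical_json(x)))
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte; the state is kept as a double < 2^32
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b)
    # 32-bit modular multiply by the FNV prime 16777619, split into 16-bit
    # halves so every intermediate stays exactly representable in a double
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

canonical_json <- function(x) {
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = 12,
                                null = "null", na = "null"))
}

is_count <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) &&
  x >= 1 && x == floor(x)
is_prob <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) &&
  x >= 0 && x <= 1
is_num1 <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x)
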