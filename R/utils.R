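#' @keywords internal
"_PACKAGE"

# 32-bit FNV-1a over the UTF-8 bytes of a string; returned as 8 hex chars.
# Used for prompt/config fingerprints only (auditing, not cryptography).
fnv1a_hex <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(enc2utf8(x))
  # work in doubles; a 32x24-bit product exceeds 2^53, so multiply in halves
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    hi <- h %/% 65536
    h <- (h %% 65536 * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Fingerprint a string or R object
#'
#' Stable 8-hex-digit fingerprint used to stamp prompts, predictions and
#' resolved run configurations so that an artifact can be traced back to the
#' exact configuration that produced it.
#'
#' @param x A character scalar or any object serialisable by
#'   [jsonlite::toJSON()].
#' @return An 8-character lowercase hex string.
#' @export
#' @examples
#' fingerprint("hello")
#' fingerprint(list(a = 1, b = "x"))
fingerprint <- function(x) {
  if (!is.character(x) || length(x) != 1L) {
    x <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                       null = "null", force = TRUE))
  }
  fnv1a_hex(x)
}

# Internal: %||%
`%||%` <- function(a, b) if (is.null(a)) b else a

# Whitespace tokeniser used for word counts and word-window chunking.
ws_tokens <- function(text) {
  m <- gregexpr("\\S+", text)[[1]]
  if (m[1] == -1L) {
    return(data.frame(start = integer(0), end = integer(0),
                      token = character(0), stringsAsFactors = FALSE))
  }
  len <- attr(m, "match.length")
  data.frame(start = as.integer(m), end = as.integer(m) + len - 1L,
             token = substring(text, m, m + len - 1L),
             stringsAsFactors = FALSE)
}

word_count <- function(text) {
  vapply(text, function(t) {
    m <- gregexpr("\\S+", t)[[1]]
    if (m[1] == -1L) 0L else length(m)
  }, integer(1), USE.NAMES = FALSE)
}

# Evaluate expr under a fixed RNG state without disturbing the caller's.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# Format a date / datetime for serialization (ISO-8601, timezone-naive).
iso_date <- function(d) format(d, "%Y-%m-%d")
iso_datetime <- function(d) format(d, "%Y-%m-%dT%H:%M:%S")

parse_datetime <- function(x) {
  as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}
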