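# Small stable string hash used for reproducible identifiers (block and
# island ids, config snapshot hashes). FNV-1a, 32 bit, done in doubles with
# an exact split multiply so the result is identical on every platform.

fnv1a32 <- function(x) {
  vapply(x, function(s) {
    bytes <- utf8ToInt(enc2utf8(s))
    h <- 2166136261
    for (b in bytes) {
      h <- bitwXor32(h, b %% 256)
      # h * 16777619 mod 2^32, 16777619 = 2^24 + 403
      h <- ((h %% 256) * 16777216 + h * 403) %% 4294967296
    }
    sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
  }, character(1), USE.NAMES = FALSE)
}

bitwXor32 <- function(a, b) {
  # a < 2^32 may exceed .Machine$integer.max; split into two 16-bit halves
  hi <- bitwXor(a %/% 65536, b %/% 65536)
  lo <- bitwXor(a %% 65536, b %% 65536)
  hi * 65536 + lo
}

# Short hex id in the style of the break ids shown by the method's web
# databases (six hex digits).
stable_id <- function(..., n = 6) {
  substr(fnv1a32(paste(..., sep = "\x1f")), 1, n)
}
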