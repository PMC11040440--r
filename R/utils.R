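# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fingerprint an R object
#'
#' 64-bit FNV-1a hash of the serialized object, returned as a hex string.
#' Used to tie cohorts to the configuration that generated them and to
#' freeze discovery artifacts before validation.
#'
#' @param x any serializable R object.
#' @return a 16-character hex string.
#' @export
fingerprint <- function(x) {
  bytes <- as.integer(serialize(x, connection = NULL, version = 2))
  # drop the serialization header (platform/version dependent first 14 bytes)
  bytes <- bytes[-seq_len(14)]
  # FNV-1a, 64-bit, carried as two 32-bit halves to stay in double precision
  hi <- 0xcbf29ce4; lo <- 0x84222325
  p_hi <- 0x00000100; p_lo <- 0x000001b3
  two32 <- 4294967296
  for (b in bytes) {
    low8 <- lo %% 256
    lo <- lo - low8 + bitwXor(as.integer(low8), as.integer(b))
    # (hi,lo) * (p_hi,p_lo) mod 2^64, via 16-bit limbs
    a0 <- lo %% 65536; a1 <- lo %/% 65536; a2 <- hi %% 65536; a3 <- hi %/% 65536
    b0 <- p_lo %% 65536; b1 <- p_lo %/% 65536; b2 <- p_hi %% 65536
    c0 <- a0 * b0
    c1 <- a1 * b0 + a0 * b1 + c0 %/% 65536
    c2 <- a2 * b0 + a1 * b1 + a0 * b2 + c1 %/% 65536
    c3 <- a3 * b0 + a2 * b1 + a1 * b2 + c2 %/% 65536
    lo <- (c0 %% 65536) + (c1 %% 65536) * 65536
    hi <- (c2 %% 65536) + (c3 %% 65536) * 65536
  }
  sprintf("%04x%04x%04x%04x",
          as.integer(hi %/% 65536), as.integer(hi %% 65536),
          as.integer(lo %/% 65536), as.integer(lo %% 65536))
}

# weighted mean/variance of a 0/1 (or numeric) vector; variance is the
# sandwich-style variance of the weighted mean with frequency-type weights:
# Var(sum w y / sum w) = sum w_i^2 (y_i - m)^2 / (sum w)^2
weighted_mean_se <- function(y, w) {
  sw <- sum(w)
  m <- sum(w * y) / sw
  se <- sqrt(sum((w * (y - m))^2)) / sw
  list(mean = m, se = se)
}

# derive seed streams below 2^31 from a master seed
derive_seed <- function(seed, k) {
  (as.double(seed) * 2654435761 + k * 40503) %% 2147483647
}

stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_binary01 <- function(x) {
  (is.numeric(x) || is.logical(x)) && all(x %in% c(0, 1))
}
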