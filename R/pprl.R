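#' Extract character n-grams from a normalized value
#'
#' With padding, the value is wrapped in `n - 1` boundary symbols (`_`) on
#' each side; grams overlap with stride 1 and repeats are kept (a multiset).
#'
#' @param value Single normalized string (see [normalize_value()]).
#' @param n Gram size (default 2 = bigrams).
#' @param padding Wrap with boundary symbols (default `TRUE`).
#' @return Character vector of grams; empty for empty/missing input.
#' @export
#' @examples
#' extract_ngrams("ANNA")  # "_A" "AN" "NN" "NA" "A_"
extract_ngrams <- function(value, n = 2, padding = TRUE) {
  if (length(value) != 1 || is.na(value) || !nzchar(value)) return(character(0))
  if (padding && n > 1) {
    pad <- strrep("_", n - 1)
    value <- paste0(pad, value, pad)
  }
  len <- nchar(value)
  if (len < n) return(character(0))
  substring(value, 1:(len - n + 1), n:len)
}

#' Bloom-filter encoding configuration for privacy-preserving linkage
#'
#' Fields are encoded as fixed-length bit filters: each n-gram of the value
#' sets `k` positions obtained by keyed double hashing,
#' `pos_i = (h1 + i * h2) mod m`, where `h1`/`h2` come from HMAC-SHA256 under
#' `hmac_secret`. Similarity of two encoded values is computed on the bits
#' alone, so clear text never has to leave the encoding party.
#'
#' @param m Filter length in bits (default 500).
#' @param k Hash functions per gram (default 10).
#' @param n Gram size (default 2).
#' @param hmac_secret Secret string or raw bytes keying the hashes.
#' @param padding Pad values before gram extraction (default `TRUE`).
#' @return A `bloom_config` object (carries a per-config gram-hash cache).
#' @export
bloom_config <- function(m = 500, k = 10, n = 2, hmac_secret, padding = TRUE) {
  if (missing(hmac_secret) || length(hmac_secret) == 0) {
    stop("an hmac_secret is required", call. = FALSE)
  }
  m <- as.integer(m); k <- as.integer(k); n <- as.integer(n)
  if (m <= 0 || k < 1 || n < 1) stop("require m > 0, k >= 1, n >= 1", call. = FALSE)
  structure(
    list(m = m, k = k, n = n, hmac_secret = hmac_secret, padding = padding,
         cache = new.env(parent = emptyenv())),
    class = "bloom_config"
  )
}

# Keyed double-hash positions for a set of grams; memoised per config since
# the gram universe is small. Returns integer vector of 0-based positions.
.bloom_positions <- function(grams, config) {
  miss <- grams[!vapply(grams, exists, logical(1), envir = config$cache,
                        inherits = FALSE)]
  miss <- unique(miss)
  if (length(miss) > 0) {
    h <- openssl::sha256(miss, key = config$hmac_secret)
    h1 <- strtoi(substr(h, 1, 7), 16L)
    h2 <- strtoi(substr(h, 8, 14), 16L)
    for (i in seq_along(miss)) {
      assign(miss[i],
             as.integer((as.numeric(h1[i]) +
                           (0:(config$k - 1)) * as.numeric(h2[i])) %% config$m),
             envir = config$cache)
    }
  }
  if (length(grams) == 0) return(integer(0))
  unlist(lapply(grams, get, envir = config$cache), use.names = FALSE)
}

#' Encode a value (or its grams) as a Bloom field
#'
#' @param value Single string to encode, or `NULL` when `grams` is given.
#' @param config A [bloom_config()].
#' @param grams Optionally, a pre-extracted gram multiset.
#' @return A `bloom_field`: logical bit vector of length `m` with a
#'   `cardinality` attribute (number of set bits).
#' @export
bloom_encode <- function(value = NULL, config, grams = NULL) {
  stopifnot(inherits(config, "bloom_config"))
  if (is.null(grams)) {
    grams <- extract_ngrams(
      if (is.null(value)) NA_character_ else value,
      n = config$n, padding = config$padding
    )
  }
  bits <- logical(config$m)
  if (length(grams) > 0) {
    bits[.bloom_positions(unique(grams), config) + 1L] <- TRUE
  }
  structure(bits, cardinality = sum(bits), m = config$m, class = "bloom_field")
}

#' Dice similarity of two Bloom fields
#'
#' `2 |a AND b| / (|a| + |b|)`; defined as 1 when both filters are empty and
#' 0 when exactly one is.
#'
#' @param a,b `bloom_field` objects of equal length.
#' @return Similarity in `[0, 1]`.
#' @export
dice_similarity <- function(a, b) {
  stopifnot(inherits(a, "bloom_field"), inherits(b, "bloom_field"))
  if (length(a) != length(b)) stop("Bloom filter length mismatch", call. = FALSE)
  ca <- sum(a); cb <- sum(b)
  if (ca == 0 && cb == 0) return(1)
  if (ca == 0 || cb == 0) return(0)
  2 * sum(a & b) / (ca + cb)
}

#' Clear-text Dice similarity of two gram multisets
#'
#' The oracle the Bloom encoding approximates: `2 |A ∩ B| / (|A| + |B|)` on
#' gram multisets (intersection with multiplicity).
#'
#' @param ga,gb Character vectors of grams (repeats kept).
#' @return Similarity in `[0, 1]`.
#' @export
dice_grams <- function(ga, gb) {
  na <- length(ga); nb <- length(gb)
  if (na == 0 && nb == 0) return(1)
  if (na == 0 || nb == 0) return(0)
  u <- unique(c(ga, gb))
  inter <- sum(pmin(tabulate(match(ga, u), length(u)),
                    tabulate(match(gb, u), length(u))))
  2 * inter / (na + nb)
}

#' Serialize a Bloom field as lowercase hex
#'
#' Bit 0 of the filter is the most significant bit of byte 0; the filter is
#' zero-padded to a whole number of bytes. This layout is part of the
#' package's serialization contract.
#'
#' @param field A `bloom_field`.
#' @return Lowercase hex string.
#' @export
bloom_hex <- function(field) {
  stopifnot(inherits(field, "bloom_field"))
  bits <- as.integer(unclass(field))
  pad <- (8 - length(bits) %% 8) %% 8
  bits <- c(bits, rep(0L, pad))
  bytes <- colSums(matrix(bits, nrow = 8) * 2^(7:0))
  paste(sprintf("%02x", bytes), collapse = "")
}

#' Parse a hex-serialized Bloom field
#'
#' @param hex Lowercase hex string from [bloom_hex()].
#' @param m Filter length in bits.
#' @return A `bloom_field`.
#' @export
bloom_from_hex <- function(hex, m) {
  bytes <- strtoi(substring(hex, seq(1, nchar(hex) - 1, 2),
                            seq(2, nchar(hex), 2)), 16L)
  bits <- as.vector(vapply(bytes, function(b) as.integer((b %/% 2^(7:0)) %% 2), integer(8)))
  bits <- as.logical(bits[seq_len(m)])
  structure(bits, cardinality = sum(bits), m = as.integer(m),
            class = "bloom_field")
}

#' Locality-sensitive hashing keys for a Bloom field
#'
#' Samples `bands * band_bits` bit positions deterministically from `seed`
#' (fixed per store) and reads, for each band, the bit values at its
#' positions. Similar filters agree on most bits and therefore share bands
#' with high probability. Bands whose sampled bits are all zero emit no key,
#' so near-empty filters do not collapse into one giant bucket.
#'
#' @param field A `bloom_field`.
#' @param bands Number of bands Q (default 8).
#' @param band_bits Bits per band L (default 32).
#' @param seed Integer seed fixing the sampled positions.
#' @return Character vector of at most `bands` tagged keys.
#' @export
lsh_keys <- function(field, bands = 8, band_bits = 32, seed = 42) {
  stopifnot(inherits(field, "bloom_field"))
  m <- length(field)
  if (band_bits > m) stop("band_bits exceeds filter length", call. = FALSE)
  pos <- .lsh_positions(bands, band_bits, seed, m)
  bits <- as.integer(unclass(field))
  keys <- character(0)
  for (q in seq_len(bands)) {
    v <- bits[pos[[q]] + 1L]
    if (any(v == 1L)) {
      keys <- c(keys, paste0(q, ":", paste(v, collapse = "")))
    }
  }
  keys
}

# Deterministic band positions derived by hashing (seed, band, slot); no
# dependence on the global RNG stream.
.lsh_positions_cache <- new.env(parent = emptyenv())
.lsh_positions <- function(bands, band_bits, seed, m) {
  key <- paste(bands, band_bits, seed, m, sep = "/")
  if (!is.null(.lsh_positions_cache[[key]])) return(.lsh_positions_cache[[key]])
  labels <- as.vector(outer(seq_len(bands), seq_len(band_bits),
                            function(q, l) sprintf("lsh:%d:%d:%d", seed, q, l)))
  h <- openssl::sha256(labels)
  p <- strtoi(substr(h, 1, 7), 16L) %% m
  out <- split(p, rep(seq_len(bands), times = band_bits))
  .lsh_positions_cache[[key]] <- out
  out
}

#' @export
print.bloom_field <- function(x, ...) {
  cat(sprintf("<bloom_field> m=%d, %d bits set\n", length(x),
              attr(x, "cardinality")))
  invisible(x)
}
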