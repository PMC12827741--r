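# Bit-regrouping codec between raw bytes and a 2^b-character alphabet.
.bits_per_char <- function(alphabet) {
  n <- length(alphabet)
  b <- as.integer(round(log2(n)))
  if (2^b != n) {
    stop("output_alphabet size must be a power of two (16, 32 or 64)",
         call. = FALSE)
  }
  b
}

.raw_to_alphabet <- function(bytes, alphabet) {
  b <- .bits_per_char(alphabet)
  bits <- as.integer(rawToBits(bytes))  # little-endian within byte
  # reorder to MSB-first per byte for a stable, documented layout
  bits <- as.vector(matrix(bits, nrow = 8)[8:1, ])
  pad <- (b - length(bits) %% b) %% b
  bits <- c(bits, rep(0L, pad))
  idx <- colSums(matrix(bits, nrow = b) * 2^((b - 1):0)) + 1L
  paste(alphabet[idx], collapse = "")
}

.alphabet_to_raw <- function(x, alphabet, n_bytes) {
  b <- .bits_per_char(alphabet)
  idx <- match(strsplit(x, "")[[1]], alphabet) - 1L
  if (anyNA(idx)) stop("character outside output alphabet", call. = FALSE)
  bits <- as.vector(vapply(idx, function(v) as.integer((v %/% 2^((b - 1):0)) %% 2),
                           integer(b)))
  if (length(bits) < 8L * n_bytes) stop("encoded string too short", call. = FALSE)
  bits <- bits[seq_len(8L * n_bytes)]
  bytes <- colSums(matrix(bits, nrow = 8) * 2^(7:0))
  as.raw(bytes)
}

#' Configuration for derived, non-persistent pseudonyms (CryptoIDs)
#'
#' A CryptoID is derived from a base pseudonym by deterministic authenticated
#' symmetric encryption (an SIV construction: the IV is a keyed hash of the
#' plaintext, so equal inputs give equal outputs and tampering or a wrong key
#' is detected on inversion). Because derivation is deterministic, CryptoIDs
#' need no storage: they are regenerated on every access.
#'
#' @param secret_key Secret string or raw bytes; expanded internally to the
#'   two 256-bit keys (MAC and cipher) the construction needs.
#' @param base_type Name of the pseudonym type the CryptoID is derived from
#'   (informational; used by stores when registering the type).
#' @param output_alphabet Character set for the encoded output; its size must
#'   be a power of two. Default: the 32-character PID alphabet.
#' @return A `cryptoid_config` object.
#' @export
cryptoid_config <- function(secret_key, base_type = "pid",
                            output_alphabet = .pid_default_alphabet) {
  if (missing(secret_key) || length(secret_key) == 0) {
    stop("a secret_key is required", call. = FALSE)
  }
  chars <- strsplit(output_alphabet, "")[[1]]
  .bits_per_char(chars)  # validates size
  structure(
    list(
      mac_key = openssl::sha256(charToRaw(paste0("mac:", paste(secret_key, collapse = "")))),
      enc_key = openssl::sha256(charToRaw(paste0("enc:", paste(secret_key, collapse = "")))),
      base_type = base_type,
      alphabet = chars
    ),
    class = "cryptoid_config"
  )
}

#' Derive a CryptoID from a base pseudonym (or invert it)
#'
#' `FORWARD` maps a base pseudonym to its CryptoID; `INVERSE` recovers the
#' base pseudonym. Forward-then-inverse is the identity; inversion under a
#' wrong key or of a tampered value fails with an authentication error.
#'
#' @param value Non-empty string: the base pseudonym (`FORWARD`) or a
#'   CryptoID (`INVERSE`).
#' @param config A [cryptoid_config()].
#' @param direction `"FORWARD"` or `"INVERSE"`.
#' @return A single string.
#' @export
#' @examples
#' cfg <- cryptoid_config("secret")
#' cid <- cryptoid_derive("PID12345", cfg)
#' cryptoid_derive(cid, cfg, "INVERSE")
cryptoid_derive <- function(value, config, direction = c("FORWARD", "INVERSE")) {
  stopifnot(inherits(config, "cryptoid_config"))
  direction <- match.arg(direction)
  if (length(value) != 1 || is.na(value) || !nzchar(value)) {
    stop("value must be a single non-empty string", call. = FALSE)
  }
  if (direction == "FORWARD") {
    pt <- charToRaw(value)
    iv <- openssl::sha256(pt, key = config$mac_key)[1:16]
    ct <- openssl::aes_cbc_encrypt(pt, key = config$enc_key, iv = iv)
    .raw_to_alphabet(c(iv, as.raw(ct)), config$alphabet)
  } else {
    n_chars <- nchar(value)
    b <- .bits_per_char(config$alphabet)
    n_bytes <- (n_chars * b) %/% 8L
    bytes <- .alphabet_to_raw(value, config$alphabet, n_bytes)
    if (n_bytes <= 16L) stop("CryptoID too short to decode", call. = FALSE)
    iv <- bytes[1:16]
    ct <- bytes[-(1:16)]
    pt <- tryCatch(
      openssl::aes_cbc_decrypt(ct, key = config$enc_key, iv = iv),
      error = function(e) stop("CryptoID authentication failed (wrong key or corrupted value)",
                               call. = FALSE)
    )
    check_iv <- openssl::sha256(pt, key = config$mac_key)[1:16]
    if (!identical(as.raw(check_iv), as.raw(iv))) {
      stop("CryptoID authentication failed (wrong key or corrupted value)",
           call. = FALSE)
    }
    rawToChar(pt)
  }
}

#' Generate a vocabulary-based pseudonym (ElasticID)
#'
#' Encodes a counter into a template of word and digit slots, e.g.
#' `"{w}-{w}{d}{d}"` with a 100-word vocabulary encodes
#' `100 * 100 * 10 * 10` distinct counters. Deterministic and injective up to
#' the template capacity; useful for short human-friendly labels (biosample
#' tubes and the like).
#'
#' @param counter Non-negative integer below the template capacity.
#' @param vocabulary Non-empty character vector of words.
#' @param pattern Template string; `{w}` is a vocabulary slot, `{d}` a digit
#'   slot, all other characters are kept verbatim.
#' @param max_length Optional maximum length of the generated string; an
#'   error is raised if exceeded.
#' @return A single string.
#' @export
#' @examples
#' elasticid_generate(7, c("OAK", "ELM"), "{w}-{d}")
elasticid_generate <- function(counter, vocabulary, pattern = "{w}{d}{d}",
                               max_length = NULL) {
  if (length(vocabulary) == 0) stop("vocabulary must be non-empty", call. = FALSE)
  counter <- as.numeric(counter)
  if (length(counter) != 1 || is.na(counter) || counter < 0 ||
      counter != floor(counter)) {
    stop("counter must be a single non-negative integer", call. = FALSE)
  }
  tokens <- regmatches(pattern, gregexpr("\\{[wd]\\}|[^{]+", pattern))[[1]]
  slots <- tokens[tokens %in% c("{w}", "{d}")]
  if (length(slots) == 0) stop("pattern contains no slots", call. = FALSE)
  radix <- ifelse(slots == "{w}", length(vocabulary), 10)
  capacity <- prod(radix)
  if (counter >= capacity) {
    stop(sprintf("counter %d exceeds pattern capacity %d",
                 counter, capacity), call. = FALSE)
  }
  # most-significant slot first
  values <- integer(length(radix))
  v <- counter
  for (i in rev(seq_along(radix))) {
    values[i] <- v %% radix[i]
    v <- v %/% radix[i]
  }
  slot_i <- 0L
  out <- vapply(tokens, function(tk) {
    if (tk == "{w}") {
      slot_i <<- slot_i + 1L
      vocabulary[values[slot_i] + 1L]
    } else if (tk == "{d}") {
      slot_i <<- slot_i + 1L
      as.character(values[slot_i])
    } else tk
  }, character(1))
  res <- paste(out, collapse = "")
  if (!is.null(max_length) && nchar(res) > max_length) {
    stop(sprintf("generated ElasticID '%s' exceeds max_length %d",
                 res, max_length), call. = FALSE)
  }
  res
}
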