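#' Generate a key pair for transport encryption
#'
#' Used when pseudonyms travel to a trusted third party: the sender encrypts
#' with the recipient's public key, only the recipient's private key decrypts.
#'
#' @param bits RSA modulus size (default 2048).
#' @return List with elements `private` (keep secret) and `public`.
#' @export
transport_keypair <- function(bits = 2048) {
  key <- openssl::rsa_keygen(bits)
  list(private = key, public = key$pubkey)
}

#' Hybrid-encrypt a pseudonym for a recipient
#'
#' The pseudonym itself is encrypted with a fresh symmetric session key
#' (fast, any payload size); the session key is wrapped asymmetrically with
#' the recipient's public key. Two encryptions of the same pseudonym differ
#' because the session key and IV are freshly drawn each call.
#'
#' @param pseudonym Single string to protect.
#' @param public_key Recipient public key from [transport_keypair()].
#' @return A `transport_envelope`: base64 ciphertext, IV and wrapped session
#'   key.
#' @export
transport_encrypt <- function(pseudonym, public_key) {
  if (length(pseudonym) != 1 || is.na(pseudonym)) {
    stop("pseudonym must be a single string", call. = FALSE)
  }
  env <- openssl::encrypt_envelope(charToRaw(pseudonym), public_key)
  structure(
    list(
      data = openssl::base64_encode(env$data),
      iv = openssl::base64_encode(env$iv),
      session = openssl::base64_encode(env$session)
    ),
    class = "transport_envelope"
  )
}

#' Decrypt a transport envelope
#'
#' Fails with an error (never a wrong plaintext) when the private key does
#' not match the envelope.
#'
#' @param envelope A `transport_envelope` from [transport_encrypt()].
#' @param private_key Recipient private key.
#' @return The pseudonym string.
#' @export
transport_decrypt <- function(envelope, private_key) {
  stopifnot(inherits(envelope, "transport_envelope"))
  pt <- tryCatch(
    openssl::decrypt_envelope(
      openssl::base64_decode(envelope$data),
      iv = openssl::base64_decode(envelope$iv),
      session = openssl::base64_decode(envelope$session),
      key = private_key
    ),
    error = function(e) stop("envelope decryption failed: wrong key or corrupted envelope",
                             call. = FALSE)
  )
  rawToChar(pt)
}

#' @export
print.transport_envelope <- function(x, ...) {
  cat("<transport_envelope>", substr(x$data, 1, 24), "...\n")
  invisible(x)
}
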