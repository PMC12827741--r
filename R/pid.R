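# GF(2^5) arithmetic for the PID check code.
# Field generated by the primitive polynomial x^5 + x^2 + 1; elements are the
# integers 0..31, addition is XOR, multiplication via exp/log tables over the
# multiplicative group of order 31.
.gf32 <- local({
  exp_tab <- integer(31)
  a <- 1L
  for (i in 0:30) {
    exp_tab[i + 1L] <- a
    a <- bitwShiftL(a, 1L)
    if (bitwAnd(a, 32L) != 0L) a <- bitwXor(a, 37L)
  }
  log_tab <- rep(NA_integer_, 32)
  log_tab[exp_tab + 1L] <- 0:30
  list(exp = exp_tab, log = log_tab)
})

# Multiply a vector of field elements by field elements (vectorized, 0-aware).
gf_mul <- function(x, y) {
  out <- integer(length(x))
  nz <- x != 0L & y != 0L
  out[nz] <- .gf32$exp[(.gf32$log[x[nz] + 1L] + .gf32$log[y[nz] + 1L]) %% 31L + 1L]
  out
}

.pid_default_alphabet <- "0123456789ACDEFGHJKLMNPQRTUVWXYZ"

#' Configuration for check-character patient identifiers (PIDs)
#'
#' A PID is a fixed-length string over a 32-character alphabet: a keyed
#' scrambling of a creation counter (the payload) followed by two check
#' characters from a minimum-distance-3 code over GF(32). Distance 3 buys
#' either correction of any single wrong character (`mode = "CORRECT1"`) or
#' guaranteed detection of any two wrong characters (`mode = "DETECT2"`) —
#' never both at once, so the mode is configuration.
#'
#' @param mixing_key Secret string or raw vector keying the payload
#'   scrambling. Two stores with different keys emit disjoint-looking PID
#'   sequences for the same counters.
#' @param payload_length Number of payload characters (default 6, giving
#'   capacity `32^6 = 2^30` identifiers). Allowed range 2..10.
#' @param mode `"CORRECT1"` (default) or `"DETECT2"`.
#' @param alphabet 32 distinct characters; the default omits the visually
#'   ambiguous letters B, I, O and S.
#' @return A `pid_config` object.
#' @export
pid_config <- function(mixing_key,
                       payload_length = 6,
                       mode = c("CORRECT1", "DETECT2"),
                       alphabet = .pid_default_alphabet) {
  mode <- match.arg(mode)
  chars <- strsplit(alphabet, "")[[1]]
  if (length(chars) != 32 || anyDuplicated(chars)) {
    stop("alphabet must consist of exactly 32 distinct characters",
         call. = FALSE)
  }
  if (any(c("B", "I", "O", "S") %in% chars)) {
    stop("alphabet must not contain the ambiguous letters B, I, O, S",
         call. = FALSE)
  }
  payload_length <- as.integer(payload_length)
  if (payload_length < 2 || payload_length > 10) {
    stop("payload_length must be between 2 and 10", call. = FALSE)
  }
  if (missing(mixing_key) || length(mixing_key) == 0) {
    stop("a mixing_key is required", call. = FALSE)
  }
  structure(
    list(alphabet = chars, payload_length = payload_length,
         check_length = 2L, total_length = payload_length + 2L,
         mixing_key = mixing_key, mode = mode),
    class = "pid_config"
  )
}

# Keyed 4-round Feistel permutation on 5*payload_length bits. Round function
# is HMAC-SHA256 under the mixing key, truncated to 28 bits. Vectorized over v.
.pid_feistel <- function(v, config, inverse = FALSE) {
  bits <- 5L * config$payload_length
  b1 <- bits %/% 2L
  b2 <- bits - b1
  lsz <- ifelse((1:4) %% 2L == 1L, b1, b2)  # |L| entering round r
  rsz <- ifelse((1:4) %% 2L == 1L, b2, b1)  # |R| entering round r
  roundF <- function(R, r, width) {
    h <- openssl::sha256(sprintf("pid:%d:%.0f", r, R), key = config$mixing_key)
    strtoi(substr(h, 1, 7), 16L) %% 2^width
  }
  if (!inverse) {
    for (r in 1:4) {
      L <- v %/% 2^rsz[r]
      R <- v %% 2^rsz[r]
      Fv <- roundF(R, r, lsz[r])
      v <- R * 2^lsz[r] + bitwXor(as.integer(L), as.integer(Fv))
    }
  } else {
    for (r in 4:1) {
      X <- v %% 2^lsz[r]          # L xor F(R)
      R <- v %/% 2^lsz[r]         # former R
      Fv <- roundF(R, r, lsz[r])
      L <- bitwXor(as.integer(X), as.integer(Fv))
      v <- L * 2^rsz[r] + R
    }
  }
  v
}

# Check-symbol computation: codeword c_0..c_7 (c_0, c_1 = checks) must satisfy
# sum_j c_j alpha^j = 0 and sum_j c_j alpha^{2j} = 0, a distance-3
# Reed-Solomon-style constraint. Vectorized over rows of the payload matrix.
.pid_checks <- function(payload_mat) {
  n <- nrow(payload_mat)
  p <- ncol(payload_mat)
  A <- integer(n)
  B <- integer(n)
  for (j in seq_len(p)) {
    cj <- j + 1L  # code position of payload column j
    A <- bitwXor(A, gf_mul(payload_mat[, j], rep(.gf32$exp[cj %% 31L + 1L], n)))
    B <- bitwXor(B, gf_mul(payload_mat[, j], rep(.gf32$exp[(2L * cj) %% 31L + 1L], n)))
  }
  AB <- bitwXor(A, B)
  # c1 = (A + B) / (alpha + alpha^2); alpha = 2, alpha^2 = 4, sum = 6
  inv6 <- .gf32$exp[(31L - .gf32$log[7L]) %% 31L + 1L]  # 6 + 1 = 7 index
  c1 <- gf_mul(AB, rep(inv6, n))
  c0 <- bitwXor(A, gf_mul(c1, rep(2L, n)))
  cbind(c0, c1)
}

#' Generate PIDs from creation counters
#'
#' Deterministic and injective for a fixed configuration: the counter is
#' scrambled by a keyed Feistel permutation, written as base-32 payload
#' characters, and extended with two check characters.
#'
#' @param counter Vector of non-negative integers, each `< 32^payload_length`.
#' @param config A [pid_config()].
#' @return Character vector of PIDs (uppercase).
#' @export
#' @examples
#' cfg <- pid_config(mixing_key = "example-key")
#' pid_encode(0:2, cfg)
pid_encode <- function(counter, config) {
  stopifnot(inherits(config, "pid_config"))
  counter <- as.numeric(counter)
  cap <- 32^config$payload_length
  if (any(is.na(counter)) || any(counter < 0) || any(counter >= cap) ||
      any(counter != floor(counter))) {
    stop("counter must be an integer in [0, 32^payload_length)", call. = FALSE)
  }
  v <- .pid_feistel(counter, config)
  p <- config$payload_length
  digits <- matrix(0L, nrow = length(v), ncol = p)
  for (j in p:1) {
    digits[, j] <- as.integer(v %% 32)
    v <- v %/% 32
  }
  checks <- .pid_checks(digits)
  sym <- cbind(digits, checks)  # display order: payload then c0, c1
  apply(sym, 1L, function(s) paste(config$alphabet[s + 1L], collapse = ""))
}

#' Verify (and optionally correct) PIDs
#'
#' Input is case-insensitive. In `CORRECT1` mode any single-character
#' substitution of a valid PID is repaired and reported as `CORRECTED` with
#' the original counter; in `DETECT2` mode any one or two substitutions yield
#' `INVALID`. Malformed input (wrong length, characters outside the alphabet)
#' is `INVALID`, never an error.
#'
#' @param pid Character vector of candidate PIDs.
#' @param config A [pid_config()].
#' @return Tibble with columns `pid`, `status` (`VALID`/`CORRECTED`/
#'   `INVALID`), `counter` (original counter, `NA` if invalid) and
#'   `corrected_pid` (`NA` unless `CORRECTED`).
#' @export
pid_verify <- function(pid, config) {
  stopifnot(inherits(config, "pid_config"))
  pid_in <- as.character(pid)
  pid_up <- toupper(pid_in)
  n <- length(pid_up)
  p <- config$payload_length
  total <- config$total_length
  status <- rep("INVALID", n)
  counter <- rep(NA_real_, n)
  corrected <- rep(NA_character_, n)

  ok <- !is.na(pid_up) & nchar(pid_up) == total
  if (any(ok)) {
    chars <- matrix(NA_integer_, nrow = n, ncol = total)
    split_ok <- strsplit(pid_up[ok], "")
    idx_ok <- which(ok)
    for (i in seq_along(idx_ok)) {
      m <- match(split_ok[[i]], config$alphabet) - 1L
      chars[idx_ok[i], ] <- m
    }
    ok <- ok & !apply(is.na(chars), 1L, any)
  }

  if (any(ok)) {
    rows <- which(ok)
    sym <- chars[rows, , drop = FALSE]
    # code order: c_0 = display pos total-1, c_1 = display pos total,
    # c_{j} = display pos j-1 for j = 2..p+1
    code <- cbind(sym[, total - 1L, drop = FALSE], sym[, total, drop = FALSE],
                  sym[, 1:p, drop = FALSE])
    m <- nrow(code)
    S1 <- integer(m)
    S2 <- integer(m)
    for (j in 0:(p + 1L)) {
      S1 <- bitwXor(S1, gf_mul(code[, j + 1L], rep(.gf32$exp[j %% 31L + 1L], m)))
      S2 <- bitwXor(S2, gf_mul(code[, j + 1L], rep(.gf32$exp[(2L * j) %% 31L + 1L], m)))
    }
    clean <- S1 == 0L & S2 == 0L
    decode_counter <- function(payload_mat) {
      v <- numeric(nrow(payload_mat))
      for (j in seq_len(p)) v <- v * 32 + payload_mat[, j]
      .pid_feistel(v, config, inverse = TRUE)
    }
    if (any(clean)) {
      rws <- rows[clean]
      counter[rws] <- decode_counter(code[clean, 2L + 1:p, drop = FALSE])
      status[rws] <- "VALID"
    }
    if (config$mode == "CORRECT1") {
      fixable <- !clean & S1 != 0L & S2 != 0L
      if (any(fixable)) {
        pos <- (.gf32$log[S2[fixable] + 1L] - .gf32$log[S1[fixable] + 1L]) %% 31L
        in_range <- pos <= p + 1L
        if (any(in_range)) {
          fi <- which(fixable)[in_range]
          pp <- pos[in_range]
          err <- .gf32$exp[(.gf32$log[S1[fi] + 1L] - pp) %% 31L + 1L]
          codef <- code[fi, , drop = FALSE]
          for (q in seq_along(fi)) {
            codef[q, pp[q] + 1L] <- bitwXor(codef[q, pp[q] + 1L], err[q])
          }
          rws <- rows[fi]
          counter[rws] <- decode_counter(codef[, 2L + 1:p, drop = FALSE])
          status[rws] <- "CORRECTED"
          disp <- cbind(codef[, 2L + 1:p, drop = FALSE], codef[, 1:2, drop = FALSE])
          corrected[rws] <- apply(disp, 1L, function(s)
            paste(config$alphabet[s + 1L], collapse = ""))
        }
      }
    }
  }
  tibble::tibble(pid = pid_in, status = status, counter = counter,
                 corrected_pid = corrected)
}

#' Decode a PID back to its creation counter
#'
#' @inheritParams pid_verify
#' @return Numeric vector of counters (`NA` where invalid).
#' @export
pid_decode <- function(pid, config) {
  pid_verify(pid, config)$counter
}
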