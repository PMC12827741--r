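# Independent naive reference implementations used as oracles. Deliberately
# written from first principles (loops, table()), sharing no code with the
# package's scoring path.

oracle_bigrams <- function(x) {
  x2 <- paste0("_", x, "_")
  n <- nchar(x2)
  out <- character(n - 1)
  for (i in 1:(n - 1)) out[i] <- substr(x2, i, i + 1)
  out
}

oracle_dice <- function(a, b) {
  ta <- table(oracle_bigrams(a))
  tb <- table(oracle_bigrams(b))
  common <- intersect(names(ta), names(tb))
  inter <- 0
  for (g in common) inter <- inter + min(ta[[g]], tb[[g]])
  2 * inter / (sum(ta) + sum(tb))
}

# Weighted similarity of two normalized records under a comparator table
# (recomputes the weights log2((1-e)/f) itself).
oracle_score <- function(a, b, cmp) {
  num <- 0; den <- 0
  for (i in seq_len(nrow(cmp))) {
    f <- cmp$field[i]
    av <- a[[f]]; bv <- b[[f]]
    if (is.null(av) || is.null(bv) || is.na(av) || is.na(bv)) next
    s <- if (cmp$comparator[i] == "NGRAM_DICE") {
      oracle_dice(av, bv)
    } else {
      if (av == bv) 1 else 0
    }
    w <- log2((1 - cmp$e[i]) / cmp$f[i])
    num <- num + w * s
    den <- den + w
  }
  if (den == 0) return(NA_real_)
  num / den
}

# Naive all-pairs sequential matcher: ingests normalized records in order,
# scoring each against every previously kept record (no blocking, no index).
# Mirrors the ingestion policy: MATCH reuses the best record, TENTATIVE and
# NON_MATCH append a new one. Returns per-row decision and best index.
oracle_run <- function(norm_records, cmp, t_low, t_high) {
  kept <- list()
  decision <- character(length(norm_records))
  best <- rep(NA_integer_, length(norm_records))
  patient <- rep(NA_integer_, length(norm_records))
  for (i in seq_along(norm_records)) {
    r <- norm_records[[i]]
    bs <- -Inf; bk <- NA_integer_
    if (length(kept) > 0) {
      for (k in seq_along(kept)) {
        s <- oracle_score(r, kept[[k]], cmp)
        if (!is.na(s) && s > bs) { bs <- s; bk <- k }
      }
    }
    if (is.na(bk)) {
      decision[i] <- "NON_MATCH"
    } else if (bs >= t_high) {
      decision[i] <- "MATCH"
    } else if (bs >= t_low) {
      decision[i] <- "TENTATIVE"
    } else {
      decision[i] <- "NON_MATCH"
    }
    best[i] <- bk
    if (decision[i] == "MATCH") {
      patient[i] <- bk
    } else {
      kept[[length(kept) + 1]] <- r
      patient[i] <- length(kept)
    }
  }
  list(decision = decision, best = best, patient = patient)
}
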