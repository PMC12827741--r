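bc <- bloom_config(hmac_secret = "pprl-test")

test_that("n-gram extraction pads, overlaps and keeps repeats", {
  expect_setequal(extract_ngrams("ANNA"), c("_A", "AN", "NN", "NA", "A_"))
  expect_equal(extract_ngrams("A"), c("_A", "A_"))
  expect_equal(extract_ngrams(""), character(0))
  expect_equal(extract_ngrams(NA_character_), character(0))
  expect_equal(sort(extract_ngrams("NANA")),
               sort(c("_N", "NA", "AN", "NA", "A_")))  # repeats kept
  expect_equal(extract_ngrams("ABC", n = 3), c("__A", "_AB", "ABC", "BC_", "C__"))
})

test_that("Bloom encoding is deterministic, keyed and bounded", {
  a <- bloom_encode("MEIER", bc)
  b <- bloom_encode("MEIER", bc)
  expect_identical(unclass(a), unclass(b))
  expect_lte(attr(a, "cardinality"), bc$k * length(extract_ngrams("MEIER")))
  empty <- bloom_encode("", bc)
  expect_equal(attr(empty, "cardinality"), 0)
  other <- bloom_encode("MEIER", bloom_config(hmac_secret = "other-key"))
  expect_false(identical(unclass(a), unclass(other)))
  small <- bloom_config(m = 16, k = 2, hmac_secret = "s")
  two <- bloom_encode(grams = c("AB", "CD"), config = small)
  expect_lte(attr(two, "cardinality"), 4)
})

test_that("Dice similarity on filters matches its definition", {
  x <- bloom_encode("MEIER", bc)
  expect_equal(dice_similarity(x, x), 1)
  empty <- bloom_encode("", bc)
  expect_equal(dice_similarity(empty, empty), 1)
  expect_equal(dice_similarity(x, empty), 0)
  mk <- function(bits) structure(bits, cardinality = sum(bits), m = length(bits),
                                 class = "bloom_field")
  a <- mk(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  b <- mk(c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(dice_similarity(a, b), 2 * 2 / 6)
  expect_error(dice_similarity(x, mk(TRUE)), "mismatch")
})

test_that("hex serialization is bit-exact and reversible", {
  x <- bloom_encode("MEIER", bc)
  hx <- bloom_hex(x)
  expect_match(hx, "^[0-9a-f]+$")
  expect_equal(nchar(hx), 2 * ceiling(bc$m / 8))
  back <- bloom_from_hex(hx, bc$m)
  expect_identical(unclass(back), unclass(x))
  # bit 0 of the filter is the MSB of byte 0
  one <- structure(c(TRUE, rep(FALSE, 7)), cardinality = 1, m = 8,
                   class = "bloom_field")
  expect_equal(bloom_hex(one), "80")
  # no plaintext substring leaks into the serialization
  expect_false(grepl("meier", hx, ignore.case = TRUE))
})

test_that("Bloom Dice tracks clear-text gram Dice on typo-variant pairs", {
  # fidelity in the comparator's operating regime: pairs of a name and a
  # single-typo variant of it (what candidate pairs look like after blocking)
  fp <- name_pool("first")
  typo_model <- error_model(substitution = 0.5, insertion = 0.25,
                            deletion = 0.25, transposition = 0.25,
                            field_missing = 0, date_component_error = 0)
  withr::with_seed(31, {
    gaps <- replicate(300, {
      a <- sample(fp$name, 1)
      b <- corrupt_record(c(first_name = a), typo_model)$fields[["first_name"]]
      abs(dice_similarity(bloom_encode(a, bc), bloom_encode(b, bc)) -
            dice_grams(unique(extract_ngrams(a)), unique(extract_ngrams(b))))
    })
    expect_lte(mean(gaps), 0.05)
  })
})

test_that("Bloom Dice equals clear-text Dice in the collision-free regime", {
  # secret chosen so the 25-gram universe of these names maps to
  # distinct positions (checked): a genuinely collision-free regime
  big <- bloom_config(m = 100000, k = 10, hmac_secret = "exact-1")
  names10 <- c("ANNA", "OTTO", "MEIER", "KURT", "LISE",
               "BERT", "MIRA", "JONAS", "KATI", "ROLF")
  for (i in 1:9) for (j in (i + 1):10) {
    expect_equal(
      dice_similarity(bloom_encode(names10[i], big),
                      bloom_encode(names10[j], big)),
      dice_grams(unique(extract_ngrams(names10[i])),
                 unique(extract_ngrams(names10[j]))))
  }
})

test_that("LSH keys are deterministic and band-bounded", {
  x <- bloom_encode("MEIER", bc)
  y <- bloom_encode("MEIER", bc)
  expect_identical(lsh_keys(x), lsh_keys(y))
  k1 <- lsh_keys(x, bands = 8, band_bits = 16, seed = 1)
  expect_lte(length(k1), 8)
  # flipping one bit can only change the bands that sample that position:
  # flip every set bit in turn and compare against the unflipped key count
  baseline <- length(lsh_keys(x, 8, 16, 1))
  z0 <- unclass(x)
  n_shared <- vapply(which(z0), function(flip) {
    z <- z0
    z[flip] <- FALSE
    z <- structure(z, cardinality = sum(z), m = length(z),
                   class = "bloom_field")
    length(intersect(lsh_keys(x, 8, 16, 1), lsh_keys(z, 8, 16, 1)))
  }, numeric(1))
  # 8 bands x 16 bits sample ~128 of 500 positions, so most flips disturb
  # no band at all and none disturbs more than a few
  expect_gte(mean(n_shared), baseline - 1)
  expect_true(all(n_shared >= baseline - 3))
  expect_error(lsh_keys(x, band_bits = bc$m + 1), "exceeds")
})

test_that("similar filters share at least one key with high probability", {
  # property at the documented example parameters Q=16, L=8
  fp <- name_pool("first")
  withr::with_seed(41, {
    share <- replicate(400, {
      a <- sample(fp$name, 1)
      b <- corrupt_record(c(first_name = a),
                          error_model(substitution = 0.7))$fields[["first_name"]]
      fa <- bloom_encode(a, bc)
      fb <- bloom_encode(b, bc)
      if (dice_similarity(fa, fb) < 0.8) return(NA)
      length(intersect(lsh_keys(fa, 16, 8, 7), lsh_keys(fb, 16, 8, 7))) >= 1
    })
    expect_gte(mean(share, na.rm = TRUE), 0.95)
  })
})
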