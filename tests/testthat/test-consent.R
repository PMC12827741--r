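demo_template <- function(st, validity_days = NULL) {
  consent_template(st, "broad", tibble::tibble(
    module_id = c("store_data", "share_pseudonymous", "recontact"),
    policy_ids = list("store", c("share", "export"), "recontact"),
    required = c(TRUE, FALSE, FALSE)
  ), validity_days = validity_days)
}

test_that("consent recording versions and supersedes prior records", {
  st <- new_store()
  demo_template(st)
  k <- create_patient(st, rec_anna())
  r1 <- record_consent(st, k, "broad",
                       c(store_data = "PERMIT", share_pseudonymous = "PERMIT"),
                       signed_date = "2024-01-10")
  expect_equal(r1$version, 1L)
  expect_equal(r1$status, "ACTIVE")
  expect_equal(unname(r1$choices["recontact"]), "DENY")  # optional defaults DENY
  r2 <- record_consent(st, k, "broad",
                       c(store_data = "PERMIT", share_pseudonymous = "DENY"),
                       signed_date = "2024-05-01")
  expect_equal(r2$version, 2L)
  recs <- st$consents[[k]]
  expect_equal(vapply(recs, `[[`, character(1), "status"),
               c("SUPERSEDED", "ACTIVE"))
  expect_error(record_consent(st, k, "broad", c(share_pseudonymous = "PERMIT")),
               "required")
  expect_error(record_consent(st, k, "nope", c(store_data = "PERMIT")),
               "unknown consent template")
})

test_that("policy checks: permit, withdrawal, expiry, absent", {
  st <- new_store()
  demo_template(st, validity_days = 5 * 365)
  k <- create_patient(st, rec_anna())
  record_consent(st, k, "broad",
                 c(store_data = "PERMIT", share_pseudonymous = "PERMIT"),
                 signed_date = "2024-01-10")
  expect_equal(check_policy(st, k, "share", "2024-03-01")$outcome, "PERMIT")
  withdraw_consent(st, k, "broad", withdrawal_date = "2024-06-01")
  expect_equal(check_policy(st, k, "share", "2024-03-01")$outcome, "PERMIT")
  expect_equal(check_policy(st, k, "share", "2024-07-01")$outcome, "DENY")
  # monotone after withdrawal
  expect_equal(check_policy(st, k, "share", "2030-01-01")$outcome, "DENY")
  # no record at all -> UNKNOWN
  k2 <- create_patient(st, rec_bert())
  expect_equal(check_policy(st, k2, "share")$outcome, "UNKNOWN")
  expect_error(withdraw_consent(st, k2, "broad"), "no active consent")
})

test_that("validity expiry denies fail-safe", {
  st <- new_store()
  demo_template(st, validity_days = 5 * 365)
  k <- create_patient(st, rec_anna())
  record_consent(st, k, "broad", c(store_data = "PERMIT"),
                 signed_date = "2020-01-01")
  expect_equal(check_policy(st, k, "store", "2024-12-01")$outcome, "PERMIT")
  expect_equal(check_policy(st, k, "store", "2026-01-01")$outcome, "DENY")
})

test_that("partial withdrawal denies named modules, keeps the rest", {
  st <- new_store()
  demo_template(st)
  k <- create_patient(st, rec_anna())
  record_consent(st, k, "broad",
                 c(store_data = "PERMIT", share_pseudonymous = "PERMIT",
                   recontact = "PERMIT"),
                 signed_date = "2024-01-10")
  withdraw_consent(st, k, "broad", withdrawal_date = "2024-06-01",
                   modules = "recontact")
  expect_equal(check_policy(st, k, "recontact", "2024-07-01")$outcome, "DENY")
  expect_equal(check_policy(st, k, "share", "2024-07-01")$outcome, "PERMIT")
  # history is append-only: both versions retained
  expect_length(st$consents[[k]], 2)
})

test_that("FHIR bundles carry Provenance exactly when a scan is attached", {
  st <- new_store()
  demo_template(st)
  k <- create_patient(st, rec_anna())
  plain <- record_consent(st, k, "broad", c(store_data = "PERMIT"),
                          signed_date = "2024-01-10")
  b1 <- consent_to_fhir(plain)
  types1 <- vapply(b1$entry, function(e) e$resource$resourceType, character(1))
  expect_equal(types1, "Consent")
  scanned <- record_consent(st, k, "broad", c(store_data = "PERMIT"),
                            signed_date = "2024-02-10",
                            scan = list(content = as.raw(1:64),
                                        media_type = "application/pdf"))
  b2 <- consent_to_fhir(scanned)
  types2 <- vapply(b2$entry, function(e) e$resource$resourceType, character(1))
  expect_setequal(types2, c("Consent", "DocumentReference", "Provenance"))
  prov <- b2$entry[[which(types2 == "Provenance")]]$resource
  refs <- vapply(prov$target, `[[`, character(1), "reference")
  expect_length(refs, 2)
  expect_true(any(grepl("^Consent/", refs)))
  expect_true(any(grepl("^DocumentReference/", refs)))
  expect_error(record_consent(st, k, "broad", c(store_data = "PERMIT"),
                              scan = list(content = as.raw(1),
                                          media_type = "image/gif")),
               "media type")
})

test_that("FHIR roundtrip preserves semantic content on random records", {
  st <- new_store()
  demo_template(st)
  k <- create_patient(st, rec_anna())
  withr::with_seed(55, {
    for (i in 1:100) {
      choices <- stats::setNames(
        sample(c("PERMIT", "DENY"), 3, TRUE),
        c("store_data", "share_pseudonymous", "recontact"))
      scan <- if (runif(1) < 0.5) {
        list(content = as.raw(sample(0:255, sample(10:80, 1), TRUE)),
             media_type = sample(c("application/pdf", "image/png"), 1))
      }
      rec <- record_consent(st, k, "broad", choices,
                            signed_date = as.Date("2024-01-01") + i,
                            scan = scan)
      json <- consent_to_fhir(rec, as_json = TRUE)
      back <- consent_from_fhir(json)
      expect_equal(back$patient, rec$patient)
      expect_equal(back$template_id, rec$template_id)
      expect_equal(back$version, rec$version)
      expect_equal(back$status, rec$status)
      expect_equal(back$signed_date, rec$signed_date)
      expect_equal(back$choices[sort(names(back$choices))],
                   rec$choices[sort(names(rec$choices))])
      expect_identical(back$scan$content, rec$scan$content)
      expect_identical(back$scan$media_type, rec$scan$media_type)
    }
  })
})
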