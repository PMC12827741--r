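test_that("sessions require a known API key and have unguessable ids", {
  sv <- demo_service()
  s1 <- create_session(sv, "key-a")
  s2 <- create_session(sv, "key-a")
  expect_false(s1 == s2)
  expect_gte(nchar(s1), 32)  # >= 128 bits hex
  expect_error(create_session(sv, "wrong"), "authentication")
})

test_that("token creation enforces grants, reasons and callback allow-list", {
  sv <- demo_service()
  s <- create_session(sv, "key-a")
  expect_error(create_token(sv, s, "ADD_PATIENT"), "reason")
  t1 <- create_token(sv, s, "ADD_PATIENT", reason = "enrollment visit")
  expect_gte(nchar(t1), 32)
  # role b has no DELETE grant
  sb <- create_session(sv, "key-b")
  expect_error(create_token(sv, sb, "DELETE_PATIENT", reason = "x"),
               "may not create")
  expect_error(create_token(sv, s, "ADD_PATIENT", reason = "x",
                            callback = list(url = "https://evil.example.com/cb")),
               "allow-listed")
  t2 <- create_token(sv, s, "ADD_PATIENT", reason = "x",
                     callback = list(url = "https://edc.example.org/cb",
                                     id_types = "pid"))
  expect_true(nzchar(t2))
  # reasons are logged in the audit trail
  at <- audit_trail(sv$store)
  expect_true(any(grepl("enrollment visit", at$details)))
})

test_that("ADD_PATIENT redemption splits caller-visible and callback pseudonyms", {
  sv <- demo_service()
  s <- create_session(sv, "key-a")
  tk <- create_token(sv, s, "ADD_PATIENT",
                     payload = list(id_types = "study_a_id"),
                     callback = list(url = "https://edc.example.org/cb",
                                     id_types = "pid"),
                     reason = "new patient")
  res <- redeem_token(sv, tk, list(fields = rec_anna()))
  expect_equal(res$outcome, "created")
  # the caller sees the study pseudonym but not the pid
  expect_true("study_a_id" %in% names(res$pseudonyms))
  expect_false("pid" %in% names(res$pseudonyms))
  # the pid went to the callback instead
  d <- callback_deliveries(sv)
  expect_length(d, 1)
  expect_equal(d[[1]]$url, "https://edc.example.org/cb")
  expect_true("pid" %in% names(d[[1]]$pseudonyms))
  expect_false("study_a_id" %in% names(d[[1]]$pseudonyms))
  # enrollment minted the tenant's project pseudonym
  p <- lookup_by_pseudonym(sv$store, "study_a_id",
                           res$pseudonyms$study_a_id[1])
  expect_true("study_a" %in% p$tenants)
})

test_that("single-use tokens redeem exactly once and invalidation cascades", {
  sv <- demo_service()
  s <- create_session(sv, "key-a")
  tk <- create_token(sv, s, "ADD_PATIENT", reason = "x")
  n0 <- n_patients(sv$store)
  redeem_token(sv, tk, list(fields = rec_anna()))
  expect_equal(n_patients(sv$store), n0 + 1)
  expect_error(redeem_token(sv, tk, list(fields = rec_bert())),
               "already redeemed")
  expect_equal(n_patients(sv$store), n0 + 1)  # no side effect
  tk2 <- create_token(sv, s, "ADD_PATIENT", reason = "x")
  expect_true(invalidate_session(sv, s))
  expect_error(redeem_token(sv, tk2, list(fields = rec_bert())),
               "redeemed or invalidated")
  expect_false(invalidate_session(sv, s))  # idempotent no-op
  # other sessions unaffected
  s2 <- create_session(sv, "key-a")
  tk3 <- create_token(sv, s2, "ADD_PATIENT", reason = "x")
  expect_no_error(redeem_token(sv, tk3, list(fields = rec_bert())))
})

test_that("permissions are deny-by-default with qualifier and tenant scoping", {
  sv <- demo_service()
  expect_equal(check_permission(sv, "study_a_role", "read-idtype", "study_a_id"),
               "allow")
  expect_equal(check_permission(sv, "study_a_role", "read-idtype", "study_b_id"),
               "deny")
  expect_equal(check_permission(sv, "unknown_role", "read-idtype", "pid"),
               "deny")
  expect_equal(check_permission(sv, "study_b_role", "create-token",
                                "DELETE_PATIENT"), "deny")
})

test_that("cross-tenant reads are denied", {
  sv <- demo_service()
  sa <- create_session(sv, "key-a")
  tk <- create_token(sv, sa, "ADD_PATIENT",
                     payload = list(id_types = "study_a_id"), reason = "x")
  res <- redeem_token(sv, tk, list(fields = rec_anna()))
  sid <- res$pseudonyms$study_a_id[1]
  # role b tries to read a study_a patient
  sb <- create_session(sv, "key-b")
  tkb <- create_token(sv, sb, "READ_PATIENT",
                      payload = list(target = list(type = "study_a_id",
                                                   value = sid),
                                     id_types = "study_b_id"),
                      reason = "lookup")
  expect_error(redeem_token(sv, tkb), "not visible")
  # role a reads its own patient
  ta <- create_token(sv, sa, "READ_PATIENT",
                     payload = list(target = list(type = "study_a_id",
                                                  value = sid),
                                    id_types = "pid",
                                    include_fields = TRUE),
                     reason = "lookup")
  got <- redeem_token(sv, ta)
  expect_true("pid" %in% names(got$pseudonyms))
  expect_equal(got$fields[["first_name"]], "ANNA")
})

test_that("consent-gated grants require a PERMIT policy decision", {
  st <- new_store()
  consent_template(st, "broad", tibble::tibble(
    module_id = "share", policy_ids = list("export"), required = TRUE))
  cfg <- service_config(
    clients = tibble::tibble(api_key = "k", client = "c", role = "exporter"),
    roles = list(exporter = c("export:study_a_id?requires-policy=export"))
  )
  sv <- link_service(st, cfg)
  k <- create_patient(st, rec_anna())
  # no consent recorded: UNKNOWN -> deny
  expect_equal(check_permission(sv, "exporter", "export", "study_a_id",
                                patient = k), "deny")
  record_consent(st, k, "broad", c(share = "PERMIT"), signed_date = Sys.Date() - 10)
  expect_equal(check_permission(sv, "exporter", "export", "study_a_id",
                                patient = k), "allow")
  withdraw_consent(st, k, "broad", withdrawal_date = Sys.Date() - 1)
  expect_equal(check_permission(sv, "exporter", "export", "study_a_id",
                                patient = k), "deny")
})

test_that("every redemption writes exactly one audit record", {
  sv <- demo_service()
  s <- create_session(sv, "key-a")
  for (i in 1:5) {
    tk <- create_token(sv, s, "ADD_PATIENT", reason = paste("visit", i))
    redeem_token(sv, tk, list(fields = withr::with_seed(i, random_identity())))
  }
  at <- audit_trail(sv$store)
  expect_equal(sum(at$operation == "redeem_token"), 5)
  expect_equal(sum(at$operation == "create_token"), 5)
})
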