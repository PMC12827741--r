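# Shared fixtures: small records, stores and service configs built in code.

rec_anna <- function() {
  list(first_name = "Anna", last_name = "Bachmann", birth_date = "1980-02-01",
       zip = "10731", city = "Nordstadt")
}

rec_bert <- function() {
  list(first_name = "Bert", last_name = "Kornmeier", birth_date = "1975-11-23",
       zip = "11462", city = "Suedberg")
}

new_store <- function(...) patient_store(secret = "test-secret", ...)

demo_service <- function(store = new_store(), audit_required = TRUE) {
  cfg <- service_config(
    clients = tibble::tibble(
      api_key = c("key-a", "key-b"),
      client = c("edc_a", "edc_b"),
      role = c("study_a_role", "study_b_role")
    ),
    roles = list(
      study_a_role = c("create-token:ADD_PATIENT", "create-token:READ_PATIENT",
                       "create-token:EDIT_PATIENT",
                       "read-idtype:study_a_id", "read-idtype:pid",
                       "read-field:first_name", "read-field:last_name",
                       "tenant:study_a"),
      study_b_role = c("create-token:ADD_PATIENT", "create-token:READ_PATIENT",
                       "read-idtype:study_b_id", "tenant:study_b")
    ),
    callback_allowlist = "https://edc.example.org/",
    audit_required = audit_required
  )
  link_service(store, cfg)
}

# A random identity drawn from the synthetic pools (uses the current RNG).
random_identity <- function(p_missing = 0.1) {
  fp <- name_pool("first"); lp <- name_pool("last"); cp <- name_pool("city")
  ci <- sample.int(nrow(cp), 1)
  id <- list(
    first_name = sample(fp$name, 1, prob = fp$freq),
    last_name = sample(lp$name, 1, prob = lp$freq),
    birth_day = sprintf("%02d", sample(1:28, 1)),
    birth_month = sprintf("%02d", sample(1:12, 1)),
    birth_year = as.character(sample(1935:2004, 1)),
    zip = cp$zip[ci], city = cp$name[ci]
  )
  for (f in c("zip", "city")) {
    if (stats::runif(1) < p_missing) id[[f]] <- NA_character_
  }
  id
}
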