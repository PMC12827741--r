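test_that("cohort generation is reproducible and shaped as promised", {
  co1 <- generate_cohort(10, 0, seed = 3)
  expect_equal(nrow(co1$records), 10)
  expect_equal(nrow(co1$truth), 0)
  co2 <- generate_cohort(50, 10, seed = 3)
  co3 <- generate_cohort(50, 10, seed = 3)
  expect_identical(co2, co3)
  expect_false(identical(co2$records, generate_cohort(50, 10, seed = 4)$records))
  expect_true(all(co2$truth$base_row <= 50))
  expect_true(all(co2$truth$dup_row > 50))
  expect_error(generate_cohort(5, 10), "exceed")
})

test_that("corruption honours rates and records its tags", {
  base <- normalize_record(rec_anna())
  # all rates zero: unchanged
  clean <- corrupt_record(base, error_model(0, 0, 0, 0, 0, 0))
  expect_identical(clean$fields, base)
  expect_length(clean$corruptions, 0)
  # forced substitution changes exactly one character of the last name
  withr::with_seed(8, {
    sub <- corrupt_record(base, error_model(substitution = 1, insertion = 0,
                                            deletion = 0, transposition = 0,
                                            field_missing = 0,
                                            date_component_error = 0))
    for (f in c("first_name", "last_name")) {
      a <- strsplit(base[[f]], "")[[1]]
      b <- strsplit(sub$fields[[f]], "")[[1]]
      expect_equal(length(a), length(b))
      expect_equal(sum(a != b), 1)
    }
    expect_true(all(grepl(":substitution$", sub$corruptions)))
    # transposition swaps an adjacent pair, preserving length and multiset
    tr <- corrupt_record(c(last_name = "MEIER"),
                         error_model(0, 0, 0, transposition = 1, 0, 0))
    v <- tr$fields[["last_name"]]
    expect_equal(nchar(v), 5)
    expect_setequal(strsplit(v, "")[[1]], strsplit("MEIER", "")[[1]])
  })
})

test_that("corrupted duplicates score higher against their base than strangers", {
  co <- generate_cohort(120, 40, seed = 19)
  cfg <- linkage_config()
  recs <- co$records
  norm <- lapply(seq_len(nrow(recs)),
                 function(i) normalize_record(as.list(recs[i, -1])))
  withr::with_seed(20, {
    s_base <- numeric(nrow(co$truth)); s_rand <- numeric(nrow(co$truth))
    for (i in seq_len(nrow(co$truth))) {
      d <- norm[[co$truth$dup_row[i]]]
      s_base[i] <- epilink_score(d, norm[[co$truth$base_row[i]]], cfg)
      s_rand[i] <- epilink_score(
        d, norm[[sample(setdiff(1:120, co$truth$base_row[i]), 1)]], cfg)
    }
    expect_gt(mean(s_base), mean(s_rand))
    expect_gt(mean(s_base), 0.9)
  })
})

test_that("batch import runs the pipeline row by row with mapping", {
  st <- new_store()
  csv <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    vorname = c("Anna", "Bert", "Carla"),
    surname = c("Bachmann", "Kornmeier", "Lindwurm"),
    birth_date = c("1980-02-01", "1975-11-23", "1991-07-30"),
    city = c("Nordstadt", "Suedberg", "Ostdorf")
  ), csv)
  job <- batch_import(st, csv,
                      mapping = c(vorname = "first_name", surname = "last_name"))
  g <- glance(job)
  expect_equal(g$state, "DONE")
  expect_equal(g$created, 3)
  expect_equal(g$matched, 0)
  expect_true(all(!is.na(batch_outcomes(job)$pid)))
  expect_error(batch_import(st, csv, mapping = c(nope = "first_name")),
               "absent from input header")
})

test_that("re-importing an identical file matches everything, creates nothing", {
  st <- new_store()
  co <- generate_cohort(40, 0, seed = 23)
  j1 <- batch_import(st, co$records)
  n1 <- n_patients(st)
  j2 <- batch_import(st, co$records)
  g2 <- glance(j2)
  expect_equal(g2$created, 0)
  expect_equal(g2$matched, 40)
  expect_equal(n_patients(st), n1)
})

test_that("batch import equals sequential single-record ingestion", {
  co <- generate_cohort(60, 20, seed = 29)
  st1 <- new_store()
  batch_import(st1, co$records)
  st2 <- new_store()
  for (i in seq_len(nrow(co$records))) {
    ingest_identity(st2, as.list(co$records[i, -1]))
  }
  expect_equal(n_patients(st1), n_patients(st2))
  expect_identical(patients_tibble(st1)[names(patients_tibble(st1)) != "created_at"],
                   patients_tibble(st2)[names(patients_tibble(st2)) != "created_at"])
})

test_that("export is MAIN-only, tenant-filtered and grant-checked", {
  st <- new_store()
  sv <- demo_service(st)
  k1 <- create_patient(st, rec_anna(), tenant = "study_a")
  k2 <- create_patient(st, rec_bert(), tenant = "study_b")
  add_identity(st, k1, modifyList(rec_anna(), list(last_name = "Altberg")))
  ex <- batch_export(st, c("first_name", "last_name", "study_a_id"),
                     tenant = "study_a")
  expect_equal(nrow(ex), 1)
  expect_equal(ex$last_name, "BACHMANN")  # alias never exported
  expect_false(is.na(ex$study_a_id))
  # grant enforcement through the service
  expect_error(
    batch_export(st, c("first_name", "pid"), service = sv, role = "study_b_role"),
    "lacks")
  ok <- batch_export(st, c("first_name", "study_a_id"),
                     service = sv, role = "study_a_role")
  expect_equal(nrow(ok), 1)
})

test_that("import then export preserves field content", {
  st <- new_store()
  co <- generate_cohort(25, 0, seed = 31)
  batch_import(st, co$records)
  cols <- setdiff(default_field_schema(), character(0))
  ex <- batch_export(st, cols)
  want <- co$records[cols]
  for (c in cols) want[[c]] <- normalize_value(want[[c]])
  expect_identical(dplyr::arrange(ex, dplyr::across(dplyr::everything())),
                   dplyr::arrange(want, dplyr::across(dplyr::everything())))
})
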