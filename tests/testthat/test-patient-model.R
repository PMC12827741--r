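test_that("alias identities append and MAIN promotion demotes the old MAIN", {
  st <- new_store()
  k <- create_patient(st, rec_anna())
  add_identity(st, k, modifyList(rec_anna(), list(last_name = "Kornmeier")))
  p <- get_patient(st, k)
  expect_length(p$identities, 2)
  expect_equal(vapply(p$identities, `[[`, character(1), "kind"),
               c("MAIN", "ALIAS"))
  add_identity(st, k, modifyList(rec_anna(), list(city = "Ostdorf")),
               as_main = TRUE)
  p <- get_patient(st, k)
  expect_length(p$identities, 3)
  expect_equal(sum(vapply(p$identities, `[[`, character(1), "kind") == "MAIN"), 1)
  expect_equal(p$identities[[3]]$kind, "MAIN")
  expect_error(add_identity(st, k, list(first_name = NA)), "non-missing")
  expect_error(add_identity(st, k, list(shoe_size = "42")), "unknown field")
})

test_that("pseudonym lookup roundtrips and follows merge chains", {
  st <- new_store()
  k1 <- create_patient(st, rec_anna())
  k2 <- create_patient(st, rec_bert())
  pid1 <- get_patient(st, k1)$pseudonyms$value[1]
  pid2 <- get_patient(st, k2)$pseudonyms$value[1]
  expect_equal(lookup_by_pseudonym(st, "pid", pid1)$key, k1)
  expect_null(lookup_by_pseudonym(st, "pid", "NOSUCHID"))
  expect_error(lookup_by_pseudonym(st, "nope", "x"), "unknown pseudonym type")
  merge_patients(st, k1, k2)
  expect_equal(lookup_by_pseudonym(st, "pid", pid2)$key, k1)
})

test_that("merge absorbs identities as aliases and linkage reaches them", {
  st <- new_store()
  k1 <- create_patient(st, rec_anna())
  k2 <- create_patient(st, rec_bert())
  surv <- merge_patients(st, k1, k2)
  expect_equal(surv$key, k1)
  kinds <- vapply(surv$identities, `[[`, character(1), "kind")
  expect_equal(sum(kinds == "MAIN"), 1)
  expect_equal(surv$identities[[1]]$kind, "MAIN")
  # a record identical to the absorbed one now matches the survivor
  r <- match_candidate(st, rec_bert())
  expect_equal(r$decision, "MATCH")
  expect_equal(r$best_patient, k1)
  expect_error(merge_patients(st, k1, k1), "itself")
  k3 <- create_patient(st, modifyList(rec_bert(), list(city = "Altfelden",
                                                       first_name = "Rita")))
  expect_error(merge_patients(st, k3, k2), "already-absorbed")
})

test_that("split records a permanent exclusion and errors on unknown pairs", {
  st <- new_store()
  ingest_identity(st, rec_anna())
  r <- ingest_identity(st, modifyList(rec_anna(), list(first_name = "Anne")))
  tp <- list_tentative_pairs(st)
  split_patients(st, tp$a, tp$b)
  expect_equal(nrow(list_tentative_pairs(st)), 0)
  expect_false(get_patient(st, tp$a)$tentative)
  expect_false(get_patient(st, tp$b)$tentative)
  # both records persist and a re-linked copy of b matches b, recreating
  # no (a, b) conflict
  r2 <- ingest_identity(st, modifyList(rec_anna(), list(first_name = "Anne")))
  expect_equal(r2$outcome, "matched")
  expect_equal(r2$patient, tp$b)
  expect_equal(nrow(list_tentative_pairs(st)), 0)
  expect_error(split_patients(st, 1, 99), "unknown patient|tentative")
})

test_that("external pseudonyms are editable, internal ones immutable", {
  st <- new_store()
  register_pseudonym_type(st, "lab_id", kind = "external")
  k1 <- create_patient(st, rec_anna())
  k2 <- create_patient(st, rec_bert())
  assign_pseudonym(st, k1, "lab_id", "LAB-001")
  assign_pseudonym(st, k2, "lab_id", "LAB-002")
  edit_external_pseudonym(st, k1, "lab_id", "LAB-001", "LAB-099")
  expect_equal(lookup_by_pseudonym(st, "lab_id", "LAB-099")$key, k1)
  expect_null(lookup_by_pseudonym(st, "lab_id", "LAB-001"))
  expect_error(edit_external_pseudonym(st, k1, "lab_id", "LAB-099", "LAB-002"),
               "collides")
  pid <- get_patient(st, k1)$pseudonyms
  pidv <- pid$value[pid$type == "pid"]
  expect_error(edit_external_pseudonym(st, k1, "pid", pidv, "XXXXXXXX"),
               "immutable")
})

test_that("multi-valued pseudonym types repeat, single-valued do not", {
  st <- new_store()
  register_pseudonym_type(st, "biosample_id", kind = "external", multi = TRUE)
  register_pseudonym_type(st, "lab_id", kind = "external")
  k <- create_patient(st, rec_anna())
  assign_pseudonym(st, k, "biosample_id", "BS-1")
  assign_pseudonym(st, k, "biosample_id", "BS-2")
  expect_equal(sum(get_patient(st, k)$pseudonyms$type == "biosample_id"), 2)
  assign_pseudonym(st, k, "lab_id", "L1")
  expect_error(assign_pseudonym(st, k, "lab_id", "L2"), "already holds")
  expect_error(assign_pseudonym(st, k, "biosample_id", "BS-1"),
               "already assigned")
})

test_that("random operation sequences preserve the model invariants", {
  withr::with_seed(77, {
    st <- new_store()
    keys <- replicate(8, create_patient(st, random_identity()))
    for (step in 1:60) {
      op <- sample(c("add", "add_main", "merge"), 1)
      alive <- Filter(function(k) is.na(get_patient(st, k, resolve = FALSE)$duplicate_of),
                      seq_len(length(st$patients)))
      k <- alive[sample.int(length(alive), 1)]
      if (op == "add") {
        add_identity(st, k, random_identity())
      } else if (op == "add_main") {
        add_identity(st, k, random_identity(), as_main = TRUE)
      } else if (length(alive) > 1) {
        pair <- alive[sample.int(length(alive), 2)]
        merge_patients(st, pair[1], pair[2])
      }
      # exactly one MAIN per non-absorbed patient; identities append-only
      for (kk in seq_len(length(st$patients))) {
        p <- get_patient(st, kk, resolve = FALSE)
        if (!is.na(p$duplicate_of)) next
        kinds <- vapply(p$identities, `[[`, character(1), "kind")
        expect_equal(sum(kinds == "MAIN"), 1)
      }
      # all pseudonyms still resolve, and chains terminate
      for (kk in seq_len(length(st$patients))) {
        p <- get_patient(st, kk, resolve = FALSE)
        for (i in seq_len(nrow(p$pseudonyms))) {
          hit <- lookup_by_pseudonym(st, p$pseudonyms$type[i],
                                     p$pseudonyms$value[i])
          expect_equal(hit$key, get_patient(st, kk)$key)
        }
      }
    }
  })
})

test_that("store exports one CSV row per (patient, identity)", {
  st <- new_store()
  k <- create_patient(st, rec_anna(), tenant = "study_a")
  add_identity(st, k, modifyList(rec_anna(), list(last_name = "Kornmeier")))
  create_patient(st, rec_bert())
  tb <- patients_tibble(st)
  expect_equal(nrow(tb), 3)
  path <- withr::local_tempfile(fileext = ".csv")
  export_patients(st, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(back), 3)
  expect_true(all(c("patient", "kind", "pid", default_field_schema()) %in%
                    names(back)))
  expect_equal(nrow(patients_tibble(st, main_only = TRUE)), 2)
})
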