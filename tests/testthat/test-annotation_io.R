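test_that("annotation validation flags slot, offset and anchor problems", {
  sch <- toy_schema()
  ok <- tiny_annotated_doc()
  expect_equal(nrow(validate_annotations(ok, sch)), 0L)

  # modifier not among the fact type's slots
  doc <- ok$document
  bad_slot <- annotated_document(doc, list(
    fact_instance("Lesion", 0L, 22L, list(
      entity_span("LesionAnchor", 6L, 12L, "Läsion"),
      entity_span("Value", 0L, 5L, "Keine")))))
  iss <- validate_annotations(bad_slot, sch)
  expect_equal(iss$code, "SLOT_VIOLATION")

  # entity text not matching the section slice
  bad_offset <- annotated_document(doc, list(
    fact_instance("Lesion", 0L, 22L, list(
      entity_span("LesionAnchor", 6L, 12L, "Lasion"),
      entity_span("Negation", 0L, 5L, "Keine")))))
  expect_true("OFFSET_MISMATCH" %in% validate_annotations(bad_offset, sch)$code)

  # entity outside the fact span
  outside <- annotated_document(doc, list(
    fact_instance("Lesion", 0L, 12L, list(
      entity_span("LesionAnchor", 6L, 12L, "Läsion"),
      entity_span("Negation", 13L, 22L, "beidseits")))))
  expect_true("ENTITY_OUTSIDE_FACT" %in% validate_annotations(outside, sch)$code)

  # missing anchor is only warning severity
  anchorless <- annotated_document(doc, list(
    fact_instance("Lesion", 0L, 22L, list(
      entity_span("Negation", 0L, 5L, "Keine")))))
  iss <- validate_annotations(anchorless, sch)
  expect_equal(iss$code, "MISSING_ANCHOR")
  expect_equal(iss$severity, "warning")

  unknown <- annotated_document(doc, list(fact_instance("Nodule", 0L, 5L)))
  expect_equal(validate_annotations(unknown, sch)$code, "UNKNOWN_FACT_TYPE")
})

test_that("QA conversion emits per-instance train examples and grouped validation answers", {
  findings <- "BI-RADS 1 links. BI-RADS 2 rechts."
  doc <- report_document("qa-1", "mammography", list(findings = findings))
  adoc <- annotated_document(doc, list(
    fact_instance("Birads", 0L, 15L, list(
      entity_span("BiradsAnchor", 0L, 7L, "BI-RADS"))),
    fact_instance("Birads", 17L, 33L, list(
      entity_span("BiradsAnchor", 17L, 24L, "BI-RADS")))))

  # document in the train split: two single-answer examples with distinct ids
  qa_train <- to_qa_dataset(list(adoc), ratios = c(1, 0, 0), seed = 1)
  expect_length(qa_train$train, 2L)
  expect_equal(vapply(qa_train$train, function(e) length(e$answers), 0L), c(1L, 1L))
  expect_length(unique(vapply(qa_train$train, `[[`, "", "id")), 2L)

  # same document in the validation split: one example with both answers
  qa_val <- to_qa_dataset(list(adoc), ratios = c(0, 0, 1), seed = 1)
  expect_length(qa_val$validation, 1L)
  expect_length(qa_val$validation[[1]]$answers, 2L)
  expect_equal(qa_val$validation[[1]]$question, "Birads")

  # answer_start slice identity in every mode
  for (ex in c(qa_train$train, qa_val$validation)) {
    for (a in ex$answers) {
      expect_equal(str_slice(ex$context, a$answer_start,
                             a$answer_start + nchar(a$text)), a$text)
    }
  }
})

test_that("QA document-level split is disjoint and counts follow the instance/type sums", {
  docs <- generate_dataset(10, seed = 21)
  qa <- to_qa_dataset(docs, seed = 9)
  doc_of <- function(ex) sub(":.*$", "", ex$id)
  tr <- unique(vapply(qa$train, doc_of, ""))
  te <- unique(vapply(qa$test, doc_of, ""))
  va <- unique(vapply(qa$validation, doc_of, ""))
  expect_length(intersect(tr, te), 0L)
  expect_length(intersect(tr, va), 0L)
  expect_length(intersect(te, va), 0L)
  expect_equal(length(tr) + length(te) + length(va), length(docs))

  n_inst <- setNames(vapply(docs, function(d) length(d$facts), 0L),
                     vapply(docs, function(d) d$document$id, ""))
  n_types <- setNames(vapply(docs, function(d) {
    length(unique(vapply(d$facts, `[[`, "", "fact_type")))
  }, 0L), names(n_inst))
  expect_equal(length(qa$train), sum(n_inst[tr]))
  expect_equal(length(qa$test), sum(n_inst[te]))
  expect_equal(length(qa$validation), sum(n_types[va]))
})

test_that("IOB conversion labels entity tokens positionally and covers every instance", {
  sch <- demo_schema()
  findings <- "Der Mamillenabstand beträgt 54 mm."
  doc <- report_document("iob-1", "mammography", list(findings = findings))
  adoc <- annotated_document(doc, list(
    fact_instance("NippleDistance", 4L, 33L, list(
      entity_span("NippleDistanceAnchor", 4L, 19L, "Mamillenabstand"),
      entity_span("Measure", 28L, 33L, "54 mm")))))
  iob <- to_iob_dataset(list(adoc), sch)
  expect_length(iob, 1L)
  expect_equal(iob[[1]]$tokens, c("Mamillenabstand", "beträgt", "54", "mm"))
  expect_equal(iob[[1]]$labels,
               c("B-NippleDistanceAnchor", "O", "B-Measure", "I-Measure"))

  # a fact with no entities is all O
  bare <- annotated_document(doc, list(fact_instance("NippleDistance", 4L, 33L)))
  expect_true(all(to_iob_dataset(list(bare), sch)[[1]]$labels == "O"))

  # padded context adds O tokens on both sides
  pad <- to_iob_dataset(list(adoc), sch, context = "pad_tokens", pad_tokens = 1L)
  expect_equal(pad[[1]]$tokens[1], "Der")
  expect_equal(pad[[1]]$labels[1], "O")

  # one example per fact instance; every label in the inventory
  docs <- generate_dataset(3, seed = 13)
  iob_all <- to_iob_dataset(docs, sch)
  expect_equal(length(iob_all), sum(vapply(docs, function(d) length(d$facts), 0L)))
  inv <- label_inventory(sch)
  expect_true(all(unlist(lapply(iob_all, `[[`, "labels")) %in% inv))
})

test_that("annotated documents round-trip losslessly through JSONL", {
  docs <- generate_dataset(1, seed = 3)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_annotations_jsonl(docs, path)
  back <- read_annotations_jsonl(path)
  expect_identical(back, docs)
})

test_that("QA JSON and CoNLL TSV writers produce their documented formats", {
  docs <- generate_dataset(1, seed = 3)
  qa <- to_qa_dataset(docs, seed = 2)
  sq_path <- withr::local_tempfile(fileext = ".json")
  write_squad_json(c(qa$train, qa$test), sq_path)
  sq <- jsonlite::read_json(sq_path)
  expect_equal(sq$version, "v2.0")
  first_qa <- sq$data[[1]]$paragraphs[[1]]$qas[[1]]
  expect_true(all(c("id", "question", "answers") %in% names(first_qa)))

  iob <- to_iob_dataset(docs, demo_schema())
  cpath <- withr::local_tempfile(fileext = ".tsv")
  write_conll(iob, cpath)
  back <- read_conll(cpath)
  expect_length(back, length(iob))
  expect_equal(lapply(back, `[[`, "tokens"), lapply(iob, `[[`, "tokens"))
  expect_equal(lapply(back, `[[`, "labels"), lapply(iob, `[[`, "labels"))
})
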