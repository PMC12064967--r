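test_that("span enumeration matches the brute-force oracle", {
  cfg <- pipeline_config(max_answer_tokens = 30L, top_k_per_fact = 1L)
  got <- enumerate_spans(c(0, 5, 0), c(0, 0, 4), cfg)
  expect_equal(got, data.frame(start = 2L, end = 3L, score = 9))

  # two disjoint high-scoring spans, returned in score order
  cfg2 <- pipeline_config(top_k_per_fact = 2L, max_answer_tokens = 2L)
  got2 <- enumerate_spans(c(9, 0, 0, 7, 0), c(8, 0, 0, 6, 0), cfg2)
  expect_equal(got2$start, c(1L, 4L))
  expect_equal(got2$end, c(1L, 4L))
  expect_equal(got2$score, c(17, 13))

  # all candidates below the threshold give an empty list
  cfg3 <- pipeline_config(span_score_threshold = 100)
  expect_equal(nrow(enumerate_spans(c(1, 2), c(1, 2), cfg3)), 0L)
  expect_equal(nrow(enumerate_spans(numeric(0), numeric(0))), 0L)

  # randomized equivalence with the independent brute-force enumerator
  set.seed(41)
  for (rep in 1:25) {
    n <- sample(2:8, 1)
    ss <- round(rnorm(n), 3)
    es <- round(rnorm(n), 3)
    k <- sample(1:3, 1)
    ml <- sample(1:4, 1)
    cfg <- pipeline_config(max_answer_tokens = ml, top_k_per_fact = k)
    got <- enumerate_spans(ss, es, cfg)
    want <- oracle_enumerate(ss, es, ml, k)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$score, want$score)
  }
})

test_that("IOB decoding produces maximal legal chunks with the stated repairs", {
  got <- decode_iob(c("B-X", "I-X", "O", "B-Y"))
  expect_equal(got, data.frame(entity_type = c("X", "Y"),
                               start = c(1L, 4L), end = c(2L, 4L),
                               stringsAsFactors = FALSE))

  # illegal I- start: coerced to B- or dropped
  expect_equal(decode_iob(c("O", "I-X", "I-X"), repair = "begin-coercion"),
               data.frame(entity_type = "X", start = 2L, end = 3L,
                          stringsAsFactors = FALSE))
  expect_equal(nrow(decode_iob(c("O", "I-X", "I-X"), repair = "conservative")),
               0L)

  expect_error(decode_iob(c("B-X", "Q")), "unknown IOB label")
  expect_error(decode_iob(c("B-X"), inventory = c("O", "B-Y", "I-Y")),
               "unknown IOB label")

  # argmax path over a probability matrix
  inv <- c("O", "B-X", "I-X")
  P <- rbind(c(0.1, 0.8, 0.1), c(0.1, 0.2, 0.7), c(0.9, 0.05, 0.05))
  colnames(P) <- inv
  expect_equal(decode_iob(P)$entity_type, "X")
  expect_equal(decode_iob(P)$end, 2L)

  # round trip: decode then re-encode reproduces legal sequences
  set.seed(7)
  for (rep in 1:50) {
    labs <- random_iob(sample(3:15, 1), legal = TRUE)
    chunks <- decode_iob(labs)
    expect_equal(encode_chunks(chunks, length(labs)), labs)
  }
})

test_that("fact assembly applies the slot template and flags anchorless instances", {
  sch <- toy_schema()
  ctx <- "Keine Läsion beidseits."
  toks <- do.call(rbind, tokenize_sentences(ctx))
  span_toks <- toks[1:3, ]  # Keine Läsion beidseits

  ok <- assemble_fact("Lesion", span_toks,
                      data.frame(entity_type = c("Negation", "LesionAnchor"),
                                 start = c(1L, 2L), end = c(1L, 2L)),
                      sch, ctx)
  expect_length(ok$instance$entities, 2L)
  expect_length(ok$warnings, 0L)
  expect_false(attr(ok$instance, "anchorless"))
  expect_equal(ok$instance$entities[[2]]$text, "Läsion")

  # entity outside the fact's slots is dropped with a warning
  dropped <- assemble_fact("Lesion", span_toks,
                           data.frame(entity_type = c("LesionAnchor", "Value"),
                                      start = c(2L, 1L), end = c(2L, 1L)),
                           sch, ctx)
  expect_length(dropped$instance$entities, 1L)
  expect_match(dropped$warnings, "SLOT_VIOLATION")

  # no anchor decoded: kept but flagged
  bare <- assemble_fact("Lesion", span_toks,
                        data.frame(entity_type = "Negation",
                                   start = 1L, end = 1L),
                        sch, ctx)
  expect_true(attr(bare$instance, "anchorless"))
})

test_that("terminology lookup is case- and whitespace-insensitive and order-preserving", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("term\tterminology\tconcept_id\tpreferred_term",
               "Verkalkungen\tSNOMED-CT\tC001\tCalcification",
               "Verkalkungen\tWingert\tW077\tVERKALKUNG",
               "Läsion\tSNOMED-CT\tC002\tLesion"), path)
  term <- read_terminology(path)
  hits <- normalize_entity("Verkalkungen", term)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$terminology, c("SNOMED-CT", "Wingert"))
  expect_equal(normalize_entity("  verkalkungen ", term), hits)
  expect_equal(nrow(normalize_entity("unbekannt", term)), 0L)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("term\tterminology\tconcept_id\tpreferred_term",
               "onlyonefield"), bad)
  expect_error(read_terminology(bad), "line 2")
})

test_that("early stopping fires after patience epochs without improvement", {
  r <- early_stopping_check(c(.80, .79, .78, .77, .76, .75), patience = 5)
  expect_equal(r$decision, "stop")
  expect_equal(r$best_epoch, 1L)

  r2 <- early_stopping_check(c(.80, .79, .78, .77, .81), patience = 5)
  expect_equal(r2$decision, "continue")
  expect_equal(r2$best_epoch, 5L)

  r3 <- early_stopping_check(seq(0.1, 0.9, by = 0.1), patience = 3)
  expect_equal(r3$decision, "continue")

  expect_equal(early_stopping_check(numeric(0))$decision, "continue")
  expect_equal(early_stopping_check(c(.9, .1, .1), patience = 2)$decision, "stop")
})

test_that("training configuration carries the reference hyperparameters", {
  cfg <- training_config()
  expect_equal(cfg$qa$learning_rate, 3e-5)
  expect_equal(cfg$qa$epochs, 5L)
  expect_equal(cfg$qa$max_sequence_length, 384L)
  expect_equal(cfg$qa$doc_stride, 128L)
  expect_equal(cfg$ner$learning_rate, 5e-5)
  expect_equal(cfg$ner$max_epochs, 100L)
  expect_equal(cfg$ner$weight_decay, 1e-2)
  expect_equal(cfg$ner$batch_size, 16L)
  expect_equal(cfg$ner$early_stopping_patience, 5L)
  expect_equal(cfg$mlm$mask_probability, 0.15)
  expect_equal(cfg$mlm$learning_rate, 2e-5)
  expect_equal(cfg$mlm$epochs, 3L)
  expect_error(training_config(qa = list(learning_rate = -1)))
})

test_that("the pipeline iterates every fact type, tolerates backend failures and is deterministic", {
  sch <- demo_schema()
  bank <- demo_clause_bank()
  bk <- rule_backends(bank, sch)
  doc <- generate_report(3L, id = "p-1", seed = 77)$document

  res <- run_pipeline(doc, sch, bk$span_extractor, bk$token_labeler,
                      terminology = demo_terminology())
  expect_s3_class(res, "ff_extraction_result")
  expect_length(res$facts, 14L)
  expect_equal(vapply(res$facts, `[[`, "", "fact_type"),
               schema_fact_names_of(sch))

  # gazetteer hit: the negated-lesion clause is found with its anchor
  doc1 <- generate_report(1L, id = "p-2", seed = 78)$document
  res1 <- run_pipeline(doc1, sch, bk$span_extractor, bk$token_labeler)
  lesion <- res1$facts[[which(vapply(res1$facts, `[[`, "", "fact_type") == "Lesion")]]
  expect_gte(length(lesion$instances), 1L)
  types <- vapply(lesion$instances[[1]]$entities, `[[`, "", "type")
  expect_true("LesionAnchor" %in% types)
  # anchors carry terminology concepts when the dictionary covers them
  resn <- run_pipeline(doc1, sch, bk$span_extractor, bk$token_labeler,
                       terminology = demo_terminology())
  lesion_n <- resn$facts[[which(vapply(resn$facts, `[[`, "", "fact_type") == "Lesion")]]
  anchor_ent <- Filter(function(e) e$type == "LesionAnchor",
                       lesion_n$instances[[1]]$entities)[[1]]
  expect_gte(nrow(anchor_ent$concepts), 1L)

  # empty findings section: all-empty instance lists, no errors
  empty_doc <- report_document("p-0", "mammography", list(findings = ""))
  res0 <- run_pipeline(empty_doc, sch, bk$span_extractor, bk$token_labeler)
  expect_true(all(vapply(res0$facts, function(f) length(f$instances) == 0L, TRUE)))
  expect_true(all(vapply(res0$facts, function(f) is.null(f$error), TRUE)))

  # a failing backend is recorded per fact type; the rest still run
  bomb <- function(question, context) {
    if (question == "Density") stop("backend down")
    bk$span_extractor(question, context)
  }
  resb <- run_pipeline(doc, sch, bomb, bk$token_labeler)
  errs <- vapply(resb$facts, function(f) !is.null(f$error), TRUE)
  expect_equal(sum(errs), 1L)
  expect_equal(resb$facts[[which(errs)]]$fact_type, "Density")
  expect_gte(sum(vapply(resb$facts, function(f) length(f$instances), 0L)), 1L)

  # determinism under fixed backends and config
  res_again <- run_pipeline(doc, sch, bk$span_extractor, bk$token_labeler,
                            terminology = demo_terminology())
  expect_identical(res, res_again)

  # serialization produces parseable JSON listing every fact type
  js <- extraction_to_json(res)
  parsed <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  expect_length(parsed$facts, 14L)
})

test_that("a token labeler with unnormalized distributions is rejected", {
  sch <- demo_schema()
  bk <- rule_backends(demo_clause_bank(), sch)
  doc <- generate_report(2L, id = "p-3", seed = 79)$document
  broken <- function(tokens, context = NULL) {
    P <- bk$token_labeler(tokens, context)
    P * 2
  }
  res <- run_pipeline(doc, sch, bk$span_extractor, broken)
  expect_true(any(grepl("sum to 1",
                        unlist(lapply(res$facts, `[[`, "error")))))
})

test_that("the trainable labeler learns synthetic entities beyond the majority baseline", {
  sch <- demo_schema()
  docs <- generate_dataset(3, seed = 31)
  iob <- to_iob_dataset(docs, sch)
  expect_gte(length(iob), 200L)

  labeler <- train_token_labeler(iob, sch,
                                 config = training_config(ner = list(max_epochs = 60L)))
  baseline <- majority_baseline_labeler(iob, sch)

  eval_labeler <- function(fn) {
    pred <- lapply(iob, function(ex) {
      P <- fn(ex$tokens)
      colnames(P)[max.col(P, ties.method = "first")]
    })
    entity_prf(pred, lapply(iob, `[[`, "labels"))$f1
  }
  f1_model <- eval_labeler(labeler)
  f1_base <- eval_labeler(baseline)
  expect_gt(f1_model, f1_base)
  expect_gt(f1_model, 0.3)
})
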