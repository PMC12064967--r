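# Gold annotations: facts as continuous spans over one report section, each
# holding entity spans (one anchor, optional modifiers), plus conversion into
# the two training-data representations (single-answer extractive QA and
# per-fact IOB sequences). Offsets are 0-based half-open, section-relative.

#' Construct an entity span
#'
#' @param entity_type Entity-type name.
#' @param start,end 0-based half-open character offsets within the enclosing
#'   section.
#' @param text The covered text (checked against the section by
#'   [validate_annotations()]).
#' @return An `ff_entity_span`.
#' @export
entity_span <- function(entity_type, start, end, text) {
  stopifnot(start >= 0, start < end)
  structure(list(entity_type = entity_type, start = as.integer(start),
                 end = as.integer(end), text = text),
            class = "ff_entity_span")
}

#' Construct a fact instance
#'
#' @param fact_type Fact-type name.
#' @param start,end 0-based half-open character offsets of the continuous
#'   fact span within the section.
#' @param entities List of [entity_span()] objects inside the fact span.
#' @return An `ff_fact_instance`.
#' @export
fact_instance <- function(fact_type, start, end, entities = list()) {
  stopifnot(start >= 0, start < end)
  structure(list(fact_type = fact_type, start = as.integer(start),
                 end = as.integer(end), entities = entities),
            class = "ff_fact_instance")
}

#' Construct an annotated document
#'
#' @param document A [report_document()].
#' @param facts List of [fact_instance()] objects; stored sorted by start
#'   offset.
#' @param annotated_section Name of the annotated section (default
#'   `"findings"`, the only section annotated in this framework).
#' @return An `ff_annotated_doc`.
#' @export
annotated_document <- function(document, facts = list(),
                               annotated_section = "findings") {
  stopifnot(inherits(document, "ff_report"),
            annotated_section %in% names(document$sections))
  if (length(facts) > 1L) {
    facts <- facts[order(vapply(facts, `[[`, 0L, "start"),
                         vapply(facts, `[[`, 0L, "end"))]
  }
  structure(list(document = document, annotated_section = annotated_section,
                 facts = facts),
            class = "ff_annotated_doc")
}

#' @export
print.ff_annotated_doc <- function(x, ...) {
  cat(sprintf("<annotated document %s: %d fact instances over section '%s'>\n",
              x$document$id, length(x$facts), x$annotated_section))
  invisible(x)
}

section_text <- function(adoc) {
  adoc$document$sections[[adoc$annotated_section]]
}

#' Validate annotations against a fact schema
#'
#' Reports unknown fact or entity types, entities outside their fact span,
#' modifiers not among the fact type's slots, missing anchors (warning
#' severity), multiple anchors, and mismatches between stored entity text and
#' the section slice.
#'
#' @param doc An [annotated_document()].
#' @param schema A validated `ff_schema`.
#' @return Issue data frame (class `ff_validation_report`) with columns
#'   `code`, `name`, `message` and `severity` (`"error"` or `"warning"`).
#'   Codes: `UNKNOWN_FACT_TYPE`, `UNKNOWN_ENTITY_TYPE`, `ENTITY_OUTSIDE_FACT`,
#'   `SLOT_VIOLATION`, `MISSING_ANCHOR`, `MULTIPLE_ANCHORS`,
#'   `OFFSET_MISMATCH`, `SPAN_OUT_OF_SECTION`.
#' @export
validate_annotations <- function(doc, schema) {
  stopifnot(inherits(doc, "ff_annotated_doc"), inherits(schema, "ff_schema"))
  ctx <- section_text(doc)
  L <- nchar(ctx)
  codes <- character(); names_ <- character(); msgs <- character()
  sev <- character()
  add <- function(code, name, msg, severity = "error") {
    codes <<- c(codes, code); names_ <<- c(names_, name)
    msgs <<- c(msgs, msg); sev <<- c(sev, severity)
  }
  enames <- schema_entity_names(schema)
  roles <- vapply(schema$entity_types, `[[`, "", "role")

  for (fi in doc$facts) {
    ft <- schema_fact(schema, fi$fact_type)
    if (is.null(ft)) {
      add("UNKNOWN_FACT_TYPE", fi$fact_type,
          sprintf("fact type '%s' not in schema", fi$fact_type))
      next
    }
    if (fi$start < 0L || fi$end > L) {
      add("SPAN_OUT_OF_SECTION", fi$fact_type,
          sprintf("fact span [%d,%d) exceeds section length %d",
                  fi$start, fi$end, L))
    }
    n_anchor <- 0L
    for (es in fi$entities) {
      if (!(es$entity_type %in% enames)) {
        add("UNKNOWN_ENTITY_TYPE", es$entity_type,
            sprintf("entity type '%s' not in schema", es$entity_type))
        next
      }
      role <- roles[match(es$entity_type, enames)]
      if (role == "anchor") {
        if (es$entity_type != ft$anchor) {
          add("SLOT_VIOLATION", es$entity_type,
              sprintf("anchor '%s' does not belong to fact type '%s'",
                      es$entity_type, fi$fact_type))
        } else {
          n_anchor <- n_anchor + 1L
        }
      } else if (!(es$entity_type %in% ft$modifier_slots)) {
        add("SLOT_VIOLATION", es$entity_type,
            sprintf("modifier '%s' not among slots of fact type '%s'",
                    es$entity_type, fi$fact_type))
      }
      if (es$start < fi$start || es$end > fi$end) {
        add("ENTITY_OUTSIDE_FACT", es$entity_type,
            sprintf("entity [%d,%d) outside fact span [%d,%d)",
                    es$start, es$end, fi$start, fi$end))
      }
      if (es$end <= L && !identical(str_slice(ctx, es$start, es$end), es$text)) {
        add("OFFSET_MISMATCH", es$entity_type,
            sprintf("entity text '%s' != section slice '%s' at [%d,%d)",
                    es$text, str_slice(ctx, es$start, es$end),
                    es$start, es$end))
      }
    }
    if (n_anchor == 0L) {
      add("MISSING_ANCHOR", fi$fact_type,
          sprintf("fact instance of '%s' at [%d,%d) has no anchor entity",
                  fi$fact_type, fi$start, fi$end),
          severity = "warning")
    } else if (n_anchor > 1L) {
      add("MULTIPLE_ANCHORS", fi$fact_type,
          sprintf("fact instance of '%s' has %d anchor entities",
                  fi$fact_type, n_anchor))
    }
  }
  out <- issue_df(codes, names_, msgs)
  out$severity <- sev
  out
}

doc_split <- function(n, ratios, seed) {
  stopifnot(abs(sum(ratios) - 1) < 1e-8, length(ratios) == 3L)
  perm <- with_seed(seed, sample.int(n))
  n_train <- floor(ratios[1] * n)
  n_test <- floor(ratios[2] * n)
  list(train = perm[seq_len(n_train)],
       test = perm[n_train + seq_len(n_test)],
       validation = perm[setdiff(seq_len(n), seq_len(n_train + n_test))])
}

qa_example <- function(id, question, context, answers) {
  structure(list(id = id, question = question, context = context,
                 answers = answers),
            class = "ff_qa_example")
}

qa_examples_for_doc <- function(adoc, mode) {
  ctx <- section_text(adoc)
  if (length(adoc$facts) == 0L) return(list())
  types <- vapply(adoc$facts, `[[`, "", "fact_type")
  out <- list()
  if (mode == "instance") {
    seen <- integer(0)
    for (i in seq_along(adoc$facts)) {
      fi <- adoc$facts[[i]]
      k <- sum(types[seq_len(i)] == fi$fact_type)
      out[[length(out) + 1L]] <- qa_example(
        id = sprintf("%s:%s:%d", adoc$document$id, fi$fact_type, k),
        question = fi$fact_type, context = ctx,
        answers = list(list(text = str_slice(ctx, fi$start, fi$end),
                            answer_start = fi$start)))
    }
  } else {  # grouped: one example per fact type, all instances as answers
    for (tp in unique(types)) {
      inst <- adoc$facts[types == tp]
      out[[length(out) + 1L]] <- qa_example(
        id = sprintf("%s:%s", adoc$document$id, tp),
        question = tp, context = ctx,
        answers = lapply(inst, function(fi) {
          list(text = str_slice(ctx, fi$start, fi$end),
               answer_start = fi$start)
        }))
    }
  }
  out
}

#' Convert annotated documents to extractive-QA datasets
#'
#' Splits at the document level (seeded permutation; 70/15/15 by default) so
#' no report contributes examples to more than one split, then expands each
#' split into SQuAD-v2-style examples with the fact-type name as the
#' question and the annotated section as the context. Train and test splits
#' emit one single-answer example per fact instance (repeated fact types in a
#' document give multiple examples with distinct ids); the validation split
#' emits one example per (document, fact type) with every instance as an
#' answer. No unanswerable examples are emitted unless
#' `include_unanswerable = TRUE`, which adds one empty-answer example per
#' (train/test document, schema fact type absent from it); `schema` is then
#' required.
#'
#' @param docs List of [annotated_document()] objects.
#' @param ratios Numeric length-3 vector of train/test/validation fractions.
#' @param seed Integer seed for the document permutation.
#' @param include_unanswerable Synthesize empty-answer examples for absent
#'   fact types (off by default).
#' @param schema Schema providing the fact-type universe for unanswerable
#'   examples.
#' @return List with `train`, `test`, `validation`: lists of `ff_qa_example`.
#' @export
to_qa_dataset <- function(docs, ratios = c(0.70, 0.15, 0.15), seed = 1L,
                          include_unanswerable = FALSE, schema = NULL) {
  idx <- doc_split(length(docs), ratios, seed)
  expand <- function(ids, mode) {
    out <- list()
    for (i in ids) {
      ex <- qa_examples_for_doc(docs[[i]], mode)
      if (include_unanswerable && mode == "instance") {
        if (is.null(schema)) {
          stop("schema required when include_unanswerable = TRUE", call. = FALSE)
        }
        present <- unique(vapply(docs[[i]]$facts, `[[`, "", "fact_type"))
        for (tp in setdiff(schema_fact_names(schema), present)) {
          ex[[length(ex) + 1L]] <- qa_example(
            id = sprintf("%s:%s:0", docs[[i]]$document$id, tp),
            question = tp, context = section_text(docs[[i]]),
            answers = list())
        }
      }
      out <- c(out, ex)
    }
    out
  }
  list(train = expand(idx$train, "instance"),
       test = expand(idx$test, "instance"),
       validation = expand(idx$validation, "grouped"))
}

iob_example <- function(tokens, labels, fact_type, doc_id = NA_character_) {
  stopifnot(length(tokens) == length(labels))
  structure(list(tokens = tokens, labels = labels, fact_type = fact_type,
                 doc_id = doc_id),
            class = "ff_iob_example")
}

#' Convert annotated documents to per-fact IOB examples
#'
#' Emits one token-labeled example per fact instance. Tokens inside an entity
#' span receive `B-`/`I-` tags of its type by position; all other tokens are
#' `O`. By default the example covers only the fact span
#' (`context = "fact_span_only"`); with `context = "pad_tokens"`,
#' `pad_tokens` extra section tokens on each side are included, labeled `O`.
#' A token partially overlapping an entity boundary is given the entity label
#' in full (annotation granularity is token-level) and a warning is emitted.
#'
#' @param docs List of [annotated_document()] objects.
#' @param schema `ff_schema`; emitted labels are restricted to
#'   [label_inventory()] of it.
#' @param context `"fact_span_only"` (default) or `"pad_tokens"`.
#' @param pad_tokens Number of context tokens per side when
#'   `context = "pad_tokens"`.
#' @param abbreviation_lexicon Passed to [tokenize_sentences()].
#' @return List of `ff_iob_example` objects, one per fact instance.
#' @export
to_iob_dataset <- function(docs, schema,
                           context = c("fact_span_only", "pad_tokens"),
                           pad_tokens = 0L, abbreviation_lexicon = character()) {
  context <- match.arg(context)
  inventory <- label_inventory(schema)
  out <- list()
  for (adoc in docs) {
    ctx <- section_text(adoc)
    toks <- flatten_tokens(ctx, abbreviation_lexicon)
    for (fi in adoc$facts) {
      inside <- which(toks$end > fi$start & toks$start < fi$end)
      if (length(inside) == 0L) next
      sel <- inside
      if (context == "pad_tokens" && pad_tokens > 0L) {
        lo <- max(1L, min(inside) - pad_tokens)
        hi <- min(nrow(toks), max(inside) + pad_tokens)
        sel <- lo:hi
      }
      labels <- rep("O", length(sel))
      for (es in fi$entities) {
        hit <- which(toks$end[sel] > es$start & toks$start[sel] < es$end)
        if (length(hit) == 0L) next
        partial <- toks$start[sel[hit[1]]] < es$start ||
          toks$end[sel[hit[length(hit)]]] > es$end
        if (partial) {
          warning(sprintf("entity boundary of '%s' splits a token in document %s; whole token labeled",
                          es$entity_type, adoc$document$id), call. = FALSE)
        }
        labels[hit] <- c(paste0("B-", es$entity_type),
                         rep(paste0("I-", es$entity_type), length(hit) - 1L))
      }
      labels[!(labels %in% inventory)] <- "O"
      out[[length(out) + 1L]] <- iob_example(toks$token[sel], labels,
                                             fi$fact_type, adoc$document$id)
    }
  }
  out
}

# ---- serialization ---------------------------------------------------------

#' Read/write annotated documents as JSONL
#'
#' One JSON object per line: `{id, modality, birads, sections,
#' annotated_section, facts: [{fact_type, start, end, entities: [{entity_type,
#' start, end, text}]}]}`. The round trip is lossless.
#'
#' @param docs List of [annotated_document()] objects.
#' @param path File path.
#' @return `write_annotations_jsonl()` returns `path` invisibly;
#'   `read_annotations_jsonl()` the list of documents.
#' @export
write_annotations_jsonl <- function(docs, path) {
  lines <- vapply(docs, function(adoc) {
    d <- adoc$document
    obj <- list(
      id = d$id, modality = d$modality,
      birads = if (is.na(d$birads)) NULL else d$birads,
      sections = d$sections,
      annotated_section = adoc$annotated_section,
      facts = lapply(adoc$facts, function(fi) {
        list(fact_type = fi$fact_type, start = fi$start, end = fi$end,
             entities = lapply(fi$entities, function(es) {
               list(entity_type = es$entity_type, start = es$start,
                    end = es$end, text = es$text)
             }))
      }))
    as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null"))
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_annotations_jsonl
#' @export
read_annotations_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lapply(lines[nzchar(lines)], function(ln) {
    obj <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    doc <- report_document(obj$id, obj$modality, obj$sections,
                           birads = obj$birads %||% NA_integer_)
    facts <- lapply(obj$facts, function(f) {
      fact_instance(f$fact_type, f$start, f$end,
                    entities = lapply(f$entities, function(e) {
                      entity_span(e$entity_type, e$start, e$end, e$text)
                    }))
    })
    annotated_document(doc, facts, obj$annotated_section)
  })
}

#' Write QA examples as SQuAD-v2-style JSON
#'
#' @param examples List of `ff_qa_example` objects (one or more splits
#'   concatenated).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_squad_json <- function(examples, path) {
  paragraphs <- lapply(examples, function(ex) {
    list(context = ex$context,
         qas = list(list(id = ex$id, question = ex$question,
                         answers = lapply(ex$answers, function(a) {
                           list(text = a$text, answer_start = a$answer_start)
                         }),
                         is_impossible = length(ex$answers) == 0L)))
  })
  obj <- list(version = "v2.0",
              data = list(list(title = "reports", paragraphs = paragraphs)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' Write IOB examples as CoNLL-style TSV
#'
#' Token and label separated by a tab, one token per line, a blank line
#' between examples.
#'
#' @param examples List of `ff_iob_example` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conll <- function(examples, path) {
  blocks <- vapply(examples, function(ex) {
    paste(paste(ex$tokens, ex$labels, sep = "\t"), collapse = "\n")
  }, "")
  writeLines(paste(blocks, collapse = "\n\n"), path, useBytes = TRUE)
  invisible(path)
}

#' Read CoNLL-style TSV into IOB examples
#'
#' @param path Input path (as written by [write_conll()]).
#' @return List of `ff_iob_example` objects (fact type unknown, `NA`).
#' @export
read_conll <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  out <- list()
  toks <- character(); labs <- character()
  flush <- function() {
    if (length(toks)) {
      out[[length(out) + 1L]] <<- iob_example(toks, labs, NA_character_)
      toks <<- character(); labs <<- character()
    }
  }
  for (ln in lines) {
    if (!nzchar(ln)) { flush(); next }
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    toks <- c(toks, parts[1]); labs <- c(labs, parts[2])
  }
  flush()
  out
}
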