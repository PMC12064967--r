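# Two-step extraction: per fact type, a span extractor proposes fact spans in
# the findings section (extractive QA with the fact-type name as question),
# then a token labeler tags each span's tokens with IOB entity labels; decoded
# entities are poured into the fact type's slot template and normalized
# against a terminology dictionary. Backends are pluggable: a deterministic
# rule backend compiled from clause templates, or a trainable labeler.

#' Pipeline configuration
#'
#' @param max_answer_tokens Maximum candidate span length in tokens
#'   (default 30).
#' @param top_k_per_fact Maximum number of spans returned per fact type
#'   (default 3).
#' @param span_score_threshold Minimum candidate score (default `-Inf`).
#' @param allow_overlap Keep overlapping candidate spans (default `FALSE`:
#'   greedy non-overlap selection in score order).
#' @param decode_repair How to repair an illegal `I-x` chunk start during IOB
#'   decoding: `"conservative"` drops the tokens, `"begin-coercion"` treats
#'   the first as `B-x`.
#' @return An `ff_pipeline_config` list.
#' @export
pipeline_config <- function(max_answer_tokens = 30L, top_k_per_fact = 3L,
                            span_score_threshold = -Inf, allow_overlap = FALSE,
                            decode_repair = c("conservative", "begin-coercion")) {
  stopifnot(top_k_per_fact >= 1L, max_answer_tokens >= 1L)
  structure(list(max_answer_tokens = as.integer(max_answer_tokens),
                 top_k_per_fact = as.integer(top_k_per_fact),
                 span_score_threshold = span_score_threshold,
                 allow_overlap = isTRUE(allow_overlap),
                 decode_repair = match.arg(decode_repair)),
            class = "ff_pipeline_config")
}

#' Training configuration for the trainable backends
#'
#' Defaults follow the framework's reference fine-tuning recipe: extractive QA
#' at learning rate 3e-5 for 5 epochs with maximum sequence length 384 and
#' document stride 128; sequence labeling at learning rate 5e-5 for up to 100
#' epochs with weight decay 1e-2, batch size 16 and early-stopping patience 5;
#' masked language modeling at learning rate 2e-5, weight decay 0.01, masking
#' probability 0.15, 3 epochs.
#'
#' @param qa,ner,mlm Named lists overriding individual hyperparameters.
#' @param seed Integer seed.
#' @return An `ff_training_config` list.
#' @export
training_config <- function(qa = list(), ner = list(), mlm = list(), seed = 42L) {
  base <- list(
    qa = list(learning_rate = 3e-5, epochs = 5L, max_sequence_length = 384L,
              doc_stride = 128L),
    ner = list(learning_rate = 5e-5, max_epochs = 100L, weight_decay = 1e-2,
               batch_size = 16L, early_stopping_patience = 5L),
    mlm = list(learning_rate = 2e-5, weight_decay = 0.01,
               mask_probability = 0.15, epochs = 3L),
    seed = as.integer(seed))
  base$qa[names(qa)] <- qa
  base$ner[names(ner)] <- ner
  base$mlm[names(mlm)] <- mlm
  rates <- c(base$qa$learning_rate, base$ner$learning_rate,
             base$mlm$learning_rate, base$mlm$mask_probability)
  stopifnot(all(rates > 0), base$ner$early_stopping_patience >= 1L)
  structure(base, class = "ff_training_config")
}

#' Enumerate scored answer spans from start/end position scores
#'
#' Considers every token pair `(s, e)` with `s <= e` and
#' `e - s < max_answer_tokens`, scored as `start_scores[s] + end_scores[e]`.
#' Candidates at or above the score threshold are ranked by score (ties by
#' position); with `allow_overlap = FALSE` a greedy pass keeps the best
#' non-overlapping spans, up to `top_k_per_fact`.
#'
#' @param start_scores,end_scores Numeric vectors of equal length over the
#'   context tokens.
#' @param config An [pipeline_config()].
#' @return Data frame with columns `start`, `end` (1-based inclusive token
#'   indices) and `score`, best first.
#' @export
enumerate_spans <- function(start_scores, end_scores, config = pipeline_config()) {
  n <- length(start_scores)
  stopifnot(length(end_scores) == n)
  empty <- data.frame(start = integer(), end = integer(), score = numeric())
  if (n == 0L) return(empty)
  stopifnot(all(is.finite(start_scores)), all(is.finite(end_scores)))
  s <- rep(seq_len(n), each = n)
  e <- rep(seq_len(n), times = n)
  ok <- e >= s & (e - s) < config$max_answer_tokens
  cand <- data.frame(start = s[ok], end = e[ok],
                     score = start_scores[s[ok]] + end_scores[e[ok]])
  cand <- cand[cand$score >= config$span_score_threshold, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  cand <- cand[order(-cand$score, cand$start, cand$end), , drop = FALSE]
  if (!config$allow_overlap) {
    keep <- logical(nrow(cand))
    sel_s <- integer(); sel_e <- integer()
    for (i in seq_len(nrow(cand))) {
      if (length(sel_s) >= config$top_k_per_fact) break
      overlaps <- any(cand$start[i] <= sel_e & cand$end[i] >= sel_s)
      if (!overlaps) {
        keep[i] <- TRUE
        sel_s <- c(sel_s, cand$start[i]); sel_e <- c(sel_e, cand$end[i])
      }
    }
    cand <- cand[keep, , drop = FALSE]
  } else {
    cand <- utils::head(cand, config$top_k_per_fact)
  }
  rownames(cand) <- NULL
  cand
}

#' Decode an IOB label sequence into entity chunks
#'
#' Accepts either a character vector of labels or a per-token probability
#' matrix with the label inventory as column names (argmax is taken per
#' token). Chunks are maximal legal runs; an `I-x` that does not continue a
#' chunk of type `x` is repaired according to `repair`: `"conservative"`
#' treats it as `O`, `"begin-coercion"` as `B-x`.
#'
#' @param labels Character vector of IOB labels or numeric matrix of
#'   per-token label probabilities.
#' @param repair Repair mode for illegal chunk starts.
#' @param inventory Optional label inventory; labels outside it are an error.
#' @return Data frame with columns `entity_type`, `start`, `end` (1-based
#'   inclusive token indices).
#' @export
decode_iob <- function(labels, repair = c("conservative", "begin-coercion"),
                       inventory = NULL) {
  repair <- match.arg(repair)
  if (is.matrix(labels)) {
    stopifnot(!is.null(colnames(labels)))
    labels <- colnames(labels)[max.col(labels, ties.method = "first")]
  }
  if (!is.null(inventory) && length(labels) && !all(labels %in% inventory)) {
    stop(sprintf("unknown IOB label(s): %s",
                 paste(unique(setdiff(labels, inventory)), collapse = ", ")),
         call. = FALSE)
  }
  bad <- labels[!grepl("^(O|[BI]-.+)$", labels)]
  if (length(bad)) {
    stop(sprintf("unknown IOB label(s): %s",
                 paste(unique(bad), collapse = ", ")), call. = FALSE)
  }
  out_type <- character(); out_start <- integer(); out_end <- integer()
  cur_type <- NA_character_; cur_start <- NA_integer_
  close_chunk <- function(i) {
    if (!is.na(cur_type)) {
      out_type <<- c(out_type, cur_type)
      out_start <<- c(out_start, cur_start)
      out_end <<- c(out_end, i)
    }
    cur_type <<- NA_character_; cur_start <<- NA_integer_
  }
  for (i in seq_along(labels)) {
    lab <- labels[i]
    if (lab == "O") {
      close_chunk(i - 1L)
    } else {
      prefix <- substr(lab, 1L, 1L)
      tp <- substr(lab, 3L, nchar(lab))
      if (prefix == "B") {
        close_chunk(i - 1L)
        cur_type <- tp; cur_start <- i
      } else {  # I-
        if (!is.na(cur_type) && cur_type == tp) {
          # continues current chunk
        } else {
          close_chunk(i - 1L)
          if (repair == "begin-coercion") {
            cur_type <- tp; cur_start <- i
          }  # conservative: drop token
        }
      }
    }
  }
  close_chunk(length(labels))
  data.frame(entity_type = out_type, start = out_start, end = out_end,
             stringsAsFactors = FALSE)
}

#' Assemble a fact instance from decoded entities
#'
#' Applies the fact type's slot template: decoded entities whose type is
#' neither the fact's anchor nor one of its modifier slots are dropped with a
#' `SLOT_VIOLATION` warning; an instance without anchor is kept but flagged
#' `anchorless`. Character offsets are recomputed to section coordinates from
#' the span's token table.
#'
#' @param fact_type_name Fact-type name.
#' @param span_tokens Data frame `token`/`start`/`end` (section coordinates)
#'   of the extracted span's tokens.
#' @param decoded Data frame from [decode_iob()] with token indices into
#'   `span_tokens`.
#' @param schema `ff_schema`.
#' @param section Section text (for entity surface strings).
#' @return List with `instance` (an [fact_instance()], carrying attributes
#'   `anchorless` and `score`), and `warnings` (character vector).
#' @export
assemble_fact <- function(fact_type_name, span_tokens, decoded, schema,
                          section) {
  ft <- schema_fact(schema, fact_type_name)
  stopifnot(!is.null(ft), nrow(span_tokens) > 0L)
  allowed <- c(ft$anchor, ft$modifier_slots)
  warnings <- character()
  entities <- list()
  has_anchor <- FALSE
  if (nrow(decoded) > 0L) {
    for (i in seq_len(nrow(decoded))) {
      tp <- decoded$entity_type[i]
      if (!(tp %in% allowed)) {
        warnings <- c(warnings,
                      sprintf("SLOT_VIOLATION: entity '%s' not permitted for fact type '%s'",
                              tp, fact_type_name))
        next
      }
      cs <- span_tokens$start[decoded$start[i]]
      ce <- span_tokens$end[decoded$end[i]]
      entities[[length(entities) + 1L]] <-
        entity_span(tp, cs, ce, str_slice(section, cs, ce))
      if (tp == ft$anchor) has_anchor <- TRUE
    }
  }
  inst <- fact_instance(fact_type_name,
                        span_tokens$start[1],
                        span_tokens$end[nrow(span_tokens)],
                        entities)
  attr(inst, "anchorless") <- !has_anchor
  list(instance = inst, warnings = warnings)
}

#' Load a terminology dictionary
#'
#' Tab-separated UTF-8 file with header columns `term`, `terminology`,
#' `concept_id`, `preferred_term`; one concept candidate per row, several
#' rows per term allowed. Malformed rows abort with their line number.
#'
#' @param path TSV path.
#' @return Data frame of class `ff_terminology`.
#' @export
read_terminology <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty terminology file", call. = FALSE)
  required <- c("term", "terminology", "concept_id", "preferred_term")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!all(required %in% header)) {
    stop(sprintf("terminology header must contain: %s",
                 paste(required, collapse = ", ")), call. = FALSE)
  }
  rows <- lapply(seq_along(lines)[-1], function(i) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < length(header)) {
      stop(sprintf("malformed terminology row at line %d: expected %d fields, got %d",
                   i, length(header), length(parts)), call. = FALSE)
    }
    parts[seq_along(header)]
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- header
  class(df) <- c("ff_terminology", "data.frame")
  df
}

normalize_term <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x), perl = TRUE))
}

#' Normalize an entity string against a terminology dictionary
#'
#' Case-insensitive, whitespace-normalized exact lookup. Unknown terms give
#' zero candidates; candidates preserve dictionary row order.
#'
#' @param entity_text Extracted entity surface string.
#' @param terminology An `ff_terminology` from [read_terminology()] (or a
#'   data frame with the same columns).
#' @return Data frame with columns `terminology`, `concept_id`,
#'   `preferred_term` (possibly zero rows).
#' @export
normalize_entity <- function(entity_text, terminology) {
  hit <- normalize_term(terminology$term) == normalize_term(entity_text)
  out <- terminology[hit, c("terminology", "concept_id", "preferred_term"),
                     drop = FALSE]
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}

check_label_distributions <- function(probs, inventory) {
  stopifnot(is.matrix(probs), identical(colnames(probs), inventory))
  sums <- rowSums(probs)
  if (any(abs(sums - 1) > 1e-6)) {
    stop("token label distributions must sum to 1", call. = FALSE)
  }
  invisible(probs)
}

#' Run the two-step extraction pipeline on one report
#'
#' Iterates the schema's fact types in order ("once per fact to be
#' extracted"): the span extractor proposes candidate spans for the fact-type
#' name over the annotated section; each span's tokens are labeled by the
#' token labeler, decoded into entity chunks, assembled into a fact instance
#' via the slot template, and each entity is normalized against the
#' terminology dictionary if one is given. A backend failure for one fact
#' type is recorded and the remaining fact types are still processed.
#'
#' The span extractor is called as `span_extractor(question, context)` and
#' may return either a list with `start_scores`/`end_scores` per context
#' token (candidates are then enumerated with [enumerate_spans()]) or
#' directly a data frame of `start`/`end` (1-based inclusive token indices)
#' and `score`. The token labeler is called as
#' `token_labeler(tokens, context)` where `tokens` is the span's
#' token/start/end data frame, and must return a per-token probability matrix
#' over [label_inventory()] of the schema (each row summing to 1).
#'
#' @param report A [report_document()].
#' @param schema Validated `ff_schema`.
#' @param span_extractor,token_labeler Backend callables (see Details).
#' @param terminology Optional `ff_terminology`.
#' @param config An [pipeline_config()].
#' @param section Section to extract from (default `"findings"`).
#' @param abbreviation_lexicon Passed to the tokenizer.
#' @return An `ff_extraction_result`: list with `report_id` and `facts`, one
#'   entry per schema fact type with `fact_type`, `instances` (each holding
#'   `span`, `entities` with per-token probabilities and concept candidates,
#'   `warnings`, `anchorless`) and `error` (`NULL` or a message).
#' @export
run_pipeline <- function(report, schema, span_extractor, token_labeler,
                         terminology = NULL, config = pipeline_config(),
                         section = "findings",
                         abbreviation_lexicon = character()) {
  stopifnot(inherits(report, "ff_report"), inherits(schema, "ff_schema"))
  ctx <- report$sections[[section]] %||% ""
  toks <- flatten_tokens(ctx, abbreviation_lexicon)
  inventory <- label_inventory(schema)

  facts <- lapply(schema$fact_types, function(ft) {
    entry <- list(fact_type = ft$name, instances = list(), error = NULL)
    res <- tryCatch({
      if (!nzchar(ctx) || nrow(toks) == 0L) {
        return(entry)
      }
      raw <- span_extractor(ft$name, ctx)
      cand <- if (is.data.frame(raw)) {
        raw <- raw[order(-raw$score, raw$start), , drop = FALSE]
        raw <- raw[raw$score >= config$span_score_threshold, , drop = FALSE]
        utils::head(raw, config$top_k_per_fact)
      } else {
        enumerate_spans(raw$start_scores, raw$end_scores, config)
      }
      if (nrow(cand) == 0L) return(entry)
      for (i in seq_len(nrow(cand))) {
        span_tokens <- toks[cand$start[i]:cand$end[i], , drop = FALSE]
        probs <- token_labeler(span_tokens, ctx)
        check_label_distributions(probs, inventory)
        decoded <- decode_iob(probs, repair = config$decode_repair,
                              inventory = inventory)
        asm <- assemble_fact(ft$name, span_tokens, decoded, schema, ctx)
        inst <- asm$instance
        ents <- lapply(inst$entities, function(es) {
          tok_idx <- which(span_tokens$start >= es$start &
                             span_tokens$end <= es$end)
          concepts <- if (!is.null(terminology)) {
            normalize_entity(es$text, terminology)
          } else {
            data.frame(terminology = character(), concept_id = character(),
                       preferred_term = character())
          }
          list(type = es$entity_type,
               span = list(start = es$start, end = es$end, text = es$text),
               probabilities = probs[tok_idx, , drop = FALSE],
               concepts = concepts)
        })
        entry$instances[[length(entry$instances) + 1L]] <- list(
          span = list(start = inst$start, end = inst$end,
                      text = str_slice(ctx, inst$start, inst$end),
                      score = cand$score[i]),
          entities = ents,
          warnings = asm$warnings,
          anchorless = isTRUE(attr(inst, "anchorless")))
      }
      entry
    }, error = function(e) {
      entry$error <- conditionMessage(e)
      entry
    })
    res
  })
  structure(list(report_id = report$id, facts = facts),
            class = "ff_extraction_result")
}

#' @export
print.ff_extraction_result <- function(x, ...) {
  n_inst <- sum(vapply(x$facts, function(f) length(f$instances), 0L))
  n_err <- sum(vapply(x$facts, function(f) !is.null(f$error), FALSE))
  cat(sprintf("<extraction result for %s: %d fact types, %d instances, %d backend errors>\n",
              x$report_id, length(x$facts), n_inst, n_err))
  invisible(x)
}

#' Serialize an extraction result to JSON
#'
#' @param result An `ff_extraction_result`.
#' @param path Optional output path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when `path` is given).
#' @export
extraction_to_json <- function(result, path = NULL) {
  obj <- list(report_id = result$report_id,
              facts = lapply(result$facts, function(f) {
                list(fact_type = f$fact_type,
                     error = f$error,
                     instances = lapply(f$instances, function(ins) {
                       list(span = ins$span,
                            warnings = as.list(ins$warnings),
                            anchorless = ins$anchorless,
                            entities = lapply(ins$entities, function(e) {
                              list(type = e$type, span = e$span,
                                   probabilities = apply(e$probabilities, 1L, max),
                                   concepts = e$concepts)
                            }))
                     }))
              }))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null", digits = NA)
  if (!is.null(path)) {
    writeLines(as.character(js), path, useBytes = TRUE)
    return(invisible(as.character(js)))
  }
  as.character(js)
}

#' Early-stopping decision from a metric history
#'
#' Training stops once the monitored metric has stayed strictly below its
#' running best for `patience` consecutive epochs; the best epoch (first
#' occurrence of the maximum, 1-based) is reported for checkpoint reloading.
#'
#' @param metric_history Numeric vector of per-epoch metric values (higher is
#'   better).
#' @param patience Integer >= 1.
#' @return List with `decision` (`"continue"` or `"stop"`) and `best_epoch`
#'   (`NA` for an empty history).
#' @export
early_stopping_check <- function(metric_history, patience = 5L) {
  stopifnot(patience >= 1L)
  n <- length(metric_history)
  if (n == 0L) return(list(decision = "continue", best_epoch = NA_integer_))
  best_epoch <- which.max(metric_history)
  best <- metric_history[best_epoch]
  stop_now <- n - best_epoch >= patience &&
    all(metric_history[(n - patience + 1L):n] < best)
  list(decision = if (stop_now) "stop" else "continue",
       best_epoch = as.integer(best_epoch))
}
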