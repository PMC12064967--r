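# Deterministic pipeline backends compiled from a clause bank: the span
# extractor matches each fact type's clause templates as regular expressions
# over the findings text; the token labeler re-matches a span against the
# bank and turns the slot capture groups into one-hot IOB distributions.

regex_escape <- function(x) {
  gsub("([][{}()+*^$|\\\\?.-])", "\\\\\\1", x)
}

compile_template <- function(template) {
  pat <- ""
  slots <- character()
  for (part in template$parts) {
    if (!is.null(part$lit)) {
      pat <- paste0(pat, regex_escape(part$lit))
    } else {
      pat <- paste0(pat, "(",
                    paste(regex_escape(part$options), collapse = "|"), ")")
      slots <- c(slots, part$slot)
    }
  }
  list(pattern = pat, slots = slots, fact_type = template$fact_type)
}

match_template_exact <- function(compiled, text) {
  m <- regexpr(paste0("^", compiled$pattern, "$"), text, perl = TRUE)
  if (m == -1L) return(NULL)
  cs <- attr(m, "capture.start")[1, ]
  cl <- attr(m, "capture.length")[1, ]
  data.frame(entity_type = compiled$slots,
             start = as.integer(cs) - 1L,
             end = as.integer(cs) - 1L + as.integer(cl),
             stringsAsFactors = FALSE)
}

#' Build rule-based pipeline backends from a clause bank
#'
#' Compiles every clause template into a regular expression with one capture
#' group per entity slot. The span extractor returns, for a fact-type
#' question, the token ranges of every template match in the context (score
#' 1); the token labeler recognizes a span that exactly matches a template
#' and emits one-hot label distributions from the capture groups, or all-`O`
#' distributions for unrecognized spans. On text generated from the same
#' clause bank these backends reproduce the gold annotation exactly.
#'
#' @param bank A clause bank (see [demo_clause_bank()]).
#' @param schema The matching `ff_schema` (for the label inventory).
#' @return List with functions `span_extractor(question, context)` and
#'   `token_labeler(tokens, context)` satisfying the [run_pipeline()]
#'   contracts.
#' @export
rule_backends <- function(bank, schema = demo_schema()) {
  compiled <- lapply(bank, compile_template)
  inventory <- label_inventory(schema)

  span_extractor <- function(question, context) {
    toks <- flatten_tokens(context)
    mine <- Filter(function(cp) cp$fact_type == question, compiled)
    out <- data.frame(start = integer(), end = integer(), score = numeric())
    for (cp in mine) {
      m <- gregexpr(cp$pattern, context, perl = TRUE)[[1]]
      if (m[1] == -1L) next
      for (k in seq_along(m)) {
        cs <- as.integer(m[k]) - 1L
        ce <- cs + attr(m, "match.length")[k]
        idx <- which(toks$start >= cs & toks$end <= ce)
        if (length(idx) == 0L) next
        out <- rbind(out, data.frame(start = min(idx), end = max(idx),
                                     score = 1))
      }
    }
    if (nrow(out) > 1L) out <- out[order(out$start), , drop = FALSE]
    out
  }

  token_labeler <- function(tokens, context = NULL) {
    n <- nrow(tokens)
    labels <- rep("O", n)
    span_start <- tokens$start[1]
    span_text <- if (!is.null(context)) {
      str_slice(context, span_start, tokens$end[n])
    } else {
      paste(tokens$token, collapse = " ")
    }
    for (cp in compiled) {
      ents <- match_template_exact(cp, span_text)
      if (is.null(ents)) next
      for (i in seq_len(nrow(ents))) {
        es <- ents$start[i] + span_start
        ee <- ents$end[i] + span_start
        hit <- which(tokens$start >= es & tokens$end <= ee)
        if (length(hit) == 0L) next
        labels[hit] <- c(paste0("B-", ents$entity_type[i]),
                         rep(paste0("I-", ents$entity_type[i]),
                             length(hit) - 1L))
      }
      break
    }
    labels[!(labels %in% inventory)] <- "O"
    probs <- matrix(0, nrow = n, ncol = length(inventory),
                    dimnames = list(NULL, inventory))
    probs[cbind(seq_len(n), match(labels, inventory))] <- 1
    probs
  }

  list(span_extractor = span_extractor, token_labeler = token_labeler)
}

#' Build a terminology dictionary for the demonstration clause bank
#'
#' A small synthetic stand-in for a terminology server: maps the anchor and
#' categorical modifier surface forms of [demo_clause_bank()] to made-up
#' concept identifiers in two coding systems. Useful for exercising
#' [normalize_entity()] and the pipeline end to end.
#'
#' @return An `ff_terminology` data frame.
#' @export
demo_terminology <- function() {
  add <- function(term) {
    rbind(data.frame(term = term, terminology = "SNOMED-CT",
                     concept_id = sprintf("SCT-%06d", abs(sum(utf8ToInt(term))) %% 999983),
                     preferred_term = term, stringsAsFactors = FALSE),
          data.frame(term = term, terminology = "Wingert",
                     concept_id = sprintf("WGT-%05d", abs(sum(utf8ToInt(term)) * 7) %% 99991),
                     preferred_term = toupper(term), stringsAsFactors = FALSE))
  }
  terms <- character()
  for (t in demo_clause_bank()) {
    for (p in t$parts) {
      if (!is.null(p$slot) && length(p$options) <= 12L) {
        terms <- c(terms, p$options)
      }
    }
  }
  df <- do.call(rbind, lapply(unique(terms), add))
  rownames(df) <- NULL
  class(df) <- c("ff_terminology", "data.frame")
  df
}
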