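# Corpus curation: cleaning raw report collections, abbreviation-aware
# tokenization/sentence splitting, BI-RADS-stratified diversity sampling, and
# pretraining splits. Character offsets are 0-based and half-open everywhere.

#' Extract a 0-based half-open slice from a string
#'
#' @param text A single string.
#' @param start,end 0-based half-open character offsets.
#' @return The substring `text[start:end)`.
#' @export
str_slice <- function(text, start, end) {
  substring(text, start + 1L, end)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Construct a report document
#'
#' A report holds its sections (any of `indication`, `findings`,
#' `assessment`, in that order) plus the BI-RADS assessment category.
#' `full_text` is the newline-joined concatenation of the present sections in
#' canonical order; `token_count` is computed with the package tokenizer.
#'
#' @param id Document identifier.
#' @param modality Imaging modality tag, e.g. `"mammography"`.
#' @param sections Named list of section texts.
#' @param birads Integer BI-RADS category 0-6, or `NA`.
#' @return An object of class `ff_report`.
#' @export
report_document <- function(id, modality, sections, birads = NA_integer_) {
  stopifnot(is.list(sections), length(sections) > 0L, !is.null(names(sections)))
  order_ <- c("indication", "findings", "assessment")
  known <- intersect(order_, names(sections))
  extra <- setdiff(names(sections), order_)
  sections <- sections[c(known, extra)]
  full_text <- paste(unlist(sections), collapse = "\n")
  if (!is.na(birads)) {
    birads <- as.integer(birads)
    stopifnot(birads >= 0L, birads <= 6L)
  }
  structure(list(id = as.character(id), modality = as.character(modality),
                 sections = sections, full_text = full_text,
                 birads = birads,
                 token_count = count_tokens(full_text)),
            class = "ff_report")
}

#' @export
print.ff_report <- function(x, ...) {
  cat(sprintf("<report %s [%s], BI-RADS %s, %d tokens, sections: %s>\n",
              x$id, x$modality,
              ifelse(is.na(x$birads), "-", x$birads), x$token_count,
              paste(names(x$sections), collapse = "/")))
  invisible(x)
}

count_tokens <- function(text) {
  if (is.na(text) || !nzchar(text)) return(0L)
  m <- gregexpr("[\\p{L}\\p{N}]+|[^\\p{L}\\p{N}\\s]", text, perl = TRUE)[[1]]
  if (m[1] == -1L) 0L else length(m)
}

normalize_ws <- function(x) {
  gsub("\\s+", " ", trimws(x), perl = TRUE)
}

apply_encoding_map <- function(x, encoding_map) {
  if (is.null(encoding_map) || length(encoding_map) == 0L) return(x)
  for (i in seq_along(encoding_map)) {
    x <- gsub(names(encoding_map)[i], encoding_map[[i]], x, fixed = TRUE)
  }
  x
}

#' Default repair map for mojibake in German clinical text
#'
#' Maps the common UTF-8-read-as-Latin-1 garbles of German umlauts and sharp s
#' back to the intended characters.
#'
#' @return Named character vector, garbled sequence -> repaired character.
#' @export
default_encoding_map <- function() {
  # UTF-8 byte pairs of German special characters misread as Latin-1
  chars <- c("\u00e4", "\u00f6", "\u00fc", "\u00c4", "\u00d6", "\u00dc", "\u00df")
  out <- chars
  names(out) <- vapply(chars, function(ch) {
    intToUtf8(as.integer(charToRaw(ch)))
  }, "")
  out
}

#' Clean a raw report collection
#'
#' Applies encoding repairs, drops records failing the modality filter, and
#' collapses exact duplicates (byte equality of the whitespace-normalized full
#' text, first occurrence kept). Repairs are applied before duplicate
#' detection. Raw records carry `id`, `modality` and either a single `text`
#' column or per-section columns (`indication`, `findings`, `assessment`),
#' plus an optional `birads`.
#'
#' @param records Data frame of raw records.
#' @param modality_filter Modality string records must match to be kept.
#' @param encoding_map Named character vector of garble -> repair replacements
#'   (see [default_encoding_map()]), or `NULL` for none.
#' @return A list with `documents` (list of [report_document()]) and `stats`,
#'   a `ff_cleaning_stats` list with `n_input`, `n_encoding_fixed`,
#'   `n_duplicates_removed`, `n_nonmodality_removed`, `n_output` satisfying
#'   `n_output = n_input - n_duplicates_removed - n_nonmodality_removed`.
#' @export
clean_corpus <- function(records, modality_filter = "mammography",
                         encoding_map = default_encoding_map()) {
  stats <- list(n_input = 0L, n_encoding_fixed = 0L, n_duplicates_removed = 0L,
                n_nonmodality_removed = 0L, n_output = 0L)
  class(stats) <- "ff_cleaning_stats"
  if (is.null(records) || nrow(as.data.frame(records)) == 0L) {
    return(list(documents = list(), stats = stats))
  }
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  n <- nrow(records)
  section_cols <- intersect(c("indication", "findings", "assessment"),
                            names(records))
  if (length(section_cols) == 0L) {
    if (!"text" %in% names(records)) {
      stop("records need a 'text' column or section columns", call. = FALSE)
    }
    records$findings <- records$text
    section_cols <- "findings"
  }

  fixed <- rep(FALSE, n)
  for (col in section_cols) {
    repaired <- apply_encoding_map(records[[col]], encoding_map)
    fixed <- fixed | (!is.na(repaired) & repaired != records[[col]])
    records[[col]] <- repaired
  }

  keep_modality <- records$modality == modality_filter
  n_nonmod <- sum(!keep_modality)
  records <- records[keep_modality, , drop = FALSE]

  full <- apply(records[, section_cols, drop = FALSE], 1L, function(r) {
    paste(r[!is.na(r) & nzchar(r)], collapse = "\n")
  })
  key <- normalize_ws(full)
  dup <- duplicated(key)
  n_dup <- sum(dup)
  records <- records[!dup, , drop = FALSE]

  docs <- lapply(seq_len(nrow(records)), function(i) {
    secs <- lapply(section_cols, function(col) records[[col]][i])
    names(secs) <- section_cols
    secs <- Filter(function(s) !is.na(s) && nzchar(s), secs)
    birads <- if ("birads" %in% names(records)) records$birads[i] else NA_integer_
    if (is.null(birads) || is.na(birads)) birads <- NA_integer_
    report_document(records$id[i], records$modality[i], secs, birads)
  })

  stats$n_input <- n
  stats$n_encoding_fixed <- sum(fixed)
  stats$n_duplicates_removed <- n_dup
  stats$n_nonmodality_removed <- n_nonmod
  stats$n_output <- length(docs)
  list(documents = docs, stats = stats)
}

#' @export
print.ff_cleaning_stats <- function(x, ...) {
  cat(sprintf("<cleaning: %d in, %d encoding-fixed, %d duplicates removed, %d off-modality removed, %d out>\n",
              x$n_input, x$n_encoding_fixed, x$n_duplicates_removed,
              x$n_nonmodality_removed, x$n_output))
  invisible(x)
}

#' Tokenize text into sentences with exact character offsets
#'
#' Word-and-punctuation tokenization with sentence splitting on `.`, `!`, `?`
#' followed by whitespace or end of text. Periods inside an abbreviation from
#' `abbreviation_lexicon` (matched literally, e.g. `"Vd. a."`, `"z.B."`)
#' never terminate a sentence. Offsets are 0-based half-open into the input
#' text, so `str_slice(text, start, end) == token` for every token.
#'
#' @param text A single string.
#' @param abbreviation_lexicon Character vector of abbreviations (names may
#'   carry expansions; only the abbreviation strings are used for protection).
#' @return List of sentences, each a data frame with columns `token`, `start`,
#'   `end`. Empty text gives an empty list.
#' @export
tokenize_sentences <- function(text, abbreviation_lexicon = character()) {
  if (is.na(text) || !nzchar(text)) return(list())

  protected <- matrix(numeric(0), ncol = 2L)
  abbrs <- if (!is.null(names(abbreviation_lexicon)) &&
               any(nzchar(names(abbreviation_lexicon)))) {
    names(abbreviation_lexicon)
  } else {
    abbreviation_lexicon
  }
  for (ab in abbrs) {
    m <- gregexpr(ab, text, fixed = TRUE)[[1]]
    if (m[1] != -1L) {
      protected <- rbind(protected,
                         cbind(m, m + attr(m, "match.length") - 1L))
    }
  }
  in_protected <- function(pos) {
    nrow(protected) > 0L && any(pos >= protected[, 1] & pos <= protected[, 2])
  }

  m <- gregexpr("[\\p{L}\\p{N}]+|[^\\p{L}\\p{N}\\s]", text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(list())
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  tokens <- substring(text, starts, starts + lens - 1L)
  n <- length(tokens)

  nchar_text <- nchar(text)
  is_break <- vapply(seq_len(n), function(i) {
    tok <- tokens[i]
    if (!(tok %in% c(".", "!", "?"))) return(FALSE)
    pos <- starts[i]
    if (in_protected(pos)) return(FALSE)
    after <- pos + lens[i]
    after > nchar_text || grepl("^\\s", substr(text, after, after), perl = TRUE)
  }, logical(1))

  sentences <- list()
  first <- 1L
  for (i in seq_len(n)) {
    if (is_break[i]) {
      sentences[[length(sentences) + 1L]] <- first:i
      first <- i + 1L
    }
  }
  if (first <= n) sentences[[length(sentences) + 1L]] <- first:n

  lapply(sentences, function(idx) {
    data.frame(token = tokens[idx],
               start = starts[idx] - 1L,
               end = starts[idx] - 1L + lens[idx],
               stringsAsFactors = FALSE)
  })
}

flatten_tokens <- function(text, abbreviation_lexicon = character()) {
  sents <- tokenize_sentences(text, abbreviation_lexicon)
  if (length(sents) == 0L) {
    return(data.frame(token = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, sents)
}

# hashed character-3-gram count vectors; shared by the default diversity
# distance and the default corpus-similarity embedder
trigram_matrix <- function(texts, dim = 512L) {
  mat <- matrix(0, nrow = length(texts), ncol = dim)
  for (i in seq_along(texts)) {
    s <- tolower(normalize_ws(texts[i]))
    nc <- nchar(s)
    if (nc < 3L) next
    grams <- substring(s, 1:(nc - 2L), 3:nc)
    codes <- vapply(grams, function(g) {
      u <- utf8ToInt(g)
      sum(u * c(1, 257, 66049)) %% dim
    }, 0, USE.NAMES = FALSE)
    tab <- table(codes)
    mat[i, as.integer(names(tab)) + 1L] <- as.numeric(tab)
  }
  mat
}

cosine_dist_matrix <- function(mat) {
  nrm <- sqrt(rowSums(mat^2))
  nrm[nrm == 0] <- 1
  sim <- (mat / nrm) %*% t(mat / nrm)
  1 - pmin(pmax(sim, -1), 1)
}

#' BI-RADS-stratified diversity sampling
#'
#' Splits the eligible pool by BI-RADS category and draws, for each requested
#' dataset, an equal number of reports per category by greedy farthest-point
#' selection under a pairwise distance ("maximum variance" sampling). Datasets
#' are drawn in the order given and are pairwise disjoint. Documents longer
#' than `max_tokens` are excluded from the pool before sampling. Ties (and the
#' first pick) resolve by document id order, so a constant-zero distance
#' degenerates to stable id order.
#'
#' @param documents List of [report_document()] objects with non-`NA` birads.
#' @param sizes Named integer vector, dataset name -> total size. Each size
#'   must be divisible by the number of categories present.
#' @param max_tokens Maximum document length in tokens (default 512).
#' @param diversity Either `NULL` (default: cosine distance on hashed
#'   character-3-gram counts) or a function `(text_a, text_b) -> distance`.
#' @return Named list of document lists, one per dataset.
#' @export
stratified_sample <- function(documents, sizes, max_tokens = 512L,
                              diversity = NULL) {
  stopifnot(length(sizes) > 0L, !is.null(names(sizes)))
  birads <- vapply(documents, function(d) {
    if (is.na(d$birads)) NA_integer_ else d$birads
  }, 0L)
  eligible <- !is.na(birads) &
    vapply(documents, `[[`, 0L, "token_count") <= max_tokens
  pool <- documents[eligible]
  pool_birads <- birads[eligible]
  strata <- sort(unique(pool_birads))
  n_strata <- length(strata)
  if (n_strata == 0L) stop("no documents with a BI-RADS category", call. = FALSE)
  if (any(sizes %% n_strata != 0L)) {
    bad <- names(sizes)[sizes %% n_strata != 0L]
    stop(sprintf("dataset size(s) %s not divisible by %d strata",
                 paste(bad, collapse = ", "), n_strata), call. = FALSE)
  }

  taken <- rep(FALSE, length(pool))
  out <- vector("list", length(sizes))
  names(out) <- names(sizes)

  for (ds in names(sizes)) {
    per_stratum <- sizes[[ds]] %/% n_strata
    picked_all <- integer()
    for (s in strata) {
      cand <- which(pool_birads == s & !taken)
      cand <- cand[order(vapply(pool[cand], `[[`, "", "id"))]
      if (length(cand) < per_stratum) {
        stop(sprintf("stratum BI-RADS %d has %d eligible documents, need %d for dataset '%s'",
                     s, length(cand), per_stratum, ds), call. = FALSE)
      }
      texts <- vapply(pool[cand], `[[`, "", "full_text")
      D <- if (is.null(diversity)) {
        cosine_dist_matrix(trigram_matrix(texts))
      } else {
        outer(seq_along(texts), seq_along(texts),
              Vectorize(function(i, j) diversity(texts[i], texts[j])))
      }
      sel <- integer()
      for (k in seq_len(per_stratum)) {
        if (length(sel) == 0L) {
          pick <- 1L  # first by id order
        } else {
          mind <- apply(D[, sel, drop = FALSE], 1L, min)
          mind[sel] <- -Inf
          pick <- which.max(mind)  # which.max is first-by-order on ties
        }
        sel <- c(sel, pick)
      }
      picked_all <- c(picked_all, cand[sel])
    }
    taken[picked_all] <- TRUE
    out[[ds]] <- pool[picked_all]
  }
  out
}

#' Split a corpus into pretraining train/validation sets
#'
#' Seeded random permutation split: the first `floor(train_ratio * N)`
#' documents of the permutation form the training set, the rest validation.
#'
#' @param documents List (any element type).
#' @param train_ratio Fraction in (0, 1) (default 0.9).
#' @param seed Integer seed.
#' @return List with `train` and `validation`, disjoint and exhaustive.
#' @export
pretrain_split <- function(documents, train_ratio = 0.9, seed = 1L) {
  stopifnot(train_ratio > 0, train_ratio < 1)
  n <- length(documents)
  if (n == 0L) return(list(train = list(), validation = list()))
  perm <- with_seed(seed, sample.int(n))
  n_train <- floor(train_ratio * n)
  list(train = documents[perm[seq_len(n_train)]],
       validation = documents[perm[setdiff(seq_len(n), seq_len(n_train))]])
}

#' Empirical token-length quantile of a corpus
#'
#' Used during curation to justify a maximum document length for batched
#' inference (e.g. the 99.5% quantile relative to a 512-token cap).
#'
#' @param documents List of [report_document()] objects.
#' @param prob Quantile level (default 0.995).
#' @return Token count at that quantile (type-7 quantile).
#' @export
token_length_quantile <- function(documents, prob = 0.995) {
  counts <- vapply(documents, `[[`, 0L, "token_count")
  unname(stats::quantile(counts, prob))
}
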