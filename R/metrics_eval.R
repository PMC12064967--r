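# Evaluation machinery: unitizing inter-annotator agreement, SQuAD-style span
# EM/F1, entity-level chunk P/R/F1, perplexity, precision tallies, bootstrap
# confidence intervals, k-fold planning with a shared validation split, and
# embedding-based corpus similarity.

#' Construct a unitization
#'
#' One annotator's segmentation of a continuum (a report section, measured in
#' characters) into categorized units; the gaps are implicit. Units must be
#' non-overlapping and within the continuum.
#'
#' @param annotator Annotator identifier.
#' @param length Continuum length in characters.
#' @param units Data frame with columns `start`, `end` (0-based half-open)
#'   and `category`.
#' @return An `ff_unitization`.
#' @export
unitization <- function(annotator, length, units = data.frame(
  start = integer(), end = integer(), category = character())) {
  units <- as.data.frame(units, stringsAsFactors = FALSE)
  stopifnot(all(c("start", "end", "category") %in% names(units)))
  if (nrow(units) > 0L) {
    stopifnot(all(units$start >= 0), all(units$end <= length),
              all(units$start < units$end))
    units <- units[order(units$start, units$end), , drop = FALSE]
    if (nrow(units) > 1L && any(units$start[-1] < units$end[-nrow(units)])) {
      stop("units of one annotator must not overlap", call. = FALSE)
    }
  }
  rownames(units) <- NULL
  structure(list(annotator = as.character(annotator),
                 length = as.integer(length), units = units),
            class = "ff_unitization")
}

# Pairwise placement statistics for two unit lengths on a continuum of length
# L (integer starts, 0-based): expected squared boundary-gap distance given
# overlap, times overlap probability, and the probability of no overlap.
# Enumerated exactly and cached per (a, b, L).
unit_pair_expectation <- local({
  cache <- new.env(parent = emptyenv())
  function(a, b, L) {
    key <- paste(a, b, L, sep = "_")
    if (!is.null(cache[[key]])) return(cache[[key]])
    pa <- 0:(L - a)
    pb <- 0:(L - b)
    P <- outer(pa, pb, function(p, q) pmax(0, pmin(p + a, q + b) - pmax(p, q)) > 0)
    D <- outer(pa, pb, function(p, q) (p - q)^2 + ((p + a) - (q + b))^2)
    res <- list(mean_overlap_d2 = sum(D[P]) / length(P),
                p_no_overlap = 1 - sum(P) / length(P))
    cache[[key]] <- res
    res
  }
})

alpha_observed <- function(unitizations) {
  total <- 0
  m <- length(unitizations)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i == j) next
    ui <- unitizations[[i]]$units
    uj <- unitizations[[j]]$units
    if (nrow(ui) == 0L) next
    for (r in seq_len(nrow(ui))) {
      s <- ui$start[r]; e <- ui$end[r]; cat <- ui$category[r]
      same <- uj[uj$category == cat & uj$end > s & uj$start < e, , drop = FALSE]
      if (nrow(same) == 0L) {
        total <- total + (e - s)^2
      } else {
        total <- total + sum((s - same$start)^2 + (e - same$end)^2)
      }
    }
  }
  total
}

alpha_expected <- function(unitizations) {
  total <- 0
  m <- length(unitizations)
  L <- unitizations[[1]]$length
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i == j) next
    ui <- unitizations[[i]]$units
    uj <- unitizations[[j]]$units
    if (nrow(ui) == 0L) next
    for (r in seq_len(nrow(ui))) {
      a <- ui$end[r] - ui$start[r]
      same <- uj[uj$category == ui$category[r], , drop = FALSE]
      if (nrow(same) == 0L) {
        total <- total + a^2
      } else {
        p_none <- 1
        for (q in seq_len(nrow(same))) {
          b <- same$end[q] - same$start[q]
          st <- unit_pair_expectation(a, b, L)
          total <- total + st$mean_overlap_d2
          p_none <- p_none * st$p_no_overlap
        }
        total <- total + p_none * a^2
      }
    }
  }
  total
}

#' Krippendorff-style unitizing agreement
#'
#' Agreement coefficient for annotators who both segment and categorize a
#' continuum: `alpha = 1 - Do / De`. The observed disagreement `Do` sums, for
#' every ordered annotator pair and every unit, the squared start- and
#' end-boundary gaps to each overlapping unit of the same category of the
#' other annotator, or the squared unit length when no same-category unit
#' overlaps it. The expected disagreement `De` replaces each term by its
#' exact expectation under independent uniform placement of the involved
#' units over all integer positions of the continuum. Identical unitizations
#' give `alpha = 1`; chance-level segmentation gives `alpha` near 0 and worse
#' than chance goes negative.
#'
#' @param unitizations List of two or more [unitization()] objects over the
#'   same continuum length.
#' @return The agreement coefficient, with attributes `observed` and
#'   `expected`. `De = 0` with `Do > 0` is undefined and raises an error of
#'   class `ff_alpha_undefined`; `Do = De = 0` is degenerate perfect
#'   agreement (`alpha = 1`).
#' @export
unitizing_alpha <- function(unitizations) {
  stopifnot(length(unitizations) >= 2L,
            all(vapply(unitizations, inherits, TRUE, "ff_unitization")))
  lens <- vapply(unitizations, `[[`, 0L, "length")
  if (length(unique(lens)) != 1L) {
    stop("all unitizations must cover the same continuum length", call. = FALSE)
  }
  d_obs <- alpha_observed(unitizations)
  d_exp <- alpha_expected(unitizations)
  if (d_exp == 0) {
    if (d_obs > 0) {
      stop(structure(class = c("ff_alpha_undefined", "error", "condition"),
                     list(message = "expected disagreement is 0 with nonzero observed disagreement; alpha undefined",
                          call = NULL)))
    }
    return(structure(1, observed = 0, expected = 0))
  }
  structure(1 - d_obs / d_exp, observed = d_obs, expected = d_exp)
}

#' Convert gold annotations to a unitization
#'
#' Projects an annotated document onto the agreement continuum (the annotated
#' section) at one of three levels: `fact` (fact spans categorized by fact
#' type), `anchor` (anchor entity spans), or `modifier` (modifier entity
#' spans categorized by entity type).
#'
#' @param doc An [annotated_document()].
#' @param level `"fact"`, `"anchor"` or `"modifier"`.
#' @param schema Schema used to tell anchors from modifiers.
#' @param annotator Annotator id to record.
#' @return An [unitization()].
#' @export
annotations_to_unitization <- function(doc, level = c("fact", "anchor", "modifier"),
                                       schema, annotator = "gold") {
  level <- match.arg(level)
  L <- nchar(section_text(doc))
  roles <- vapply(schema$entity_types, `[[`, "", "role")
  names(roles) <- schema_entity_names(schema)
  rows <- list()
  for (fi in doc$facts) {
    if (level == "fact") {
      rows[[length(rows) + 1L]] <-
        data.frame(start = fi$start, end = fi$end, category = fi$fact_type,
                   stringsAsFactors = FALSE)
    } else {
      want <- if (level == "anchor") "anchor" else "modifier"
      for (es in fi$entities) {
        if (identical(unname(roles[es$entity_type]), want)) {
          rows[[length(rows) + 1L]] <-
            data.frame(start = es$start, end = es$end,
                       category = es$entity_type, stringsAsFactors = FALSE)
        }
      }
    }
  }
  units <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(), end = integer(), category = character())
  unitization(annotator, L, units)
}

# ---- span-level QA metrics -------------------------------------------------

normalize_answer <- function(x) {
  x <- tolower(x)
  x <- gsub("[^\\p{L}\\p{N}\\s]", "", x, perl = TRUE)
  gsub("\\s+", " ", trimws(x), perl = TRUE)
}

token_f1 <- function(pred, gold) {
  pt <- strsplit(pred, " ", fixed = TRUE)[[1]]
  gt <- strsplit(gold, " ", fixed = TRUE)[[1]]
  pt <- pt[nzchar(pt)]; gt <- gt[nzchar(gt)]
  if (length(pt) == 0L && length(gt) == 0L) return(1)
  if (length(pt) == 0L || length(gt) == 0L) return(0)
  common <- 0
  tab <- table(gt)
  for (tok in names(table(pt))) {
    if (tok %in% names(tab)) {
      common <- common + min(sum(pt == tok), tab[[tok]])
    }
  }
  if (common == 0) return(0)
  p <- common / length(pt)
  r <- common / length(gt)
  2 * p * r / (p + r)
}

#' Span-level exact match and token-overlap F1
#'
#' SQuAD-style evaluation adapted for German text: answers are normalized by
#' lowercasing, stripping punctuation and collapsing whitespace (no
#' English-article removal), then scored per example against all gold
#' answers, taking the maximum; results are averaged and reported as
#' percentages.
#'
#' @param predictions Named character vector, example id -> predicted text.
#' @param gold Named list, example id -> character vector of gold answers.
#' @return List with `em` and `f1`, both on the 0-100 scale.
#' @export
qa_em_f1 <- function(predictions, gold) {
  ids <- names(predictions)
  if (!setequal(ids, names(gold)) || length(ids) != length(gold)) {
    stop("prediction and gold id sets differ", call. = FALSE)
  }
  em <- numeric(length(ids)); f1 <- numeric(length(ids))
  for (k in seq_along(ids)) {
    p <- normalize_answer(predictions[[ids[k]]])
    gs <- vapply(gold[[ids[k]]], normalize_answer, "")
    if (length(gs) == 0L) gs <- ""
    em[k] <- as.numeric(any(p == gs))
    f1[k] <- max(vapply(gs, function(g) token_f1(p, g), 0))
  }
  list(em = 100 * mean(em), f1 = 100 * mean(f1))
}

# ---- entity-level chunk metrics --------------------------------------------

#' Entity-level precision, recall and F1 over IOB sequences
#'
#' Chunks are decoded conservatively; a predicted chunk is a true positive
#' iff its type and exact token range match a gold chunk of the same
#' sequence. Per-class precision/recall/F1 use counts over all sequences;
#' means are unweighted (macro) over the classes present in gold or
#' prediction; accuracy is token-level.
#'
#' @param pred,gold Lists of IOB label character vectors, aligned and of
#'   pairwise equal lengths.
#' @return List with `per_class` (data frame: class, tp, n_pred, n_gold,
#'   precision, recall, f1), macro `precision`, `recall`, `f1`, and token
#'   `accuracy`.
#' @export
entity_prf <- function(pred, gold) {
  stopifnot(length(pred) == length(gold))
  for (k in seq_along(pred)) {
    if (length(pred[[k]]) != length(gold[[k]])) {
      stop(sprintf("sequence %d: prediction and gold lengths differ", k),
           call. = FALSE)
    }
  }
  tp <- integer(); np <- integer(); ng <- integer()
  classes <- character()
  bump <- function(cls, dtp, dnp, dng) {
    i <- match(cls, classes)
    if (is.na(i)) {
      classes <<- c(classes, cls)
      tp <<- c(tp, 0L); np <<- c(np, 0L); ng <<- c(ng, 0L)
      i <- length(classes)
    }
    tp[i] <<- tp[i] + dtp; np[i] <<- np[i] + dnp; ng[i] <<- ng[i] + dng
  }
  n_tok <- 0L; n_tok_ok <- 0L
  for (k in seq_along(pred)) {
    pc <- decode_iob(pred[[k]], repair = "conservative")
    gc <- decode_iob(gold[[k]], repair = "conservative")
    pkey <- sprintf("%s:%d:%d", pc$entity_type, pc$start, pc$end)
    gkey <- sprintf("%s:%d:%d", gc$entity_type, gc$start, gc$end)
    for (cls in unique(c(pc$entity_type, gc$entity_type))) {
      pk <- pkey[pc$entity_type == cls]
      gk <- gkey[gc$entity_type == cls]
      bump(cls, length(intersect(pk, gk)), length(pk), length(gk))
    }
    n_tok <- n_tok + length(pred[[k]])
    n_tok_ok <- n_tok_ok + sum(pred[[k]] == gold[[k]])
  }
  prec <- ifelse(np > 0L, tp / np, 0)
  rec <- ifelse(ng > 0L, tp / ng, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  ord <- order(classes)
  per_class <- data.frame(class = classes, tp = tp, n_pred = np, n_gold = ng,
                          precision = prec, recall = rec, f1 = f1,
                          stringsAsFactors = FALSE)[ord, , drop = FALSE]
  rownames(per_class) <- NULL
  list(per_class = per_class,
       precision = if (length(prec)) mean(prec) else NA_real_,
       recall = if (length(rec)) mean(rec) else NA_real_,
       f1 = if (length(f1)) mean(f1) else NA_real_,
       accuracy = if (n_tok > 0L) n_tok_ok / n_tok else NA_real_)
}

# ---- scalar metrics --------------------------------------------------------

#' Perplexity from a mean language-model loss
#'
#' @param mean_loss Nonnegative finite mean validation loss (natural log
#'   scale).
#' @return `exp(mean_loss)`.
#' @export
perplexity_from_loss <- function(mean_loss) {
  if (!is.finite(mean_loss)) stop("mean loss must be finite", call. = FALSE)
  if (mean_loss < 0) stop("mean loss must be nonnegative", call. = FALSE)
  exp(mean_loss)
}

#' Precision percentage from a correctness tally
#'
#' `100 * n_correct / n_total`, rounded half-up to `digits` decimals.
#'
#' @param n_total Number of assessed items.
#' @param n_correct Number judged correct; must not exceed `n_total`.
#' @param digits Decimal places (default 1).
#' @return Percentage; `NA` with a warning when `n_total` is 0 (undefined,
#'   not 0).
#' @export
precision_tally <- function(n_total, n_correct, digits = 1L) {
  if (n_correct > n_total || n_correct < 0L || n_total < 0L) {
    stop("need 0 <= n_correct <= n_total", call. = FALSE)
  }
  if (n_total == 0L) {
    warning("precision of an empty tally is undefined")
    return(NA_real_)
  }
  x <- 100 * n_correct / n_total
  round_half_up(x, digits)
}

round_half_up <- function(x, digits = 0L) {
  scale <- 10^digits
  floor(x * scale + 0.5) / scale
}

#' Percentile bootstrap confidence interval
#'
#' Seeded resampling with replacement; the interval is the percentile
#' interval of the resample statistics and the standard error their standard
#' deviation. Deterministic given the seed.
#'
#' @param metric Function mapping a sample (subset of `items`) to a scalar.
#' @param items Nonempty vector or list of evaluation items.
#' @param n_resamples Number of bootstrap resamples (default 599).
#' @param confidence Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return List with `estimate`, `low`, `high`, `se`, `n_resamples`,
#'   `confidence`.
#' @export
bootstrap_ci <- function(metric, items, n_resamples = 599L, confidence = 0.95,
                         seed = 1L) {
  n <- length(items)
  if (n == 0L) stop("cannot bootstrap an empty item list", call. = FALSE)
  stats_ <- with_seed(seed, {
    vapply(seq_len(n_resamples), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      metric(items[idx])
    }, 0)
  })
  qs <- stats::quantile(stats_, c((1 - confidence) / 2, 1 - (1 - confidence) / 2),
                        names = FALSE)
  list(estimate = metric(items), low = qs[1], high = qs[2],
       se = stats::sd(stats_), n_resamples = as.integer(n_resamples),
       confidence = confidence)
}

#' Cross-validation plan with a shared validation split
#'
#' Draws one seeded validation set of `round(shared_validation * n)` items
#' used by every fold, then partitions the remainder into `k` near-equal test
#' blocks; each fold trains on the remainder minus its test block (with the
#' defaults: 9 folds of 80% train / 10% test plus the shared 10% validation).
#'
#' @param n_items Number of items.
#' @param k Number of folds (default 9).
#' @param shared_validation Fraction held out once for all folds (default
#'   0.1).
#' @param seed Integer seed.
#' @return List with `validation` (indices) and `folds`, a list of
#'   `list(train, test)` index vectors.
#' @export
kfold_plan <- function(n_items, k = 9L, shared_validation = 0.1, seed = 1L) {
  n_val <- round(shared_validation * n_items)
  m <- n_items - n_val
  if (m < k || k < 2L) {
    stop(sprintf("infeasible plan: %d items leave %d for %d folds",
                 n_items, m, k), call. = FALSE)
  }
  perm <- with_seed(seed, sample.int(n_items))
  val <- sort(perm[seq_len(n_val)])
  rest <- perm[(n_val + 1L):n_items]
  sizes <- rep(m %/% k, k) + c(rep(1L, m %% k), rep(0L, k - m %% k))
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  folds <- lapply(seq_len(k), function(f) {
    test <- sort(rest[starts[f]:ends[f]])
    list(train = sort(setdiff(rest, test)), test = test)
  })
  list(validation = val, folds = folds)
}

#' Mean cross-corpus embedding similarity
#'
#' Embeds both text sets and averages the cosine similarity over all cross
#' pairs. The embedder is pluggable; the default hashes character 3-gram
#' counts into a fixed 512-dimensional vector. Texts with all-zero embeddings
#' are excluded with a warning; if nothing remains, an error is raised.
#'
#' @param set_a,set_b Nonempty character vectors.
#' @param embedder `NULL` for the default, or a function mapping a character
#'   vector to a numeric matrix (one row per text, fixed width).
#' @return Mean pairwise cosine similarity in `[-1, 1]`.
#' @export
dataset_similarity <- function(set_a, set_b, embedder = NULL) {
  stopifnot(length(set_a) > 0L, length(set_b) > 0L)
  embed <- if (is.null(embedder)) function(x) trigram_matrix(x) else embedder
  A <- embed(set_a); B <- embed(set_b)
  stopifnot(is.matrix(A), is.matrix(B), ncol(A) == ncol(B))
  drop_zero <- function(M, nm) {
    nrm <- sqrt(rowSums(M^2))
    if (any(nrm == 0)) {
      warning(sprintf("%d zero-embedding text(s) excluded from %s",
                      sum(nrm == 0), nm))
    }
    M[nrm > 0, , drop = FALSE] / nrm[nrm > 0]
  }
  A <- drop_zero(A, "set_a"); B <- drop_zero(B, "set_b")
  if (nrow(A) == 0L || nrow(B) == 0L) {
    stop("all embeddings are zero vectors", call. = FALSE)
  }
  mean(A %*% t(B))
}
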