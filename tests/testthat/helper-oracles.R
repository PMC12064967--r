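# Independent reference implementations used to cross-check the package:
# written as naive enumerations, sharing no code with the implementation.

# exhaustive placement statistics for two unit lengths on continuum L
oracle_unit_stats <- function(a, b, L) {
  d2_sum <- 0; n_overlap <- 0; total <- 0
  for (p in 0:(L - a)) {
    for (q in 0:(L - b)) {
      total <- total + 1
      ov <- min(p + a, q + b) - max(p, q)
      if (ov > 0) {
        d2_sum <- d2_sum + (p - q)^2 + ((p + a) - (q + b))^2
        n_overlap <- n_overlap + 1
      }
    }
  }
  list(mean_overlap_d2 = d2_sum / total,
       p_no_overlap = 1 - n_overlap / total)
}

# brute-force unitizing agreement on toy continua
oracle_alpha <- function(unitizations) {
  m <- length(unitizations)
  L <- unitizations[[1]]$length
  d_obs <- 0; d_exp <- 0
  for (i in 1:m) {
    for (j in 1:m) {
      if (i == j) next
      ui <- unitizations[[i]]$units
      uj <- unitizations[[j]]$units
      if (nrow(ui) == 0) next
      for (r in 1:nrow(ui)) {
        s <- ui$start[r]; e <- ui$end[r]; a <- e - s
        cat <- ui$category[r]
        partners <- uj[uj$category == cat, , drop = FALSE]
        overlapping <- partners[partners$end > s & partners$start < e, ,
                                drop = FALSE]
        if (nrow(overlapping) == 0) {
          d_obs <- d_obs + a^2
        } else {
          for (q in 1:nrow(overlapping)) {
            d_obs <- d_obs + (s - overlapping$start[q])^2 +
              (e - overlapping$end[q])^2
          }
        }
        if (nrow(partners) == 0) {
          d_exp <- d_exp + a^2
        } else {
          p_none <- 1
          for (q in 1:nrow(partners)) {
            b <- partners$end[q] - partners$start[q]
            st <- oracle_unit_stats(a, b, L)
            d_exp <- d_exp + st$mean_overlap_d2
            p_none <- p_none * st$p_no_overlap
          }
          d_exp <- d_exp + p_none * a^2
        }
      }
    }
  }
  if (d_exp == 0) return(if (d_obs == 0) 1 else NA_real_)
  1 - d_obs / d_exp
}

# simple left-to-right chunk scanner (conservative semantics: chunks begin
# only at B- labels)
oracle_chunks <- function(labels) {
  chunks <- list()
  i <- 1L; n <- length(labels)
  while (i <= n) {
    if (startsWith(labels[i], "B-")) {
      tp <- substring(labels[i], 3L)
      j <- i + 1L
      while (j <= n && labels[j] == paste0("I-", tp)) j <- j + 1L
      chunks[[length(chunks) + 1L]] <- list(type = tp, start = i, end = j - 1L)
      i <- j
    } else {
      i <- i + 1L
    }
  }
  chunks
}

# quadratic chunk matcher: per-class precision/recall/F1 plus token accuracy
oracle_prf <- function(pred, gold) {
  classes <- character(); tp <- c(); np <- c(); ng <- c()
  n_tok <- 0; n_ok <- 0
  for (k in seq_along(pred)) {
    pc <- oracle_chunks(pred[[k]])
    gc <- oracle_chunks(gold[[k]])
    cls <- unique(c(sapply(pc, `[[`, "type"), sapply(gc, `[[`, "type")))
    cls <- cls[!is.na(cls)]
    for (cl in cls) {
      if (!(cl %in% classes)) {
        classes <- c(classes, cl); tp[cl] <- 0; np[cl] <- 0; ng[cl] <- 0
      }
      pcl <- Filter(function(x) x$type == cl, pc)
      gcl <- Filter(function(x) x$type == cl, gc)
      np[cl] <- np[cl] + length(pcl)
      ng[cl] <- ng[cl] + length(gcl)
      for (u in pcl) {
        for (v in gcl) {
          if (u$start == v$start && u$end == v$end) {
            tp[cl] <- tp[cl] + 1
            break
          }
        }
      }
    }
    n_tok <- n_tok + length(pred[[k]])
    n_ok <- n_ok + sum(pred[[k]] == gold[[k]])
  }
  if (length(classes) == 0) {
    return(list(precision = NA_real_, recall = NA_real_, f1 = NA_real_,
                accuracy = if (n_tok > 0) n_ok / n_tok else NA_real_))
  }
  prec <- ifelse(np > 0, tp / np, 0)
  rec <- ifelse(ng > 0, tp / ng, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  list(precision = mean(prec), recall = mean(rec), f1 = mean(f1),
       accuracy = n_ok / n_tok,
       by_class = data.frame(class = classes, precision = unname(prec[classes]),
                             recall = unname(rec[classes]),
                             f1 = unname(f1[classes])))
}

# random IOB sequences over a few entity types; legal and illegal variants
random_iob <- function(n, types = c("X", "Y", "Z"), legal = TRUE) {
  labs <- character(n)
  prev_type <- NA_character_
  for (i in seq_len(n)) {
    r <- runif(1)
    if (legal) {
      if (!is.na(prev_type) && r < 0.4) {
        labs[i] <- paste0("I-", prev_type)
      } else if (r < 0.7) {
        prev_type <- sample(types, 1L)
        labs[i] <- paste0("B-", prev_type)
      } else {
        labs[i] <- "O"
        prev_type <- NA_character_
      }
    } else {
      labs[i] <- sample(c("O", paste0("B-", types), paste0("I-", types)), 1L)
    }
  }
  labs
}

# re-encode decoded chunks (data frame entity_type/start/end) as IOB labels
encode_chunks <- function(chunks, n) {
  labs <- rep("O", n)
  if (nrow(chunks) > 0) {
    for (i in 1:nrow(chunks)) {
      rng <- chunks$start[i]:chunks$end[i]
      labs[rng] <- c(paste0("B-", chunks$entity_type[i]),
                     rep(paste0("I-", chunks$entity_type[i]),
                         length(rng) - 1L))
    }
  }
  labs
}

# brute-force span enumeration: all pairs, threshold, greedy non-overlap
oracle_enumerate <- function(start_scores, end_scores, max_len, top_k,
                             threshold = -Inf) {
  n <- length(start_scores)
  cand <- data.frame(start = integer(), end = integer(), score = numeric())
  for (s in seq_len(n)) {
    for (e in seq_len(n)) {
      if (e >= s && (e - s) < max_len) {
        sc <- start_scores[s] + end_scores[e]
        if (sc >= threshold) {
          cand <- rbind(cand, data.frame(start = s, end = e, score = sc))
        }
      }
    }
  }
  cand <- cand[order(-cand$score, cand$start, cand$end), , drop = FALSE]
  sel <- cand[0, ]
  for (i in seq_len(nrow(cand))) {
    if (nrow(sel) >= top_k) break
    ok <- TRUE
    if (nrow(sel) > 0) {
      for (j in 1:nrow(sel)) {
        if (cand$start[i] <= sel$end[j] && cand$end[i] >= sel$start[j]) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok) sel <- rbind(sel, cand[i, ])
  }
  rownames(sel) <- NULL
  sel
}
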