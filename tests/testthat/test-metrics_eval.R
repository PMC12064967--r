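test_that("unitizing agreement matches the brute-force oracle on toy continua", {
  # identical unitizations agree perfectly
  u1 <- unitization("A", 100L, data.frame(start = c(10L, 40L), end = c(20L, 55L),
                                          category = c("fact", "fact")))
  expect_equal(as.numeric(unitizing_alpha(list(u1, u1))), 1)

  # one unit each, zero overlap, same category: frozen oracle value
  a1 <- unitization("A", 100L, data.frame(start = 10L, end = 20L, category = "fact"))
  a2 <- unitization("B", 100L, data.frame(start = 50L, end = 70L, category = "fact"))
  got <- unitizing_alpha(list(a1, a2))
  expect_equal(as.numeric(got), -0.0866488581, tolerance = 1e-9)
  expect_equal(as.numeric(got), oracle_alpha(list(a1, a2)), tolerance = 1e-12)
  expect_lt(as.numeric(got), 1)

  # one annotator annotates, the other nothing: below perfect agreement
  silent <- unitization("B", 100L)
  got2 <- unitizing_alpha(list(a1, silent))
  expect_lt(as.numeric(got2), 1)
  expect_equal(as.numeric(got2), oracle_alpha(list(a1, silent)), tolerance = 1e-12)

  # randomized equivalence on small continua, including multiple categories
  set.seed(99)
  for (rep in 1:12) {
    L <- sample(20:40, 1)
    mk <- function(nm) {
      n <- sample(0:3, 1)
      if (n == 0) return(unitization(nm, L))
      starts <- sort(sample(0:(L - 3L), n))
      ends <- pmin(starts + sample(1:4, n, replace = TRUE), L)
      # enforce non-overlap
      for (i in seq_len(n - 1L)) {
        if (ends[i] > starts[i + 1L]) ends[i] <- starts[i + 1L]
      }
      keep <- starts < ends
      unitization(nm, L, data.frame(start = starts[keep], end = ends[keep],
                                    category = sample(c("x", "y"), sum(keep),
                                                      replace = TRUE)))
    }
    us <- list(mk("A"), mk("B"))
    want <- oracle_alpha(us)
    if (is.na(want)) {
      expect_error(unitizing_alpha(us), class = "ff_alpha_undefined")
    } else {
      expect_equal(as.numeric(unitizing_alpha(us)), want, tolerance = 1e-10)
    }
  }
})

test_that("unitizing agreement is symmetric in annotators and translation-invariant", {
  u1 <- unitization("A", 60L, data.frame(start = c(5L, 30L), end = c(12L, 41L),
                                         category = c("x", "y")))
  u2 <- unitization("B", 60L, data.frame(start = c(6L, 29L), end = c(13L, 40L),
                                         category = c("x", "y")))
  expect_equal(as.numeric(unitizing_alpha(list(u1, u2))),
               as.numeric(unitizing_alpha(list(u2, u1))))

  shift <- function(u, d) {
    unitization(u$annotator, u$length,
                transform(u$units, start = start + d, end = end + d))
  }
  expect_equal(as.numeric(unitizing_alpha(list(shift(u1, 9L), shift(u2, 9L)))),
               as.numeric(unitizing_alpha(list(u1, u2))),
               tolerance = 1e-12)

  expect_error(unitizing_alpha(list(u1, unitization("C", 50L))),
               "continuum length")
})

test_that("span EM/F1 normalizes text and takes the maximum over gold answers", {
  r <- qa_em_f1(c(q1 = "Keine Läsion"), list(q1 = "keine Läsion."))
  expect_equal(r$em, 100)
  expect_equal(r$f1, 100)

  r2 <- qa_em_f1(c(q1 = "Läsion"), list(q1 = "keine Läsion"))
  expect_equal(r2$em, 0)
  expect_equal(r2$f1, 100 * 2 / 3, tolerance = 1e-9)

  r3 <- qa_em_f1(c(q1 = ""), list(q1 = "keine Läsion"))
  expect_equal(r3$em, 0)
  expect_equal(r3$f1, 0)

  # max over gold answers, averaged across ids
  r4 <- qa_em_f1(c(a = "BI-RADS 3", b = "falsch"),
                 list(a = c("etwas anderes", "bi-rads 3"), b = "richtig"))
  expect_equal(r4$em, 50)

  expect_error(qa_em_f1(c(x = "a"), list(y = "a")), "id sets differ")
})

test_that("entity-level metrics equal the independent chunk matcher", {
  identical_seq <- list(c("B-X", "I-X", "O", "B-Y"))
  r <- entity_prf(identical_seq, identical_seq)
  expect_equal(r$precision, 1)
  expect_equal(r$recall, 1)
  expect_equal(r$f1, 1)
  expect_equal(r$accuracy, 1)

  # off-by-one chunk: no partial credit, accuracy below 1
  pred <- list(c("O", "B-X", "I-X", "O"))
  gold <- list(c("B-X", "I-X", "O", "O"))
  r2 <- entity_prf(pred, gold)
  expect_equal(r2$per_class$f1[r2$per_class$class == "X"], 0)
  expect_lt(r2$accuracy, 1)

  expect_error(entity_prf(list(c("O")), list(c("O", "O"))), "lengths differ")

  # randomized equivalence with the quadratic oracle
  set.seed(17)
  for (rep in 1:60) {
    n_seq <- sample(1:3, 1)
    pred <- lapply(seq_len(n_seq), function(i) random_iob(sample(4:12, 1), legal = FALSE))
    gold <- lapply(pred, function(p) random_iob(length(p), legal = FALSE))
    got <- entity_prf(pred, gold)
    want <- oracle_prf(pred, gold)
    expect_equal(got$precision, want$precision, tolerance = 1e-12)
    expect_equal(got$recall, want$recall, tolerance = 1e-12)
    expect_equal(got$f1, want$f1, tolerance = 1e-12)
    expect_equal(got$accuracy, want$accuracy, tolerance = 1e-12)
  }
})

test_that("perplexity is the exponential of the mean loss", {
  expect_equal(perplexity_from_loss(0), 1)
  expect_equal(perplexity_from_loss(1), exp(1))
  expect_equal(perplexity_from_loss(log(1.21)), 1.21, tolerance = 1e-12)
  expect_error(perplexity_from_loss(-0.1), "nonnegative")
  expect_error(perplexity_from_loss(Inf), "finite")
})

test_that("precision tallies round half-up and reject impossible counts", {
  expect_equal(precision_tally(10, 10), 100.0)
  expect_equal(precision_tally(10, 0), 0.0)
  expect_equal(precision_tally(3, 2), 66.7)
  expect_equal(precision_tally(8, 1, digits = 2), 12.5)
  expect_warning(res <- precision_tally(0, 0), "undefined")
  expect_true(is.na(res))
  expect_error(precision_tally(5, 6), "n_correct")
})

test_that("bootstrap intervals are seeded, collapse at zero variance and track binomial spread", {
  const <- rep(0.7, 25)
  b <- bootstrap_ci(mean, const, seed = 3)
  expect_equal(b$low, 0.7)
  expect_equal(b$high, 0.7)
  expect_equal(b$se, 0)
  expect_equal(b$estimate, 0.7)

  items <- rep(c(0, 1), each = 300)
  b1 <- bootstrap_ci(mean, items, seed = 11)
  b2 <- bootstrap_ci(mean, items, seed = 11)
  expect_identical(b1, b2)
  expect_true(b1$low < 0.5 && b1$high > 0.5)
  binom_se <- sqrt(0.25 / length(items))
  expect_equal(b1$se, binom_se, tolerance = 0.15)
  expect_equal(b1$n_resamples, 599L)

  expect_error(bootstrap_ci(mean, numeric(0)), "empty")
})

test_that("k-fold planning shares one validation split and partitions the rest", {
  plan <- kfold_plan(100, k = 9, shared_validation = 0.1, seed = 2)
  expect_length(plan$validation, 10L)
  expect_length(plan$folds, 9L)
  for (f in plan$folds) {
    expect_length(f$test, 10L)
    expect_length(f$train, 80L)
    expect_length(intersect(f$test, plan$validation), 0L)
    expect_length(intersect(f$train, f$test), 0L)
  }
  all_test <- sort(unlist(lapply(plan$folds, `[[`, "test")))
  expect_equal(all_test, sort(setdiff(1:100, plan$validation)))

  expect_identical(plan, kfold_plan(100, k = 9, shared_validation = 0.1, seed = 2))
  expect_error(kfold_plan(5, k = 9), "infeasible")
})

test_that("corpus similarity averages cross-pair cosines and handles degenerate embeddings", {
  expect_equal(dataset_similarity("Keine Läsion", "Keine Läsion"), 1,
               tolerance = 1e-12)

  onehot <- function(texts) {
    M <- matrix(0, length(texts), 2)
    M[cbind(seq_along(texts), as.integer(texts == "b") + 1L)] <- 1
    M
  }
  expect_equal(dataset_similarity(c("a"), c("b"), embedder = onehot), 0)

  # 2x2 toy vectors: cos(p,r)=0, cos(p,s)=1/sqrt2, cos(q,r)=1/sqrt2, cos(q,s)=0
  emb <- function(texts) {
    rbind(c(1, 0), c(1, 1), c(0, 1), c(1, -1))[match(texts, c("p", "q", "r", "s")), ,
                                               drop = FALSE]
  }
  want <- mean(c(0, 1 / sqrt(2), 1 / sqrt(2), 0))
  got <- dataset_similarity(c("p", "q"), c("r", "s"), embedder = emb)
  expect_equal(got, want, tolerance = 1e-12)

  zero_emb <- function(texts) matrix(0, length(texts), 3)
  expect_error(suppressWarnings(dataset_similarity("a", "b", embedder = zero_emb)),
               "zero vectors")
  expect_warning(dataset_similarity(c("a"), c("z", "a"), embedder = function(t) {
    M <- matrix(1, length(t), 2)
    M[t == "z", ] <- 0
    M
  }), "zero-embedding")
})
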