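# A lightweight trainable token-labeling backend: a single-hidden-layer
# neural network (nnet) over hashed token-context features, parameterized by
# the ner block of the training configuration. It satisfies the token-labeler
# contract of run_pipeline() and is small enough to fine-tune on a few
# hundred synthetic IOB examples in seconds on one CPU.

hash_token <- function(token, buckets) {
  u <- utf8ToInt(tolower(token))
  (sum(u * (seq_along(u) %% 7L + 1L)) %% buckets) + 1L
}

token_features <- function(tokens, buckets = 48L) {
  n <- length(tokens)
  X <- matrix(0, nrow = n, ncol = 3L * buckets + 3L)
  prev <- c("<s>", tokens[-n])
  nxt <- c(tokens[-1], "</s>")
  for (i in seq_len(n)) {
    X[i, hash_token(tokens[i], buckets)] <- 1
    X[i, buckets + hash_token(prev[i], buckets)] <- 1
    X[i, 2L * buckets + hash_token(nxt[i], buckets)] <- 1
  }
  X[, 3L * buckets + 1L] <- grepl("^[0-9]+$", tokens)
  X[, 3L * buckets + 2L] <- grepl("^[^\\p{L}\\p{N}]+$", tokens, perl = TRUE)
  X[, 3L * buckets + 3L] <- grepl("^[A-ZÄÖÜ]", tokens, perl = TRUE)
  X
}

#' Train the lightweight token-labeling backend
#'
#' Fits a single-hidden-layer softmax network over hashed token, neighbour
#' and shape features of the IOB training examples. The ner block of
#' `config` supplies the effective hyperparameters: `max_epochs` bounds the
#' optimizer iterations and `weight_decay` is the L2 penalty. The returned
#' function satisfies the token-labeler contract of [run_pipeline()]
#' (per-token probability rows over the schema's label inventory, summing
#' to 1).
#'
#' @param examples List of `ff_iob_example` objects (see [to_iob_dataset()]).
#' @param schema `ff_schema` fixing the label inventory.
#' @param config An [training_config()].
#' @param hidden Hidden-layer width (default 12).
#' @param buckets Hash buckets per feature family (default 48).
#' @return A function `(tokens, context) -> probability matrix`, with the
#'   fitted `nnet` model in attribute `"model"`.
#' @export
train_token_labeler <- function(examples, schema, config = training_config(),
                                hidden = 12L, buckets = 48L) {
  stopifnot(length(examples) > 0L)
  inventory <- label_inventory(schema)
  toks <- unlist(lapply(examples, `[[`, "tokens"))
  labs <- unlist(lapply(examples, `[[`, "labels"))
  stopifnot(all(labs %in% inventory))
  X <- do.call(rbind, lapply(examples, function(ex) token_features(ex$tokens, buckets)))
  Y <- matrix(0, nrow = length(labs), ncol = length(inventory),
              dimnames = list(NULL, inventory))
  Y[cbind(seq_along(labs), match(labs, inventory))] <- 1

  fit <- with_seed(config$seed, {
    nnet::nnet(X, Y, size = hidden, softmax = TRUE,
               decay = config$ner$weight_decay,
               maxit = config$ner$max_epochs,
               MaxNWts = 100000L, trace = FALSE)
  })

  labeler <- function(tokens, context = NULL) {
    tok <- if (is.data.frame(tokens)) tokens$token else tokens
    P <- stats::predict(fit, token_features(tok, buckets))
    colnames(P) <- inventory
    P / rowSums(P)
  }
  attr(labeler, "model") <- fit
  labeler
}

#' Majority-class baseline token labeler
#'
#' Assigns the most frequent training label (virtually always `O`) to every
#' token with probability 1; the reference point the trained labeler must
#' beat.
#'
#' @param examples IOB training examples.
#' @param schema `ff_schema`.
#' @return A token-labeler function.
#' @export
majority_baseline_labeler <- function(examples, schema) {
  inventory <- label_inventory(schema)
  labs <- unlist(lapply(examples, `[[`, "labels"))
  major <- names(sort(table(labs), decreasing = TRUE))[1]
  function(tokens, context = NULL) {
    n <- if (is.data.frame(tokens)) nrow(tokens) else length(tokens)
    P <- matrix(0, nrow = n, ncol = length(inventory),
                dimnames = list(NULL, inventory))
    P[, major] <- 1
    P
  }
}

#' Masked-language-modeling data preparation
#'
#' Prepares the self-supervised pretraining view of a corpus: tokenizes each
#' document and masks each token independently with the configured masking
#' probability (the classic MLM objective). Returned masked positions carry
#' the original token as the prediction target. Large-scale pretraining
#' itself is out of scope; this supplies the data contract plus the
#' perplexity computation (see [perplexity_from_loss()]).
#'
#' @param documents List of [report_document()] objects.
#' @param config An [training_config()]; `mlm$mask_probability` is used.
#' @param seed Integer seed.
#' @param mask_token Mask symbol (default `"[MASK]"`).
#' @return List per document: `tokens` (masked sequence), `targets` (data
#'   frame `position`/`token` of masked positions).
#' @export
mlm_prepare <- function(documents, config = training_config(), seed = 1L,
                        mask_token = "[MASK]") {
  p <- config$mlm$mask_probability
  with_seed(seed, {
    lapply(documents, function(d) {
      toks <- flatten_tokens(d$full_text)$token
      if (length(toks) == 0L) {
        return(list(tokens = character(),
                    targets = data.frame(position = integer(),
                                         token = character())))
      }
      masked <- stats::runif(length(toks)) < p
      out <- toks
      out[masked] <- mask_token
      list(tokens = out,
           targets = data.frame(position = which(masked),
                                token = toks[masked],
                                stringsAsFactors = FALSE))
    })
  })
}
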