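#' Configuration for the next-word-prediction language model
#'
#' The LM shares the SG model's input and recurrent stack (embedding layer
#' plus one-layer LSTM and a post-recurrent tanh hidden layer) but ends in a
#' softmax over the lexicon. Training minimizes next-word cross-entropy with
#' Adamax (learning rate 0.002), mini-batches of 32 sentences, a 90/10
#' batch-level train/validation split and early stopping.
#'
#' @inheritParams sg_config
#' @param hidden_size post-recurrent hidden-layer size.
#' @param recurrent_size LSTM hidden size.
#' @return A list of class `lm_config`.
#' @export
lm_config <- function(preset = c("desk", "paper"),
                      embedding_size = NULL, recurrent_size = NULL,
                      hidden_size = NULL, learning_rate = 0.002,
                      batch_size = 32L, max_epochs = NULL,
                      val_fraction = 0.1, patience = 10L, seed = 1L,
                      max_lexicon = NULL) {
  preset <- match.arg(preset)
  def <- if (preset == "desk")
    list(embedding_size = 32L, recurrent_size = 64L, hidden_size = 64L,
         max_epochs = 30L, max_lexicon = 6000L)
  else
    list(embedding_size = 600L, recurrent_size = 1200L, hidden_size = 1200L,
         max_epochs = 150L, max_lexicon = 300000L)
  cfg <- list(preset = preset,
              embedding_size = as.integer(embedding_size %||% def$embedding_size),
              recurrent_size = as.integer(recurrent_size %||% def$recurrent_size),
              hidden_size = as.integer(hidden_size %||% def$hidden_size),
              learning_rate = learning_rate, batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs %||% def$max_epochs),
              val_fraction = val_fraction, patience = as.integer(patience),
              seed = as.integer(seed),
              max_lexicon = as.integer(max_lexicon %||% def$max_lexicon),
              prob_floor = 1e-12, log_base = "e")
  stopifnot(cfg$embedding_size >= 1, cfg$recurrent_size >= 1,
            cfg$val_fraction > 0, cfg$val_fraction < 1)
  class(cfg) <- "lm_config"
  cfg
}

lm_init_params <- function(cfg, lexicon) {
  V <- lexicon_size(lexicon)
  list(E = matrix(stats::rnorm(V * cfg$embedding_size, 0, 0.1),
                  V, cfg$embedding_size),
       lstm = init_lstm(cfg$embedding_size, cfg$recurrent_size),
       Wh2 = init_linear(cfg$recurrent_size, cfg$hidden_size),
       bh2 = numeric(cfg$hidden_size),
       Wo = init_linear(cfg$hidden_size, V),
       bo = numeric(V))
}

row_softmax <- function(logits) {
  z <- exp(logits - apply(logits, 1L, max))
  z / rowSums(z)
}

# one shape group (equal sentence length): forward and optional backward.
# ids: B x T matrix of 1-based target ids; inputs are <s> followed by the
# first T-1 targets (per-sentence conditioning).
lm_group_pass <- function(params, ids, start_row, weight = NULL) {
  B <- nrow(ids); Tn <- ncol(ids)
  in_ids <- cbind(matrix(start_row, B, 1L), ids[, -Tn, drop = FALSE])
  fw <- lstm_forward(params$E, params$lstm, in_ids)
  loss <- 0
  dH_ext <- vector("list", Tn)
  grads <- NULL
  if (!is.null(weight))
    grads <- list(Wh2 = params$Wh2 * 0, bh2 = params$bh2 * 0,
                  Wo = params$Wo * 0, bo = params$bo * 0)
  for (t in seq_len(Tn)) {
    h <- fw$H[[t]]
    Hq <- tanh(sweep(h %*% params$Wh2, 2L, params$bh2, "+"))
    p <- row_softmax(sweep(Hq %*% params$Wo, 2L, params$bo, "+"))
    tgt <- cbind(seq_len(B), ids[, t])
    loss <- loss - sum(log(pmax(p[tgt], 1e-12)))
    if (!is.null(weight)) {
      dlog <- p * weight
      dlog[tgt] <- dlog[tgt] - weight
      grads$Wo <- grads$Wo + crossprod(Hq, dlog)
      grads$bo <- grads$bo + colSums(dlog)
      dHq <- (dlog %*% t(params$Wo)) * (1 - Hq^2)
      grads$Wh2 <- grads$Wh2 + crossprod(h, dHq)
      grads$bh2 <- grads$bh2 + colSums(dHq)
      dH_ext[[t]] <- dHq %*% t(params$Wh2)
    }
  }
  if (!is.null(weight)) {
    # dH_ext already carries the batch weight via the softmax gradient
    lg <- lstm_backward(params$E, params$lstm, in_ids, fw, dH_ext)
    grads$E <- lg$E
    grads$lstm <- list(Wx = lg$Wx, Wh = lg$Wh, b = lg$b)
  }
  list(loss = loss, grads = grads)
}

lm_batch_pass <- function(params, prep, batch, start_row, train = TRUE) {
  Bmb <- length(batch)
  lens <- vapply(prep[batch], length, 1L)
  loss <- 0
  total <- NULL
  for (grp in split(seq_along(lens), lens)) {
    ids <- do.call(rbind, prep[batch][grp])
    res <- lm_group_pass(params, ids, start_row,
                         weight = if (train) 1 / Bmb else NULL)
    loss <- loss + res$loss
    if (train) total <- if (is.null(total)) res$grads else
      tree_add(total, res$grads)
  }
  list(loss = loss / Bmb, grads = total)
}

#' Train the language model
#'
#' Trains on the raw token sequences of the corpus (any semantic annotation
#' is ignored) with the next-word cross-entropy objective, Adamax, a 90/10
#' batch-level train/validation split, and early stopping on validation loss;
#' the best-validation weights are returned. Each sentence is conditioned on
#' a sentence-start symbol, so the first word has a defined probability.
#'
#' @param corpus list of [frame_sentence()] objects or plain character token
#'   vectors.
#' @param config an [lm_config()].
#' @param lexicon an `sg_lexicon`; built from the corpus when `NULL`.
#' @return An object of class `lm_model` with `params`, `config`, `lexicon`,
#'   `loss_log` and `best_epoch`.
#' @export
train_lm <- function(corpus, config = lm_config(), lexicon = NULL) {
  if (length(corpus) == 0L) stop2("`corpus` must be non-empty")
  tokens <- lapply(corpus, function(s) if (is.character(s)) s else s$tokens)
  if (is.null(lexicon)) lexicon <- build_lexicon(tokens, config$max_lexicon)
  prep <- lapply(tokens, function(tk) lexicon_lookup(lexicon, tk) + 1L)
  start_row <- lexicon$start_id + 1L

  with_seed(config$seed, {
    params <- lm_init_params(config, lexicon)
    ord <- sample.int(length(prep))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    n_val <- floor(config$val_fraction * length(batches))
    val_batches <- if (n_val > 0) batches[seq_len(n_val)] else list()
    train_batches <- batches[seq.int(n_val + 1L, length(batches))]

    opt <- adamax_init(params)
    best <- list(loss = Inf, params = params, epoch = 0L)
    log <- data.frame(epoch = integer(), train_loss = double(),
                      val_loss = double())
    wait <- 0L
    for (epoch in seq_len(config$max_epochs)) {
      tr_loss <- 0
      for (b in train_batches) {
        res <- lm_batch_pass(params, prep, b, start_row, train = TRUE)
        tr_loss <- tr_loss + res$loss
        st <- adamax_step(params, res$grads, opt, config$learning_rate)
        params <- st$params
        opt <- st$state
      }
      tr_loss <- tr_loss / length(train_batches)
      val_loss <- if (length(val_batches) == 0) tr_loss else
        mean(vapply(val_batches, function(b)
          lm_batch_pass(params, prep, b, start_row, train = FALSE)$loss, 0))
      log <- rbind(log, data.frame(epoch = epoch, train_loss = tr_loss,
                                   val_loss = val_loss))
      if (val_loss < best$loss - 1e-10) {
        best <- list(loss = val_loss, params = params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
    structure(list(params = best$params, config = config, lexicon = lexicon,
                   loss_log = log, best_epoch = best$epoch),
              class = "lm_model")
  })
}

#' @export
print.lm_model <- function(x, ...) {
  cat(sprintf(paste0("<lm_model> recurrent %d, embedding %d, lexicon %d\n",
                     "  trained %d epochs (best validation loss %.4f at ",
                     "epoch %d)\n"),
              x$config$recurrent_size, x$config$embedding_size,
              lexicon_size(x$lexicon), nrow(x$loss_log),
              min(x$loss_log$val_loss), x$best_epoch))
  invisible(x)
}

#' Run the language model over a sentence
#'
#' Prepends the sentence-start symbol and processes the tokens sequentially.
#' Returns, for every position t, the model's probability distribution over
#' the lexicon for the word at t given the preceding words, together with the
#' recurrent-layer trajectory (the LSTM hidden state after each actual word).
#'
#' @param model a trained `lm_model`.
#' @param tokens character vector of words.
#' @return List with `dist` (`T x V` matrix, rows sum to 1), `trajectory`
#'   (`T x H` matrix) and `ids` (0-based lexicon ids of the tokens).
#' @export
lm_forward <- function(model, tokens) {
  if (length(tokens) == 0L) stop2("empty sentence")
  ids <- lexicon_lookup(model$lexicon, tokens) + 1L
  in_ids <- matrix(c(model$lexicon$start_id + 1L, ids), nrow = 1L)
  fw <- lstm_forward(model$params$E, model$params$lstm, in_ids)
  Tn <- length(tokens)
  dist <- matrix(0, Tn, lexicon_size(model$lexicon))
  for (t in seq_len(Tn)) {
    Hq <- tanh(drop(fw$H[[t]] %*% model$params$Wh2) + model$params$bh2)
    dist[t, ] <- drop(row_softmax(matrix(
      drop(Hq %*% model$params$Wo) + model$params$bo, nrow = 1L)))
  }
  trajectory <- do.call(rbind, lapply(fw$H[-1L], function(h) h[1L, ]))
  list(dist = dist, trajectory = trajectory, ids = ids - 1L, tokens = tokens)
}

#' Per-word surprisal
#'
#' `surp(w_t) = -ln P(w_t | w_1:t-1)` in natural-log units (nats), with the
#' first word conditioned on the sentence-start symbol. Probabilities are
#' floored at the configured `prob_floor` (default 1e-12) with a warning, so
#' surprisal stays finite. By the chain rule the per-sentence sum equals
#' `-ln P(sentence)` under the model.
#'
#' @param model a trained `lm_model`.
#' @param tokens character vector of words.
#' @return Numeric vector of nonnegative surprisals, one per word.
#' @export
surprisal <- function(model, tokens) {
  fw <- lm_forward(model, tokens)
  p <- fw$dist[cbind(seq_along(tokens), fw$ids + 1L)]
  floor_ <- model$config$prob_floor
  if (any(p < floor_))
    warning("probability below floor; surprisal capped at ",
            format(-log(floor_)), " nats", call. = FALSE)
  -log(pmax(p, floor_))
}

#' Update of the language model's recurrent representations
#'
#' The same mean-absolute-difference measure as [semantic_update()], applied
#' to the LM's recurrent-layer trajectory: the per-word mean absolute change
#' of the hidden state, with the pre-sentence state taken as the zero vector.
#'
#' @param trajectory a `T x H` matrix (the `trajectory` element of
#'   [lm_forward()] output).
#' @return Numeric vector of nonnegative per-word updates.
#' @export
internal_update <- function(trajectory) {
  semantic_update(trajectory)
}

# per-word surprisal + internal update table for a corpus
lm_score_corpus <- function(model, corpus) {
  rows <- lapply(seq_along(corpus), function(i) {
    toks <- if (is.character(corpus[[i]])) corpus[[i]] else corpus[[i]]$tokens
    fw <- lm_forward(model, toks)
    p <- fw$dist[cbind(seq_along(toks), fw$ids + 1L)]
    data.frame(sentence_id = i, position = seq_along(toks), token = toks,
               surprisal = -log(pmax(p, model$config$prob_floor)),
               internal_lm = internal_update(fw$trajectory),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Corpus perplexity of a trained language model
#'
#' `exp(total negative log-likelihood / total token count)` over the corpus.
#'
#' @inheritParams train_lm
#' @param model a trained `lm_model`.
#' @return A single number.
#' @export
lm_perplexity <- function(model, corpus) {
  sc <- lm_score_corpus(model, corpus)
  exp(sum(sc$surprisal) / nrow(sc))
}
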