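#' Configuration for the Sentence Gestalt model
#'
#' The update network is an embedding layer followed by a one-layer LSTM whose
#' hidden state is the Sentence Gestalt; the query network combines the
#' gestalt with a role-filler probe in a tanh hidden layer and emits a
#' logistic unit per role-filler feature. Training uses Adamax with
#' mini-batches of 32 sentences, a 90/10 train/validation split over batches,
#' and early stopping on validation loss.
#'
#' The `"desk"` preset uses sizes small enough for laptop-scale experiments
#' and tests (embedding 32, gestalt 64); the `"paper"` preset uses the
#' full-scale sizes (embedding 600, gestalt 1,200, learning rate 0.01, up to
#' 150 epochs).
#'
#' @param preset `"desk"` or `"paper"`; fills in size defaults.
#' @param embedding_size input embedding dimension.
#' @param gestalt_size LSTM hidden size (the SG layer).
#' @param query_hidden hidden-layer size of the query network.
#' @param feature_size number of binary filler features (semantic mode).
#' @param learning_rate Adamax learning rate (default 0.01).
#' @param batch_size sentences per mini-batch (default 32).
#' @param max_epochs training-epoch cap.
#' @param val_fraction fraction of batches held out for validation.
#' @param patience early-stopping patience in epochs.
#' @param seed RNG seed controlling initialization and batch shuffling.
#' @param filler_mode `"semantic"` (binary feature fillers) or `"lexical"`
#'   (one-hot over the lexicon).
#' @param max_lexicon maximum lexicon size.
#' @param n_frames maximum frame index K encoded in the frame one-hot block.
#' @return A list of class `sg_config`.
#' @export
sg_config <- function(preset = c("desk", "paper"),
                      embedding_size = NULL, gestalt_size = NULL,
                      query_hidden = NULL, feature_size = NULL,
                      learning_rate = 0.01, batch_size = 32L,
                      max_epochs = NULL, val_fraction = 0.1, patience = 10L,
                      seed = 1L, filler_mode = c("semantic", "lexical"),
                      max_lexicon = NULL, n_frames = 8L) {
  preset <- match.arg(preset)
  filler_mode <- match.arg(filler_mode)
  def <- if (preset == "desk")
    list(embedding_size = 32L, gestalt_size = 64L, query_hidden = 64L,
         feature_size = 32L, max_epochs = 60L, max_lexicon = 6000L)
  else
    list(embedding_size = 600L, gestalt_size = 1200L, query_hidden = 1200L,
         feature_size = 300L, max_epochs = 150L, max_lexicon = 300000L)
  cfg <- list(preset = preset,
              embedding_size = as.integer(embedding_size %||% def$embedding_size),
              gestalt_size = as.integer(gestalt_size %||% def$gestalt_size),
              query_hidden = as.integer(query_hidden %||% def$query_hidden),
              feature_size = as.integer(feature_size %||% def$feature_size),
              learning_rate = learning_rate, batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs %||% def$max_epochs),
              val_fraction = val_fraction, patience = as.integer(patience),
              seed = as.integer(seed), filler_mode = filler_mode,
              max_lexicon = as.integer(max_lexicon %||% def$max_lexicon),
              n_frames = as.integer(n_frames),
              # loss aggregation: mean over probes within word, sum over
              # words, mean over sentences in the batch
              loss_aggregation = "probe-mean/word-sum/batch-mean")
  stopifnot(cfg$embedding_size >= 1, cfg$gestalt_size >= 1,
            cfg$query_hidden >= 1, cfg$val_fraction > 0, cfg$val_fraction < 1,
            cfg$batch_size >= 1, cfg$max_epochs >= 1)
  class(cfg) <- "sg_config"
  cfg
}

# initialize all SG parameters; output width = layout$width
sg_init_params <- function(cfg, lexicon, layout) {
  V <- lexicon_size(lexicon)
  list(E = matrix(stats::rnorm(V * cfg$embedding_size, 0, 0.1),
                  V, cfg$embedding_size),
       lstm = init_lstm(cfg$embedding_size, cfg$gestalt_size),
       Wq_sg = init_linear(cfg$gestalt_size, cfg$query_hidden),
       Wq_p = init_linear(layout$width, cfg$query_hidden),
       bq = numeric(cfg$query_hidden),
       Wo = init_linear(cfg$query_hidden, layout$width),
       bo = numeric(layout$width))
}

# forward + optional backward over one shape group (equal length, equal probe
# count). Returns loss (sum over sentences of per-sentence loss) and, when
# `weight` is non-NULL, gradients scaled so that minibatch loss is the mean
# over `1/weight` sentences.
sg_group_pass <- function(params, ids, Pmat, Ymat, n_probes, weight = NULL) {
  B <- nrow(ids); Tn <- ncol(ids); P <- n_probes
  fw <- lstm_forward(params$E, params$lstm, ids)
  rep_idx <- rep(seq_len(B), each = P)
  loss <- 0
  dH_ext <- vector("list", Tn)
  grads <- NULL
  if (!is.null(weight)) {
    grads <- list(Wq_sg = params$Wq_sg * 0, Wq_p = params$Wq_p * 0,
                  bq = params$bq * 0, Wo = params$Wo * 0, bo = params$bo * 0)
  }
  QsgT <- t(params$Wq_sg)
  for (t in seq_len(Tn)) {
    SG <- fw$H[[t]]
    SGrep <- SG[rep_idx, , drop = FALSE]
    Hq <- tanh(sweep(SGrep %*% params$Wq_sg + Pmat %*% params$Wq_p,
                     2L, params$bq, "+"))
    logits <- sweep(Hq %*% params$Wo, 2L, params$bo, "+")
    p <- sigmoid(logits)
    pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    ce <- -(Ymat * log(pc) + (1 - Ymat) * log(1 - pc))
    loss <- loss + sum(ce) / P
    if (!is.null(weight)) {
      dlog <- (p - Ymat) * (weight / P)
      grads$Wo <- grads$Wo + crossprod(Hq, dlog)
      grads$bo <- grads$bo + colSums(dlog)
      dHq <- (dlog %*% t(params$Wo)) * (1 - Hq^2)
      grads$Wq_sg <- grads$Wq_sg + crossprod(SGrep, dHq)
      grads$Wq_p <- grads$Wq_p + crossprod(Pmat, dHq)
      grads$bq <- grads$bq + colSums(dHq)
      dH_ext[[t]] <- rowsum(dHq %*% QsgT, group = rep_idx)
    }
  }
  if (!is.null(weight)) {
    # dH_ext already carries the batch weight via the query-loss gradient
    lg <- lstm_backward(params$E, params$lstm, ids, fw, dH_ext)
    grads$E <- lg$E
    grads$lstm <- list(Wx = lg$Wx, Wh = lg$Wh, b = lg$b)
  }
  list(loss = loss, grads = grads)
}

# split a set of prepared sentences into shape groups
sg_shape_groups <- function(prep) {
  key <- vapply(prep, function(s) paste(length(s$ids), nrow(s$P)), "")
  split(seq_along(prep), key)
}

sg_batch_pass <- function(params, prep, batch, train = TRUE) {
  Bmb <- length(batch)
  loss <- 0
  total <- NULL
  for (grp in sg_shape_groups(prep[batch])) {
    sub <- prep[batch][grp]
    ids <- do.call(rbind, lapply(sub, `[[`, "ids"))
    Pmat <- do.call(rbind, lapply(sub, `[[`, "P"))
    Ymat <- do.call(rbind, lapply(sub, `[[`, "Y"))
    res <- sg_group_pass(params, ids, Pmat, Ymat,
                         n_probes = nrow(sub[[1]]$P),
                         weight = if (train) 1 / Bmb else NULL)
    loss <- loss + res$loss
    if (train) total <- if (is.null(total)) res$grads else
      tree_add(total, res$grads)
  }
  list(loss = loss / Bmb, grads = total)
}

#' Train a Sentence Gestalt model
#'
#' Sentences are presented word by word; after every word, every sentence
#' probe is presented to the query network and the Bernoulli cross-entropy
#' between its completion and the full role-filler target is accumulated and
#' backpropagated through the whole network. Optimization uses Adamax. The
#' training filters of [filter_training_sentences()] are applied first; 90% of
#' the mini-batches are used for training, 10% for validation, and the weights
#' with the best validation loss are returned (early stopping with the
#' configured patience).
#'
#' @param corpus list of [frame_sentence()] objects.
#' @param config an [sg_config()].
#' @param features binary filler feature matrix; synthesized via
#'   [synthetic_features()] when `NULL` in semantic mode.
#' @param lexicon an `sg_lexicon`; built from the corpus when `NULL`.
#' @param roles role inventory for the role one-hot block.
#' @return An object of class `sg_model` with elements `params`, `config`,
#'   `lexicon`, `roles`, `layout`, `features`, `loss_log` (per-epoch train and
#'   validation loss) and `best_epoch`.
#' @export
train_sg <- function(corpus, config = sg_config(), features = NULL,
                     lexicon = NULL, roles = micro_roles()) {
  corpus <- filter_training_sentences(corpus)
  if (length(corpus) == 0L)
    stop2("no sentences left after applying the training filters")
  if (is.null(lexicon)) lexicon <- build_lexicon(corpus, config$max_lexicon)
  if (config$filler_mode == "semantic" && is.null(features)) {
    types <- sort(unique(tolower(unlist(lapply(corpus, `[[`, "tokens")))))
    features <- synthetic_features(types, dim = config$feature_size,
                                   seed = config$seed %% 1000L + 17L)
  }
  Fsz <- if (config$filler_mode == "lexical") lexicon_size(lexicon)
         else ncol(features)
  layout <- probe_layout(Fsz, roles, config$n_frames)

  prep <- lapply(corpus, function(s) {
    pm <- probe_matrices(s, features, roles, config$n_frames,
                         config$filler_mode, lexicon)
    list(ids = lexicon_lookup(lexicon, s$tokens) + 1L, P = pm$P, Y = pm$Y)
  })

  with_seed(config$seed, {
    params <- sg_init_params(config, lexicon, layout)
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
        res <- sg_batch_pass(params, prep, b, train = TRUE)
        tr_loss <- tr_loss + res$loss
        st <- adamax_step(params, res$grads, opt, config$learning_rate)
        params <- st$params
        opt <- st$state
      }
      tr_loss <- tr_loss / length(train_batches)
      val_loss <- if (length(val_batches) == 0) tr_loss else
        mean(vapply(val_batches, function(b)
          sg_batch_pass(params, prep, b, train = FALSE)$loss, 0))
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
                   roles = roles, layout = layout, features = features,
                   loss_log = log, best_epoch = best$epoch),
              class = "sg_model")
  })
}

#' @export
print.sg_model <- function(x, ...) {
  cat(sprintf(paste0("<sg_model> gestalt %d, embedding %d, output width %d ",
                     "(%s fillers)\n  trained %d epochs (best validation loss ",
                     "%.4f at epoch %d)\n"),
              x$config$gestalt_size, x$config$embedding_size, x$layout$width,
              x$config$filler_mode, nrow(x$loss_log),
              min(x$loss_log$val_loss), x$best_epoch))
  invisible(x)
}

#' Run the update network over a sentence
#'
#' Processes the tokens sequentially through the embedding layer and the LSTM
#' and returns the Sentence Gestalt trajectory: one row of SG-layer activation
#' per input word. No probe information is consumed at this stage. The
#' initial gestalt is the zero vector.
#'
#' @param model a trained `sg_model`.
#' @param tokens character vector of words (out-of-vocabulary tokens map to
#'   the OOV symbol).
#' @param state `"hidden"` reads the LSTM hidden (output) vector as the SG
#'   layer; `"hidden+cell"` concatenates hidden and cell state.
#' @return A `T x H` matrix of class `sg_trajectory` (attribute `tokens`).
#' @export
sg_forward <- function(model, tokens, state = c("hidden", "hidden+cell")) {
  state <- match.arg(state)
  if (length(tokens) == 0L) stop2("empty sentence")
  ids <- matrix(lexicon_lookup(model$lexicon, tokens) + 1L, nrow = 1L)
  fw <- lstm_forward(model$params$E, model$params$lstm, ids)
  traj <- do.call(rbind, lapply(fw$H, function(h) h[1L, ]))
  if (state == "hidden+cell")
    traj <- cbind(traj, do.call(rbind, lapply(fw$C, function(c) c[1L, ])))
  structure(traj, tokens = tokens, class = c("sg_trajectory", "matrix"))
}

#' Complete a role-filler probe from a gestalt state
#'
#' Applies the query network to a single SG state and probe and returns the
#' completion vector: one value in (0, 1) per role-filler unit, interpreted as
#' per-unit feature probabilities.
#'
#' @param model a trained `sg_model`.
#' @param sg_state numeric vector of length `gestalt_size` (one row of an
#'   [sg_forward()] trajectory).
#' @param probe numeric probe vector of length `F + R + K` (see
#'   [encode_probes()]).
#' @return Numeric completion vector of length `F + R + K`.
#' @export
sg_query <- function(model, sg_state, probe) {
  H <- model$config$gestalt_size
  if (length(sg_state) != H)
    stop2("`sg_state` must have length ", H)
  if (length(probe) != model$layout$width)
    stop2("`probe` must have length ", model$layout$width,
          " (got ", length(probe), ")")
  h <- tanh(drop(sg_state %*% model$params$Wq_sg +
                   probe %*% model$params$Wq_p) + model$params$bq)
  drop(sigmoid(drop(h %*% model$params$Wo) + model$params$bo))
}

#' Semantic Update of a gestalt trajectory
#'
#' The Semantic Update at word t is the mean absolute difference between the
#' SG-layer activation after that word and its activation before:
#' `SU_t = mean(|sg_t - sg_(t-1)|)`, with `sg_0` the zero vector. The
#' sentence-initial value (the mean absolute activation of the first state) is
#' retained unless `drop_first = TRUE`.
#'
#' @param trajectory a matrix of per-word states ([sg_forward()] output, or
#'   any `T x H` numeric matrix).
#' @param drop_first drop the sentence-initial value (returned as `NA`)?
#' @return Numeric vector of nonnegative per-word updates, length `T`.
#' @export
semantic_update <- function(trajectory, drop_first = FALSE) {
  m <- unclass(trajectory)
  if (!is.matrix(m) || nrow(m) < 1L) stop2("`trajectory` must be a non-empty matrix")
  prev <- rbind(numeric(ncol(m)), m[-nrow(m), , drop = FALSE])
  su <- rowMeans(abs(m - prev))
  if (drop_first) su[1L] <- NA_real_
  su
}

# per-word SU table for a corpus of sentences
sg_score_corpus <- function(model, corpus) {
  rows <- lapply(seq_along(corpus), function(i) {
    toks <- if (is.character(corpus[[i]])) corpus[[i]] else corpus[[i]]$tokens
    su <- semantic_update(sg_forward(model, toks))
    data.frame(sentence_id = i, position = seq_along(toks), token = toks,
               su = su, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
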