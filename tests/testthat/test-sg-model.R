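test_that("semantic update equals the stated mean-absolute-difference formula", {
  # identical consecutive states produce zero update
  m <- rbind(c(1, 2, 3), c(1, 2, 3))
  expect_equal(semantic_update(m)[2], 0)

  # H = 4, sg_0 = 0, sg_1 = (0.2, -0.6, 0.4, 0) -> SU_1 = 0.3
  expect_equal(semantic_update(rbind(c(0.2, -0.6, 0.4, 0)))[1], 0.3)

  # 1,000 random trajectories against the brute-force loop oracle
  set.seed(21)
  for (i in 1:1000) {
    nr <- sample(1:6, 1)
    nc <- sample(1:8, 1)
    m <- matrix(rnorm(nr * nc), nr, nc)
    expect_equal(semantic_update(m), loop_update_oracle(m), tolerance = 1e-12)
  }
})

test_that("semantic update is nonnegative, sign-symmetric and scale-linear", {
  set.seed(31)
  for (i in 1:25) {
    m <- matrix(rnorm(24), 6, 4)
    su <- semantic_update(m)
    expect_true(all(su >= 0))
    expect_equal(semantic_update(-m), su)
    expect_equal(semantic_update(3.7 * m), 3.7 * su)
  }
  expect_true(is.na(semantic_update(matrix(rnorm(8), 2), drop_first = TRUE)[1]))
})

test_that("the update network yields deterministic, shape-correct trajectories", {
  model <- cached_sg_model()
  toks <- c("the", "man", "eats", "the", "cookie", ".")
  tr <- sg_forward(model, toks)
  expect_equal(dim(unclass(tr)), c(6L, model$config$gestalt_size))
  expect_true(all(is.finite(tr)))
  expect_equal(unclass(sg_forward(model, toks)), unclass(tr))
  expect_error(sg_forward(model, character(0)), "empty")

  # word order matters for a trained, non-degenerate model
  tr_perm <- sg_forward(model, rev(toks))
  expect_gt(max(abs(unclass(tr_perm) - unclass(tr))), 1e-4)

  # hidden+cell reading doubles the state width
  tr2 <- sg_forward(model, toks, state = "hidden+cell")
  expect_equal(ncol(tr2), 2L * model$config$gestalt_size)
})

test_that("the query network outputs per-unit probabilities", {
  model <- cached_sg_model()
  sg <- sg_forward(model, c("the", "man", "eats", "the", "cookie", "."))
  probe <- numeric(model$layout$width)
  probe[model$layout$F + 3L] <- 1
  out <- sg_query(model, sg[6, ], probe)
  expect_length(out, model$layout$width)
  expect_true(all(out > 0 & out < 1))
  expect_error(sg_query(model, sg[6, ], numeric(3)), "length")
})

test_that("a trained model decodes fillers correctly; an untrained one is at chance", {
  model <- cached_sg_model()
  spec <- micro_world()
  lay <- model$layout
  patient_words <- unique(unlist(lapply(spec$patients, names)))
  # filler-probe for A1 after the full sentence: nearest-target decoding
  decode_patient <- function(m, tokens) {
    sg <- sg_forward(m, tokens)
    probe <- numeric(lay$width)
    probe[lay$F + match("A1", m$roles)] <- 1
    probe[lay$F + lay$R + 1L] <- 1  # frame 1
    out <- sg_query(m, sg[nrow(sg), ], probe)[seq_len(lay$F)]
    cand <- m$features[patient_words, , drop = FALSE]
    patient_words[which.min(rowSums((cand - rep(out, each = nrow(cand)))^2))]
  }
  acts <- names(spec$actions)
  stim <- lapply(acts, function(a) {
    pat <- names(spec$patients[[a]])[which.max(spec$patients[[a]])]
    list(tokens = c("the", "man", a, "the", pat, "."), truth = pat)
  })
  acc <- mean(vapply(stim, function(s)
    decode_patient(model, s$tokens) == s$truth, TRUE))
  expect_gte(acc, 5 / 6)

  # untrained model: accuracy compatible with the 1/6 chance level
  untrained <- model
  untrained$params <- with_seed_params <- local({
    set.seed(99)
    gestaltN400:::sg_init_params(model$config, model$lexicon, lay)
  })
  acc0 <- mean(replicate(10, vapply(stim, function(s)
    decode_patient(untrained, s$tokens) == s$truth, TRUE)))
  expect_lt(acc0, 0.5)
})

test_that("training reduces the probing loss and respects configuration", {
  corpus <- sample_corpus(micro_world(), 150L, seed = 8L)
  cfg <- sg_config(max_epochs = 8L, seed = 8L)
  model <- train_sg(corpus, cfg)
  expect_lt(model$loss_log$train_loss[nrow(model$loss_log)],
            model$loss_log$train_loss[1])
  expect_true(all(is.finite(model$loss_log$train_loss)))

  # the cached (longer-trained) model improves on its validation loss too
  m <- cached_sg_model()
  expect_lt(min(m$loss_log$val_loss), m$loss_log$val_loss[1])

  # lexical filler mode: output width = lexicon size + R + K
  cfg_lex <- sg_config(max_epochs = 2L, seed = 3L, filler_mode = "lexical")
  mlex <- train_sg(corpus[1:40], cfg_lex)
  expect_equal(mlex$layout$width,
               lexicon_size(mlex$lexicon) + length(mlex$roles) +
                 cfg_lex$n_frames)

  # sentences failing the training filters are excluded up front
  short <- list(frame_sentence(c("a", "b"),
                               list(list(index = 1L, predicate = "b",
                                         args = list()))))
  expect_error(train_sg(short, cfg), "training filters")
})

test_that("SG gradients match finite differences on a tiny model", {
  ns <- asNamespace("gestaltN400")
  set.seed(12)
  corpus <- sample_corpus(micro_world(), 2L, seed = 12L)
  lex <- build_lexicon(corpus, 50L)
  feat <- synthetic_features(
    sort(unique(tolower(unlist(lapply(corpus, `[[`, "tokens"))))),
    dim = 4L, seed = 5L)
  cfg <- sg_config(embedding_size = 3L, gestalt_size = 4L, query_hidden = 5L,
                   feature_size = 4L)
  lay <- ns$probe_layout(4L, micro_roles(), 8L)
  params <- ns$sg_init_params(cfg, lex, lay)
  prep <- lapply(corpus, function(s) {
    pm <- ns$probe_matrices(s, feat, micro_roles(), 8L, "semantic", lex)
    list(ids = ns$lexicon_lookup(lex, s$tokens) + 1L, P = pm$P, Y = pm$Y)
  })
  res <- ns$sg_batch_pass(params, prep, seq_along(prep), train = TRUE)
  loss_fn <- function(p)
    ns$sg_batch_pass(p, prep, seq_along(prep), train = FALSE)$loss
  modify <- function(tree, path, i, d) {
    if (length(path) == 1) { tree[[path]][i] <- tree[[path]][i] + d; tree }
    else { tree[[path[1]]] <- modify(tree[[path[1]]], path[-1], i, d); tree }
  }
  paths <- list("E", c("lstm", "Wx"), c("lstm", "Wh"), c("lstm", "b"),
                "Wq_sg", "Wq_p", "bq", "Wo", "bo")
  for (pp in paths) {
    g <- res$grads
    for (k in pp) g <- g[[k]]
    for (i in sample(length(g), min(4L, length(g)))) {
      num <- (loss_fn(modify(params, pp, i, 1e-5)) -
                loss_fn(modify(params, pp, i, -1e-5))) / 2e-5
      expect_lt(abs(num - g[i]) / max(1e-6, abs(num) + abs(g[i])), 1e-4)
    }
  }
})
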