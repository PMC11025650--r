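test_that("frame corpus serialization round-trips and validates", {
  spec <- micro_world()
  corpus <- sample_corpus(spec, 50L, seed = 7L)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_frame_corpus(corpus, path)
  back <- read_frame_corpus(path, roles = micro_roles())
  expect_length(back, 50L)
  for (i in seq_along(corpus)) {
    expect_identical(back[[i]]$tokens, corpus[[i]]$tokens)
    expect_equal(back[[i]]$frames, corpus[[i]]$frames)
  }

  # a nested multi-frame record: 13 tokens, three frames
  nested <- frame_sentence(
    c("then", "she", "took", "great", "heaving", "breaths", "as", "though",
      "she", "had", "come", "up", "."),
    list(list(index = 1L, predicate = "took",
              args = list(list(role = "A0", filler = "she"),
                          list(role = "A1", filler = "breaths"),
                          list(role = "AM-MNR", filler = "though"))),
         list(index = 2L, predicate = "heaving",
              args = list(list(role = "A1", filler = "breaths"))),
         list(index = 3L, predicate = "come",
              args = list(list(role = "A0", filler = "she"),
                          list(role = "AM-DIR", filler = "up")))))
  expect_length(nested$tokens, 13L)
  write_frame_corpus(list(nested), path)
  back <- read_frame_corpus(path)
  expect_length(back[[1]]$frames, 3L)
  expect_equal(back[[1]], nested)
})

test_that("malformed corpus records raise parse errors naming the line", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  good <- '{"tokens":["a","b"],"frames":[{"index":1,"predicate":"b","args":[{"role":"A0","filler":"a"}]}]}'
  bad_role <- '{"tokens":["a","b"],"frames":[{"index":1,"predicate":"b","args":[{"role":"XYZ","filler":"a"}]}]}'
  writeLines(c(good, bad_role), path)
  expect_error(read_frame_corpus(path), "line 2.*XYZ|XYZ.*line 2")
  writeLines(c(good, '{"frames":[]}'), path)
  expect_error(read_frame_corpus(path), "line 2")
  # non-contiguous frame indices
  writeLines('{"tokens":["a"],"frames":[{"index":2,"predicate":"a","args":[]}]}',
             path)
  expect_error(read_frame_corpus(path), "contiguous")
})

test_that("build_lexicon keeps the most frequent forms with lexicographic ties", {
  corpus <- list(c(rep("a", 5), rep("b", 3), "c"))
  lex <- build_lexicon(corpus, max_size = 2L)
  expect_setequal(lex$words, c("<s>", "<oov>", "a", "b"))
  expect_identical(unname(lex$index[lex$words]), 0:3)

  # ties broken lexicographically
  lex1 <- build_lexicon(list(c("b", "a", "b", "a")), max_size = 1L)
  expect_true("a" %in% lex1$words && !"b" %in% lex1$words)

  # no truncation when max_size exceeds the number of types
  lex_all <- build_lexicon(corpus, max_size = 100L)
  expect_setequal(lex_all$words, c("<s>", "<oov>", "a", "b", "c"))
  expect_error(build_lexicon(corpus, max_size = 0L), "max_size")

  # lookup lower-cases and maps unknowns to OOV
  expect_identical(lexicon_size(lex), 4L)
  ids <- gestaltN400:::lexicon_lookup(lex, c("A", "zzz"))
  expect_identical(ids[2], lex$oov_id)
  expect_identical(ids[1], unname(lex$index[["a"]]))
})

test_that("embedding binarization follows the strict threshold rule", {
  m <- matrix(c(0.3, -0.2, 0.0), nrow = 1, dimnames = list("w", NULL))
  expect_equal(unname(binarize_embeddings(m)[1, ]), c(1, 0, 0))
  allpos <- matrix(runif(5) + 0.1, nrow = 1, dimnames = list("w", NULL))
  expect_true(all(binarize_embeddings(allpos) == 1))
  expect_error(binarize_embeddings(list(a = c(1, 2), b = c(1, 2, 3))),
               "ragged")

  # elementwise agreement with a scalar comparison oracle on a 300-dim table
  set.seed(11)
  emb <- matrix(rnorm(40 * 300), 40, 300,
                dimnames = list(sprintf("w%02d", 1:40), NULL))
  bin <- binarize_embeddings(emb, threshold = 0.1)
  for (i in sample(length(emb), 1000L))
    expect_identical(unname(bin[i]), as.numeric(emb[i] > 0.1))
})

test_that("embeddings round-trip through word2vec text format", {
  emb <- matrix(rnorm(12), 3, 4,
                dimnames = list(c("alpha", "beta", "gamma"), NULL))
  path <- withr::local_tempfile(fileext = ".txt")
  write_embeddings(emb, path)
  expect_identical(readLines(path, n = 1L), "3 4")
  back <- read_embeddings(path)
  expect_equal(back, emb, tolerance = 1e-6)
})

test_that("probe encoding emits a role- and a filler-probe per argument", {
  s <- frame_sentence(
    c("the", "boy", "eats", "the", "cookie", "in", "the", "kitchen", "."),
    list(list(index = 1L, predicate = "eats",
              args = list(list(role = "A0", filler = "boy"),
                          list(role = "V", filler = "eats"),
                          list(role = "A1", filler = "cookie"),
                          list(role = "AM-LOC", filler = "kitchen")))),
    roles = micro_roles())
  feat <- synthetic_features(c("boy", "eats", "cookie", "kitchen"), dim = 8)
  pr <- encode_probes(s, feat, roles = micro_roles(), n_frames = 8L)
  expect_length(pr, 8L)  # 4 arguments x 2 probes

  lay <- gestaltN400:::probe_layout(8L, micro_roles(), 8L)
  role_block <- lay$F + seq_len(lay$R)
  frame_block <- lay$F + lay$R + seq_len(lay$K)
  for (p in pr) {
    expect_length(p$probe, lay$width)
    # target invariants: exactly one 1 in role and frame blocks
    expect_equal(sum(p$target[role_block]), 1)
    expect_equal(sum(p$target[frame_block]), 1)
    if (p$kind == "role-probe") {
      expect_true(all(p$probe[role_block] == 0))
      expect_true(any(p$probe[seq_len(lay$F)] != 0))
    } else {
      expect_true(all(p$probe[seq_len(lay$F)] == 0))
      expect_equal(sum(p$probe[role_block]), 1)
    }
  }
  # role-probe for <boy, A0>: target has the A0 unit set
  rp <- pr[[1]]
  expect_identical(rp$kind, "role-probe")
  expect_equal(p_a0 <- rp$target[lay$F + match("A0", micro_roles())], 1)

  # frame index beyond K errors
  s2 <- frame_sentence(c("a", "b"), list(list(index = 1L, predicate = "b",
                                              args = list())))
  pr2 <- encode_probes(toy_sentence(), feat, n_frames = 1L)
  expect_length(pr2, 6L)
  bad <- toy_sentence()
  bad$frames[[1]]$index <- 9L
  expect_error(encode_probes(bad, feat, n_frames = 8L), "exceeds")

  # OOV filler maps to the all-zero feature vector with a warning
  expect_warning(pr3 <- encode_probes(toy_sentence(), feat[1:2, ]), "OOV")
})

test_that("training filters keep 6-15 token, <= 8 frame sentences in order", {
  mk <- function(n_tok, n_frames = 1L) {
    frame_sentence(rep("w", n_tok),
                   lapply(seq_len(n_frames), function(i)
                     list(index = i, predicate = "w", args = list())))
  }
  corpus <- list(mk(5), mk(6), mk(15), mk(16), mk(10, 8), mk(10, 9))
  kept <- filter_training_sentences(corpus)
  expect_equal(vapply(kept, function(s) length(s$tokens), 1L), c(6L, 15L, 10L))
  expect_equal(filter_training_sentences(list()), list())
  # subsequence + idempotence
  expect_identical(filter_training_sentences(kept), kept)
  expect_true(all(vapply(kept, function(s)
    any(vapply(corpus, identical, TRUE, s)), TRUE)))
})
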