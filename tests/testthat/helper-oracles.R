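# Independent oracles used across tests. These deliberately avoid the
# package's own vectorized implementations.

# brute-force elementwise loop for the mean-absolute-difference update
loop_update_oracle <- function(m) {
  Tn <- nrow(m); H <- ncol(m)
  prev <- rep(0, H)
  out <- numeric(Tn)
  for (t in seq_len(Tn)) {
    s <- 0
    for (j in seq_len(H)) s <- s + abs(m[t, j] - prev[j])
    out[t] <- s / H
    prev <- m[t, ]
  }
  out
}

# exhaustive Benjamini-Hochberg step-up: largest k with p_(k) <= alpha*k/m
bh_step_up_oracle <- function(p, alpha) {
  n <- length(p)
  o <- order(p)
  k <- 0L
  for (i in seq_len(n)) if (p[o[i]] <= alpha * i / n) k <- i
  rej <- logical(n)
  if (k > 0L) rej[o[seq_len(k)]] <- TRUE
  rej
}

# a fixed first-order Markov chain over a small vocabulary
bigram_world <- function() {
  V <- c("ga", "ro", "mi", "tu", "ke", "po")
  A <- matrix(c(
    0.50, 0.20, 0.10, 0.10, 0.05, 0.05,
    0.10, 0.40, 0.25, 0.10, 0.10, 0.05,
    0.05, 0.10, 0.45, 0.20, 0.10, 0.10,
    0.20, 0.05, 0.05, 0.40, 0.20, 0.10,
    0.10, 0.30, 0.10, 0.05, 0.35, 0.10,
    0.15, 0.15, 0.15, 0.15, 0.20, 0.20),
    nrow = 6, byrow = TRUE, dimnames = list(V, V))
  pi0 <- c(ga = 0.35, ro = 0.25, mi = 0.15, tu = 0.10, ke = 0.10, po = 0.05)
  list(V = V, A = A, pi0 = pi0)
}

sample_bigram_corpus <- function(n, len, seed, world = bigram_world()) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    s <- character(len)
    s[1] <- sample(world$V, 1L, prob = world$pi0)
    for (t in 2:len) s[t] <- sample(world$V, 1L, prob = world$A[s[t - 1], ])
    s
  })
}

analytic_bigram_surprisal <- function(tokens, world = bigram_world()) {
  c(-log(world$pi0[tokens[1]]),
    -log(world$A[cbind(tokens[-length(tokens)], tokens[-1])]))
}

# a well-formed multi-frame sentence used in several corpus tests
toy_sentence <- function() {
  frame_sentence(
    c("the", "boy", "eats", "the", "cookie", "."),
    list(list(index = 1L, predicate = "eats",
              args = list(list(role = "A0", filler = "boy"),
                          list(role = "V", filler = "eats"),
                          list(role = "A1", filler = "cookie")))),
    roles = micro_roles())
}

# shared trained models (training is the expensive step; several tests probe
# the same fitted model)
.model_cache <- new.env(parent = emptyenv())

cached_sg_model <- function() {
  if (is.null(.model_cache$sg)) {
    corpus <- sample_corpus(micro_world(), 400L, seed = 1L)
    .model_cache$sg <- train_sg(corpus, sg_config(seed = 1L))
  }
  .model_cache$sg
}

cached_lm_model <- function() {
  if (is.null(.model_cache$lm)) {
    corpus <- sample_corpus(micro_world(), 300L, seed = 2L)
    .model_cache$lm <- train_lm(corpus, lm_config(seed = 2L, max_epochs = 20L))
  }
  .model_cache$lm
}

# standardized synthetic predictors for regression simulations
simulated_predictors <- function(n_words, seed) {
  set.seed(seed)
  data.frame(word_id = sprintf("w%04d", seq_len(n_words)),
             su = as.numeric(scale(stats::rgamma(n_words, 4, 10))),
             surprisal = as.numeric(scale(stats::rgamma(n_words, 3, 1))))
}
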