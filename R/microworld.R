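#' Define a synthetic micro-world
#'
#' A small event world with controllable conditional structure, used to
#' generate frame-annotated training corpora for which ground-truth statistics
#' are known. Three sentence templates are produced:
#'
#' * transitive: `the AGENT ACTION the PATIENT .` (6 tokens)
#' * located: `the AGENT ACTION the PATIENT in the LOCATION .` (9 tokens)
#' * conjunction: `the AGENT sees the NOUN1 and the NOUN2 .` (9 tokens)
#'
#' The patient distribution of each action sets cloze probability (high- vs.
#' low-probability completions); words outside an action's patient set are
#' incongruent completions; agent sampling weights set lexical frequency; the
#' conjunction template implements associative priming: the second noun is the
#' partner of the first with probability `related_prob`, so partner nouns are
#' predictable from their primes.
#'
#' In the default world the patient distributions are arranged in cyclic
#' triples (each patient word is the 0.7-cloze completion of one action, the
#' 0.2 completion of another and the 0.1 completion of a third), so that all
#' patient words have identical marginal corpus frequency and the cloze
#' contrast manipulates conditional probability only.
#'
#' All conditional probability vectors must sum to 1 (tolerance 1e-9).
#'
#' @param agents named numeric vector of agent sampling weights.
#' @param actions named numeric vector of action probabilities.
#' @param patients named list: per action, a named probability vector over
#'   patients.
#' @param locations named list: per action, a named probability vector over
#'   locations.
#' @param prime_nouns nouns used by the conjunction template.
#' @param prime_pairs named character vector mapping each prime noun to its
#'   related partner (made symmetric automatically).
#' @param related_prob probability that the second conjunct is the partner of
#'   the first.
#' @param p_template named probabilities of the three templates.
#' @param p_agent_sees probability weights of agents in conjunction sentences
#'   (defaults to `agents`).
#' @return An object of class `micro_world`.
#' @export
micro_world <- function(
    agents = c(man = 0.3, woman = 0.3, boy = 0.15, girl = 0.15,
               dog = 0.07, chef = 0.03),
    actions = c(eats = 1/6, bakes = 1/6, picks = 1/6,
                reads = 1/6, writes = 1/6, opens = 1/6),
    patients = list(
      eats   = c(cookie = 0.7, bread = 0.2, apple = 0.1),
      bakes  = c(bread = 0.7, apple = 0.2, cookie = 0.1),
      picks  = c(apple = 0.7, cookie = 0.2, bread = 0.1),
      reads  = c(book = 0.7, letter = 0.2, note = 0.1),
      writes = c(letter = 0.7, note = 0.2, book = 0.1),
      opens  = c(note = 0.7, book = 0.2, letter = 0.1)),
    locations = list(
      eats   = c(kitchen = 0.8, cafe = 0.2),
      bakes  = c(kitchen = 0.8, house = 0.2),
      picks  = c(garden = 0.8, kitchen = 0.2),
      reads  = c(library = 0.8, garden = 0.2),
      writes = c(office = 0.8, library = 0.2),
      opens  = c(house = 0.8, office = 0.2)),
    prime_nouns = c("salt", "pepper", "cup", "saucer",
                    "needle", "thread", "lock", "key"),
    prime_pairs = c(salt = "pepper", cup = "saucer",
                    needle = "thread", lock = "key"),
    related_prob = 0.8,
    p_template = c(transitive = 0.35, located = 0.32, conjunction = 0.33),
    p_agent_sees = NULL) {
  pairs <- c(prime_pairs, stats::setNames(names(prime_pairs),
                                          unname(prime_pairs)))
  spec <- list(agents = agents / sum(agents), actions = actions,
               patients = patients, locations = locations,
               prime_nouns = prime_nouns, prime_pairs = pairs,
               related_prob = related_prob, p_template = p_template,
               p_agent_sees = p_agent_sees %||% (agents / sum(agents)))
  check1 <- function(p, what) {
    if (abs(sum(p) - 1) > 1e-9)
      stop2(what, " probabilities must sum to 1 (got ", sum(p), ")")
  }
  check1(spec$actions, "action")
  check1(spec$p_template, "template")
  for (a in names(spec$patients)) check1(spec$patients[[a]],
                                         paste("patient |", a))
  for (a in names(spec$locations)) check1(spec$locations[[a]],
                                          paste("location |", a))
  if (!all(names(spec$actions) %in% names(spec$patients)))
    stop2("every action needs a patient distribution")
  if (!all(spec$prime_nouns %in% names(spec$prime_pairs)))
    stop2("every prime noun needs a partner")
  structure(spec, class = "micro_world")
}

#' @export
print.micro_world <- function(x, ...) {
  cat(sprintf(paste0("<micro_world> %d agents, %d actions, %d prime nouns; ",
                     "templates: %s\n"),
              length(x$agents), length(x$actions), length(x$prime_nouns),
              paste(sprintf("%s %.2f", names(x$p_template), x$p_template),
                    collapse = ", ")))
  invisible(x)
}

sample1 <- function(p) sample(names(p), 1L, prob = p)

mw_transitive <- function(spec, located) {
  agent <- sample1(spec$agents)
  action <- sample1(spec$actions)
  patient <- sample1(spec$patients[[action]])
  args <- list(list(role = "A0", filler = agent),
               list(role = "V", filler = action),
               list(role = "A1", filler = patient))
  tokens <- c("the", agent, action, "the", patient)
  if (located) {
    loc <- sample1(spec$locations[[action]])
    tokens <- c(tokens, "in", "the", loc)
    args <- c(args, list(list(role = "AM-LOC", filler = loc)))
  }
  frame_sentence(c(tokens, "."),
                 list(list(index = 1L, predicate = action, args = args)),
                 roles = micro_roles())
}

mw_conjunction <- function(spec) {
  agent <- sample1(spec$p_agent_sees)
  n1 <- sample(spec$prime_nouns, 1L)
  partner <- spec$prime_pairs[[n1]]
  n2 <- if (stats::runif(1) < spec$related_prob) partner else
    sample(setdiff(spec$prime_nouns, c(n1, partner)), 1L)
  frame_sentence(
    c("the", agent, "sees", "the", n1, "and", "the", n2, "."),
    list(list(index = 1L, predicate = "sees",
              args = list(list(role = "A0", filler = agent),
                          list(role = "V", filler = "sees"),
                          list(role = "A1", filler = n1),
                          list(role = "A2", filler = n2)))),
    roles = micro_roles())
}

#' Sample a frame-annotated corpus from a micro-world
#'
#' Sentences are generated template by template with full frame annotation by
#' construction; given the same seed the corpus is identical across calls.
#' Empirical conditional frequencies converge to the probabilities in the
#' world specification.
#'
#' @param spec a [micro_world()].
#' @param n_sentences number of sentences (>= 1).
#' @param seed RNG seed.
#' @return List of [frame_sentence()] objects.
#' @export
sample_corpus <- function(spec, n_sentences, seed = 1L) {
  if (!inherits(spec, "micro_world")) stop2("`spec` must be a micro_world")
  if (n_sentences < 1L) stop2("`n_sentences` must be >= 1")
  with_seed(seed, {
    lapply(seq_len(n_sentences), function(i) {
      tmpl <- sample1(spec$p_template)
      switch(tmpl,
             transitive = mw_transitive(spec, located = FALSE),
             located = mw_transitive(spec, located = TRUE),
             conjunction = mw_conjunction(spec))
    })
  })
}

#' Evaluation stimuli for the micro-world effect contrasts
#'
#' Builds fixed stimulus sets for the four qualitative contrasts the
#' micro-world supports: semantic congruity (attested vs. never-attested
#' patient), cloze probability (most vs. least probable patient), sentence
#' position (per-position updates in 9-token located sentences) and
#' associative priming (partner vs. non-partner second conjunct). Each
#' stimulus is a token vector plus the index of the critical word.
#'
#' @param spec a [micro_world()].
#' @param agent agent used in all stimulus sentences (a high-frequency one by
#'   default so stimuli are well inside the training distribution).
#' @return Named list of contrasts; each contrast is a list of two conditions
#'   (`a` = condition expected to yield the larger Semantic Update), each a
#'   list of `list(tokens, target)` stimuli. The `position` contrast instead
#'   holds one stimulus set under `sentences`.
#' @export
contrast_stimuli <- function(spec, agent = NULL) {
  agent <- agent %||% names(spec$agents)[which.max(spec$agents)]
  acts <- names(spec$actions)
  mk <- function(action, patient)
    list(tokens = c("the", agent, action, "the", patient, "."), target = 5L)

  all_patients <- unique(unlist(lapply(spec$patients, names)))
  congr <- lapply(acts, function(a) {
    p <- spec$patients[[a]]
    list(congruent = mk(a, names(p)[which.max(p)]),
         incongruent = mk(a, setdiff(all_patients, names(p))[1L]))
  })
  cloze <- lapply(acts, function(a) {
    p <- spec$patients[[a]]
    list(high = mk(a, names(p)[which.max(p)]),
         low = mk(a, names(p)[which.min(p)]))
  })
  prime <- unlist(lapply(spec$prime_nouns, function(n1) {
    partner <- spec$prime_pairs[[n1]]
    base <- c("the", agent, "sees", "the", n1, "and", "the")
    lapply(setdiff(spec$prime_nouns, c(n1, partner)), function(unrel)
      list(related = list(tokens = c(base, partner, "."), target = 8L),
           unrelated = list(tokens = c(base, unrel, "."), target = 8L)))
  }), recursive = FALSE)
  position <- lapply(acts, function(a) {
    p <- spec$patients[[a]]
    loc <- spec$locations[[a]]
    list(tokens = c("the", agent, a, "the", names(p)[which.max(p)],
                    "in", "the", names(loc)[which.max(loc)], "."),
         target = NA_integer_)
  })
  list(
    congruity = list(a = lapply(congr, `[[`, "incongruent"),
                     b = lapply(congr, `[[`, "congruent")),
    cloze = list(a = lapply(cloze, `[[`, "low"),
                 b = lapply(cloze, `[[`, "high")),
    priming = list(a = lapply(prime, `[[`, "unrelated"),
                   b = lapply(prime, `[[`, "related")),
    position = list(sentences = position))
}

# mean SU at the critical word over a stimulus set
mean_target_su <- function(model, stimuli) {
  mean(vapply(stimuli, function(s) {
    su <- semantic_update(sg_forward(model, s$tokens))
    su[s$target]
  }, 0))
}

#' Semantic-update effect battery on the micro-world
#'
#' For each seed: samples a training corpus, trains an SG model at the given
#' configuration, and measures the Semantic Update differences for the four
#' contrasts of [contrast_stimuli()] — incongruent minus congruent, low minus
#' high cloze, unrelated minus related prime, and early minus late sentence
#' position (mean SU at positions 2-4 minus positions 7-9 of the located
#' template). Positive differences are the directions in which N400 amplitudes
#' are empirically larger.
#'
#' @param spec a [micro_world()].
#' @param seeds integer vector of seeds (one model per seed).
#' @param n_sentences training-corpus size per seed.
#' @param config an [sg_config()]; its seed is replaced per run.
#' @return Data frame with columns `seed`, `contrast`, `delta`.
#' @export
sg_effect_battery <- function(spec = micro_world(), seeds = 1:10,
                              n_sentences = 400L, config = sg_config()) {
  stim <- contrast_stimuli(spec)
  rows <- lapply(seeds, function(sd) {
    corpus <- sample_corpus(spec, n_sentences, seed = sd)
    cfg <- config
    cfg$seed <- as.integer(sd)
    model <- train_sg(corpus, cfg)
    deltas <- c(
      congruity = mean_target_su(model, stim$congruity$a) -
        mean_target_su(model, stim$congruity$b),
      cloze = mean_target_su(model, stim$cloze$a) -
        mean_target_su(model, stim$cloze$b),
      priming = mean_target_su(model, stim$priming$a) -
        mean_target_su(model, stim$priming$b),
      position = {
        su <- vapply(stim$position$sentences, function(s)
          semantic_update(sg_forward(model, s$tokens)), numeric(9L))
        mean(su[2:4, ]) - mean(su[7:9, ])
      })
    data.frame(seed = sd, contrast = names(deltas), delta = unname(deltas))
  })
  do.call(rbind, rows)
}

#' Sign test over per-seed effect directions
#'
#' Exact one-sided binomial test that an effect is positive in more than half
#' of independent training runs.
#'
#' @param deltas numeric vector of per-seed effect differences.
#' @return List with `n_positive`, `n` and `p_value`.
#' @export
sign_test <- function(deltas) {
  n <- length(deltas)
  k <- sum(deltas > 0)
  list(n_positive = k, n = n,
       p_value = stats::pbinom(k - 1L, n, 0.5, lower.tail = FALSE))
}
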