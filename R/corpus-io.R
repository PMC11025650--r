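#' PropBank-style role inventories
#'
#' `propbank_roles()` returns the default 26-label role inventory used for
#' frame-annotated corpora: the numbered arguments `A0`-`A5`, the predicate
#' label `V`, and 19 adjunct modifier labels (`AM-*`). `micro_roles()` returns
#' the 6-label subset used by the synthetic micro-world.
#'
#' @return Character vector of role labels.
#' @export
propbank_roles <- function() {
  c(paste0("A", 0:5), "V",
    paste0("AM-", c("ADV", "CAU", "DIR", "DIS", "EXT", "LOC", "MNR", "MOD",
                    "NEG", "PNC", "PRD", "PRP", "REC", "TMP", "GOL", "COM",
                    "ADJ", "LVB", "CXN")))
}

#' @rdname propbank_roles
#' @export
micro_roles <- function() c("A0", "V", "A1", "A2", "AM-LOC", "AM-MNR")

#' Construct a frame-annotated sentence
#'
#' The basic training unit: a token sequence plus one or more event frames,
#' each frame consisting of a predicate and a list of role-filler arguments.
#'
#' @param tokens character vector of word tokens (length >= 1).
#' @param frames list of frames; each frame is a list with elements `index`
#'   (positive integer, unique and contiguous from 1 across the sentence),
#'   `predicate` (single word) and `args` (list of `list(role =, filler =)`
#'   pairs; fillers are single word strings).
#' @param roles role inventory that every `role` label must belong to.
#' @return An object of class `frame_sentence`.
#' @export
frame_sentence <- function(tokens, frames, roles = propbank_roles()) {
  if (!is.character(tokens) || length(tokens) < 1L || anyNA(tokens))
    stop2("`tokens` must be a non-empty character vector")
  if (!is.list(frames)) stop2("`frames` must be a list of frames")
  idx <- vapply(frames, function(f) as.integer(f$index %||% NA_integer_), 1L)
  if (length(frames) > 0L && !identical(sort(idx), seq_along(frames)))
    stop2("frame indices must be unique and contiguous from 1")
  for (f in frames) {
    if (is.null(f$predicate) || length(f$predicate) != 1L)
      stop2("every frame needs a single-word `predicate`")
    for (a in f$args) {
      if (is.null(a$role) || !(a$role %in% roles))
        stop2("unknown role label: ", a$role %||% "<missing>")
      if (is.null(a$filler) || length(a$filler) != 1L || !nzchar(a$filler))
        stop2("every argument needs a single-word `filler`")
    }
  }
  structure(list(tokens = tokens, frames = frames), class = "frame_sentence")
}

#' @export
print.frame_sentence <- function(x, ...) {
  cat("<frame_sentence> ", paste(x$tokens, collapse = " "), "\n", sep = "")
  for (f in x$frames) {
    args <- vapply(f$args, function(a) paste0(a$role, "=", a$filler), "")
    cat(sprintf("  frame %d [%s]: %s\n", f$index, f$predicate,
                paste(args, collapse = ", ")))
  }
  invisible(x)
}

n_frames_of <- function(s) length(s$frames)
n_args_of <- function(s) sum(vapply(s$frames, function(f) length(f$args), 1L))

#' Read and write frame-annotated corpora (JSON Lines)
#'
#' One sentence per line, UTF-8, with schema
#' `{"tokens": [...], "frames": [{"index": 1, "predicate": "opened",
#' "args": [{"role": "A0", "filler": "boy"}, ...]}, ...]}`.
#' `write_frame_corpus()` followed by `read_frame_corpus()` is the identity on
#' well-formed corpora.
#'
#' @param path file path.
#' @param roles role inventory used to validate `role` labels.
#' @return `read_frame_corpus()` returns a list of [frame_sentence()] objects
#'   in file order; `write_frame_corpus()` returns `path` invisibly.
#' @export
read_frame_corpus <- function(path, roles = propbank_roles()) {
  if (!file.exists(path)) stop2("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                    error = function(e) NULL)
    if (is.null(rec) || is.null(rec$tokens))
      stop2("parse error at line ", i, ": malformed sentence record")
    frames <- lapply(rec$frames %||% list(), function(f) {
      list(index = f$index, predicate = f$predicate,
           args = lapply(f$args %||% list(), function(a)
             list(role = a$role, filler = a$filler)))
    })
    out[[i]] <- tryCatch(
      frame_sentence(unlist(rec$tokens, use.names = FALSE), frames, roles),
      error = function(e) stop2("parse error at line ", i, ": ",
                                conditionMessage(e)))
  }
  out
}

#' @param corpus list of [frame_sentence()] objects.
#' @rdname read_frame_corpus
#' @export
write_frame_corpus <- function(corpus, path) {
  lines <- vapply(corpus, function(s) {
    rec <- list(
      tokens = s$tokens,
      frames = lapply(s$frames, function(f)
        list(index = jsonlite::unbox(f$index),
             predicate = jsonlite::unbox(f$predicate),
             args = lapply(f$args, function(a)
               list(role = jsonlite::unbox(a$role),
                    filler = jsonlite::unbox(a$filler))))))
    as.character(jsonlite::toJSON(rec, auto_unbox = FALSE))
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Build a frequency-ranked lexicon
#'
#' Collects the `max_size` most frequent (lower-cased) word forms of a corpus,
#' breaking frequency ties lexicographically, and adds the sentence-start and
#' out-of-vocabulary symbols. Indices are contiguous from 0, with the specials
#' first.
#'
#' @param corpus list of [frame_sentence()] objects (or a list of character
#'   token vectors).
#' @param max_size maximum number of word forms retained (specials excluded).
#' @return An object of class `sg_lexicon` with fields `words` (character, in
#'   index order), `index` (named 0-based integer vector), `start_id`,
#'   `oov_id`.
#' @export
build_lexicon <- function(corpus, max_size = 6000L) {
  if (length(corpus) == 0L) stop2("`corpus` must be non-empty")
  if (max_size < 1L) stop2("`max_size` must be >= 1")
  toks <- tolower(unlist(lapply(corpus, function(s)
    if (is.character(s)) s else s$tokens), use.names = FALSE))
  cnt <- table(toks)
  ord <- order(-as.integer(cnt), names(cnt))
  kept <- names(cnt)[ord][seq_len(min(max_size, length(cnt)))]
  kept <- setdiff(kept, c("<s>", "<oov>"))
  words <- c("<s>", "<oov>", kept)
  idx <- seq_along(words) - 1L
  names(idx) <- words
  structure(list(words = words, index = idx, start_id = 0L, oov_id = 1L),
            class = "sg_lexicon")
}

#' @export
print.sg_lexicon <- function(x, ...) {
  cat(sprintf("<sg_lexicon> %d word forms (+2 specials)\n",
              length(x$words) - 2L))
  invisible(x)
}

lexicon_size <- function(lex) length(lex$words)

# map tokens to 0-based lexicon ids (lower-cased; unknown -> OOV)
lexicon_lookup <- function(lex, tokens) {
  id <- unname(lex$index[tolower(tokens)])
  id[is.na(id)] <- lex$oov_id
  as.integer(id)
}

#' Read and write word embeddings in word2vec text format
#'
#' The file starts with a header line `"V F"` (vocabulary size, dimension)
#' followed by one line per word: the word and `F` whitespace-separated floats.
#'
#' @param path file path.
#' @return `read_embeddings()` returns a numeric matrix with one row per word
#'   (rownames are the words).
#' @export
read_embeddings <- function(path) {
  if (!file.exists(path)) stop2("no such file: ", path)
  header <- scan(path, what = integer(), n = 2L, quiet = TRUE)
  tab <- utils::read.table(path, skip = 1L, row.names = 1L,
                           colClasses = c("character", rep("numeric", header[2])))
  m <- as.matrix(tab)
  colnames(m) <- NULL
  if (ncol(m) != header[2]) stop2("embedding file dimension mismatch")
  m
}

#' @param embeddings numeric matrix with rownames.
#' @rdname read_embeddings
#' @export
write_embeddings <- function(embeddings, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(embeddings), ncol(embeddings)), con)
  body <- vapply(seq_len(nrow(embeddings)), function(i)
    paste(c(rownames(embeddings)[i],
            formatC(embeddings[i, ], format = "g", digits = 8)),
          collapse = " "), "")
  writeLines(body, con)
  invisible(path)
}

#' Binarize real-valued embeddings into semantic feature vectors
#'
#' Each entry becomes 1 if the raw value is strictly greater than `threshold`
#' and 0 otherwise, turning dense embeddings into presence/absence feature
#' codes suitable for the cross-entropy training objective of the query
#' network.
#'
#' @param embeddings numeric matrix (words in rows, rownames set) or a list of
#'   equal-length numeric vectors.
#' @param threshold binarization threshold; default 0.
#' @return Binary (0/1) matrix with the same rownames.
#' @export
binarize_embeddings <- function(embeddings, threshold = 0) {
  if (is.list(embeddings)) {
    len <- vapply(embeddings, length, 1L)
    if (length(unique(len)) > 1L) stop2("ragged embedding vectors")
    embeddings <- do.call(rbind, embeddings)
  }
  if (!is.matrix(embeddings) || !is.numeric(embeddings))
    stop2("`embeddings` must be a numeric matrix")
  (embeddings > threshold) * 1
}

#' Generate synthetic binary semantic features
#'
#' Stand-in for binarized pre-trained embeddings when none are supplied: each
#' word gets an independent random binary feature vector (each feature is 1
#' with probability `p`). Labelled synthetic; carries no distributional
#' semantics.
#'
#' @param words character vector of words.
#' @param dim number of features per word.
#' @param p probability that a feature is on.
#' @param seed RNG seed.
#' @return Binary matrix with one row per word.
#' @export
synthetic_features <- function(words, dim = 32L, p = 0.5, seed = 1L) {
  with_seed(seed, {
    m <- matrix(as.numeric(stats::runif(length(words) * dim) < p),
                nrow = length(words), dimnames = list(words, NULL))
    m
  })
}

# layout of the role-filler / probe vector space
probe_layout <- function(feature_size, roles, n_frames) {
  list(F = as.integer(feature_size), R = length(roles), K = as.integer(n_frames),
       roles = roles,
       width = as.integer(feature_size) + length(roles) + as.integer(n_frames))
}

# feature vector for one filler word under either filler mode
filler_features <- function(filler, features, layout, lexicon = NULL,
                            filler_mode = c("semantic", "lexical")) {
  filler_mode <- match.arg(filler_mode)
  if (filler_mode == "lexical") {
    id <- lexicon_lookup(lexicon, filler)
    return(one_hot(id + 1L, layout$F))
  }
  key <- tolower(filler)
  if (key %in% rownames(features)) return(as.numeric(features[key, ]))
  warning("OOV filler '", filler, "': using all-zero feature vector",
          call. = FALSE)
  numeric(layout$F)
}

#' Encode the role-filler probes and targets of a sentence
#'
#' For every argument of every frame, emits exactly two (probe, target) pairs:
#' a role-probe (role identifier zeroed; the model must fill in the role) and a
#' filler-probe (filler features zeroed; the model must fill in the filler).
#' Both share the complete role-filler vector as target. Only arguments that
#' are actually present in the sentence are probed. Probes are ordered
#' frame-major, with the role-probe before the filler-probe of each argument.
#'
#' The vector layout is `[filler features (F) | role one-hot (R) | frame
#' one-hot (K)]`; the frame part is kept intact in both probe kinds.
#'
#' @param sentence a [frame_sentence()].
#' @param features binary feature matrix (rownames = words); required for
#'   `filler_mode = "semantic"`. Out-of-vocabulary fillers map to the all-zero
#'   feature vector with a warning.
#' @param roles role inventory defining the role one-hot block.
#' @param n_frames maximum frame index `K`; a frame index exceeding it is an
#'   error.
#' @param filler_mode `"semantic"` (binary feature fillers) or `"lexical"`
#'   (one-hot over `lexicon`).
#' @param lexicon an `sg_lexicon`, required for `filler_mode = "lexical"`.
#' @return List of `list(probe, target, kind, role, filler, frame)`; `probe`
#'   and `target` are numeric vectors of length `F + R + K`.
#' @export
encode_probes <- function(sentence, features = NULL, roles = micro_roles(),
                          n_frames = 8L,
                          filler_mode = c("semantic", "lexical"),
                          lexicon = NULL) {
  filler_mode <- match.arg(filler_mode)
  Fsz <- if (filler_mode == "lexical") {
    if (is.null(lexicon)) stop2("`lexicon` required for lexical filler mode")
    lexicon_size(lexicon)
  } else {
    if (is.null(features)) stop2("`features` required for semantic filler mode")
    ncol(features)
  }
  lay <- probe_layout(Fsz, roles, n_frames)
  out <- list()
  for (f in sentence$frames) {
    if (f$index > lay$K)
      stop2("frame index ", f$index, " exceeds configured maximum K = ", lay$K)
    for (a in f$args) {
      feat <- filler_features(a$filler, features, lay, lexicon, filler_mode)
      target <- c(feat,
                  one_hot(match(a$role, lay$roles), lay$R),
                  one_hot(f$index, lay$K))
      role_probe <- target
      role_probe[lay$F + seq_len(lay$R)] <- 0
      filler_probe <- target
      filler_probe[seq_len(lay$F)] <- 0
      out[[length(out) + 1L]] <- list(probe = role_probe, target = target,
                                      kind = "role-probe", role = a$role,
                                      filler = a$filler, frame = f$index)
      out[[length(out) + 1L]] <- list(probe = filler_probe, target = target,
                                      kind = "filler-probe", role = a$role,
                                      filler = a$filler, frame = f$index)
    }
  }
  out
}

# stacked probe/target matrices for one sentence (rows = probes)
probe_matrices <- function(sentence, features, roles, n_frames, filler_mode,
                           lexicon = NULL) {
  pr <- encode_probes(sentence, features, roles, n_frames, filler_mode, lexicon)
  list(P = do.call(rbind, lapply(pr, `[[`, "probe")),
       Y = do.call(rbind, lapply(pr, `[[`, "target")))
}

#' Apply the training-corpus filters
#'
#' Keeps exactly the sentences with between `min_tokens` and `max_tokens`
#' tokens (inclusive) and at most `max_frames` frames, preserving order. The
#' defaults limit the number of complex subordinate events and make
#' mini-batch training practical.
#'
#' @param corpus list of [frame_sentence()] objects.
#' @param min_tokens,max_tokens inclusive token-count bounds (default 6 and 15).
#' @param max_frames maximum number of frames (default 8).
#' @return Filtered list (a subsequence of the input).
#' @export
filter_training_sentences <- function(corpus, min_tokens = 6L,
                                      max_tokens = 15L, max_frames = 8L) {
  keep <- vapply(corpus, function(s) {
    nt <- length(s$tokens)
    nt >= min_tokens && nt <= max_tokens && n_frames_of(s) <= max_frames
  }, TRUE)
  corpus[keep]
}
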