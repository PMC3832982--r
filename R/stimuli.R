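#' @useDynLib npstroop, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif setNames aov anova ave pt sd t.test var cor
#' @importFrom utils read.csv write.csv
NULL

# Stimulus vocabulary. Word identity among the four neutral words is not
# represented in the network: all four map onto one non-color input unit and
# one "neutral" output unit, which is what the stated unit counts require.
np_colors <- c("red", "green", "blue", "yellow")
np_color_words <- c("RED", "GREEN", "BLUE", "YELLOW")
np_neutral_words <- c("LOT", "KNIFE", "SHIP", "FLOWER")
np_words <- c(np_color_words, np_neutral_words)
np_responses <- c("red", "green", "blue", "yellow", "neutral")
np_tasks <- c("color-naming", "word-reading")

#' Classify the Stroop condition of a test stimulus
#'
#' A test stimulus is a word written in an ink color, responded to under color
#' naming. It is congruent when the word is the color word naming its own ink,
#' neutral when the word is one of the four non-color words, and incongruent
#' when the word is a color word naming a different color.
#'
#' @param word Character vector of words (`RED`, `GREEN`, `BLUE`, `YELLOW`,
#'   `LOT`, `KNIFE`, `SHIP`, `FLOWER`).
#' @param ink Character vector of ink colors (`red`, `green`, `blue`,
#'   `yellow`), recycled against `word`.
#' @return Character vector with values `"congruent"`, `"neutral"` or
#'   `"incongruent"`.
#' @examples
#' stroop_condition(c("RED", "LOT", "BLUE"), "red")
#' @export
stroop_condition <- function(word, ink) {
  n <- max(length(word), length(ink))
  word <- rep_len(word, n)
  ink <- rep_len(ink, n)
  if (any(is.na(word) | is.na(ink) | word == "NONE" | ink == "NONE"))
    stop("test stimuli must have both a word and an ink color")
  if (!all(word %in% np_words))
    stop("unknown word: ", paste(setdiff(word, np_words), collapse = ", "))
  if (!all(ink %in% np_colors))
    stop("unknown ink color: ", paste(setdiff(ink, np_colors), collapse = ", "))
  ifelse(word %in% np_neutral_words, "neutral",
         ifelse(tolower(word) == ink, "congruent", "incongruent"))
}

#' Encode a stimulus as an input activation vector
#'
#' The input layer has 12 units: four ink-color units, one color-side
#' non-color unit, four color-word units, one word-side non-color unit (lit by
#' any of the four neutral words), and two task-demand units. The demand unit
#' of the instructed task is set to 1 and the other to 0.
#'
#' @param word Word of the stimulus, or `"NONE"` for a color-only training
#'   item.
#' @param ink Ink color, or `"NONE"` for a word-only training item.
#' @param task `"color-naming"` or `"word-reading"`.
#' @return Named numeric vector of length 12.
#' @examples
#' encode_stimulus("BLUE", "green", "color-naming")
#' @export
encode_stimulus <- function(word, ink, task = "color-naming") {
  task <- match.arg(task, np_tasks)
  x <- setNames(numeric(12), c(np_colors, "noncolor.color",
                               np_color_words, "noncolor.word",
                               "demand.color", "demand.word"))
  if (word == "NONE" && ink == "NONE")
    stop("at least one of word/ink must be set")
  if (ink != "NONE") {
    if (!ink %in% np_colors) stop("unknown ink color: ", ink)
    x[ink] <- 1
  }
  if (word != "NONE") {
    if (word %in% np_color_words) x[word] <- 1
    else if (word %in% np_neutral_words) x["noncolor.word"] <- 1
    else stop("unknown word: ", word)
  }
  x[if (task == "color-naming") "demand.color" else "demand.word"] <- 1
  x
}

# 0-based content-unit indices used by the C++ core
content_index <- function(word, ink) {
  ink_idx <- match(ink, np_colors) - 1L
  word_idx <- ifelse(word %in% np_color_words,
                     4L + match(word, np_color_words),
                     9L)
  cbind(ink = ink_idx, word = word_idx)
}

#' Label an ordered prime-probe pair
#'
#' Negative-priming (NP) pairs have an incongruent prime whose ignored word
#' names the probe's ink color; the suffix I/N/C is the probe's Stroop
#' condition. The matching controls (`contra-NP-*`) have an incongruent prime
#' and a probe of the same Stroop condition sharing no feature with the prime:
#' the prime word does not name the probe ink, the inks differ, the words
#' differ, and the probe word does not name the prime ink. Positive-priming
#' (`PP`) pairs repeat the target ink color from prime to probe (NP takes
#' precedence; the two cannot in fact coincide because an incongruent prime's
#' word never names its own ink). Everything else is `other`.
#'
#' @param prime_word,prime_ink Prime stimulus (vectors recycled to a common
#'   length).
#' @param probe_word,probe_ink Probe stimulus.
#' @return Character vector of labels: `NP-I`, `NP-N`, `NP-C`, `contra-NP-I`,
#'   `contra-NP-N`, `contra-NP-C`, `PP` or `other`.
#' @examples
#' pair_label("RED", "blue", "GREEN", "red")    # NP-I
#' pair_label("RED", "blue", "YELLOW", "green") # contra-NP-I
#' @export
pair_label <- function(prime_word, prime_ink, probe_word, probe_ink) {
  n <- max(length(prime_word), length(prime_ink),
           length(probe_word), length(probe_ink))
  prime_word <- rep_len(prime_word, n); prime_ink <- rep_len(prime_ink, n)
  probe_word <- rep_len(probe_word, n); probe_ink <- rep_len(probe_ink, n)
  prime_cond <- stroop_condition(prime_word, prime_ink)
  probe_cond <- stroop_condition(probe_word, probe_ink)
  suffix <- c(congruent = "C", neutral = "N", incongruent = "I")[probe_cond]
  np <- prime_cond == "incongruent" & tolower(prime_word) == probe_ink
  pp <- !np & prime_ink == probe_ink
  contra <- !np & !pp &
    prime_cond == "incongruent" &
    tolower(prime_word) != probe_ink &
    prime_ink != probe_ink &
    prime_word != probe_word &
    tolower(probe_word) != prime_ink
  out <- rep("other", n)
  out[np] <- paste0("NP-", suffix[np])
  out[contra] <- paste0("contra-NP-", suffix[contra])
  out[pp] <- "PP"
  out
}

#' Generate a single-dimension training stream
#'
#' Training items carry exactly one content dimension (a word with no ink, or
#' an ink with no word) together with the matching task demand. Word-reading
#' items outnumber color-naming items by `word_color_ratio` (default 4:1,
#' emulating the reading pre-experience of literate participants), and the
#' four neutral words are supplied at four-fold multiplicity within the
#' word-reading stream, so that half of it is neutral-word reading.
#'
#' Uses the current R random number generator; call `set.seed()` first for a
#' reproducible stream.
#'
#' @param n Number of training items.
#' @param word_color_ratio Ratio of word-reading to color-naming items; 0
#'   yields a pure color-naming stream.
#' @return Data frame with columns `word`, `ink`, `task`.
#' @export
training_stream <- function(n, word_color_ratio = 4) {
  if (length(n) != 1 || is.na(n) || n <= 0) stop("n must be positive")
  if (word_color_ratio < 0) stop("word_color_ratio must be >= 0")
  p_word <- word_color_ratio / (word_color_ratio + 1)
  is_word <- runif(n) < p_word
  word <- rep("NONE", n)
  ink <- rep("NONE", n)
  # word stream: RED:GREEN:BLUE:YELLOW:neutral = 1:1:1:1:4
  nw <- sum(is_word)
  if (nw > 0) {
    pick <- sample.int(8, nw, replace = TRUE)
    word[is_word] <- ifelse(pick <= 4, np_color_words[pick],
                            np_neutral_words[sample.int(4, nw, replace = TRUE)])
  }
  if (nw < n) ink[!is_word] <- sample(np_colors, n - nw, replace = TRUE)
  data.frame(word = word, ink = ink,
             task = ifelse(is_word, "word-reading", "color-naming"),
             stringsAsFactors = FALSE)
}

# uniform draw of one test stimulus per condition label
draw_stimulus <- function(condition) {
  ink <- sample(np_colors, 1)
  word <- switch(condition,
    congruent = np_color_words[match(ink, np_colors)],
    neutral = sample(np_neutral_words, 1),
    incongruent = sample(np_color_words[np_colors != ink], 1))
  c(word = word, ink = ink)
}

#' Generate a randomized Stroop test sequence
#'
#' One third of trials each are congruent, neutral and incongruent (exact up
#' to rounding), in randomized order, all under color naming. Prime-probe
#' pairs (NP, controls, PP) arise by chance and are labeled post hoc.
#'
#' @param n Number of trials.
#' @return Data frame with columns `word`, `ink`, `condition`.
#' @export
test_sequence <- function(n) {
  if (length(n) != 1 || is.na(n) || n <= 0) stop("n must be positive")
  base <- n %/% 3
  counts <- base + (seq_len(3) <= n %% 3)
  cond <- sample(rep(c("congruent", "neutral", "incongruent"), counts))
  st <- t(vapply(cond, draw_stimulus, c(word = "", ink = "")))
  data.frame(word = unname(st[, "word"]), ink = unname(st[, "ink"]),
             condition = cond, row.names = NULL, stringsAsFactors = FALSE)
}

# construct a probe realizing `label` after an incongruent prime
construct_probe <- function(prime_word, prime_ink, label) {
  np <- !startsWith(label, "contra")
  suffix <- substring(label, nchar(label))
  ink <- if (np) tolower(prime_word) else
    sample(setdiff(np_colors, c(tolower(prime_word), prime_ink)), 1)
  word <- switch(suffix,
    C = np_color_words[match(ink, np_colors)],
    N = sample(np_neutral_words, 1),
    I = {
      cand <- np_color_words[np_colors != ink]
      if (!np) cand <- setdiff(cand, c(prime_word, np_color_words[match(prime_ink, np_colors)]))
      sample(cand, 1)
    })
  c(word = word, ink = ink)
}

#' Generate a designed prime-probe test sequence
#'
#' Interleaves constructed prime-probe pairs so that NP subtypes and their
#' controls occur at high frequency; a free-running random sequence yields
#' only a few NP pairs per thousand trials, which is too few for powered
#' contrasts at reduced simulation scale. Primes are random incongruent
#' stimuli; probes are constructed to realize the requested labels, which are
#' re-derived post hoc by [pair_label()] exactly as in the free-running mode.
#'
#' @param n_pairs Number of prime-probe pairs (sequence length `2 * n_pairs`).
#' @param labels Pair labels to cycle through.
#' @return Data frame with columns `word`, `ink`, `condition`.
#' @export
designed_pair_sequence <- function(n_pairs,
                                   labels = c("NP-I", "NP-N", "NP-C",
                                              "contra-NP-I", "contra-NP-N",
                                              "contra-NP-C")) {
  if (n_pairs <= 0) stop("n_pairs must be positive")
  lab <- rep_len(labels, n_pairs)
  word <- ink <- character(2 * n_pairs)
  for (p in seq_len(n_pairs)) {
    prime <- draw_stimulus("incongruent")
    probe <- construct_probe(prime[["word"]], prime[["ink"]], lab[p])
    word[2 * p - 1] <- prime[["word"]]; ink[2 * p - 1] <- prime[["ink"]]
    word[2 * p] <- probe[["word"]]; ink[2 * p] <- probe[["ink"]]
  }
  data.frame(word = word, ink = ink,
             condition = stroop_condition(word, ink),
             stringsAsFactors = FALSE)
}
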