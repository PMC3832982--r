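all_words <- c("RED", "GREEN", "BLUE", "YELLOW",
               "LOT", "KNIFE", "SHIP", "FLOWER")
all_inks <- c("red", "green", "blue", "yellow")

test_that("stroop_condition partitions all 32 word-ink combinations", {
  grid <- expand.grid(word = all_words, ink = all_inks,
                      stringsAsFactors = FALSE)
  cond <- stroop_condition(grid$word, grid$ink)
  expect_true(all(cond %in% c("congruent", "neutral", "incongruent")))
  expect_equal(sum(cond == "congruent"), 4)    # each color word on its ink
  expect_equal(sum(cond == "neutral"), 16)     # 4 neutral words x 4 inks
  expect_equal(sum(cond == "incongruent"), 12) # 4 color words x 3 other inks
  expect_equal(stroop_condition("RED", "red"), "congruent")
  expect_equal(stroop_condition("LOT", "red"), "neutral")
  expect_equal(stroop_condition("BLUE", "red"), "incongruent")
  expect_error(stroop_condition("NONE", "red"), "both a word and an ink")
})

test_that("encode_stimulus produces the documented one-hot layout", {
  x <- encode_stimulus("BLUE", "green", "color-naming")
  expect_length(x, 12)
  expect_equal(sum(x), 3)
  expect_equal(x[["green"]], 1)
  expect_equal(x[["BLUE"]], 1)
  expect_equal(x[["demand.color"]], 1)
  expect_equal(x[["demand.word"]], 0)

  x <- encode_stimulus("NONE", "red", "color-naming")
  expect_equal(which(x == 1), c(red = 1, demand.color = 11))

  # any neutral word lights the word-pathway non-color unit
  for (w in c("SHIP", "LOT", "KNIFE", "FLOWER")) {
    x <- encode_stimulus(w, "yellow", "color-naming")
    expect_equal(x[["noncolor.word"]], 1)
    expect_equal(x[["yellow"]], 1)
  }
  expect_error(encode_stimulus("NONE", "NONE"), "at least one")
})

test_that("pair_label reproduces the canonical examples", {
  expect_equal(pair_label("RED", "blue", "GREEN", "red"), "NP-I")
  expect_equal(pair_label("RED", "blue", "YELLOW", "green"), "contra-NP-I")
  expect_equal(pair_label("RED", "blue", "LOT", "green"), "contra-NP-N")
  expect_equal(pair_label("RED", "blue", "GREEN", "green"), "contra-NP-C")
  expect_equal(pair_label("RED", "blue", "KNIFE", "blue"), "PP")
})

test_that("pair_label agrees with the brute-force rule table on all pairs", {
  grid <- expand.grid(pw = all_words, pi = all_inks,
                      qw = all_words, qi = all_inks,
                      stringsAsFactors = FALSE)
  got <- pair_label(grid$pw, grid$pi, grid$qw, grid$qi)
  want <- mapply(bruteforce_pair_label, grid$pw, grid$pi, grid$qw, grid$qi)
  expect_equal(got, unname(want))
  # NP requires an incongruent prime; NP and contra are disjoint by having
  # incompatible word-ink relations
  np <- startsWith(got, "NP")
  expect_true(all(stroop_condition(grid$pw[np], grid$pi[np]) == "incongruent"))
  expect_true(all(tolower(grid$pw[np]) == grid$qi[np]))
  contra <- startsWith(got, "contra")
  expect_true(all(tolower(grid$pw[contra]) != grid$qi[contra]))
})

test_that("NP pairs occur at the combinatorial rate in random sequences", {
  # per the rule table, P(NP-*) for an iid uniform pair: P(prime incongruent)
  # = 1/3 times P(prime word names probe ink) = 1/4
  set.seed(7)
  s <- test_sequence(30000)
  lab <- pair_label(s$word[-nrow(s)], s$ink[-nrow(s)],
                    s$word[-1], s$ink[-1])
  p_np <- mean(startsWith(lab, "NP"))
  expect_lt(abs(p_np - 1 / 12), 4 * sqrt((1 / 12) * (11 / 12) / 30000))
})

test_that("training streams respect ratio, multiplicity and determinism", {
  set.seed(3)
  s <- training_stream(40000)
  is_word <- s$ink == "NONE"
  expect_true(all(xor(s$word == "NONE", s$ink == "NONE")))
  expect_true(all(s$task[is_word] == "word-reading"))
  expect_lt(abs(mean(is_word) - 0.8), 0.01)
  # half of the word stream is neutral-word reading (4-fold multiplicity)
  p_neutral <- mean(s$word[is_word] %in% c("LOT", "KNIFE", "SHIP", "FLOWER"))
  expect_lt(abs(p_neutral - 0.5), 0.02)

  set.seed(9); a <- training_stream(5)
  set.seed(9); b <- training_stream(5)
  expect_identical(a, b)

  set.seed(1)
  s0 <- training_stream(100, word_color_ratio = 0)
  expect_true(all(s0$task == "color-naming"))
  expect_error(training_stream(0), "positive")
})

test_that("test sequences hit exact thirds and randomize order", {
  set.seed(2)
  s <- test_sequence(999)
  expect_equal(unname(table(s$condition)[c("congruent", "incongruent",
                                           "neutral")]),
               c(333L, 333L, 333L), ignore_attr = TRUE)
  set.seed(4); a <- test_sequence(1000)
  set.seed(8); b <- test_sequence(1000)
  expect_false(identical(a$word, b$word))
  expect_equal(sort(table(a$condition)), sort(table(b$condition)),
               tolerance = 1, ignore_attr = TRUE)
  expect_error(test_sequence(-5), "positive")
})

test_that("designed pair sequences realize the requested labels", {
  set.seed(6)
  s <- designed_pair_sequence(600)
  lab <- pair_label(s$word[-nrow(s)], s$ink[-nrow(s)], s$word[-1], s$ink[-1])
  designed <- lab[seq(1, length(lab), by = 2)]  # pair positions (2k-1, 2k)
  expect_equal(unname(table(designed)),
               rep(100L, 6), ignore_attr = TRUE)
  expect_setequal(unique(designed),
                  c("NP-I", "NP-N", "NP-C",
                    "contra-NP-I", "contra-NP-N", "contra-NP-C"))
})
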