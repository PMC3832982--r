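make_trials <- function(rt, condition, correct = TRUE,
                        pair_label = "other") {
  n <- length(rt)
  data.frame(epoch = 1L, trial_index = seq_len(n), word = "RED", ink = "red",
             condition = rep_len(condition, n),
             pair_label = rep_len(pair_label, n), response = "red",
             correct = rep_len(correct, n), rt = rt,
             stringsAsFactors = FALSE)
}

test_that("filter_trials drops incorrect trials then 3-SD outliers", {
  tr <- make_trials(c(rnorm(200, 100, 5), 250, 90), "neutral",
                    correct = c(rep(TRUE, 201), FALSE))
  out <- filter_trials(tr)
  expect_equal(attr(out, "n_removed")[["incorrect"]], 1)
  expect_false(250 %in% out$rt)

  set.seed(51)
  tr <- make_trials(rnorm(10000, 100, 10), "congruent")
  out <- filter_trials(tr)
  frac <- 1 - nrow(out) / nrow(tr)
  expect_gt(frac, 0.0005)  # normal tail mass beyond 3 SD ~ 0.27%
  expect_lt(frac, 0.006)

  tr <- make_trials(rep(100, 10), "neutral", correct = rep(c(TRUE, FALSE),
                                                           c(8, 2)))
  expect_equal(nrow(tr) - attr(filter_trials(tr), "n_removed")[["incorrect"]],
               8)
})

test_that("outlier filtering is per condition", {
  set.seed(52)
  tr <- rbind(make_trials(rnorm(500, 20, 2), "congruent"),
              make_trials(rnorm(500, 100, 10), "incongruent"))
  out <- filter_trials(tr)
  # a 20-iteration congruent trial is typical, not an outlier of the pooled
  # distribution's left tail
  expect_gt(sum(out$condition == "congruent"), 490)
})

test_that("ANOVA, t and Levene agree with brute-force oracles to 1e-10", {
  set.seed(53)
  for (rep in 1:5) {
    g <- rep(c("a", "b", "c"), times = sample(5:30, 3))
    v <- rnorm(length(g), mean = match(g, c("a", "b", "c")))
    a <- anova_oneway(v, g)
    o <- bruteforce_anova(v, g)
    expect_equal(a$statistic, o$F, tolerance = 1e-10)
    expect_equal(a$p, o$p, tolerance = 1e-10)
    expect_equal(a$df, c(o$df1, o$df2))

    x <- v[g == "a"]; y <- v[g == "b"]
    tt <- t_independent(x, y)
    ot <- bruteforce_t(x, y)
    expect_equal(tt$statistic, ot$t, tolerance = 1e-10)
    expect_equal(tt$p, ot$p, tolerance = 1e-10)

    # Levene = ANOVA on absolute deviations from group means
    dev <- abs(v - ave(v, g))
    expect_equal(levene_test(v, g)$statistic, bruteforce_anova(dev, g)$F,
                 tolerance = 1e-10)
  }
})

test_that("Levene matches the car implementation", {
  skip_if_not_installed("car")
  set.seed(54)
  g <- factor(rep(c("a", "b", "c"), each = 40))
  v <- rnorm(120, sd = as.integer(g))
  ours <- levene_test(v, g)
  ref <- car::leveneTest(v, g, center = mean)
  expect_equal(ours$statistic, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(ours$p, ref$`Pr(>F)`[1], tolerance = 1e-10)
})

test_that("a fixed worked dataset yields the hand-computed F", {
  v <- c(6, 8, 4, 5, 3, 4,
         8, 12, 9, 11, 6, 8,
         13, 9, 11, 8, 7, 12)
  g <- rep(c("low", "mid", "high"), each = 6)
  o <- bruteforce_anova(v, g)
  a <- anova_oneway(v, g)
  expect_equal(a$statistic, o$F, tolerance = 1e-10)
  expect_equal(a$groups$n, rep(6L, 3))
})

test_that("identical groups give t = 0, p = 1", {
  x <- c(3, 5, 7, 9)
  tt <- t_independent(x, x)
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p, 1)
})

test_that("the ANOVA type-I error rate sits near alpha under the null", {
  set.seed(55)
  p <- replicate(600, {
    v <- rnorm(45)
    g <- rep(c("a", "b", "c"), each = 15)
    bruteforce_anova(v, g)$p
  })
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.025)
})

test_that("post-hoc p-values are monotone in the mean difference", {
  set.seed(56)
  base <- rnorm(60)
  shift_p <- function(method, d) {
    v <- c(base, base + d, base + 2 * d)
    g <- rep(c("a", "b", "c"), each = 60)
    tab <- method(v, g)
    tab$p[tab$contrast %in% c("b-a", "a-b")]
  }
  for (m in list(tukey_hsd, tamhane_t2)) {
    ps <- vapply(c(0.1, 0.4, 0.8), function(d) shift_p(m, d), numeric(1))
    expect_true(all(diff(ps) < 0))
  }
})

test_that("the variance gate dispatches between Tukey and Tamhane", {
  set.seed(57)
  g <- rep(c("a", "b", "c"), each = 50)
  equal <- rnorm(150)
  unequal <- rnorm(150, sd = rep(c(1, 1, 6), each = 50))
  expect_equal(attr(posthoc_pairwise(equal, g), "method"), "tukey_hsd")
  expect_equal(attr(posthoc_pairwise(unequal, g), "method"), "tamhane_t2")
})

test_that("summarize_np detects an injected NP-I slowdown and nothing else", {
  set.seed(58)
  labs <- c("NP-I", "NP-N", "NP-C", "contra-NP-I", "contra-NP-N",
            "contra-NP-C")
  n <- 500
  tr <- do.call(rbind, lapply(labs, function(l) {
    rt <- rnorm(n, 100, 15) + if (l == "NP-I") 10 else 0
    t2 <- make_trials(rt, "incongruent", pair_label = l)
    t2$condition <- c(`I` = "incongruent", `N` = "neutral",
                      `C` = "congruent")[[substring(l, nchar(l))]]
    t2
  }))
  np <- summarize_np(tr)
  expect_lt(np$subtype$I$p, 1e-6)
  expect_gt(np$subtype$I$groups$mean[1], np$subtype$I$groups$mean[2])
  expect_gt(np$subtype$N$p, 0.05)
  expect_gt(np$subtype$C$p, 0.05)

  # label shuffling destroys the contrast
  tr$pair_label <- sample(tr$pair_label)
  np2 <- summarize_np(tr)
  expect_gt(np2$subtype$I$p, 0.001)
})

test_that("missing label classes are reported, not fatal", {
  tr <- make_trials(rnorm(50, 100, 10), "congruent", pair_label = "NP-C")
  expect_warning(np <- summarize_np(tr), "empty cell")
  expect_null(np$subtype$C)
})

test_that("summarize_stroop computes the three derived effects", {
  set.seed(59)
  tr <- rbind(make_trials(rnorm(300, 90, 8), "congruent"),
              make_trials(rnorm(300, 100, 8), "neutral"),
              make_trials(rnorm(300, 115, 8), "incongruent"))
  s <- summarize_stroop(tr)
  expect_lt(s$anova$p, 1e-10)
  expect_equal(unname(s$effects["stroop_effect"]),
               unname(s$effects["interference"] + s$effects["facilitation"]))
  expect_gt(s$effects[["interference"]], 0)
  expect_gt(s$effects[["facilitation"]], 0)
})
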