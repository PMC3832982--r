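# Shared simulation runs, computed lazily once per test session. Sizes are
# reduced relative to the full 100 x 1000 protocol to keep the suite fast;
# contrasts that need power use the designed-pairs mode.

.run_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .run_cache)) {
    assign(name, force(expr), envir = .run_cache)
  }
  get(name, envir = .run_cache)
}

small_trained_network <- function() {
  cached("net_small", {
    set.seed(101)
    net <- init_network(network_params())
    train_network(net, training_stream(100000))
  })
}

variant_run <- function(model, n_epochs = 6, trials = 1000, seed = 1,
                        designed = FALSE, ...) {
  key <- paste("run", model, n_epochs, trials, seed, designed, sep = "_")
  cached(key, {
    cfg <- experiment_config(model = model, n_epochs = n_epochs,
                             trials_per_epoch = trials, seed = seed,
                             designed_pairs = designed, ...)
    run_experiment(cfg)
  })
}

# independent brute-force one-way ANOVA used as an oracle for the stats tests
bruteforce_anova <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  n <- length(values)
  gm <- mean(values)
  ssb <- 0
  ssw <- 0
  for (g in levels(groups)) {
    v <- values[groups == g]
    ssb <- ssb + length(v) * (mean(v) - gm)^2
    ssw <- ssw + sum((v - mean(v))^2)
  }
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(F = f, df1 = k - 1, df2 = n - k,
       p = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}

# independent brute-force pooled t-test
bruteforce_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = tt, df = nx + ny - 2, p = 2 * stats::pt(-abs(tt), nx + ny - 2))
}

# brute-force rule table for prime-probe labels, written directly from the
# pair taxonomy (independent of the vectorized implementation)
bruteforce_pair_label <- function(pw, pi, qw, qi) {
  cwords <- c("RED", "GREEN", "BLUE", "YELLOW")
  cond <- function(w, i) {
    if (!w %in% cwords) "neutral"
    else if (tolower(w) == i) "congruent" else "incongruent"
  }
  suf <- c(congruent = "C", neutral = "N", incongruent = "I")[[cond(qw, qi)]]
  if (cond(pw, pi) == "incongruent" && tolower(pw) == qi)
    return(paste0("NP-", suf))
  if (pi == qi) return("PP")
  if (cond(pw, pi) == "incongruent" &&
      tolower(pw) != qi && pi != qi && pw != qw &&
      !(qw %in% cwords && tolower(qw) == pi))
    return(paste0("contra-NP-", suf))
  "other"
}
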