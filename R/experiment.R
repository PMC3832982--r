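#' Experiment configuration
#'
#' Bundles every parameter of the simulation protocol. The defaults are the
#' full protocol: per epoch, a freshly initialized network is trained on
#' 100,000 single-dimension stimuli (4:1 word:color), the selected memory
#' variant is attached, and 1000 sequential randomized color-naming Stroop
#' trials are simulated with memory carried trial-to-trial; memory resets
#' between epochs.
#'
#' @param model `"pdp_wm"` (time-delayed layer), `"pdp"` (conventional,
#'   running-average dynamics) or `"pdp_refined"` (no memory).
#' @param n_epochs Number of re-initialized train/test epochs.
#' @param trials_per_epoch Test trials per epoch.
#' @param seed Root seed; every random stage (initialization, training
#'   stream, noise, test sequence, accumulator) descends from it, so a run is
#'   a deterministic function of the configuration.
#' @param designed_pairs If `TRUE`, test sequences interleave constructed
#'   prime-probe pairs ([designed_pair_sequence()]) instead of the
#'   free-running random stream, for powered NP contrasts at reduced scale.
#' @param network A [network_params()] object.
#' @param learning_rate,n_stimuli,word_color_ratio Training-stage settings.
#' @param accumulator An [accumulator_params()] object.
#' @param w_delay Working-memory weight of the time-delayed layer.
#' @param delay_store What the delay layer stores; see [delay_state()].
#' @param tau Running-average rate constant of the conventional model.
#' @param iti_steps Blank-input settling steps between trials for the
#'   conventional model (the inter-stimulus interval).
#' @param pdp_rate Evidence-accumulation rate of the conventional model,
#'   whose evidence accrues while the running average settles (see the
#'   vignette; the refined/WM variants use the accumulator's `alpha`).
#' @return List of class `np_config`.
#' @export
experiment_config <- function(model = c("pdp_wm", "pdp", "pdp_refined"),
                              n_epochs = 100, trials_per_epoch = 1000,
                              seed = 1, designed_pairs = FALSE,
                              network = network_params(),
                              learning_rate = 0.03, n_stimuli = 100000,
                              word_color_ratio = 4,
                              accumulator = accumulator_params(),
                              w_delay = 0.8,
                              delay_store = c("activation", "net",
                                              "combined"),
                              tau = 0.2, iti_steps = 20, pdp_rate = 1.0) {
  model <- match.arg(model)
  delay_store <- match.arg(delay_store)
  if (n_epochs <= 0 || trials_per_epoch <= 0)
    stop("n_epochs and trials_per_epoch must be positive")
  if (w_delay < 0 || w_delay > 1) stop("w_delay must be in [0, 1]")
  if (tau <= 0 || tau > 1) stop("tau must be in (0, 1]")
  structure(list(model = model, n_epochs = as.integer(n_epochs),
                 trials_per_epoch = as.integer(trials_per_epoch),
                 seed = as.integer(seed), designed_pairs = designed_pairs,
                 network = network, learning_rate = learning_rate,
                 n_stimuli = as.integer(n_stimuli),
                 word_color_ratio = word_color_ratio,
                 accumulator = accumulator, w_delay = w_delay,
                 delay_store = delay_store, tau = tau,
                 iti_steps = as.integer(iti_steps), pdp_rate = pdp_rate),
            class = "np_config")
}

#' @export
print.np_config <- function(x, ...) {
  cat(sprintf("<np_config> model %s, %d epochs x %d trials, seed %d\n",
              x$model, x$n_epochs, x$trials_per_epoch, x$seed))
  cat(sprintf("  training: %d stimuli, lr %g, word:color %g:1\n",
              x$n_stimuli, x$learning_rate, x$word_color_ratio))
  cat(sprintf("  noise_sd %g; accumulator alpha %g sigma %g threshold %g\n",
              x$network$noise_sd, x$accumulator$alpha, x$accumulator$sigma,
              x$accumulator$threshold))
  if (x$model == "pdp_wm")
    cat(sprintf("  w_delay %g (stores %s)\n", x$w_delay, x$delay_store))
  if (x$model == "pdp")
    cat(sprintf("  tau %g, %d ITI settling steps\n", x$tau, x$iti_steps))
  invisible(x)
}

variant_code <- function(model) {
  c(pdp_refined = 0L, pdp_wm = 1L, pdp = 2L)[[model]]
}

# simulate one epoch's trial table given a trained network
simulate_epoch <- function(network, seq_df, cfg) {
  X <- content_index(seq_df$word, seq_df$ink)
  acc <- cfg$accumulator
  sim <- cpp_simulate(network$W1, network$W2, X,
                      variant_code(cfg$model), cfg$network$noise_sd,
                      cfg$network$hidden_bias, cfg$network$w_td,
                      acc$alpha, acc$sigma, acc$threshold, acc$max_iter,
                      cfg$w_delay,
                      match(cfg$delay_store,
                            c("activation", "net", "combined")) - 1L,
                      cfg$tau, cfg$iti_steps, cfg$pdp_rate)
  response <- ifelse(sim$response < 0, "none",
                     np_responses[sim$response + 1])
  n <- nrow(seq_df)
  lab <- c("other",
           pair_label(seq_df$word[-n], seq_df$ink[-n],
                      seq_df$word[-1], seq_df$ink[-1]))
  data.frame(word = seq_df$word, ink = seq_df$ink,
             condition = seq_df$condition, pair_label = lab,
             response = response,
             correct = response == seq_df$ink,
             rt = ifelse(sim$response < 0, NA_integer_, sim$rt),
             stringsAsFactors = FALSE)
}

#' Run the full simulation protocol
#'
#' For each epoch: initialize fresh weights, train the memoryless core on the
#' configured stream, attach the configured memory variant with reset state,
#' and simulate one sequence of color-naming Stroop trials, labeling each
#' adjacent prime-probe pair post hoc. Trials are sequential within an epoch
#' (memory carries trial-to-trial); epochs are independent simulated
#' participants.
#'
#' @param cfg An [experiment_config()].
#' @param progress Print a line per epoch block.
#' @return A data frame of class `np_trials` with columns `epoch`,
#'   `trial_index`, `word`, `ink`, `condition`, `pair_label`, `response`,
#'   `correct`, `rt` (accumulator iterations; `NA` on timeout). Attributes:
#'   `config`, `epoch_mse` (final training MSE per epoch).
#' @export
run_experiment <- function(cfg = experiment_config(), progress = FALSE) {
  set.seed(cfg$seed)
  epoch_seeds <- sample.int(.Machine$integer.max - 1L, cfg$n_epochs)
  out <- vector("list", cfg$n_epochs)
  mse <- numeric(cfg$n_epochs)
  for (e in seq_len(cfg$n_epochs)) {
    set.seed(epoch_seeds[e])
    net <- init_network(cfg$network)
    stream <- training_stream(cfg$n_stimuli, cfg$word_color_ratio)
    net <- train_network(net, stream, cfg$learning_rate)
    mse[e] <- net$final_mse
    seq_df <- if (cfg$designed_pairs)
      designed_pair_sequence(ceiling(cfg$trials_per_epoch / 2))
    else test_sequence(cfg$trials_per_epoch)
    tab <- simulate_epoch(net, seq_df, cfg)
    tab <- cbind(epoch = e, trial_index = seq_len(nrow(tab)), tab)
    out[[e]] <- tab
    if (progress && e %% 10 == 0)
      message(sprintf("epoch %d/%d (MSE %.4f)", e, cfg$n_epochs, mse[e]))
  }
  trials <- do.call(rbind, out)
  trials$trial_index <- seq_len(nrow(trials))
  structure(trials, config = cfg, epoch_mse = mse, epoch_seeds = epoch_seeds,
            class = c("np_trials", "data.frame"))
}

#' Sweep the working-memory weight
#'
#' Re-runs the PDP-WM experiment over a grid of `w_delay` values, reusing the
#' same epoch seeds at every level so that levels differ only in the delay
#' weight, and tests the pooled NP effect (all NP-labeled probe RTs vs all
#' contra-NP controls, pooled-variance t-test) at each level.
#'
#' @param cfg A PDP-WM [experiment_config()].
#' @param w_delays Grid of delay weights (default 10\% to 90\%).
#' @return Data frame with one row per level: `w_delay`, group sizes, the
#'   pooled NP effect with `t`, `df`, `p`, `significant`, and the classic
#'   NP-I contrast (`npi_effect`, `npi_p`, `npi_significant`). Attribute
#'   `reports` holds the full [summarize_np()] output per level.
#' @export
wm_sweep <- function(cfg = experiment_config(), w_delays = seq(0.1, 0.9, 0.1)) {
  if (cfg$model != "pdp_wm") stop("wm_sweep requires the pdp_wm model")
  rows <- vector("list", length(w_delays))
  reports <- vector("list", length(w_delays))
  for (i in seq_along(w_delays)) {
    cfg_i <- cfg
    cfg_i$w_delay <- w_delays[i]
    trials <- run_experiment(cfg_i)
    rep_i <- summarize_np(trials)
    reports[[i]] <- rep_i
    pooled <- rep_i$pooled
    npi <- rep_i$subtype$I
    rows[[i]] <- data.frame(w_delay = w_delays[i],
                            n_np = pooled$groups$n[1],
                            n_contra = pooled$groups$n[2],
                            np_effect = pooled$groups$mean[1] -
                              pooled$groups$mean[2],
                            t = pooled$statistic, df = pooled$df,
                            p = pooled$p,
                            significant = pooled$p < 0.05,
                            npi_effect = if (is.null(npi)) NA_real_ else
                              npi$groups$mean[1] - npi$groups$mean[2],
                            npi_p = if (is.null(npi)) NA_real_ else npi$p,
                            npi_significant = if (is.null(npi)) NA else
                              npi$p < 0.05)
  }
  out <- do.call(rbind, rows)
  structure(out, reports = reports, class = c("np_sweep", "data.frame"))
}

#' Smallest working-memory weight with a significant NP effect
#'
#' @param sweep Result of [wm_sweep()].
#' @param contrast `"np_i"` (default) takes the classic NP contrast, NP-I vs
#'   contra-NP-I — the channel that carries the NP effect in this model
#'   family; `"pooled"` takes all NP-labeled trials vs all contra-NP
#'   controls.
#' @return The smallest `w_delay` (as a percentage) whose contrast is
#'   significant at the 0.05 level, or `NA` if none is.
#' @export
np_threshold_weight <- function(sweep, contrast = c("np_i", "pooled")) {
  contrast <- match.arg(contrast)
  sig <- sweep$w_delay[if (contrast == "np_i") sweep$npi_significant
                       else sweep$significant]
  sig <- sig[!is.na(sig)]
  if (length(sig) == 0) return(NA_real_)
  100 * min(sig)
}

#' Positive-priming report
#'
#' Compares PP-labeled probe trials (target ink repeated from the prime)
#' against non-PP trials of the same Stroop condition, per condition, on the
#' filtered trial table.
#'
#' @param trials An `np_trials` table (or any trial data frame).
#' @param filtered Whether `trials` has already passed [filter_trials()];
#'   if `FALSE` (default) filtering is applied first.
#' @return Data frame with one row per condition: group sizes, means, SDs,
#'   pooled t, df, p. Conditions with no PP trials yield an `NA` row with a
#'   warning.
#' @export
pp_report <- function(trials, filtered = FALSE) {
  if (!filtered) trials <- filter_trials(trials)
  out <- lapply(c("congruent", "neutral", "incongruent"), function(cond) {
    sub <- trials[trials$condition == cond, ]
    pp <- sub$rt[sub$pair_label == "PP"]
    base <- sub$rt[sub$pair_label != "PP"]
    if (length(pp) < 2) {
      warning("no PP trials in the ", cond, " condition")
      return(data.frame(condition = cond, n_base = length(base),
                        n_pp = length(pp), base_mean = mean(base),
                        base_sd = sd(base), pp_mean = NA_real_,
                        pp_sd = NA_real_, t = NA_real_, df = NA_real_,
                        p = NA_real_))
    }
    tt <- t_independent(base, pp, var_equal = TRUE)
    data.frame(condition = cond, n_base = length(base), n_pp = length(pp),
               base_mean = mean(base), base_sd = sd(base),
               pp_mean = mean(pp), pp_sd = sd(pp),
               t = tt$statistic, df = tt$df, p = tt$p)
  })
  do.call(rbind, out)
}
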