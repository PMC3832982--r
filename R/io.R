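#' Default configuration as a flat list
#'
#' Every protocol parameter with its default, in the flat key set understood
#' by [load_config()] and the command-line tool.
#'
#' @return Named list.
#' @export
default_config <- function() {
  list(model = "pdp_wm", n_epochs = 100L, trials_per_epoch = 1000L,
       seed = 1L, designed_pairs = FALSE,
       hidden_bias = -6, w_td = 6, slope = -1, noise_sd = 0.1,
       learning_rate = 0.03, n_stimuli = 100000L, word_color_ratio = 4,
       alpha = 0.1, sigma = 0.1, threshold = 6, max_iter = 10000L,
       w_delay = 0.8, delay_store = "activation",
       tau = 0.2, iti_steps = 20L, pdp_rate = 1.0)
}

config_from_list <- function(vals) {
  # normalize scalar types so configs rebuilt from YAML/JSON manifests
  # compare identical to ones built in R
  for (k in c("hidden_bias", "w_td", "slope", "noise_sd", "learning_rate",
              "word_color_ratio", "alpha", "sigma", "threshold", "w_delay",
              "tau", "pdp_rate"))
    vals[[k]] <- as.numeric(vals[[k]])
  vals$designed_pairs <- as.logical(vals$designed_pairs)
  experiment_config(model = vals$model, n_epochs = vals$n_epochs,
                    trials_per_epoch = vals$trials_per_epoch,
                    seed = vals$seed, designed_pairs = vals$designed_pairs,
                    network = network_params(hidden_bias = vals$hidden_bias,
                                             w_td = vals$w_td,
                                             slope = vals$slope,
                                             noise_sd = vals$noise_sd),
                    learning_rate = vals$learning_rate,
                    n_stimuli = vals$n_stimuli,
                    word_color_ratio = vals$word_color_ratio,
                    accumulator = accumulator_params(alpha = vals$alpha,
                                                     sigma = vals$sigma,
                                                     threshold = vals$threshold,
                                                     max_iter = vals$max_iter),
                    w_delay = vals$w_delay, delay_store = vals$delay_store,
                    tau = vals$tau, iti_steps = vals$iti_steps,
                    pdp_rate = vals$pdp_rate)
}

#' Load an experiment configuration from a YAML file
#'
#' Keys override the defaults of [default_config()]; unknown keys are
#' rejected (with the offending key named), and values are validated by the
#' underlying constructors. An empty file yields the full default protocol.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return An [experiment_config()].
#' @export
load_config <- function(path = NULL) {
  vals <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    unknown <- setdiff(names(user), names(vals))
    if (length(unknown))
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    vals[names(user)] <- user
  }
  config_from_list(vals)
}

#' Write a trial table as CSV
#'
#' Columns: `epoch, trial_index, word, ink, condition, pair_label, response,
#' correct, rt` (`rt` in accumulator iterations for simulated tables,
#' milliseconds for human data; empty on timeout). The `epoch` column keeps
#' memory-reset boundaries recoverable on re-analysis.
#'
#' @param trials Trial table.
#' @param path Output CSV path.
#' @export
write_trials <- function(trials, path) {
  cols <- intersect(c("epoch", "trial_index", "word", "ink", "condition",
                      "pair_label", "response", "correct", "rt"),
                    names(trials))
  write.csv(as.data.frame(trials)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Read a trial table written by [write_trials()] (or human data in the same
#' schema)
#'
#' @param path CSV path.
#' @return `np_trials` data frame.
#' @export
read_trials <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("word", "ink", "condition", "pair_label", "response", "correct",
            "rt")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("trial table lacks column(s): ", paste(missing, collapse = ", "))
  df$correct <- as.logical(df$correct)
  structure(df, class = c("np_trials", "data.frame"))
}

#' Build a run manifest
#'
#' Records everything needed to reproduce a run bit-identically: the full
#' configuration, the derived per-epoch seeds, per-epoch training MSE, and
#' the package version.
#'
#' @param trials Result of [run_experiment()].
#' @return Named list (JSON-serializable).
#' @export
run_manifest <- function(trials) {
  cfg <- attr(trials, "config")
  list(package = "npstroop",
       version = as.character(utils::packageVersion("npstroop")),
       config = list(model = cfg$model, n_epochs = cfg$n_epochs,
                     trials_per_epoch = cfg$trials_per_epoch,
                     seed = cfg$seed, designed_pairs = cfg$designed_pairs,
                     hidden_bias = cfg$network$hidden_bias,
                     w_td = cfg$network$w_td, slope = cfg$network$slope,
                     noise_sd = cfg$network$noise_sd,
                     learning_rate = cfg$learning_rate,
                     n_stimuli = cfg$n_stimuli,
                     word_color_ratio = cfg$word_color_ratio,
                     alpha = cfg$accumulator$alpha,
                     sigma = cfg$accumulator$sigma,
                     threshold = cfg$accumulator$threshold,
                     max_iter = cfg$accumulator$max_iter,
                     w_delay = cfg$w_delay, delay_store = cfg$delay_store,
                     tau = cfg$tau, iti_steps = cfg$iti_steps,
                     pdp_rate = cfg$pdp_rate),
       epoch_seeds = attr(trials, "epoch_seeds"),
       epoch_mse = attr(trials, "epoch_mse"),
       n_trials = nrow(trials))
}

#' Write run outputs to a directory
#'
#' Writes `trials.csv` (schema of [write_trials()]), `report.json` (Stroop
#' and NP summaries) and `manifest.json`; optionally PNG summary plots.
#'
#' @param trials Result of [run_experiment()].
#' @param outdir Output directory (created if needed).
#' @param plots Also write `stroop.png` / `np.png` bar charts.
#' @return The directory, invisibly.
#' @export
write_outputs <- function(trials, outdir, plots = FALSE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_trials(trials, file.path(outdir, "trials.csv"))
  filt <- filter_trials(trials)
  stroop <- summarize_stroop(filt, filtered = TRUE)
  np <- summarize_np(filt, filtered = TRUE)
  report <- list(
    stroop = list(groups = stroop$anova$groups, F = stroop$anova$statistic,
                  df = stroop$anova$df, p = stroop$anova$p,
                  effects = as.list(stroop$effects),
                  posthoc = stroop$posthoc),
    np = list(table = np$table,
              subtype = lapply(np$subtype, function(s) if (is.null(s)) NULL
                               else list(t = s$statistic, df = s$df,
                                         p = s$p, groups = s$groups)),
              pooled = if (is.null(np$pooled)) NULL
                       else list(t = np$pooled$statistic, df = np$pooled$df,
                                 p = np$pooled$p)))
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       null = "null")
  jsonlite::write_json(run_manifest(trials),
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (plots) {
    ggplot2::ggsave(file.path(outdir, "stroop.png"), plot_stroop(filt),
                    width = 5, height = 4, dpi = 150)
    ggplot2::ggsave(file.path(outdir, "np.png"), plot_np(filt),
                    width = 6, height = 4, dpi = 150)
  }
  invisible(outdir)
}

#' Bar chart of mean RT per Stroop condition
#'
#' @param trials Filtered trial table.
#' @return A ggplot object.
#' @export
plot_stroop <- function(trials) {
  tab <- group_table(trials$rt, trials$condition)
  tab$group <- factor(tab$group, c("congruent", "neutral", "incongruent"))
  tab$se <- tab$sd / sqrt(tab$n)
  ggplot2::ggplot(tab, ggplot2::aes(x = group, y = mean)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = mean - se, ymax = mean + se),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "mean RT (iterations)") +
    ggplot2::theme_classic()
}

#' Bar chart of mean RT per NP subtype and its control
#'
#' @param trials Filtered trial table.
#' @return A ggplot object.
#' @export
plot_np <- function(trials) {
  keep <- trials$pair_label %in% c("NP-I", "NP-N", "NP-C", "contra-NP-I",
                                   "contra-NP-N", "contra-NP-C")
  tab <- group_table(trials$rt[keep], trials$pair_label[keep])
  tab$subtype <- sub(".*-(I|N|C)$", "\\1", tab$group)
  tab$kind <- ifelse(startsWith(tab$group, "contra"), "contra-NP", "NP")
  tab$se <- tab$sd / sqrt(tab$n)
  ggplot2::ggplot(tab, ggplot2::aes(x = factor(subtype, c("I", "N", "C")),
                                    y = mean, fill = kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = mean - se, ymax = mean + se),
                           position = ggplot2::position_dodge(0.9),
                           width = 0.2) +
    ggplot2::scale_fill_manual(values = c(`contra-NP` = "grey70",
                                          NP = "grey30")) +
    ggplot2::labs(x = "probe Stroop type", y = "mean RT (iterations)",
                  fill = NULL) +
    ggplot2::theme_classic()
}
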