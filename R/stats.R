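#' Filter a trial table the way the analyses expect
#'
#' Drops incorrect responses and timeouts, then removes reaction times more
#' than three SDs above or below the mean of their own Stroop condition. The
#' outlier pass runs once, on the accuracy-filtered data, with the condition
#' means and SDs computed from that data (not iterated).
#'
#' @param trials Trial table with columns `condition`, `correct`, `rt`.
#' @return The filtered table; attribute `n_removed` records counts for the
#'   accuracy and outlier passes. A condition left empty after filtering is
#'   flagged with a warning.
#' @export
filter_trials <- function(trials) {
  before <- nrow(trials)
  keep <- !is.na(trials$correct) & trials$correct & !is.na(trials$rt)
  trials <- trials[keep, ]
  n_acc <- before - nrow(trials)
  m <- tapply(trials$rt, trials$condition, mean)
  s <- tapply(trials$rt, trials$condition, sd)
  lo <- (m - 3 * s)[trials$condition]
  hi <- (m + 3 * s)[trials$condition]
  inlier <- trials$rt >= lo & trials$rt <= hi
  out <- trials[inlier, ]
  empty <- setdiff(unique(trials$condition), unique(out$condition))
  if (length(empty))
    warning("condition(s) empty after filtering: ",
            paste(empty, collapse = ", "))
  structure(out, n_removed = c(incorrect = n_acc,
                               outlier = sum(!inlier)))
}

group_table <- function(values, groups) {
  groups <- factor(groups)
  data.frame(group = levels(groups),
             n = as.integer(table(groups)),
             mean = as.numeric(tapply(values, groups, mean)),
             sd = as.numeric(tapply(values, groups, sd)),
             row.names = NULL, stringsAsFactors = FALSE)
}

np_effect_report <- function(test, statistic, df, p, groups,
                             pairwise = NULL, alpha = 0.05) {
  structure(list(test = test, statistic = unname(statistic),
                 df = unname(df), p = unname(p), groups = groups,
                 pairwise = pairwise, alpha = alpha),
            class = "np_effect")
}

#' @export
print.np_effect <- function(x, ...) {
  dfs <- paste(formatC(x$df, format = "fg", digits = 6), collapse = ", ")
  cat(sprintf("%s: statistic = %.4g, df = (%s), p = %.4g\n",
              x$test, x$statistic, dfs, x$p))
  print(x$groups, row.names = FALSE)
  if (!is.null(x$pairwise)) {
    cat("pairwise:\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' One-way analysis of variance
#'
#' Fixed-effects one-way ANOVA (via [stats::aov()]) of `values` on the group
#' factor.
#'
#' @param values Numeric response vector.
#' @param groups Group labels.
#' @return An `np_effect` report with F, degrees of freedom, p, and the
#'   per-group n/mean/SD table.
#' @export
anova_oneway <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  fit <- aov(values ~ groups)
  tab <- anova(fit)
  np_effect_report("one-way ANOVA", tab$`F value`[1], tab$Df, tab$`Pr(>F)`[1],
                   group_table(values, groups))
}

#' Tukey HSD post-hoc comparisons
#'
#' Studentized-range pairwise comparisons after a one-way ANOVA (via
#' [stats::TukeyHSD()]); appropriate when group variances are equal.
#'
#' @inheritParams anova_oneway
#' @return Data frame of pairwise contrasts with the difference, confidence
#'   bounds and adjusted p.
#' @export
tukey_hsd <- function(values, groups) {
  groups <- factor(groups)
  tk <- stats::TukeyHSD(aov(values ~ groups))$groups
  data.frame(contrast = rownames(tk), diff = tk[, "diff"],
             lwr = tk[, "lwr"], upr = tk[, "upr"], p = tk[, "p adj"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Tamhane's T2 post-hoc comparisons
#'
#' Pairwise comparisons that do not assume equal variances: Welch-type t
#' statistics with Welch-Satterthwaite degrees of freedom and a Sidak-style
#' correction `p_adj = 1 - (1 - p)^m` over the m comparisons.
#'
#' @inheritParams anova_oneway
#' @return Data frame of pairwise contrasts with t, df, and adjusted p.
#' @export
tamhane_t2 <- function(values, groups) {
  groups <- factor(groups)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  m <- ncol(pairs)
  out <- apply(pairs, 2, function(pr) {
    x <- values[groups == pr[1]]
    y <- values[groups == pr[2]]
    vx <- var(x) / length(x)
    vy <- var(y) / length(y)
    tt <- (mean(x) - mean(y)) / sqrt(vx + vy)
    df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
    p <- 2 * pt(-abs(tt), df)
    c(t = tt, df = df, p_adj = min(1, 1 - (1 - p)^m))
  })
  data.frame(contrast = paste(pairs[1, ], pairs[2, ], sep = "-"),
             diff = apply(pairs, 2, function(pr)
               mean(values[groups == pr[1]]) - mean(values[groups == pr[2]])),
             t = out["t", ], df = out["df", ], p = out["p_adj", ],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Levene's test for homogeneity of variance
#'
#' One-way ANOVA on absolute deviations from the group means (mean-centered
#' Levene, the variant used to gate the choice of post-hoc test).
#'
#' @inheritParams anova_oneway
#' @return An `np_effect` report.
#' @export
levene_test <- function(values, groups) {
  groups <- factor(groups)
  dev <- abs(values - ave(values, groups))
  fit <- anova(aov(dev ~ groups))
  np_effect_report("Levene's test (mean-centered)", fit$`F value`[1],
                   fit$Df, fit$`Pr(>F)`[1], group_table(values, groups))
}

#' Independent two-sample t-test
#'
#' @param x,y The two samples.
#' @param var_equal Pooled-variance (classical) t-test if `TRUE` (the
#'   headline form, matching the huge pooled dfs of simulation-scale
#'   contrasts), Welch if `FALSE`.
#' @return An `np_effect` report.
#' @export
t_independent <- function(x, y, var_equal = TRUE) {
  tt <- t.test(x, y, var.equal = var_equal)
  np_effect_report(if (var_equal) "pooled t-test" else "Welch t-test",
                   tt$statistic, tt$parameter, tt$p.value,
                   group_table(c(x, y),
                               rep(c("x", "y"), c(length(x), length(y)))))
}

#' Post-hoc comparisons gated by a variance-homogeneity test
#'
#' Runs [levene_test()] at the 0.05 level and dispatches to [tukey_hsd()]
#' (equal variances assumed) or [tamhane_t2()] otherwise.
#'
#' @inheritParams anova_oneway
#' @return The pairwise table, with attribute `method` and `levene_p`.
#' @export
posthoc_pairwise <- function(values, groups) {
  lev <- levene_test(values, groups)
  if (lev$p < 0.05) {
    out <- tamhane_t2(values, groups)
    attr(out, "method") <- "tamhane_t2"
  } else {
    out <- tukey_hsd(values, groups)
    attr(out, "method") <- "tukey_hsd"
  }
  attr(out, "levene_p") <- lev$p
  out
}

#' Stroop-condition analysis of a trial table
#'
#' Filters the table, then reports per-condition means, the one-way ANOVA
#' over the three Stroop conditions, variance-gated post-hoc contrasts, and
#' the three derived effects (Stroop effect = incongruent - congruent,
#' interference = incongruent - neutral, facilitation = neutral - congruent).
#'
#' @param trials Trial table.
#' @param filtered Set `TRUE` if `trials` is already filtered.
#' @return List with `anova` (`np_effect`), `posthoc`, and `effects`.
#' @export
summarize_stroop <- function(trials, filtered = FALSE) {
  if (!filtered) trials <- filter_trials(trials)
  g <- trials$condition
  a <- anova_oneway(trials$rt, g)
  ph <- posthoc_pairwise(trials$rt, g)
  m <- a$groups$mean[match(c("congruent", "neutral", "incongruent"),
                           a$groups$group)]
  effects <- c(stroop_effect = m[3] - m[1], interference = m[3] - m[2],
               facilitation = m[2] - m[1])
  list(anova = a, posthoc = ph, effects = effects)
}

#' Negative-priming analysis of a trial table
#'
#' Filters the table, then contrasts each NP subtype with its matching
#' control (`NP-I` vs `contra-NP-I`, etc.) by pooled t-test, the three NP
#' subtypes against each other by one-way ANOVA with variance-gated post-hoc
#' contrasts, and all NP trials against all contra-NP trials pooled.
#'
#' @param trials Trial table with `pair_label`.
#' @param filtered Set `TRUE` if `trials` is already filtered.
#' @return List with `subtype` (named list of `np_effect`, one per subtype),
#'   `across` (ANOVA across NP-I/N/C), `across_posthoc`, `pooled`
#'   (all-NP vs all-contra), and `table` (mean and SD per label). Subtypes
#'   with an empty cell are reported as `NULL` with a warning, not an error.
#' @export
summarize_np <- function(trials, filtered = FALSE) {
  if (!filtered) trials <- filter_trials(trials)
  lab <- trials$pair_label
  rt <- trials$rt
  subtype <- setNames(vector("list", 3), c("I", "N", "C"))
  for (s in names(subtype)) {
    np <- rt[lab == paste0("NP-", s)]
    co <- rt[lab == paste0("contra-NP-", s)]
    if (length(np) < 2 || length(co) < 2) {
      warning("NP-", s, " contrast skipped: empty cell")
      next
    }
    subtype[[s]] <- t_independent(np, co)
  }
  is_np <- lab %in% c("NP-I", "NP-N", "NP-C")
  is_co <- lab %in% c("contra-NP-I", "contra-NP-N", "contra-NP-C")
  across <- across_ph <- NULL
  if (all(table(factor(lab[is_np],
                       c("NP-I", "NP-N", "NP-C"))) >= 2)) {
    across <- anova_oneway(rt[is_np], lab[is_np])
    across_ph <- posthoc_pairwise(rt[is_np], lab[is_np])
  }
  pooled <- if (sum(is_np) >= 2 && sum(is_co) >= 2)
    t_independent(rt[is_np], rt[is_co]) else NULL
  if (!is.null(pooled))
    pooled$groups$group <- c("NP", "contra-NP")
  keep <- lab != "other"
  list(subtype = subtype, across = across, across_posthoc = across_ph,
       pooled = pooled, table = group_table(rt[keep], lab[keep]))
}
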