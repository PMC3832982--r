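#' Network parameters
#'
#' Fixed structural constants of the feedforward core. The hidden layer is
#' split into a color pool and a word pool of five units each; every hidden
#' unit carries a fixed inhibitory bias, and the task-demand unit of the
#' attended task adds a fixed weight that exactly compensates the bias, so
#' that only the ignored pathway is gated down.
#'
#' @param hidden_bias Inhibitory bias on hidden net inputs (default -6).
#' @param w_td Fixed task-demand weight (default 6); must satisfy
#'   `w_td + hidden_bias == 0` so the attended pool is un-biased.
#' @param slope Slope constant `s` of the logistic `1 / (1 + exp(s * net))`
#'   (fixed at -1, the increasing orientation).
#' @param noise_sd SD of the Gaussian processing noise added to the net input
#'   of every non-input unit, during training and test alike (default 0.1,
#'   the scale shared by the accumulator's increment SD; see the package
#'   vignette for the sensitivity analysis).
#' @param n_hidden,n_output Layer sizes (10 and 5; the architecture is fixed,
#'   these are recorded for validation).
#' @return A list of class `np_network_params`.
#' @export
network_params <- function(hidden_bias = -6, w_td = 6, slope = -1,
                           noise_sd = 0.1, n_hidden = 10, n_output = 5) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_hidden != 10 || n_output != 5)
    stop("the architecture is fixed at 10 hidden and 5 output units")
  if (abs(w_td + hidden_bias) > 1e-12)
    warning("w_td + hidden_bias != 0: the attended pathway is no longer ",
            "exactly compensated")
  structure(list(hidden_bias = hidden_bias, w_td = w_td, slope = slope,
                 noise_sd = noise_sd, n_hidden = n_hidden,
                 n_output = n_output),
            class = "np_network_params")
}

#' Logistic unit activation
#'
#' `1 / (1 + exp(slope * net))`; with the default `slope = -1` this is the
#' standard increasing sigmoid, strictly increasing in `net` with range (0,1).
#'
#' @param net Net input (numeric vector).
#' @param slope Slope constant `s`.
#' @export
logistic_act <- function(net, slope = -1) 1 / (1 + exp(slope * net))

# structural mask: color inputs (1..5) feed the color pool (hidden 1..5),
# word inputs (6..10) feed the word pool (hidden 6..10)
pathway_mask <- function() {
  m <- matrix(0, 10, 10)
  m[1:5, 1:5] <- 1
  m[6:10, 6:10] <- 1
  m
}

#' Initialize a network
#'
#' Trainable weights (input-to-hidden within each pathway, hidden-to-output)
#' are drawn uniformly from `[-init_range, init_range]`; cross-pathway
#' input-to-hidden weights are structurally zero. Task-demand connections and
#' the hidden bias are fixed, not trained.
#'
#' @param params A [network_params()] object.
#' @param init_range Half-width of the uniform initialization interval
#'   (default 0.5).
#' @return A list of class `np_network` with weight matrices `W1` (10 content
#'   inputs x 10 hidden) and `W2` (10 hidden x 5 outputs).
#' @export
init_network <- function(params = network_params(), init_range = 0.5) {
  mask <- pathway_mask()
  W1 <- matrix(runif(100, -init_range, init_range), 10, 10) * mask
  W2 <- matrix(runif(50, -init_range, init_range), 10, 5)
  structure(list(W1 = W1, W2 = W2, params = params, trained = FALSE,
                 final_mse = NA_real_),
            class = "np_network")
}

#' @export
print.np_network <- function(x, ...) {
  cat("<np_network> 12-10-5 feedforward Stroop network\n")
  cat(sprintf("  trained: %s", x$trained))
  if (!is.na(x$final_mse)) cat(sprintf("  (final MSE %.4f)", x$final_mse))
  cat(sprintf("\n  noise_sd %.3g, bias %g, w_td %g\n",
              x$params$noise_sd, x$params$hidden_bias, x$params$w_td))
  invisible(x)
}

#' Forward pass through the network
#'
#' Reference (R-level) implementation of a single forward pass. The attended
#' pool's hidden net input is `sum(a_i w_ij) + w_td + hidden_bias`; the
#' ignored pool's is `sum(a_i w_ij) + hidden_bias`. Gaussian noise of SD
#' `noise_sd` is added to the net input of every hidden and output unit.
#'
#' @param network An [init_network()] (or trained) object.
#' @param x Length-12 encoded input from [encode_stimulus()].
#' @param noise_sd Processing-noise SD; defaults to the network's parameter.
#'   Set 0 for a deterministic pass.
#' @return List with `hidden_net`, `hidden_act`, `output_net`, `output_act`.
#' @export
forward_pass <- function(network, x, noise_sd = network$params$noise_sd) {
  if (length(x) != 12) stop("x must be a length-12 encoded input")
  p <- network$params
  content <- x[1:10]
  demand <- rep(c(x[11], x[12]), each = 5) * p$w_td
  hidden_net <- drop(content %*% network$W1) + p$hidden_bias + demand +
    rnorm(10, 0, noise_sd)
  hidden_act <- logistic_act(hidden_net, p$slope)
  output_net <- drop(hidden_act %*% network$W2) + rnorm(5, 0, noise_sd)
  list(hidden_net = hidden_net, hidden_act = hidden_act,
       output_net = output_net,
       output_act = setNames(logistic_act(output_net, p$slope), np_responses))
}

#' Serialize network weights to a plain-text file
#'
#' Writes the two weight matrices and the fixed parameters as a flat,
#' named-vector text representation; [read_network()] restores them exactly
#' (values round-trip via full-precision decimal strings).
#'
#' @param network An `np_network`.
#' @param path Output file.
#' @export
write_network <- function(network, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# npstroop network weights v1", con)
  p <- network$params
  writeLines(sprintf("param %s %.17g",
                     c("hidden_bias", "w_td", "slope", "noise_sd", "final_mse"),
                     c(p$hidden_bias, p$w_td, p$slope, p$noise_sd,
                       network$final_mse)),
             con)
  dump_mat <- function(name, m) {
    writeLines(sprintf("matrix %s %d %d", name, nrow(m), ncol(m)), con)
    writeLines(apply(m, 1, function(r)
      paste(sprintf("%.17g", r), collapse = " ")), con)
  }
  dump_mat("W1", network$W1)
  dump_mat("W2", network$W2)
  invisible(path)
}

#' Restore a network written by [write_network()]
#'
#' @param path File written by [write_network()].
#' @return An `np_network`.
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  params <- list()
  mats <- list()
  i <- 1
  while (i <= length(lines)) {
    f <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (f[1] == "param") {
      params[[f[2]]] <- as.numeric(f[3])
      i <- i + 1
    } else if (f[1] == "matrix") {
      nr <- as.integer(f[3]); nc <- as.integer(f[4])
      vals <- lapply(lines[i + seq_len(nr)], function(l)
        as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1]]))
      mats[[f[2]]] <- matrix(unlist(vals), nr, nc, byrow = TRUE)
      i <- i + 1 + nr
    } else stop("malformed network file at line: ", lines[i])
  }
  np <- network_params(hidden_bias = params$hidden_bias, w_td = params$w_td,
                       slope = params$slope, noise_sd = params$noise_sd)
  structure(list(W1 = mats$W1, W2 = mats$W2, params = np,
                 trained = !is.na(params$final_mse),
                 final_mse = params$final_mse),
            class = "np_network")
}
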