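#' Training target for a single-dimension stimulus
#'
#' One-hot activation over the five output units: the named or inked color's
#' unit, or the shared neutral-word unit for neutral-word reading.
#'
#' @param word,ink,task Stimulus fields; exactly one of `word`/`ink` must be
#'   set (`"NONE"` for the other), as in a training item.
#' @return Named numeric vector of length 5.
#' @export
target_vector <- function(word, ink, task) {
  if ((word == "NONE") == (ink == "NONE"))
    stop("a training stimulus has exactly one of word/ink set")
  tgt <- setNames(numeric(5), np_responses)
  unit <- if (ink != "NONE") ink
          else if (word %in% np_color_words) tolower(word)
          else if (word %in% np_neutral_words) "neutral"
          else stop("unknown word: ", word)
  tgt[unit] <- 1
  tgt
}

# 0-based (input unit, attended pool, target unit) triple for the C++ trainer
training_indices <- function(stream) {
  is_word <- stream$ink == "NONE"
  input <- integer(nrow(stream))
  input[!is_word] <- match(stream$ink[!is_word], np_colors) - 1L
  input[is_word] <- ifelse(stream$word[is_word] %in% np_color_words,
                           4L + match(stream$word[is_word], np_color_words),
                           9L)
  target <- integer(nrow(stream))
  target[!is_word] <- match(stream$ink[!is_word], np_colors) - 1L
  target[is_word] <- ifelse(stream$word[is_word] %in% np_color_words,
                            match(stream$word[is_word], np_color_words) - 1L,
                            4L)
  list(input = input, attended = as.integer(is_word), target = target)
}

#' Train the network by online backpropagation
#'
#' Squared-error backpropagation with a fixed learning rate, one weight update
#' per stimulus, on single-dimension training items. Task-demand connections
#' and the hidden bias stay fixed; processing noise is active during training
#' passes (it is a property of the units, not a training device). The model
#' trained here is the memoryless PDP-refined core; the running average or the
#' time-delayed layer is attached afterwards, at test time.
#'
#' @param network An [init_network()] object.
#' @param stream Training stimuli from [training_stream()].
#' @param learning_rate Step size (default 0.03).
#' @param mse_window Number of final patterns over which the reported MSE
#'   (per-pattern mean of unit-wise squared output errors) is averaged.
#' @param fail_threshold Final MSE above this value raises a training-failure
#'   error (divergence guard).
#' @return The network with trained weights, `final_mse`, and an `mse_trace`
#'   (per-pattern MSE averaged over consecutive blocks of 1000).
#' @export
train_network <- function(network, stream, learning_rate = 0.03,
                          mse_window = 1000, fail_threshold = 0.05) {
  if (nrow(stream) == 0) stop("empty training stream")
  if (learning_rate < 0) stop("learning_rate must be >= 0")
  idx <- training_indices(stream)
  p <- network$params
  fit <- cpp_train(network$W1, network$W2, idx$input, idx$attended,
                   idx$target, learning_rate, p$noise_sd, p$hidden_bias,
                   p$w_td)
  network$W1 <- fit$W1
  network$W2 <- fit$W2
  n <- length(fit$mse)
  network$final_mse <- mean(fit$mse[max(1, n - mse_window + 1):n])
  block <- rep(seq_len(ceiling(n / 1000)), each = 1000, length.out = n)
  network$mse_trace <- as.numeric(tapply(fit$mse, block, mean))
  network$trained <- TRUE
  if (network$final_mse > fail_threshold)
    stop(sprintf(paste0("training failed to converge (final MSE %.4f > %g); ",
                        "re-run with another seed"),
                 network$final_mse, fail_threshold))
  network
}

# R reference implementation of one noiseless forward + gradient computation,
# used to cross-check the compiled trainer (finite differences in the tests)
backprop_gradients <- function(network, x, target) {
  p <- network$params
  content <- x[1:10]
  demand <- rep(c(x[11], x[12]), each = 5) * p$w_td
  hidden_net <- drop(content %*% network$W1) + p$hidden_bias + demand
  h <- logistic_act(hidden_net, p$slope)
  output_net <- drop(h %*% network$W2)
  a <- logistic_act(output_net, p$slope)
  err <- a - target
  dout <- err * a * (1 - a)
  dhid <- drop(network$W2 %*% dout) * h * (1 - h)
  list(loss = sum(err^2) / 5,
       gW2 = outer(h, dout) * 2 / 5,
       gW1 = outer(content, dhid) * pathway_mask() * 2 / 5)
}
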