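#' Running-average state (conventional PDP dynamics)
#'
#' The conventional model smooths net inputs through an exponential running
#' average, `avg <- tau * net + (1 - tau) * avg`, applied at every processing
#' step; the average persists across trials and is the model's only memory of
#' preceding stimuli.
#'
#' @param tau Rate constant in (0, 1]; `tau = 1` disables averaging.
#' @param n Number of units tracked.
#' @return List of class `np_running_avg` with fields `tau` and `avg`.
#' @export
running_average_state <- function(tau = 0.2, n = 5) {
  if (tau <= 0 || tau > 1) stop("tau must be in (0, 1]")
  structure(list(tau = tau, avg = numeric(n)), class = "np_running_avg")
}

#' Apply one running-average update
#'
#' @param net_t Current net-input vector.
#' @param state A [running_average_state()].
#' @return The updated state; the averaged vector is `state$avg`.
#' @export
running_average <- function(net_t, state) {
  if (length(net_t) != length(state$avg)) stop("length mismatch")
  state$avg <- state$tau * net_t + (1 - state$tau) * state$avg
  state
}

#' Time-delayed working-memory state (PDP-WM)
#'
#' Five temporal-storage nodes, one per output unit, hold values from the
#' previous trial's moment of response and feed them back additively into the
#' next trial's output net inputs with weight `w_delay`. What is stored is
#' controlled by `store`: the output activations (default; bounded in (0,1),
#' the reading consistent with the simulated reaction-time scale), the raw
#' output nets, or the delay-combined nets (under which memory decays
#' geometrically across trials instead of being fully overwritten).
#'
#' @param w_delay Delay weight in \[0, 1\] (default 0.8; 0 reduces the model
#'   to PDP-refined).
#' @param store One of `"activation"`, `"net"`, `"combined"`.
#' @param n_output Number of output units.
#' @return List of class `np_delay` with fields `w_delay`, `store`, `stored`.
#' @export
delay_state <- function(w_delay = 0.8, store = c("activation", "net",
                                                 "combined"),
                        n_output = 5) {
  if (w_delay < 0 || w_delay > 1) stop("w_delay must be in [0, 1]")
  structure(list(w_delay = w_delay, store = match.arg(store),
                 stored = numeric(n_output), n_seen = 0L),
            class = "np_delay")
}

#' Combine current output nets with the stored trace
#'
#' Returns `net_t + w_delay * stored` without updating the store; storing
#' happens separately at the moment of response via [store_response()].
#'
#' @param net_t Output net-input vector (length 5).
#' @param state A [delay_state()].
#' @export
time_delay_combine <- function(net_t, state) {
  if (length(net_t) != length(state$stored)) stop("length mismatch")
  net_t + state$w_delay * state$stored
}

#' Store the output-layer values at the moment of response
#'
#' Called once per trial when the accumulator crosses threshold; only the
#' latest trial's values survive (one-trial storage). Which of the three
#' supplied vectors is kept follows the state's `store` setting.
#'
#' @param state A [delay_state()].
#' @param output_net Raw output nets of the trial.
#' @param output_act Output activations (post-combination).
#' @param combined_net Delay-combined nets of the trial.
#' @return The updated state.
#' @export
store_response <- function(state, output_net, output_act = NULL,
                           combined_net = NULL) {
  val <- switch(state$store,
                activation = output_act,
                net = output_net,
                combined = combined_net)
  if (is.null(val)) stop("required vector for store = '", state$store,
                         "' not supplied")
  state$stored <- val
  state$n_seen <- state$n_seen + 1L
  state
}

#' Reset a memory state to its pre-first-trial value
#'
#' @param state A [delay_state()] or [running_average_state()].
#' @export
reset_memory <- function(state) {
  if (inherits(state, "np_delay")) {
    state$stored <- numeric(length(state$stored))
    state$n_seen <- 0L
  } else {
    state$avg <- numeric(length(state$avg))
  }
  state
}
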