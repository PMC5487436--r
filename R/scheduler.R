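#' Event-driven netlist simulation
#'
#' A small event-driven simulation kernel in the style of AER hardware
#' simulators: the user declares a netlist of *modules* interconnected
#' through AER links (*nodes*), preloads source nodes with time-stamped
#' events, and [run_netlist()] repeatedly picks the globally earliest
#' unprocessed event, marks it processed, and hands it to every module that
#' consumes its node. Events a module emits are stamped with
#' `pre_rqst = now` (creation time) and delivered at `now + delay`; an
#' event is *unprocessed* while its `rqst`/`ack` fields are -1 and both are
#' set to the dispatch time once it is picked.
#'
#' Ties between simultaneous deliverable events are broken by node
#' registration order, then first-in-first-out within a node - a stated,
#' deterministic total order.
#'
#' @param name node / module name.
#' @param nl a netlist, started with `netlist()`.
#' @param events tibble of payload events with a `t` column (microseconds);
#'   remaining columns are free-form payload.
#' @return `netlist()` returns an empty netlist; `nl_source()` and
#'   `nl_module()` return the extended netlist.
#' @examples
#' nl <- netlist() |>
#'   nl_node("out") |>
#'   nl_source("in", tibble::tibble(t = c(0, 10), v = 1:2)) |>
#'   nl_module("id", "in", "out", function(ev, state, t) list(emit = ev),
#'             delay = 7)
#' run_netlist(nl)$out$t  # 7, 17
#' @export
netlist <- function() {
  structure(list(nodes = list(), modules = list()), class = "spikehist_netlist")
}

#' @rdname netlist
#' @export
nl_node <- function(nl, name) {
  stopifnot(inherits(nl, "spikehist_netlist"))
  if (!name %in% names(nl$nodes)) nl$nodes[name] <- list(NULL)
  nl
}

#' @rdname netlist
#' @export
nl_source <- function(nl, name, events) {
  nl <- nl_node(nl, name)
  events <- as_tibble(events)
  stopifnot("t" %in% names(events))
  events <- events[order(events$t, method = "radix"), , drop = FALSE]
  events$pre_rqst <- events$t
  events$rqst <- -1
  events$ack <- -1
  nl$nodes[[name]] <- events
  nl
}

#' @rdname netlist
#' @param inputs,output input node names and the single output node name.
#' @param f process callback `function(event, state, t_now)` returning a
#'   list with optional `state` (carried over) and `emit` (tibble of payload
#'   events, emitted on `output` at `t_now + delay`).
#' @param delay fixed processing delay in microseconds (>= 0; default 0 -
#'   latency in these networks arises from neuron dynamics, not module
#'   delays).
#' @param state initial module state.
#' @export
nl_module <- function(nl, name, inputs, output, f, delay = 0, state = NULL) {
  stopifnot(inherits(nl, "spikehist_netlist"), delay >= 0)
  for (nm in inputs) {
    if (!nm %in% names(nl$nodes)) {
      abort(paste0("unknown input node: ", nm), class = "spikehist_config_error")
    }
  }
  nl <- nl_node(nl, output)
  nl$modules[[name]] <- list(inputs = inputs, output = output, f = f,
                             delay = delay, state = state)
  nl
}

#' @rdname netlist
#' @param t_max stop once the earliest unprocessed event is later than this
#'   (default `Inf`: run to exhaustion).
#' @param event_budget abort with a livelock error after this many processed
#'   events (guards cyclic zero-delay event generation).
#' @return `run_netlist()` returns a named list of per-node processed event
#'   tibbles (payload columns plus `pre_rqst`, `rqst`, `ack`), in dispatch
#'   order.
#' @export
run_netlist <- function(nl, t_max = Inf, event_budget = 1e6) {
  nodes <- nl$nodes
  mods <- nl$modules
  node_names <- names(nodes)
  consumers <- lapply(node_names, function(nm) {
    which(vapply(mods, function(m) nm %in% m$inputs, logical(1)))
  })
  names(consumers) <- node_names
  processed <- 0
  repeat {
    best_node <- NA_integer_; best_row <- NA_integer_; best_t <- Inf
    for (i in seq_along(nodes)) {
      ev <- nodes[[i]]
      if (is.null(ev) || !nrow(ev)) next
      un <- which(ev$rqst == -1)
      if (!length(un)) next
      j <- un[which.min(ev$t[un])]
      # which.min returns the first minimum: FIFO within the node
      if (ev$t[j] < best_t) {
        best_t <- ev$t[j]; best_node <- i; best_row <- j
      }
    }
    if (is.na(best_node) || best_t > t_max) break
    processed <- processed + 1
    if (processed > event_budget) {
      abort(sprintf("event budget (%g) exhausted: possible zero-delay livelock",
                    event_budget), class = "spikehist_livelock_error")
    }
    nodes[[best_node]]$rqst[best_row] <- best_t
    nodes[[best_node]]$ack[best_row] <- best_t
    ev_row <- nodes[[best_node]][best_row, , drop = FALSE]
    for (mi in consumers[[node_names[best_node]]]) {
      m <- mods[[mi]]
      res <- m$f(ev_row, m$state, best_t)
      if (!is.null(res$state)) mods[[mi]]$state <- res$state
      if (!is.null(res$emit) && nrow(res$emit)) {
        out <- as_tibble(res$emit)
        out$pre_rqst <- best_t
        out$t <- best_t + m$delay
        out$rqst <- -1
        out$ack <- -1
        nodes[[m$output]] <- bind_rows(nodes[[m$output]], out)
      }
    }
  }
  lapply(nodes, function(ev) {
    if (is.null(ev)) return(tibble(t = numeric()))
    done <- ev[ev$rqst != -1, , drop = FALSE]
    done[order(done$rqst, method = "radix"), , drop = FALSE]
  })
}

#' Build the ConvNet as an explicit netlist
#'
#' Reference construction of the full topology - source, convolution layer,
#' subsampling, flatten, and (when `weights` are given) the spiking
#' classifier - as modules on the generic scheduler, using the pure-R neuron
#' model ([lif_receive()]). It is exact but slow; [run_convnet()] is the
#' equivalent fast path (the two are cross-checked on random streams).
#' Nodes are registered deepest-first (classifier first), which makes the
#' earliest-first dispatch drain each input event's downstream cascade
#' before a simultaneous later input - the same order the fast path uses.
#'
#' @param config a [convnet_config()].
#' @param stream an [event_stream()] preloaded on the source node.
#' @param weights optional integer classifier weights (`classes x h`).
#' @param leak engage the leakage time constants.
#' @return a netlist; run it with [run_netlist()]. Node `"flatten"` carries
#'   `(t, idx, sign)` events, node `"fc_out"` carries `(t, class)` events.
#' @export
build_convnet_netlist <- function(config, stream, weights = NULL,
                                  leak = FALSE) {
  geom <- config$geometry
  n <- config$input_size; k <- config$kernel_size
  side <- geom$c1_side; pside <- geom$pooled_side; n_fm <- geom$n_fm
  c1_par <- neuron_params(th_plus = config$c1_th_plus,
                          th_minus = config$c1_th_minus,
                          tl_plus = if (leak) config$c1_tl_us else Inf,
                          emit_negative = config$c1_emit_negative)
  fc_par <- neuron_params(th_plus = config$fc_th, th_minus = -2^31,
                          tl_plus = if (leak) config$fc_tl_us else Inf)
  conv_state <- list(
    vm = lapply(seq_len(n_fm), function(i) matrix(0, side, side)),
    tl = lapply(seq_len(n_fm), function(i) matrix(0, side, side)))
  conv_f <- function(ev, state, t_now) {
    x <- ev$x; y <- ev$y; s <- ev$sign
    emit <- list()
    for (fm in seq_len(n_fm)) {
      km <- config$bank[[fm]]
      for (yo in max(0, y - k + 1):min(side - 1, y)) {
        for (xo in max(0, x - k + 1):min(side - 1, x)) {
          st <- list(vm = state$vm[[fm]][yo + 1, xo + 1],
                     t_last = state$tl[[fm]][yo + 1, xo + 1],
                     t_refrac_end = -Inf)
          r <- lif_receive(st, c1_par, km[y - yo + 1, x - xo + 1], s, t_now)
          state$vm[[fm]][yo + 1, xo + 1] <- r$state$vm
          state$tl[[fm]][yo + 1, xo + 1] <- r$state$t_last
          if (r$spike != 0) {
            emit[[length(emit) + 1L]] <-
              tibble(t = t_now, x = xo, y = yo, fm = fm - 1, sign = r$spike)
          }
        }
      }
    }
    list(state = state, emit = bind_rows(emit))
  }
  pool_f <- function(ev, state, t_now) {
    list(emit = tibble(t = t_now, x = ev$x %/% config$pool,
                       y = ev$y %/% config$pool, fm = ev$fm, sign = ev$sign))
  }
  flat_f <- function(ev, state, t_now) {
    list(emit = tibble(t = t_now,
                       idx = flatten_index(ev$fm, ev$x, ev$y, pside),
                       sign = ev$sign))
  }
  nl <- netlist() |>
    nl_node("fc_out") |> nl_node("flatten") |> nl_node("s1") |>
    nl_node("c1") |>
    nl_source("input", unclass_stream(stream)[c("t", "x", "y", "sign")])
  if (!is.null(weights)) {
    fc_state <- list(vm = numeric(nrow(weights)),
                     tl = numeric(nrow(weights)))
    fc_f <- function(ev, state, t_now) {
      emit <- list()
      for (c in seq_len(nrow(weights))) {
        st <- list(vm = state$vm[c], t_last = state$tl[c], t_refrac_end = -Inf)
        r <- lif_receive(st, fc_par, weights[c, ev$idx + 1], ev$sign, t_now)
        state$vm[c] <- r$state$vm
        state$tl[c] <- r$state$t_last
        if (r$spike > 0) {
          emit[[length(emit) + 1L]] <- tibble(t = t_now, class = c - 1)
        }
      }
      list(state = state, emit = bind_rows(emit))
    }
    nl <- nl_module(nl, "classifier", "flatten", "fc_out", fc_f,
                    state = fc_state)
  }
  nl |>
    nl_module("conv", "input", "c1", conv_f, state = conv_state) |>
    nl_module("pool", "c1", "s1", pool_f) |>
    nl_module("flatten", "s1", "flatten", flat_f)
}
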