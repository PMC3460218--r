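#' Symbol detection neurons
#'
#' A symbol detector is a simple matched perceptron: it fires when a
#' specific slot's activation has normalized overlap of at least
#' `threshold` with a specific symbol's piece. Slots normally sit exactly
#' on attractor pieces, so the default threshold of 0.9 leaves a margin
#' for transient noise while a blank slot (overlap 0) never triggers.
#'
#' @param k Partition id the detector watches.
#' @param symbol Symbol name it matches.
#' @param threshold Normalized-overlap firing threshold in (0, 1].
#' @return Object of class `dpaan_sd`.
#' @export
symbol_detector <- function(k, symbol, threshold = 0.9) {
  if (threshold <= 0 || threshold > 1) stopf("threshold must lie in (0, 1]")
  structure(list(k = as.integer(k), symbol = as.character(symbol),
                 threshold = threshold),
            class = "dpaan_sd")
}

sd_name <- function(d) paste0("sd_", d$k, "_", d$symbol)

#' Evaluate a bank of symbol detectors
#'
#' @param net A `dpaan` network (or a `dpaan_vocab`).
#' @param state A `dpaan_state`.
#' @param detectors List of [symbol_detector()] objects.
#' @return Named integer 0/1 vector, names `"sd_k_symbol"`.
#' @export
symbol_detection <- function(net, state, detectors) {
  vocab <- if (inherits(net, "dpaan")) net$vocab else net
  out <- vapply(detectors, function(d) {
    piece <- vocab_piece(vocab, d$symbol, d$k)
    as.integer(slot_overlap(state, d$k, piece) >= d$threshold)
  }, integer(1))
  names(out) <- vapply(detectors, sd_name, character(1))
  out
}

#' Production-rule condition inputs
#'
#' A production neuron is a linear summing, thresholded unit receiving
#' signed synapses from equality-detection and symbol-detection neurons.
#' `eq_input(k, kp)` wires it to the equality neuron of the slot pair;
#' `sd_input(k, symbol)` to a symbol detector. A weight of `-1` makes the
#' input a veto: an active vetoing neuron subtracts from the net input and
#' can keep the rule below threshold regardless of its other conditions.
#'
#' @param k,kp Partition ids.
#' @param symbol Symbol name.
#' @param weight `+1` (required condition) or `-1` (veto).
#' @return A condition-input descriptor used by [rule()].
#' @export
eq_input <- function(k, kp, weight = 1) {
  structure(list(type = "eq", k = as.integer(min(k, kp)),
                 kp = as.integer(max(k, kp)), weight = weight),
            class = "dpaan_rule_input")
}

#' @rdname eq_input
#' @export
sd_input <- function(k, symbol, weight = 1) {
  structure(list(type = "sd", k = as.integer(k),
                 symbol = as.character(symbol), weight = weight),
            class = "dpaan_rule_input")
}

#' Production-rule actions
#'
#' The then-clause of a production is an ordered list of actions:
#' `action_set` overwrites a slot with a symbol (the `Set` control
#' signal), `action_transfer` activates a directed transfer-control gate
#' and runs the slot-to-slot transfer, and `action_dm` requests a
#' declarative-memory retrieval, blanking the listed DM slots beforehand
#' so the recall can fill them in.
#'
#' @param k Target slot of a set.
#' @param symbol Symbol to write.
#' @param from,to Transfer source and target slots.
#' @param blank Integer ids of slots to blank before the retrieval.
#' @return An action descriptor used by [rule()].
#' @export
action_set <- function(k, symbol) {
  structure(list(type = "set", k = as.integer(k),
                 symbol = as.character(symbol)),
            class = "dpaan_action")
}

#' @rdname action_set
#' @export
action_transfer <- function(from, to) {
  structure(list(type = "transfer", from = as.integer(from),
                 to = as.integer(to)),
            class = "dpaan_action")
}

#' @rdname action_set
#' @export
action_dm <- function(blank = integer()) {
  structure(list(type = "dm", blank = as.integer(blank)),
            class = "dpaan_action")
}

#' Define a production rule
#'
#' @param name Rule name.
#' @param inputs List of [eq_input()] / [sd_input()] signed conditions
#'   (at least one).
#' @param threshold Integer firing threshold (>= 1); the rule fires when
#'   the signed sum of its inputs reaches it. It must be reachable from
#'   the positive inputs alone — negative weights act only as vetoes.
#' @param actions Ordered list of actions ([action_set()],
#'   [action_transfer()], [action_dm()]). May be empty.
#' @param halt Should firing this rule stop a run loop (e.g. an ACT-R
#'   "stop" production)?
#' @return Object of class `dpaan_rule`.
#' @export
rule <- function(name, inputs, threshold, actions = list(), halt = FALSE) {
  if (length(inputs) < 1L) stopf("a rule needs at least one input")
  if (threshold < 1) stopf("rule threshold must be at least 1")
  pos <- sum(vapply(inputs, function(i) max(i$weight, 0), numeric(1)))
  if (pos < threshold) {
    stopf("rule '%s' can never fire: positive input weights sum to %g < threshold %g",
          name, pos, threshold)
  }
  structure(list(name = name, inputs = inputs, threshold = threshold,
                 actions = actions, halt = isTRUE(halt)),
            class = "dpaan_rule")
}

#' @export
print.dpaan_rule <- function(x, ...) {
  cond <- vapply(x$inputs, function(i) {
    lab <- if (i$type == "eq") sprintf("Eq_%d,%d", i$k, i$kp)
           else sprintf("SD_%d,\"%s\"", i$k, i$symbol)
    paste0(ifelse(i$weight >= 0, "+", "-"), abs(i$weight), " ", lab)
  }, character(1))
  cat(sprintf("Rule '%s': %s >= %g -> %d action(s)%s\n", x$name,
              paste(cond, collapse = " "), x$threshold, length(x$actions),
              if (x$halt) " [halt]" else ""))
  invisible(x)
}

# Detectors a rule bank needs, deduplicated.
rules_detectors <- function(rules, threshold = 0.9) {
  seen <- character()
  out <- list()
  for (r in rules) {
    for (i in r$inputs) {
      if (i$type == "sd") {
        nm <- paste0(i$k, ":", i$symbol)
        if (!nm %in% seen) {
          seen <- c(seen, nm)
          out[[length(out) + 1L]] <-
            symbol_detector(i$k, i$symbol, threshold)
        }
      }
    }
  }
  out
}

#' Match productions against the current readouts
#'
#' Each rule's net input is the signed sum of its equality and
#' symbol-detection inputs; a rule is satisfied when the net input reaches
#' its threshold. Conflict resolution among satisfied rules: highest net
#' input wins, ties break by definition order. A pure function of its
#' arguments.
#'
#' @param rules List of [rule()] objects.
#' @param eq Equality vector from [equality_readout()].
#' @param sd Symbol-detection vector from [symbol_detection()].
#' @return List with `fired` (rule name or `NA_character_`), `net`
#'   (named net inputs) and `satisfied` (named logical).
#' @export
evaluate_productions <- function(rules, eq, sd) {
  if (length(rules) == 0L) {
    return(list(fired = NA_character_, net = numeric(0),
                satisfied = logical(0)))
  }
  net <- vapply(rules, function(r) {
    sum(vapply(r$inputs, function(i) {
      val <- if (i$type == "eq") {
        eq_bit(eq, i$k, i$kp)
      } else {
        nm <- paste0("sd_", i$k, "_", i$symbol)
        if (!nm %in% names(sd)) stopf("no symbol detector '%s'", nm)
        unname(sd[[nm]])
      }
      i$weight * val
    }, numeric(1)))
  }, numeric(1))
  names(net) <- vapply(rules, `[[`, character(1), "name")
  thr <- vapply(rules, `[[`, numeric(1), "threshold")
  satisfied <- net >= thr
  fired <- if (any(satisfied)) {
    cand <- which(satisfied)
    names(net)[cand[which.max(net[cand])]]  # first max: definition order
  } else {
    NA_character_
  }
  list(fired = fired, net = net, satisfied = satisfied)
}

#' Execute a production's actions
#'
#' Set actions are applied first, then transfers in their listed order
#' (each a full slot-to-slot transfer with the given step budget); a
#' declarative-memory action is not executed here but returned as a
#' request for the runtime to schedule.
#'
#' @param net A `dpaan` network.
#' @param state A `dpaan_state`.
#' @param actions Ordered action list.
#' @param gates Background gate configuration (default: isolated slots).
#' @param transfer_steps Settle budget per transfer.
#' @param trace Record transfer trajectories?
#' @return List with `state`, `dm_requested` (flag), `dm_blank` (slots the
#'   DM action wants blanked) and, when traced, `trace` rows.
#' @export
execute_actions <- function(net, state, actions, gates = NULL,
                            transfer_steps = 40L, trace = FALSE) {
  if (is.null(gates)) gates <- gate_matrix(state$layout$K)
  dm_requested <- FALSE
  dm_blank <- integer()
  rows <- NULL
  sets <- Filter(function(a) a$type == "set", actions)
  rest <- Filter(function(a) a$type != "set", actions)
  for (a in sets) state <- set_slot(state, a$k, a$symbol, net)
  for (a in rest) {
    if (a$type == "transfer") {
      tr <- transfer(net, state, gates = gates, from = a$from, to = a$to,
                     steps = transfer_steps, trace = trace)
      state <- tr$state
      if (trace) rows <- rbind(rows, tr$trace)
    } else if (a$type == "dm") {
      dm_requested <- TRUE
      dm_blank <- union(dm_blank, a$blank)
    }
  }
  list(state = state, dm_requested = dm_requested, dm_blank = dm_blank,
       trace = rows)
}
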