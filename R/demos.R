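#' Perceptual binding demonstration
#'
#' Five slots of `slot_size` neurons represent the colour and shape of
#' two attended objects (slots 1-4) plus a vocalization buffer (slot 5).
#' The vocabulary is "red", "blue", "square", "circle". The scene is a
#' red circle and a red square: slot 1 = red, slot 2 = circle, slot 3 =
#' red, slot 4 = square, slot 5 blank. All between-slot synapse blocks
#' are masked off except the block projecting from slot 1 to slot 5, so
#' the network holds slots 1-4 constant while attractor completion
#' transfers "red" into the vocalization slot. The equality neurons start
#' with only the (1,3) pair active — the two objects share a colour — and
#' end with (1,3), (1,5) and (3,5) active once the transfer completes.
#'
#' @param seed Integer run seed.
#' @param slot_size Neurons per slot (default 100).
#' @param steps Settle budget (default 40).
#' @return Object of class `dpaan_run` whose `report` element gives the
#'   initial and final active equality sets and decoded slots.
#' @export
run_binding_demo <- function(seed = 1L, slot_size = 100L, steps = 40L) {
  symbols <- c("red", "blue", "square", "circle")
  net <- dpaan(rep(slot_size, 5L), symbols, seed = seed)
  st <- new_state(net)
  st <- set_slot(st, 1, "red", net)
  st <- set_slot(st, 2, "circle", net)
  st <- set_slot(st, 3, "red", net)
  st <- set_slot(st, 4, "square", net)
  gates <- open_gate(gate_matrix(net), from = 1, to = 5)
  eq0 <- equality_readout(net, st)
  dec0 <- decode_slots(st, net)
  traj <- settle(net, st, gates = gates, max_steps = steps, trace = TRUE)
  eq1 <- equality_readout(net, traj$state)
  dec1 <- decode_slots(traj$state, net)
  report <- list(
    initial_eq = names(eq0)[eq0 == 1],
    final_eq = names(eq1)[eq1 == 1],
    initial_decoded = dec0,
    final_decoded = dec1,
    converged = traj$converged,
    steps = traj$steps
  )
  structure(list(
    raster = traj$trace,
    events = list(list(cycle = 1L, fired = NA_character_,
                       eq = as.list(eq1), sd = list(),
                       decoded = as.list(dec1), halt = FALSE)),
    fired = NA_character_, decoded = rbind(dec1), halted = FALSE,
    cycles = 1L, report = report,
    config = list(model = "binding", partition_sizes = rep(slot_size, 5L),
                  slot_names = paste0("X", 1:5), symbols = symbols,
                  coding_level = 0.5,
                  init = c("red", "circle", "red", "square", NA),
                  schedule = list(steps = steps)),
    seed = as.integer(seed)
  ), class = "dpaan_run")
}

jealousy_vocab <- c("John", "Mary", "Sam", "Leela", "Fry", "Zap", "Kif",
                    "Amy", "who")

#' The Jealousy rule as a production
#'
#' "If X1 loves X2, X3 loves X4, X5 is jealous of X6, X1 = X5, X2 = X3,
#' X1 != X4 and X6 = 'who', then transfer X4 to X6." Wired as a single
#' thresholded neuron: +1 synapses from the (1,5) and (2,3) equality
#' neurons and from the symbol detector for "who" on slot 6, a -1 veto
#' synapse from the (1,4) equality neuron, firing threshold 3.
#'
#' @return A [rule()].
#' @export
jealousy_rule <- function() {
  rule("jealousy",
       inputs = list(eq_input(1, 5), eq_input(2, 3),
                     eq_input(1, 4, weight = -1),
                     sd_input(6, "who")),
       threshold = 3,
       actions = list(action_transfer(4, 6)))
}

#' Jealousy-rule demonstration
#'
#' Six slots hold the roles of "X1 loves X2; X3 loves X4; X5 is jealous
#' of X6 = who?" over a nine-name vocabulary. In the `"jealous"` scenario
#' (John, Mary, Mary, Sam, John, who) all conditions hold and the rule
#' transfers "Sam" into slot 6. In the `"mutual"` scenario the love is
#' mutual (slot 4 = John), the (1,4) equality veto blocks the rule, and
#' slot 6 keeps "who".
#'
#' @param scenario `"jealous"`, `"mutual"`, or `"custom"` with
#'   `assignment`.
#' @param seed Integer run seed.
#' @param slot_size Neurons per slot.
#' @param assignment For `scenario = "custom"`: character vector of six
#'   names from the demo vocabulary.
#' @return List of class `dpaan_report`: `fired` (logical), `slot6`
#'   (final decode), `net` (rule net input), `eq`, `sd`, `assignment`.
#' @export
run_jealousy_demo <- function(scenario = c("jealous", "mutual", "custom"),
                              seed = 1L, slot_size = 100L,
                              assignment = NULL) {
  scenario <- match.arg(scenario)
  assignment <- switch(scenario,
    jealous = c("John", "Mary", "Mary", "Sam", "John", "who"),
    mutual = c("John", "Mary", "Mary", "John", "John", "who"),
    custom = {
      if (length(assignment) != 6L) {
        stopf("custom scenario needs six slot assignments")
      }
      bad <- setdiff(assignment, jealousy_vocab)
      if (length(bad)) stopf("unknown names: %s", paste(bad, collapse = ", "))
      assignment
    })
  net <- dpaan(rep(slot_size, 6L), jealousy_vocab, seed = seed)
  st <- new_state(net)
  for (k in 1:6) st <- set_slot(st, k, assignment[k], net)
  r <- jealousy_rule()
  eq <- equality_readout(net, st)
  sd <- symbol_detection(net, st, rules_detectors(list(r)))
  ev <- evaluate_productions(list(r), eq, sd)
  if (!is.na(ev$fired)) {
    st <- execute_actions(net, st, r$actions)$state
  }
  structure(list(
    scenario = scenario, assignment = assignment,
    fired = !is.na(ev$fired), net = unname(ev$net["jealousy"]),
    slot6 = unname(decode_slot(st, 6, net)),
    eq = eq, sd = sd, decoded = decode_slots(st, net),
    seed = as.integer(seed)
  ), class = "dpaan_report")
}

#' @export
print.dpaan_report <- function(x, ...) {
  cat(sprintf("Jealousy demo ('%s' scenario): rule %s; slot 6 = \"%s\"\n",
              x$scenario, if (x$fired) "FIRED" else "did not fire",
              x$slot6))
  invisible(x)
}

#' Counting demonstration
#'
#' Builds and runs the Count Model (see [build_count_model()]) and
#' attaches a per-cycle report: the fired production, the decoded count
#' slot, the number of increment firings and the traversed count
#' sequence.
#'
#' @param start,end Number names ("one" ... "eight"), start before end.
#' @param seed Integer run seed.
#' @param slot_size Neurons per slot.
#' @param schedule A [cycle_schedule()].
#' @param trace Record the activity raster?
#' @return A `dpaan_run` with an additional `report` element.
#' @export
run_count_demo <- function(start = "two", end = "seven", seed = 1L,
                           slot_size = 100L, schedule = cycle_schedule(),
                           trace = TRUE) {
  model <- build_count_model(start, end, slot_size = slot_size,
                             schedule = schedule)
  run <- run_model(model, seed = seed, trace = trace)
  counts <- run$decoded[, 4L]
  run$report <- list(
    start = start, end = end,
    fired = run$fired,
    increments = sum(run$fired == "increment", na.rm = TRUE),
    cycles = run$cycles,
    halted = run$halted,
    count_sequence = unique(counts[!is.na(counts) & counts != "nil"]),
    final_count = counts[length(counts)]
  )
  run
}
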