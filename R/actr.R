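#' Timing of one match-execute cycle
#'
#' Step budgets for the phases of a production cycle: a pre-match settle,
#' a per-transfer completion budget, a blank period before a
#' declarative-memory retrieval, and a post-retrieval settle. The defaults
#' (10 / 40 / 5 / 5 simulated time steps) are the schedule of the
#' reference counting simulation.
#'
#' @param pre_match Settle steps before production matching.
#' @param transfer_steps Settle budget per slot-to-slot transfer.
#' @param blank_steps Steps the retrieval slots stay blank before recall.
#' @param post_steps Settle steps after the recall.
#' @param max_cycles Maximum number of match-execute cycles in a run.
#' @return List of class `dpaan_schedule`.
#' @export
cycle_schedule <- function(pre_match = 10L, transfer_steps = 40L,
                           blank_steps = 5L, post_steps = 5L,
                           max_cycles = 20L) {
  vals <- c(pre_match, transfer_steps, blank_steps, post_steps, max_cycles)
  if (any(vals < 1L)) stopf("all schedule parameters must be positive")
  structure(list(pre_match = as.integer(pre_match),
                 transfer_steps = as.integer(transfer_steps),
                 blank_steps = as.integer(blank_steps),
                 post_steps = as.integer(post_steps),
                 max_cycles = as.integer(max_cycles)),
            class = "dpaan_schedule")
}

count_model_numbers <- c("one", "two", "three", "four", "five", "six",
                         "seven", "eight")

#' Build the ACT-R Count Model
#'
#' The Count Model counts aloud from one number to another. Its goal
#' module has four slots (IsA / start / end / count, partitions 1-4) and
#' its declarative-memory module three (IsA / first / second, partitions
#' 5-7). The vocabulary holds 11 symbols: the numbers "one" through
#' "eight" plus "count-from", "count-order" and "nil". Declarative memory
#' stores the seven count-order facts (one precedes two, ..., seven
#' precedes eight). Three productions drive the behaviour:
#'
#' * **start** (threshold 2): if the goal IsA slot holds "count-from" and
#'   the count slot holds "nil", set the DM IsA slot to "count-order",
#'   transfer start to count (2 to 4) and start to DM-first (2 to 6), and
#'   request a retrieval.
#' * **increment** (threshold 3): if goal IsA is "count-from", DM IsA is
#'   "count-order", count equals DM-first (equality 4,6) and count does
#'   *not* equal end (a -1 veto synapse from equality 3,4), transfer
#'   DM-second to count (7 to 4) and to DM-first (7 to 6) and request a
#'   retrieval.
#' * **stop** (threshold 2): if goal IsA is "count-from" and count equals
#'   end, halt the run.
#'
#' A retrieval request blanks the DM "second" slot (partition 7) before
#' recall, so the store completes it from the count-order cue.
#'
#' @param start,end Number names from "one" to "eight"; `start` must
#'   precede `end` in counting order.
#' @param slot_size Neurons per partition (default 100).
#' @param coding_level Fraction of active units per pattern.
#' @param schedule A [cycle_schedule()].
#' @return Object of class `dpaan_model`: list with `name`,
#'   `partition_sizes`, `slot_names`, `symbols`, `coding_level`, `init`
#'   (initial slot assignment), `chunks`, `dm_slots`, `rules`,
#'   `detectors` and `schedule`.
#' @examples
#' m <- build_count_model("two", "seven")
#' m$init
#' @export
build_count_model <- function(start = "two", end = "seven",
                              slot_size = 100L, coding_level = 0.5,
                              schedule = cycle_schedule()) {
  i <- match(start, count_model_numbers)
  j <- match(end, count_model_numbers)
  if (is.na(i) || is.na(j)) {
    stopf("start and end must be one of: %s",
          paste(count_model_numbers, collapse = ", "))
  }
  if (i >= j) stopf("start ('%s') must precede end ('%s')", start, end)
  chunks <- lapply(seq_len(length(count_model_numbers) - 1L), function(n) {
    dm_chunk(IsA = "count-order",
             first = count_model_numbers[n],
             second = count_model_numbers[n + 1L])
  })
  rules <- list(
    rule("start",
         inputs = list(sd_input(1, "count-from"), sd_input(4, "nil")),
         threshold = 2,
         actions = list(action_set(5, "count-order"),
                        action_transfer(2, 4),
                        action_transfer(2, 6),
                        action_dm(blank = 7L))),
    rule("increment",
         inputs = list(sd_input(1, "count-from"),
                       sd_input(5, "count-order"),
                       eq_input(3, 4, weight = -1),
                       eq_input(4, 6, weight = 1)),
         threshold = 3,
         actions = list(action_transfer(7, 4),
                        action_transfer(7, 6),
                        action_dm(blank = 7L))),
    rule("stop",
         inputs = list(sd_input(1, "count-from"), eq_input(3, 4)),
         threshold = 2,
         actions = list(), halt = TRUE)
  )
  structure(list(
    name = "count",
    partition_sizes = rep(as.integer(slot_size), 7L),
    slot_names = c("IsA", "start", "end", "count",
                   "dm_IsA", "dm_first", "dm_second"),
    symbols = c(count_model_numbers, "count-from", "count-order", "nil"),
    coding_level = coding_level,
    init = c("count-from", start, end, "nil", "nil", "nil", "nil"),
    chunks = chunks,
    dm_slots = 5:7,
    rules = rules,
    detectors = rules_detectors(rules),
    schedule = schedule
  ), class = "dpaan_model")
}

#' @export
print.dpaan_model <- function(x, ...) {
  cat(sprintf("Model '%s': %d slots, %d symbols, %d chunk(s), %d rule(s)\n",
              x$name, length(x$partition_sizes), length(x$symbols),
              length(x$chunks), length(x$rules)))
  invisible(x)
}

# Initial network state from a model's slot assignment.
model_initial_state <- function(net, model) {
  st <- new_state(net)
  for (k in seq_along(model$init)) {
    if (!is.na(model$init[k])) st <- set_slot(st, k, model$init[k], net)
  }
  st
}

#' Run one match-execute cycle
#'
#' The four phases of a cognition step: (1) *matching* — the partitioned
#' network settles with all between-slot gates off, then the equality and
#' symbol-detection readouts drive the production neurons and the winning
#' production (if any) is selected; (2) *pre-retrieval transfers* — the
#' fired production's set actions and slot-to-slot transfers run; (3)
#' *retrieval* — if requested, the production's retrieval slots are
#' blanked for a few steps and the closest declarative chunk completes
#' them; (4) *post-retrieval settle*.
#'
#' @param net A `dpaan` network trained on the model's vocabulary.
#' @param model A `dpaan_model`.
#' @param state Current `dpaan_state`.
#' @param store A [dm_store()] (`NULL` if the model has no chunks).
#' @param schedule A [cycle_schedule()]; defaults to the model's.
#' @param trace Record the activity raster of the cycle?
#' @return List with `state`, `events` (fired rule, net inputs, equality
#'   and symbol-detection readouts, decoded slots, halt flag) and `raster`
#'   (matrix of the cycle's timesteps when traced).
#' @export
run_cycle <- function(net, model, state, store = NULL,
                      schedule = model$schedule, trace = FALSE) {
  gates <- gate_matrix(state$layout$K)
  rows <- NULL
  add <- function(tr) {
    # drop the incoming state row so segments concatenate cleanly
    if (trace && !is.null(tr$trace)) {
      rows <<- rbind(rows, tr$trace[-1L, , drop = FALSE])
    }
  }
  # matching phase
  tr <- settle(net, state, gates = gates, max_steps = schedule$pre_match,
               trace = trace)
  state <- tr$state
  add(tr)
  eq <- equality_readout(net, state)
  sd <- symbol_detection(net, state, model$detectors)
  ev <- evaluate_productions(model$rules, eq, sd)
  halt <- FALSE
  retrieved <- NA_integer_
  if (!is.na(ev$fired)) {
    r <- model$rules[[match(ev$fired, vapply(model$rules, `[[`,
                                             character(1), "name"))]]
    halt <- r$halt
    ex <- execute_actions(net, state, r$actions, gates = gates,
                          transfer_steps = schedule$transfer_steps,
                          trace = trace)
    state <- ex$state
    if (trace && !is.null(ex$trace)) rows <- rbind(rows, ex$trace)
    if (ex$dm_requested) {
      if (is.null(store)) stopf("rule '%s' requested a DM retrieval but no store was given", ev$fired)
      for (k in ex$dm_blank) state <- blank_slot(state, k)
      tr <- settle(net, state, gates = gates,
                   max_steps = schedule$blank_steps, trace = trace)
      state <- tr$state
      add(tr)
      ret <- dm_retrieve(net, state, store)
      state <- ret$state
      retrieved <- ret$chunk
      tr <- settle(net, state, gates = gates,
                   max_steps = schedule$post_steps, trace = trace)
      state <- tr$state
      add(tr)
    }
  }
  events <- list(fired = ev$fired, net = as.list(ev$net),
                 eq = as.list(eq), sd = as.list(sd),
                 retrieved_chunk = retrieved,
                 decoded = as.list(decode_slots(state, net$vocab)),
                 halt = halt)
  list(state = state, events = events, raster = rows)
}

#' Run a model to completion
#'
#' Repeats the match-execute cycle until a halting production fires or
#' the cycle budget is exhausted. The run trace holds the full activity
#' raster (one row per simulated time step) plus per-cycle event
#' summaries: the fired production and the symbolic interpretation of
#' every slot.
#'
#' @param model A `dpaan_model` (e.g. [build_count_model()]).
#' @param seed Integer run seed for the vocabulary patterns.
#' @param schedule A [cycle_schedule()]; defaults to the model's.
#' @param net Optional pre-built `dpaan` network for the model's layout
#'   and vocabulary (rebuilt from `seed` when `NULL`).
#' @param trace Record the activity raster?
#' @return Object of class `dpaan_run`: list with `raster`, `events` (one
#'   record per cycle), `fired` (character vector of fired rules,
#'   `NA` where none matched), `decoded` (cycles x slots character
#'   matrix), `halted`, `cycles`, `config` and `seed`.
#' @examples
#' \donttest{
#' run <- run_model(build_count_model("two", "seven"), seed = 1)
#' run$fired
#' }
#' @export
run_model <- function(model, seed = 1L, schedule = model$schedule,
                      net = NULL, trace = TRUE) {
  stopifnot(inherits(model, "dpaan_model"))
  if (is.null(net)) {
    net <- dpaan(model$partition_sizes, model$symbols,
                 coding_level = model$coding_level, seed = seed)
  }
  store <- if (length(model$chunks)) dm_store(net, model$chunks,
                                              model$dm_slots)
  state <- model_initial_state(net, model)
  raster <- if (trace) matrix(state$x, nrow = 1L) else NULL
  events <- list()
  fired <- character()
  decoded <- NULL
  halted <- FALSE
  for (cyc in seq_len(schedule$max_cycles)) {
    out <- run_cycle(net, model, state, store, schedule, trace = trace)
    state <- out$state
    events[[cyc]] <- c(list(cycle = cyc), out$events)
    fired[cyc] <- out$events$fired
    decoded <- rbind(decoded, unlist(out$events$decoded))
    if (trace && !is.null(out$raster)) raster <- rbind(raster, out$raster)
    if (out$events$halt) {
      halted <- TRUE
      break
    }
  }
  structure(list(
    raster = raster, events = events, fired = fired, decoded = decoded,
    halted = halted, cycles = length(fired),
    config = list(model = model$name,
                  partition_sizes = model$partition_sizes,
                  slot_names = model$slot_names,
                  symbols = model$symbols,
                  coding_level = model$coding_level,
                  init = model$init,
                  schedule = unclass(schedule)),
    seed = as.integer(seed)
  ), class = "dpaan_run")
}

#' @export
print.dpaan_run <- function(x, ...) {
  if (identical(x$config$model, "binding")) {
    cat("Binding demo run\n")
    cat("  initial equality set:",
        paste(x$report$initial_eq, collapse = ", "), "\n")
    cat("  final equality set:  ",
        paste(x$report$final_eq, collapse = ", "), "\n")
    cat("  final decoded slots: ",
        paste(x$report$final_decoded, collapse = ", "), "\n")
  } else {
    cat(sprintf("Model run: %d cycle(s), %s\n", x$cycles,
                if (x$halted) "halted by a stop production"
                else "cycle budget exhausted"))
    cat("  fired:", paste(ifelse(is.na(x$fired), "<none>", x$fired),
                          collapse = ", "), "\n")
  }
  if (!is.null(x$raster)) {
    cat(sprintf("  raster: %d timesteps x %d neurons\n",
                nrow(x$raster), ncol(x$raster)))
  }
  invisible(x)
}
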