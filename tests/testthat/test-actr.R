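test_that("the count model initializes its goal and DM slots", {
  m <- build_count_model("two", "seven")
  expect_length(m$partition_sizes, 7L)
  expect_length(m$symbols, 11L)
  expect_length(m$chunks, 7L)
  net <- dpaan(m$partition_sizes, m$symbols, seed = 1)
  st <- dpaan:::model_initial_state(net, m)
  expect_identical(unname(decode_slots(st, net)[1:4]),
                   c("count-from", "two", "seven", "nil"))
  expect_error(build_count_model("four", "three"), "precede")
  expect_error(build_count_model("two", "two"), "precede")
  expect_error(build_count_model("zero", "two"), "must be one of")
})

test_that("schedule parameters must be positive", {
  expect_error(cycle_schedule(pre_match = 0), "positive")
  s <- cycle_schedule(pre_match = 3, transfer_steps = 20)
  expect_equal(s$pre_match, 3L)
  expect_equal(s$blank_steps, 5L)
})

test_that("cycle one fires start and loads the first count-order fact", {
  m <- build_count_model("two", "seven")
  net <- dpaan(m$partition_sizes, m$symbols, seed = 1)
  store <- dm_store(net, m$chunks, m$dm_slots)
  st <- dpaan:::model_initial_state(net, m)
  out <- run_cycle(net, m, st, store)
  expect_identical(out$events$fired, "start")
  dec <- unlist(out$events$decoded)
  expect_identical(unname(dec[4:7]),
                   c("two", "count-order", "two", "three"))
  expect_false(out$events$halt)
})

test_that("stop fires when the count slot reaches the end value", {
  m <- build_count_model("two", "seven")
  net <- dpaan(m$partition_sizes, m$symbols, seed = 1)
  store <- dm_store(net, m$chunks, m$dm_slots)
  st <- state_with(net, c("count-from", "two", "seven", "seven",
                          "count-order", "seven", "eight"))
  out <- run_cycle(net, m, st, store)
  expect_identical(out$events$fired, "stop")
  expect_true(out$events$halt)
  # stop has no actions: the decoded contents are unchanged
  expect_identical(unname(unlist(out$events$decoded)),
                   c("count-from", "two", "seven", "seven",
                     "count-order", "seven", "eight"))
})

test_that("a cycle with no matching rule leaves the state alone", {
  m <- build_count_model("two", "seven")
  net <- dpaan(m$partition_sizes, m$symbols, seed = 1)
  store <- dm_store(net, m$chunks, m$dm_slots)
  st <- state_with(net, c("one", "two", "seven", "one",
                          "nil", "nil", "nil"))
  out <- run_cycle(net, m, st, store)
  expect_true(is.na(out$events$fired))
  expect_identical(out$state$x, st$x)
})

test_that("counting from two to seven reproduces the reference trace", {
  run <- run_model(build_count_model("two", "seven"), seed = 1)
  expect_identical(run$fired,
                   c("start", rep("increment", 5), "stop"))
  expect_equal(run$cycles, 7L)
  expect_true(run$halted)
  counts <- run$decoded[, 4]
  expect_identical(unique(counts),
                   c("two", "three", "four", "five", "six", "seven"))
  # full raster: one column per neuron
  expect_equal(ncol(run$raster), 700L)
})

test_that("increment count and cycle count generalize over start/end pairs", {
  nums <- c("one", "two", "three", "four", "five", "six", "seven", "eight")
  for (seed in 0:4) {
    net <- dpaan(rep(100, 7),
                 build_count_model("one", "two")$symbols, seed = seed)
    for (i in seq_len(7)) {
      for (j in seq.int(i + 1, 8)) {
        run <- run_model(build_count_model(nums[i], nums[j]),
                         seed = seed, net = net, trace = FALSE)
        expect_equal(sum(run$fired == "increment", na.rm = TRUE), j - i)
        expect_equal(run$cycles, j - i + 2L)
        expect_true(run$halted)
        expect_identical(unname(run$decoded[run$cycles, 4]), nums[j])
        # after each retrieval the DM "second" slot holds the successor
        # of the DM "first" slot (when a fact for that cue is stored; the
        # final increment of a run ending at "eight" cues past the table)
        for (c in seq_len(run$cycles - 1L)) {
          first <- unname(run$decoded[c, 6])
          second <- unname(run$decoded[c, 7])
          if (!first %in% nums[1:7]) next
          expect_identical(second, nums[match(first, nums) + 1L])
        }
      }
    }
  }
})

test_that("the run loop flags cycle-budget exhaustion", {
  m <- build_count_model("two", "seven",
                         schedule = cycle_schedule(max_cycles = 2))
  run <- run_model(m, seed = 1, trace = FALSE)
  expect_false(run$halted)
  expect_equal(run$cycles, 2L)
})
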