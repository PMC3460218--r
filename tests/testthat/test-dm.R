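count_net <- function(seed = 1) {
  m <- build_count_model("two", "seven")
  net <- dpaan(m$partition_sizes, m$symbols, seed = seed)
  list(model = m, net = net,
       store = dm_store(net, m$chunks, m$dm_slots))
}

test_that("the seven count-order facts are stored as seven vectors", {
  cn <- count_net()
  expect_equal(nrow(cn$store$chunks), 7L)
  expect_identical(cn$store$slot_names, c("IsA", "first", "second"))
  # every stored vector decodes slotwise to its source chunk
  for (i in 1:7) {
    st <- new_state(cn$net)
    for (s in 1:3) {
      st$x[slot_index(cn$net$layout, cn$store$dm_slots[s])] <-
        cn$store$vectors[[s]][i, ]
    }
    expect_identical(unname(decode_slots(st, cn$net)[5:7]),
                     unname(cn$store$chunks[i, ]))
  }
})

test_that("store construction validates chunks", {
  cn <- count_net()
  expect_error(dm_store(cn$net, list(), 5:7), "at least one chunk")
  expect_error(dm_store(cn$net, list(dm_chunk(IsA = "count-order",
                                              first = "nine",
                                              second = "ten")), 5:7),
               "not in vocabulary")
  expect_error(dm_store(cn$net, list(dm_chunk(a = "one")), 5:7), "DM partitions")
  one <- dm_store(cn$net, list(dm_chunk(IsA = "count-order", first = "one",
                                        second = "two")), 5:7)
  expect_equal(nrow(one$chunks), 1L)
})

test_that("retrieval completes the blank slot from the cue", {
  cn <- count_net()
  st <- state_with(cn$net, c(NA, NA, NA, NA, "count-order", "three", NA))
  ret <- dm_retrieve(cn$net, st, cn$store)
  expect_identical(decode_slot(ret$state, 7, cn$net), "four")
  # non-blank DM slots and non-DM partitions are untouched
  expect_identical(ret$state$x[slot_index(cn$net$layout, 6)],
                   st$x[slot_index(cn$net$layout, 6)])
  expect_identical(ret$state$x[slot_index(cn$net$layout, 1)],
                   st$x[slot_index(cn$net$layout, 1)])
})

test_that("a complete exact cue leaves the state unchanged", {
  cn <- count_net()
  st <- state_with(cn$net, c(NA, NA, NA, NA, "count-order", "six", "seven"))
  ret <- dm_retrieve(cn$net, st, cn$store)
  expect_identical(ret$state$x, st$x)
  expect_equal(ret$chunk, 6L)
})

test_that("retrieval tolerates cue noise", {
  cn <- count_net()
  st <- state_with(cn$net, c(NA, NA, NA, NA, "count-order", "six", NA))
  idx6 <- slot_index(cn$net$layout, 6)
  st$x[idx6[1:5]] <- -st$x[idx6[1:5]]  # 5% unit noise on the first slot
  ret <- dm_retrieve(cn$net, st, cn$store)
  expect_identical(decode_slot(ret$state, 7, cn$net), "seven")
})

test_that("every stored chunk is recalled from its own noiseless cue", {
  cn <- count_net()
  for (i in 1:7) {
    st <- state_with(cn$net, c(NA, NA, NA, NA, "count-order",
                               cn$store$chunks[i, "first"], NA))
    ret <- dm_retrieve(cn$net, st, cn$store)
    expect_equal(ret$chunk, i)
    expect_identical(decode_slot(ret$state, 7, cn$net),
                     unname(cn$store$chunks[i, "second"]))
  }
})

test_that("degenerate retrievals error and duplicates tie by storage order", {
  cn <- count_net()
  st <- new_state(cn$net)
  expect_error(dm_retrieve(cn$net, st, cn$store), "blank")
  dup <- dm_store(cn$net, list(
    dm_chunk(IsA = "count-order", first = "one", second = "two"),
    dm_chunk(IsA = "count-order", first = "one", second = "two")
  ), 5:7)
  st2 <- state_with(cn$net, c(NA, NA, NA, NA, "count-order", "one", NA))
  expect_equal(dm_retrieve(cn$net, st2, dup)$chunk, 1L)
})
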