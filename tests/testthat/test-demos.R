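test_that("the binding demo transfers red into the vocalization slot", {
  b <- run_binding_demo(seed = 1)
  expect_identical(b$report$initial_eq, "eq_1_3")
  expect_identical(sort(b$report$final_eq),
                   c("eq_1_3", "eq_1_5", "eq_3_5"))
  # slots 1-4 decode identically at start and end
  expect_identical(b$report$initial_decoded[1:4], b$report$final_decoded[1:4])
  expect_identical(unname(b$report$final_decoded[5]), "red")
})

test_that("demo runs are seed-deterministic, symbolically seed-invariant", {
  b1 <- run_binding_demo(seed = 1)
  b2 <- run_binding_demo(seed = 1)
  expect_identical(b1$raster, b2$raster)
  b3 <- run_binding_demo(seed = 2)
  expect_false(identical(b1$raster, b3$raster))
  expect_identical(b1$report$final_eq, b3$report$final_eq)
  r1 <- run_count_demo("two", "four", seed = 1)
  r2 <- run_count_demo("two", "four", seed = 7)
  expect_false(identical(r1$raster, r2$raster))
  expect_identical(r1$report[c("fired", "increments", "cycles",
                               "count_sequence")],
                   r2$report[c("fired", "increments", "cycles",
                               "count_sequence")])
})

test_that("the jealousy demo fires only when the syntax is right", {
  j <- run_jealousy_demo("jealous", seed = 1)
  expect_true(j$fired)
  expect_identical(j$slot6, "Sam")
  jm <- run_jealousy_demo("mutual", seed = 1)
  expect_false(jm$fired)
  expect_identical(jm$slot6, "who")
  # slot 6 not holding "who" blocks the rule
  jc <- run_jealousy_demo("custom", seed = 1,
                          assignment = c("John", "Mary", "Mary", "Sam",
                                         "John", "Amy"))
  expect_false(jc$fired)
  expect_error(run_jealousy_demo("custom", assignment = c("Bob", "Mary",
                                                          "Mary", "Sam",
                                                          "John", "who")),
               "unknown names")
})

test_that("the count demo reports the reference behaviour", {
  r <- run_count_demo("two", "seven", seed = 1)
  expect_equal(r$report$increments, 5L)
  expect_equal(r$report$cycles, 7L)
  expect_identical(r$report$fired[7], "stop")
  expect_identical(r$report$count_sequence,
                   c("two", "three", "four", "five", "six", "seven"))
  r2 <- run_count_demo("five", "six", seed = 1, trace = FALSE)
  expect_equal(r2$report$increments, 1L)
})

test_that("exported traces round-trip through the text formats", {
  r <- run_count_demo("two", "three", seed = 1)
  dir <- withr::local_tempdir()
  export_trace(r, dir)
  back <- read_trace(dir)
  expect_identical(back$raster, r$raster)
  expect_identical(back$fired, r$fired)
  expect_identical(unname(back$decoded), unname(r$decoded))
  expect_identical(back$seed, r$seed)
  expect_equal(ncol(back$raster), 700L)
  # the raster file uses the 0/1/blank-marker alphabet
  first <- strsplit(readLines(file.path(dir, "raster.tsv"), n = 1), "\t")[[1]]
  expect_true(all(first %in% c("0", "1", ".")))
  # a second export of the reloaded trace is byte-identical
  dir2 <- withr::local_tempdir()
  export_trace(back, dir2)
  expect_identical(readLines(file.path(dir, "raster.tsv")),
                   readLines(file.path(dir2, "raster.tsv")))
  expect_identical(readLines(file.path(dir, "events.jsonl")),
                   readLines(file.path(dir2, "events.jsonl")))
})

test_that("an event-free trace exports and reloads as an empty log", {
  r <- structure(list(raster = NULL, events = list(), fired = character(),
                      decoded = NULL, halted = FALSE, cycles = 0L,
                      config = list(model = "empty"), seed = 1L),
                 class = "dpaan_run")
  dir <- withr::local_tempdir()
  export_trace(r, dir)
  back <- read_trace(dir)
  expect_length(back$events, 0L)
  expect_equal(nrow(back$raster), 0L)
})
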