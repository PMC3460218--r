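test_that("symbol detectors fire on their piece and stay quiet on blanks", {
  net <- tiny_net(c(100, 100), 3, seed = 1)
  det <- list(symbol_detector(1, "a"), symbol_detector(2, "b"))
  st <- set_slot(new_state(net), 1, "a", net)
  sd <- symbol_detection(net, st, det)
  expect_identical(unname(sd), c(1L, 0L))
  expect_identical(names(sd), c("sd_1_a", "sd_2_b"))
  # 5/100 flipped units still pass a 0.8 threshold
  st$x[1:5] <- -st$x[1:5]
  det08 <- list(symbol_detector(1, "a", threshold = 0.8))
  expect_identical(unname(symbol_detection(net, st, det08)), 1L)
  expect_error(symbol_detection(net, st, list(symbol_detector(1, "zz"))),
               "unknown symbol")
})

test_that("production evaluation sums signed inputs against a threshold", {
  r <- rule("inc",
            inputs = list(sd_input(1, "go"), eq_input(1, 2),
                          eq_input(1, 3, weight = -1)),
            threshold = 2)
  eq <- c(eq_1_2 = 1L, eq_1_3 = 0L)
  sd <- c(sd_1_go = 1L)
  ev <- evaluate_productions(list(r), eq, sd)
  expect_identical(ev$fired, "inc")
  expect_equal(unname(ev$net), 2)
  # an active veto input blocks firing regardless of positive inputs
  eq["eq_1_3"] <- 1L
  expect_true(is.na(evaluate_productions(list(r), eq, sd)$fired))
  # pure function: repeated calls agree
  expect_identical(evaluate_productions(list(r), eq, sd),
                   evaluate_productions(list(r), eq, sd))
  # empty rule list
  expect_true(is.na(evaluate_productions(list(), eq, sd)$fired))
})

test_that("a satisfied veto blocks firing over the full input truth table", {
  r <- rule("v", inputs = list(eq_input(1, 2), eq_input(1, 3),
                               eq_input(2, 3, weight = -1)),
            threshold = 2)
  for (a in 0:1) for (b in 0:1) for (v in 0:1) {
    eq <- c(eq_1_2 = a, eq_1_3 = b, eq_2_3 = v)
    fired <- !is.na(evaluate_productions(list(r), eq, integer(0))$fired)
    expect_identical(fired, a + b - v >= 2)
  }
})

test_that("conflict resolution picks the highest net input, then order", {
  r1 <- rule("low", inputs = list(eq_input(1, 2)), threshold = 1)
  r2 <- rule("high", inputs = list(eq_input(1, 2), eq_input(1, 3)),
             threshold = 1)
  eq <- c(eq_1_2 = 1L, eq_1_3 = 1L)
  expect_identical(evaluate_productions(list(r1, r2), eq, integer(0))$fired,
                   "high")
  # tie on net input: definition order wins
  r3 <- rule("also-low", inputs = list(eq_input(1, 3)), threshold = 1)
  eq2 <- c(eq_1_2 = 1L, eq_1_3 = 1L)
  expect_identical(evaluate_productions(list(r1, r3), eq2, integer(0))$fired,
                   "low")
})

test_that("rule construction validates threshold reachability", {
  expect_error(rule("r", list(eq_input(1, 2)), threshold = 0), "at least 1")
  expect_error(rule("r", list(), threshold = 1), "at least one input")
  # negative weights must never be needed to reach threshold
  expect_error(rule("r", list(eq_input(1, 2), eq_input(1, 3, weight = -1)),
                    threshold = 2),
               "never fire")
})

test_that("the jealousy rule matches its brute-force predicate oracle", {
  # all 256 assignments of slots 1-4 from a reduced 4-name vocabulary,
  # slot 5 fixed to "John", slot 6 = "who"; the equality readout comes
  # from the trained network, the prediction from the symbolic predicate
  # (s1 == s5) & (s2 == s3) & (s1 != s4)
  names4 <- c("John", "Mary", "Sam", "Leela")
  net <- dpaan(rep(60, 6), c(names4, "who"), seed = 1)
  r <- jealousy_rule()
  det <- list(symbol_detector(6, "who"))
  grid <- expand.grid(s1 = names4, s2 = names4, s3 = names4, s4 = names4,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    s <- unlist(grid[i, ])
    st <- state_with(net, c(s, "John", "who"))
    eq <- equality_readout(net, st)
    sd <- symbol_detection(net, st, det)
    fired <- !is.na(evaluate_productions(list(r), eq, sd)$fired)
    want <- (s[["s1"]] == "John") && (s[["s2"]] == s[["s3"]]) &&
      (s[["s1"]] != s[["s4"]])
    expect_identical(fired, want)
  }
})

test_that("actions apply sets first, then transfers, and flag DM requests", {
  net <- tiny_net(c(60, 60, 60), 4, seed = 6)
  st <- set_slot(new_state(net), 1, "b", net)
  out <- execute_actions(net, st,
                         list(action_transfer(1, 2), action_set(3, "d"),
                              action_dm(blank = 3L)))
  expect_identical(decode_slot(out$state, 2, net), "b")
  expect_identical(decode_slot(out$state, 3, net), "d")
  expect_true(out$dm_requested)
  expect_identical(out$dm_blank, 3L)
  # empty action list: state unchanged, flag clear
  out2 <- execute_actions(net, st, list())
  expect_identical(out2$state$x, st$x)
  expect_false(out2$dm_requested)
  # transferring from a blank slot propagates the error
  expect_error(execute_actions(net, st, list(action_transfer(2, 3))),
               "blank")
})
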