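test_that("structurally impossible precedence violations pass", {
  # B can only switch on after A is on, so A>=1-before-B>=1 must hold
  m <- toy_chain()
  p <- precedence_property(c("A", 1), c("B", 1), "a_before_b")
  v <- check_precedence(m, c(A = 0L, B = 0L), p)
  expect_identical(v$status, "pass")
})

test_that("precedence verdicts agree with simple-path enumeration on random
           networks", {
  n_checked <- 0L
  for (seed in 1:50) {
    for (sem in c("multilevel", "li_binary")) {
      m <- random_network(3L + seed %% 3L, sem, seed = 300 + seed)
      nn <- m$nodes$name
      ant <- c(nn[2], 1)
      cons <- c(nn[3], 1)
      p <- precedence_property(ant, cons, "rand")
      got <- check_precedence(m, stimulated_g1(m), p)$status
      want <- oracle_precedence(m, stimulated_g1(m), ant, cons)
      expect_identical(got, want, info = sprintf("%s seed %d", sem, seed))
      n_checked <- n_checked + 1L
    }
  }
  expect_identical(n_checked, 100L)
})

test_that("failed precedence checks ship shortest replayable witnesses", {
  m <- yeast_model("mangla")
  p <- precedence_property(c("Clb2", 1), c("Cdc20", 1), "clb2_before_cdc20")
  v <- check_precedence(m, stimulated_g1(m), p)
  expect_identical(v$status, "fail")
  ce <- v$counterexample
  expect_s3_class(ce, "ccn_trajectory")
  expect_true(replay_counterexample(m, ce))
  # the witness shows Cdc20 reaching 1 while Clb2 is still 0 throughout
  expect_true(all(ce$states[, "Clb2"] == 0))
  expect_identical(ce$states[nrow(ce$states), "Cdc20"], c(Cdc20 = 1L))
})

test_that("response checking flags oscillations that never discharge", {
  m <- toy_async_oscillator()
  # trigger X>=1 is reachable, obligation (0,0) is outside the oscillating SCC
  p <- response_property(c("X", 1), c(C = 0L, X = 0L), "x_leads_home")
  v <- check_response(m, stimulated_g1(m), p)
  expect_identical(v$status, "fail")
  expect_true(replay_counterexample(m, v$counterexample))
  # with an obligation inside the long-run SCC the property holds
  p2 <- response_property(c("X", 1), c("C", 1), "x_leads_c")
  expect_identical(check_response(m, stimulated_g1(m), p2)$status, "pass")
})

test_that("global-attractor checking distinguishes the three outcomes", {
  # pass: chain converges to (1,1)
  ch <- toy_chain()
  v <- check_global_attractor(ch, stimulated_g1(ch), c(A = 1L, B = 1L),
                              name = "chain_sink")
  expect_identical(v$status, "pass")
  # fail with a lasso: async oscillator never settles
  ao <- toy_async_oscillator()
  v2 <- check_global_attractor(ao, stimulated_g1(ao), stationary_g1(ao))
  expect_identical(v2$status, "fail")
  expect_identical(v2$note, "cycle outside target")
  # the lasso revisits a state (path + cycle)
  keys <- apply(v2$counterexample$states, 1, paste, collapse = "")
  expect_true(anyDuplicated(keys) > 0)
  # precondition: target must be a fixed point
  expect_error(check_global_attractor(ch, stimulated_g1(ch),
                                      c(A = 1L, B = 0L)),
               "not a fixed point")
})

test_that("the revised model satisfies every checkpoint ordering and the
           graded activation responses", {
  v <- check_properties(yeast_model("proposed"))
  td <- tidy(v)
  # all precedence (checkpoint ordering) properties hold exhaustively
  expect_true(all(td$status[td$type == "precedence"] == "pass"))
  # Cdc20 activation forces full Swi5 activation; full Swi5 forces Sic1
  expect_identical(td$status[td$property == "cdc20_leads_to_swi5"], "pass")
  expect_identical(td$status[td$property == "swi5_leads_to_sic1"], "pass")
})

test_that("the graded base model exhibits both documented hazards while
           the S/G2 checkpoint holds", {
  v <- check_properties(yeast_model("mangla"))
  td <- tidy(v)
  failing_groups <- unique(td$group[td$status == "fail"])
  # hazard 1 (metaphase ordering) and hazard 2 (telophase response) present
  expect_true(all(c("m_metaphase", "m_telophase") %in% failing_groups))
  # the S/G2 ordering checkpoint holds
  expect_identical(td$status[td$group == "s_g2"], "pass")
  # hazard 1 witness: Cdc20 reaches 1 with Clb2 still below 1
  vd <- v$verdicts[[which(td$property == "clb2_before_cdc20")]]
  expect_identical(vd$status, "fail")
  expect_true(replay_counterexample(yeast_model("mangla"), vd$counterexample))
  # the telophase group failure includes the return-to-G1 response
  expect_identical(td$status[td$property == "cdc20_leads_to_g1"], "fail")
})

test_that("the binary model fails the metaphase precedence and the global
           attractor", {
  m <- yeast_model("li")
  v <- check_properties(m)
  td <- tidy(v)
  expect_true("m_metaphase" %in% td$group[td$status == "fail"])
  expect_identical(td$status[td$property == "g1_global_attractor"], "fail")
  for (vd in v$verdicts) {
    if (vd$status == "fail" && !is.null(vd$counterexample)) {
      expect_true(replay_counterexample(m, vd$counterexample))
    }
  }
})

test_that("properties passing on the full async graph hold along the sync
           schedule too", {
  # sync is one asynchronous schedule (up to simultaneous updates), so a
  # precedence property passing exhaustively must hold on the sync path
  m <- yeast_model("proposed")
  tr <- simulate_model(m, stimulated_g1(m), "sync")
  td <- tidy(check_properties(m))
  props <- default_property_set(m)
  for (p in props[vapply(props, function(p) p$type == "precedence", TRUE)]) {
    stopifnot(td$status[td$property == p$name] == "pass")
    ant_t <- which(cond_holds(p$antecedent, tr$states, m))[1]
    cons_t <- which(cond_holds(p$consequent, tr$states, m))[1]
    if (!is.na(cons_t)) expect_lte(ant_t, cons_t)
  }
})

test_that("property configs load from JSON", {
  cfg <- tempfile(fileext = ".json")
  writeLines('[
    {"type": "precedence", "name": "p1", "group": "g",
     "antecedent": ["Clb2", 1], "consequent": ["Cdc20", 1]},
    {"type": "response", "name": "p2",
     "trigger": ["Cdc20", 1], "obligation": ["Swi5", 1]},
    {"type": "global_attractor", "name": "p3",
     "target": {"Cln3":0,"MBF":0,"SBF":0,"Cln2":0,"Cdh1":1,"Swi5":0,
                "Cdc20":0,"Clb5":0,"Sic1":1,"Clb2":0,"Mcm1":0}}
  ]', cfg)
  props <- load_properties(cfg)
  expect_length(props, 3)
  expect_identical(props[[1]]$type, "precedence")
  expect_identical(props[[1]]$group, "g")
  expect_identical(props[[2]]$obligation$node, "Swi5")
  v <- check_properties(yeast_model("proposed"), properties = props)
  expect_identical(nrow(tidy(v)), 3L)
})
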