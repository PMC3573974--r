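test_that("the graded update rule climbs, decays and clamps by one level", {
  nodes <- tibble::tibble(name = c("X", "Y"), max_level = c(2L, 1L),
                          self_degrading = FALSE)
  m <- network_model("toy", "multilevel", nodes,
                     tibble::tibble(from = "Y", to = "X", weight = "3"),
                     c(X = 0L, Y = 0L))
  # sum 3 >= theta_1: 0 -> 1 (one level only, never a jump to 2)
  expect_identical(local_target(m, c(X = 0L, Y = 1L), "X"), 1L)
  # sum 3 >= theta_2: 1 -> 2
  expect_identical(local_target(m, c(X = 1L, Y = 1L), "X"), 2L)
  # zero input: levels decay...
  expect_identical(local_target(m, c(X = 2L, Y = 0L), "X"), 1L)
  # ...but never below zero
  expect_identical(local_target(m, c(X = 0L, Y = 0L), "X"), 0L)
  expect_error(local_target(m, c(X = 0L, Y = 0L), "Z"), "unknown node")
})

test_that("the binary rule ties hold unless the node is self-degrading", {
  nodes <- tibble::tibble(name = c("P", "Q"), max_level = 1L,
                          self_degrading = c(TRUE, FALSE))
  m <- network_model("toy", "li_binary", nodes,
                     tibble::tibble(from = "P", to = "Q", weight = "-1"),
                     c(P = 0L, Q = 0L))
  # zero weighted sum: self-degrading P decays, plain Q holds
  expect_identical(local_target(m, c(P = 1L, Q = 1L), "P"), 0L)
  expect_identical(local_target(m, c(P = 0L, Q = 1L), "Q"), 1L)
  # negative sum switches off
  expect_identical(local_target(m, c(P = 1L, Q = 1L), "Q"), 0L)
})

test_that("sync_step equals per-node recomputation on random networks", {
  for (seed in 1:20) {
    for (sem in c("multilevel", "li_binary")) {
      m <- random_network(2L + seed %% 5L, sem, seed = seed)
      for (s in 1:5) {
        st <- random_state(m, seed * 100 + s)
        expect_identical(unname(sync_step(m, st)),
                         unname(oracle_sync_step(m, st)),
                         info = sprintf("%s seed %d", sem, seed))
      }
    }
  }
})

test_that("asynchronous successors change exactly one node by one level", {
  for (seed in 1:10) {
    m <- random_network(5, "multilevel", seed = seed)
    st <- random_state(m, seed)
    for (s2 in async_successors(m, st)) {
      d <- which(s2 != st)
      expect_length(d, 1)
      expect_identical(unname(abs(s2[d] - st[d])), 1L)
      expect_true(all(s2 >= 0 & s2 <= m$nodes$max_level))
    }
  }
})

test_that("fixed points have no asynchronous successors", {
  m <- toy_chain()
  expect_length(async_successors(m, c(A = 1L, B = 1L)), 0)
  tr <- simulate_model(yeast_model("proposed"), stationary_g1(yeast_model("proposed")),
                       "async", seed = 1)
  expect_identical(nrow(tr$states), 1L)
  expect_true(tr$converged)
})

test_that("seeded asynchronous simulation is reproducible", {
  m <- yeast_model("mangla")
  t1 <- simulate_model(m, stimulated_g1(m), "async", max_steps = 100, seed = 7)
  t2 <- simulate_model(m, stimulated_g1(m), "async", max_steps = 100, seed = 7)
  expect_identical(t1$states, t2$states)
  expect_identical(t1$updated, t2$updated)
})

test_that("synchronous runs of all fixtures return to stationary G1", {
  for (m in bundled_fixtures()) {
    tr <- simulate_model(m, stimulated_g1(m), "sync", max_steps = 100)
    expect_true(tr$converged)
    expect_same_levels(tr$states[nrow(tr$states), ], stationary_g1(m))
  }
})

test_that("revised-model synchronous trajectory shows the Clb2/Mcm1 feedback
           and graded Swi5 activation in order", {
  m <- yeast_model("proposed")
  tr <- simulate_model(m, stimulated_g1(m), "sync", max_steps = 100)
  first_time <- function(node, level) {
    hit <- which(tr$states[, node] >= level)
    expect_true(length(hit) > 0, label = paste(node, "reaches", level))
    hit[1]
  }
  t_clb2_1 <- first_time("Clb2", 1)
  t_clb2_2 <- first_time("Clb2", 2)
  t_mcm1 <- first_time("Mcm1", 1)
  t_swi5_1 <- first_time("Swi5", 1)
  t_swi5_2 <- first_time("Swi5", 2)
  t_cdc20 <- first_time("Cdc20", 1)
  # low Clb2 first, then Mcm1, then high Clb2 (positive feedback closed)
  expect_lt(t_clb2_1, t_mcm1)
  expect_lt(t_mcm1, t_clb2_2)
  # Swi5 transcribed at low level after Mcm1, high only after Cdc20
  expect_lt(t_mcm1, t_swi5_1)
  expect_lt(t_cdc20, t_swi5_2)
})

test_that("after Clb5 activates, the graded base model lets Clb2 and Mcm1
           race while the revised model enables only Clb2", {
  ma <- yeast_model("mangla")
  tr <- simulate_model(ma, stimulated_g1(ma), "sync", max_steps = 100)
  s_entry <- tr$states[which(tr$states[, "Clb5"] >= 1)[1], ]
  succ <- async_successors(ma, s_entry)
  expect_true(all(c("Clb2", "Mcm1") %in% names(succ)))
  # if Mcm1 rises first, Cdc20 becomes enabled (the hazard opening)
  s_m <- succ[["Mcm1"]]
  expect_true("Cdc20" %in% names(async_successors(ma, s_m)))

  pr <- yeast_model("proposed")
  tr2 <- simulate_model(pr, stimulated_g1(pr), "sync", max_steps = 100)
  s_entry2 <- tr2$states[which(tr2$states[, "Clb5"] >= 1)[1], ]
  succ2 <- async_successors(pr, s_entry2)
  expect_true("Clb2" %in% names(succ2))
  expect_false("Mcm1" %in% names(succ2))
})

test_that("trajectory tidier and TSV export carry the canonical columns", {
  m <- yeast_model("li")
  tr <- simulate_model(m, stimulated_g1(m), "async", max_steps = 30, seed = 3)
  td <- tidy(tr)
  expect_setequal(unique(as.character(td$node)), m$nodes$name)
  path <- tempfile(fileext = ".tsv")
  write_trajectory(tr, path)
  got <- utils::read.delim(path)
  expect_identical(nrow(got), nrow(tr$states))
  expect_true("updated_node" %in% names(got))
})
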