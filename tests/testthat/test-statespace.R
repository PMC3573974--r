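test_that("reachable graphs are exact closures with the expected shape", {
  m <- toy_chain()
  # from a fixed point: one state, no edges
  g0 <- reachable_graph(m, c(A = 1L, B = 1L), "async")
  expect_identical(nrow(g0$states), 1L)
  expect_identical(nrow(g0$edges), 0L)
  # sync from the stimulated state: a single path to the fixed point
  gs <- reachable_graph(m, stimulated_g1(m), "sync")
  expect_identical(nrow(gs$states), 2L)
  # async edges change exactly one node
  ga <- reachable_graph(yeast_model("li"), stimulated_g1(yeast_model("li")),
                        "async")
  d <- rowSums(ga$states[ga$edges$from, , drop = FALSE] !=
                 ga$states[ga$edges$to, , drop = FALSE])
  expect_true(all(d == 1))
  # deterministic construction
  gb <- reachable_graph(yeast_model("li"), stimulated_g1(yeast_model("li")),
                        "async")
  expect_identical(ga$states, gb$states)
  expect_identical(ga$edges, gb$edges)
})

test_that("sync reachable set is no larger than async reachable set", {
  for (m in bundled_fixtures()) {
    gs <- reachable_graph(m, stimulated_g1(m), "sync")
    ga <- reachable_graph(m, stimulated_g1(m), "async")
    expect_lte(nrow(gs$states), nrow(ga$states))
  }
})

test_that("the state cap aborts oversized explorations explicitly", {
  m <- yeast_model("li")
  expect_error(reachable_graph(m, stimulated_g1(m), "async", max_states = 10),
               "state cap exceeded")
})

test_that("terminal SCC detection handles fixed points and cycles", {
  m <- toy_chain()
  g0 <- reachable_graph(m, c(A = 1L, B = 1L), "async")
  expect_identical(terminal_sccs(g0), list(1L))
  # two-state oscillator: one terminal SCC of size 2 (sync mode)
  osc <- toy_oscillator()
  g <- reachable_graph(osc, stimulated_g1(osc), "sync")
  sccs <- terminal_sccs(g)
  expect_length(sccs, 1)
  expect_length(sccs[[1]], 2)
})

test_that("cyclic synchronous attractors are detected on a toy oscillator", {
  att <- synchronous_attractors(toy_oscillator())
  kinds <- vapply(att$attractors, function(a) a$kind, "")
  expect_true("cycle" %in% kinds)
  cyc <- att$attractors[[which(kinds == "cycle")[1]]]
  expect_identical(nrow(cyc$states), 2L)
})

test_that("basin sizes always partition the full state space", {
  for (m in bundled_fixtures()) {
    att <- synchronous_attractors(m)
    expect_identical(sum(vapply(att$attractors, function(a) a$basin_size, 1L)),
                     state_space_size(m))
  }
})

table_rows <- function(att) {
  td <- tidy(att)
  apply(td[, -(1:2)], 1, paste, collapse = "")
}

test_that("binary fixture reproduces its published basin table exactly", {
  att <- synchronous_attractors(yeast_model("li"))
  td <- tidy(att)
  expect_identical(td$basin_size, c(1764L, 151L, 109L, 9L, 7L, 7L, 1L))
  expect_true(all(td$kind == "fixed_point"))
  expect_identical(table_rows(att)[1], "00001000100")
  expect_identical(table_rows(att)[2], "00110000000")
  expect_identical(table_rows(att)[3], "01001000100")
})

test_that("graded base fixture has the nine published attractor states", {
  att <- synchronous_attractors(yeast_model("mangla"))
  td <- tidy(att)
  expect_length(att$attractors, 9)
  expect_true(all(td$kind == "fixed_point"))
  expect_setequal(table_rows(att),
                  c("00001000100", "01110110100", "00110000000",
                    "01001000100", "00110110100", "00000000100",
                    "00000000000", "01000000100", "00001000000"))
  # the stationary G1 basin dominates (~90% of the space)
  expect_identical(table_rows(att)[1], "00001000100")
  expect_gt(td$basin_size[1] / state_space_size(yeast_model("mangla")), 0.85)
})

test_that("revised fixture has the nine published attractor states and the
           largest resting-state basin of the three models", {
  att <- synchronous_attractors(yeast_model("proposed"))
  td <- tidy(att)
  expect_length(att$attractors, 9)
  expect_true(all(td$kind == "fixed_point"))
  expect_setequal(table_rows(att),
                  c("00001000100", "01110210100", "00110000000",
                    "01001000100", "00000000000", "00110210100",
                    "00001000000", "00000000100", "01000000100"))
  expect_identical(table_rows(att)[1], "00001000100")
  frac <- function(nm) {
    a <- tidy(synchronous_attractors(yeast_model(nm)))
    a$basin_size[1] / state_space_size(yeast_model(nm))
  }
  # stability ordering: revised > graded base > binary
  expect_gt(frac("proposed"), frac("mangla"))
  expect_gt(frac("mangla"), frac("li"))
})

test_that("attractor reports write the published table layout", {
  att <- synchronous_attractors(yeast_model("li"))
  path <- tempfile(fileext = ".tsv")
  write_attractors(att, path)
  got <- utils::read.delim(path)
  expect_identical(names(got)[1], "basin_size")
  expect_identical(names(got)[-1],
                   c("Cln3", "MBF", "SBF", "Cln2", "Cdh1", "Swi5", "Cdc20",
                     "Clb5", "Sic1", "Clb2", "Mcm1"))
  expect_identical(nrow(got), 7L)
})

test_that("transition-graph export renders states as level strings", {
  m <- toy_chain()
  g <- reachable_graph(m, stimulated_g1(m), "async")
  path <- tempfile(fileext = ".tsv")
  write_transition_graph(g, path)
  got <- utils::read.delim(path, colClasses = "character")
  expect_identical(got$src[1], "10")
  expect_identical(got$dst[1], "11")
})
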