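# allow the full suite to run even when the known-unattainable
# reference-table assertions fail
options(testthat.progress.max_fails = 1000)

# Toy networks and independent brute-force oracles used across the suite.

# two-node activation chain: A -> B, A self-sustaining
toy_chain <- function() {
  nodes <- tibble::tibble(name = c("A", "B"), max_level = 1L,
                          self_degrading = FALSE)
  edges <- tibble::tibble(from = c("A", "A"), to = c("A", "B"),
                          weight = c("1", "1"))
  network_model("chain", "multilevel", nodes, edges,
                stationary_g1 = c(A = 0L, B = 0L),
                stimulated_g1 = c(A = 1L, B = 0L))
}

# two-node synchronous 2-cycle: A -> B and B -> A with no self-loops, so
# (1,0) and (0,1) swap forever under simultaneous update
toy_oscillator <- function() {
  nodes <- tibble::tibble(name = c("A", "B"), max_level = 1L,
                          self_degrading = FALSE)
  edges <- tibble::tibble(from = c("A", "B"), to = c("B", "A"),
                          weight = c("1", "1"))
  network_model("osc", "multilevel", nodes, edges,
                stationary_g1 = c(A = 0L, B = 0L),
                stimulated_g1 = c(A = 1L, B = 0L))
}

# asynchronous oscillator: C sustains itself and drives X, X inhibits
# itself, so X toggles forever while C stays on; (0,0) is a fixed point
# that is unreachable once C is on
toy_async_oscillator <- function() {
  nodes <- tibble::tibble(name = c("C", "X"), max_level = 1L,
                          self_degrading = FALSE)
  edges <- tibble::tibble(from = c("C", "C", "X"), to = c("C", "X", "X"),
                          weight = c("1", "1", "-1"))
  network_model("aosc", "multilevel", nodes, edges,
                stationary_g1 = c(C = 0L, X = 0L),
                stimulated_g1 = c(C = 1L, X = 0L))
}

# seeded random small network in either semantics
random_network <- function(n_nodes, semantics = "multilevel", seed = 1,
                           p_edge = 0.5) {
  set.seed(seed)
  nm <- LETTERS[seq_len(n_nodes)]
  maxlev <- if (semantics == "multilevel") {
    sample(1:2, n_nodes, replace = TRUE)
  } else rep(1L, n_nodes)
  nodes <- tibble::tibble(
    name = nm, max_level = as.integer(maxlev),
    self_degrading = if (semantics == "li_binary") {
      sample(c(TRUE, FALSE), n_nodes, replace = TRUE)
    } else FALSE)
  alphabet <- if (semantics == "multilevel") {
    c("-3", "-1", "-1/3", "1/3", "1", "3")
  } else c("-1", "1")
  pairs <- expand.grid(from = nm, to = nm, stringsAsFactors = FALSE)
  keep <- stats::runif(nrow(pairs)) < p_edge
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) == 0) pairs <- data.frame(from = nm[1], to = nm[1])
  edges <- tibble::tibble(from = pairs$from, to = pairs$to,
                          weight = sample(alphabet, nrow(pairs),
                                          replace = TRUE))
  st <- stats::setNames(integer(n_nodes), nm)
  network_model(paste0("rand", seed), semantics, nodes, edges,
                stationary_g1 = st,
                stimulated_g1 = {
                  s <- st
                  s[1] <- 1L
                  s
                })
}

random_state <- function(model, seed) {
  set.seed(seed)
  lv <- vapply(model$nodes$max_level, function(m) sample(0:m, 1), 1L)
  stats::setNames(as.integer(lv), model$nodes$name)
}

# scalar, loop-based recomputation of the update rule, independent of the
# vectorised implementation
oracle_target <- function(model, state, node) {
  i <- match(node, model$nodes$name)
  w6 <- parse_rational6(model$edges$weight)
  sum6 <- 0L
  for (k in seq_len(nrow(model$edges))) {
    if (model$edges$to[k] == node) {
      sum6 <- sum6 + w6[k] * state[[model$edges$from[k]]]
    }
  }
  s <- state[[node]]
  if (model$semantics == "li_binary") {
    if (sum6 > 0) return(1L)
    if (sum6 < 0) return(0L)
    if (model$nodes$self_degrading[i]) return(0L)
    return(as.integer(s))
  }
  th <- parse_rational6(unlist(model$nodes$thresholds[[i]]))
  maxl <- model$nodes$max_level[i]
  if (s < maxl && sum6 >= th[s + 1]) return(as.integer(s + 1L))
  if (s > 0 && sum6 < th[s]) return(as.integer(s - 1L))
  as.integer(s)
}

oracle_sync_step <- function(model, state) {
  out <- vapply(model$nodes$name, function(nd)
    oracle_target(model, state, nd), 1L)
  stats::setNames(out, model$nodes$name)
}

# brute-force precedence check by explicit enumeration of simple paths
# (monitor is monotone, so a violation is witnessed on a simple path)
oracle_precedence <- function(model, initial, antecedent, consequent) {
  holds <- function(state, cond) state[[cond[[1]]]] >= as.integer(cond[[2]])
  violated <- FALSE
  rec <- function(state, seen_ant, visited) {
    if (violated) return(invisible())
    seen_ant <- seen_ant || holds(state, antecedent)
    if (holds(state, consequent) && !seen_ant) {
      violated <<- TRUE
      return(invisible())
    }
    key <- paste(state, collapse = ",")
    if (key %in% visited) return(invisible())
    visited <- c(visited, key)
    for (s2 in async_successors(model, state)) rec(s2, seen_ant, visited)
  }
  rec(validate_state_vec(initial, model$nodes, "initial"), FALSE, character(0))
  if (violated) "fail" else "pass"
}

expect_same_levels <- function(a, b) {
  expect_equal(unname(a[names(b)]), unname(b))
}
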