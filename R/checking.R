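# Checkpoint property language, hazard detection, global-attractor
# verification, and NuSMV export.
#
# Fairness reduction.  The SMV encoding of asynchrony uses a control variable
# that may select any node at any instant, including nodes whose update is a
# no-op; a FAIRNESS constraint per node value rules out schedules that starve
# a node forever.  Because no-op selections are always available, any cycle
# of the (no-op-free) transition graph can be decorated into a fair run by
# inserting stuttering selections of the starved nodes.  Consequently "every
# fair path eventually reaches T" holds if and only if the reachable graph
# contains no cycle outside T and every maximal path ends in T.  This reduces
# fair-CTL liveness checking to reachability plus SCC analysis, which is what
# the checkers below implement; the SMV exporter emits the corresponding
# fair AF formulas for optional cross-validation with NuSMV.

#' Checkpoint properties
#'
#' `precedence_property(a, b)` demands that on every path from the initial
#' state, node `b` reaches its level only after (or at the same instant as)
#' node `a` has reached its level.  `response_property(t, o)` demands that
#' from every reachable state satisfying the trigger, every fair path
#' eventually satisfies the obligation.  `global_attractor_property(target)`
#' demands that the target fixed point is the unique fair long-run fate of
#' the initial state.  Conditions are pairs `c(node, level)` (meaning the
#' node is at or above the level) or, for obligations and targets, a full
#' named state (exact match).
#'
#' @param antecedent,consequent,trigger Conditions `c(node, level)`.
#' @param obligation A condition `c(node, level)` or a named state vector.
#' @param target A named state vector (must be a fixed point).
#' @param name Property identifier.
#' @param group Optional checkpoint group label.
#' @return A `ccn_property`.
#' @export
precedence_property <- function(antecedent, consequent, name,
                                group = NA_character_) {
  structure(list(type = "precedence", antecedent = as_cond(antecedent),
                 consequent = as_cond(consequent), name = name,
                 group = group),
            class = "ccn_property")
}

#' @rdname precedence_property
#' @export
response_property <- function(trigger, obligation, name,
                              group = NA_character_) {
  structure(list(type = "response", trigger = as_cond(trigger),
                 obligation = as_cond(obligation), name = name,
                 group = group),
            class = "ccn_property")
}

#' @rdname precedence_property
#' @export
global_attractor_property <- function(target, name = "global_attractor",
                                      group = "global") {
  structure(list(type = "global_attractor", target = as_cond(target),
                 name = name, group = group),
            class = "ccn_property")
}

as_cond <- function(x) {
  if (inherits(x, "ccn_cond")) return(x)
  if (!is.null(names(x)) && all(nzchar(names(x)))) {
    structure(list(kind = "state", state = x), class = "ccn_cond")
  } else {
    structure(list(kind = "level", node = as.character(x[[1]]),
                   level = as.integer(x[[2]])), class = "ccn_cond")
  }
}

cond_holds <- function(cond, states, model) {
  if (cond$kind == "level") {
    j <- match(cond$node, model$nodes$name)
    if (is.na(j)) stop("property names unknown node '", cond$node, "'",
                       call. = FALSE)
    if (cond$level > model$nodes$max_level[j]) {
      stop("property level ", cond$level, " exceeds max_level of '",
           cond$node, "'", call. = FALSE)
    }
    states[, j] >= cond$level
  } else {
    st <- validate_state_vec(cond$state, model$nodes, "property state")
    rowSums(states != matrix(st, nrow(states), length(st),
                             byrow = TRUE)) == 0
  }
}

describe_cond <- function(cond) {
  if (cond$kind == "level") paste0(cond$node, ">=", cond$level)
  else paste0("state[", paste0(names(cond$state), "=", cond$state,
                               collapse = ","), "]")
}

#' @export
print.ccn_property <- function(x, ...) {
  desc <- switch(x$type,
    precedence = paste(describe_cond(x$antecedent), "before",
                       describe_cond(x$consequent)),
    response = paste(describe_cond(x$trigger), "leads to",
                     describe_cond(x$obligation)),
    global_attractor = paste("global attractor", describe_cond(x$target)))
  cat(sprintf("<ccn_property '%s'> %s: %s\n", x$name, x$type, desc))
  invisible(x)
}

verdict <- function(prop, status, counterexample = NULL, note = NA_character_) {
  structure(list(property = prop, status = status,
                 counterexample = counterexample, note = note),
            class = "ccn_verdict")
}

#' @export
print.ccn_verdict <- function(x, ...) {
  cat(sprintf("<ccn_verdict> %s [%s]: %s%s\n", x$property$name,
              x$property$type, toupper(x$status),
              if (!is.null(x$counterexample))
                sprintf(" (counterexample, %d steps)",
                        nrow(x$counterexample$states) - 1) else ""))
  invisible(x)
}

# path of row indices -> ccn_trajectory over the graph's states
path_trajectory <- function(graph, model, idx_path, annotation = NULL) {
  states <- graph$states[idx_path, , drop = FALSE]
  updated <- character(0)
  if (length(idx_path) > 1) {
    for (i in seq_len(length(idx_path) - 1)) {
      d <- which(states[i, ] != states[i + 1, ])
      updated <- c(updated, model$nodes$name[d][1])
    }
  }
  structure(list(states = states, mode = "async", updated = updated,
                 converged = FALSE, seed = NULL, model_name = model$name,
                 annotation = annotation),
            class = "ccn_trajectory")
}

adjacency_list <- function(graph) {
  split(graph$edges$to, factor(graph$edges$from,
                               levels = seq_len(nrow(graph$states))))
}

# BFS shortest path in the index graph from `from` to any node with
# goal[v] TRUE, restricted to nodes with allowed[v] TRUE.  Returns index
# vector or NULL.
bfs_path <- function(adj, from, goal, allowed = NULL) {
  n <- length(adj)
  parent <- rep(NA_integer_, n)
  visited <- rep(FALSE, n)
  queue <- from
  visited[from] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    if (goal[v]) {
      path <- v
      while (!is.na(parent[path[1]])) path <- c(parent[path[1]], path)
      return(path)
    }
    for (w in adj[[v]]) {
      if (!visited[w] && (is.null(allowed) || allowed[w])) {
        visited[w] <- TRUE
        parent[w] <- v
        queue <- c(queue, w)
      }
    }
  }
  NULL
}

#' Check a precedence (checkpoint ordering) property
#'
#' Explores the asynchronous state space augmented with a monitor bit
#' recording whether the antecedent has held at some instant.  The property
#' fails iff a state satisfying the consequent is reachable while the
#' monitor is still false; on failure a shortest witnessing path is
#' returned.
#'
#' @param model A `ccn_model`.
#' @param initial Initial state.
#' @param prop A precedence `ccn_property`.
#' @param max_states State cap for the exploration.
#' @return A `ccn_verdict`.
#' @examples
#' m <- yeast_model("mangla")
#' p <- precedence_property(c("Clb2", 1), c("Cdc20", 1), "m_metaphase")
#' check_precedence(m, stimulated_g1(m), p)
#' @export
check_precedence <- function(model, initial, prop, max_states = 1e6) {
  stopifnot(prop$type == "precedence")
  graph <- reachable_graph(model, initial, "async", max_states)
  ant <- cond_holds(prop$antecedent, graph$states, model)
  cons <- cond_holds(prop$consequent, graph$states, model)
  adj <- adjacency_list(graph)
  # BFS on (state, monitor) product; monitor latches once ant holds.
  n <- nrow(graph$states)
  seen <- matrix(FALSE, n, 2)        # columns: monitor FALSE / TRUE
  parent <- matrix(NA_integer_, n, 2)
  pmon <- matrix(NA_integer_, n, 2)
  m0 <- ant[1] + 1L
  seen[1, m0] <- TRUE
  queue <- list(c(1L, m0))
  bad <- NULL
  if (cons[1] && m0 == 1L) bad <- c(1L, m0)
  while (length(queue) && is.null(bad)) {
    v <- queue[[1]]; queue <- queue[-1]
    for (w in adj[[v[1]]]) {
      mw <- if (v[2] == 2L || ant[w]) 2L else 1L
      if (!seen[w, mw]) {
        seen[w, mw] <- TRUE
        parent[w, mw] <- v[1]
        pmon[w, mw] <- v[2]
        if (cons[w] && mw == 1L) {
          bad <- c(w, mw)
          break
        }
        queue <- c(queue, list(c(w, mw)))
      }
    }
  }
  if (is.null(bad)) return(verdict(prop, "pass"))
  path <- bad
  repeat {
    v <- path[1:2]
    p <- parent[v[1], v[2]]
    if (is.na(p)) break
    path <- c(p, pmon[v[1], v[2]], path)
  }
  idx <- path[seq(1, length(path), by = 2)]
  tr <- path_trajectory(graph, model, idx,
                        annotation = sprintf("violates %s: %s reached before %s",
                                             prop$name,
                                             describe_cond(prop$consequent),
                                             describe_cond(prop$antecedent)))
  verdict(prop, "fail", tr)
}

# nodes lying on a cycle of the (sub)graph: SCC size > 1 or explicit
# self-loop
on_cycle_nodes <- function(n, edges) {
  if (nrow(edges) == 0) return(logical(n))
  g <- igraph::graph_from_edgelist(cbind(edges$from, edges$to),
                                   directed = TRUE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  memb <- igraph::components(g, mode = "strong")$membership
  big <- tabulate(memb) > 1
  out <- big[memb]
  out[unique(edges$from[edges$from == edges$to])] <- TRUE
  out
}

#' Check a response (trigger leads to obligation) property
#'
#' Under the all-cycles-fair reduction, the property fails iff from some
#' reachable trigger state there is a path avoiding the obligation that
#' reaches either a cycle containing no obligation state or a terminal
#' fixed point that is not an obligation state.  The counterexample is a
#' path from the initial state through a trigger state to the offending
#' cycle or dead end.
#'
#' @inheritParams check_precedence
#' @param prop A response `ccn_property`.
#' @return A `ccn_verdict`.
#' @export
check_response <- function(model, initial, prop, max_states = 1e6) {
  stopifnot(prop$type == "response")
  graph <- reachable_graph(model, initial, "async", max_states)
  trig <- cond_holds(prop$trigger, graph$states, model)
  obl <- cond_holds(prop$obligation, graph$states, model)
  n <- nrow(graph$states)
  adj <- adjacency_list(graph)
  if (!any(trig)) return(verdict(prop, "pass", note = "trigger unreachable"))
  # restrict to non-obligation states
  sub_edges <- dplyr::filter(graph$edges, !obl[.data$from], !obl[.data$to])
  cyc <- on_cycle_nodes(n, sub_edges)
  sinks <- !(seq_len(n) %in% graph$edges$from)   # terminal fixed points
  bad <- (!obl) & (cyc | sinks)
  if (!any(bad)) return(verdict(prop, "pass"))
  # reachable from a trigger state while avoiding obligation states?
  sub_adj <- split(sub_edges$to, factor(sub_edges$from, levels = seq_len(n)))
  # forward BFS from trigger states (themselves non-obligation;
  # a trigger state that satisfies the obligation discharges immediately)
  start <- which(trig & !obl)
  if (length(start) == 0) return(verdict(prop, "pass"))
  reach <- rep(FALSE, n)
  reach[start] <- TRUE
  queue <- start
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in sub_adj[[v]]) {
      if (!reach[w]) {
        reach[w] <- TRUE
        queue <- c(queue, w)
      }
    }
  }
  if (!any(bad & reach)) return(verdict(prop, "pass"))
  # counterexample: initial -> trigger state t with a bad state reachable
  # from t, then t -> bad (avoiding obligation)
  # pick reachable-bad-serving trigger states: those that can reach bad in sub
  target_bad <- which(bad & reach)
  p1 <- bfs_path(adj, 1L, trig & !obl)
  t0 <- p1[length(p1)]
  p2 <- bfs_path(sub_adj, t0, seq_len(n) %in% target_bad,
                 allowed = !obl)
  if (is.null(p2)) {
    # the first trigger state found cannot reach a bad state; search from all
    for (t0 in start) {
      p2 <- bfs_path(sub_adj, t0, seq_len(n) %in% target_bad, allowed = !obl)
      if (!is.null(p2)) {
        p1 <- bfs_path(adj, 1L, seq_len(n) == t0)
        break
      }
    }
  }
  idx <- c(p1, p2[-1])
  tr <- path_trajectory(graph, model, idx,
                        annotation = sprintf(
                          "violates %s: %s not followed by %s", prop$name,
                          describe_cond(prop$trigger),
                          describe_cond(prop$obligation)))
  verdict(prop, "fail", tr)
}

#' Check that a fixed point is the global attractor
#'
#' Passes iff the asynchronous reachable graph from the initial state has
#' exactly one terminal strongly connected component, equal to the target
#' fixed point, and contains no other cycle (so that, under the fairness
#' reduction, every fair run reaches the target).  On failure the verdict
#' carries either a lasso-shaped counterexample (path plus cycle) or a path
#' to a wrong terminal state.
#'
#' @inheritParams check_precedence
#' @param target A named state vector; must be a fixed point of the model.
#' @param name Property name for the verdict.
#' @return A `ccn_verdict`.
#' @examples
#' m <- yeast_model("li")
#' check_global_attractor(m, stimulated_g1(m), stationary_g1(m))
#' @export
check_global_attractor <- function(model, initial, target,
                                   name = "g1_global_attractor",
                                   max_states = 1e6) {
  target <- validate_state_vec(target, model$nodes, "target")
  if (!identical(unname(sync_step(model, target)), unname(target))) {
    stop("target is not a fixed point of the model", call. = FALSE)
  }
  prop <- global_attractor_property(target, name)
  graph <- reachable_graph(model, initial, "async", max_states)
  n <- nrow(graph$states)
  tgt_row <- which(cond_holds(prop$target, graph$states, model))
  adj <- adjacency_list(graph)
  # cycles outside the target
  non_tgt_edges <- graph$edges[!(graph$edges$from %in% tgt_row) &
                                 !(graph$edges$to %in% tgt_row), ]
  cyc <- on_cycle_nodes(n, non_tgt_edges)
  if (any(cyc)) {
    # lasso: shortest path to a cycle node, then around its cycle
    p <- bfs_path(adj, 1L, cyc)
    v <- p[length(p)]
    sub_adj <- split(non_tgt_edges$to,
                     factor(non_tgt_edges$from, levels = seq_len(n)))
    loop <- NULL
    for (w in sub_adj[[v]]) {
      back <- if (w == v) w else {
        bp <- bfs_path(sub_adj, w, seq_len(n) == v)
        if (!is.null(bp)) bp
      }
      if (!is.null(back)) {
        loop <- back
        break
      }
    }
    idx <- c(p, loop)
    tr <- path_trajectory(graph, model, idx,
                          annotation = sprintf(
                            "violates %s: fair cycle never reaching target",
                            name))
    return(verdict(prop, "fail", tr, note = "cycle outside target"))
  }
  sinks <- which(!(seq_len(n) %in% graph$edges$from))
  wrong <- setdiff(sinks, tgt_row)
  if (length(wrong) > 0) {
    p <- bfs_path(adj, 1L, seq_len(n) %in% wrong)
    tr <- path_trajectory(graph, model, p,
                          annotation = sprintf(
                            "violates %s: trajectory absorbed at a wrong fixed point",
                            name))
    return(verdict(prop, "fail", tr, note = "wrong terminal state"))
  }
  if (length(tgt_row) == 0) {
    stop("target fixed point not reachable and no other sink: inconsistent graph")
  }
  verdict(prop, "pass")
}

#' Default checkpoint property set
#'
#' The built-in rendering of the cell-cycle checkpoint conditions: the S/G2
#' checkpoint (Clb5 activation precedes Clb2 activation), the M-metaphase
#' group (Clb2 and Mcm1 activation precede Cdc20 activation), the
#' M-telophase group (Cdc20 activation leads to full Swi5 activation, full
#' Swi5 activation leads to Sic1 activation, and Cdc20 activation leads back
#' to the stationary G1 state), and the global-attractor property.  "Full"
#' activation means the node's own maximal level, so the set adapts to
#' models in which Swi5 is graded.  The set is data: edit, extend, or load
#' one from JSON with [load_properties()].
#'
#' @param model A `ccn_model` with the canonical 11-node roster.
#' @return A list of `ccn_property`.
#' @export
default_property_set <- function(model) {
  canonical <- c("Cln3", "MBF", "SBF", "Cln2", "Cdh1", "Swi5", "Cdc20",
                 "Clb5", "Sic1", "Clb2", "Mcm1")
  if (!setequal(model$nodes$name, canonical)) {
    stop("default properties need the canonical 11-node roster", call. = FALSE)
  }
  swi5_max <- model$nodes$max_level[match("Swi5", model$nodes$name)]
  list(
    precedence_property(c("Clb5", 1), c("Clb2", 1),
                        "clb5_before_clb2", group = "s_g2"),
    precedence_property(c("Clb2", 1), c("Cdc20", 1),
                        "clb2_before_cdc20", group = "m_metaphase"),
    precedence_property(c("Mcm1", 1), c("Cdc20", 1),
                        "mcm1_before_cdc20", group = "m_metaphase"),
    response_property(c("Cdc20", 1), c("Swi5", swi5_max),
                      "cdc20_leads_to_swi5", group = "m_telophase"),
    response_property(c("Swi5", swi5_max), c("Sic1", 1),
                      "swi5_leads_to_sic1", group = "m_telophase"),
    response_property(c("Cdc20", 1), stationary_g1(model),
                      "cdc20_leads_to_g1", group = "m_telophase"),
    global_attractor_property(stationary_g1(model), "g1_global_attractor"))
}

#' Check a set of properties
#'
#' Dispatches each property to its checker and collects the verdicts.
#'
#' @param model A `ccn_model`.
#' @param initial Initial state; defaults to the model's stimulated G1.
#' @param properties List of `ccn_property`; defaults to
#'   [default_property_set()].
#' @param max_states State cap per check.
#' @return A `ccn_verdicts` object (list of verdicts; `tidy()` gives one
#'   row per property, `glance()` a one-row summary).
#' @examples
#' v <- check_properties(yeast_model("proposed"))
#' tidy(v)
#' @export
check_properties <- function(model, initial = stimulated_g1(model),
                             properties = default_property_set(model),
                             max_states = 1e6) {
  verdicts <- lapply(properties, function(p) {
    switch(p$type,
      precedence = check_precedence(model, initial, p, max_states),
      response = check_response(model, initial, p, max_states),
      global_attractor = check_global_attractor(
        model, initial,
        validate_state_vec(p$target$state, model$nodes, "target"),
        p$name, max_states),
      stop("unknown property type: ", p$type))
  })
  structure(list(verdicts = verdicts, model_name = model$name),
            class = "ccn_verdicts")
}

#' @export
print.ccn_verdicts <- function(x, ...) {
  cat(sprintf("<ccn_verdicts> model '%s': %d/%d pass\n", x$model_name,
              sum(vapply(x$verdicts, function(v) v$status == "pass", TRUE)),
              length(x$verdicts)))
  print(tidy(x), n = length(x$verdicts))
  invisible(x)
}

#' One row per property verdict
#'
#' @param x A `ccn_verdicts`.
#' @param ... Unused.
#' @return Tibble with `property`, `type`, `group`, `status`,
#'   `counterexample_steps`.
#' @export
tidy.ccn_verdicts <- function(x, ...) {
  dplyr::bind_rows(lapply(x$verdicts, function(v) {
    tibble::tibble(
      property = v$property$name, type = v$property$type,
      group = v$property$group, status = v$status,
      counterexample_steps = if (is.null(v$counterexample)) NA_integer_
        else nrow(v$counterexample$states) - 1L)
  }))
}

#' @rdname tidy.ccn_verdicts
#' @export
glance.ccn_verdicts <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(model = x$model_name, n_properties = nrow(td),
                 n_fail = sum(td$status == "fail"),
                 failing_groups = paste(sort(unique(td$group[td$status ==
                                                               "fail"])),
                                        collapse = ","))
}

#' Replay a counterexample
#'
#' Mechanically validates a counterexample trajectory: every step must be a
#' legal asynchronous successor (exactly one node changing to its target
#' level).  Used by the test suite to guarantee that reported hazards are
#' real trajectories of the model.
#'
#' @param model A `ccn_model`.
#' @param traj A `ccn_trajectory` (typically `verdict$counterexample`).
#' @return TRUE (invisibly) if the trajectory replays; otherwise an error.
#' @export
replay_counterexample <- function(model, traj) {
  st <- traj$states
  for (i in seq_len(nrow(st) - 1)) {
    succs <- async_successors(model, st[i, ])
    ok <- any(vapply(succs, function(s)
      all(s == st[i + 1, ]), TRUE))
    if (!ok) {
      stop("counterexample step ", i, " is not a legal asynchronous successor",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Load a property set from JSON
#'
#' The config is a JSON list of objects with fields `type`
#' (`"precedence"`, `"response"` or `"global_attractor"`), `name`, and the
#' type's condition fields (`antecedent`/`consequent`, `trigger`/
#' `obligation` as `[node, level]` pairs or named level maps, `target` as a
#' named level map); optional `group`.
#'
#' @param path JSON file path.
#' @return List of `ccn_property`.
#' @export
load_properties <- function(path) {
  doc <- jsonlite::read_json(path)
  parse_c <- function(x) {
    if (!is.null(names(x)) && length(names(x)) > 0 && all(nzchar(names(x)))) {
      unlist(x)
    } else {
      c(x[[1]], x[[2]])
    }
  }
  lapply(doc, function(p) {
    grp <- if (is.null(p$group)) NA_character_ else p$group
    switch(p$type,
      precedence = precedence_property(parse_c(p$antecedent),
                                       parse_c(p$consequent), p$name, grp),
      response = response_property(parse_c(p$trigger),
                                   parse_c(p$obligation), p$name, grp),
      global_attractor = global_attractor_property(unlist(p$target),
                                                   p$name, grp),
      stop("unknown property type in config: ", p$type))
  })
}
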