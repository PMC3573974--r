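# Cell-cycle phase segmentation and per-phase statistics.
#
# Phase boundaries are data, not code: a phase config is an ordered list of
# (phase name, entry condition).  A position of a trajectory is labelled
# with the last entry condition satisfied so far (latched), so phases never
# revert within a cycle.  Two configs ship as defaults: a 2-segment config
# (S, then G2/M at Clb2 activation) used for segment-length statistics, and
# a 4-segment config (G1; S at Clb5 activation; G2 at Clb2 activation; M at
# Cdc20 activation) used for transition counting.  The two published tables
# are not reconcilable under a single boundary definition, hence two
# configs.

#' Phase configurations
#'
#' `phase_config()` builds a config from an ordered list of entry
#' conditions; `phase_config_2seg()` and `phase_config_4seg()` are the
#' defaults described above.  The first phase's entry condition is the
#' cycle-start state itself.
#'
#' @param phases Named list: phase name -> entry condition (`c(node,
#'   level)` or `NULL` for the cycle start).
#' @param cycle_start,cycle_end Conditions (or named states) opening and
#'   closing the cycle; default to the model's stimulated and stationary G1
#'   when applied.
#' @return A `ccn_phase_config`.
#' @export
phase_config <- function(phases, cycle_start = NULL, cycle_end = NULL) {
  structure(list(phases = phases, cycle_start = cycle_start,
                 cycle_end = cycle_end),
            class = "ccn_phase_config")
}

#' @rdname phase_config
#' @export
phase_config_2seg <- function() {
  phase_config(list(S = NULL, `G2/M` = c("Clb2", 1)))
}

#' @rdname phase_config
#' @export
phase_config_4seg <- function() {
  phase_config(list(G1 = NULL, S = c("Clb5", 1), G2 = c("Clb2", 1),
                    M = c("Cdc20", 1)))
}

phase_markers <- function(config, model) {
  ph <- config$phases
  conds <- lapply(ph, function(x) if (is.null(x)) NULL else as_cond(x))
  list(names = names(ph), conds = conds)
}

# latched phase index per row of a state matrix along a path: the running
# maximum of the marker index satisfied so far
latched_labels <- function(states, markers, model) {
  k <- length(markers$names)
  idx <- rep(1L, nrow(states))
  for (j in seq_len(k)[-1]) {
    hit <- cond_holds(markers$conds[[j]], states, model)
    idx[hit] <- pmax(idx[hit], j)
  }
  cummax(idx)
}

#' Label trajectory positions with cell-cycle phases
#'
#' @param traj A `ccn_trajectory` starting at the cycle-start state
#'   (stimulated G1 by default).
#' @param model The `ccn_model` the trajectory came from.
#' @param config A `ccn_phase_config`.
#' @return Character vector of phase names, one per trajectory position;
#'   length 0 for a trajectory that is already at the cycle end.
#' @export
label_trajectory <- function(traj, model, config = phase_config_2seg()) {
  start <- config$cycle_start
  if (is.null(start)) start <- stimulated_g1(model)
  end <- config$cycle_end
  if (is.null(end)) end <- stationary_g1(model)
  end <- validate_state_vec(end, model$nodes, "cycle_end")
  if (nrow(traj$states) == 1 && all(traj$states[1, ] == end)) {
    return(character(0))
  }
  if (!all(traj$states[1, ] == validate_state_vec(start, model$nodes,
                                                  "cycle_start"))) {
    stop("trajectory does not start at the cycle-start state", call. = FALSE)
  }
  markers <- phase_markers(config, model)
  markers$names[latched_labels(traj$states, markers, model)]
}

# --- exact path-ensemble statistics -------------------------------------

# Per-state latched phase label over the whole reachable graph: the maximum
# latched label over all paths from the initial state (computed by fixpoint
# propagation; deterministic).
graph_phase_labels <- function(graph, model, config) {
  markers <- phase_markers(config, model)
  k <- length(markers$names)
  own <- rep(1L, nrow(graph$states))
  for (j in seq_len(k)[-1]) {
    hit <- cond_holds(markers$conds[[j]], graph$states, model)
    own[hit] <- pmax(own[hit], j)
  }
  lab <- own
  repeat {
    prop <- pmax(lab[graph$edges$to],
                 pmax(lab[graph$edges$from], own[graph$edges$to]))
    upd <- tapply(prop, graph$edges$to, max)
    new_lab <- lab
    ids <- as.integer(names(upd))
    new_lab[ids] <- pmax(new_lab[ids], as.integer(upd))
    if (all(new_lab == lab)) break
    lab <- new_lab
  }
  list(labels = lab, names = markers$names)
}

# Exact equal-weight statistics of per-phase segment lengths over all
# distinct simple paths from the initial state to `end`, by dynamic
# programming over the product of the transition DAG with the latched phase
# index.  Requires the graph (minus the end state) to be acyclic; falls
# back to capped DFS enumeration otherwise.
path_phase_moments <- function(graph, model, config, end_row,
                               max_paths = 5e6) {
  markers <- phase_markers(config, model)
  k <- length(markers$names)
  n <- nrow(graph$states)
  own <- rep(1L, n)
  for (j in seq_len(k)[-1]) {
    hit <- cond_holds(markers$conds[[j]], graph$states, model)
    own[hit] <- pmax(own[hit], j)
  }
  edges <- graph$edges[graph$edges$from != end_row, ]
  acyclic <- !any(on_cycle_nodes(n, edges))
  if (!acyclic) {
    return(path_phase_moments_dfs(graph, model, config, end_row, max_paths))
  }
  # product node id: (state, latched phase) -> (state - 1) * k + phase
  # moments per product node: paths to end, per-phase sum, per-phase sumsq
  adj <- adjacency_list(graph)
  # topological order via igraph on the state graph (end excluded from
  # sources); process states in reverse topological order
  g <- graph_as_igraph(graph)
  topo <- as.integer(igraph::topo_sort(
    igraph::delete_edges(g, which(graph$edges$from == end_row)), mode = "out"))
  npaths <- matrix(0, n, k)
  ssum <- array(0, c(n, k, k))
  ssq <- array(0, c(n, k, k))
  npaths[end_row, ] <- 1
  for (v in rev(topo)) {
    if (v == end_row) next
    for (phi in seq_len(k)) {
      if (phi < own[v]) next
      tot_n <- 0; tot_s <- numeric(k); tot_q <- numeric(k)
      for (w in adj[[v]]) {
        phw <- max(phi, own[w])
        nw <- npaths[w, phw]
        if (nw == 0 && w != end_row) {
          # w cannot reach end under this latch; contributes nothing
        }
        if (w == end_row) nw <- 1
        if (nw == 0) next
        sw <- ssum[w, phw, ]; qw <- ssq[w, phw, ]
        # edge v->w counts one step in phase phi (phase of the source)
        sw2 <- sw; qw2 <- qw
        qw2[phi] <- qw2[phi] + 2 * sw[phi] + nw
        sw2[phi] <- sw2[phi] + nw
        tot_n <- tot_n + nw
        tot_s <- tot_s + sw2
        tot_q <- tot_q + qw2
      }
      npaths[v, phi] <- tot_n
      ssum[v, phi, ] <- tot_s
      ssq[v, phi, ] <- tot_q
    }
  }
  phi0 <- own[1]
  nend <- npaths[1, phi0]
  if (nend == 0) {
    stop("no path from the initial state to the cycle end", call. = FALSE)
  }
  tibble::tibble(
    phase = markers$names,
    n_paths = nend,
    mean_length = ssum[1, phi0, ] / nend,
    var_length = ssq[1, phi0, ] / nend - (ssum[1, phi0, ] / nend)^2,
    exact = TRUE)
}

# fallback: explicit simple-path enumeration with a cap
path_phase_moments_dfs <- function(graph, model, config, end_row, max_paths) {
  markers <- phase_markers(config, model)
  k <- length(markers$names)
  n <- nrow(graph$states)
  own <- rep(1L, n)
  for (j in seq_len(k)[-1]) {
    hit <- cond_holds(markers$conds[[j]], graph$states, model)
    own[hit] <- pmax(own[hit], j)
  }
  adj <- adjacency_list(graph)
  count <- 0L
  sums <- numeric(k); sqs <- numeric(k)
  seg <- numeric(k)
  visited <- rep(FALSE, n)
  rec <- function(v, phi) {
    if (v == end_row) {
      count <<- count + 1L
      if (count > max_paths) {
        stop("simple-path cap exceeded (", max_paths,
             "); use sampled statistics instead", call. = FALSE)
      }
      sums <<- sums + seg
      sqs <<- sqs + seg^2
      return(invisible())
    }
    visited[v] <<- TRUE
    for (w in adj[[v]]) {
      if (!visited[w]) {
        phw <- max(phi, own[w])
        seg[phi] <<- seg[phi] + 1
        rec(w, phw)
        seg[phi] <<- seg[phi] - 1
      }
    }
    visited[v] <<- FALSE
  }
  rec(1L, own[1])
  if (count == 0) stop("no path from the initial state to the cycle end",
                       call. = FALSE)
  tibble::tibble(phase = markers$names, n_paths = count,
                 mean_length = sums / count,
                 var_length = sqs / count - (sums / count)^2,
                 exact = FALSE)
}

#' Per-phase segment-length statistics
#'
#' Enumerates all distinct simple trajectories of the asynchronous
#' transition graph from the stimulated G1 state to the stationary G1 state
#' (exactly, by dynamic programming when the graph is acyclic; by capped
#' enumeration otherwise), labels each with the phase config, and reports
#' the mean and population variance of the per-phase segment lengths with
#' every distinct path weighted equally.  Lengths are counted in
#' state-changing asynchronous updates.
#'
#' @param model A `ccn_model`.
#' @param config A `ccn_phase_config` (default: the 2-segment S / G2-M
#'   config).
#' @param max_states State cap for graph construction.
#' @param max_paths Cap for the enumeration fallback on cyclic graphs.
#' @return A tibble with columns `phase`, `n_paths`, `mean_length`,
#'   `var_length`, `exact`.
#' @examples
#' phase_length_stats(yeast_model("proposed"))
#' @export
phase_length_stats <- function(model, config = phase_config_2seg(),
                               max_states = 1e6, max_paths = 5e6) {
  graph <- reachable_graph(model, stimulated_g1(model), "async", max_states)
  end <- which(cond_holds(as_cond(stationary_g1(model)), graph$states, model))
  if (length(end) != 1) {
    stop("stationary G1 not reachable from stimulated G1", call. = FALSE)
  }
  path_phase_moments(graph, model, config, end, max_paths)
}

#' Sampled per-phase segment-length statistics
#'
#' Monte-Carlo alternative to [phase_length_stats()]: runs the uniform
#' asynchronous scheduler repeatedly and averages per-phase segment lengths
#' over the runs that reach the stationary G1 state.  Here trajectories are
#' weighted by scheduler probability rather than equally.
#'
#' @inheritParams phase_length_stats
#' @param n_runs Number of seeded simulation runs.
#' @param seed Integer seed.
#' @param max_steps Per-run step cap.
#' @return A tibble like [phase_length_stats()] plus `n_runs_used`.
#' @export
phase_length_stats_sampled <- function(model, config = phase_config_2seg(),
                                       n_runs = 1000, seed = 1,
                                       max_steps = 500) {
  markers <- phase_markers(config, model)
  k <- length(markers$names)
  end <- stationary_g1(model)
  lens <- matrix(NA_real_, n_runs, k)
  used <- 0L
  for (r in seq_len(n_runs)) {
    tr <- simulate_model(model, stimulated_g1(model), "async",
                         max_steps = max_steps, seed = seed + r)
    last <- tr$states[nrow(tr$states), ]
    if (!tr$converged || !all(last == end)) next
    used <- used + 1L
    lab <- latched_labels(tr$states, markers, model)
    src <- lab[-length(lab)]   # phase of the source state of each step
    lens[used, ] <- vapply(seq_len(k), function(j) sum(src == j), 1)
  }
  if (used == 0) stop("no sampled run reached the cycle end", call. = FALSE)
  lens <- lens[seq_len(used), , drop = FALSE]
  tibble::tibble(phase = markers$names, n_runs_used = used,
                 mean_length = colMeans(lens),
                 var_length = apply(lens, 2, function(x)
                   mean((x - mean(x))^2)))
}

#' Distinct transition counts per phase
#'
#' Counts the distinct transitions (ordered state pairs) of the
#' asynchronous reachable graph from stimulated G1, grouped by the phase
#' label of the source state under the 4-segment config (G1, S at Clb5
#' activation, G2 at Clb2 activation, M at Cdc20 activation).  State labels
#' are latched along paths and propagated to a per-state label by fixpoint
#' (the maximal phase under which the state is visited).
#'
#' @param model A `ccn_model`.
#' @param config A `ccn_phase_config` (default 4-segment).
#' @param max_states State cap.
#' @return A tibble with columns `phase` and `n_transitions`; counts sum to
#'   the total transition count of the reachable graph.
#' @examples
#' phase_transition_counts(yeast_model("proposed"))
#' @export
phase_transition_counts <- function(model, config = phase_config_4seg(),
                                    max_states = 1e6) {
  graph <- reachable_graph(model, stimulated_g1(model), "async", max_states)
  gl <- graph_phase_labels(graph, model, config)
  src_lab <- gl$labels[graph$edges$from]
  counts <- vapply(seq_along(gl$names), function(j) sum(src_lab == j), 1L)
  tibble::tibble(phase = gl$names, n_transitions = counts)
}
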