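# Explicit transition graphs, attractors and basins, terminal SCCs.
#
# States are packed into 1-based mixed-radix indices (2 levels per binary
# node, 3 per graded node) so that sets of states are integer vectors and
# the synchronous update of the entire state space is a single matrix
# operation.

pack_states <- function(model, S) {
  if (is.vector(S)) S <- matrix(S, nrow = 1)
  as.integer(S %*% model$internal$radix) + 1L
}

unpack_states <- function(model, idx) {
  int <- model$internal
  n <- length(int$maxlev)
  S <- matrix(0L, length(idx), n, dimnames = list(NULL, model$nodes$name))
  rem <- idx - 1L
  for (i in seq_len(n)) {
    S[, i] <- rem %/% int$radix[i]
    rem <- rem %% int$radix[i]
  }
  S
}

enumerate_states <- function(model) {
  int <- model$internal
  unpack_states(model, seq_len(int$n_states))
}

#' Explicit reachable transition graph
#'
#' Breadth-first closure of the synchronous or asynchronous successor
#' relation from an initial state.  Asynchronous edges change exactly one
#' node; edge labels name the updated node.  Exploration order is canonical
#' (frontiers expanded in packed-state order) so that the result is
#' deterministic.
#'
#' @param model A `ccn_model`.
#' @param initial Initial state (named integer vector).
#' @param mode `"sync"` or `"async"`.
#' @param max_states Cap on the number of explored states; exceeding it is
#'   an error.
#' @return A `ccn_graph`: list with `states` (integer matrix, one row per
#'   reachable state), `edges` (tibble `from`, `node`, `to`; indices into
#'   the state rows), `initial` (row index, always 1), and `mode`.
#' @examples
#' m <- yeast_model("proposed")
#' g <- reachable_graph(m, stimulated_g1(m), "async")
#' glance(g)
#' @export
reachable_graph <- function(model, initial, mode = c("sync", "async"),
                            max_states = 1e6) {
  mode <- match.arg(mode)
  initial <- validate_state_vec(initial, model$nodes, "initial")
  n <- nrow(model$nodes)

  seen <- new.env(hash = TRUE, size = 4096L)
  order_idx <- integer(0)
  S_rows <- list()
  edges_from <- integer(0); edges_to <- integer(0); edges_node <- integer(0)

  key0 <- pack_states(model, initial)
  assign(as.character(key0), 1L, envir = seen)
  S_rows[[1]] <- initial
  frontier <- matrix(initial, nrow = 1)
  frontier_id <- 1L
  n_seen <- 1L

  while (nrow(frontier) > 0) {
    tgt <- target_matrix(model, frontier)
    if (mode == "sync") {
      succ_states <- tgt
      succ_from <- frontier_id
      succ_node <- rep(NA_integer_, nrow(tgt))
      fixed <- rowSums(tgt != frontier) == 0
      succ_states <- succ_states[!fixed, , drop = FALSE]
      succ_from <- succ_from[!fixed]
      succ_node <- succ_node[!fixed]
    } else {
      chg <- which(tgt != frontier, arr.ind = TRUE)
      if (nrow(chg) == 0) break
      succ_states <- frontier[chg[, 1], , drop = FALSE]
      succ_states[cbind(seq_len(nrow(chg)), chg[, 2])] <-
        tgt[cbind(chg[, 1], chg[, 2])]
      succ_from <- frontier_id[chg[, 1]]
      succ_node <- chg[, 2]
    }
    if (nrow(succ_states) == 0) break
    keys <- pack_states(model, succ_states)
    # order new states canonically for deterministic ids
    ord <- order(keys)
    succ_states <- succ_states[ord, , drop = FALSE]
    succ_from <- succ_from[ord]; succ_node <- succ_node[ord]
    keys <- keys[ord]
    to_id <- integer(length(keys))
    new_rows <- list(); new_ids <- integer(0)
    for (j in seq_along(keys)) {
      k <- as.character(keys[j])
      id <- get0(k, envir = seen, inherits = FALSE)
      if (is.null(id)) {
        n_seen <- n_seen + 1L
        if (n_seen > max_states) {
          stop("state cap exceeded (", max_states, " states); raise max_states",
               call. = FALSE)
        }
        id <- n_seen
        assign(k, id, envir = seen)
        S_rows[[id]] <- succ_states[j, ]
        new_ids <- c(new_ids, id)
      }
      to_id[j] <- id
    }
    edges_from <- c(edges_from, succ_from)
    edges_to <- c(edges_to, to_id)
    edges_node <- c(edges_node, succ_node)
    if (length(new_ids) == 0) {
      frontier <- matrix(integer(0), 0, n)
      frontier_id <- integer(0)
    } else {
      frontier <- do.call(rbind, S_rows[new_ids])
      frontier_id <- new_ids
    }
  }

  states <- do.call(rbind, S_rows)
  colnames(states) <- model$nodes$name
  edges <- tibble::tibble(
    from = edges_from,
    node = ifelse(is.na(edges_node), NA_character_,
                  model$nodes$name[edges_node]),
    to = edges_to)
  edges <- dplyr::distinct(edges)
  structure(list(states = states, edges = edges, initial = 1L, mode = mode,
                 model_name = model$name),
            class = "ccn_graph")
}

#' @export
print.ccn_graph <- function(x, ...) {
  cat(sprintf("<ccn_graph>  %s, %d states, %d transitions\n", x$mode,
              nrow(x$states), nrow(x$edges)))
  invisible(x)
}

#' @rdname reachable_graph
#' @param x A `ccn_graph`.
#' @param ... Unused.
#' @export
glance.ccn_graph <- function(x, ...) {
  tibble::tibble(mode = x$mode, n_states = nrow(x$states),
                 n_transitions = nrow(x$edges))
}

graph_as_igraph <- function(graph) {
  igraph::graph_from_edgelist(
    cbind(graph$edges$from, graph$edges$to), directed = TRUE) |>
    (\(g) if (igraph::vcount(g) < nrow(graph$states)) {
      igraph::add_vertices(g, nrow(graph$states) - igraph::vcount(g))
    } else g)()
}

#' Terminal strongly connected components
#'
#' Strongly connected components of the transition graph with no outgoing
#' edges.  Under the fairness reduction these are where every fair
#' asynchronous run ultimately resides.
#'
#' @param graph A `ccn_graph`.
#' @return A list of integer vectors of state row indices, in deterministic
#'   order (by smallest member).
#' @export
terminal_sccs <- function(graph) {
  if (nrow(graph$edges) == 0) return(list(graph$initial))
  g <- graph_as_igraph(graph)
  comp <- igraph::components(g, mode = "strong")
  memb <- comp$membership
  has_out <- rep(FALSE, comp$no)
  cross <- memb[graph$edges$from] != memb[graph$edges$to]
  has_out[unique(memb[graph$edges$from[cross]])] <- TRUE
  terminal <- which(!has_out)
  out <- lapply(terminal, function(cc) sort(which(memb == cc)))
  out[order(vapply(out, min, 1L))]
}

#' Exhaustive synchronous attractor analysis
#'
#' Iterates the synchronous update from every state of the full state space
#' and partitions it into basins of attraction.  Attractors are fixed points
#' or cycles, reported in descending basin-size order (ties broken by
#' canonical state order), mirroring the layout of the published attractor
#' tables.
#'
#' @param model A `ccn_model`.
#' @param max_states Cap on the enumerable state-space size.
#' @return A `ccn_attractors` object: list of attractors (each with `kind`,
#'   `states` matrix, `basin_size`) plus the model name; `tidy()` renders
#'   the basin-size table.
#' @examples
#' att <- synchronous_attractors(yeast_model("li"))
#' tidy(att)
#' @export
synchronous_attractors <- function(model, max_states = 1e6) {
  int <- model$internal
  if (int$n_states > max_states) {
    stop("state space (", int$n_states, ") exceeds cap", call. = FALSE)
  }
  S <- enumerate_states(model)
  nxt <- pack_states(model, target_matrix(model, S))
  # functional graph: advance every state far enough to land in its
  # attractor (repeated self-composition doubles the step count each time)
  cur <- nxt
  steps <- ceiling(log2(int$n_states)) + 1L
  for (i in seq_len(steps)) cur <- cur[cur]
  # canonical attractor representative: minimum index on the cycle
  rep_ <- cur
  walk <- cur
  for (i in seq_len(64)) {
    walk <- nxt[walk]
    rep_ <- pmin(rep_, walk)
    if (all(walk == cur)) break
  }
  tab <- table(rep_)
  reps <- as.integer(names(tab))
  sizes <- as.integer(tab)
  cycles <- lapply(reps, function(r) {
    cyc <- r
    x <- nxt[r]
    while (x != r) {
      cyc <- c(cyc, x)
      x <- nxt[x]
    }
    cyc
  })
  ord <- order(-sizes, reps)
  attractors <- lapply(ord, function(i) {
    st <- unpack_states(model, cycles[[i]])
    list(kind = if (length(cycles[[i]]) == 1) "fixed_point" else "cycle",
         states = st, basin_size = sizes[i])
  })
  structure(list(attractors = attractors, model_name = model$name,
                 n_states = int$n_states),
            class = "ccn_attractors")
}

#' @export
print.ccn_attractors <- function(x, ...) {
  cat(sprintf("<ccn_attractors>  model '%s': %d attractors over %d states\n",
              x$model_name, length(x$attractors), x$n_states))
  print(tidy(x), n = length(x$attractors))
  invisible(x)
}

#' Attractor table
#'
#' One row per attractor: basin size followed by the node levels of the
#' attractor state (first cycle state for cyclic attractors), in canonical
#' node order -- the layout of the published basin tables.
#'
#' @param x A `ccn_attractors`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ccn_attractors <- function(x, ...) {
  rows <- lapply(x$attractors, function(a) {
    st <- a$states[1, , drop = TRUE]
    tibble::as_tibble_row(c(list(basin_size = a$basin_size, kind = a$kind),
                            as.list(st)))
  })
  dplyr::bind_rows(rows)
}

#' @rdname tidy.ccn_attractors
#' @export
glance.ccn_attractors <- function(x, ...) {
  tibble::tibble(model = x$model_name, n_attractors = length(x$attractors),
                 n_states = x$n_states,
                 largest_basin = max(vapply(x$attractors,
                                            function(a) a$basin_size, 1L)),
                 all_fixed_points = all(vapply(x$attractors, function(a)
                   a$kind == "fixed_point", TRUE)))
}

#' Bar chart of basin sizes
#'
#' @param object A `ccn_attractors`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ccn_attractors <- function(object, ...) {
  df <- tidy(object)
  df$attractor <- factor(seq_len(nrow(df)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$attractor,
                                   y = .data$basin_size)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::labs(x = "attractor (descending basin)", y = "basin size",
                  title = object$model_name) +
    ggplot2::theme_bw()
}

#' Write an attractor report
#'
#' TSV mirroring the published basin tables: basin size plus canonical node
#' columns.
#'
#' @param x A `ccn_attractors`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_attractors <- function(x, path) {
  df <- as.data.frame(tidy(x))
  df$kind <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a transition graph as a TSV edge list
#'
#' Each line is `src<TAB>node<TAB>dst` with states rendered as level strings
#' in canonical node order.
#'
#' @param graph A `ccn_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transition_graph <- function(graph, path) {
  lab <- apply(graph$states, 1, paste, collapse = "")
  df <- data.frame(src = lab[graph$edges$from],
                   node = graph$edges$node,
                   dst = lab[graph$edges$to])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
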