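# Update rules and synchronous/asynchronous stepping.
#
# Both rules are threshold functions of the weighted input sum
# sum_j w_ij S_j(t-1), computed exactly in units of 1/6 (see rational.R).
#
# li_binary:   next = 1 if sum > 0; 0 if sum < 0; on a tie the node decays to
#              0 when flagged self-degrading and otherwise holds its level.
# multilevel:  with current level s, the node climbs to s+1 when the sum
#              reaches the entry threshold of level s+1 (default 1/2 for
#              level 1, 3/2 for level 2), decays by one when the sum falls
#              below the entry threshold of its current level, and otherwise
#              holds.  Levels change by at most one per update and are
#              clamped to [0, max_level]; a node at level 0 never decays,
#              which is equivalent to treating its level-0 threshold as
#              -infinity.

# Vectorised per-node target levels for a batch of states.
# S: integer matrix (k x n), rows are states in model node order.
# Returns a k x n matrix of target levels.
target_matrix <- function(model, S) {
  int <- model$internal
  if (is.vector(S)) S <- matrix(S, nrow = 1)
  sig <- S %*% t(int$W6)
  n <- ncol(S)
  if (model$semantics == "li_binary") {
    cur <- S
    out <- ifelse(sig > 0L, 1L, ifelse(sig < 0L, 0L, cur))
    sdm <- matrix(int$sd, nrow(S), n, byrow = TRUE)
    out[sdm & sig == 0L] <- 0L
    storage.mode(out) <- "integer"
    out
  } else {
    th1 <- matrix(int$th6[, 1], nrow(S), n, byrow = TRUE)
    th2 <- matrix(ifelse(is.na(int$th6[, 2]), int$th6[, 1], int$th6[, 2]),
                  nrow(S), n, byrow = TRUE)
    maxl <- matrix(int$maxlev, nrow(S), n, byrow = TRUE)
    th_up <- ifelse(S == 0L, th1, th2)   # entry threshold of level s+1
    th_dn <- ifelse(S == 1L, th1, th2)   # entry threshold of level s
    up <- (S < maxl) & (sig >= th_up)
    dn <- !up & (S > 0L) & (sig < th_dn)
    out <- S + up - dn
    storage.mode(out) <- "integer"
    out
  }
}

#' Target level of one node
#'
#' The level a node would take at the next time instant, given the current
#' state, under the model's update rule.
#'
#' @param model A `ccn_model`.
#' @param state Named integer vector (a full state).
#' @param node Node name.
#' @return Integer level.
#' @examples
#' m <- yeast_model("proposed")
#' local_target(m, stimulated_g1(m), "MBF")
#' @export
local_target <- function(model, state, node) {
  if (!node %in% model$nodes$name) {
    stop("unknown node: '", node, "'", call. = FALSE)
  }
  state <- validate_state_vec(state, model$nodes, "state")
  tgt <- target_matrix(model, matrix(state, nrow = 1))
  as.integer(tgt[1, match(node, model$nodes$name)])
}

#' Synchronous update step
#'
#' Applies the update rule to every node simultaneously against the same
#' predecessor state.
#'
#' @inheritParams local_target
#' @return The successor state (named integer vector).
#' @export
sync_step <- function(model, state) {
  state <- validate_state_vec(state, model$nodes, "state")
  out <- as.integer(target_matrix(model, matrix(state, nrow = 1)))
  names(out) <- model$nodes$name
  out
}

#' Asynchronous successors of a state
#'
#' One successor per node whose target level differs from its current level;
#' the successor changes only that node (by exactly one level under the
#' multilevel rule).  A fixed point has no successors.  No-op updates are
#' omitted: they only stutter and are collapsed by the fairness reduction
#' used in property checking.
#'
#' @inheritParams local_target
#' @return A named list of successor states; names are the updated nodes.
#' @export
async_successors <- function(model, state) {
  state <- validate_state_vec(state, model$nodes, "state")
  tgt <- as.integer(target_matrix(model, matrix(state, nrow = 1)))
  chg <- which(tgt != state)
  out <- lapply(chg, function(i) {
    s2 <- state
    s2[i] <- tgt[i]
    s2
  })
  names(out) <- model$nodes$name[chg]
  out
}

#' Stationary and stimulated G1 reference states
#'
#' Accessors for a model's named reference states.  The stimulated G1 state
#' equals stationary G1 except that Cln3 is at level 1.
#'
#' @param model A `ccn_model`.
#' @return Named integer state vector.
#' @export
stationary_g1 <- function(model) model$states$stationary_g1

#' @rdname stationary_g1
#' @export
stimulated_g1 <- function(model) model$states$stimulated_g1

#' Simulate a trajectory
#'
#' Synchronous simulation is deterministic.  Asynchronous simulation picks,
#' at each step, one node uniformly at random among the nodes whose target
#' level differs from their current level (the enabled nodes); it is
#' reproducible given `seed`.  Simulation stops at a fixed point or after
#' `max_steps` updates.
#'
#' @param model A `ccn_model`.
#' @param start Start state (named integer vector).
#' @param mode `"sync"` or `"async"`.
#' @param max_steps Maximum number of update steps.
#' @param seed Integer seed for the asynchronous scheduler; ignored for
#'   synchronous runs.
#' @return A `ccn_trajectory`: a list with `states` (matrix, one row per
#'   time point, columns in canonical node order), `mode`, `updated`
#'   (character vector of updated nodes, async only), `converged` (did the
#'   run reach a fixed point), and `seed`.
#' @examples
#' m <- yeast_model("proposed")
#' tr <- simulate_model(m, stimulated_g1(m), "sync")
#' tidy(tr)
#' @export
simulate_model <- function(model, start, mode = c("sync", "async"),
                           max_steps = 200L, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(max_steps > 0)
  start <- validate_state_vec(start, model$nodes, "start")
  states <- matrix(start, nrow = 1)
  updated <- character(0)
  s <- start
  if (mode == "async" && !is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  converged <- FALSE
  for (step in seq_len(max_steps)) {
    tgt <- as.integer(target_matrix(model, matrix(s, nrow = 1)))
    chg <- which(tgt != s)
    if (length(chg) == 0) {
      converged <- TRUE
      break
    }
    if (mode == "sync") {
      s2 <- tgt
    } else {
      i <- if (length(chg) == 1) chg else sample(chg, 1)
      s2 <- s
      s2[i] <- tgt[i]
      updated <- c(updated, model$nodes$name[i])
    }
    names(s2) <- model$nodes$name
    states <- rbind(states, s2)
    s <- s2
  }
  colnames(states) <- model$nodes$name
  rownames(states) <- NULL
  structure(list(states = states, mode = mode, updated = updated,
                 converged = converged, seed = seed, model_name = model$name),
            class = "ccn_trajectory")
}

#' @export
print.ccn_trajectory <- function(x, ...) {
  cat(sprintf("<ccn_trajectory>  %s, %d steps%s\n", x$mode,
              nrow(x$states) - 1,
              if (x$converged) ", reached a fixed point" else ""))
  invisible(x)
}

#' Tidy a trajectory into long format
#'
#' @param x A `ccn_trajectory`.
#' @param ... Unused.
#' @return A tibble with columns `step`, `node`, `level` (plus
#'   `updated_node` for asynchronous runs).
#' @export
tidy.ccn_trajectory <- function(x, ...) {
  df <- tibble::as_tibble(x$states)
  df$step <- seq_len(nrow(df)) - 1L
  out <- tidyr::pivot_longer(df, -"step", names_to = "node",
                             values_to = "level")
  out$node <- factor(out$node, levels = colnames(x$states))
  if (x$mode == "async" && length(x$updated)) {
    upd <- tibble::tibble(step = seq_along(x$updated),
                          updated_node = x$updated)
    out <- dplyr::left_join(out, upd, by = "step")
  }
  out
}

#' Plot per-node activity levels along a trajectory
#'
#' Mirrors the temporal-evolution panels used to compare the discrete models
#' with the continuous kinetic model: one stepped line per node, level
#' against update step.
#'
#' @param object A `ccn_trajectory`.
#' @param nodes Optional subset of node names to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ccn_trajectory <- function(object, nodes = NULL, ...) {
  df <- tidy(object)
  if (!is.null(nodes)) df <- dplyr::filter(df, .data$node %in% nodes)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$level)) +
    ggplot2::geom_step(linewidth = 0.6, colour = "#2c7fb8") +
    ggplot2::facet_wrap(ggplot2::vars(.data$node)) +
    ggplot2::scale_y_continuous(breaks = 0:2) +
    ggplot2::labs(x = "update step", y = "activity level") +
    ggplot2::theme_bw()
}

#' Export a trajectory as TSV
#'
#' One row per time point, columns in canonical node order, plus an
#' `updated_node` column for asynchronous runs.
#'
#' @param traj A `ccn_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj$states)
  df <- cbind(step = seq_len(nrow(df)) - 1L, df)
  if (traj$mode == "async") {
    df$updated_node <- c(NA, traj$updated)[seq_len(nrow(df))]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
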