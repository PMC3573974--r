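# Model container and file I/O for multi-valued threshold networks.

#' Construct a multi-valued threshold network model
#'
#' A network model is a set of nodes, each with a maximal activity level
#' (1 for ordinary Boolean nodes, 2 for graded three-valued nodes), a set of
#' weighted signed edges, and two named reference states: the stationary G1
#' state and the stimulated G1 state (stationary G1 with Cln3 switched on).
#' Two update semantics are supported: `"li_binary"` (threshold 0 with
#' maintain-on-tie and optional self-degradation) and `"multilevel"`
#' (graded levels with entry thresholds 1/2 and 3/2 and unit-step decay).
#'
#' @param name Model identifier.
#' @param semantics `"li_binary"` or `"multilevel"`.
#' @param nodes Data frame with columns `name`, `max_level`,
#'   `self_degrading`, and `thresholds` (list column of rational tokens,
#'   one per level; may be omitted to use the semantics defaults).
#' @param edges Data frame with columns `from`, `to`, `weight` (rational
#'   tokens from the signed alphabet 1/3, 1, 3; the Li semantics admits
#'   only +/-1).
#' @param stationary_g1,stimulated_g1 Named integer vectors giving the level
#'   of every node; `stimulated_g1` may be omitted, in which case it is
#'   derived from `stationary_g1` by setting Cln3 to 1.
#' @return An object of class `ccn_model`.
#' @examples
#' m <- yeast_model("proposed")
#' glance(m)
#' @export
network_model <- function(name, semantics = c("multilevel", "li_binary"),
                          nodes, edges, stationary_g1,
                          stimulated_g1 = NULL) {
  semantics <- match.arg(semantics)
  nodes <- tibble::as_tibble(nodes)
  edges <- tibble::as_tibble(edges)

  if (anyDuplicated(nodes$name)) {
    dup <- nodes$name[duplicated(nodes$name)][1]
    stop("duplicate node name: '", dup, "'", call. = FALSE)
  }
  if (!all(nodes$max_level %in% c(1L, 2L))) {
    bad <- nodes$name[!nodes$max_level %in% c(1L, 2L)][1]
    stop("node '", bad, "': max_level must be 1 or 2", call. = FALSE)
  }
  if (!"self_degrading" %in% names(nodes)) nodes$self_degrading <- FALSE
  if (!"thresholds" %in% names(nodes)) {
    nodes$thresholds <- lapply(nodes$max_level, default_thresholds, semantics)
  }
  # validate thresholds: strictly increasing, one per level
  for (i in seq_len(nrow(nodes))) {
    th <- parse_rational6(unlist(nodes$thresholds[[i]]))
    if (length(th) != nodes$max_level[i]) {
      stop("node '", nodes$name[i], "': need ", nodes$max_level[i],
           " thresholds, got ", length(th), call. = FALSE)
    }
    if (length(th) > 1 && any(diff(th) <= 0)) {
      stop("node '", nodes$name[i], "': thresholds must be strictly increasing",
           call. = FALSE)
    }
  }

  unknown <- setdiff(c(edges$from, edges$to), nodes$name)
  if (length(unknown) > 0) {
    stop("edge endpoint '", unknown[1], "' is not a declared node",
         call. = FALSE)
  }
  if (anyDuplicated(edges[c("from", "to")])) {
    i <- which(duplicated(edges[c("from", "to")]))[1]
    stop("duplicate edge ", edges$from[i], " -> ", edges$to[i], call. = FALSE)
  }
  w6 <- parse_rational6(edges$weight)
  alphabet <- weight_alphabet6(semantics)
  if (!all(w6 %in% alphabet)) {
    i <- which(!w6 %in% alphabet)[1]
    stop("edge ", edges$from[i], " -> ", edges$to[i], ": weight '",
         edges$weight[i], "' is not in the ", semantics, " alphabet",
         call. = FALSE)
  }
  edges$weight <- format_rational6(w6)

  stationary_g1 <- validate_state_vec(stationary_g1, nodes, "stationary_g1")
  if (is.null(stimulated_g1)) {
    stimulated_g1 <- stationary_g1
    if ("Cln3" %in% nodes$name) stimulated_g1[["Cln3"]] <- 1L
  }
  stimulated_g1 <- validate_state_vec(stimulated_g1, nodes, "stimulated_g1")

  model <- structure(
    list(name = name, semantics = semantics, nodes = nodes, edges = edges,
         states = list(stationary_g1 = stationary_g1,
                       stimulated_g1 = stimulated_g1)),
    class = "ccn_model")
  model$internal <- compile_model(model)
  model
}

default_thresholds <- function(max_level, semantics) {
  if (semantics == "li_binary") return("0")
  c("1/2", "3/2")[seq_len(max_level)]
}

validate_state_vec <- function(state, nodes, what) {
  if (is.null(state)) stop("missing reference state '", what, "'", call. = FALSE)
  if (is.null(names(state)) || !setequal(names(state), nodes$name)) {
    stop(what, " must assign a level to every node", call. = FALSE)
  }
  state <- as.integer(state[nodes$name])
  names(state) <- nodes$name
  bad <- state < 0L | state > nodes$max_level
  if (any(bad)) {
    stop(what, ": level of '", nodes$name[bad][1], "' out of range",
         call. = FALSE)
  }
  state
}

# Precomputed integer machinery shared by every analysis: the weight matrix on
# the sixths scale (rows = targets), per-node maximal levels, self-degradation
# flags, level-entry thresholds (sixths), and the mixed-radix multipliers that
# pack a state vector into a single index.
compile_model <- function(model) {
  nn <- model$nodes$name
  n <- length(nn)
  W6 <- matrix(0L, n, n, dimnames = list(nn, nn))
  w6 <- parse_rational6(model$edges$weight)
  for (i in seq_along(w6)) {
    W6[model$edges$to[i], model$edges$from[i]] <- w6[i]
  }
  maxlev <- as.integer(model$nodes$max_level)
  th6 <- matrix(NA_integer_, n, 2)
  for (i in seq_len(n)) {
    th <- parse_rational6(unlist(model$nodes$thresholds[[i]]))
    th6[i, seq_along(th)] <- th
  }
  radix <- rev(cumprod(rev(c(maxlev[-1] + 1L, 1L))))
  list(W6 = W6, maxlev = maxlev, sd = model$nodes$self_degrading,
       th6 = th6, radix = radix, n_states = as.integer(prod(maxlev + 1L)))
}

#' @export
print.ccn_model <- function(x, ...) {
  cat(sprintf("<ccn_model '%s'>  semantics: %s\n", x$name, x$semantics))
  cat(sprintf("  %d nodes (%d multi-valued), %d edges, %d states\n",
              nrow(x$nodes), sum(x$nodes$max_level > 1), nrow(x$edges),
              x$internal$n_states))
  invisible(x)
}

#' Number of states of a model
#'
#' The size of the full state space: the product over nodes of
#' `max_level + 1`.
#'
#' @param model A `ccn_model`.
#' @return Integer count of states.
#' @export
state_space_size <- function(model) {
  model$internal$n_states
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' One-row model summary
#'
#' @param x A `ccn_model`.
#' @param ... Unused.
#' @return A one-row tibble with the model name, semantics, node and edge
#'   counts, number of multi-valued nodes and state-space size.
#' @export
glance.ccn_model <- function(x, ...) {
  tibble::tibble(
    name = x$name, semantics = x$semantics,
    n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
    n_multilevel = sum(x$nodes$max_level > 1L),
    n_states = x$internal$n_states)
}

#' Tidy the edge list of a model
#'
#' @param x A `ccn_model`.
#' @param ... Unused.
#' @return A tibble with one row per edge (`from`, `to`, `weight`,
#'   `sign`).
#' @export
tidy.ccn_model <- function(x, ...) {
  w6 <- parse_rational6(x$edges$weight)
  dplyr::mutate(x$edges, sign = ifelse(w6 > 0, "activation", "inhibition"))
}

canonical_model <- function(model) {
  nodes <- dplyr::arrange(model$nodes, .data$name)
  edges <- dplyr::arrange(model$edges, .data$from, .data$to)
  states <- lapply(model$states, function(s) s[nodes$name])
  list(name = model$name, semantics = model$semantics,
       nodes = nodes, edges = edges, states = states)
}

#' Save a network model
#'
#' Writes a canonical serialization (nodes and edges sorted by name) so that
#' files produced from equivalent models are byte-identical.  Weights and
#' thresholds are written as exact rational tokens (`"1/3"`, never a float).
#'
#' @param model A `ccn_model`.
#' @param path Output file path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
save_network <- function(model, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  cm <- canonical_model(model)
  if (format == "json") {
    doc <- list(
      name = cm$name, semantics = cm$semantics,
      nodes = lapply(seq_len(nrow(cm$nodes)), function(i) {
        list(name = cm$nodes$name[i],
             max_level = cm$nodes$max_level[i],
             self_degrading = cm$nodes$self_degrading[i],
             thresholds = as.list(unlist(cm$nodes$thresholds[[i]])))
      }),
      edges = lapply(seq_len(nrow(cm$edges)), function(i) {
        list(from = cm$edges$from[i], to = cm$edges$to[i],
             weight = cm$edges$weight[i])
      }),
      states = lapply(cm$states, as.list))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("#name\t", cm$name), con)
    writeLines(paste0("#semantics\t", cm$semantics), con)
    for (i in seq_len(nrow(cm$nodes))) {
      writeLines(sprintf("#node\t%s\t%d\t%d\t%s", cm$nodes$name[i],
                         cm$nodes$max_level[i],
                         as.integer(cm$nodes$self_degrading[i]),
                         paste(unlist(cm$nodes$thresholds[[i]]),
                               collapse = ",")), con)
    }
    for (s in names(cm$states)) {
      lv <- cm$states[[s]]
      writeLines(sprintf("#state\t%s\t%s", s,
                         paste0(names(lv), "=", lv, collapse = ",")), con)
    }
    writeLines(sprintf("%s\t%s\t%s", cm$edges$from, cm$edges$to,
                       cm$edges$weight), con)
  }
  invisible(path)
}

#' Load a network model
#'
#' Reads the JSON or TSV schema written by [save_network()] and returns a
#' fully validated model; weights are parsed as exact rationals (the token
#' `"1/3"` never passes through floating point).
#'
#' @param path Input file path.
#' @param format `"json"` or `"tsv"`; inferred from the extension when
#'   missing.
#' @return A `ccn_model`.
#' @export
load_network <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(format)) {
    format <- if (grepl("\\.tsv$", path)) "tsv" else "json"
  }
  format <- match.arg(format, c("json", "tsv"))
  if (format == "json") {
    doc <- jsonlite::read_json(path)
    need <- c("name", "semantics", "nodes", "edges", "states")
    miss <- setdiff(need, names(doc))
    if (length(miss)) stop("model file missing field '", miss[1], "'",
                           call. = FALSE)
    nodes <- tibble::tibble(
      name = vapply(doc$nodes, function(n) n$name, ""),
      max_level = vapply(doc$nodes, function(n) as.integer(n$max_level), 1L),
      self_degrading = vapply(doc$nodes, function(n)
        isTRUE(n$self_degrading), TRUE),
      thresholds = lapply(doc$nodes, function(n)
        as.character(unlist(n$thresholds))))
    edges <- tibble::tibble(
      from = vapply(doc$edges, function(e) e$from, ""),
      to = vapply(doc$edges, function(e) e$to, ""),
      weight = vapply(doc$edges, function(e) as.character(e$weight), ""))
    states <- lapply(doc$states, function(s) unlist(s))
    network_model(doc$name, doc$semantics, nodes, edges,
                  states$stationary_g1, states$stimulated_g1)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    meta <- strsplit(lines[startsWith(lines, "#")], "\t", fixed = TRUE)
    body <- strsplit(lines[!startsWith(lines, "#")], "\t", fixed = TRUE)
    getm <- function(tag) Filter(function(x) x[1] == paste0("#", tag), meta)
    name <- getm("name")[[1]][2]
    semantics <- getm("semantics")[[1]][2]
    nd <- getm("node")
    if (length(nd) == 0) stop("TSV model has no #node declarations",
                              call. = FALSE)
    nodes <- tibble::tibble(
      name = vapply(nd, `[`, "", 2),
      max_level = as.integer(vapply(nd, `[`, "", 3)),
      self_degrading = vapply(nd, `[`, "", 4) == "1",
      thresholds = lapply(nd, function(x) strsplit(x[5], ",")[[1]]))
    states <- lapply(getm("state"), function(x) {
      kv <- strsplit(strsplit(x[3], ",")[[1]], "=")
      stats::setNames(as.integer(vapply(kv, `[`, "", 2)),
                      vapply(kv, `[`, "", 1))
    })
    names(states) <- vapply(getm("state"), `[`, "", 2)
    bad <- which(lengths(body) != 3)
    if (length(bad)) stop("malformed edge line: '",
                          paste(body[[bad[1]]], collapse = "\t"), "'",
                          call. = FALSE)
    edges <- tibble::tibble(
      from = vapply(body, `[`, "", 1),
      to = vapply(body, `[`, "", 2),
      weight = vapply(body, `[`, "", 3))
    network_model(name, semantics, nodes, edges,
                  states$stationary_g1, states$stimulated_g1)
  }
}
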