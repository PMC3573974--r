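# Random edge-mutation robustness screening.
#
# A mutant differs from its base model by a fixed number (the mutation
# distance, 1-3) of elementary edge edits drawn from the edge slots related
# to one cell-cycle phase: deleting an existing edge, adding an absent one,
# or re-weighting an existing one.  Each mutant is screened for preservation
# of the stationary G1 state as the global attractor under full asynchrony;
# the fraction of screened mutants passing measures the timing robustness
# of that phase's wiring.

#' Edge slots related to a cell-cycle phase
#'
#' The phase's active nodes are those whose level changes during the phase
#' segment of the reference synchronous trajectory (stimulated G1 to
#' stationary G1, labelled with the 4-segment config).  The related slots
#' are all existing edges with such a node as source or target, plus all
#' absent ordered node pairs among the active nodes (candidates for edge
#' addition).
#'
#' @param model A `ccn_model`.
#' @param phase Phase name from the config.
#' @param config Phase config (default 4-segment).
#' @return Tibble with columns `from`, `to`, `existing`, `weight` (NA for
#'   absent slots).
#' @examples
#' phase_related_edges(yeast_model("proposed"), "G2")
#' @export
phase_related_edges <- function(model, phase, config = phase_config_4seg()) {
  if (!phase %in% names(config$phases)) {
    stop("unknown phase '", phase, "'", call. = FALSE)
  }
  traj <- simulate_model(model, stimulated_g1(model), "sync")
  labels <- label_trajectory(traj, model, config)
  in_phase <- labels == phase
  if (!any(in_phase)) {
    stop("phase '", phase, "' does not occur on the reference trajectory",
         call. = FALSE)
  }
  st <- traj$states
  changed <- character(0)
  for (i in which(in_phase)) {
    if (i < nrow(st)) {
      changed <- union(changed, colnames(st)[st[i, ] != st[i + 1, ]])
    }
  }
  if (length(changed) == 0) {
    stop("no node changes level during phase '", phase, "'", call. = FALSE)
  }
  existing <- dplyr::filter(model$edges,
                            .data$from %in% changed | .data$to %in% changed)
  pairs <- tidyr::expand_grid(from = changed, to = changed)
  pairs <- dplyr::anti_join(pairs, model$edges, by = c("from", "to"))
  dplyr::bind_rows(
    dplyr::mutate(existing, existing = TRUE),
    dplyr::mutate(pairs, weight = NA_character_, existing = FALSE)) |>
    dplyr::arrange(.data$from, .data$to)
}

random_weight6 <- function(current6, alphabet_mag, rng_keep_sign = NULL) {
  # re-weight: magnitude uniform over the alphabet, sign kept with
  # probability 1/2, resampled until different from the current weight
  repeat {
    mag <- sample(alphabet_mag, 1)
    sign_keep <- stats::runif(1) < 0.5
    s <- if (is.null(current6)) {
      sample(c(-1L, 1L), 1)
    } else if (sign_keep) sign(current6) else -sign(current6)
    w <- as.integer(s * mag)
    if (is.null(current6) || w != current6) return(w)
  }
}

apply_mutation <- function(model, ops) {
  edges <- model$edges
  for (i in seq_len(nrow(ops))) {
    op <- ops[i, ]
    hit <- edges$from == op$from & edges$to == op$to
    if (op$op == "delete") {
      edges <- edges[!hit, ]
    } else if (op$op == "reweight") {
      edges$weight[hit] <- op$weight
    } else {
      edges <- dplyr::bind_rows(edges,
                                tibble::tibble(from = op$from, to = op$to,
                                               weight = op$weight))
    }
  }
  network_model(paste0(model$name, "_mut"), model$semantics, model$nodes,
                edges, stationary_g1(model), stimulated_g1(model))
}

#' Generate random mutant networks
#'
#' Seeded and reproducible: each mutant applies exactly `distance` edits to
#' distinct phase-related edge slots (delete or re-weight an existing edge,
#' add an absent one).  Sampling is with replacement across mutants, so
#' duplicates can occur, mirroring blind random generation.
#'
#' @param model Base `ccn_model`.
#' @param phase Phase whose related edges are mutated.
#' @param distance Number of edge edits per mutant (1-3).
#' @param n Number of mutants.
#' @param seed Integer seed.
#' @param config Phase config used to determine related edges.
#' @return A list of `n` elements, each with `spec` (tibble of edits) and
#'   `model` (the mutant `ccn_model`).
#' @examples
#' mu <- generate_mutants(yeast_model("proposed"), "G2", 1, n = 3, seed = 1)
#' mu[[1]]$spec
#' @export
generate_mutants <- function(model, phase, distance, n, seed,
                             config = phase_config_4seg()) {
  stopifnot(n > 0, distance %in% 1:3)
  slots <- phase_related_edges(model, phase, config)
  if (nrow(slots) < distance) {
    stop("fewer than ", distance, " editable slots for phase '", phase, "'",
         call. = FALSE)
  }
  alphabet_mag <- unique(abs(weight_alphabet6(model$semantics)))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    rows <- sample(nrow(slots), distance)
    ops <- lapply(rows, function(r) {
      slot <- slots[r, ]
      if (slot$existing) {
        cur6 <- parse_rational6(slot$weight)
        if (stats::runif(1) < 0.5) {
          tibble::tibble(from = slot$from, to = slot$to, op = "delete",
                         weight = NA_character_)
        } else {
          tibble::tibble(from = slot$from, to = slot$to, op = "reweight",
                         weight = format_rational6(
                           random_weight6(cur6, alphabet_mag)))
        }
      } else {
        tibble::tibble(from = slot$from, to = slot$to, op = "add",
                       weight = format_rational6(
                         random_weight6(NULL, alphabet_mag)))
      }
    })
    spec <- dplyr::bind_rows(ops)
    list(spec = spec, model = apply_mutation(model, spec))
  })
}

#' Screen mutants for timing robustness
#'
#' Runs the global-attractor check (stationary G1 as the unique fair fate
#' of stimulated G1 under full asynchrony) on every mutant and aggregates
#' the fraction passing.  A mutant whose exploration exceeds the state cap
#' is counted as non-robust and flagged.
#'
#' @param mutants List from [generate_mutants()] (or a list of bare
#'   `ccn_model` objects).
#' @param initial Initial state; defaults to the first mutant's stimulated
#'   G1.
#' @param target Target state; defaults to the first mutant's stationary
#'   G1.
#' @param max_states Per-mutant state cap.
#' @return A `ccn_screen`: list with `table` (per-mutant tibble) and
#'   `summary` (one-row tibble with `n_mutants`, `n_robust`, `fraction`).
#' @export
screen_mutants <- function(mutants, initial = NULL, target = NULL,
                           max_states = 1e6) {
  models <- lapply(mutants, function(m) if (inherits(m, "ccn_model")) m
                   else m$model)
  if (length(models) == 0) stop("no mutants to screen", call. = FALSE)
  if (is.null(initial)) initial <- stimulated_g1(models[[1]])
  if (is.null(target)) target <- stationary_g1(models[[1]])
  rows <- lapply(seq_along(models), function(i) {
    m <- models[[i]]
    res <- tryCatch({
      tgt <- validate_state_vec(target, m$nodes, "target")
      if (!identical(unname(sync_step(m, tgt)), unname(tgt))) {
        list(status = "fail", note = "target not a fixed point")
      } else {
        v <- check_global_attractor(m, initial, tgt, max_states = max_states)
        list(status = v$status, note = v$note)
      }
    }, error = function(e) list(status = "fail",
                                note = paste("error:", conditionMessage(e))))
    tibble::tibble(mutant = i, robust = res$status == "pass",
                   note = if (is.null(res$note)) NA_character_ else res$note)
  })
  tab <- dplyr::bind_rows(rows)
  structure(list(
    table = tab,
    summary = tibble::tibble(n_mutants = nrow(tab),
                             n_robust = sum(tab$robust),
                             fraction = mean(tab$robust))),
    class = "ccn_screen")
}

#' @export
print.ccn_screen <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<ccn_screen> %d/%d mutants timing-robust (fraction %.2f)\n",
              s$n_robust, s$n_mutants, s$fraction))
  invisible(x)
}

#' @rdname screen_mutants
#' @param x A `ccn_screen`.
#' @param ... Unused.
#' @export
tidy.ccn_screen <- function(x, ...) x$table

#' @rdname screen_mutants
#' @export
glance.ccn_screen <- function(x, ...) x$summary

#' Full robustness screen over phases and distances
#'
#' Convenience wrapper mirroring the published screen layout: for each
#' requested phase and mutation distance, generates `n` mutants and screens
#' them, returning one row per (phase, distance) cell.
#'
#' @param model Base `ccn_model`.
#' @param phases Character vector of phase names.
#' @param distances Integer vector of mutation distances.
#' @param n Mutants per cell.
#' @param seed Integer seed (each cell derives its own sub-seed).
#' @param config Phase config.
#' @param max_states Per-mutant state cap.
#' @return Tibble with columns `phase`, `distance`, `n`, `n_robust`,
#'   `fraction`, `seed`.
#' @export
robustness_screen <- function(model, phases = c("G1", "S", "G2", "M"),
                              distances = 1:3, n = 200, seed = 1,
                              config = phase_config_4seg(),
                              max_states = 1e6) {
  grid <- tidyr::expand_grid(phase = phases, distance = distances)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    ph <- grid$phase[i]; d <- grid$distance[i]
    sub_seed <- (seed * 1000L + i) %% .Machine$integer.max
    mu <- generate_mutants(model, ph, d, n, sub_seed, config)
    sc <- screen_mutants(mu, stimulated_g1(model), stationary_g1(model),
                         max_states)
    tibble::tibble(phase = ph, distance = d, n = n,
                   n_robust = sc$summary$n_robust,
                   fraction = sc$summary$fraction, seed = sub_seed)
  })
  dplyr::bind_rows(rows)
}
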