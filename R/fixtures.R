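# The three bundled yeast cell-cycle network fixtures.
#
# Canonical node order (the column order of the published attractor
# tables): Cln3, MBF, SBF, Cln2, Cdh1, Swi5, Cdc20, Clb5, Sic1, Clb2, Mcm1.
#
# The Li model is the classical binary threshold network of the yeast cell
# cycle: all weights +/-1, threshold 0 with maintain-on-tie, and
# self-degradation on the five nodes that decay in the absence of input
# (Cln3, Cln2, Swi5, Cdc20, Mcm1).
#
# The graded models replace the tie rule with explicit level-entry
# thresholds (1/2 and 3/2) and the weight alphabet {1/3, 1, 3}; nodes that
# persist without input carry an explicit self-sustaining loop, and Clb2
# (plus Swi5 in the revised model) is three-valued.  Their edge tables are
# transcriptions of the corresponding network diagrams, pinned down by
# requiring bit-exact reproduction of the published basin-size tables,
# which act as checksums of the transcription.
#
# The revised ("proposed") model differs from the graded base model in
# exactly four edges plus the graded Swi5: the Clb5->Mcm1 weight is lowered
# to 1/3 (so Mcm1 activation needs Clb2, closing the Clb2/Mcm1 positive
# feedback), Cdc20->Swi5 is strengthened and Clb2->Swi5 weakened (so Cdc20
# activates Swi5 regardless of the Clb2 level), and Swi5->Sic1 is weakened
# (so only fully activated Swi5 turns Sic1 on).

canonical_nodes <- c("Cln3", "MBF", "SBF", "Cln2", "Cdh1", "Swi5", "Cdc20",
                     "Clb5", "Sic1", "Clb2", "Mcm1")

li_edge_table <- function() {
  e <- c(
    "Cln3", "MBF",   "1",
    "Cln3", "SBF",   "1",
    "Clb2", "MBF",   "-1",
    "Clb2", "SBF",   "-1",
    "SBF",  "Cln2",  "1",
    "MBF",  "Clb5",  "1",
    "Sic1", "Clb5",  "-1",
    "Cdc20", "Clb5", "-1",
    "Cln2", "Sic1",  "-1",
    "Clb5", "Sic1",  "-1",
    "Clb2", "Sic1",  "-1",
    "Swi5", "Sic1",  "1",
    "Cdc20", "Sic1", "1",
    "Clb5", "Clb2",  "1",
    "Mcm1", "Clb2",  "1",
    "Sic1", "Clb2",  "-1",
    "Cdh1", "Clb2",  "-1",
    "Cdc20", "Clb2", "-1",
    "Cln2", "Cdh1",  "-1",
    "Clb5", "Cdh1",  "-1",
    "Clb2", "Cdh1",  "-1",
    "Cdc20", "Cdh1", "1",
    "Clb2", "Cdc20", "1",
    "Mcm1", "Cdc20", "1",
    "Mcm1", "Swi5",  "1",
    "Cdc20", "Swi5", "1",
    "Clb2", "Swi5",  "-1",
    "Clb5", "Mcm1",  "1",
    "Clb2", "Mcm1",  "1")
  m <- matrix(e, ncol = 3, byrow = TRUE)
  tibble::tibble(from = m[, 1], to = m[, 2], weight = m[, 3])
}

g1_state <- function() {
  st <- stats::setNames(rep(0L, 11), canonical_nodes)
  st[c("Cdh1", "Sic1")] <- 1L
  st
}

li_fixture <- function() {
  nodes <- tibble::tibble(
    name = canonical_nodes,
    max_level = 1L,
    self_degrading = canonical_nodes %in%
      c("Cln3", "Cln2", "Swi5", "Cdc20", "Mcm1"))
  network_model("li", "li_binary", nodes, li_edge_table(), g1_state())
}

# Graded-model edge weights.  Entries override the +/-1 magnitudes of the
# binary table; self-loops and the Cdh1 -| Cdc20 edge are additions.
mangla_edge_table <- function() {
  base <- li_edge_table()
  w <- mangla_weights()
  key <- paste(base$from, base$to)
  base$weight <- ifelse(key %in% names(w), w[key], base$weight)
  base <- base[!is.na(base$weight), ]
  extra <- mangla_extra_edges()
  dplyr::bind_rows(base, extra)
}

proposed_edge_table <- function() {
  e <- mangla_edge_table()
  ovr <- proposed_overrides()
  key <- paste(e$from, e$to)
  e$weight <- ifelse(key %in% names(ovr), ovr[key], e$weight)
  e
}

mangla_fixture <- function() {
  nodes <- tibble::tibble(
    name = canonical_nodes,
    max_level = ifelse(canonical_nodes == "Clb2", 2L, 1L),
    self_degrading = FALSE)
  network_model("mangla", "multilevel", nodes, mangla_edge_table(),
                g1_state())
}

proposed_fixture <- function() {
  nodes <- tibble::tibble(
    name = canonical_nodes,
    max_level = ifelse(canonical_nodes %in% c("Clb2", "Swi5"), 2L, 1L),
    self_degrading = FALSE)
  network_model("proposed", "multilevel", nodes, proposed_edge_table(),
                g1_state())
}

#' Bundled yeast cell-cycle models
#'
#' `yeast_model()` returns one of the three reference models by name;
#' `bundled_fixtures()` returns all three.  `"li"` is the classical binary
#' model (2048 states); `"mangla"` its graded timing-robust extension with
#' three-valued Clb2 (3072 states); `"proposed"` the revised hazard-free
#' model with three-valued Clb2 and Swi5 (4608 states).
#'
#' @param name `"li"`, `"mangla"` or `"proposed"`.
#' @return A `ccn_model` (or a named list of all three).
#' @examples
#' vapply(bundled_fixtures(), state_space_size, 1L)
#' @export
yeast_model <- function(name = c("li", "mangla", "proposed")) {
  name <- match.arg(name)
  switch(name,
         li = li_fixture(),
         mangla = mangla_fixture(),
         proposed = proposed_fixture())
}

#' @rdname yeast_model
#' @export
bundled_fixtures <- function() {
  list(li = yeast_model("li"), mangla = yeast_model("mangla"),
       proposed = yeast_model("proposed"))
}
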