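# Numeric weight tables of the two graded fixtures.
#
# Kept in one place so the transcription is easy to audit.  Names are
# "from to" keys into the binary edge table; values are rational weight
# tokens (sign as in the binary model); NA drops the edge.  The assignment
# was pinned down by requiring the published synchronous basin tables (the
# transcription checksums) together with the documented qualitative
# dynamics and the documented hazard/checkpoint verdict pattern; the
# methods vignette discusses what these checks do and do not determine.

mangla_weights <- function() {
  c("Cln3 MBF"   = "3",
    "Cln3 SBF"   = "3",
    "Cdc20 Clb5" = "-1/3",
    "Cln2 Sic1"  = "-3",
    "Clb2 Sic1"  = "-3",
    "Swi5 Sic1"  = "3",
    "Cdc20 Sic1" = "3",
    "Clb5 Sic1"  = NA,
    "Cdh1 Clb2"  = NA,
    "Cdc20 Clb2" = "-1/3",
    "Clb2 Cdc20" = NA)
}

# self-sustaining loops and the APC/Cdh1-mediated Cdc20 shut-off
mangla_extra_edges <- function() {
  tibble::tibble(
    from   = c("MBF", "SBF", "Cdh1", "Sic1", "Cdc20", "Clb2", "Cdh1"),
    to     = c("MBF", "SBF", "Cdh1", "Sic1", "Cdc20", "Clb2", "Cdc20"),
    weight = c("1", "1", "1", "1", "1", "1/3", "-3"))
}

# the four documented revisions of the graded base model
proposed_overrides <- function() {
  c("Clb5 Mcm1"  = "1/3",
    "Cdc20 Swi5" = "3",
    "Clb2 Swi5"  = "-1/3",
    "Swi5 Sic1"  = "1/3")
}
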