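# Exact rational weights.
#
# Edge weights come from the alphabet {1/3, 1, 3} (signed) and thresholds are
# half-integers (1/2, 3/2).  1/3 has no binary floating-point representation,
# and threshold comparisons must be bit-exact, so weights and thresholds are
# carried as integer numerators over the common denominator 6.  All weighted
# sums are therefore computed in units of 1/6 and compared with integer
# arithmetic; floating point never enters the update rule.

#' Parse a rational token
#'
#' Parses strings such as `"1/3"`, `"-3"` or `"3/2"` into an exact integer
#' numerator over the denominator 6.
#'
#' @param x Character vector of rational tokens (`"a"` or `"a/b"` with
#'   `b` dividing 6).
#' @return Integer vector of numerators on the denominator-6 scale
#'   (`"1/3"` becomes `2L`, `"1"` becomes `6L`).
#' @keywords internal
parse_rational6 <- function(x) {
  out <- vapply(x, function(tok) {
    tok <- trimws(tok)
    if (!grepl("^-?[0-9]+(/[0-9]+)?$", tok)) {
      stop("invalid rational token: '", tok, "'", call. = FALSE)
    }
    parts <- strsplit(tok, "/", fixed = TRUE)[[1]]
    num <- as.integer(parts[1])
    den <- if (length(parts) == 2) as.integer(parts[2]) else 1L
    if (den <= 0 || 6L %% den != 0L) {
      stop("rational '", tok, "' is not representable on sixths", call. = FALSE)
    }
    num * (6L %/% den)
  }, integer(1), USE.NAMES = FALSE)
  out
}

#' Render a denominator-6 numerator back to its canonical token
#'
#' Inverse of [parse_rational6()]: `2L` becomes `"1/3"`, `6L` becomes `"1"`.
#'
#' @param w6 Integer vector on the denominator-6 scale.
#' @return Character vector of canonical rational tokens in lowest terms.
#' @keywords internal
format_rational6 <- function(w6) {
  vapply(w6, function(v) {
    g <- gcd_int(abs(v), 6L)
    num <- v %/% g
    den <- 6L %/% g
    if (den == 1L) as.character(num) else paste0(num, "/", den)
  }, character(1))
}

gcd_int <- function(a, b) {
  while (b != 0L) {
    t <- b
    b <- a %% b
    a <- t
  }
  if (a == 0L) 1L else a
}

# signed weight alphabet on the sixths scale: +/- 1/3, 1, 3
weight_alphabet6 <- function(semantics = c("multilevel", "li_binary")) {
  semantics <- match.arg(semantics)
  if (semantics == "li_binary") c(-6L, 6L) else c(-18L, -6L, -2L, 2L, 6L, 18L)
}
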