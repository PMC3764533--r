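## Base-pair rule sets. Canonical pairs are G-C and A-U; the wobble set adds
## G:U; the extended set additionally admits the A:G / A:C classes that
## structure diagrams mark as noncanonical, plus any pairs supplied
## explicitly.

#' Base-pair rule sets
#'
#' @param name `"canonical"` (A-U, G-C), `"canonical+wobble"` (adds G:U) or
#'   `"extended"` (adds the noncanonical A:G and A:C classes).
#' @param extra Character vector of additional unordered pairs, e.g.
#'   `c("AA", "UU")`, admitted only when explicitly given.
#' @return An object of class `pair_rule`: `name` plus the set of allowed
#'   unordered residue pairs.
#' @examples
#' pair_rule("canonical+wobble")
#' @export
pair_rule <- function(name = c("canonical+wobble", "canonical", "extended"),
                      extra = character(0)) {
  name <- match.arg(name)
  allowed <- switch(name,
    "canonical" = c("AU", "GC"),
    "canonical+wobble" = c("AU", "GC", "GU"),
    "extended" = c("AU", "GC", "GU", "AG", "AC")
  )
  extra <- toupper(extra)
  if (length(extra) > 0L && any(nchar(extra) != 2L)) {
    stop("extra pairs must be 2-letter codes", call. = FALSE)
  }
  allowed <- unique(c(allowed, extra))
  structure(list(name = name, allowed = allowed), class = "pair_rule")
}

#' @export
print.pair_rule <- function(x, ...) {
  cat(sprintf(
    "<pair_rule> %s: {%s}\n", x$name,
    paste(x$allowed, collapse = ", ")
  ))
  invisible(x)
}

## 5x5 logical lookup over A,C,G,U,N ('N' never pairs).
pair_matrix <- function(rule) {
  stopifnot(inherits(rule, "pair_rule"))
  m <- matrix(FALSE, 5, 5, dimnames = list(RNA_ALPHABET, RNA_ALPHABET))
  for (p in rule$allowed) {
    a <- substr(p, 1, 1)
    b <- substr(p, 2, 2)
    if (a == "N" || b == "N") next
    m[a, b] <- TRUE
    m[b, a] <- TRUE
  }
  m
}

#' Is a residue pair allowed under a rule?
#'
#' Vectorized over `a`, `b`; `N` (and gaps) never pair.
#'
#' @param a,b Residue characters.
#' @param rule A [pair_rule()].
#' @return Logical vector.
#' @export
pair_allowed <- function(a, b, rule = pair_rule()) {
  m <- pair_matrix(rule)
  a <- toupper(a)
  b <- toupper(b)
  ok <- a %in% RNA_ALPHABET & b %in% RNA_ALPHABET
  out <- logical(length(a))
  out[ok] <- m[cbind(a[ok], b[ok])]
  out
}
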