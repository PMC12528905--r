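# Minimal arbitrary-precision non-negative integers.
#
# Theoretical library diversities are products like 32^28, far beyond the
# 2^53 exactly-representable range of doubles, so diversity accounting is
# done on exact integers.  Values are stored little-endian in base 1e4;
# every intermediate product/sum stays well below 2^53.

BI_BASE <- 10000L

#' Exact non-negative integers of arbitrary size
#'
#' Constructor for the `big_integer` class used by the diversity
#' calculators ([cassette_dna_diversity()], [theoretical_library_stats()]).
#' Supports construction from a non-negative integer-valued scalar or a
#' decimal digit string.
#'
#' @param x A single non-negative whole number (must be below 2^53 so it is
#'   exact as a double) or a string of decimal digits.
#' @return An object of class `big_integer`.
#' @examples
#' big_integer(32)
#' big_integer("1208925819614629174706176") # 32^16
#' @export
big_integer <- function(x) {
  if (inherits(x, "big_integer")) return(x)
  if (is.character(x)) {
    stopifnot(length(x) == 1L, grepl("^[0-9]+$", x))
    digs <- as.integer(strsplit(x, "")[[1]])
    chunks <- integer(0)
    while (length(digs)) {
      take <- tail(digs, 4L)
      chunks <- c(chunks, sum(take * 10L^(rev(seq_along(take)) - 1L)))
      digs <- head(digs, -4L)
    }
    return(bi_trim(structure(list(chunks = chunks), class = "big_integer")))
  }
  stopifnot(length(x) == 1L, is.numeric(x), x >= 0, x == floor(x), x < 2^53)
  chunks <- integer(0)
  repeat {
    chunks <- c(chunks, as.integer(x %% BI_BASE))
    x <- floor(x / BI_BASE)
    if (x == 0) break
  }
  structure(list(chunks = chunks), class = "big_integer")
}

bi_trim <- function(b) {
  ch <- b$chunks
  while (length(ch) > 1L && ch[length(ch)] == 0L) ch <- ch[-length(ch)]
  b$chunks <- ch
  b
}

#' @export
#' @method print big_integer
print.big_integer <- function(x, ...) {
  cat(format(x), if (bi_compare(x, big_integer(1e6)) > 0)
    paste0(" (~", format_sci(x), ")") else "", "\n", sep = "")
  invisible(x)
}

#' @export
#' @method format big_integer
format.big_integer <- function(x, ...) {
  ch <- rev(x$chunks)
  paste0(ch[1L], paste(sprintf("%04d", ch[-1L]), collapse = ""))
}

#' @export
#' @method as.double big_integer
as.double.big_integer <- function(x, ...) {
  sum(x$chunks * as.numeric(BI_BASE)^(seq_along(x$chunks) - 1))
}

#' @export
#' @method as.character big_integer
as.character.big_integer <- function(x, ...) format(x)

format_sci <- function(b, digits = 3) {
  s <- format(b)
  if (nchar(s) <= digits + 1) return(s)
  mant <- as.numeric(paste0(substr(s, 1, 1), ".", substr(s, 2, digits + 1)))
  sprintf("%.*fe+%02d", digits, mant, nchar(s) - 1L)
}

bi_add <- function(a, b) {
  a <- big_integer(a); b <- big_integer(b)
  n <- max(length(a$chunks), length(b$chunks))
  x <- c(a$chunks, integer(n - length(a$chunks)))
  y <- c(b$chunks, integer(n - length(b$chunks)))
  out <- integer(0); carry <- 0L
  for (i in seq_len(n)) {
    s <- x[i] + y[i] + carry
    out <- c(out, s %% BI_BASE)
    carry <- s %/% BI_BASE
  }
  if (carry > 0L) out <- c(out, carry)
  bi_trim(structure(list(chunks = out), class = "big_integer"))
}

# multiply by a machine integer 0 <= k < 2^31
bi_mul_small <- function(a, k) {
  a <- big_integer(a)
  stopifnot(k >= 0, k == floor(k), k < 2^31)
  if (k == 0) return(big_integer(0))
  out <- numeric(0); carry <- 0
  for (ch in a$chunks) {
    p <- ch * k + carry
    out <- c(out, p %% BI_BASE)
    carry <- floor(p / BI_BASE)
  }
  while (carry > 0) {
    out <- c(out, carry %% BI_BASE)
    carry <- floor(carry / BI_BASE)
  }
  bi_trim(structure(list(chunks = as.integer(out)), class = "big_integer"))
}

bi_mul <- function(a, b) {
  a <- big_integer(a); b <- big_integer(b)
  acc <- big_integer(0)
  for (i in seq_along(b$chunks)) {
    part <- bi_mul_small(a, b$chunks[i])
    if (i > 1L) part$chunks <- c(integer(i - 1L), part$chunks)
    acc <- bi_add(acc, bi_trim(part))
  }
  acc
}

bi_prod <- function(ks) Reduce(bi_mul_small, ks, accumulate = FALSE, init = big_integer(1))

# -1 / 0 / 1 for a < b, a == b, a > b
bi_compare <- function(a, b) {
  a <- big_integer(a); b <- big_integer(b)
  if (length(a$chunks) != length(b$chunks))
    return(sign(length(a$chunks) - length(b$chunks)))
  for (i in rev(seq_along(a$chunks))) {
    if (a$chunks[i] != b$chunks[i]) return(sign(a$chunks[i] - b$chunks[i]))
  }
  0L
}

#' @export
#' @method == big_integer
"==.big_integer" <- function(e1, e2) bi_compare(e1, e2) == 0L
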