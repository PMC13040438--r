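# Exact rational arithmetic for stoichiometric bookkeeping.
#
# Every flux multiplier and stoichiometric coefficient in a scenario ledger is
# a small rational number (quarters, halves, small integers), and the module
# contract is that carrier balances close to exactly zero -- not to within a
# floating-point tolerance.  Numerators and denominators are whole numbers
# stored as doubles; everything a ledger computes stays far below 2^53, so
# the arithmetic is exact.

#' Exact rational numbers
#'
#' A vectorised rational number class used by the stoichiometric ledger so
#' that carrier and species balances close to exactly zero.  Supports the
#' usual arithmetic (`+`, `-`, `*`, `/`), comparisons, `sum()`, `abs()`,
#' names, and conversion to/from numeric and strings such as `"5/4"`.
#'
#' @param num Numerator(s): whole numbers, `rational` objects, or strings
#'   like `"3/4"`.  Plain doubles are accepted when they are exactly
#'   representable with a denominator up to 4096 (e.g. `0.25`).
#' @param den Denominator(s), whole and non-zero.  Recycled against `num`.
#' @return A `rational` vector.
#' @examples
#' rational(5, 4) + rational("3/4")   # exactly 2
#' sum(rational(1, 3), rational(1, 3), rational(1, 3)) == 1
#' @export
rational <- function(num, den = 1) {
  if (is_rational(num)) {
    if (!all(den == 1)) stop("cannot combine a rational numerator with a denominator")
    return(num)
  }
  if (is.character(num)) return(rational_from_string(num))
  if (!is.numeric(num) || !is.numeric(den)) stop("rational() expects numeric input")
  k <- max(length(num), length(den))
  num <- rep_len(as.double(num), k)
  den <- rep_len(as.double(den), k)
  if (any(den == 0)) stop("zero denominator")
  if (any(num != round(num)) || any(den != round(den))) {
    stop("numerator and denominator must be whole numbers; use as_rational() for decimals")
  }
  new_rational(num, den)
}

new_rational <- function(num, den, nms = NULL) {
  neg <- den < 0
  num[neg] <- -num[neg]
  den[neg] <- -den[neg]
  g <- rat_gcd(abs(num), den)
  g[g == 0] <- 1
  structure(list(num = num / g, den = den / g, names = nms), class = "rational")
}

rat_gcd <- function(a, b) {
  while (any(b != 0)) {
    t <- b
    b <- ifelse(b == 0, 0, a %% b)
    a <- t
  }
  a
}

rational_from_string <- function(x) {
  parts <- strsplit(x, "/", fixed = TRUE)
  num <- vapply(parts, function(p) as.double(p[[1]]), 0)
  den <- vapply(parts, function(p) if (length(p) > 1) as.double(p[[2]]) else 1, 0)
  if (any(is.na(num)) || any(is.na(den))) stop("malformed rational string")
  out <- rational(num, den)
  out$names <- names(x)
  out
}

#' Coerce to rational
#'
#' Accepts `rational` vectors, whole numbers, fraction strings (`"5/4"`) and
#' decimals that are exactly representable with denominator at most
#' `max_denominator` (so `0.25` works, `1/3` written as `0.333` does not).
#'
#' @param x Object to coerce.
#' @param max_denominator Largest denominator tried for decimal input.
#' @return A `rational` vector.
#' @export
as_rational <- function(x, max_denominator = 4096L) {
  if (is_rational(x)) return(x)
  if (is.character(x)) return(rational_from_string(x))
  if (!is.numeric(x)) stop("cannot coerce to rational")
  num <- den <- numeric(length(x))
  for (i in seq_along(x)) {
    if (!is.finite(x[i])) stop("cannot coerce non-finite value to rational")
    q <- 1
    while (q <= max_denominator && abs(x[i] * q - round(x[i] * q)) > 1e-9) q <- q + 1
    if (q > max_denominator) stop("value ", x[i], " is not an exact small rational")
    num[i] <- round(x[i] * q)
    den[i] <- q
  }
  out <- new_rational(num, den, names(x))
  out
}

#' @export
is_rational <- function(x) inherits(x, "rational")

#' @export
length.rational <- function(x) length(x$num)

#' @export
names.rational <- function(x) x$names

#' @export
`names<-.rational` <- function(x, value) {
  x$names <- value
  x
}

#' @export
`[.rational` <- function(x, i) {
  if (is.character(i)) i <- match(i, x$names)
  new_rational(x$num[i], x$den[i], if (!is.null(x$names)) x$names[i])
}

#' @export
c.rational <- function(...) {
  parts <- lapply(list(...), as_rational)
  nms <- unlist(lapply(parts, function(p) if (is.null(p$names)) rep("", length(p)) else p$names))
  if (all(nms == "")) nms <- NULL
  new_rational(
    unlist(lapply(parts, `[[`, "num")),
    unlist(lapply(parts, `[[`, "den")),
    nms
  )
}

#' @export
as.double.rational <- function(x, ...) {
  out <- x$num / x$den
  names(out) <- x$names
  out
}

#' @export
format.rational <- function(x, ...) {
  out <- ifelse(x$den == 1, sprintf("%g", x$num), sprintf("%g/%g", x$num, x$den))
  names(out) <- x$names
  out
}

#' @export
print.rational <- function(x, ...) {
  print(format(x), quote = FALSE)
  invisible(x)
}

#' @export
as.character.rational <- function(x, ...) format(x)

#' @export
Ops.rational <- function(e1, e2) {
  if (missing(e2)) {
    e1 <- as_rational(e1)
    return(switch(.Generic,
      "-" = new_rational(-e1$num, e1$den, e1$names),
      "+" = e1,
      stop("unary ", .Generic, " not defined for rational")
    ))
  }
  a <- as_rational(e1)
  b <- as_rational(e2)
  nms <- if (!is.null(a$names)) a$names else b$names
  switch(.Generic,
    "+" = new_rational(a$num * b$den + b$num * a$den, a$den * b$den, nms),
    "-" = new_rational(a$num * b$den - b$num * a$den, a$den * b$den, nms),
    "*" = new_rational(a$num * b$num, a$den * b$den, nms),
    "/" = {
      if (any(b$num == 0)) stop("division by zero rational")
      new_rational(a$num * b$den, a$den * b$num, nms)
    },
    "==" = a$num * b$den == b$num * a$den,
    "!=" = a$num * b$den != b$num * a$den,
    "<" = a$num * b$den < b$num * a$den,
    "<=" = a$num * b$den <= b$num * a$den,
    ">" = a$num * b$den > b$num * a$den,
    ">=" = a$num * b$den >= b$num * a$den,
    stop(.Generic, " not defined for rational")
  )
}

#' @export
Summary.rational <- function(..., na.rm = FALSE) {
  x <- c.rational(...)
  switch(.Generic,
    sum = {
      acc <- rational(0)
      for (i in seq_along(x)) acc <- acc + x[i]
      acc$names <- NULL
      acc
    },
    min = x[which.min(as.double(x))],
    max = x[which.max(as.double(x))],
    range = c(min(x), max(x)),
    stop(.Generic, " not defined for rational")
  )
}

#' @export
Math.rational <- function(x, ...) {
  switch(.Generic,
    abs = new_rational(abs(x$num), x$den, x$names),
    sign = sign(x$num),
    get(.Generic)(as.double(x), ...)
  )
}

# Fold (name, rational) pairs into a named rational of per-name totals.
rat_accumulate <- function(names_vec, values) {
  keys <- unique(names_vec)
  num <- den <- numeric(length(keys))
  for (k in seq_along(keys)) {
    tot <- rational(0)
    for (i in which(names_vec == keys[k])) tot <- tot + values[i]
    num[k] <- tot$num
    den[k] <- tot$den
  }
  new_rational(num, den, keys)
}
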