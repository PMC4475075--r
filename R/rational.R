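# Exact rational arithmetic on reduced integer pairs.
#
# Numerators and denominators are stored as integer-valued doubles, which are
# exact below 2^53; every constructor reduces by the gcd and re-checks the
# bound, so silent precision loss is impossible.  Shapes (vector or matrix)
# follow the numerator.

.RAT_MAX <- 2^52

.gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (any(b > 0)) {
    r <- ifelse(b > 0, a %% b, 0)
    a <- ifelse(b > 0, b, a)
    b <- r
  }
  a
}

new_rat <- function(num, den) structure(list(num = num, den = den), class = "rat")

#' Exact rational numbers
#'
#' Construct a vector or matrix of exact rationals from integer-valued
#' numerators and denominators.  All stoichiometric and kernel arithmetic in
#' the package runs on this representation so that worked examples are
#' reproduced bit-exactly, with no floating-point drift.
#'
#' @param num integer-valued numeric vector or matrix of numerators.
#' @param den integer-valued denominators, recycled against `num`.
#' @return an object of class `"rat"` supporting arithmetic (`+`, `-`, `*`,
#'   `/`), comparison, subsetting and `as.numeric()`.
#' @examples
#' rat(1, 2) + rat(1, 3)   # 5/6
#' as.numeric(rat(-3, 6))  # -0.5
#' @export
rat <- function(num, den = 1) {
  if (inherits(num, "rat")) return(num)
  stopifnot(is.numeric(num), is.numeric(den))
  if (length(den) == 1 && length(num) > 1) {
    d <- num; d[] <- den; den <- d
  }
  if (any(num != round(num)) || any(den != round(den)))
    stop("rational components must be integer-valued", call. = FALSE)
  if (any(den == 0)) stop("zero denominator", call. = FALSE)
  .rat_reduce(num, den)
}

.rat_reduce <- function(num, den) {
  s <- sign(den)
  num <- num * s
  den <- den * s
  g <- .gcd(num, den)
  g[g == 0] <- 1
  num <- num / g
  den <- den / g
  den[num == 0] <- 1
  if (any(abs(num) >= .RAT_MAX) || any(den >= .RAT_MAX))
    stop("rational overflow: magnitude exceeds exact double range", call. = FALSE)
  new_rat(num, den)
}

#' @export
Ops.rat <- function(e1, e2) {
  if (nargs() == 1L) {
    if (.Generic == "-") return(new_rat(-e1$num, e1$den))
    if (.Generic == "+") return(e1)
    stop("unary ", .Generic, " undefined for rat")
  }
  if (!inherits(e1, "rat")) e1 <- rat(e1)
  if (!inherits(e2, "rat")) e2 <- rat(e2)
  # let length-1 operands broadcast against any shape
  if (length(e1$num) == 1L) { e1$num <- c(e1$num); e1$den <- c(e1$den) }
  if (length(e2$num) == 1L) { e2$num <- c(e2$num); e2$den <- c(e2$den) }
  switch(.Generic,
    "+" = .rat_reduce(e1$num * e2$den + e2$num * e1$den, e1$den * e2$den),
    "-" = .rat_reduce(e1$num * e2$den - e2$num * e1$den, e1$den * e2$den),
    "*" = .rat_reduce(e1$num * e2$num, e1$den * e2$den),
    "/" = {
      if (any(e2$num == 0)) stop("rational division by zero", call. = FALSE)
      .rat_reduce(e1$num * e2$den, e1$den * e2$num)
    },
    "==" = e1$num * e2$den == e2$num * e1$den,
    "!=" = e1$num * e2$den != e2$num * e1$den,
    "<"  = e1$num * e2$den <  e2$num * e1$den,
    "<=" = e1$num * e2$den <= e2$num * e1$den,
    ">"  = e1$num * e2$den >  e2$num * e1$den,
    ">=" = e1$num * e2$den >= e2$num * e1$den,
    stop(.Generic, " undefined for rat")
  )
}

#' @export
`[.rat` <- function(x, i, j, ..., drop = FALSE) {
  if (is.matrix(x$num) && nargs() > 2L) {
    if (missing(i)) i <- seq_len(nrow(x$num))
    if (missing(j)) j <- seq_len(ncol(x$num))
    new_rat(x$num[i, j, drop = drop], x$den[i, j, drop = drop])
  } else {
    new_rat(x$num[i], x$den[i])
  }
}

#' @export
`[<-.rat` <- function(x, i, j, ..., value) {
  value <- rat(value)
  if (is.matrix(x$num) && nargs() > 3L) {
    if (missing(i)) i <- seq_len(nrow(x$num))
    if (missing(j)) j <- seq_len(ncol(x$num))
    x$num[i, j] <- value$num
    x$den[i, j] <- value$den
  } else {
    x$num[i] <- value$num
    x$den[i] <- value$den
  }
  x
}

#' @export
length.rat <- function(x) length(x$num)

#' @export
dim.rat <- function(x) dim(x$num)

#' @export
as.double.rat <- function(x, ...) as.numeric.rat(x, ...)

#' @export
as.numeric.rat <- function(x, ...) {
  out <- x$num / x$den
  attributes(out) <- attributes(x$num)
  out
}

#' @export
as.matrix.rat <- function(x, ...) {
  m <- x$num / x$den
  if (!is.matrix(m)) m <- matrix(m, ncol = 1)
  m
}

#' @export
format.rat <- function(x, ...) {
  out <- ifelse(x$den == 1, format(x$num, scientific = FALSE, trim = TRUE),
                paste0(format(x$num, scientific = FALSE, trim = TRUE), "/",
                       format(x$den, scientific = FALSE, trim = TRUE)))
  attributes(out) <- attributes(x$num)
  out
}

#' @export
print.rat <- function(x, ...) {
  print(format(x), quote = FALSE)
  invisible(x)
}

rat_sign <- function(x) sign(x$num)

rat_is_zero <- function(x) x$num == 0

rat_abs <- function(x) new_rat(abs(x$num), x$den)

rat_matrix <- function(x, nrow, ncol) {
  x <- rat(x)
  new_rat(matrix(x$num, nrow, ncol), matrix(x$den, nrow, ncol))
}

rat_cbind <- function(...) {
  parts <- list(...)
  new_rat(do.call(cbind, lapply(parts, `[[`, "num")),
          do.call(cbind, lapply(parts, `[[`, "den")))
}

rat_rbind <- function(...) {
  parts <- list(...)
  new_rat(do.call(rbind, lapply(parts, `[[`, "num")),
          do.call(rbind, lapply(parts, `[[`, "den")))
}

rat_t <- function(x) new_rat(t(x$num), t(x$den))

rat_sum <- function(x) {
  acc <- rat(0)
  for (k in seq_along(x$num)) acc <- acc + new_rat(x$num[k], x$den[k])
  acc
}

# Exact matrix product.
rat_mm <- function(a, b) {
  n <- nrow(a$num); m <- ncol(b$num)
  out <- rat_matrix(0, n, m)
  bt <- rat_t(b)
  for (i in seq_len(n)) {
    ai <- a[i, , drop = FALSE]
    for (j in seq_len(m)) {
      out[i, j] <- rat_sum(ai * bt[j, , drop = FALSE])
    }
  }
  out
}

# Parse strings into rationals: integers, p/q fractions, or plain decimals.
rat_parse <- function(x) {
  x <- trimws(as.character(x))
  num <- den <- numeric(length(x))
  for (k in seq_along(x)) {
    s <- x[k]
    if (grepl("^[+-]?[0-9]+$", s)) {
      num[k] <- as.numeric(s); den[k] <- 1
    } else if (grepl("^[+-]?[0-9]+/[0-9]+$", s)) {
      parts <- strsplit(s, "/", fixed = TRUE)[[1]]
      num[k] <- as.numeric(parts[1]); den[k] <- as.numeric(parts[2])
    } else if (grepl("^[+-]?[0-9]*\\.[0-9]+$", s)) {
      sgn <- if (startsWith(s, "-")) -1 else 1
      s2 <- sub("^[+-]", "", s)
      parts <- strsplit(s2, ".", fixed = TRUE)[[1]]
      ip <- if (nzchar(parts[1])) as.numeric(parts[1]) else 0
      fp <- parts[2]
      den[k] <- 10^nchar(fp)
      num[k] <- sgn * (ip * den[k] + as.numeric(fp))
    } else {
      stop("cannot parse '", s, "' as a rational number", call. = FALSE)
    }
  }
  rat(num, den)
}

# Reduced row echelon form with a fixed first-nonzero pivot rule, so the
# result (and every nullspace basis derived from it) is deterministic.
rat_rref <- function(a) {
  n <- nrow(a$num); m <- ncol(a$num)
  pivots <- integer(0)
  r <- 1L
  for (j in seq_len(m)) {
    if (r > n) break
    piv <- which(a$num[r:n, j] != 0)
    if (length(piv) == 0) next
    piv <- r + piv[1] - 1L
    if (piv != r) {
      tmp <- a[r, , drop = FALSE]
      a[r, ] <- a[piv, , drop = FALSE]
      a[piv, ] <- tmp
    }
    a[r, ] <- a[r, , drop = FALSE] / a[r, j]
    for (i in seq_len(n)) {
      if (i != r && a$num[i, j] != 0) {
        a[i, ] <- a[i, , drop = FALSE] - a[r, , drop = FALSE] * a[i, j]
      }
    }
    pivots <- c(pivots, j)
    r <- r + 1L
  }
  list(rref = a, pivots = pivots)
}

# Exact basis of the right nullspace {x : a x = 0}; one column per free
# variable, free variable set to 1.
rat_nullspace <- function(a) {
  m <- ncol(a$num)
  rr <- rat_rref(a)
  pivots <- rr$pivots
  free <- setdiff(seq_len(m), pivots)
  basis <- rat_matrix(0, m, length(free))
  for (k in seq_along(free)) {
    f <- free[k]
    basis[f, k] <- rat(1)
    for (i in seq_along(pivots)) {
      basis[pivots[i], k] <- -rr$rref[i, f]
    }
  }
  basis
}

rat_rank <- function(a) length(rat_rref(a)$pivots)
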