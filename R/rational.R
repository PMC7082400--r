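# Vectorised exact rational arithmetic for stoichiometric coefficients.
# Numerators/denominators are stored as doubles holding integers; every
# operation reduces by the gcd so magnitudes stay far below 2^53.

gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0.5) { t <- a %% b; a <- b; b <- t }
  a
}

new_rq <- function(n, d) structure(list(n = n, d = d), class = "rq")

# constructor: rq(n, d) is the rational vector n/d, canonicalised
rq <- function(n = numeric(0), d = 1) {
  if (!is.numeric(n) || !is.numeric(d)) stop("rq() needs numeric parts")
  if (any(!is.finite(n)) || any(!is.finite(d))) stop("rq() parts must be finite")
  if (any(d == 0)) stop("rq() zero denominator")
  if (any(n != round(n)) || any(d != round(d))) stop("rq() parts must be integers")
  if (length(n) == 0) return(new_rq(numeric(0), numeric(0)))
  k <- max(length(n), length(d))
  n <- rep_len(n, k); d <- rep_len(d, k)
  s <- ifelse(d < 0, -1, 1)
  n <- n * s; d <- d * s
  g <- mapply(gcd2, n, d)
  g[g == 0] <- 1
  new_rq(n / g, d / g)
}

is_rq <- function(x) inherits(x, "rq")

as_rq <- function(x, ...) UseMethod("as_rq")

#' @export
as_rq.rq <- function(x, ...) x

#' @export
as_rq.numeric <- function(x, max_den = 1e6, tol = 1e-9, ...) {
  n <- d <- numeric(length(x))
  for (i in seq_along(x)) {
    v <- x[i]
    if (!is.finite(v)) stop("cannot convert non-finite value to rational")
    # continued fractions; exact for the short decimal coefficients used here
    h1 <- 1; h0 <- 0; k1 <- 0; k0 <- 1; b <- v
    repeat {
      a <- floor(b)
      h <- a * h1 + h0; k <- a * k1 + k0
      if (k > max_den) break
      h0 <- h1; h1 <- h; k0 <- k1; k1 <- k
      if (abs(v - h1 / k1) <= tol * max(1, abs(v))) break
      if (b == a) break
      b <- 1 / (b - a)
    }
    n[i] <- h1; d[i] <- k1
  }
  bad <- abs(n / d - x) > tol * pmax(1, abs(x))
  if (any(bad)) stop("value has no exact small rational representation: ", x[which(bad)[1]])
  rq(n, d)
}

#' @export
as_rq.character <- function(x, ...) {
  n <- d <- numeric(length(x))
  for (i in seq_along(x)) {
    s <- trimws(x[i])
    if (grepl("^-?[0-9]+/[0-9]+$", s)) {
      p <- strsplit(s, "/", fixed = TRUE)[[1]]
      n[i] <- as.numeric(p[1]); d[i] <- as.numeric(p[2])
    } else if (grepl("^-?[0-9]*\\.[0-9]+$", s)) {
      dec <- nchar(sub("^-?[0-9]*\\.", "", s))
      d[i] <- 10^dec
      n[i] <- round(as.numeric(s) * d[i])
    } else if (grepl("^-?[0-9]+$", s)) {
      n[i] <- as.numeric(s); d[i] <- 1
    } else {
      stop("malformed rational coefficient: '", s, "'")
    }
  }
  rq(n, d)
}

#' @export
as_rq.integer <- function(x, ...) rq(as.numeric(x), 1)

#' @export
length.rq <- function(x) length(x$n)

#' @export
`[.rq` <- function(x, i) new_rq(x$n[i], x$d[i])

#' @export
`[<-.rq` <- function(x, i, value) {
  v <- as_rq(value)
  n <- x$n; d <- x$d
  n[i] <- v$n; d[i] <- v$d
  new_rq(n, d)
}

c_rq <- function(...) {
  parts <- lapply(list(...), as_rq)
  new_rq(unlist(lapply(parts, `[[`, "n")), unlist(lapply(parts, `[[`, "d")))
}

rep_rq <- function(x, times) new_rq(rep(x$n, times), rep(x$d, times))

#' @export
as.double.rq <- function(x, ...) x$n / x$d

#' @export
format.rq <- function(x, ...) ifelse(x$d == 1, format(x$n, trim = TRUE),
                                     paste0(format(x$n, trim = TRUE), "/",
                                            format(x$d, trim = TRUE)))

#' @export
print.rq <- function(x, ...) {
  cat("<rational> ", paste(format(x), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
Ops.rq <- function(e1, e2) {
  if (missing(e2)) {
    if (.Generic == "-") return(new_rq(-e1$n, e1$d))
    if (.Generic == "+") return(e1)
    stop("unary ", .Generic, " not defined for rationals")
  }
  a <- as_rq(e1); b <- as_rq(e2)
  k <- max(length(a), length(b))
  an <- rep_len(a$n, k); ad <- rep_len(a$d, k)
  bn <- rep_len(b$n, k); bd <- rep_len(b$d, k)
  switch(.Generic,
    "+" = rq(an * bd + bn * ad, ad * bd),
    "-" = rq(an * bd - bn * ad, ad * bd),
    "*" = rq(an * bn, ad * bd),
    "/" = { if (any(bn == 0)) stop("rational division by zero"); rq(an * bd, ad * bn) },
    "==" = an * bd == bn * ad,
    "!=" = an * bd != bn * ad,
    "<"  = an * bd < bn * ad,
    "<=" = an * bd <= bn * ad,
    ">"  = an * bd > bn * ad,
    ">=" = an * bd >= bn * ad,
    stop(.Generic, " not defined for rationals"))
}

rq_sum <- function(x) {
  acc <- rq(0)
  for (i in seq_along(x)) acc <- acc + x[i]
  acc
}

rq_dot <- function(a, b) rq_sum(a * b)

rq_abs <- function(x) new_rq(abs(x$n), x$d)

rq_zero <- function(x) x$n == 0

# Exact solve of A x = b by Gauss-Jordan elimination over the rationals.
# A: list of rq row vectors (equal length m); b: rq vector, one per row.
# Returns solution with free variables set to 0, a consistency flag,
# the null-space dimension, and the inconsistent row residuals (rref rows).
rq_solve <- function(A, b) {
  nr <- length(A)
  m <- if (nr > 0) length(A[[1]]) else 0
  stopifnot(length(b) == nr)
  aug <- lapply(seq_len(nr), function(i) c_rq(A[[i]], b[i]))
  piv <- integer(0)
  r <- 1
  for (col in seq_len(m)) {
    if (r > nr) break
    pr <- 0
    for (i in r:nr) if (aug[[i]]$n[col] != 0) { pr <- i; break }
    if (pr == 0) next
    tmp <- aug[[r]]; aug[[r]] <- aug[[pr]]; aug[[pr]] <- tmp
    aug[[r]] <- aug[[r]] / aug[[r]][col]
    for (i in seq_len(nr)) {
      if (i != r && aug[[i]]$n[col] != 0) {
        aug[[i]] <- aug[[i]] - aug[[r]] * rep_rq(aug[[i]][col], m + 1)
      }
    }
    piv <- c(piv, col)
    r <- r + 1
  }
  bad <- rq(0)
  consistent <- TRUE
  for (i in seq_len(nr)) {
    row <- aug[[i]]
    if (all(row$n[seq_len(m)] == 0) && row$n[m + 1] != 0) {
      consistent <- FALSE
      bad <- c_rq(bad, row[m + 1])
    }
  }
  x <- rq(rep(0, m))
  for (j in seq_along(piv)) x[piv[j]] <- aug[[j]][m + 1]
  list(solution = x, consistent = consistent,
       nullspace_dim = m - length(piv),
       inconsistent_rhs = if (consistent) rq(numeric(0)) else bad[-1])
}
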