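# internal helpers

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else suppressWarnings(rm(".Random.seed", envir = globalenv()))
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    stopf("'%s' must be a single number", name)
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (x < lower) stopf("'%s' must be >= %g (got %g)", name, lower, x)
  if (x > upper) stopf("'%s' must be <= %g (got %g)", name, upper, x)
  invisible(x)
}

# shoelace area of a polygon given vertex coordinates (closed implicitly)
polygon_area <- function(x, y) {
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  abs(sum(x * y2 - x2 * y)) / 2
}

polygon_perimeter <- function(x, y) {
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  sum(sqrt((x2 - x)^2 + (y2 - y)^2))
}

# minimal union-find over 1..n
uf_new <- function(n) seq_len(n)

uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

# union components for an edge list (two integer vectors); returns component
# ids 1..n (root index per element)
uf_components <- function(n, from, to) {
  parent <- seq_len(n)
  for (k in seq_along(from)) {
    a <- from[k]; b <- to[k]
    while (parent[a] != a) { parent[a] <- parent[parent[a]]; a <- parent[a] }
    while (parent[b] != b) { parent[b] <- parent[parent[b]]; b <- parent[b] }
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  # path-compress everything
  for (i in seq_len(n)) {
    r <- i
    while (parent[r] != r) r <- parent[r]
    parent[i] <- r
  }
  parent
}
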