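# Independent oracles used across the suite.  These deliberately do not
# share code paths with the package: the Z-score oracle takes moments from
# the enumerated hypergeometric pmf, the logic oracle uses explicit Kleene
# truth tables instead of R's NA semantics, and the mapping oracle is a
# plain breadth-first search.

# --- hypergeometric moments by pmf enumeration ------------------------------

hyper_moments <- function(n, N, R) {
  x <- max(0, n - (N - R)):min(n, R)
  p <- stats::dhyper(x, R, N - R, n)
  mu <- sum(x * p)
  list(mean = mu, var = sum((x - mu)^2 * p))
}

zscore_oracle <- function(n, r, N, R) {
  mo <- hyper_moments(n, N, R)
  if (mo$var <= 0) return(NA_real_)
  (r - mo$mean) / sqrt(mo$var)
}

# Closed-form oracle from the exact rational mean nR/N and variance
# n R (N-R) (N-n) / (N^2 (N-1)): every product below is an exact (or
# 1-ulp) integer for N <= 10^4, so no compounding of divisions.
zscore_oracle_rational <- function(n, r, N, R) {
  n <- as.numeric(n); r <- as.numeric(r); N <- as.numeric(N); R <- as.numeric(R)
  vp <- n * R * (N - R) * (N - n)
  if (vp <= 0) return(NA_real_)
  ((r * N - n * R) / N) / sqrt(vp / (N * N * (N - 1)))
}

# --- Kleene three-valued logic oracle ---------------------------------------
# tri-states encoded as "T", "F", "U"

kleene_not <- c(T = "F", F = "T", U = "U")
kleene_and <- function(a, b) {
  if (a == "F" || b == "F") return("F")
  if (a == "T" && b == "T") return("T")
  "U"
}
kleene_or <- function(a, b) {
  if (a == "T" || b == "T") return("T")
  if (a == "F" && b == "F") return("F")
  "U"
}

# Evaluate a criterion AST (as produced by parse_criterion) against a named
# list of scalar values, returning "T"/"F"/"U".
oracle_eval <- function(node, row) {
  val <- function(nd) {
    switch(nd$op,
      num = nd$value,
      str = nd$value,
      col = row[[nd$name]],
      abs = { v <- val(nd$arg); if (is.na(v)) NA_real_ else abs(v) })
  }
  switch(node$op,
    not = kleene_not[[oracle_eval(node$arg, row)]],
    and = kleene_and(oracle_eval(node$lhs, row), oracle_eval(node$rhs, row)),
    or  = kleene_or(oracle_eval(node$lhs, row), oracle_eval(node$rhs, row)),
    cmp = {
      l <- val(node$lhs); r <- val(node$rhs)
      if (is.na(l) || is.na(r)) return("U")
      ok <- switch(node$cmp,
        "<" = l < r, "<=" = l <= r, ">" = l > r, ">=" = l >= r,
        "=" = l == r, "<>" = l != r)
      if (ok) "T" else "F"
    })
}

tri_of <- function(x) if (is.na(x)) "U" else if (x) "T" else "F"

# All boolean expression texts of nesting depth <= `depth` over a fixed set
# of atomic comparisons.
enumerate_expressions <- function(atoms, depth) {
  level <- atoms
  all <- atoms
  for (d in seq_len(depth - 1L)) {
    nxt <- paste0("(NOT ", level, ")")
    for (a in level) {
      nxt <- c(nxt, paste0("(", a, " AND ", level, ")"),
               paste0("(", a, " OR ", level, ")"))
    }
    all <- c(all, nxt)
    level <- nxt
    if (length(all) > 5000L) break
  }
  unique(all)
}

# Random criterion source text for parser fuzzing; always syntactically
# valid (built from the grammar, independently of the package printer).
random_expr_text <- function(depth = 3L) {
  rand_value <- function() {
    switch(sample(4, 1),
      sprintf("[%s]", sample(c("a", "b"), 1)),
      as.character(sample(c(-1, 0, 1, 0.5, 2.5), 1)),
      sprintf("ABS(%s)", sprintf("[%s]", sample(c("a", "b"), 1))),
      as.character(sample(c(-1, 0, 1), 1)))
  }
  rand_cmp <- function() {
    sprintf("%s %s %s", rand_value(),
            sample(c("<", "<=", ">", ">=", "=", "<>"), 1), rand_value())
  }
  rec <- function(d) {
    if (d <= 0L || runif(1) < 0.35) return(rand_cmp())
    switch(sample(4, 1),
      sprintf("NOT %s", rec(d - 1L)),
      sprintf("%s AND %s", rec(d - 1L), rec(d - 1L)),
      sprintf("%s OR %s", rec(d - 1L), rec(d - 1L)),
      sprintf("(%s)", rec(d - 1L)))
  }
  rec(depth)
}

# --- graph-traversal closure oracle for the id mapper -----------------------

# pairs: data frame with the four mapping-table columns; returns the set of
# "system\tid" keys reachable from key through the undirected pair graph.
closure_oracle <- function(pairs, key) {
  a <- paste(pairs$source_system, pairs$source_id, sep = "\t")
  b <- paste(pairs$target_system, pairs$target_id, sep = "\t")
  adj <- list()
  for (i in seq_along(a)) {
    adj[[a[i]]] <- c(adj[[a[i]]], b[i])
    adj[[b[i]]] <- c(adj[[b[i]]], a[i])
  }
  seen <- character(); queue <- key
  while (length(queue)) {
    k <- queue[1]; queue <- queue[-1]
    if (k %in% seen) next
    seen <- c(seen, k)
    queue <- c(queue, adj[[k]])
  }
  setdiff(seen, key)
}

random_mapper_pairs <- function(n_pairs, n_systems = 4, n_ids = 40) {
  tibble::tibble(
    source_system = sprintf("Sys%d", sample(n_systems, n_pairs, replace = TRUE)),
    source_id = sprintf("id%02d", sample(n_ids, n_pairs, replace = TRUE)),
    target_system = sprintf("Sys%d", sample(n_systems, n_pairs, replace = TRUE)),
    target_id = sprintf("id%02d", sample(n_ids, n_pairs, replace = TRUE)))
}
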