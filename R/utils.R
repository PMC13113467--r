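# Internal helpers shared across modules.

# Run `expr` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All randomness in the package flows
# through explicit integer seeds; nothing leaks into the global stream.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a counter, staying within the
# 32-bit signed integer range. Deterministic, no hidden state.
derive_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 48271 + as.double(counter) * 16807) %% 2147483587) + 1L
}

# Apply `f` to every numeric leaf of a nested list of parameter arrays.
tree_map <- function(tree, f) {
  if (is.list(tree)) {
    out <- lapply(tree, tree_map, f = f)
    attributes(out) <- attributes(tree)
    out
  } else {
    f(tree)
  }
}

# Zip two parameter trees of identical shape with `f`. When both levels are
# named, `b` is aligned to `a`'s names, so grad trees may list fields in a
# different order than the parameter tree they mirror.
tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    stopifnot(is.list(b), length(a) == length(b))
    if (!is.null(names(a)) && !is.null(names(b)) &&
        all(nzchar(names(a))) && setequal(names(a), names(b))) {
      b <- b[names(a)]
    }
    out <- mapply(tree_map2, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
    attributes(out) <- attributes(a)
    names(out) <- names(a)
    out
  } else {
    f(a, b)
  }
}

# Flatten a parameter tree into one numeric vector (used for hashing and
# determinism checks).
tree_unlist <- function(tree) {
  unlist(tree_map(tree, as.numeric), use.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
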