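# Internal helpers shared across modules.

# Deterministic, locale-independent label ordering (byte order).
sort_c <- function(x) sort(x, method = "radix")

# Run expr under a temporary RNG state seeded with `seed`; restores the
# caller's RNG stream afterwards. A NULL seed leaves the RNG untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  expr
}

# Stable 31-bit string hash (polynomial rolling hash); used to derive
# per-polytomy RNG streams that do not depend on processing order.
hash31 <- function(x) {
  h <- 0
  for (code in utf8ToInt(paste(x, collapse = "\x1f"))) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer(h)
}

SEP <- "\x1f"

split_key <- function(side) paste(sort_c(side), collapse = SEP)

key_to_side <- function(key) strsplit(key, SEP, fixed = TRUE)[[1]]

# Canonical side of a bipartition: the side NOT containing the reference
# taxon (byte-order minimum of the universe). If the reference is absent
# from both sides (partial split on a larger universe) the lexicographically
# smaller key wins, which is still polarity-independent.
canonical_side <- function(side, universe) {
  ref <- sort_c(universe)[1L]
  if (ref %in% side) {
    sort_c(setdiff(universe, side))
  } else if (ref %in% universe) {
    sort_c(side)
  } else {
    other <- sort_c(setdiff(universe, side))
    a <- sort_c(side)
    if (split_key(a) <= split_key(other)) a else other
  }
}

# Two splits (given as canonical sides over the same universe) are
# compatible iff one of the four intersections is empty.
sides_compatible <- function(a, b, universe) {
  if (!length(intersect(a, b))) return(TRUE)
  if (all(a %in% b) || all(b %in% a)) return(TRUE)
  length(union(a, b)) == length(universe)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
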