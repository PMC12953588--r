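# Internal helpers shared across modules.

# Locale-independent (C collation) string sort so node order, pair
# canonicalization and tie-breaks are reproducible across machines.
sort_c <- function(x) {
  if (is.null(x)) {
    return(character())
  }
  sort(x, method = "radix")
}

order_c <- function(...) order(..., method = "radix")

# Canonicalize unordered node pairs: u is always the radix-smaller name.
canonical_pairs <- function(u, v) {
  stopifnot(length(u) == length(v))
  if (length(u) == 0) {
    return(tibble::tibble(u = character(), v = character()))
  }
  lv <- sort_c(unique(c(u, v)))
  swap <- match(u, lv) > match(v, lv)
  tibble::tibble(
    u = ifelse(swap, v, u),
    v = ifelse(swap, u, v)
  )
}

# Single string key per unordered pair (for set operations on pair tables).
pair_key <- function(u, v) paste(u, v, sep = "\x1f")

pair_keys <- function(pairs) pair_key(pairs$u, pairs$v)

empty_pairs <- function() tibble::tibble(u = character(), v = character())

# Derive a child seed from a master seed, kept inside 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 131L + as.numeric(k) * 7919) %%
    (.Machine$integer.max - 1) + 1)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
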