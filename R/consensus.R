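# Greedy (extended majority-rule) consensus: bipartitions are admitted in
# decreasing frequency order while they remain compatible with the ones
# already accepted, so all majority (>50%) bipartitions are present plus
# any compatible minority ones.

#' Greedy consensus of trees on one leaf set
#'
#' @param trees A list of \code{phylo} objects on identical leaf sets.
#' @return A \code{phylo}; refines the majority-rule consensus. Frequency
#'   ties are broken by the canonical ordering of the bipartitions (byte
#'   order of the canonical side), making the result deterministic.
#' @export
greedy_consensus <- function(trees) {
  stopifnot(length(trees) >= 1L)
  taxa <- sort_c(trees[[1L]]$tip.label)
  for (t in trees) {
    if (!identical(sort_c(t$tip.label), taxa)) {
      stop("greedy consensus requires identical leaf sets", call. = FALSE)
    }
  }
  if (length(trees) == 1L) return(trees[[1L]])
  keys <- unlist(lapply(trees, split_keys))
  if (!length(keys)) return(tree_from_splits(list(), taxa))
  freq <- table(keys)
  ord <- order(-as.vector(freq), names(freq), method = "radix")
  accepted <- list()
  for (key in names(freq)[ord]) {
    side <- key_to_side(key)
    ok <- all(vapply(accepted, sides_compatible, TRUE, b = side,
                     universe = taxa))
    if (ok) accepted[[key]] <- side
  }
  tree_from_splits(accepted, taxa)
}
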