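# Source-tree profiles: an ordered collection of unrooted source trees
# plus the union taxon set S, the input to encoding, SCM and SuperFine.

#' Construct a source-tree profile
#'
#' @param trees A list of \code{phylo} objects; each must have at least 4
#'   leaves (smaller trees carry no unrooted topology) and unique labels.
#' @return An object of class \code{source_profile} with elements
#'   \code{trees} and \code{taxa} (the union S of all leaf sets).
#' @export
source_profile <- function(trees) {
  stopifnot(is.list(trees), length(trees) >= 1L)
  for (i in seq_along(trees)) {
    t <- trees[[i]]
    if (!inherits(t, "phylo")) {
      stop("profile element ", i, " is not a phylo object", call. = FALSE)
    }
    if (ape::Ntip(t) < 4L) {
      stop("source tree ", i, " has fewer than 4 leaves", call. = FALSE)
    }
    if (anyDuplicated(t$tip.label)) {
      stop("source tree ", i, " has duplicate leaf labels", call. = FALSE)
    }
  }
  taxa <- sort_c(unique(unlist(lapply(trees, function(t) t$tip.label))))
  structure(list(trees = trees, taxa = taxa), class = "source_profile")
}

#' @export
print.source_profile <- function(x, ...) {
  cat("source_profile:", length(x$trees), "source trees,",
      length(x$taxa), "taxa (union)\n")
  sizes <- vapply(x$trees, ape::Ntip, 0L)
  cat("  leaves per tree:", paste(sizes, collapse = " "), "\n")
  invisible(x)
}

#' Load a profile from newick files
#'
#' Accepts a single file with one newick string per line, a vector of such
#' files, or a directory (all regular files inside are read).
#'
#' @param path File path(s) or a directory.
#' @export
read_profile <- function(path) {
  files <- path
  if (length(path) == 1L && dir.exists(path)) {
    files <- list.files(path, full.names = TRUE)
  }
  trees <- list()
  for (f in files) {
    for (line in readLines(f, warn = FALSE)) {
      if (nzchar(trimws(line))) trees[[length(trees) + 1L]] <- parse_newick(line)
    }
  }
  source_profile(trees)
}

#' Write a profile to a multi-newick file
#'
#' @param profile A \code{source_profile}.
#' @param file Output path (one newick string per line).
#' @export
write_profile <- function(profile, file) {
  writeLines(vapply(profile$trees, write_newick, ""), file)
  invisible(file)
}
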