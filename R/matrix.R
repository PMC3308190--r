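# Baum-Ragan matrix representation of a source-tree profile, plus
# relaxed-PHYLIP and NEXUS (datatype=standard) readers/writers.

#' Construct an MRP character matrix
#'
#' @param states Integer matrix over \{0, 1, NA\} (NA encodes '?'), rows
#'   named by taxa.
#' @param provenance Data frame with one row per column: \code{tree}
#'   (source-tree index or NA) and \code{edge} (canonical bipartition key
#'   or "external").
#' @export
mrp_matrix <- function(states, provenance = NULL) {
  stopifnot(is.matrix(states), !is.null(rownames(states)))
  storage.mode(states) <- "integer"
  if (!all(states %in% c(0L, 1L, NA))) {
    stop("matrix states must be 0, 1 or NA ('?')", call. = FALSE)
  }
  if (is.null(provenance)) {
    provenance <- data.frame(tree = rep(NA_integer_, ncol(states)),
                             edge = rep("external", ncol(states)))
  }
  structure(list(taxa = rownames(states), states = states,
                 provenance = provenance),
            class = "mrp_matrix")
}

#' @export
print.mrp_matrix <- function(x, ...) {
  cat("mrp_matrix:", nrow(x$states), "taxa x", ncol(x$states), "columns;",
      sum(is.na(x$states)), "missing entries\n")
  invisible(x)
}

#' @export
dim.mrp_matrix <- function(x) dim(x$states)

#' Baum-Ragan encoding of a source-tree profile
#'
#' One column per internal edge of each source tree: taxa on one side of
#' the edge get 1, taxa on the other side 0, and taxa absent from that
#' tree '?'. Under reversible Fitch parsimony the polarity is immaterial;
#' it is fixed deterministically here by giving state 1 to the canonical
#' side of each bipartition (the side excluding the byte-order smallest
#' taxon of that source tree's leaf set). Columns follow profile order,
#' and within a tree a deterministic preorder of the internal edges.
#'
#' @param profile A \code{source_profile}.
#' @return An \code{mrp_matrix} on the union taxon set.
#' @export
encode_baum_ragan <- function(profile) {
  stopifnot(inherits(profile, "source_profile"))
  taxa <- profile$taxa
  cols <- list()
  prov_tree <- integer(0)
  prov_edge <- character(0)
  for (i in seq_along(profile$trees)) {
    t <- profile$trees[[i]]
    sp <- tree_splits(t)
    for (k in seq_along(sp)) {
      col <- rep(NA_integer_, length(taxa))
      names(col) <- taxa
      col[t$tip.label] <- 0L
      col[sp[[k]]] <- 1L
      cols[[length(cols) + 1L]] <- col
      prov_tree <- c(prov_tree, i)
      prov_edge <- c(prov_edge, names(sp)[k])
    }
  }
  states <- if (length(cols)) {
    do.call(cbind, cols)
  } else {
    matrix(integer(0), nrow = length(taxa), ncol = 0L,
           dimnames = list(taxa, NULL))
  }
  rownames(states) <- taxa
  mrp_matrix(states, data.frame(tree = prov_tree, edge = prov_edge,
                                stringsAsFactors = FALSE))
}

sanitize_taxa <- function(taxa) {
  clean <- gsub("[[:space:]]+", "_", taxa)
  if (!identical(clean, taxa)) {
    changed <- taxa != clean
    warning("taxon labels containing whitespace were sanitized: ",
            paste(sprintf("'%s' -> '%s'", taxa[changed], clean[changed]),
                  collapse = ", "), call. = FALSE)
  }
  clean
}

states_to_char <- function(states) {
  ch <- matrix("?", nrow(states), ncol(states))
  ch[!is.na(states)] <- as.character(states[!is.na(states)])
  ch
}

#' Write an MRP matrix in relaxed-PHYLIP or NEXUS format
#'
#' Relaxed PHYLIP: a "ntax ncol" header then one whitespace-separated row
#' per taxon. NEXUS: a DATA block with FORMAT datatype=standard
#' symbols="01" missing=?. Missing entries are always written as '?'.
#'
#' @param matrix An \code{mrp_matrix}.
#' @param format "phylip" or "nexus".
#' @param file Optional path; when NULL the text is returned invisibly as
#'   a character vector of lines.
#' @export
write_matrix <- function(matrix, format = c("phylip", "nexus"), file = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(matrix, "mrp_matrix"))
  taxa <- sanitize_taxa(matrix$taxa)
  rows <- apply(states_to_char(matrix$states), 1L, paste, collapse = "")
  if (!length(rows)) rows <- rep("", length(taxa))
  lines <- if (format == "phylip") {
    c(paste(length(taxa), ncol(matrix$states)),
      paste(formatC(taxa, width = max(nchar(taxa)) + 2L, flag = "-"), rows))
  } else {
    c("#NEXUS",
      "BEGIN DATA;",
      sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(taxa),
              ncol(matrix$states)),
      "  FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=?;",
      "  MATRIX",
      paste0("    ", formatC(taxa, width = max(nchar(taxa)) + 2L, flag = "-"),
             rows),
      "  ;",
      "END;")
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  invisible(lines)
}

#' Read a binary character matrix
#'
#' Reads relaxed-PHYLIP or NEXUS (datatype=standard) matrices over
#' \{0, 1, ?\}; '-' is accepted as an alias of '?'. Provenance is marked
#' "external".
#'
#' @param input A file path, or the file content as a character vector of
#'   lines (or a single string with embedded newlines).
#' @param format "phylip" or "nexus".
#' @export
read_matrix <- function(input, format = c("phylip", "nexus")) {
  format <- match.arg(format)
  lines <- if (length(input) == 1L && !grepl("\n", input) &&
               file.exists(input)) {
    readLines(input, warn = FALSE)
  } else {
    unlist(strsplit(input, "\n", fixed = TRUE))
  }
  if (format == "nexus") {
    start <- grep("^\\s*MATRIX\\s*$", lines, ignore.case = TRUE)
    if (!length(start)) stop("no MATRIX block found in NEXUS input",
                             call. = FALSE)
    end <- grep("^\\s*;\\s*$", lines)
    end <- end[end > start[1L]][1L]
    body <- lines[(start[1L] + 1L):(end - 1L)]
    dimline <- grep("DIMENSIONS", lines, ignore.case = TRUE, value = TRUE)
    ntax <- as.integer(sub(".*NTAX\\s*=\\s*(\\d+).*", "\\1", dimline[1L],
                           ignore.case = TRUE))
    nchar_ <- as.integer(sub(".*NCHAR\\s*=\\s*(\\d+).*", "\\1", dimline[1L],
                             ignore.case = TRUE))
  } else {
    header <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
    if (length(header) < 2L || anyNA(suppressWarnings(as.integer(header[1:2])))) {
      stop("malformed relaxed-PHYLIP header", call. = FALSE)
    }
    ntax <- as.integer(header[1L])
    nchar_ <- as.integer(header[2L])
    body <- lines[-1L]
  }
  body <- body[nzchar(trimws(body))]
  if (length(body) != ntax) {
    stop(sprintf("header declares %d taxa but %d matrix rows found",
                 ntax, length(body)), call. = FALSE)
  }
  taxa <- character(ntax)
  states <- matrix(NA_integer_, ntax, nchar_)
  for (i in seq_len(ntax)) {
    parts <- strsplit(trimws(body[i]), "\\s+")[[1L]]
    taxa[i] <- parts[1L]
    symb <- strsplit(paste(parts[-1L], collapse = ""), "")[[1L]]
    bad <- setdiff(unique(symb), c("0", "1", "?", "-"))
    if (length(bad)) {
      stop("unsupported state symbol(s): ", paste(bad, collapse = " "),
           call. = FALSE)
    }
    if (length(symb) != nchar_) {
      stop(sprintf("row '%s' has %d characters, expected %d", taxa[i],
                   length(symb), nchar_), call. = FALSE)
    }
    symb[symb %in% c("?", "-")] <- NA_character_
    states[i, ] <- as.integer(symb)
  }
  if (anyDuplicated(taxa)) stop("duplicate taxon labels in matrix",
                                call. = FALSE)
  rownames(states) <- taxa
  mrp_matrix(states)
}
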