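#' Read a linkage matrix from a 4-column table
#'
#' Accepts whitespace- or comma-separated tables with one row per merge and
#' an optional header line. Two node-numbering dialects are supported:
#' `"one-based"` (the canonical on-disk form: leaves `1..n`, row `t` makes
#' node `n+t`) and `"zero-based"` (the dominant scientific-Python linkage
#' convention: leaves `0..n-1`, internals `n..2n-2`), which is converted on
#' read — the shift is uniformly +1 on the two child columns.
#'
#' @param path file to read.
#' @param dialect `"one-based"` (default) or `"zero-based"`.
#' @return A validated `linkage_matrix` (canonical one-based convention).
#' @export
read_linkage <- function(path, dialect = c("one-based", "zero-based")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty linkage file: ", path, call. = FALSE)
  sep <- if (grepl(",", lines[[1L]], fixed = TRUE) ||
             (length(lines) > 1L && grepl(",", lines[[2L]], fixed = TRUE))) "," else ""
  parse_row <- function(ln) {
    toks <- if (sep == ",") trimws(strsplit(ln, ",", fixed = TRUE)[[1L]])
            else strsplit(trimws(ln), "[[:space:]]+")[[1L]]
    toks[nzchar(toks)]
  }
  first <- suppressWarnings(as.numeric(parse_row(lines[[1L]])))
  if (anyNA(first)) lines <- lines[-1L]  # header
  if (!length(lines)) stop("linkage file has a header but no rows: ", path, call. = FALSE)
  rows <- lapply(seq_along(lines), function(i) {
    toks <- parse_row(lines[[i]])
    if (length(toks) != 4L)
      stop(sprintf("row %d of %s: expected 4 columns, found %d",
                   i, path, length(toks)), call. = FALSE)
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals))
      stop(sprintf("row %d of %s: non-numeric entry", i, path), call. = FALSE)
    vals
  })
  m <- do.call(rbind, rows)
  if (dialect == "zero-based") m[, 1:2] <- m[, 1:2] + 1
  linkage_matrix(m)
}

#' Write a linkage matrix as a 4-column table
#'
#' @param Z a `linkage_matrix`.
#' @param path output file.
#' @param dialect see [read_linkage()].
#' @param sep column separator (default tab).
#' @return `path`, invisibly.
#' @export
write_linkage <- function(Z, path, dialect = c("one-based", "zero-based"),
                          sep = "\t") {
  stopifnot(inherits(Z, "linkage_matrix"))
  dialect <- match.arg(dialect)
  m <- as.matrix(Z)
  if (dialect == "zero-based") m[, 1:2] <- m[, 1:2] - 1
  write.table(m, path, sep = sep, row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Read a leaf-label table
#'
#' Two tab-separated columns: leaf id, label string.
#'
#' @param path file to read.
#' @return Named character vector (names are leaf ids).
#' @export
read_labels <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, quote = "",
                   comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) != 2L)
    stop("label table must have exactly 2 tab-separated columns", call. = FALSE)
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Serialize a linkage matrix to Newick
#'
#' Sibling order in the Newick string equals column order in the linkage
#' matrix, so the drawn layout (and hence [leaf_order()]) round-trips
#' exactly. Branch lengths are the height differences between parent and
#' child merges where those are consistent (non-negative); otherwise unit
#' lengths are written with a warning. Leaves are labelled by `labels` or,
#' by default, their ids.
#'
#' @param Z a `linkage_matrix`.
#' @param labels optional character vector/map of leaf labels, indexed by
#'   leaf id.
#' @return A single Newick string (terminated by `;`).
#' @export
to_newick <- function(Z, labels = NULL) {
  stopifnot(inherits(Z, "linkage_matrix"))
  n <- Z$n_leaves
  nr <- n - 1L
  tip_lab <- vapply(seq_len(n), function(k) {
    if (!is.null(labels)) {
      lab <- if (!is.null(names(labels))) unname(labels[as.character(k)]) else labels[k]
      if (!is.na(lab)) return(as.character(lab))
    }
    as.character(k)
  }, "")
  node_height <- c(rep(0, n), Z$height)
  edge <- matrix(0L, 2L * nr, 2L)
  elen <- numeric(2L * nr)
  counter <- n + 2L
  row_no <- 0L
  rec <- function(node_id, ph_parent) {
    t <- node_id - n
    for (child in Z$merge[t, ]) {
      row_no <<- row_no + 1L
      my_row <- row_no
      elen[my_row] <<- node_height[node_id] - node_height[child]
      if (child <= n) {
        edge[my_row, ] <<- c(ph_parent, child)
      } else {
        ph_child <- counter
        counter <<- counter + 1L
        edge[my_row, ] <<- c(ph_parent, ph_child)
        rec(child, ph_child)
      }
    }
  }
  rec(2L * n - 1L, n + 1L)
  if (any(elen < 0)) {
    warning("non-monotone heights; writing unit branch lengths")
    elen[] <- 1
  }
  phy <- structure(list(edge = edge, edge.length = elen,
                        tip.label = tip_lab, Nnode = nr),
                   class = "phylo", order = "cladewise")
  ape::write.tree(phy)
}

#' Parse a strictly binary Newick string into a linkage matrix
#'
#' The inverse of [to_newick()]: sibling order becomes child-column order,
#' so `leaf_order(from_newick(to_newick(Z))) == leaf_order(Z)`. Tips
#' labelled with the integers `1..n` are taken as leaf ids directly;
#' otherwise ids are assigned alphabetically and the label map is returned
#' in the `"labels"` attribute. Node heights are rebuilt from branch
#' lengths (leaves at height 0); without branch lengths, merge depth is
#' used.
#'
#' @param text a Newick string (or a file path via `file`).
#' @param file optional path to a Newick file, used when `text` is missing.
#' @return A `linkage_matrix`, possibly with a `"labels"` attribute.
#' @export
from_newick <- function(text, file = NULL) {
  phy <- if (is.null(file)) ape::read.tree(text = text) else ape::read.tree(file)
  if (is.null(phy)) stop("could not parse Newick input", call. = FALSE)
  n <- length(phy$tip.label)
  if (n < 2L) stop("need at least 2 leaves", call. = FALSE)
  if (phy$Nnode != n - 1L)
    stop("unsupported topology: tree is not strictly binary (multifurcation present)",
         call. = FALSE)
  labs <- phy$tip.label
  if (all(grepl("^[0-9]+$", labs)) && setequal(as.integer(labs), seq_len(n))) {
    leaf_id <- as.integer(labs)
    labels <- NULL
  } else {
    leaf_id <- match(labs, sort(labs))
    labels <- stats::setNames(labs, as.character(leaf_id))
  }
  has_len <- !is.null(phy$edge.length)
  kids <- split(seq_len(nrow(phy$edge)), phy$edge[, 1L])
  rows <- matrix(0L, n - 1L, 2L)
  heights <- numeric(n - 1L)
  sizes <- integer(n - 1L)
  cnt <- 0L
  rec <- function(ph_node) {
    # returns c(our_id, size, height)
    if (ph_node <= n) return(c(leaf_id[ph_node], 1L, 0))
    eidx <- kids[[as.character(ph_node)]]
    if (length(eidx) != 2L)
      stop("unsupported topology: tree is not strictly binary (multifurcation present)",
           call. = FALSE)
    a <- rec(phy$edge[eidx[1L], 2L])
    b <- rec(phy$edge[eidx[2L], 2L])
    cnt <<- cnt + 1L
    h <- if (has_len)
      max(a[3L] + phy$edge.length[eidx[1L]], b[3L] + phy$edge.length[eidx[2L]])
    else cnt
    rows[cnt, ] <<- c(a[1L], b[1L])
    heights[cnt] <<- h
    sizes[cnt] <<- a[2L] + b[2L]
    c(n + cnt, a[2L] + b[2L], h)
  }
  rec(n + 1L)
  Z <- linkage_matrix(cbind(rows, heights, sizes))
  if (!is.null(labels)) attr(Z, "labels") <- labels
  Z
}
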