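#' Rooted ultrametric time-trees
#'
#' A `time_tree` is a rooted, strictly bifurcating tree whose nodes carry ages
#' in Ma (million years before present; tips are at age 0, ages increase into
#' the past). Internally ages are stored per node rather than branch lengths,
#' because divergence dating operates on node ages; branch lengths are
#' recovered as `age[parent] - age[child]` on output.
#'
#' Node numbering follows the `ape` convention: tips `1..n` (in the order of
#' `tip_label`), root `n + 1`, internal nodes `n+1 .. 2n-1`.
#'
#' @param phy an [ape::phylo] object, rooted and binary, with branch lengths
#'   that make the tree ultrametric (tolerance `tol`).
#' @param tol ultrametricity tolerance in Ma. Inputs whose tip depths differ
#'   from the maximum by more than `tol` are rejected.
#' @return an object of class `time_tree` with elements `n_tip`, `tip_label`,
#'   `parent` (integer vector over all `2n-1` nodes, 0 at the root),
#'   `children` (2-column integer matrix, one row per internal node, rows
#'   named by node id), `age` (numeric vector over all nodes, Ma) and `root`
#'   (the root node id).
#' @seealso [parse_newick()], [write_newick()], [mrca_node()]
#' @export
time_tree <- function(phy, tol = 1e-6) {
  if (!inherits(phy, "phylo")) stop2("'phy' must be an ape \"phylo\" object")
  if (is.null(phy$edge.length)) stop2("tree has no branch lengths")
  if (anyDuplicated(phy$tip.label))
    stop2("duplicate taxon labels: ",
          paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  n <- length(phy$tip.label)
  if (n < 2L) stop2("tree must have at least 2 tips")
  if (!ape::is.binary(phy) || !ape::is.rooted(phy))
    stop2("tree must be rooted and strictly bifurcating (polytomies are rejected)")
  n_node <- 2L * n - 1L
  root <- n + 1L
  depth <- ape::node.depth.edgelength(phy)     # distance from root
  tip_depth <- depth[seq_len(n)]
  h <- max(tip_depth)
  if (any(abs(tip_depth - h) > tol)) {
    bad <- which(abs(tip_depth - h) > tol)[1L]
    stop2("tree is not ultrametric within tolerance ", tol,
          ": tip '", phy$tip.label[bad], "' has depth ", format(tip_depth[bad]),
          " vs tree height ", format(h))
  }
  age <- h - depth
  age[seq_len(n)] <- 0                          # contemporaneous sampling
  parent <- integer(n_node)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  parent[root] <- 0L
  children <- matrix(0L, n - 1L, 2L,
                     dimnames = list(as.character(root:n_node), NULL))
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1L]
    r <- as.character(p)
    if (children[r, 1L] == 0L) children[r, 1L] <- phy$edge[i, 2L]
    else children[r, 2L] <- phy$edge[i, 2L]
  }
  tr <- structure(list(n_tip = n, tip_label = phy$tip.label, parent = parent,
                       children = children, age = age, root = root),
                  class = "time_tree")
  validate_time_tree(tr)
  tr
}

validate_time_tree <- function(tr, tol = 1e-9) {
  with(tr, {
    if (any(age[seq_len(n_tip)] != 0)) stop2("leaf ages must be 0")
    for (nd in (n_tip + 1L):(2L * n_tip - 1L)) {
      ch <- children[as.character(nd), ]
      if (any(age[nd] <= age[ch] - tol))
        stop2("internal node ", nd, " (", format(age[nd]),
              " Ma) is not older than its children")
    }
  })
  invisible(tr)
}

#' @export
print.time_tree <- function(x, ...) {
  cat("time_tree:", x$n_tip, "tips, root age",
      format(x$age[x$root], digits = 6), "Ma\n")
  invisible(x)
}

#' Parse a Newick string or file into a time-tree
#'
#' Branch lengths are converted to node ages (leaf age 0, node age = child age
#' + branch length). Input must be rooted, binary and ultrametric.
#'
#' @param text a Newick string, or `NULL` if `file` is given.
#' @param file path to a Newick file.
#' @param tol ultrametricity tolerance in Ma (default `1e-6`).
#' @return a [time_tree()].
#' @examples
#' tr <- parse_newick("((A:1.0,B:1.0):1.0,C:2.0);")
#' tr$age[tr$root]   # 2 Ma
#' @export
parse_newick <- function(text = NULL, file = NULL, tol = 1e-6) {
  if (is.null(text)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  check_parens(text)
  phy <- ape::read.tree(text = text)
  if (is.null(phy)) stop2("could not parse Newick string")
  time_tree(phy, tol = tol)
}

# explicit bracket balance check so malformed input is rejected with position
check_parens <- function(text) {
  chars <- strsplit(text, "")[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    else if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop2("unbalanced parentheses: unmatched ')' at position ", i)
    }
  }
  if (depth != 0L)
    stop2("unbalanced parentheses: ", depth, " '(' left open at end of input")
  invisible(TRUE)
}

#' Convert a time-tree back to an ape phylo object
#'
#' @param x a [time_tree()].
#' @param ... unused.
#' @return an [ape::phylo] with branch lengths `age[parent] - age[child]`.
#' @export
as_phylo <- function(x, ...) {
  n <- x$n_tip
  nonroot <- setdiff(seq_len(2L * n - 1L), x$root)
  edge <- cbind(x$parent[nonroot], nonroot)
  len <- x$age[edge[, 1L]] - x$age[edge[, 2L]]
  phy <- structure(list(edge = edge, edge.length = len,
                        tip.label = x$tip_label, Nnode = n - 1L),
                   class = "phylo", order = "cladewise")
  ape::reorder.phylo(phy)
}

#' Write a time-tree as Newick
#'
#' @param tree a [time_tree()].
#' @param file optional path; if `NULL` the Newick string is returned.
#' @param digits significant digits for branch lengths.
#' @return the Newick string, invisibly when written to file.
#' @export
write_newick <- function(tree, file = NULL, digits = 12) {
  s <- ape::write.tree(as_phylo(tree), digits = digits)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Read / write NEXUS trees blocks
#'
#' Thin wrappers over the NEXUS trees-block machinery (translate tables
#' supported). Reading returns the first tree as a [time_tree()] unless
#' `all = TRUE`.
#'
#' @param file path to a NEXUS file.
#' @param all return a list of all trees instead of the first one.
#' @param tol ultrametricity tolerance.
#' @return a [time_tree()] or list of them.
#' @export
read_nexus_tree <- function(file, all = FALSE, tol = 1e-6) {
  phy <- ape::read.nexus(file)
  if (inherits(phy, "phylo")) phy <- list(phy)
  out <- lapply(phy, time_tree, tol = tol)
  if (all) out else out[[1L]]
}

#' @rdname read_nexus_tree
#' @param tree a [time_tree()] (or list of them) to write.
#' @param translate use a NEXUS translate table.
#' @export
write_nexus_tree <- function(tree, file, translate = TRUE) {
  if (inherits(tree, "time_tree")) tree <- list(tree)
  phy <- lapply(tree, as_phylo)
  class(phy) <- "multiPhylo"
  ape::write.nexus(phy, file = file, translate = translate)
  invisible(file)
}

#' Most recent common ancestor of a taxon set
#'
#' @param tree a [time_tree()].
#' @param taxa character vector of at least two taxon names present in the
#'   tree.
#' @return the node id of the unique lowest node ancestral to all `taxa`.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' mrca_node(tr, c("A", "B"))
#' @export
mrca_node <- function(tree, taxa) {
  idx <- match(taxa, tree$tip_label)
  if (anyNA(idx))
    stop2("unknown taxa: ", paste(taxa[is.na(idx)], collapse = ", "))
  if (length(idx) < 2L) stop2("need at least two taxa for an MRCA")
  anc <- ancestor_path(tree, idx[1L])
  common <- anc
  for (i in idx[-1L]) common <- intersect(common, ancestor_path(tree, i))
  common[which.min(tree$age[common])]
}

# node ids on the path from a node (inclusive) to the root
ancestor_path <- function(tree, node) {
  path <- node
  while (tree$parent[node] != 0L) {
    node <- tree$parent[node]
    path <- c(path, node)
  }
  path
}

# tip ids descending from each node; list over all nodes
descendant_tips <- function(tree) {
  n <- tree$n_tip
  out <- vector("list", 2L * n - 1L)
  for (i in seq_len(n)) out[[i]] <- i
  ord <- order(tree$age[(n + 1L):(2L * n - 1L)])  # young to old
  for (nd in ((n + 1L):(2L * n - 1L))[ord]) {
    ch <- tree$children[as.character(nd), ]
    out[[nd]] <- c(out[[ch[1L]]], out[[ch[2L]]])
  }
  out
}

# postorder edge traversal: matrix (child, parent), children before parents
postorder_edges <- function(tree) {
  n <- tree$n_tip
  nodes <- (n + 1L):(2L * n - 1L)
  nodes <- nodes[order(tree$age[nodes])]        # young internal nodes first
  child <- integer(0); par <- integer(0)
  for (nd in nodes) {
    ch <- tree$children[as.character(nd), ]
    child <- c(child, ch); par <- c(par, nd, nd)
  }
  cbind(child = child, parent = par)
}
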