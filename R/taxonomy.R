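#' Concept taxonomy with corpus counts
#'
#' A rooted single-parent taxonomy (a tree of concept nodes) carrying
#' nonnegative corpus frequency counts, used to compute information content
#' and Lin semantic similarity. Cumulative counts (a node's own count plus
#' all of its descendants') are computed at construction.
#'
#' @param child,parent Character vectors describing the edge list; the root is
#'   the single node that appears as a parent but never as a child (it may
#'   also be given an own count via a `child == parent` self row being
#'   disallowed — use `root_count` instead).
#' @param own_count Nonnegative numeric own (non-cumulative) count per child
#'   node.
#' @param word_map Named character vector mapping surface words to node ids.
#' @param root_count Own count of the root node (default 0).
#' @return An object of class `taxonomy`.
#' @export
taxonomy <- function(child, parent, own_count, word_map = NULL, root_count = 0) {
  child <- as.character(child); parent <- as.character(parent)
  stopifnot(length(child) == length(parent), length(child) == length(own_count))
  if (anyDuplicated(child)) stop("each node may have only one parent (duplicate child ids)")
  if (any(own_count < 0)) stop("counts must be nonnegative")
  roots <- setdiff(parent, child)
  if (length(roots) != 1L) {
    stop("taxonomy must have exactly one root, found: ", paste(roots, collapse = ", "))
  }
  root <- roots
  nodes <- c(root, child)
  own <- c(root_count, as.numeric(own_count))
  names(own) <- nodes
  parent_of <- c(stats::setNames(NA_character_, root), stats::setNames(parent, child))

  # cycle check + depth: every node must reach the root
  depth <- stats::setNames(integer(length(nodes)), nodes)
  for (nd in nodes) {
    seen <- character(0); cur <- nd
    while (!is.na(parent_of[[cur]])) {
      if (cur %in% seen) stop("cycle detected at node ", nd)
      seen <- c(seen, cur)
      cur <- parent_of[[cur]]
      if (!cur %in% nodes) stop("parent ", cur, " of ", nd, " is not a node")
    }
    depth[[nd]] <- length(seen)
  }

  # cumulative counts: push every node's own count onto itself and ancestors
  cum <- stats::setNames(numeric(length(nodes)), nodes)
  for (nd in nodes) {
    cur <- nd
    repeat {
      cum[[cur]] <- cum[[cur]] + own[[nd]]
      if (is.na(parent_of[[cur]])) break
      cur <- parent_of[[cur]]
    }
  }

  if (!is.null(word_map)) {
    word_map <- stats::setNames(as.character(word_map), names(word_map))
    bad <- setdiff(unname(word_map), nodes)
    if (length(bad)) stop("word_map points at unknown nodes: ", paste(bad, collapse = ", "))
  }

  structure(list(nodes = nodes, root = root, parent = parent_of, own = own,
                 cumulative = cum, depth = depth, word_map = word_map),
            class = "taxonomy")
}

#' @export
print.taxonomy <- function(x, ...) {
  cat("<taxonomy> ", length(x$nodes), " nodes, root '", x$root,
      "', total count ", x$cumulative[[x$root]], sep = "")
  if (!is.null(x$word_map)) cat(", ", length(x$word_map), " mapped words", sep = "")
  cat("\n")
  invisible(x)
}

# chain of ancestors from a node up to (and including) the root
ancestor_chain <- function(tax, node) {
  chain <- node
  while (!is.na(tax$parent[[node]])) {
    node <- tax$parent[[node]]
    chain <- c(chain, node)
  }
  chain
}

#' Information content of a taxonomy node
#'
#' \eqn{IC(c) = -\log(\mathrm{count}(c) / \mathrm{count}(root))} using
#' cumulative corpus counts and the natural logarithm. The root has IC 0;
#' IC weakly increases toward the leaves.
#'
#' @param node Node id.
#' @param tax A [taxonomy()].
#' @return Nonnegative numeric.
#' @export
information_content <- function(node, tax) {
  stopifnot(inherits(tax, "taxonomy"))
  if (!node %in% tax$nodes) stop("unknown node: ", node)
  total <- tax$cumulative[[tax$root]]
  if (total <= 0) stop("taxonomy has zero total count; IC undefined")
  p <- tax$cumulative[[node]] / total
  if (p <= 0) stop("node '", node, "' has zero cumulative count; IC undefined")
  -log(p)
}

# least common subsumer: deepest node on both root-chains
least_common_subsumer <- function(tax, node_a, node_b) {
  chain_a <- ancestor_chain(tax, node_a)
  chain_b <- ancestor_chain(tax, node_b)
  common <- chain_b[chain_b %in% chain_a]
  common[1L]  # chains run self -> root, so the first hit is the deepest
}

#' Lin semantic similarity between two words
#'
#' \eqn{sim(a, b) = 2\,IC(lcs(a,b)) / (IC(a) + IC(b))}, where `lcs` is the
#' least common subsumer (most specific shared ancestor) of the two words'
#' concept nodes. Identical words score 1; words whose only shared ancestor
#' is the root (IC 0) score 0. The measure is symmetric and lies in \[0, 1\].
#'
#' @param a,b Surface words, resolved through the taxonomy's word map (or
#'   node ids if no word map is attached).
#' @inheritParams information_content
#' @export
lin_similarity <- function(a, b, tax) {
  stopifnot(inherits(tax, "taxonomy"))
  node_a <- resolve_word(tax, a)
  node_b <- resolve_word(tax, b)
  ic_a <- information_content(node_a, tax)
  ic_b <- information_content(node_b, tax)
  if (ic_a == 0 || ic_b == 0) {
    # a word sitting at the root carries no information; similarity undefined
    stop("word maps to a node with zero information content")
  }
  lcs <- least_common_subsumer(tax, node_a, node_b)
  2 * information_content(lcs, tax) / (ic_a + ic_b)
}

resolve_word <- function(tax, word) {
  if (!is.null(tax$word_map) && word %in% names(tax$word_map)) {
    return(tax$word_map[[word]])
  }
  if (word %in% tax$nodes) return(word)
  stop("word '", word, "' cannot be resolved in the taxonomy")
}

#' Read / write a taxonomy as delimited text
#'
#' The edge list is a TSV with columns `child`, `parent`, `own_count`; the
#' optional word map is a TSV with columns `word`, `node`.
#'
#' @param edge_file Path to the edge-list TSV.
#' @param word_map_file Optional path to the word-map TSV.
#' @param root_count Own count for the root node.
#' @return A [taxonomy()].
#' @export
read_taxonomy <- function(edge_file, word_map_file = NULL, root_count = 0) {
  edges <- utils::read.delim(edge_file, stringsAsFactors = FALSE)
  stopifnot(all(c("child", "parent", "own_count") %in% names(edges)))
  wm <- NULL
  if (!is.null(word_map_file)) {
    map <- utils::read.delim(word_map_file, stringsAsFactors = FALSE)
    stopifnot(all(c("word", "node") %in% names(map)))
    wm <- stats::setNames(map$node, map$word)
  }
  taxonomy(edges$child, edges$parent, edges$own_count, word_map = wm,
           root_count = root_count)
}

#' @rdname read_taxonomy
#' @param tax A [taxonomy()].
#' @param edge_file,word_map_file Output paths.
#' @export
write_taxonomy <- function(tax, edge_file, word_map_file = NULL) {
  stopifnot(inherits(tax, "taxonomy"))
  kids <- setdiff(tax$nodes, tax$root)
  edges <- data.frame(child = kids,
                      parent = unname(tax$parent[kids]),
                      own_count = unname(tax$own[kids]))
  utils::write.table(edges, edge_file, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(word_map_file) && !is.null(tax$word_map)) {
    map <- data.frame(word = names(tax$word_map), node = unname(tax$word_map))
    utils::write.table(map, word_map_file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(edge_file)
}
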