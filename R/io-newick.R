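#' Read a time-calibrated Newick tree
#'
#' Two dialects are supported and must be declared by the caller:
#' \describe{
#'   \item{\code{"ultrametric"}}{Branch lengths are in million years and all
#'     leaves are contemporaneous; node ages are recovered from leaf depths.
#'     Leaf depths differing by more than \code{tolerance} is an error.}
#'   \item{\code{"node_labels"}}{Internal-node labels carry the node ages in
#'     million years directly; branch lengths are ignored.}
#' }
#' Leaves always have age 0; a parent is never younger than its child.
#'
#' @param path Newick file (or a Newick string containing ";").
#' @param dialect \code{"ultrametric"} (default) or \code{"node_labels"}.
#' @param tolerance Maximum allowed spread of leaf depths (MY) under the
#'   ultrametric dialect.
#' @return An object of class \code{"dated_tree"}: list with \code{phylo}
#'   (the \pkg{ape} tree), \code{ages} (numeric vector indexed by \pkg{ape}
#'   node number, leaves first), and \code{taxa} (leaf labels).
#' @examples
#' tr <- read_newick_dated(textConnection_newick("((A:10,B:10):5,C:15);"))
#' tr$ages  # A B C root inner
#' @export
read_newick_dated <- function(path, dialect = c("ultrametric", "node_labels"),
                              tolerance = 1e-6) {
  dialect <- match.arg(dialect)
  txt <- if (grepl(";", path, fixed = TRUE)) path else paste(readLines(path), collapse = "")
  txt <- trimws(txt)
  # single-leaf degenerate tree, which ape cannot represent
  if (grepl("^\\(?[^(),:]+(:[0-9.eE+-]+)?\\)?;$", txt) && !grepl(",", txt)) {
    label <- sub("^\\(?([^(),:;]+).*$", "\\1", txt)
    out <- list(phylo = NULL, ages = setNames(0, label), taxa = label)
    class(out) <- "dated_tree"
    return(out)
  }
  phy <- ape::read.tree(text = txt)
  if (is.null(phy)) stop("could not parse Newick input")
  n_tip <- length(phy$tip.label)
  n_node <- phy$Nnode
  if (dialect == "ultrametric") {
    if (is.null(phy$edge.length)) stop("ultrametric dialect requires branch lengths")
    depth <- ape::node.depth.edgelength(phy)   # root = 0, increasing toward tips
    tip_depth <- depth[seq_len(n_tip)]
    if (diff(range(tip_depth)) > tolerance) {
      stop(sprintf(
        "tree is not ultrametric: leaf depths span %.6g to %.6g MY",
        min(tip_depth), max(tip_depth)))
    }
    ages <- max(tip_depth) - depth
    ages[seq_len(n_tip)] <- 0
  } else {
    labs <- phy$node.label
    if (is.null(labs) || any(!nzchar(labs))) {
      stop("node_labels dialect requires an age label on every internal node")
    }
    node_ages <- suppressWarnings(as.numeric(labs))
    if (anyNA(node_ages)) stop("non-numeric internal-node age label")
    ages <- c(rep(0, n_tip), node_ages)
  }
  # parent age must be >= child age
  parent_age <- ages[phy$edge[, 1]]
  child_age <- ages[phy$edge[, 2]]
  if (any(parent_age < child_age - tolerance)) {
    stop("node ages are not monotone toward the root")
  }
  names(ages) <- c(phy$tip.label,
                   if (!is.null(phy$node.label) && all(nzchar(phy$node.label)))
                     phy$node.label
                   else paste0("node", n_tip + seq_len(n_node)))
  out <- list(phylo = phy, ages = ages, taxa = phy$tip.label)
  class(out) <- "dated_tree"
  out
}

#' @export
print.dated_tree <- function(x, ...) {
  cat(sprintf("dated tree: %d taxa, root age %.4g MY\n",
              length(x$taxa), max(x$ages)))
  invisible(x)
}

# helper so examples can pass literal newick text through the path argument
#' @rdname read_newick_dated
#' @param newick Newick text.
#' @export
textConnection_newick <- function(newick) newick

#' Simulate a random dated (ultrametric) tree
#'
#' Coalescent-shaped topology rescaled so the root sits at \code{root_age}.
#' Used by the presence simulator and in property tests.
#'
#' @param n_taxa Number of leaves.
#' @param root_age Root age in MY.
#' @param seed Optional integer seed.
#' @return A \code{"dated_tree"}.
#' @export
simulate_dated_tree <- function(n_taxa, root_age = 100, seed = NULL) {
  phy <- with_seed(seed, ape::rcoal(n_taxa, tip.label = paste0("t", seq_len(n_taxa))))
  depth <- ape::node.depth.edgelength(phy)
  n_tip <- length(phy$tip.label)
  scale <- root_age / max(depth[seq_len(n_tip)])
  phy$edge.length <- phy$edge.length * scale
  ages <- (max(depth[seq_len(n_tip)]) - depth) * scale
  ages[seq_len(n_tip)] <- 0
  names(ages) <- c(phy$tip.label, paste0("node", n_tip + seq_len(phy$Nnode)))
  out <- list(phylo = phy, ages = ages, taxa = phy$tip.label)
  class(out) <- "dated_tree"
  out
}
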