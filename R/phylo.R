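# Distance-based monomer phylogenetics: K2P distance matrices,
# neighbor-joining (implemented here, verifiable exactly on additive
# matrices) and column-resampling bootstrap supports.

#' Randomly subsample monomers
#'
#' Uniform sampling without replacement, deterministic under a fixed seed;
#' inputs at or below \code{n} are returned unchanged.
#'
#' @param monomers Character vector (named or not) or list of sequences.
#' @param n Target sample size; default 100.
#' @param seed Optional integer seed.
#' @return Subset of \code{monomers} (original order not preserved when
#'   sampling occurs).
#' @export
subsample_monomers <- function(monomers, n = 100L, seed = NULL) {
  stopifnot(n > 0)
  if (length(monomers) <= n) return(monomers)
  idx <- with_seed(seed, sample.int(length(monomers), n))
  monomers[idx]
}

#' Pairwise K2P distance matrix of aligned monomers
#'
#' Sequences must be equal length (monomers extracted by the annotator are
#' already in consensus coordinates; externally collected monomers should be
#' multiple-aligned first). Gap (\code{-}) and \code{N} columns are excluded
#' pairwise. Sequences involved in saturated (infinite-distance) pairs are
#' dropped greedily, most-saturated first, with a log message; if nothing
#' finite remains an error is raised.
#'
#' @param monomers Named character vector of aligned sequences, length >= 3.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(monomers) {
  n <- length(monomers)
  if (n < 3L) stop("need at least 3 monomers for a distance matrix")
  if (is.null(names(monomers))) names(monomers) <- paste0("m", seq_len(n))
  lens <- nchar(monomers)
  if (length(unique(lens)) > 1L) {
    stop("monomers must be aligned to equal length (run an MSA first)")
  }
  ptq <- .pairwise_ptq_cpp(toupper(unname(monomers)))
  D <- k2p_from_pq(ptq$P, ptq$Q)
  D[ptq$sites == 0L] <- Inf
  diag(D) <- 0
  dimnames(D) <- list(names(monomers), names(monomers))
  while (any(!is.finite(D))) {
    sat_count <- rowSums(!is.finite(D))
    drop <- which.max(sat_count)
    if (nrow(D) <= 3L) stop("all monomer pairs saturated: no usable distances")
    sat_log("dropping %s: %d saturated pair(s)", rownames(D)[drop], sat_count[drop])
    D <- D[-drop, -drop, drop = FALSE]
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic agglomeration: at each step the pair minimising
#' \eqn{Q(i,j) = (n-2) d_{ij} - r_i - r_j} is joined, ties broken by
#' row-major order. On additive matrices the tree's path-length matrix
#' reproduces the input exactly. Degenerate (star-like) matrices yield
#' zero-length internal branches and are flagged in a log message.
#'
#' @param D Symmetric numeric matrix with labels, at least 4 of them for a
#'   non-trivial topology.
#' @return Unrooted \code{ape::phylo} tree with branch lengths.
#' @export
nj_tree <- function(D) {
  if (!isSymmetric(unname(as.matrix(D)), tol = 1e-8)) {
    stop("distance matrix must be symmetric")
  }
  D <- as.matrix(D)
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(D)))
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 taxa")
  # each active entry carries its partial-tree newick fragment
  frag <- labels
  active <- seq_len(n)
  Dm <- D
  fmt <- function(x) sprintf("%.10g", x)
  while (length(active) > 3L) {
    m <- length(active)
    sub <- Dm[active, active]
    r <- rowSums(sub)
    Q <- (m - 2) * sub - outer(r, r, "+")
    diag(Q) <- Inf
    idx <- which(Q == min(Q), arr.ind = TRUE)[1, ]
    i <- idx[1]; j <- idx[2]
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    dij <- sub[i, j]
    li <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- dij - li
    new_frag <- sprintf("(%s:%s,%s:%s)",
                        frag[active[i]], fmt(li), frag[active[j]], fmt(lj))
    dnew <- (sub[i, ] + sub[j, ] - dij) / 2
    u <- active[i]
    Dm[u, active] <- dnew
    Dm[active, u] <- dnew
    Dm[u, u] <- 0
    frag[u] <- new_frag
    active <- active[-j]
  }
  a <- active[1]; b <- active[2]; cc <- active[3]
  la <- (Dm[a, b] + Dm[a, cc] - Dm[b, cc]) / 2
  lb <- Dm[a, b] - la
  lc <- Dm[a, cc] - la
  if (max(abs(c(la, lb, lc))) < 1e-12) {
    sat_log("star-like distance matrix: zero-length internal structure")
  }
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);",
                    frag[a], fmt(la), frag[b], fmt(lb), frag[cc], fmt(lc))
  ape::read.tree(text = newick)
}

#' Bootstrap supports for a neighbor-joining monomer tree
#'
#' Resamples alignment columns with replacement, rebuilds a K2P + NJ tree
#' per replicate, and reports for each internal edge of the original tree
#' the fraction of replicates containing the same bipartition.
#'
#' @param alignment Named character vector of equal-length aligned
#'   sequences, at least 4 rows.
#' @param n_replicates Number of replicates; default 100.
#' @param seed Optional integer seed.
#' @return List with \code{tree} (the original NJ tree), \code{support}
#'   (numeric in \[0,1\], one per internal node of \code{tree}),
#'   \code{n_replicates}.
#' @export
bootstrap_support <- function(alignment, n_replicates = 100L, seed = NULL) {
  if (length(alignment) < 4L) stop("bootstrap needs an alignment of >= 4 sequences")
  if (is.null(names(alignment))) names(alignment) <- paste0("m", seq_along(alignment))
  cols <- do.call(rbind, strsplit(toupper(alignment), ""))
  L <- ncol(cols)
  tree0 <- nj_tree(distance_matrix(alignment))
  boot <- with_seed(seed, {
    lapply(seq_len(n_replicates), function(b) {
      res <- cols[, sample.int(L, L, replace = TRUE), drop = FALSE]
      seqs <- setNames(apply(res, 1, paste, collapse = ""), names(alignment))
      tryCatch(nj_tree(distance_matrix(seqs)), error = function(e) NULL)
    })
  })
  boot <- boot[!vapply(boot, is.null, logical(1))]
  counts <- ape::prop.clades(tree0, boot, rooted = FALSE)
  counts[is.na(counts)] <- 0
  list(tree = tree0, support = counts / length(boot),
       n_replicates = n_replicates)
}
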