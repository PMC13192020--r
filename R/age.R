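# Taxonomic presence filtering and MRCA-based minimal-age estimation on a
# time-calibrated tree.

#' Build a presence matrix from a coverage hit table
#'
#' A taxon qualifies for a family when its best query coverage strictly
#' exceeds \code{coverage_threshold} (presence must be "exceeded", not
#' reached). The focal taxon, when given, is present for every family with
#' coverage 1 by construction.
#'
#' @param hits data.frame with columns \code{taxon}, \code{family},
#'   \code{query_coverage} (fraction of the consensus covered, in \[0,1\]),
#'   e.g. parsed from BLAST-style tabular output or the presence simulator.
#' @param coverage_threshold Strict threshold; default 0.5.
#' @param focal_taxon Optional focal taxon name.
#' @param families Optional family ids fixing the column set.
#' @return List of class \code{"presence_matrix"}: \code{coverage} (taxa x
#'   families, best coverage), \code{present} (logical), \code{threshold}.
#' @export
filter_presence <- function(hits, coverage_threshold = 0.5, focal_taxon = NULL,
                            families = NULL) {
  stopifnot(all(c("taxon", "family", "query_coverage") %in% names(hits)))
  if (nrow(hits) && (any(hits$query_coverage < 0) || any(hits$query_coverage > 1))) {
    stop("query coverage must lie in [0, 1]")
  }
  taxa <- sort(unique(c(hits$taxon, focal_taxon)))
  fams <- if (is.null(families)) sort(unique(hits$family)) else families
  if (!length(taxa)) taxa <- character(0)
  cov <- matrix(0, nrow = length(taxa), ncol = length(fams),
                dimnames = list(taxa, fams))
  for (i in seq_len(nrow(hits))) {
    r <- hits[i, ]
    if (!r$family %in% fams) next
    cov[r$taxon, r$family] <- max(cov[r$taxon, r$family], r$query_coverage)
  }
  if (!is.null(focal_taxon) && length(fams)) cov[focal_taxon, ] <- 1
  structure(list(coverage = cov, present = cov > coverage_threshold,
                 threshold = coverage_threshold),
            class = "presence_matrix")
}

#' Collapse a species-level hit table to a higher rank
#'
#' Maps each taxon to its group (e.g. species to order) and keeps the best
#' coverage per group; one qualifying species suffices for its group.
#'
#' @param hits Hit table as in \code{\link{filter_presence}}.
#' @param mapping data.frame with columns \code{taxon}, \code{group}.
#' @return Hit table at group rank.
#' @export
collapse_rank <- function(hits, mapping) {
  stopifnot(all(c("taxon", "group") %in% names(mapping)))
  idx <- match(hits$taxon, mapping$taxon)
  if (anyNA(idx)) {
    stop("taxa missing from rank mapping: ",
         paste(unique(hits$taxon[is.na(idx)]), collapse = ", "))
  }
  hits$taxon <- mapping$group[idx]
  agg <- stats::aggregate(query_coverage ~ taxon + family, data = hits, FUN = max)
  agg[, c("taxon", "family", "query_coverage")]
}

#' Minimal evolutionary age of a satellite family
#'
#' The minimal age is the age of the most recent common ancestor of the
#' focal taxon and every taxon in which the family qualifies as present: the
#' family must already have existed when those lineages separated. A family
#' present only in the focal taxon gives no MRCA bound; its age is reported
#' as the interval \[0, \code{clade_bound}\], the bound being the dated
#' emergence of the focal taxon's most recent qualifying ancestral clade
#' (supplied from configuration).
#'
#' @param presence A \code{"presence_matrix"} from
#'   \code{\link{filter_presence}}.
#' @param tree A \code{"dated_tree"} whose leaves are the presence taxa.
#' @param family Family id (column of the presence matrix).
#' @param focal_taxon Leaf from whose viewpoint the age is estimated.
#' @param clade_bound Upper bound in MY used for the singleton case;
#'   default \code{NA}.
#' @return List of class \code{"age_estimate"}: \code{family_id},
#'   \code{taxa}, \code{mrca_node}, \code{minimal_age}, \code{upper_bound}.
#' @export
minimal_age <- function(presence, tree, family, focal_taxon,
                        clade_bound = NA_real_) {
  stopifnot(inherits(presence, "presence_matrix"), inherits(tree, "dated_tree"))
  if (!family %in% colnames(presence$present)) {
    stop("unknown family: ", family)
  }
  qual <- rownames(presence$present)[presence$present[, family]]
  qual <- union(qual, focal_taxon)
  missing <- setdiff(qual, tree$taxa)
  if (length(missing)) {
    stop("qualifying taxa missing from the dated tree: ",
         paste(missing, collapse = ", "))
  }
  if (length(qual) == 1L) {
    est <- list(family_id = family, taxa = qual, mrca_node = NA_integer_,
                minimal_age = 0, upper_bound = as.numeric(clade_bound))
  } else {
    node <- ape::getMRCA(tree$phylo, qual)
    est <- list(family_id = family, taxa = sort(qual), mrca_node = node,
                minimal_age = unname(tree$ages[node]), upper_bound = NA_real_)
  }
  class(est) <- "age_estimate"
  est
}

#' @export
print.age_estimate <- function(x, ...) {
  if (is.na(x$mrca_node)) {
    cat(sprintf("%s: detected only in %s; age in [0, %s] MY\n", x$family_id,
                x$taxa, format(x$upper_bound)))
  } else {
    cat(sprintf("%s: minimal age %.4g MY (MRCA of %s)\n", x$family_id,
                x$minimal_age, paste(x$taxa, collapse = ", ")))
  }
  invisible(x)
}

#' Simulate a presence matrix with a planted MRCA per family
#'
#' For each family the qualifying set is the focal taxon plus a random
#' subset of leaves chosen so that the MRCA of the set is exactly the
#' planted node; present taxa draw coverages strictly above the threshold,
#' absent taxa below (or no hit at all). The planted node must lie on the
#' focal taxon's root path (or be the focal leaf itself, giving singleton
#' presence).
#'
#' @param tree A \code{"dated_tree"}.
#' @param planted Named integer vector: for each family, the planted node
#'   number (ape numbering; a leaf number gives singleton presence).
#' @param focal_taxon Focal leaf label.
#' @param coverage_threshold Threshold the simulated coverages straddle;
#'   default 0.5.
#' @param seed Optional integer seed.
#' @return List of class \code{"presence_sim"}: \code{hits} (taxon, family,
#'   query_coverage), \code{truth} (family, planted_node, planted_age).
#' @export
simulate_presence <- function(tree, planted, focal_taxon,
                              coverage_threshold = 0.5, seed = NULL) {
  stopifnot(inherits(tree, "dated_tree"), focal_taxon %in% tree$taxa)
  phy <- tree$phylo
  n_tip <- length(phy$tip.label)
  focal_num <- match(focal_taxon, phy$tip.label)
  root_path <- c(focal_num, path_to_root(phy, focal_num))
  with_seed(seed, {
    hits <- list()
    truth <- list()
    for (f in names(planted)) {
      node <- planted[[f]]
      if (node < 1L || node > n_tip + phy$Nnode) {
        stop("planted node ", node, " not in tree for family ", f)
      }
      if (!node %in% root_path) {
        stop("planted node ", node, " for family ", f,
             " is not an ancestor of the focal taxon ", focal_taxon)
      }
      present <- focal_taxon
      if (node != focal_num) {
        kids <- phy$edge[phy$edge[, 1] == node, 2]
        # pin the MRCA: at least one leaf from a child subtree not holding focal
        off_focal <- kids[!vapply(kids, function(k)
          focal_num %in% clade_tips(phy, k), logical(1))]
        anchor_clade <- off_focal[sample.int(length(off_focal), 1L)]
        anchor_tips <- clade_tips(phy, anchor_clade)
        anchor <- phy$tip.label[anchor_tips[sample.int(length(anchor_tips), 1L)]]
        pool <- setdiff(phy$tip.label[clade_tips(phy, node)],
                        c(focal_taxon, anchor))
        extra <- if (length(pool)) {
          pool[runif(length(pool)) < 0.4]
        } else character(0)
        present <- c(present, anchor, extra)
      }
      absent <- setdiff(phy$tip.label, present)
      hits[[length(hits) + 1L]] <- rbind(
        data.frame(taxon = present, family = f,
                   query_coverage = runif(length(present),
                                          min(coverage_threshold + 0.05, 1), 1),
                   stringsAsFactors = FALSE),
        if (length(absent)) {
          has_hit <- runif(length(absent)) < 0.5
          data.frame(taxon = absent[has_hit], family = f,
                     query_coverage = runif(sum(has_hit), 0, coverage_threshold),
                     stringsAsFactors = FALSE)
        })
      truth[[length(truth) + 1L]] <- data.frame(
        family = f, planted_node = node,
        planted_age = if (node <= n_tip) 0 else unname(tree$ages[node]),
        stringsAsFactors = FALSE)
    }
    structure(list(hits = do.call(rbind, hits), truth = do.call(rbind, truth)),
              class = "presence_sim")
  })
}

path_to_root <- function(phy, node) {
  out <- integer(0)
  repeat {
    parent <- phy$edge[phy$edge[, 2] == node, 1]
    if (!length(parent)) break
    out <- c(out, parent)
    node <- parent
  }
  out
}

clade_tips <- function(phy, node) {
  n_tip <- length(phy$tip.label)
  if (node <= n_tip) return(node)
  kids <- phy$edge[phy$edge[, 1] == node, 2]
  unlist(lapply(kids, clade_tips, phy = phy))
}
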