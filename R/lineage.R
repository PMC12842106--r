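#' Read a gene tree and bind deme (morph) labels to its tips
#'
#' Accepts rooted or unrooted newick, bifurcating or multifurcating;
#' polytomies are preserved as-is. Every tip must resolve in the deme map.
#'
#' @param newick_path path to a newick file.
#' @param deme_map named character vector (tip -> morph) or path to a CSV
#'   with columns \code{id, morph}.
#' @return An object of class \code{gene_tree}: list with \code{tree}
#'   (an \code{ape::phylo}) and \code{demes} (named character per tip).
#' @export
read_gene_tree <- function(newick_path, deme_map) {
  tr <- ape::read.tree(newick_path)
  if (is.null(tr)) stop("could not parse newick in ", newick_path)
  gene_tree(tr, deme_map)
}

#' Construct a gene_tree from a phylo and a deme map
#' @param tree an \code{ape::phylo}.
#' @param deme_map named character vector (tip -> morph) or CSV path.
#' @return A \code{gene_tree}.
#' @export
gene_tree <- function(tree, deme_map) {
  stopifnot(inherits(tree, "phylo"))
  if (is.character(deme_map) && length(deme_map) == 1 &&
      file.exists(deme_map)) {
    tab <- utils::read.csv(deme_map, stringsAsFactors = FALSE)
    deme_map <- stats::setNames(tab$morph, tab$id)
  }
  missing <- setdiff(tree$tip.label, names(deme_map))
  if (length(missing))
    stop("tip without a deme label: ", missing[1])
  demes <- deme_map[tree$tip.label]
  structure(list(tree = tree, demes = demes), class = "gene_tree")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Desk-scale plumbing for building a gene tree from pairwise sequence
#' differences (the pipeline otherwise accepts an externally estimated
#' tree). Delegates to \code{ape::nj}.
#'
#' @param distances symmetric non-negative matrix.
#' @param ids optional taxon names (defaults to the matrix dimnames).
#' @return An \code{ape::phylo}.
#' @export
neighbor_joining <- function(distances, ids = NULL) {
  distances <- as.matrix(distances)
  if (!isSymmetric(unname(distances), tol = 1e-8))
    stop("distance matrix must be symmetric")
  if (any(distances < 0)) stop("distances must be non-negative")
  if (!is.null(ids)) dimnames(distances) <- list(ids, ids)
  ape::nj(as.dist(distances))
}

# resolve (tree, demes) from either a gene_tree or a pair (internal)
as_labeled_tree <- function(tree, demes = NULL) {
  if (inherits(tree, "gene_tree")) return(tree)
  gene_tree(tree, demes)
}

#' Slatkin-Maddison s statistic
#'
#' Minimum number of deme-state transitions needed to explain the deme
#' membership of the tips of a gene tree: unit-cost parsimony of the deme
#' character, computed exactly on arbitrary (possibly multifurcating)
#' trees by a per-node minimum-cost dynamic program, and invariant to root
#' placement. For k reciprocally monophyletic demes s = k - 1; under
#' complete mixing s approaches its maximum n - max deme count.
#'
#' @param tree a \code{gene_tree}, or an \code{ape::phylo} with
#'   \code{demes} supplied.
#' @param demes named character vector tip -> deme (when \code{tree} is a
#'   phylo).
#' @return integer minimum transition count.
#' @export
s_statistic <- function(tree, demes = NULL) {
  gt <- as_labeled_tree(tree, demes)
  tr <- gt$tree
  states <- unique(unname(gt$demes))
  k <- length(states)
  ntip <- length(tr$tip.label)
  if (ntip == 1 || k == 1) return(0L)
  if (is.null(tr$edge) || nrow(tr$edge) == 0) return(k - 1L)
  tr <- ape::reorder.phylo(tr, "postorder")
  nnode <- ntip + tr$Nnode
  # cost[v, s]: minimal transitions in the subtree of v given state s at v
  cost <- matrix(0, nnode, k)
  cost[seq_len(ntip), ] <- Inf
  cost[cbind(seq_len(ntip), match(gt$demes[tr$tip.label], states))] <- 0
  for (r in seq_len(nrow(tr$edge))) {
    par <- tr$edge[r, 1]
    ch <- tr$edge[r, 2]
    cost[par, ] <- cost[par, ] + pmin(cost[ch, ], min(cost[ch, ]) + 1)
  }
  root <- tr$edge[nrow(tr$edge), 1]
  as.integer(min(cost[root, ]))
}

#' Brute-force s by exhaustive internal-state enumeration
#'
#' Test oracle: enumerates every assignment of observed deme states to the
#' internal nodes and counts edges whose endpoints disagree, returning the
#' minimum. Restricted to small trees (<= 12 tips).
#'
#' @inheritParams s_statistic
#' @return integer minimum transition count; equals [s_statistic].
#' @export
brute_force_s <- function(tree, demes = NULL) {
  gt <- as_labeled_tree(tree, demes)
  tr <- gt$tree
  ntip <- length(tr$tip.label)
  if (ntip > 12) stop("brute_force_s limited to 12 tips")
  states <- unique(unname(gt$demes))
  k <- length(states)
  if (ntip == 1 || k == 1) return(0L)
  m <- tr$Nnode
  if (k^m > 5e6) stop("state space too large for brute force")
  tip_state <- match(gt$demes[tr$tip.label], states)
  edge <- tr$edge
  total <- k^m
  best <- Inf
  chunk <- 2e5
  for (start in seq(0, total - 1, by = chunk)) {
    idx <- start:min(start + chunk - 1, total - 1)
    # decode assignment digits: row j is the state of internal node j
    assign <- lapply(seq_len(m) - 1L, function(j) (idx %/% k^j) %% k + 1L)
    state_of <- function(node) {
      if (node <= ntip) rep(tip_state[node], length(idx))
      else assign[[node - ntip]]
    }
    changes <- Reduce(`+`, lapply(seq_len(nrow(edge)), function(r)
      as.integer(state_of(edge[r, 1]) != state_of(edge[r, 2]))))
    best <- min(best, min(changes))
  }
  as.integer(best)
}
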