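#' Collapse an alignment into haplotypes
#'
#' Groups identical sequences into haplotypes, numbered by first occurrence
#' (H1, H2, ...). A sequence containing missing data (\code{N}/gap) is
#' assigned to the first existing haplotype it is compatible with
#' (identical at all mutually non-missing sites); such assignments are
#' recorded in the \code{ambiguous} element.
#'
#' @param aln a [seq_alignment].
#' @return An object of class \code{haplotype_set}: list with
#'   \code{haplotypes} (data.frame: hap, count, plus one count column per
#'   morph), \code{members} (list of sequence ids per haplotype),
#'   \code{representative} (character matrix of representative sequences),
#'   \code{distance} (pairwise Hamming steps between haplotypes),
#'   \code{ambiguous} (ids assigned via missing-data compatibility).
#' @export
collapse_haplotypes <- function(aln) {
  stopifnot(inherits(aln, "seq_alignment"))
  ids <- rownames(aln$seqs)
  reps <- list()      # representative rows
  members <- list()
  ambiguous <- character(0)
  is_missing <- function(x) !(x %in% c("A", "C", "G", "T"))
  for (id in ids) {
    s <- aln$seqs[id, ]
    hit <- NA_integer_
    for (h in seq_along(reps)) {
      r <- reps[[h]]
      ok <- !is_missing(s) & !is_missing(r)
      if (all(s[ok] == r[ok])) { hit <- h; break }
    }
    if (is.na(hit)) {
      reps[[length(reps) + 1L]] <- s
      members[[length(members) + 1L]] <- id
    } else {
      if (any(is_missing(s)) || any(is_missing(reps[[hit]])))
        ambiguous <- c(ambiguous, id)
      members[[hit]] <- c(members[[hit]], id)
    }
  }
  nh <- length(reps)
  hap_ids <- paste0("H", seq_len(nh))
  rep_mat <- do.call(rbind, reps)
  rownames(rep_mat) <- hap_ids
  morphs <- unique(aln$labels[!is.na(aln$labels)])
  counts <- do.call(rbind, lapply(members, function(m) {
    c(count = length(m),
      vapply(morphs, function(mo)
        sum(aln$labels[m] == mo, na.rm = TRUE), numeric(1)))
  }))
  haplotypes <- data.frame(hap = hap_ids, counts, check.names = FALSE)
  rep_aln <- seq_alignment(rep_mat)
  distance <- if (nh > 1) pairwise_diff_matrix(rep_aln) else
    matrix(0, 1, 1, dimnames = list(hap_ids, hap_ids))
  names(members) <- hap_ids
  structure(list(haplotypes = haplotypes, members = members,
                 representative = rep_mat, distance = distance,
                 ambiguous = ambiguous),
            class = "haplotype_set")
}

#' Minimum spanning haplotype network
#'
#' Union of all minimum spanning trees over the haplotype Hamming-distance
#' graph (classic MSN semantics): edges are examined in ascending distance
#' classes and every edge of a class that joins two components distinct at
#' the start of the class is kept. \code{epsilon > 0} additionally admits
#' edges up to \code{epsilon} steps longer than the current class.
#'
#' @param haps a \code{haplotype_set} from [collapse_haplotypes].
#' @param epsilon non-negative integer relaxation (default 0).
#' @return An object of class \code{haplotype_network}: list with
#'   \code{nodes} (the haplotype table), \code{edges} (data.frame: from, to,
#'   steps, with \code{steps - 1} missing intermediates implied per edge)
#'   and \code{graph} (an igraph object with the same attributes).
#' @export
minimum_spanning_network <- function(haps, epsilon = 0) {
  stopifnot(inherits(haps, "haplotype_set"), epsilon >= 0)
  nh <- nrow(haps$haplotypes)
  hap_ids <- haps$haplotypes$hap
  if (nh == 1) {
    edges <- data.frame(from = character(0), to = character(0),
                        steps = integer(0))
  } else {
    d <- haps$distance
    all_e <- which(upper.tri(d), arr.ind = TRUE)
    ew <- d[all_e]
    comp <- seq_len(nh)              # union-find, path-halving not needed
    find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
    keep <- logical(nrow(all_e))
    for (w in sort(unique(ew))) {
      snapshot <- vapply(seq_len(nh), find, integer(1))
      cls <- which(ew >= w & ew <= w + epsilon)
      added <- FALSE
      for (e in cls) {
        a <- snapshot[all_e[e, 1]]; b <- snapshot[all_e[e, 2]]
        if (a != b) { keep[e] <- TRUE; added <- TRUE }
      }
      if (added) {
        for (e in which(keep)) {
          ra <- find(all_e[e, 1]); rb <- find(all_e[e, 2])
          if (ra != rb) comp[ra] <- rb
        }
      }
      if (length(unique(vapply(seq_len(nh), find, integer(1)))) == 1) break
    }
    edges <- data.frame(from = hap_ids[all_e[keep, 1]],
                        to = hap_ids[all_e[keep, 2]],
                        steps = as.integer(ew[keep]))
    edges <- edges[order(edges$steps, edges$from, edges$to), ]
    rownames(edges) <- NULL
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = haps$haplotypes)
  structure(list(nodes = haps$haplotypes, edges = edges, graph = g,
                 epsilon = epsilon),
            class = "haplotype_network")
}

#' Export a haplotype network to GraphML and plain-text tables
#'
#' Writes GraphML (node frequency and per-morph counts; edge mutational
#' steps), a CSV edge list, and a CSV node table.
#'
#' @param net a \code{haplotype_network}.
#' @param graphml_path output GraphML path.
#' @param edges_path optional CSV edge-list path.
#' @param nodes_path optional CSV node-table path.
#' @return Invisibly, the paths written.
#' @export
export_network <- function(net, graphml_path, edges_path = NULL,
                           nodes_path = NULL) {
  stopifnot(inherits(net, "haplotype_network"))
  igraph::write_graph(net$graph, graphml_path, format = "graphml")
  if (!is.null(edges_path))
    utils::write.csv(net$edges, edges_path, row.names = FALSE)
  if (!is.null(nodes_path))
    utils::write.csv(net$nodes, nodes_path, row.names = FALSE)
  invisible(c(graphml_path, edges_path, nodes_path))
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat("haplotype_network:", nrow(x$nodes), "haplotypes,",
      nrow(x$edges), "edges")
  if (nrow(x$edges))
    cat(", steps 1..", max(x$edges$steps),
        " (", sum(pmax(x$edges$steps - 1, 0)),
        " missing intermediates)", sep = "")
  cat("\n")
  invisible(x)
}
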