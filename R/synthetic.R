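#' Study-shaped sampling configuration
#'
#' The four-morph sampling design used throughout the package examples:
#' Red-Green 11, Green 10, Red 9, Blue 11 individuals (41 in total), with
#' one collecting area per morph in the labels table.
#'
#' @return list with \code{config} (a [sample_config]) and \code{labels}
#'   (data.frame id, morph, locality) whose ids match the tip ids produced
#'   by [simulate_gene_tree] / [simulate_alignment].
#' @export
fixture_study_config <- function() {
  sizes <- c("Red-Green" = 11L, "Green" = 10L, "Red" = 9L, "Blue" = 11L)
  locality <- c("Red-Green" = "Cerro Cordoba", "Green" = "Camino Tolhuaca",
                "Red" = "Salto de la Princesa", "Blue" = "Termas Malleco")
  labels <- do.call(rbind, lapply(names(sizes), function(m) {
    data.frame(id = paste0(m, "_", seq_len(sizes[[m]])), morph = m,
               locality = locality[[m]])
  }))
  list(config = sample_config(sizes), labels = labels)
}

# tips descending from each node of a phylo (internal)
tips_under <- function(tr) {
  ntip <- length(tr$tip.label)
  po <- ape::reorder.phylo(tr, "postorder")
  under <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) under[[i]] <- i
  for (r in seq_len(nrow(po$edge)))
    under[[po$edge[r, 1]]] <- c(under[[po$edge[r, 1]]],
                                under[[po$edge[r, 2]]])
  under
}

#' Simulate a coalescent sequence alignment with known truth
#'
#' Simulates a gene tree under the structured coalescent, then drops
#' Poisson mutations on its branches (expected \code{length * theta /
#' (2 Ne)} per branch) under an infinite-sites model mapped onto distinct
#' positions of a finite sequence: the ancestral sequence is all-A and
#' each mutation assigns one random alternative base at one unused site to
#' all descendant tips. In \code{"monophyly"} mode each morph's subtree is
#' instead simulated as an isolated population and the subtrees are joined
#' by long stem branches, so every morph is reciprocally monophyletic by
#' construction.
#'
#' @param mt a [morph_tree] (its \code{ne} also scales the per-generation
#'   mutation rate as \code{theta / (2 ne)}).
#' @param config a [sample_config].
#' @param theta per-locus population mutation parameter (2 Ne mu, > 0).
#' @param seq_length alignment length in sites (default 658).
#' @param sorting \code{"neutral"} or \code{"monophyly"}.
#' @param stem_length stem branch length joining morph subtrees in
#'   monophyly mode (default 10 Ne generations).
#' @param seed integer seed.
#' @return list of class \code{sim_alignment}: \code{alignment} (a
#'   [seq_alignment] with morph labels), \code{tree} (the true
#'   \code{gene_tree}), \code{n_mutations}, \code{sites} (positions hit).
#' @export
simulate_alignment <- function(mt, config, theta, seq_length = 658,
                               sorting = c("neutral", "monophyly"),
                               stem_length = 10 * mt$ne, seed = NULL) {
  sorting <- match.arg(sorting)
  stopifnot(inherits(mt, "morph_tree"), theta > 0, seq_length >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (!inherits(config, "sample_config")) config <- sample_config(config)
  if (sorting == "neutral") {
    gt <- simulate_gene_tree(mt, config)
  } else {
    gt <- simulate_monophyletic_tree(mt, config, stem_length)
  }
  tr <- gt$tree
  ntip <- length(tr$tip.label)
  mu <- theta / (2 * mt$ne)             # per generation, per locus
  nmut_edge <- stats::rpois(nrow(tr$edge), tr$edge.length * mu)
  total <- sum(nmut_edge)
  if (total > seq_length)
    stop("infinite-sites exhausted: ", total, " mutations for ",
         seq_length, " sites; lower theta or shorten branches")
  sites <- if (total > 0) sample.int(seq_length, total) else integer(0)
  seqs <- matrix("A", ntip, seq_length,
                 dimnames = list(tr$tip.label, NULL))
  under <- tips_under(tr)
  m <- 0L
  for (e in seq_len(nrow(tr$edge))) {
    if (nmut_edge[e] == 0) next
    tips <- under[[tr$edge[e, 2]]]
    for (j in seq_len(nmut_edge[e])) {
      m <- m + 1L
      seqs[tips, sites[m]] <- sample(c("C", "G", "T"), 1)
    }
  }
  aln <- seq_alignment(seqs, labels = gt$demes)
  structure(list(alignment = aln, tree = gt, n_mutations = total,
                 sites = sort(sites)),
            class = "sim_alignment")
}

# reciprocally monophyletic gene tree: isolated per-morph coalescents
# joined by a star root with long stems (internal)
simulate_monophyletic_tree <- function(mt, config, stem_length) {
  sizes <- config_sizes(mt, config)
  subs <- lapply(seq_along(mt$labels), function(i) {
    morph <- mt$labels[i]
    n <- sizes[i]
    sim <- cpp_sim_tree(n, mt$ne, numeric(0), list())
    tips <- paste0(morph, "_", seq_len(n))
    list(tree = phylo_from_parent(sim$parent, sim$age, tips),
         age = if (n > 1) max(sim$age) else 0, morph = morph)
  })
  root_age <- max(vapply(subs, `[[`, numeric(1), "age")) + stem_length
  parts <- vapply(subs, function(s) {
    nwk <- ape::write.tree(s$tree)
    nwk <- sub(";$", "", nwk)
    if (length(s$tree$tip.label) == 1)
      nwk <- sub(":0$", "", nwk)          # single tip written as "x:0"
    paste0(nwk, ":", root_age - s$age)
  }, character(1))
  tr <- ape::read.tree(text = paste0("(", paste(parts, collapse = ","),
                                     ");"))
  demes <- stats::setNames(sub("_[0-9]+$", "", tr$tip.label),
                           tr$tip.label)
  gene_tree(tr, demes)
}

#' Simulate a Bernoulli predation table
#'
#' Independent attack outcomes per container with a per-cell probability.
#'
#' @param p_cells data.frame with columns \code{site}, \code{phenotype},
#'   \code{p} (attack probability in [0, 1]).
#' @param n_per_cell containers per site-by-phenotype cell (default 50).
#' @param seed integer seed.
#' @return A \code{predation_table} with \code{n_per_cell * nrow(p_cells)}
#'   rows.
#' @export
simulate_predation <- function(p_cells, n_per_cell = 50, seed = NULL) {
  stopifnot(all(c("site", "phenotype", "p") %in% names(p_cells)),
            all(p_cells$p >= 0 & p_cells$p <= 1))
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_len(nrow(p_cells)), function(i) {
    data.frame(site = p_cells$site[i], phenotype = p_cells$phenotype[i],
               attacked = stats::rbinom(n_per_cell, 1, p_cells$p[i]))
  })
  tab <- do.call(rbind, rows)
  predation_table(tab$site, tab$phenotype, tab$attacked)
}

#' Build a predation table from aggregated cell counts
#'
#' Deterministic expansion of per-cell attack counts into container-level
#' 0/1 rows (e.g., to reconstruct a reported design exactly).
#'
#' @param counts data.frame with columns \code{site}, \code{phenotype},
#'   \code{attacks}, \code{n}.
#' @return A \code{predation_table} with \code{sum(counts$n)} rows.
#' @export
predation_from_counts <- function(counts) {
  stopifnot(all(c("site", "phenotype", "attacks", "n") %in% names(counts)),
            all(counts$attacks <= counts$n))
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    data.frame(site = counts$site[i], phenotype = counts$phenotype[i],
               attacked = rep(c(1L, 0L), c(counts$attacks[i],
                                           counts$n[i] -
                                             counts$attacks[i])))
  })
  tab <- do.call(rbind, rows)
  predation_table(tab$site, tab$phenotype, tab$attacked)
}

#' Write a simulated alignment scenario to disk
#'
#' Emits FASTA, labels CSV, the true tree in newick, and a JSON manifest
#' recording paths and the scenario parameters.
#'
#' @param sim a \code{sim_alignment} from [simulate_alignment].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Invisibly, the manifest path.
#' @export
write_sim_alignment <- function(sim, dir, prefix = "sim") {
  stopifnot(inherits(sim, "sim_alignment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fasta <- file.path(dir, paste0(prefix, ".fasta"))
  labels <- file.path(dir, paste0(prefix, "_labels.csv"))
  tree <- file.path(dir, paste0(prefix, "_true_tree.nwk"))
  manifest <- file.path(dir, paste0(prefix, "_manifest.json"))
  write_alignment(sim$alignment, fasta, labels)
  ape::write.tree(sim$tree$tree, tree)
  jsonlite::write_json(
    list(fasta = fasta, labels = labels, tree = tree,
         n_mutations = sim$n_mutations, sites = sim$sites),
    manifest, auto_unbox = TRUE)
  invisible(manifest)
}
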