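#' Morph (population) tree for structured-coalescent simulation
#'
#' A population tree over k morph labels with constant haploid effective
#' size \code{ne} in every population (tip, internal and ancestral). Two
#' topologies are supported: a star (all morphs merge simultaneously at
#' \code{branch_length} generations before present) and an arbitrary
#' user-supplied \code{ape::phylo} over the morph labels, whose edges by
#' default all have the same length \code{branch_length} (per-edge
#' multiples can be taken from \code{phylo$edge.length} with
#' \code{use_branch_lengths = TRUE}).
#'
#' @param labels character vector of morph labels (k >= 2 for \code{star}).
#' @param branch_length terminal branch length in generations (>= 0).
#' @param ne haploid effective population size (> 0).
#' @param topology \code{"star"} or an \code{ape::phylo} whose tip labels
#'   are the morph labels.
#' @param use_branch_lengths when a phylo is supplied, interpret its edge
#'   lengths as multiples of \code{branch_length} (default: every edge has
#'   multiple 1).
#' @return An object of class \code{morph_tree}.
#' @export
morph_tree <- function(labels, branch_length, ne, topology = "star",
                       use_branch_lengths = FALSE) {
  stopifnot(ne > 0, branch_length >= 0)
  if (inherits(topology, "phylo")) {
    phy <- topology
    if (!setequal(phy$tip.label, labels))
      stop("phylo tip labels must match morph labels")
    labels <- phy$tip.label
    kind <- "phylo"
    unit <- if (use_branch_lengths) {
      if (is.null(phy$edge.length)) stop("phylo has no edge lengths")
      phy$edge.length
    } else rep(1, nrow(phy$edge))
  } else {
    if (!identical(topology, "star")) stop("topology must be 'star' or a phylo")
    if (length(labels) < 2) stop("star topology needs k >= 2 morphs")
    phy <- NULL
    kind <- "star"
    unit <- NULL
  }
  structure(list(labels = labels, branch_length = branch_length, ne = ne,
                 kind = kind, phylo = phy, unit = unit),
            class = "morph_tree")
}

#' @rdname morph_tree
#' @export
star_morph_tree <- function(labels, branch_length, ne = 10000)
  morph_tree(labels, branch_length, ne, "star")

# replace the terminal branch length, keeping topology (internal)
set_branch_length <- function(mt, branch_length) {
  mt$branch_length <- branch_length
  mt
}

# merge-event schedule for the C++ engine: 0-based population ids, tips
# 0..k-1 in label order; event e creates population k+e (internal)
morph_events <- function(mt) {
  k <- length(mt$labels)
  if (mt$kind == "star") {
    return(list(times = mt$branch_length, members = list(0:(k - 1))))
  }
  phy <- mt$phylo
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  elen <- mt$unit * mt$branch_length
  # node ages: tips at 0, parent age = max(child age + edge length)
  age <- rep(0, nnode)
  po <- ape::reorder.phylo(phy, "postorder")
  pe <- po$edge
  plen <- elen[match(paste(pe[, 1], pe[, 2]),
                     paste(phy$edge[, 1], phy$edge[, 2]))]
  for (r in seq_len(nrow(pe)))
    age[pe[r, 1]] <- max(age[pe[r, 1]], age[pe[r, 2]] + plen[r])
  # children's merge events must precede their parent's even at tied
  # ages (e.g. a zero-length tree), so break age ties by node height
  height <- rep(0L, nnode)
  for (r in seq_len(nrow(pe)))
    height[pe[r, 1]] <- max(height[pe[r, 1]], height[pe[r, 2]] + 1L)
  internal <- (ntip + 1):nnode
  ord <- internal[order(age[internal], height[internal])]
  pop_of_node <- integer(nnode)
  pop_of_node[seq_len(ntip)] <- seq_len(ntip) - 1L
  times <- numeric(length(ord))
  members <- vector("list", length(ord))
  for (e in seq_along(ord)) {
    node <- ord[e]
    kids <- pe[pe[, 1] == node, 2]
    members[[e]] <- pop_of_node[kids]
    times[e] <- age[node]
    pop_of_node[node] <- k + e - 1L
  }
  # strictly non-decreasing times; nudge exact ties into processing order
  times <- cummax(times)
  list(times = times, members = members)
}

#' Per-morph sample sizes
#'
#' @param sizes named integer vector (morph -> gene copies sampled, each
#'   >= 1).
#' @return validated named integer vector of class \code{sample_config}.
#' @export
sample_config <- function(sizes) {
  if (is.null(names(sizes)) || any(!nzchar(names(sizes))))
    stop("sample sizes must be named by morph")
  if (any(sizes < 1)) stop("every morph needs at least one sample")
  structure(as.integer(round(sizes)), names = names(sizes),
            class = "sample_config")
}

# align config to morph_tree label order (internal)
config_sizes <- function(mt, config) {
  if (!setequal(names(config), mt$labels))
    stop("sample config morphs do not match morph tree labels")
  as.integer(config[mt$labels])
}

#' Simulate one structured-coalescent gene tree
#'
#' Within each population, lineages coalesce at rate j(j-1)/(2 Ne) per
#' generation (continuous-time Kingman approximation) until the
#' population's branch ends; at each population-tree merge the surviving
#' lineages pool, and the root population coalesces to a single lineage.
#' Tips are labeled \code{<morph>_<i>} and carry their morph of origin.
#'
#' @param mt a [morph_tree].
#' @param config a [sample_config] over the same morph labels.
#' @param seed optional integer seed.
#' @return A \code{gene_tree} whose \code{tree} has branch lengths in
#'   generations.
#' @export
simulate_gene_tree <- function(mt, config, seed = NULL) {
  stopifnot(inherits(mt, "morph_tree"))
  if (!is.null(seed)) set.seed(seed)
  sizes <- config_sizes(mt, config)
  ev <- morph_events(mt)
  sim <- cpp_sim_tree(sizes, mt$ne, ev$times, ev$members)
  demes <- mt$labels[sim$deme + 1L]
  tip_ids <- paste0(demes, "_", stats::ave(seq_along(demes), demes,
                                           FUN = seq_along))
  tr <- phylo_from_parent(sim$parent, sim$age, tip_ids)
  gene_tree(tr, stats::setNames(demes, tip_ids))
}

# build an ape::phylo from a 0-based parent vector and node ages (internal)
phylo_from_parent <- function(parent, age, tip_ids) {
  n <- length(tip_ids)
  if (n == 1) {
    tr <- structure(list(edge = matrix(c(2L, 1L), 1, 2),
                         edge.length = 0, tip.label = tip_ids, Nnode = 1L),
                    class = "phylo")
    return(tr)
  }
  ntot <- 2L * n - 1L
  # cpp index i -> phylo id: tips i < n -> i+1; internal: root (ntot-1)
  # becomes n+1, then descending cpp index
  newid <- integer(ntot)
  newid[seq_len(n)] <- seq_len(n)
  newid[(n + 1):ntot] <- n + 1L + (ntot - 1L) - ((n + 1):ntot - 1L)
  child <- which(parent >= 0)            # 1-based cpp positions
  edge <- cbind(newid[parent[child] + 1L], newid[child])
  elen <- age[parent[child] + 1L] - age[child]
  tr <- structure(list(edge = edge, edge.length = elen,
                       tip.label = tip_ids, Nnode = n - 1L),
                  class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}

#' Null distribution of the s statistic under the structured coalescent
#'
#' Simulates \code{reps} gene trees within the morph tree and computes the
#' minimum-transition (s) statistic on each.
#'
#' @inheritParams simulate_gene_tree
#' @param reps number of replicates (>= 1).
#' @return An object of class \code{s_distribution}: list with the integer
#'   vector \code{s}, \code{reps}, \code{seed}, \code{quantiles} and the
#'   frequency \code{table}.
#' @export
s_distribution <- function(mt, config, reps = 10000, seed = NULL) {
  stopifnot(inherits(mt, "morph_tree"), reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  sizes <- config_sizes(mt, config)
  ev <- morph_events(mt)
  out <- cpp_sim_batch(sizes, mt$ne, ev$times, ev$members, as.integer(reps),
                       FALSE)
  s <- out$s
  structure(list(s = s, reps = reps, seed = seed,
                 quantiles = stats::quantile(s, c(.01, .05, .25, .5, .75,
                                                  .95, .99), type = 1),
                 table = table(s)),
            class = "s_distribution")
}

#' @export
print.s_distribution <- function(x, ...) {
  cat("s_distribution:", x$reps, "replicates; min =", min(x$s),
      "median =", stats::median(x$s), "max =", max(x$s), "\n")
  print(x$quantiles)
  invisible(x)
}

#' Tune the morph-tree branch length to the 5\% criterion
#'
#' Finds, by bracketing and bisection on the monotone tail proportion, the
#' largest branch length T at which at least the criterion fraction
#' (default 5\%) of simulated gene trees still show lineage sorting as
#' weak as the data, i.e. P(s >= s_obs) >= quantile. Longer branches give
#' more within-morph coalescence and smaller s, so this tail is
#' non-increasing in T and the tuned value is the conservative maximum
#' branch length compatible with the observed s: at the tuned length the
#' tail is >= the quantile, one resolution step longer it falls below.
#'
#' @param s_obs observed s on the empirical gene tree (>= k - 1).
#' @param mt a [morph_tree]; its current branch length is ignored.
#' @param config a [sample_config].
#' @param quantile criterion tail probability (default 0.05).
#' @param reps simulation replicates per candidate length.
#' @param resolution generations; search stops at this granularity.
#' @param seed integer seed (each candidate uses a derived substream).
#' @param upper bracket upper bound in generations (default 20 Ne).
#' @return An object of class \code{tuning_result}: \code{tuned_length}
#'   (generations), \code{tuned_in_ne}, \code{achieved_tail},
#'   \code{criterion_quantile}, \code{trace} (data.frame of candidate
#'   lengths and tails), \code{reps}, \code{seed}.
#' @export
tune_branch_length <- function(s_obs, mt, config, quantile = 0.05,
                               reps = 10000, resolution = 1, seed = NULL,
                               upper = 20 * mt$ne) {
  stopifnot(inherits(mt, "morph_tree"))
  k <- length(mt$labels)
  if (s_obs < k - 1)
    stop("s_obs = ", s_obs, " is below the minimum possible s = ", k - 1)
  if (is.null(seed)) seed <- sample.int(2^31 - 1, 1)
  eval_i <- 0L
  trace <- list()
  tail_at <- function(T) {
    eval_i <<- eval_i + 1L
    sd <- s_distribution(set_branch_length(mt, T), config, reps,
                         seed = (seed + 7919L * eval_i) %% (2^31 - 1))
    tail <- mean(sd$s >= s_obs)
    trace[[length(trace) + 1L]] <<- data.frame(length = T, tail = tail)
    tail
  }
  t_up <- tail_at(upper)
  if (t_up >= quantile)
    stop("tail P(s >= ", s_obs, ") = ", t_up, " still meets the ",
         quantile, " criterion at the upper search bound ", upper,
         " generations; increase `upper` or check s_obs")
  t_lo <- tail_at(0)
  flag <- NULL
  if (t_lo < quantile) {
    # the observed s is higher (less sorted) than even instantaneous
    # divergence typically allows: boundary behavior, report zero length
    flag <- paste0("P(s >= s_obs) = ", t_lo,
                   " is below the criterion even at zero branch length")
    lo <- 0; t_lo <- t_lo
  } else {
    lo <- 0; hi <- upper
    while (hi - lo > resolution) {
      mid <- (lo + hi) / 2
      t_mid <- tail_at(mid)
      if (t_mid >= quantile) { lo <- mid; t_lo <- t_mid } else hi <- mid
    }
  }
  structure(list(tuned_length = lo, tuned_in_ne = lo / mt$ne,
                 achieved_tail = t_lo, criterion_quantile = quantile,
                 trace = do.call(rbind, trace), reps = reps, seed = seed,
                 flag = flag),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat("tuned branch length:", round(x$tuned_length, 1), "generations (",
      signif(x$tuned_in_ne, 4), "Ne );",
      "tail P(s >= s_obs) =", signif(x$achieved_tail, 3),
      "at criterion", x$criterion_quantile, "\n")
  if (!is.null(x$flag)) cat("note:", x$flag, "\n")
  invisible(x)
}

#' Rescale a mitochondrial branch length to a nuclear locus
#'
#' Mitochondrial loci have one quarter the effective size of nuclear
#' autosomes; with Ne held fixed, the equivalent nuclear branch length is
#' the mitochondrial one divided by four, floored to whole generations.
#'
#' @param t_mt branch length in generations (>= 0).
#' @return \code{floor(t_mt / 4)} generations.
#' @export
nuclear_rescale <- function(t_mt) {
  stopifnot(t_mt >= 0)
  floor(t_mt / 4)
}

#' Drift test: is complete phenotypic sorting plausible?
#'
#' Simulates the null distribution of s at the (nuclear-rescaled) branch
#' length and asks how often the simulated sorting is at least as complete
#' as the observed sorting of the phenotype (s <= \code{s_target};
#' complete sorting of k morphs is s = k - 1). Drift is rejected when that
#' frequency falls below \code{alpha}; a frequency of zero is reported as
#' the bound p < 1/reps.
#'
#' @param mt a [morph_tree] whose branch length is the nuclear length.
#' @param config a [sample_config].
#' @param reps simulation replicates.
#' @param seed integer seed.
#' @param s_target observed sorting to test against (default k - 1,
#'   complete sorting).
#' @param alpha rejection level (default 0.05).
#' @return An object of class \code{selection_test}: \code{min_s},
#'   \code{freq_complete_sorting}, \code{p_value} (the frequency, or the
#'   1/reps bound when zero), \code{p_label}, \code{reject_drift},
#'   \code{nuclear_length}, \code{reps}, \code{seed}, \code{s_target}.
#' @export
selection_test <- function(mt, config, reps = 10000, seed = NULL,
                           s_target = length(mt$labels) - 1, alpha = 0.05) {
  sd <- s_distribution(mt, config, reps, seed)
  freq <- mean(sd$s <= s_target)
  p_value <- if (freq == 0) 1 / reps else freq
  p_label <- if (freq == 0) paste0("< ", format(1 / reps)) else
    format(freq)
  structure(list(min_s = min(sd$s), freq_complete_sorting = freq,
                 p_value = p_value, p_label = p_label,
                 reject_drift = freq < alpha,
                 nuclear_length = mt$branch_length, reps = reps,
                 seed = seed, s_target = s_target, alpha = alpha,
                 distribution = sd),
            class = "selection_test")
}

#' @export
print.selection_test <- function(x, ...) {
  cat("selection test at branch length", x$nuclear_length, "generations:\n")
  cat("  min simulated s =", x$min_s, "over", x$reps, "replicates\n")
  cat("  P(s <=", x$s_target, ") =", x$p_label, "\n")
  cat("  neutral drift", if (x$reject_drift) "REJECTED" else
    "not rejected", "at alpha =", x$alpha, "\n")
  invisible(x)
}

#' Full drift-versus-selection test
#'
#' Orchestrates the whole procedure: the observed s (given directly or
#' computed from a labeled gene tree), branch-length tuning at the
#' lower-tail criterion on the mitochondrial locus, division by four for a
#' nuclear phenotype locus, and the selection test asking whether sorting
#' as complete as observed (default: full reciprocal monophyly, s = k - 1)
#' can arise under neutral drift.
#'
#' @param s_obs observed s on the mitochondrial gene tree; alternatively
#'   supply \code{tree} (a \code{gene_tree}) and it is computed.
#' @param samples a [sample_config] (named morph sample sizes).
#' @param tree optional \code{gene_tree} used to compute \code{s_obs}.
#' @param topology \code{"star"} or an \code{ape::phylo} over the morphs.
#' @param ne haploid effective population size (default 10000).
#' @param reps replicates per simulation stage (default 10000).
#' @param quantile tuning criterion (default 0.05).
#' @param resolution tuning granularity in generations (default 1).
#' @param seed integer seed.
#' @param s_target sorting level to test (default k - 1).
#' @param alpha rejection level.
#' @return An object of class \code{drift_test} with elements
#'   \code{s_obs}, \code{tuning}, \code{nuclear_length}, \code{test},
#'   \code{config} (the resolved parameters).
#' @export
run_drift_test <- function(s_obs = NULL, samples, tree = NULL,
                           topology = "star", ne = 10000, reps = 10000,
                           quantile = 0.05, resolution = 1, seed = NULL,
                           s_target = NULL, alpha = 0.05) {
  if (!inherits(samples, "sample_config")) samples <- sample_config(samples)
  if (is.null(s_obs)) {
    if (is.null(tree)) stop("supply s_obs or a labeled gene tree")
    s_obs <- s_statistic(tree)
  }
  if (is.null(seed)) seed <- sample.int(2^31 - 1, 1)
  labels <- names(samples)
  mt <- morph_tree(labels, 0, ne, topology)
  k <- length(mt$labels)
  if (is.null(s_target)) s_target <- k - 1
  tuning <- tune_branch_length(s_obs, mt, samples, quantile = quantile,
                               reps = reps, resolution = resolution,
                               seed = seed)
  nuc <- nuclear_rescale(tuning$tuned_length)
  test <- selection_test(set_branch_length(mt, nuc), samples, reps = reps,
                         seed = (seed + 104729L) %% (2^31 - 1),
                         s_target = s_target, alpha = alpha)
  structure(list(s_obs = s_obs, tuning = tuning, nuclear_length = nuc,
                 test = test,
                 config = list(topology = if (mt$kind == "star") "star"
                               else "phylo",
                               ne = ne, samples = as.integer(samples),
                               morphs = labels, reps = reps,
                               quantile = quantile,
                               resolution = resolution, seed = seed,
                               s_target = s_target, alpha = alpha)),
            class = "drift_test")
}

#' @export
print.drift_test <- function(x, ...) {
  cat("Drift-vs-selection test\n")
  cat("observed s =", x$s_obs, "on", sum(x$config$samples), "tips,",
      length(x$config$morphs), "morphs\n")
  print(x$tuning)
  cat("nuclear branch length:", x$nuclear_length, "generations\n")
  print(x$test)
  invisible(x)
}
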