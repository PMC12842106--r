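#' Number of segregating (polymorphic) sites
#'
#' Counts alignment columns with at least two distinct nucleotides among
#' \code{A,C,G,T}; columns varying only through \code{N} or gaps do not
#' count.
#'
#' @param aln a [seq_alignment] with at least 2 sequences.
#' @return integer count of polymorphic sites.
#' @export
segregating_sites <- function(aln) {
  stopifnot(inherits(aln, "seq_alignment"))
  if (aln$n < 2) stop("need at least 2 sequences")
  sum(apply(aln$seqs, 2, function(col) {
    length(unique(col[col %in% c("A", "C", "G", "T")])) >= 2
  }))
}

# pairwise difference matrix with pairwise deletion of N/gap sites (internal)
pairwise_diff_matrix <- function(aln) {
  n <- aln$n
  good <- aln$seqs %in% c("A", "C", "G", "T")
  dim(good) <- dim(aln$seqs)
  d <- matrix(0, n, n, dimnames = list(rownames(aln$seqs), rownames(aln$seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- good[i, ] & good[j, ]
      d[i, j] <- d[j, i] <- sum(aln$seqs[i, ok] != aln$seqs[j, ok])
    }
  }
  d
}

#' Nucleotide diversity (mean pairwise differences)
#'
#' Average number of nucleotide differences per sequence pair (not per
#' site), with pairwise deletion of sites containing \code{N} or a gap.
#'
#' @param aln a [seq_alignment] with at least 2 sequences.
#' @return mean pairwise Hamming difference (pi).
#' @export
nucleotide_diversity <- function(aln) {
  stopifnot(inherits(aln, "seq_alignment"))
  if (aln$n < 2) stop("need at least 2 sequences")
  d <- pairwise_diff_matrix(aln)
  mean(d[upper.tri(d)])
}

# Tajima (1989) constants (internal)
tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D statistic
#'
#' Normalized difference between the mean-pairwise-difference and
#' segregating-sites estimators of theta:
#' \deqn{D = \frac{\pi - S/a_1}{\sqrt{e_1 S + e_2 S (S-1)}}}
#' with \eqn{a_1 = \sum_{i=1}^{n-1} 1/i} and the usual constants of the
#' statistic. Can be called either on a [seq_alignment] (computes
#' \eqn{n, S, \pi} first) or directly on the three summaries.
#'
#' @param x a [seq_alignment], or the sample size \code{n} (>= 4).
#' @param S number of segregating sites (when \code{x} is numeric).
#' @param pi mean pairwise differences (when \code{x} is numeric).
#' @return D, or \code{NA_real_} when \code{S == 0} (undefined).
#' @export
tajimas_d <- function(x, S = NULL, pi = NULL) {
  if (inherits(x, "seq_alignment")) {
    n <- x$n
    S <- segregating_sites(x)
    pi <- nucleotide_diversity(x)
  } else {
    n <- x
    if (is.null(S) || is.null(pi)) stop("supply S and pi with a numeric n")
  }
  if (n < 4) stop("Tajima's D requires n >= 4")
  if (S == 0) return(NA_real_)
  k <- tajima_constants(n)
  (pi - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

# One neutral-coalescent replicate of (S, pi) given n and theta.
# Times in units of 2N generations; mutations Poisson(theta/2 * L).
# Returns c(S, pi); pi from per-mutation descendant counts, so no
# sequences are materialized. (internal)
sim_neutral_summaries <- function(n, theta) {
  desc <- rep(1L, n)
  seg_desc <- integer(0)
  j <- n
  while (j >= 2) {
    tj <- stats::rexp(1, rate = j * (j - 1) / 2)
    nmut <- stats::rpois(1, theta / 2 * j * tj)
    if (nmut > 0) {
      hit <- sample.int(j, nmut, replace = TRUE)
      seg_desc <- c(seg_desc, desc[hit])
    }
    pair <- sample.int(j, 2)
    desc[pair[1]] <- desc[pair[1]] + desc[pair[2]]
    desc <- desc[-pair[2]]
    j <- j - 1L
  }
  S <- length(seg_desc)
  pi <- if (S == 0) 0 else sum(seg_desc * (n - seg_desc)) / choose(n, 2)
  c(S = S, pi = pi)
}

#' Significance of Tajima's D by neutral-coalescent simulation
#'
#' Two-sided probability that a D as extreme as observed arises under a
#' neutral coalescent with theta matched to the observed number of
#' segregating sites (Watterson estimate S/a1). Each replicate simulates a
#' coalescent genealogy, drops Poisson mutations, and recomputes D;
#' replicates with no mutations contribute D = 0.
#'
#' @param aln a [seq_alignment] (n >= 4).
#' @param reps number of simulation replicates (>= 100).
#' @param seed integer seed for reproducibility.
#' @return list with elements \code{D}, \code{p}, \code{reps};
#'   \code{p} is \code{NA} when D is undefined (S = 0).
#' @export
tajimas_d_test <- function(aln, reps = 1000, seed = NULL) {
  stopifnot(inherits(aln, "seq_alignment"))
  if (reps < 100) stop("reps must be >= 100")
  n <- aln$n
  S <- segregating_sites(aln)
  D_obs <- tajimas_d(aln)
  if (is.na(D_obs)) return(list(D = NA_real_, p = NA_real_, reps = reps))
  if (!is.null(seed)) set.seed(seed)
  theta_hat <- S / tajima_constants(n)$a1
  d_null <- vapply(seq_len(reps), function(r) {
    sm <- sim_neutral_summaries(n, theta_hat)
    if (sm["S"] == 0) 0 else tajimas_d(n, S = sm["S"], pi = sm["pi"])
  }, numeric(1))
  list(D = D_obs, p = mean(abs(d_null) >= abs(D_obs)), reps = reps)
}

#' Per-morph summary statistics table
#'
#' One row per morph with sample size, segregating sites, nucleotide
#' diversity, Tajima's D and its simulation p-value.
#'
#' @param aln a [seq_alignment] with morph labels.
#' @param reps replicates for the D significance test (0 skips it).
#' @param seed integer seed.
#' @return data.frame with columns \code{morph, N, S, pi, D, p}.
#' @export
morph_summary <- function(aln, reps = 1000, seed = NULL) {
  stopifnot(inherits(aln, "seq_alignment"))
  if (!is.null(seed)) set.seed(seed)
  morphs <- unique(aln$labels[!is.na(aln$labels)])
  rows <- lapply(morphs, function(m) {
    sub <- aln_subset(aln, names(aln$labels)[!is.na(aln$labels) &
                                               aln$labels == m])
    S <- segregating_sites(sub)
    pi <- nucleotide_diversity(sub)
    D <- if (sub$n >= 4 && S > 0) tajimas_d(sub$n, S, pi) else NA_real_
    p <- if (!is.na(D) && reps > 0) tajimas_d_test(sub, reps)$p else NA_real_
    data.frame(morph = m, N = sub$n, S = S, pi = pi, D = D, p = p)
  })
  do.call(rbind, rows)
}
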