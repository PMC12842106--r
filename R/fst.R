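#' Pairwise Fst between morphs
#'
#' Distance-based Phi-st (default): for each pair of groups,
#' \code{1 - mean(within-group pairwise differences) / mean(all pairwise
#' differences)} over the pooled pair of groups, using pairwise deletion of
#' missing sites. A conventional haplotype-frequency Fst
#' (\code{(Ht - Hs)/Ht} on haplotype identities) is available via
#' \code{method = "haplotype"}. Values are reported as computed and may be
#' slightly negative; pairs where a group has fewer than 2 sequences are
#' \code{NA}.
#'
#' @param aln a [seq_alignment] with morph labels.
#' @param method \code{"phist"} (distance-based, default) or
#'   \code{"haplotype"}.
#' @return An object of class \code{fst_matrix}: list with \code{groups},
#'   symmetric \code{values} matrix (diagonal \code{NA}), and \code{p}
#'   (\code{NULL} until [fst_permutation_test] fills it).
#' @export
pairwise_fst <- function(aln, method = c("phist", "haplotype")) {
  method <- match.arg(method)
  stopifnot(inherits(aln, "seq_alignment"))
  labs <- aln$labels[!is.na(aln$labels)]
  groups <- unique(labs)
  if (length(groups) < 2) stop("need at least 2 labeled groups")
  d <- pairwise_diff_matrix(aln)
  values <- matrix(NA_real_, length(groups), length(groups),
                   dimnames = list(groups, groups))
  for (i in seq_along(groups)) for (j in seq_along(groups)) {
    if (j >= i) next
    ids_i <- names(labs)[labs == groups[i]]
    ids_j <- names(labs)[labs == groups[j]]
    values[i, j] <- values[j, i] <-
      fst_pair(d, aln$seqs, ids_i, ids_j, method)
  }
  structure(list(groups = groups, values = values, p = NULL,
                 method = method),
            class = "fst_matrix")
}

# Fst for one pair of groups given the full difference matrix (internal)
fst_pair <- function(d, seqs, ids_i, ids_j, method) {
  if (length(ids_i) < 2 || length(ids_j) < 2) return(NA_real_)
  if (method == "phist") {
    ids <- c(ids_i, ids_j)
    sub <- d[ids, ids]
    grp <- rep(c(1L, 2L), c(length(ids_i), length(ids_j)))
    same <- outer(grp, grp, "==")
    ut <- upper.tri(sub)
    mean_within <- mean(sub[ut & same])
    mean_total <- mean(sub[ut])
    if (mean_total == 0) return(0)
    1 - mean_within / mean_total
  } else {
    hap <- apply(seqs[c(ids_i, ids_j), , drop = FALSE], 1, paste,
                 collapse = "")
    het <- function(x) 1 - sum((table(x) / length(x))^2)
    ht <- het(hap)
    hs <- mean(c(het(hap[seq_along(ids_i)]),
                 het(hap[length(ids_i) + seq_along(ids_j)])))
    if (ht == 0) return(0)
    (ht - hs) / ht
  }
}

#' Permutation test for pairwise Fst
#'
#' For each pair of morphs, permutes group membership among the pooled
#' sequences and reports the one-sided probability that a permuted Fst is
#' at least as large as the observed value.
#'
#' @param aln a [seq_alignment] with morph labels.
#' @param reps number of label permutations (>= 100).
#' @param seed integer seed.
#' @param method as in [pairwise_fst].
#' @return A \code{fst_matrix} with the \code{p} matrix filled.
#' @export
fst_permutation_test <- function(aln, reps = 1000, seed = NULL,
                                 method = c("phist", "haplotype")) {
  method <- match.arg(method)
  if (reps < 100) stop("reps must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  fst <- pairwise_fst(aln, method)
  labs <- aln$labels[!is.na(aln$labels)]
  d <- pairwise_diff_matrix(aln)
  groups <- fst$groups
  p <- matrix(NA_real_, length(groups), length(groups),
              dimnames = list(groups, groups))
  for (i in seq_along(groups)) for (j in seq_along(groups)) {
    if (j >= i) next
    obs <- fst$values[i, j]
    if (is.na(obs)) next
    ids_i <- names(labs)[labs == groups[i]]
    ids_j <- names(labs)[labs == groups[j]]
    pool <- c(ids_i, ids_j)
    ni <- length(ids_i)
    perm <- vapply(seq_len(reps), function(r) {
      shuf <- sample(pool)
      fst_pair(d, aln$seqs, shuf[seq_len(ni)], shuf[-seq_len(ni)], method)
    }, numeric(1))
    p[i, j] <- p[j, i] <- mean(perm >= obs - 1e-12)
  }
  fst$p <- p
  fst$reps <- reps
  fst
}

#' @export
print.fst_matrix <- function(x, digits = 3, ...) {
  cat("Pairwise Fst (", x$method, ")\n", sep = "")
  v <- round(x$values, digits)
  v[upper.tri(v, diag = TRUE)] <- NA
  if (!is.null(x$p)) {
    star <- ifelse(!is.na(x$p) & x$p < 0.05, " *", "  ")
    out <- matrix(paste0(format(v), ifelse(lower.tri(v), star, "  ")),
                  nrow(v), dimnames = dimnames(v))
    out[upper.tri(out, diag = TRUE)] <- ""
    print(out, quote = FALSE)
    cat("* p < 0.05 (", x$reps, " permutations)\n", sep = "")
  } else {
    print(v, na.print = "")
  }
  invisible(x)
}
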