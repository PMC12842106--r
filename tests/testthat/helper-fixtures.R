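# small in-code fixtures shared across test files

`%||%` <- function(a, b) if (is.null(a)) b else a

# alignment from named strings, optionally with morph labels
mk_aln <- function(strings, morphs = NULL) {
  labels <- if (!is.null(morphs)) stats::setNames(morphs, names(strings))
  seq_alignment(as.list(strings), labels = labels)
}

# four-morph study-shaped sampling design
study_fixture <- fixture_study_config()

# a tree with four reciprocally monophyletic demes, two tips each
monophyletic_tree4 <- function() {
  tr <- ape::read.tree(
    text = "(((a1,a2),(b1,b2)),((c1,c2),(d1,d2)));")
  demes <- setNames(rep(c("A", "B", "C", "D"), each = 2),
                    c("a1", "a2", "b1", "b2", "c1", "c2", "d1", "d2"))
  gene_tree(tr, demes)
}

# random gene_tree: ntip tips, deme labels drawn from k states (all k
# guaranteed present when ntip >= k)
random_labeled_tree <- function(ntip, k) {
  tr <- ape::rtree(ntip)
  st <- LETTERS[seq_len(k)]
  demes <- setNames(sample(c(st, sample(st, ntip - k, replace = TRUE))),
                    tr$tip.label)
  gene_tree(tr, demes)
}

# independent minimum-transition oracle on a cpp parent/deme encoding:
# plain R Fitch pass over the binary simulated tree
fitch_oracle <- function(parent, deme) {
  n <- length(deme)
  ntot <- 2L * n - 1L
  mask <- integer(ntot)
  mask[seq_len(n)] <- bitwShiftL(1L, deme)
  kids <- split(seq_len(ntot)[parent >= 0], parent[parent >= 0])
  steps <- 0L
  for (i in (n + 1L):ntot) {
    ch <- kids[[as.character(i - 1L)]]
    m <- bitwAnd(mask[ch[1]], mask[ch[2]])
    if (m == 0L) {
      m <- bitwOr(mask[ch[1]], mask[ch[2]])
      steps <- steps + 1L
    }
    mask[i] <- m
  }
  steps
}
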