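#' Aligned haploid sequences with morph labels
#'
#' Container for a multiple sequence alignment of haploid (e.g.,
#' mitochondrial COI) sequences together with the morph/deme label of each
#' individual. Sequences are stored as an upper-case character matrix over
#' \code{A,C,G,T,N,-}; rows are individuals, columns alignment sites.
#'
#' @param seqs character matrix (rows named by sequence id) or list of
#'   equal-length character vectors/strings.
#' @param labels named character vector mapping sequence id to morph label;
#'   ids absent from \code{labels} are retained unlabeled (\code{NA}).
#' @param locality optional named character vector of locality per id.
#' @return An object of class \code{seq_alignment} with elements
#'   \code{seqs}, \code{labels}, \code{locality}, \code{n}, \code{length}.
#' @export
seq_alignment <- function(seqs, labels = NULL, locality = NULL) {
  if (is.list(seqs)) {
    seqs <- lapply(seqs, function(x) {
      if (length(x) == 1L) strsplit(x, "")[[1]] else as.character(x)
    })
    lens <- lengths(seqs)
    if (length(unique(lens)) > 1L)
      stop("alignment error: sequences have unequal lengths (",
           paste(unique(lens), collapse = ", "), ")")
    seqs <- do.call(rbind, seqs)
  }
  if (!is.matrix(seqs)) stop("seqs must be a character matrix or list")
  if (is.null(rownames(seqs))) stop("sequences must be named")
  if (anyDuplicated(rownames(seqs)))
    stop("format error: duplicate sequence id: ",
         rownames(seqs)[duplicated(rownames(seqs))][1])
  if (ncol(seqs) == 0L) stop("alignment error: zero-length alignment")
  seqs[] <- toupper(seqs)
  bad <- !(seqs %in% c("A", "C", "G", "T", "N", "-"))
  if (any(bad)) seqs[bad] <- "N"
  ids <- rownames(seqs)
  lab <- rep(NA_character_, nrow(seqs))
  names(lab) <- ids
  if (!is.null(labels)) {
    extra <- setdiff(names(labels), ids)
    if (length(extra))
      stop("label id not present in alignment: ", extra[1])
    lab[names(labels)] <- unname(labels)
  }
  loc <- rep(NA_character_, nrow(seqs))
  names(loc) <- ids
  if (!is.null(locality)) loc[names(locality)] <- unname(locality)
  structure(
    list(seqs = seqs, labels = lab, locality = loc,
         n = nrow(seqs), length = ncol(seqs)),
    class = "seq_alignment")
}

#' Read an alignment from FASTA plus a morph-label table
#'
#' Reads an aligned FASTA file and attaches morph labels from a CSV with
#' columns \code{id}, \code{morph} and optionally \code{locality}. Every id
#' in the CSV must be present in the FASTA; FASTA records missing from the
#' CSV are kept unlabeled with a warning. Ragged (unequal-length) FASTA
#' input is rejected.
#'
#' @param fasta_path path to an aligned FASTA file.
#' @param labels_path optional path to the labels CSV.
#' @return A [seq_alignment] object.
#' @export
read_alignment <- function(fasta_path, labels_path = NULL) {
  dna <- ape::read.FASTA(fasta_path)
  if (length(dna) == 0L) stop("alignment error: no sequences in ", fasta_path)
  lens <- lengths(dna)
  if (length(unique(lens)) > 1L)
    stop("alignment error: unequal sequence lengths in ", fasta_path,
         " (", paste(sort(unique(lens)), collapse = ", "), ")")
  if (anyDuplicated(names(dna)))
    stop("format error: duplicate sequence id: ",
         names(dna)[duplicated(names(dna))][1])
  mat <- toupper(as.character(as.matrix(dna)))
  labels <- NULL
  locality <- NULL
  if (!is.null(labels_path)) {
    tab <- utils::read.csv(labels_path, stringsAsFactors = FALSE)
    need <- c("id", "morph")
    if (!all(need %in% names(tab)))
      stop("labels CSV must have columns 'id' and 'morph'")
    missing_in_fasta <- setdiff(tab$id, rownames(mat))
    if (length(missing_in_fasta))
      stop("label id not present in FASTA: ", missing_in_fasta[1])
    labels <- stats::setNames(tab$morph, tab$id)
    if ("locality" %in% names(tab))
      locality <- stats::setNames(tab$locality, tab$id)
    unlabeled <- setdiff(rownames(mat), tab$id)
    if (length(unlabeled))
      warning(length(unlabeled), " sequence(s) without a morph label ",
              "retained unlabeled: ", paste(utils::head(unlabeled, 3),
                                            collapse = ", "))
  }
  seq_alignment(mat, labels = labels, locality = locality)
}

#' Write an alignment and its labels to FASTA + CSV
#'
#' @param aln a [seq_alignment].
#' @param fasta_path output FASTA path.
#' @param labels_path output labels CSV path (columns id, morph, locality).
#' @return Invisibly, the two paths.
#' @export
write_alignment <- function(aln, fasta_path, labels_path = NULL) {
  stopifnot(inherits(aln, "seq_alignment"))
  lines <- character(2L * aln$n)
  ids <- rownames(aln$seqs)
  lines[seq(1, by = 2, length.out = aln$n)] <- paste0(">", ids)
  lines[seq(2, by = 2, length.out = aln$n)] <-
    apply(aln$seqs, 1, paste, collapse = "")
  writeLines(lines, fasta_path)
  if (!is.null(labels_path)) {
    utils::write.csv(
      data.frame(id = ids, morph = unname(aln$labels[ids]),
                 locality = unname(aln$locality[ids])),
      labels_path, row.names = FALSE)
  }
  invisible(c(fasta_path, labels_path))
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat("seq_alignment:", x$n, "sequences x", x$length, "sites\n")
  tab <- table(x$labels, useNA = "ifany")
  if (length(tab)) {
    cat("morphs:\n")
    print(tab)
  }
  invisible(x)
}

# subset an alignment by sequence ids (internal)
aln_subset <- function(aln, ids) {
  seq_alignment(aln$seqs[ids, , drop = FALSE],
                labels = aln$labels[ids][!is.na(aln$labels[ids])],
                locality = aln$locality[ids][!is.na(aln$locality[ids])])
}
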