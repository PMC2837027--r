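## Doublet/triplet nearest-neighbour classes under rotational identity.
##
## A stack of k adjacent Watson-Crick base pairs read 5'->3' on one strand
## is physically identical to the same stack read 5'->3' on the other
## strand, i.e. to its reverse complement.  Grouping all 4^k k-mers by
## {w, revcomp(w)} therefore yields 10 classes for k = 2 (four doublets
## are their own reverse complement) and 32 classes for k = 3 (no odd-
## length word is).

.BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA sequence
#'
#' @param seq Character vector of DNA sequences (A/C/G/T, 5'->3').
#' @return Character vector of reverse complements, 5'->3'.  The
#'   operation is an involution: `revcomp(revcomp(x)) == x`.
#' @examples
#' revcomp("GAC")   # "GTC"
#' revcomp("AT")    # "AT" (its own reverse complement)
#' @export
revcomp <- function(seq) {
  check_dna(seq)
  vapply(seq, function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                 collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

## base-wise complement, no reversal (used for the BOTTOM strand of a label)
complement <- function(seq) chartr("ACGT", "TGCA", seq)

check_dna <- function(seq, arg = deparse(substitute(seq))) {
  if (!is.character(seq) || length(seq) < 1L || anyNA(seq))
    stop(sprintf("'%s' must be a character vector of DNA sequences", arg))
  bad <- grepl("[^ACGT]", seq)
  if (any(bad))
    stop(sprintf("non-ACGT character in sequence '%s'", seq[which(bad)[1]]))
  invisible(seq)
}

#' Canonical nearest-neighbour class of a k-mer
#'
#' Maps a doublet or triplet to its rotational-identity class.  The class
#' label has the form `"TOP/BOTTOM"`: TOP is the lexicographically
#' smaller of the k-mer and its reverse complement, and BOTTOM is TOP's
#' base-wise complement written 3'->5', so `"GAC/CTG"` denotes 5'-GAC-3'
#' paired with 3'-CTG-5'.
#'
#' @param word Character vector of k-mers, k = 2 or 3.
#' @return Character vector of canonical class labels.
#' @examples
#' canonical_class("GTC")  # "GAC/CTG"
#' canonical_class("TT")   # "AA/TT"
#' @export
canonical_class <- function(word) {
  check_dna(word)
  k <- nchar(word)
  if (any(k != k[1]) || !(k[1] %in% c(2L, 3L)))
    stop("motif words must all have length 2 or 3")
  rc <- revcomp(word)
  top <- ifelse(word <= rc, word, rc)
  paste0(top, "/", complement(top))
}

#' Enumerate all nearest-neighbour classes of a given order
#'
#' Partitions the 4^order k-mers into reverse-complement equivalence
#' classes: 10 doublet classes (order 2) or 32 triplet classes (order 3),
#' in lexicographic order of their canonical labels.
#'
#' @param order Motif length: 2 (doublets) or 3 (triplets).
#' @return Character vector of canonical class labels (length 10 or 32).
#' @examples
#' enumerate_classes(2)
#' length(enumerate_classes(3))  # 32
#' @export
enumerate_classes <- function(order) {
  order <- check_order(order)
  sort(unique(as.character(class_lookup(order))))
}

## memoized k-mer -> canonical label lookup over all 4^order words,
## plus the integer index of each word's class for fast counting
.motif_cache <- new.env(parent = emptyenv())
class_lookup <- function(order) {
  key <- as.character(order)
  if (is.null(.motif_cache[[key]])) {
    words <- apply(do.call(expand.grid, rep(list(.BASES), order)),
                   1L, paste, collapse = "")
    lk <- canonical_class(words)
    names(lk) <- words
    classes <- sort(unique(as.character(lk)))
    idx <- match(lk, classes)
    names(idx) <- words
    .motif_cache[[key]] <- lk
    .motif_cache[[paste0("idx", key)]] <- idx
    .motif_cache[[paste0("classes", key)]] <- classes
  }
  .motif_cache[[key]]
}
class_index <- function(order) {
  class_lookup(order)
  list(idx = .motif_cache[[paste0("idx", order)]],
       classes = .motif_cache[[paste0("classes", order)]])
}

check_order <- function(order) {
  if (length(order) != 1L || !(order %in% c(2, 3)))
    stop("'order' must be 2 (doublets) or 3 (triplets)")
  as.integer(order)
}

#' Count nearest-neighbour motifs in a sequence
#'
#' Slides a window of `order` nucleotides along the sequence 5'->3' in
#' steps of one and tallies the canonical class of each window.  Only one
#' strand is scanned; the complementary strand contributes no extra
#' information because each window and its reverse complement share a
#' class.  The counts always sum to `nchar(seq) - order + 1`.
#'
#' @param seq A single DNA sequence (the 5'->3' top strand of a duplex).
#' @param order Motif length, 2 or 3.
#' @return Named integer vector over all classes from
#'   [enumerate_classes()], in that order.
#' @examples
#' count_motifs("ATAT", 2)  # AT/TA: 2, TA/AT: 1
#' @export
count_motifs <- function(seq, order) {
  check_dna(seq)
  order <- check_order(order)
  if (length(seq) != 1L) stop("'seq' must be a single sequence")
  n <- nchar(seq)
  if (n < order)
    stop(sprintf("sequence of length %d is shorter than the motif order %d",
                 n, order))
  ci <- class_index(order)
  windows <- substring(seq, 1:(n - order + 1L), order:n)
  counts <- tabulate(ci$idx[windows], nbins = length(ci$classes))
  names(counts) <- ci$classes
  counts
}

## counts matrix for many sequences (rows) over the class set (columns)
motif_count_matrix <- function(seqs, order) {
  classes <- enumerate_classes(order)
  m <- t(vapply(seqs, count_motifs, integer(length(classes)), order = order))
  dimnames(m) <- list(NULL, classes)
  m
}
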