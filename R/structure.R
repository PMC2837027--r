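## Secondary-structure comparison for duplexes.
##
## A duplex structure is the pair of dot-parenthesis strings of its two
## strands; base pairs are recovered by nested matching of '(' with ')'
## over the concatenation struct1 + struct2 (positions 0-based, second
## strand offset by the first strand's length).  Comparison measures:
## SSSI, the percentage of structure-string positions at which two
## annotations agree, and base-pair-level sensitivity / positive
## predictive value / F-measure.

#' Parse a duplex secondary structure
#'
#' Extracts base pairs by nested matching over the concatenation of the
#' two strands' dot-parenthesis strings.  Pseudoknots cannot be
#' represented in this dialect and unbalanced input is an error.
#'
#' @param struct1,struct2 Dot-parenthesis strings (characters `.(` and
#'   `)`) for the first and second strand.
#' @return A list of class `duplex_structure`: `struct1`, `struct2`,
#'   and `pairs`, a two-column integer matrix of 0-based `(i, j)`
#'   positions (i < j) over the concatenation.
#' @examples
#' parse_duplex_structure("((((", "))))")$pairs   # (0,7) (1,6) (2,5) (3,4)
#' @export
parse_duplex_structure <- function(struct1, struct2) {
  stopifnot(is.character(struct1), length(struct1) == 1L,
            is.character(struct2), length(struct2) == 1L)
  combined <- paste0(struct1, struct2)
  chars <- strsplit(combined, "", fixed = TRUE)[[1]]
  if (any(!chars %in% c(".", "(", ")")))
    stop("invalid structure character at position ",
         which(!chars %in% c(".", "(", ")"))[1])
  stack <- integer(0)
  pairs <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("i", "j")))
  for (pos in seq_along(chars)) {
    if (chars[pos] == "(") {
      stack <- c(stack, pos - 1L)
    } else if (chars[pos] == ")") {
      if (!length(stack))
        stop("unmatched ')' at position ", pos - 1L)
      pairs <- rbind(pairs, c(stack[length(stack)], pos - 1L))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack))
    stop("unmatched '(' at position ", stack[length(stack)])
  structure(list(struct1 = struct1, struct2 = struct2, pairs = pairs),
            class = "duplex_structure")
}

pair_keys <- function(s) {
  if (nrow(s$pairs) == 0L) character(0) else
    paste(s$pairs[, 1], s$pairs[, 2], sep = "-")
}

as_duplex_structure <- function(x) {
  if (inherits(x, "duplex_structure")) x else
    parse_duplex_structure(x[[1]], x[[2]])
}

## strand strings only, no base-pair extraction: character-level
## measures apply even to annotations that do not parse as pair sets
structure_strings <- function(x) {
  if (inherits(x, "duplex_structure"))
    list(struct1 = x$struct1, struct2 = x$struct2)
  else list(struct1 = x[[1]], struct2 = x[[2]])
}

#' Secondary-structure similarity index (SSSI)
#'
#' Percentage of positions at which the experimental and calculated
#' structure strings carry identical characters, summed over both
#' strands and normalized by the total length.  Character-level
#' comparison automatically gives one point of credit per correctly
#' placed pairing end, i.e. a base pair that shares only its start or
#' only its end with the reference contributes half of a fully correct
#' pair.
#'
#' @param exp,calc `duplex_structure` objects (or 2-element character
#'   vectors/lists of dot-parenthesis strings) of matching strand
#'   lengths.  Being character-level, SSSI does not require the strings
#'   to parse into a valid pair set.
#' @return Similarity percentage in \[0, 100\].
#' @export
sssi <- function(exp, calc) {
  exp <- structure_strings(exp); calc <- structure_strings(calc)
  if (nchar(exp$struct1) != nchar(calc$struct1) ||
      nchar(exp$struct2) != nchar(calc$struct2))
    stop("structure length mismatch between experimental and calculated")
  a <- strsplit(paste0(exp$struct1, exp$struct2), "", fixed = TRUE)[[1]]
  b <- strsplit(paste0(calc$struct1, calc$struct2), "", fixed = TRUE)[[1]]
  100 * sum(a == b) / length(a)
}

#' Base-pair confusion counts between two duplex structures
#'
#' True positives are base pairs (exact `(i, j)` index pairs) present in
#' both structures; false positives those only in the calculated one;
#' false negatives those only in the experimental one.
#'
#' @inheritParams sssi
#' @return List of class `confusion_counts` with integer `tp`, `fp`,
#'   `fn`.
#' @export
structure_confusion <- function(exp, calc) {
  exp <- as_duplex_structure(exp); calc <- as_duplex_structure(calc)
  if (nchar(exp$struct1) != nchar(calc$struct1) ||
      nchar(exp$struct2) != nchar(calc$struct2))
    stop("structure length mismatch between experimental and calculated")
  pe <- pair_keys(exp); pc <- pair_keys(calc)
  structure(list(tp = length(intersect(pe, pc)),
                 fp = length(setdiff(pc, pe)),
                 fn = length(setdiff(pe, pc))),
            class = "confusion_counts")
}

#' Sensitivity, PPV and F-measure from confusion counts
#'
#' `sens = tp/(tp + fn)`, `ppv = tp/(tp + fp)`, and F is their harmonic
#' mean.  Degenerate cases are defined, not errors: when neither
#' structure has any base pair, all three are 1 (two empty structures
#' agree perfectly); when the prediction is empty but the reference is
#' not — or there are no true positives at all — all three are 0.
#'
#' @param counts A `confusion_counts` list from [structure_confusion()]
#'   (or any list with `tp`, `fp`, `fn`).
#' @return Named numeric vector `sens, ppv, f`, each in \[0, 1\].
#' @export
sens_ppv_f <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  if (tp + fp + fn == 0L)
    return(c(sens = 1, ppv = 1, f = 1))
  sens <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  ppv <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  f <- if (sens + ppv == 0) 0 else 2 * sens * ppv / (sens + ppv)
  c(sens = sens, ppv = ppv, f = f)
}

#' Structure-prediction accuracy stratified by length or GC content
#'
#' Scores each experimental/calculated structure pair with
#' [sens_ppv_f()] and averages the measures per sequence-length bin and
#' per 10-point GC-content bin.
#'
#' @param seq1 Character vector of first-strand sequences.
#' @param exp_struct1,exp_struct2 Experimental dot-parenthesis strings.
#' @param calc_struct1,calc_struct2 Calculated dot-parenthesis strings.
#' @return List with data.frames `by_length` and `by_gc`, each holding
#'   the bin, the number of duplexes and mean `sens`, `ppv`, `f`; empty
#'   input gives empty tables.
#' @export
stratified_metrics <- function(seq1, exp_struct1, exp_struct2,
                               calc_struct1, calc_struct2) {
  n <- length(seq1)
  stopifnot(length(exp_struct1) == n, length(exp_struct2) == n,
            length(calc_struct1) == n, length(calc_struct2) == n)
  empty <- data.frame(bin = numeric(0), n = integer(0), sens = numeric(0),
                      ppv = numeric(0), f = numeric(0))
  if (n == 0L) return(list(by_length = empty, by_gc = empty))
  scores <- t(vapply(seq_len(n), function(i)
    sens_ppv_f(structure_confusion(
      parse_duplex_structure(exp_struct1[i], exp_struct2[i]),
      parse_duplex_structure(calc_struct1[i], calc_struct2[i]))),
    numeric(3)))
  strat <- function(bin) {
    out <- do.call(rbind, lapply(split(seq_len(n), bin), function(i)
      data.frame(bin = bin[i[1]], n = length(i),
                 sens = mean(scores[i, "sens"]),
                 ppv = mean(scores[i, "ppv"]),
                 f = mean(scores[i, "f"]))))
    rownames(out) <- NULL
    out
  }
  list(by_length = strat(nchar(seq1)),
       by_gc = strat(pmin(floor(gc_content(seq1) / 10) * 10, 90)))
}
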