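## Duplex benchmark datasets.
##
## A dataset is a data.frame of class "duplex_dataset" with one row per
## measured duplex and the 15 columns of the benchmark exchange format:
## two sequences (5'->3'), a duplex id, two dot-parenthesis structure
## strings, experimental dG/dS/dH with their errors, the hybridization
## temperature, two sequence concentrations and the sodium concentration.
## The same duplex may appear several times (measured at different
## temperatures), so ids need not be unique.

DUPLEX_COLUMNS <- c("seq1", "seq2", "duplex_id", "struct1", "struct2",
                    "dg_exp", "dg_err", "ds_exp", "ds_err",
                    "dh_exp", "dh_err", "temperature",
                    "conc_self", "conc_nonself", "na_conc")
.NUMERIC_COLS <- setdiff(DUPLEX_COLUMNS,
                         c("seq1", "seq2", "duplex_id", "struct1", "struct2"))

#' Construct a duplex dataset
#'
#' Validates and classes a data.frame of duplex records.  Invariants
#' checked: sequences are A/C/G/T; structure strings use only
#' `.`, `(`, `)`; each structure has the same length as its sequence;
#' the total number of `(` across both strands equals the total number
#' of `)`.  Sequence lengths outside 4--30 nt raise a warning (the
#' format targets short oligonucleotides) but are kept.
#'
#' @param records data.frame with the columns listed in
#'   [duplex_columns()]; missing numeric values as `NA`.
#' @param source_label Optional label describing the dataset's origin.
#' @return The records as a `duplex_dataset` (a classed data.frame).
#' @export
duplex_dataset <- function(records, source_label = "unknown") {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(DUPLEX_COLUMNS, names(records))
  if (length(missing_cols))
    stop("missing duplex columns: ", paste(missing_cols, collapse = ", "))
  records <- as.data.frame(records)[DUPLEX_COLUMNS]
  for (col in .NUMERIC_COLS) records[[col]] <- as.numeric(records[[col]])
  for (col in c("seq1", "seq2", "duplex_id", "struct1", "struct2"))
    records[[col]] <- as.character(records[[col]])
  if (nrow(records) > 0L) {
    validate_duplex_rows(records)
    len <- nchar(records$seq1)
    if (any(len < 4L | len > 30L))
      warning(sum(len < 4L | len > 30L),
              " sequence(s) outside the expected 4-30 nt length range")
  }
  rownames(records) <- NULL
  structure(records, source_label = source_label,
            class = c("duplex_dataset", "data.frame"))
}

validate_duplex_rows <- function(records) {
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    for (sc in c("seq1", "seq2"))
      if (grepl("[^ACGT]", r[[sc]]) || !nzchar(r[[sc]]))
        stop(sprintf("row %d, field %s: non-ACGT base in '%s'",
                     i, sc, r[[sc]]))
    for (pair in list(c("struct1", "seq1"), c("struct2", "seq2"))) {
      st <- r[[pair[1]]]
      if (grepl("[^.()]", st))
        stop(sprintf("row %d, field %s: invalid structure character", i,
                     pair[1]))
      if (nchar(st) != nchar(r[[pair[2]]]))
        stop(sprintf(
          "row %d, field %s: structure length %d != sequence length %d",
          i, pair[1], nchar(st), nchar(r[[pair[2]]])))
    }
    both <- paste0(r$struct1, r$struct2)
    n_open <- lengths(regmatches(both, gregexpr("(", both, fixed = TRUE)))
    n_close <- lengths(regmatches(both, gregexpr(")", both, fixed = TRUE)))
    if (n_open != n_close)
      stop(sprintf("row %d: unbalanced structure, %d '(' vs %d ')'",
                   i, n_open, n_close))
  }
  invisible(records)
}

#' Column names of the 15-column duplex exchange format
#'
#' @return Character vector of the 15 column names, in file order.
#' @export
duplex_columns <- function() DUPLEX_COLUMNS

#' @export
print.duplex_dataset <- function(x, ...) {
  cat(sprintf("Duplex dataset '%s': %d record(s)\n",
              attr(x, "source_label") %||% "unknown", nrow(x)))
  if (nrow(x) > 0L) {
    pm <- sum(is_perfect_match(x))
    cat(sprintf("  perfect matches: %d; sequence lengths: %d-%d\n",
                pm, min(nchar(x$seq1)), max(nchar(x$seq1))))
  }
  NextMethod()
}

## "", "NA" and the literature's "n.r." (not reported) all mean missing.
parse_missing <- function(x) {
  x <- trimws(x)
  x[x %in% c("", "NA", "n.r.", "n.r", "nr")] <- NA_character_
  x
}

#' Read a duplex dataset from the 15-column comma-separated format
#'
#' The format has no mandatory header; a header line is auto-detected
#' (first field not a valid DNA sequence).  Missing numeric fields may be
#' empty, `NA` or `n.r.` and are parsed as `NA`, never as zero.
#'
#' @param path Path to a comma-separated file with 15 fields per row.
#' @param exclude_ids Optional character vector of duplex ids to drop
#'   after parsing (e.g. a curation exclusion list).
#' @param source_label Label for the dataset; defaults to the file name.
#' @return A [duplex_dataset()].
#' @export
read_duplex_dataset <- function(path, exclude_ids = NULL,
                                source_label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character",
                         strip.white = TRUE, blank.lines.skip = TRUE)
  if (ncol(raw) != 15L)
    stop(sprintf("expected 15 comma-separated fields, found %d in '%s'",
                 ncol(raw), path))
  ## header detection: the first field is no DNA sequence *and* the
  ## free-energy field is neither numeric nor a missing-value marker
  if (nrow(raw) > 0L && grepl("[^ACGT]", toupper(raw[1, 1])) &&
      is.na(suppressWarnings(as.numeric(raw[1, 6]))) &&
      !is.na(parse_missing(raw[1, 6])))
    raw <- raw[-1, , drop = FALSE]                      # header line
  names(raw) <- DUPLEX_COLUMNS
  for (col in .NUMERIC_COLS) {
    txt <- parse_missing(raw[[col]])
    num <- suppressWarnings(as.numeric(txt))
    bad <- which(!is.na(txt) & is.na(num))
    if (length(bad))
      stop(sprintf("row %d, field %s: cannot parse '%s' as a number",
                   bad[1], col, txt[bad[1]]))
    raw[[col]] <- num
  }
  d <- duplex_dataset(raw, source_label = source_label)
  if (!is.null(exclude_ids))
    d <- d[!(d$duplex_id %in% exclude_ids), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Write a duplex dataset in the 15-column format
#'
#' Writes a header line followed by one comma-separated row per record;
#' missing values are serialized as empty fields.  The output
#' round-trips through [read_duplex_dataset()].
#'
#' @param d A [duplex_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_duplex_dataset <- function(d, path) {
  stopifnot(inherits(d, "duplex_dataset"))
  out <- as.data.frame(d)
  for (col in .NUMERIC_COLS)
    out[[col]] <- ifelse(is.na(out[[col]]),
                         "", format(out[[col]], digits = 15, trim = TRUE,
                                    scientific = FALSE))
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Identify perfect-match duplexes
#'
#' A duplex is a perfect match when the second strand is the exact
#' reverse complement of the first *and* both structure annotations show
#' every base paired (`struct1` all `(`, `struct2` all `)`).  Requiring
#' both conditions means a malformed structure annotation can never
#' promote a mismatch duplex to perfect match.
#'
#' @param d A [duplex_dataset()] (or data.frame with the same columns).
#' @return Logical vector, one element per record.
#' @export
is_perfect_match <- function(d) {
  if (nrow(d) == 0L) return(logical(0))
  n1 <- nchar(d$seq1)
  full1 <- d$struct1 == strrep("(", n1)
  full2 <- d$struct2 == strrep(")", nchar(d$seq2))
  rc <- vapply(d$seq1, function(s) revcomp(s), character(1),
               USE.NAMES = FALSE)
  full1 & full2 & d$seq2 == rc
}

#' Filter a duplex dataset
#'
#' Subsets records by perfect-match status, hybridization temperature
#' (matched within +/- 0.01 degrees C) and sodium concentration, always
#' preserving record order.  An empty result is an empty dataset, not an
#' error.
#'
#' @param d A [duplex_dataset()].
#' @param perfect_only Keep only perfect-match duplexes?
#' @param temperature Optional temperature in degrees C.
#' @param na_conc Optional Na+ concentration in mol/L.
#' @return The filtered [duplex_dataset()].
#' @export
filter_duplexes <- function(d, perfect_only = FALSE, temperature = NULL,
                            na_conc = NULL) {
  stopifnot(inherits(d, "duplex_dataset"))
  keep <- rep(TRUE, nrow(d))
  if (perfect_only) keep <- keep & is_perfect_match(d)
  if (!is.null(temperature))
    keep <- keep & !is.na(d$temperature) &
      abs(d$temperature - temperature) <= 0.01
  if (!is.null(na_conc))
    keep <- keep & !is.na(d$na_conc) & d$na_conc == na_conc
  out <- d[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "source_label") <- attr(d, "source_label")
  out
}

#' GC content of DNA sequences
#'
#' @param seq Character vector of nonempty A/C/G/T sequences.
#' @return Percentage of G+C bases, per sequence (0--100).
#' @examples
#' gc_content(c("ATAT", "GCGC", "ATGC"))  # 0, 100, 50
#' @export
gc_content <- function(seq) {
  check_dna(seq)
  if (any(!nzchar(seq))) stop("empty sequence")
  gc <- nchar(gsub("[^GC]", "", seq))
  100 * gc / nchar(seq)
}

## ids of the form "<source>:<n>" (as written by the generator) carry
## their source; anything else is grouped under the dataset label.
duplex_source <- function(d) {
  src <- sub(":.*$", "", d$duplex_id)
  src[!grepl(":", d$duplex_id)] <- attr(d, "source_label") %||% "all"
  src
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize a duplex dataset
#'
#' Per-source summary (record count, sequence length range, temperature
#' and Na+ levels, concentration range) together with histograms of
#' sequence length and of GC content in 10-point bins.  Sources are
#' taken from the `"<source>:<n>"` convention in duplex ids where
#' present.
#'
#' @param d A [duplex_dataset()].
#' @return A list of class `duplexnn_summary` with elements `groups`
#'   (data.frame), `length_hist` and `gc_hist` (named integer tables)
#'   and `total`.
#' @export
dataset_summary <- function(d) {
  stopifnot(inherits(d, "duplex_dataset"))
  if (nrow(d) == 0L) {
    out <- list(groups = data.frame(), length_hist = table(integer(0)),
                gc_hist = table(integer(0)), total = 0L)
    class(out) <- "duplexnn_summary"
    return(out)
  }
  src <- duplex_source(d)
  fmt_set <- function(x) {
    x <- sort(unique(x[!is.na(x)]))
    if (!length(x)) "n.r." else paste(x, collapse = ", ")
  }
  fmt_range <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return("n.r.")
    if (min(x) == max(x)) format(min(x)) else
      paste0("[", format(min(x)), ", ", format(max(x)), "]")
  }
  groups <- do.call(rbind, lapply(split(seq_len(nrow(d)), src), function(i) {
    g <- d[i, , drop = FALSE]
    len <- nchar(g$seq1)
    conc <- c(g$conc_self, g$conc_nonself)
    data.frame(source = src[i[1]], n = length(i),
               seq_len = if (min(len) == max(len)) format(min(len)) else
                 paste0(min(len), " - ", max(len)),
               temperature = fmt_set(g$temperature),
               na_conc = fmt_set(g$na_conc),
               seq_conc = fmt_range(conc),
               stringsAsFactors = FALSE)
  }))
  rownames(groups) <- NULL
  len <- nchar(d$seq1)
  gc_bin <- pmin(floor(gc_content(d$seq1) / 10) * 10, 90)
  out <- list(groups = groups,
              length_hist = table(factor(len, levels = min(len):max(len))),
              gc_hist = table(factor(gc_bin, levels = seq(0, 90, 10))),
              total = nrow(d))
  class(out) <- "duplexnn_summary"
  out
}

#' @export
print.duplexnn_summary <- function(x, ...) {
  cat("Duplex dataset summary\n")
  if (x$total == 0L) {
    cat("  (empty dataset)\n")
    return(invisible(x))
  }
  print(x$groups, row.names = FALSE)
  cat(sprintf("TOTAL: %d\n\nSequence length histogram:\n", x$total))
  print(x$length_hist)
  cat("\nGC-content histogram (10-point bins, lower edge):\n")
  print(x$gc_hist)
  invisible(x)
}
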