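## Parameter sets: one free-energy weight (kcal/mol) per canonical
## doublet or triplet class.  Stored as a named numeric vector so the
## usual coef() arithmetic works directly.

#' Create a nearest-neighbour parameter set
#'
#' @param values Named numeric vector of free-energy weights (kcal/mol);
#'   names must be exactly the canonical labels of
#'   [enumerate_classes()] for the given order (10 or 32 entries, any
#'   order; they are stored in canonical order).
#' @param order Motif order, 2 or 3.
#' @param provenance Free-text origin of the values.
#' @return A named numeric vector of class `nn_params` with attributes
#'   `order` and `provenance`.
#' @export
nn_params <- function(values, order, provenance = "user") {
  order <- check_order(order)
  classes <- enumerate_classes(order)
  if (is.null(names(values)) || !setequal(names(values), classes) ||
      length(values) != length(classes))
    stop(sprintf("parameter set for order %d must have exactly the %d canonical class labels",
                 order, length(classes)))
  v <- as.numeric(values[classes])
  names(v) <- classes
  structure(v, order = order, provenance = provenance,
            class = "nn_params")
}

#' @export
print.nn_params <- function(x, ...) {
  cat(sprintf("Nearest-neighbour %s parameters (%s), kcal/mol:\n",
              if (attr(x, "order") == 2L) "doublet" else "triplet",
              attr(x, "provenance")))
  print(round(unclass(x), 6))
  invisible(x)
}

#' Bundled reference parameter sets
#'
#' Doublet and triplet free-energy parameters shipped with the package,
#' obtained from a least-squares fit to 340 experimental perfect-match
#' duplex free energies spanning 25--50 degrees C and 0.1--1 M Na+.
#' They are the default ground truth of the synthetic-data generator.
#'
#' @param order Motif order, 2 or 3.
#' @return An [nn_params()] object.
#' @export
duplexnn_params <- function(order = 3) {
  order <- check_order(order)
  file <- system.file("extdata",
                      sprintf("reference_params_order%d.tsv", order),
                      package = "duplexnn", mustWork = TRUE)
  read_nn_params(file, provenance = "bundled reference fit")
}

#' Read a parameter set from a two-column table
#'
#' The format is tab- or whitespace-separated with two columns: the
#' canonical class label and its weight in kcal/mol.  Lines starting
#' with `#` are comments.  The loader validates completeness (all 10 or
#' 32 classes present exactly once).
#'
#' @param path Input file.
#' @param provenance Provenance string recorded on the result.
#' @return An [nn_params()] object.
#' @export
read_nn_params <- function(path, provenance = basename(path)) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("class", "dg"),
                           colClasses = c("character", "numeric"))
  if (anyDuplicated(tab$class))
    stop("duplicate class label in ", path)
  order <- unique(nchar(sub("/.*", "", tab$class)))
  if (length(order) != 1L)
    stop("mixed motif orders in ", path)
  v <- tab$dg
  names(v) <- tab$class
  nn_params(v, order, provenance = provenance)
}

#' Write a parameter set as a two-column table
#'
#' @param params An [nn_params()] object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_nn_params <- function(params, path) {
  stopifnot(inherits(params, "nn_params"))
  lines <- c(sprintf("# nearest-neighbour parameters, order %d (%s)",
                     attr(params, "order"), attr(params, "provenance")),
             sprintf("%s\t%.6f", names(params), as.numeric(params)))
  writeLines(lines, path)
  invisible(path)
}
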