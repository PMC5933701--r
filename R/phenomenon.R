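# Nodes of an evidence map: a phenomenon is identified by three free-text
# properties (What / Where / When). Identity is determined by the
# whitespace-normalized, case-folded triple; original casing is kept for
# display only.

#' Create a phenomenon (an evidence-map node)
#'
#' A phenomenon is any biological entity whose level or probability can be
#' manipulated or measured: a gene, protein, cell population, behaviour, and
#' so on. Three complementary text properties identify it: `what` (the name
#' it is known by), `where` (its location: organ, cell type, species, ...),
#' and `when` (temporal context: age, phase, task epoch, ...). `where` and
#' `when` may be empty but still take part in identity, so the same protein
#' measured in two locations yields two distinct nodes.
#'
#' Two phenomena are the same node exactly when their trimmed,
#' whitespace-collapsed, case-folded `(what, where, when)` triples are equal.
#' None of the fields is constrained by an ontology.
#'
#' @param what Free-text entity identifier; must be non-empty after
#'   whitespace normalization.
#' @param where Free-text location; may be empty (the default).
#' @param when Free-text temporal context; may be empty (the default).
#' @return An object of class `phenomenon`.
#' @examples
#' creb <- phenomenon("CREB", "lateral amygdala")
#' arc  <- phenomenon("number of Arc neurons", "lateral amygdala")
#' identical(node_key(creb), node_key(phenomenon("  creb ", "Lateral  Amygdala")))
#' @export
phenomenon <- function(what, where = "", when = "") {
  what <- as_field(what)
  where <- as_field(where)
  when <- as_field(when)
  if (!nzchar(normalize_field(what))) {
    stop("`what` must be non-empty after whitespace normalization", call. = FALSE)
  }
  structure(list(what = what, where = where, when = when), class = "phenomenon")
}

as_field <- function(x) {
  if (is.null(x) || length(x) == 0) return("")
  x <- as.character(x)[1]
  if (is.na(x)) "" else x
}

#' Normalize a What/Where/When field for comparison
#'
#' Trims surrounding whitespace, collapses internal whitespace runs to a
#' single space, and case-folds. Used for node identity and for term search.
#'
#' @param x Character vector.
#' @return Normalized character vector.
#' @export
normalize_field <- function(x) {
  tolower(gsub("\\s+", " ", trimws(as.character(x))))
}

# Field separator for composite node keys; never occurs in normalized text.
KEY_SEP <- "\u001f"

#' Node key of a phenomenon
#'
#' Computes the canonical identity key of a node. In `"full"` mode the key is
#' the normalized `(what, where, when)` triple; in `"what_only"` mode nodes
#' sharing a normalized What collapse onto one key regardless of Where/When
#' (useful to shrink large merged maps).
#'
#' @param p A [phenomenon()], or an object with `what`/`where`/`when` fields.
#' @param mode `"full"` or `"what_only"`.
#' @return A single string.
#' @export
node_key <- function(p, mode = c("full", "what_only")) {
  mode <- match.arg(mode)
  if (mode == "what_only") {
    normalize_field(p$what)
  } else {
    paste(normalize_field(p$what), normalize_field(p$where),
          normalize_field(p$when), sep = KEY_SEP)
  }
}

#' Test whether two phenomena denote the same node
#'
#' @param a,b Phenomena.
#' @return Logical scalar.
#' @export
same_phenomenon <- function(a, b) identical(node_key(a), node_key(b))

#' @export
format.phenomenon <- function(x, ...) {
  parts <- c(x$what, x$where, x$when)
  paste(parts[nzchar(parts)], collapse = " | ")
}

#' @export
print.phenomenon <- function(x, ...) {
  cat("<phenomenon> ", format(x), "\n", sep = "")
  invisible(x)
}

is_phenomenon <- function(x) inherits(x, "phenomenon")

as_phenomenon <- function(x, where = "") {
  if (is_phenomenon(x)) return(x)
  if (is.list(x) && !is.null(x$what)) {
    return(phenomenon(x$what, as_field(x$where), as_field(x$when)))
  }
  if (is.character(x) && length(x) == 1) return(phenomenon(x))
  stop("cannot interpret object as a phenomenon", call. = FALSE)
}
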