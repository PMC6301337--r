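# Document trees -------------------------------------------------------------
#
# The universal internal record form. Conventions (chosen so that jsonlite
# round-trips them exactly):
#   * object : a *named* list (names attribute present, possibly character(0));
#              member names unique, insertion-ordered
#   * array  : an *unnamed* list
#   * scalar : length-1 character / numeric / integer / logical
#   * null   : NULL
# Trees are plain values; all operations are copy-on-write.

#' Construct a document-tree object node
#'
#' @param ... named members, each itself a document tree.
#' @return an ordered object node (named list).
#' @export
#' @examples
#' tree_object(a = "1", b = tree_array("x", "y"))
tree_object <- function(...) {
  x <- list(...)
  nm <- names(x)
  if (length(x) == 0L) nm <- character(0)
  if (is.null(nm) || any(nm == "")) {
    stop_parse("all members of a tree object must be named")
  }
  if (anyDuplicated(nm)) {
    stop_parse("duplicate member name in tree object: ",
               nm[duplicated(nm)][1L])
  }
  names(x) <- nm
  x
}

#' Construct a document-tree array node
#'
#' @param ... elements (document trees), in order.
#' @return an array node (unnamed list).
#' @export
tree_array <- function(...) {
  x <- list(...)
  names(x) <- NULL
  x
}

#' Test document-tree node kinds
#'
#' An object is a named list (names present even when empty), an array an
#' unnamed list, a scalar a length-1 atomic vector; `NULL` represents null.
#'
#' @param x a document tree node.
#' @return logical scalar.
#' @export
is_tree_object <- function(x) is.list(x) && !is.null(names(x))

#' @rdname is_tree_object
#' @export
is_tree_array <- function(x) is.list(x) && is.null(names(x))

#' @rdname is_tree_object
#' @export
is_tree_scalar <- function(x) is.atomic(x) && length(x) == 1L && !is.null(x)

# normalize a structure parsed by jsonlite into tree conventions
normalize_tree <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.list(x)) {
    nm <- names(x)
    out <- lapply(x, normalize_tree)
    if (is.null(nm)) names(out) <- NULL else {
      if (anyDuplicated(nm)) {
        stop_parse("duplicate member name in JSON object: ",
                   nm[duplicated(nm)][1L])
      }
      names(out) <- nm
    }
    return(out)
  }
  if (length(x) != 1L) {
    # atomic vector from a caller; treat as array of scalars
    return(lapply(unname(x), identity))
  }
  x
}

#' Parse JSON text (or a file) into a document tree
#'
#' @param x JSON text, or a path to a JSON file.
#' @return a document tree.
#' @export
json_to_tree <- function(x) {
  if (length(x) == 1L && !grepl("[{\\[\"]", x) && file.exists(x)) {
    x <- paste(readLines(x, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  } else if (length(x) > 1L) {
    x <- paste(x, collapse = "\n")
  }
  parsed <- tryCatch(
    jsonlite::parse_json(x, simplifyVector = FALSE),
    error = function(e) stop_parse("invalid JSON: ", conditionMessage(e))
  )
  normalize_tree(parsed)
}

# mark scalars for jsonlite so arrays of length 1 stay arrays
box_tree <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.list(x)) {
    out <- lapply(x, box_tree)
    names(out) <- names(x)
    return(out)
  }
  jsonlite::unbox(x)
}

#' Serialize a document tree to JSON text
#'
#' @param tree a document tree.
#' @param pretty pretty-print?
#' @return a JSON string.
#' @export
tree_to_json <- function(tree, pretty = FALSE) {
  as.character(jsonlite::toJSON(box_tree(tree), auto_unbox = FALSE,
                                null = "null", na = "null", digits = NA,
                                pretty = pretty))
}

# XML conversion -------------------------------------------------------------

#' Convert an XML document to a document tree
#'
#' Mapping conventions: an element becomes an object with one `@`-prefixed
#' string member per attribute, one member per child-element name (repeated
#' names collapse into an array, in document order) and a `_$` member holding
#' the element's own concatenated, trimmed text content when non-empty.
#' Namespace prefixes are kept verbatim in member names (e.g. `PDBx:date`).
#' CDATA is treated as text; comments and processing instructions are dropped.
#'
#' @param x XML text, raw bytes, a path, or an `xml2` document/node.
#' @return a document tree (object node for the root element).
#' @export
#' @examples
#' xml_to_tree('<rev num="1"><date>1999-01-08</date></rev>')
xml_to_tree <- function(x) {
  node <- x
  if (!inherits(node, "xml_node")) {
    node <- tryCatch(
      xml2::read_xml(x, options = c("NOBLANKS", "NOCDATA")),
      error = function(e) stop_parse("malformed XML: ", conditionMessage(e))
    )
  }
  ns <- tryCatch(xml2::xml_ns(node), error = function(e) NULL)
  element_to_tree(node, ns)
}

element_to_tree <- function(node, ns) {
  obj <- tree_object()

  ats <- if (is.null(ns)) xml2::xml_attrs(node) else xml2::xml_attrs(node, ns = ns)
  if (length(ats)) {
    keep <- !grepl("^xmlns(:|$)", names(ats))
    for (nm in names(ats)[keep]) {
      obj[[paste0("@", nm)]] <- unname(ats[[nm]])
    }
  }

  texts <- character(0)
  kids <- xml2::xml_contents(node)
  for (k in seq_along(kids)) {
    kid <- kids[[k]]
    tp <- xml2::xml_type(kid)
    if (tp == "element") {
      nm <- if (is.null(ns)) xml2::xml_name(kid) else xml2::xml_name(kid, ns = ns)
      val <- element_to_tree(kid, ns)
      if (is.null(obj[[nm]])) {
        obj[[nm]] <- val
      } else if (is_tree_array(obj[[nm]]) && isTRUE(attr(obj[[nm]], "xml_rep"))) {
        arr <- obj[[nm]]
        arr[[length(arr) + 1L]] <- val
        attr(arr, "xml_rep") <- TRUE
        obj[[nm]] <- arr
      } else {
        arr <- tree_array(obj[[nm]], val)
        attr(arr, "xml_rep") <- TRUE
        obj[[nm]] <- arr
      }
    } else if (tp %in% c("text", "cdata")) {
      tx <- trimws(xml2::xml_text(kid))
      if (nzchar(tx)) texts <- c(texts, tx)
    }
  }
  if (length(texts)) obj[["_$"]] <- paste(texts, collapse = " ")
  strip_rep_marks(obj)
}

strip_rep_marks <- function(x) {
  if (is.list(x)) {
    attr(x, "xml_rep") <- NULL
    x[] <- lapply(x, strip_rep_marks)
  }
  x
}

# CSV conversion -------------------------------------------------------------

#' Convert one CSV row to a flat document tree
#'
#' @param header character vector of column names.
#' @param row character vector of cell values, same length as `header`.
#' @return a flat object; empty cells become empty strings.
#' @export
csv_row_to_tree <- function(header, row) {
  if (length(header) != length(row)) {
    stop_record("CSV row has ", length(row), " cells but header has ",
                length(header))
  }
  row <- as.character(row)
  row[is.na(row)] <- ""
  obj <- as.list(row)
  names(obj) <- as.character(header)
  if (anyDuplicated(names(obj))) {
    stop_record("duplicate CSV column name: ",
                names(obj)[duplicated(names(obj))][1L])
  }
  obj
}

# Canonical form and checksums ----------------------------------------------

# deterministic serialization: object members sorted by name, arrays in order,
# scalars type-tagged. Used for hashing and order-insensitive equality.
tree_canonical <- function(x) {
  if (is.null(x)) return("z")
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm)) {
      o <- order(nm, method = "radix")
      parts <- vapply(o, function(i) {
        paste0(encode_str(nm[i]), ":", tree_canonical(x[[i]]))
      }, character(1))
      return(paste0("{", paste(parts, collapse = ","), "}"))
    }
    parts <- vapply(x, tree_canonical, character(1))
    return(paste0("[", paste(parts, collapse = ","), "]"))
  }
  if (is.character(x)) return(paste0("s", encode_str(x)))
  if (is.logical(x)) return(paste0("b", if (isTRUE(x)) "1" else "0"))
  paste0("n", format(unclass(x), digits = 15, scientific = FALSE, trim = TRUE))
}

encode_str <- function(s) {
  s <- gsub("\\", "\\\\", s, fixed = TRUE)
  s <- gsub('"', '\\"', s, fixed = TRUE)
  paste0('"', s, '"')
}

#' Content checksum of a document tree
#'
#' SHA-256 of the canonical serialization (object members sorted by name,
#' arrays in order, scalars typed), so equal trees modulo member order hash
#' identically across runs and platforms. Used for duplicate detection.
#'
#' @param tree a document tree.
#' @return lowercase hex string.
#' @export
tree_checksum <- function(tree) {
  digest::digest(tree_canonical(tree), algo = "sha256", serialize = FALSE)
}

#' Compare two document trees modulo object member order
#'
#' @param a,b document trees.
#' @return logical scalar.
#' @export
tree_equal <- function(a, b) {
  identical(tree_canonical(a), tree_canonical(b))
}

# Error conditions ------------------------------------------------------------

crucible_stop <- function(class, ...) {
  stop(structure(class = c(class, "crucible_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_parse <- function(...) crucible_stop("crucible_parse_error", ...)
stop_record <- function(...) crucible_stop("crucible_record_error", ...)
stop_transform <- function(...) crucible_stop("crucible_transform_error", ...)
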