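#' Construct an information table
#'
#' An information table is the basic decision-table container: a universe of
#' objects described by nonnegative numeric condition attributes, plus a
#' binary decision attribute whose positive class defines the target concept
#' \eqn{X \subseteq U}.
#'
#' @param values numeric matrix or data frame of condition-attribute values,
#'   rows = objects, columns = attributes.  All entries must be finite and
#'   nonnegative.  Row names (or `object_ids`) identify the objects.
#' @param decision logical vector (one element per object): `TRUE` for
#'   members of the target concept.
#' @param object_ids optional character vector of unique object labels;
#'   defaults to the row names of `values`, or `o1, o2, ...`.
#' @param decision_attr name of the decision attribute (for reporting).
#' @param positive_label the label of the positive decision class (for
#'   reporting); defaults to `"1"`.
#'
#' @return An object of class `"information_table"`: a list with elements
#'   `values` (numeric matrix with object ids as row names), `object_ids`,
#'   `condition_attrs`, `decision` (named logical), `decision_attr`,
#'   `positive_label`, and `concept` (character vector of positive-class
#'   object ids).
#'
#' @examples
#' tab <- information_table(
#'   values   = matrix(c(8, 45, 80, 20, 3, 100), nrow = 2, byrow = TRUE,
#'                     dimnames = list(c("c1", "c2"), c("a", "b", "c"))),
#'   decision = c(TRUE, FALSE))
#' tab$concept
#' @export
information_table <- function(values, decision, object_ids = NULL,
                              decision_attr = "d", positive_label = "1") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(object_ids)) {
    object_ids <- rownames(values)
    if (is.null(object_ids)) object_ids <- paste0("o", seq_len(nrow(values)))
  }
  object_ids <- as.character(object_ids)
  if (nrow(values) < 1L)
    stop("an information table needs at least one object", call. = FALSE)
  if (anyDuplicated(object_ids))
    stop("duplicate object ids: ",
         paste(unique(object_ids[duplicated(object_ids)]), collapse = ", "),
         call. = FALSE)
  if (length(object_ids) != nrow(values))
    stop("object_ids and values disagree on the number of objects", call. = FALSE)
  if (any(!is.finite(values)))
    stop("all condition values must be finite", call. = FALSE)
  if (any(values < 0))
    stop("condition values must be nonnegative; shift or re-encode negative ",
         "attributes before building the table", call. = FALSE)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("a", seq_len(ncol(values)))
  decision <- as.logical(decision)
  if (length(decision) != nrow(values) || anyNA(decision))
    stop("decision must be a complete logical vector, one value per object",
         call. = FALSE)
  rownames(values) <- object_ids
  names(decision) <- object_ids
  structure(
    list(values = values,
         object_ids = object_ids,
         condition_attrs = colnames(values),
         decision = decision,
         decision_attr = decision_attr,
         positive_label = positive_label,
         concept = object_ids[decision]),
    class = "information_table")
}

#' Read a decision table from CSV
#'
#' Reads a delimited text file (header row required) into an
#' [information_table()].  One column holds the object ids, one the binary
#' decision; the remaining columns are condition attributes.  Non-numeric
#' condition columns are rejected unless an encoding policy is supplied, in
#' which case they are passed through [encode_categoricals()] first.
#'
#' @param path path to a CSV file.
#' @param id_col name of the object-id column; `NULL` means rows are labelled
#'   `o1, o2, ...` in file order.
#' @param decision_col name of the decision column (required).
#' @param positive_label value in `decision_col` marking membership of the
#'   target concept.
#' @param encoding `NULL` (condition columns must already be numeric) or an
#'   encoding policy as accepted by [encode_categoricals()].
#' @param ... further arguments passed to [utils::read.csv()].
#'
#' @return An [information_table()]; row order of the file is preserved and
#'   is the canonical object order for all downstream reports.
#' @export
read_information_table <- function(path, decision_col, id_col = NULL,
                                   positive_label = "1", encoding = NULL, ...) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE, ...)
  if (!decision_col %in% names(df))
    stop("decision column '", decision_col, "' not present in ", path,
         call. = FALSE)
  if (!is.null(id_col)) {
    if (!id_col %in% names(df))
      stop("id column '", id_col, "' not present in ", path, call. = FALSE)
    ids <- as.character(df[[id_col]])
    df[[id_col]] <- NULL
  } else {
    ids <- paste0("o", seq_len(nrow(df)))
  }
  decision_raw <- as.character(df[[decision_col]])
  df[[decision_col]] <- NULL
  if (!as.character(positive_label) %in% decision_raw)
    warning("positive label '", positive_label,
            "' does not occur in the decision column")
  is_num <- vapply(df, is.numeric, logical(1))
  if (any(!is_num)) {
    if (is.null(encoding))
      stop("non-numeric condition column(s) ",
           paste(names(df)[!is_num], collapse = ", "),
           " need an encoding policy", call. = FALSE)
    df <- encode_categoricals(df, policy = encoding)$data
  }
  information_table(as.matrix(df),
                    decision = decision_raw == as.character(positive_label),
                    object_ids = ids,
                    decision_attr = decision_col,
                    positive_label = as.character(positive_label))
}

#' Encode categorical condition attributes numerically
#'
#' Similarity granulation needs nonnegative numeric attributes, so
#' categorical columns have to be encoded before a table can be granulated.
#' Two policies are supported: `"ordinal"` maps the categories of a column
#' to 0, 1, 2, ... (in the order given by an explicit level vector, or
#' alphabetically), and `"onehot"` expands a k-category column to k binary
#' indicator columns.
#'
#' @param data a data frame; numeric columns are passed through untouched.
#' @param policy either a single string (`"ordinal"` or `"onehot"`) applied
#'   to every non-numeric column, or a named list mapping column names to
#'   `"ordinal"`, `"onehot"`, or a named numeric vector giving an explicit
#'   category -> value map.
#'
#' @return A list with `data` (all-numeric data frame) and `map` (per-column
#'   record of the encoding applied, for reporting).
#' @examples
#' enc <- encode_categoricals(
#'   data.frame(x = c("yes", "no", "yes"), y = 1:3),
#'   policy = list(x = c(no = 0, yes = 1)))
#' enc$data$x
#' @export
encode_categoricals <- function(data, policy = "ordinal") {
  stopifnot(is.data.frame(data))
  map <- list()
  global <- if (is.character(policy) && length(policy) == 1L) policy else NULL
  out <- data
  for (nm in names(data)) {
    col <- data[[nm]]
    if (is.numeric(col)) next
    col <- as.character(col)
    pol <- if (!is.null(global)) global else policy[[nm]]
    if (is.null(pol))
      stop("no encoding policy for categorical column '", nm, "'",
           call. = FALSE)
    if (is.numeric(pol)) {            # explicit category -> value map
      unseen <- setdiff(unique(col), names(pol))
      if (length(unseen))
        stop("unseen categor", if (length(unseen) > 1) "ies" else "y",
             " in column '", nm, "': ", paste(unseen, collapse = ", "),
             call. = FALSE)
      out[[nm]] <- unname(pol[col])
      map[[nm]] <- list(policy = "explicit", levels = pol)
    } else if (identical(pol, "ordinal")) {
      lev <- sort(unique(col))
      out[[nm]] <- match(col, lev) - 1
      map[[nm]] <- list(policy = "ordinal",
                        levels = stats::setNames(seq_along(lev) - 1, lev))
    } else if (identical(pol, "onehot")) {
      lev <- sort(unique(col))
      ind <- as.data.frame(vapply(lev, function(l) as.numeric(col == l),
                                  numeric(length(col))))
      names(ind) <- paste(nm, lev, sep = "_")
      pos <- match(nm, names(out))
      parts <- list(out[seq_len(pos - 1L)], ind,
                    if (pos < ncol(out)) out[(pos + 1L):ncol(out)])
      out <- do.call(cbind, Filter(function(d) !is.null(d) && ncol(d) > 0,
                                   parts))
      map[[nm]] <- list(policy = "onehot", levels = lev)
    } else {
      stop("unknown encoding policy '", pol, "' for column '", nm, "'",
           call. = FALSE)
    }
  }
  list(data = out, map = map)
}

#' Max-normalize an information table
#'
#' Divides every condition-attribute column by its maximum, mapping all
#' values into \[0, 1\] while preserving ratios within a column:
#' \deqn{N(c)(a) = f(c)(a) / \max_{y \in U} f(y)(a).}
#' A column whose maximum is zero is necessarily all-zero (values are
#' nonnegative) and is left at zero with a warning, since a constant column
#' carries no similarity information.
#'
#' @param table an [information_table()].
#' @return The table with class `c("normalized_table", "information_table")`
#'   and an additional element `column_maxima` recording the original column
#'   maxima, so `values * column_maxima` recovers the input.
#' @examples
#' tab <- information_table(matrix(c(8, 45, 40, 9), 2,
#'                                 dimnames = list(c("c1", "c3"), c("a", "b"))),
#'                          decision = c(TRUE, TRUE))
#' max_normalize(tab)$values
#' @export
max_normalize <- function(table) {
  stopifnot(inherits(table, "information_table"))
  if (inherits(table, "normalized_table")) return(table)
  v <- table$values
  cmax <- apply(v, 2, max)
  zero <- cmax == 0
  if (any(zero)) {
    warning("constant zero column(s) ",
            paste(names(cmax)[zero], collapse = ", "),
            " normalized to 0 (similarity-inert)")
  }
  scale <- ifelse(zero, 1, cmax)   # avoid 0/0; zero columns stay zero
  table$values <- sweep(v, 2, scale, "/")
  table$column_maxima <- cmax
  class(table) <- c("normalized_table", class(table))
  table
}

#' @export
print.information_table <- function(x, ...) {
  cat(if (inherits(x, "normalized_table")) "Max-normalized information table"
      else "Information table",
      sprintf("(%d objects, %d condition attributes)\n",
              length(x$object_ids), length(x$condition_attrs)))
  cat("Concept X (", x$decision_attr, " = ", x$positive_label, "): ",
      length(x$concept), " of ", length(x$object_ids), " objects\n", sep = "")
  print(utils::head(cbind(as.data.frame(x$values),
                          stats::setNames(data.frame(x$decision),
                                          x$decision_attr)), 10))
  if (length(x$object_ids) > 10) cat("...\n")
  invisible(x)
}

#' @export
as.data.frame.information_table <- function(x, ...) {
  df <- as.data.frame(x$values)
  df[[x$decision_attr]] <- as.integer(x$decision)
  df
}

#' Write an information table back to CSV
#'
#' @param table an [information_table()].
#' @param path output file path.
#' @param id_col name for the object-id column in the output.
#' @return `path`, invisibly.
#' @export
write_information_table <- function(table, path, id_col = "id") {
  df <- as.data.frame(table)
  df <- cbind(stats::setNames(data.frame(table$object_ids,
                                         stringsAsFactors = FALSE), id_col),
              df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
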