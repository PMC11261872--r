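#' Partition a universe into equivalence classes
#'
#' Groups objects that carry identical values on every attribute of `attrs`
#' — the indiscernibility partition \eqn{U/E_A} of classical rough set
#' theory.  Blocks are ordered by their first-occurring object, so the
#' result is deterministic given row order.
#'
#' @param table an [information_table()].
#' @param attrs nonempty character vector of condition attributes to use.
#' @return An object of class `"equivalence_partition"`: a list with
#'   `blocks` (list of character vectors of object ids), `block_of`
#'   (named integer vector mapping each object to its block index) and
#'   `attrs_used`.
#' @examples
#' tab <- information_table(matrix(c(1, 1, 2, 0, 0, 5), 3,
#'                                 dimnames = list(NULL, c("a", "b"))),
#'                          decision = c(TRUE, FALSE, FALSE))
#' equivalence_partition(tab, "a")$blocks
#' @export
equivalence_partition <- function(table, attrs) {
  stopifnot(inherits(table, "information_table"))
  if (length(attrs) == 0L)
    stop("attrs must be a nonempty attribute subset", call. = FALSE)
  bad <- setdiff(attrs, table$condition_attrs)
  if (length(bad))
    stop("unknown attribute(s): ", paste(bad, collapse = ", "), call. = FALSE)
  v <- table$values[, attrs, drop = FALSE]
  key <- apply(v, 1, paste, collapse = "\r")
  first <- !duplicated(key)
  block_of <- match(key, key[first])
  names(block_of) <- table$object_ids
  blocks <- split(table$object_ids, block_of)
  names(blocks) <- NULL
  structure(list(blocks = blocks, block_of = block_of, attrs_used = attrs),
            class = "equivalence_partition")
}

#' Bray-Curtis-style pairwise similarity
#'
#' Similarity between two nonnegative attribute vectors:
#' \deqn{S(x, y) = 1 - \frac{\sum_l |x_l - y_l|}{\sum_l (x_l + y_l)},}
#' a ratio of sums (the complement of the Bray-Curtis dissimilarity).
#' Reflexive (\eqn{S(x,x)=1}), symmetric, and equal to 1 exactly when the
#' vectors are identical.  Two all-zero vectors are identical, so their
#' similarity is 1 (the 0/0 limit is resolved that way).
#'
#' @param x,y numeric vectors of equal length with nonnegative entries,
#'   typically rows of a [max_normalize()]d table.
#' @return A similarity score in \[0, 1\].
#' @examples
#' pairwise_similarity(c(0.16, 1, 0.8), c(0.4, 3 / 45, 1))  # 0.59922179
#' @export
pairwise_similarity <- function(x, y) {
  if (length(x) != length(y))
    stop("attribute vectors differ in length", call. = FALSE)
  if (any(x < 0) || any(y < 0))
    stop("similarity is defined for nonnegative values only", call. = FALSE)
  denom <- sum(x + y)
  if (denom == 0) return(1)
  1 - sum(abs(x - y)) / denom
}

#' Full pairwise similarity matrix
#'
#' Applies [pairwise_similarity()] to every unordered pair of objects of a
#' normalized table.  The diagonal is set to exactly 1.
#'
#' @param table a [max_normalize()]d table (a raw [information_table()] is
#'   normalized on the fly with a message-free pass-through).
#' @return A symmetric numeric matrix of class `"similarity_matrix"` with
#'   object ids as dimnames.
#' @export
similarity_matrix <- function(table) {
  stopifnot(inherits(table, "information_table"))
  table <- max_normalize(table)
  v <- table$values
  n <- nrow(v)
  s <- diag(1, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        s[i, j] <- s[j, i] <- pairwise_similarity(v[i, ], v[j, ])
      }
    }
  }
  dimnames(s) <- list(table$object_ids, table$object_ids)
  class(s) <- c("similarity_matrix", class(s))
  s
}

#' xi-thresholded similarity classes (a tolerance covering)
#'
#' The similarity class of an object c at threshold xi collects every
#' object at least xi-similar to it:
#' \eqn{S_\xi(c) = \{y \in U : S(c, y) \ge \xi\}} (boundary-inclusive).
#' Reflexivity guarantees \eqn{c \in S_\xi(c)}, so the classes cover U;
#' they generally overlap, so this is a covering, not a partition.
#' At xi = 1 the classes coincide with the equivalence partition on all
#' condition attributes (similarity 1 means identical rows).
#'
#' @param matrix a [similarity_matrix()].
#' @param xi threshold in (0, 1].
#' @return A `"similarity_covering"`: list with `xi`, `class_of` (named
#'   list: object id -> character vector of class members, in universe
#'   order) and `member_index` (named list: object id -> ids of the class
#'   owners whose class contains it).
#' @examples
#' tab <- information_table(matrix(c(0, 1, 1, 0), 2), c(TRUE, FALSE))
#' sim <- similarity_matrix(max_normalize(tab))
#' similarity_classes(sim, 0.5)$class_of
#' @export
similarity_classes <- function(matrix, xi) {
  if (!is.numeric(xi) || length(xi) != 1L || xi <= 0 || xi > 1)
    stop("xi must be a single threshold in (0, 1]", call. = FALSE)
  ids <- rownames(matrix)
  class_of <- lapply(seq_along(ids),
                     function(i) ids[matrix[i, ] >= xi])
  names(class_of) <- ids
  similarity_covering(class_of, xi = xi)
}

#' Build a similarity covering from an explicit class list
#'
#' Low-level constructor used by [similarity_classes()] and by tests that
#' need arbitrary (not necessarily similarity-derived) coverings.  Each
#' object owns one candidate class; the covering property requires every
#' object to appear in at least one class.
#'
#' @param class_of named list mapping each object id to the character
#'   vector of members of its class.
#' @param xi the threshold the covering was built at (informational).
#' @return A `"similarity_covering"` object; see [similarity_classes()].
#' @export
similarity_covering <- function(class_of, xi = NA_real_) {
  ids <- names(class_of)
  if (is.null(ids)) stop("class_of must be a named list", call. = FALSE)
  member_index <- lapply(ids, function(c) {
    ids[vapply(class_of, function(s) c %in% s, logical(1))]
  })
  names(member_index) <- ids
  uncovered <- ids[lengths(member_index) == 0L]
  if (length(uncovered))
    stop("not a covering: object(s) ", paste(uncovered, collapse = ", "),
         " belong to no class", call. = FALSE)
  structure(list(xi = xi, class_of = class_of, member_index = member_index),
            class = "similarity_covering")
}

#' @export
print.similarity_covering <- function(x, ...) {
  cat(sprintf("Similarity covering at xi = %s over %d objects\n",
              format(x$xi), length(x$class_of)))
  for (id in utils::head(names(x$class_of), 10)) {
    cat("  S(", id, ") = {", paste(x$class_of[[id]], collapse = ", "),
        "}\n", sep = "")
  }
  if (length(x$class_of) > 10) cat("  ...\n")
  invisible(x)
}

#' Export a similarity matrix as CSV
#'
#' @param matrix a [similarity_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_similarity_matrix <- function(matrix, path) {
  utils::write.csv(as.data.frame(unclass(matrix)), path, quote = FALSE)
  invisible(path)
}
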