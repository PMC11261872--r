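#' Classical conditional probability of a concept given a granule
#'
#' The rough membership of a granule (equivalence block or similarity
#' class) in a concept X: \eqn{\Pr(X \mid B) = |X \cap B| / |B|}.
#'
#' @param X character vector of concept members.
#' @param block nonempty character vector, the granule.
#' @return The fraction of `block` lying in `X`, in \[0, 1\].
#' @examples
#' conditional_probability(c("c1", "c2"), c("c1", "c2", "c3", "c4"))  # 0.5
#' @export
conditional_probability <- function(X, block) {
  if (length(block) == 0L)
    stop("conditional probability of an empty granule is undefined",
         call. = FALSE)
  sum(block %in% X) / length(block)
}

#' Covering-based (generalized) rough membership
#'
#' With a similarity covering the granules containing an object overlap, so
#' the single rough-membership ratio of the partition case generalizes to a
#' family of per-class ratios \eqn{|S \cap X| / |S|}, one for every class
#' \eqn{S} of the covering that contains the object.  Classes are
#' enumerated per owner: object y contributes its class \eqn{S_\xi(y)}
#' whenever \eqn{c \in S_\xi(y)}, and owners with set-equal classes each
#' contribute a term.  The three aggregations are the pessimistic minimum,
#' the optimistic maximum, and the average — the average is the engine
#' default, being the most stable of the three.  When the covering is a
#' partition, all three reduce to [conditional_probability()] of the
#' object's block.
#'
#' @param X character vector of concept members (may be a subset of a
#'   shrinking sub-universe; class denominators always use the full class).
#' @param covering a [similarity_covering()].
#' @param object a single object id in the covering's universe.
#' @param mode `"average"` (default), `"minimum"`, or `"maximum"`.
#' @return A membership probability in \[0, 1\].
#' @examples
#' cov <- similarity_covering(list(c1 = c("c1", "c2"), c2 = c("c1", "c2"),
#'                                 c3 = c("c3", "c4", "c5"),
#'                                 c4 = c("c3", "c4"), c5 = c("c3", "c5")))
#' generalized_membership(c("c1", "c3", "c5"), cov, "c3")  # 13/18
#' @export
generalized_membership <- function(X, covering, object,
                                   mode = c("average", "minimum", "maximum")) {
  mode <- match.arg(mode)
  owners <- covering$member_index[[object]]
  if (is.null(owners))
    stop("object '", object, "' is not in the covering's universe",
         call. = FALSE)
  ratios <- vapply(covering$class_of[owners],
                   function(s) sum(s %in% X) / length(s), numeric(1))
  switch(mode,
         average = mean(ratios),
         minimum = min(ratios),
         maximum = max(ratios))
}
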