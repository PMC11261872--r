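#' Construct a 3x2 decision loss matrix
#'
#' Costs of the three actions (accept into POS, defer to BND, reject into
#' NEG) in the two states (object in X, object not in X).  The usual
#' rationality constraints are enforced: accepting a true member costs no
#' more than deferring it, which costs less than rejecting it
#' (\eqn{\lambda_{PP} \le \lambda_{BP} < \lambda_{NP}}), and symmetrically
#' for non-members (\eqn{\lambda_{NN} \le \lambda_{BN} < \lambda_{PN}}).
#' The strict inequalities keep the induced thresholds well defined.
#'
#' @param lam_PP,lam_BP,lam_NP costs of accept/defer/reject when the object
#'   is in X.
#' @param lam_PN,lam_BN,lam_NN costs of accept/defer/reject when the object
#'   is not in X.
#' @return A named numeric vector of class `"loss_matrix"`.
#' @examples
#' loss_matrix(0, 1, 4, 4, 1, 0)   # induces (alpha, beta) = (0.75, 0.25)
#' @export
loss_matrix <- function(lam_PP, lam_BP, lam_NP, lam_PN, lam_BN, lam_NN) {
  lam <- c(PP = lam_PP, BP = lam_BP, NP = lam_NP,
           PN = lam_PN, BN = lam_BN, NN = lam_NN)
  if (any(lam < 0)) stop("losses must be nonnegative", call. = FALSE)
  if (!(lam["PP"] <= lam["BP"] && lam["BP"] < lam["NP"]))
    stop("need lam_PP <= lam_BP < lam_NP", call. = FALSE)
  if (!(lam["NN"] <= lam["BN"] && lam["BN"] < lam["PN"]))
    stop("need lam_NN <= lam_BN < lam_PN", call. = FALSE)
  structure(lam, class = "loss_matrix")
}

#' Construct an (alpha, beta) threshold pair
#'
#' @param alpha acceptance threshold; membership >= alpha lands in POS.
#' @param beta rejection threshold; membership <= beta lands in NEG.
#'   Requires `0 <= beta < alpha <= 1`.
#' @return A named numeric vector `c(alpha =, beta =)` of class
#'   `"threshold_pair"`.
#' @export
threshold_pair <- function(alpha, beta) {
  alpha <- unname(alpha)
  beta <- unname(beta)
  if (!is.finite(alpha) || !is.finite(beta) ||
      beta < 0 || alpha > 1 || alpha <= beta)
    stop("need 0 <= beta < alpha <= 1 (got alpha = ", alpha,
         ", beta = ", beta, ")", call. = FALSE)
  structure(c(alpha = alpha, beta = beta), class = "threshold_pair")
}

#' Three-way classification by probability thresholds
#'
#' POS if membership >= alpha, NEG if membership <= beta, BND otherwise;
#' both comparisons are boundary-inclusive.
#'
#' @param p numeric vector of membership probabilities in \[0, 1\].
#' @param thresholds a [threshold_pair()].
#' @return Character vector over `{"POS", "BND", "NEG"}`, same length as `p`.
#' @examples
#' classify_by_thresholds(c(0.85, 0.5, 0.1), threshold_pair(0.8, 0.2))
#' @export
classify_by_thresholds <- function(p, thresholds) {
  if (any(p < 0 | p > 1))
    stop("membership probabilities must lie in [0, 1]", call. = FALSE)
  ifelse(p >= thresholds[["alpha"]], "POS",
         ifelse(p <= thresholds[["beta"]], "NEG", "BND"))
}

#' Expected risks of the three actions
#'
#' Bayesian expected cost of each action given membership probability p:
#' \eqn{R(a \mid p) = \lambda_{aP}\,p + \lambda_{aN}\,(1 - p)} for
#' a in {accept, defer, reject}.
#'
#' @param p numeric vector of membership probabilities in \[0, 1\].
#' @param loss a [loss_matrix()].
#' @return A matrix with one row per element of `p` and columns
#'   `P`, `B`, `N`.
#' @export
expected_risks <- function(p, loss) {
  if (any(p < 0 | p > 1))
    stop("membership probabilities must lie in [0, 1]", call. = FALSE)
  cbind(P = loss[["PP"]] * p + loss[["PN"]] * (1 - p),
        B = loss[["BP"]] * p + loss[["BN"]] * (1 - p),
        N = loss[["NP"]] * p + loss[["NN"]] * (1 - p))
}

#' Minimum-risk Bayesian three-way classification
#'
#' Assigns each object to the action of minimum expected risk.  Risk ties
#' are broken in the order accept > defer > reject (P over B over N), which
#' is the unique order consistent with the boundary-inclusive threshold
#' rules (POS uses >= alpha, NEG uses <= beta).
#'
#' @inheritParams expected_risks
#' @return Character vector over `{"POS", "BND", "NEG"}`.
#' @export
bayes_classify <- function(p, loss) {
  r <- expected_risks(p, loss)
  c("POS", "BND", "NEG")[max.col(-r, ties.method = "first")]
}

#' Derive (alpha, beta) thresholds from a loss matrix
#'
#' Solving the pairwise risk inequalities R_P <= R_B and R_N <= R_B for the
#' membership probability gives the closed forms
#' \deqn{\alpha = \frac{\lambda_{PN}-\lambda_{BN}}
#'                     {(\lambda_{PN}-\lambda_{BN})+(\lambda_{BP}-\lambda_{PP})},
#'       \quad
#'       \beta = \frac{\lambda_{BN}-\lambda_{NN}}
#'                    {(\lambda_{BN}-\lambda_{NN})+(\lambda_{NP}-\lambda_{BP})}.}
#' With these thresholds [classify_by_thresholds()] and [bayes_classify()]
#' agree everywhere (a property the test suite checks on a dense
#' probability grid).  Thresholds are invariant to rescaling all six losses
#' by a positive constant.
#'
#' @param loss a [loss_matrix()].
#' @return A [threshold_pair()].
#' @examples
#' thresholds_from_losses(loss_matrix(0, 1, 4, 4, 1, 0))  # alpha 0.75, beta 0.25
#' @export
thresholds_from_losses <- function(loss) {
  da <- loss[["PN"]] - loss[["BN"]]   # > 0 by construction
  db <- loss[["BP"]] - loss[["PP"]]   # >= 0
  dc <- loss[["BN"]] - loss[["NN"]]   # >= 0
  dd <- loss[["NP"]] - loss[["BP"]]   # > 0
  alpha <- da / (da + db)
  beta <- dc / (dc + dd)
  if (alpha <= beta)
    stop("loss matrix induces alpha <= beta (alpha = ", signif(alpha, 4),
         ", beta = ", signif(beta, 4),
         "); the deferred region would be empty or inverted", call. = FALSE)
  threshold_pair(alpha, beta)
}

#' Tri-partition a sub-universe by membership thresholds
#'
#' Applies [classify_by_thresholds()] object-by-object, returning the three
#' disjoint regions whose union is the classified sub-universe.
#'
#' @param membership named numeric vector: object id -> membership
#'   probability; must cover `sub_universe`.
#' @param sub_universe character vector of the objects to classify.
#' @param thresholds a [threshold_pair()].
#' @return A `"tri_regions"` list with `pos`, `bnd`, `neg` (character
#'   vectors in `sub_universe` order), `membership`, and `thresholds`.
#' @export
tri_partition <- function(membership, sub_universe, thresholds) {
  missing <- setdiff(sub_universe, names(membership))
  if (length(missing))
    stop("no membership value for object(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  m <- membership[sub_universe]
  tag <- classify_by_thresholds(m, thresholds)
  structure(list(pos = sub_universe[tag == "POS"],
                 bnd = sub_universe[tag == "BND"],
                 neg = sub_universe[tag == "NEG"],
                 membership = m,
                 thresholds = thresholds),
            class = "tri_regions")
}

#' @export
print.tri_regions <- function(x, ...) {
  cat(sprintf("Three-way regions at (alpha, beta) = (%g, %g)\n",
              x$thresholds[["alpha"]], x$thresholds[["beta"]]))
  cat("  POS (", length(x$pos), "): ", paste(x$pos, collapse = ", "), "\n",
      "  BND (", length(x$bnd), "): ", paste(x$bnd, collapse = ", "), "\n",
      "  NEG (", length(x$neg), "): ", paste(x$neg, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}
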