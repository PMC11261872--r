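#' Linear (alpha, beta) threshold schedule
#'
#' Sequential three-way classification relaxes its thresholds level by
#' level: alpha decreases and beta increases by a fixed step, so ever more
#' of the deferred boundary gets classified.  The schedule is truncated
#' before the first level at which alpha would not exceed beta.
#'
#' @param alpha0,beta0 initial thresholds, `0 <= beta0 < alpha0 <= 1`.
#' @param step positive per-level decrement of alpha / increment of beta.
#' @param levels maximum number of levels.
#' @return A matrix with columns `alpha` and `beta`, one row per level;
#'   attribute `"truncated"` is `TRUE` when the requested length was cut
#'   short by the alpha > beta requirement.
#' @examples
#' linear_threshold_schedule(1, 0, 0.0225, 20)[20, ]   # 0.5725 0.4275
#' @export
linear_threshold_schedule <- function(alpha0 = 1, beta0 = 0,
                                      step = 0.0225, levels = 20L) {
  if (alpha0 <= beta0 || beta0 < 0 || alpha0 > 1)
    stop("need 0 <= beta0 < alpha0 <= 1", call. = FALSE)
  if (step <= 0) stop("step must be positive", call. = FALSE)
  i <- seq_len(levels)
  alpha <- alpha0 - (i - 1) * step
  beta <- beta0 + (i - 1) * step
  keep <- alpha > beta
  sched <- cbind(alpha = alpha[keep], beta = beta[keep])
  attr(sched, "truncated") <- any(!keep)
  sched
}

as_threshold_matrix <- function(thresholds) {
  if (is.matrix(thresholds) || is.data.frame(thresholds)) {
    m <- as.matrix(thresholds)
    if (is.null(colnames(m)) && ncol(m) == 2) colnames(m) <- c("alpha", "beta")
  } else if (is.list(thresholds)) {
    m <- do.call(rbind, lapply(thresholds, function(t) c(t[["alpha"]],
                                                         t[["beta"]])))
    colnames(m) <- c("alpha", "beta")
  } else {
    stop("thresholds must be a matrix/data.frame with alpha and beta ",
         "columns or a list of threshold pairs", call. = FALSE)
  }
  apply(m, 1, function(r) threshold_pair(r[["alpha"]], r[["beta"]]))  # validate
  m
}

new_seq3wd <- function(engine, levels, universe, concept, stop_reason,
                       mode = NULL, call = NULL) {
  pos <- unique(unlist(lapply(levels, `[[`, "pos")))
  neg <- unique(unlist(lapply(levels, `[[`, "neg")))
  bnd <- if (length(levels)) levels[[length(levels)]]$bnd else universe
  structure(list(engine = engine,
                 levels = levels,
                 universe = universe,
                 concept = concept,
                 accumulated_pos = universe[universe %in% pos],
                 accumulated_neg = universe[universe %in% neg],
                 terminal_bnd = universe[universe %in% bnd],
                 stop_reason = stop_reason,
                 mode = mode,
                 call = call),
            class = "seq3wd")
}

#' Sequential three-way classification over explicit granulation levels
#'
#' The classical sequential decision-theoretic rough-set procedure: at each
#' level a coarser-to-finer equivalence granulation of the universe and a
#' threshold pair (alpha_i, beta_i) tri-partition the objects still
#' deferred; the boundary region becomes the next level's universe, the
#' concept is restricted to it, and POS/NEG accumulate across levels.
#' Conditional probabilities use each object's full equivalence block as
#' denominator and the current concept X_i as numerator; only objects of
#' the current sub-universe U_i are classified.
#'
#' @param levels a list of level specifications, processed in order.  Each
#'   element is a list with `alpha`, `beta`, and either `attrs` (attribute
#'   subset; requires `x`) or `partition` (explicit list of disjoint object
#'   blocks covering the universe), plus an optional `label`.
#' @param x an [information_table()], required when any level is given by
#'   `attrs`; supplies the universe and default concept.
#' @param concept character vector of concept members X; defaults to
#'   `x$concept`.
#' @param universe character vector of object ids; defaults to
#'   `x$object_ids`, required when `x` is absent.
#' @return A `"seq3wd"` trace object; see [gseq_dtrs()] for its contents.
#' @seealso [gseq_dtrs()] for the similarity-covering generalization that
#'   needs no attribute reduction between levels.
#' @export
seq_dtrs <- function(levels, x = NULL, concept = NULL, universe = NULL) {
  if (length(levels) == 0L) stop("empty level specification", call. = FALSE)
  if (is.null(universe)) {
    if (is.null(x)) stop("need either x or universe", call. = FALSE)
    universe <- x$object_ids
  }
  if (is.null(concept)) {
    if (is.null(x)) stop("need either x or concept", call. = FALSE)
    concept <- x$concept
  }
  if (!all(concept %in% universe))
    stop("concept must be a subset of the universe", call. = FALSE)

  recs <- vector("list", length(levels))
  Ui <- universe
  Xi <- concept
  stop_reason <- "schedule_exhausted"
  nlev <- 0L
  for (i in seq_along(levels)) {
    spec <- levels[[i]]
    thr <- threshold_pair(spec$alpha, spec$beta)
    if (!is.null(spec$partition)) {
      blocks <- lapply(spec$partition, as.character)
      flat <- unlist(blocks)
      if (anyDuplicated(flat) || !setequal(flat, universe))
        stop("level ", i, ": partition must consist of disjoint blocks ",
             "covering the universe", call. = FALSE)
    } else if (!is.null(spec$attrs)) {
      if (is.null(x))
        stop("level ", i, ": attribute-based granulation needs x",
             call. = FALSE)
      blocks <- equivalence_partition(x, spec$attrs)$blocks
    } else {
      stop("level ", i, ": give either attrs or partition", call. = FALSE)
    }
    block_ix <- integer(0)
    for (b in seq_along(blocks)) block_ix[blocks[[b]]] <- b
    memb <- vapply(Ui, function(c) {
      conditional_probability(Xi, blocks[[block_ix[[c]]]])
    }, numeric(1))
    regions <- tri_partition(memb, Ui, thr)
    recs[[i]] <- list(level = i,
                      label = if (!is.null(spec$label)) spec$label else
                        paste0("L", i),
                      universe = Ui, concept = Xi,
                      granulation = if (!is.null(spec$attrs)) spec$attrs else
                        "explicit partition",
                      xi = NA_real_,
                      alpha = thr[["alpha"]], beta = thr[["beta"]],
                      membership = memb,
                      pos = regions$pos, bnd = regions$bnd, neg = regions$neg)
    nlev <- i
    Ui <- regions$bnd
    Xi <- intersect(Xi, Ui)
    if (length(Ui) == 0L) { stop_reason <- "bnd_empty"; break }
  }
  new_seq3wd("seq_dtrs", recs[seq_len(nlev)], universe, concept, stop_reason,
             call = match.call())
}

#' Generalized sequential three-way classification (similarity coverings)
#'
#' The generalized sequential engine replaces per-level attribute reduction
#' with per-level similarity granulation, so no information is discarded
#' between levels.  At level i the full universe is covered by
#' xi_i-thresholded Bray-Curtis similarity classes of the max-normalized
#' table; every still-deferred object is scored with the covering-based
#' rough membership of the current concept X_i ([generalized_membership()],
#' average mode by default) and tri-partitioned at (alpha_i, beta_i).  The
#' boundary becomes the next sub-universe, X_{i+1} = X_i intersected with
#' it, and the run stops when the boundary empties, the schedule is
#' exhausted, or the schedule was truncated at alpha <= beta.
#'
#' @param x an [information_table()]; its `concept` is the target unless
#'   overridden.
#' @param xi numeric vector of similarity thresholds in (0, 1], one per
#'   level (a single value is recycled to the schedule length).
#' @param thresholds optional explicit schedule: matrix/data.frame with
#'   `alpha`, `beta` columns or list of [threshold_pair()]s.  When absent a
#'   [linear_threshold_schedule()] is generated from `alpha0`, `beta0`,
#'   `step`, `max_levels`.
#' @param alpha0,beta0,step,max_levels parameters of the generated
#'   schedule; ignored when `thresholds` is given.
#' @param mode rough-membership aggregation, see [generalized_membership()].
#' @param concept character vector overriding `x$concept`.
#' @param force_assign if `TRUE`, a terminal non-empty boundary is
#'   force-classified after the run (POS when last membership >= 0.5, else
#'   NEG).  Off by default: abstention is the point of the third region.
#' @return An object of class `c("gseq_dtrs", "seq3wd")`: a list with
#'   `levels` (per-level records: sub-universe, concept, xi, alpha, beta,
#'   memberships, POS/BND/NEG), `accumulated_pos`, `accumulated_neg`,
#'   `terminal_bnd` (a partition of the universe), and `stop_reason`.
#' @examples
#' fix <- example_fixture("fiveobj_gseq")
#' fit <- gseq_dtrs(fix$table, xi = c(0.59, 0.6, 0.7),
#'                  thresholds = fix$thresholds)
#' summary(fit)
#' @export
gseq_dtrs <- function(x, xi, thresholds = NULL,
                      alpha0 = 1, beta0 = 0, step = 0.0225, max_levels = 20L,
                      mode = c("average", "minimum", "maximum"),
                      concept = NULL, force_assign = FALSE) {
  stopifnot(inherits(x, "information_table"))
  mode <- match.arg(mode)
  truncated <- FALSE
  if (is.null(thresholds)) {
    sched <- linear_threshold_schedule(alpha0, beta0, step, max_levels)
    truncated <- isTRUE(attr(sched, "truncated"))
  } else {
    sched <- as_threshold_matrix(thresholds)
  }
  nlev <- nrow(sched)
  if (length(xi) == 1L) xi <- rep(xi, nlev)
  if (length(xi) < nlev) {
    nlev <- length(xi)
    sched <- sched[seq_len(nlev), , drop = FALSE]
  }
  if (any(xi <= 0 | xi > 1))
    stop("xi thresholds must lie in (0, 1]", call. = FALSE)
  if (is.null(concept)) concept <- x$concept
  universe <- x$object_ids
  if (!all(concept %in% universe))
    stop("concept must be a subset of the universe", call. = FALSE)

  sim <- similarity_matrix(max_normalize(x))
  coverings <- list()   # cache per distinct xi
  recs <- vector("list", nlev)
  Ui <- universe
  Xi <- concept
  stop_reason <- if (truncated) "alpha_le_beta" else "schedule_exhausted"
  used <- 0L
  for (i in seq_len(nlev)) {
    key <- format(xi[i], digits = 15)
    if (is.null(coverings[[key]]))
      coverings[[key]] <- similarity_classes(sim, xi[i])
    cov <- coverings[[key]]
    memb <- vapply(Ui, function(c) generalized_membership(Xi, cov, c, mode),
                   numeric(1))
    thr <- threshold_pair(sched[i, "alpha"], sched[i, "beta"])
    regions <- tri_partition(memb, Ui, thr)
    recs[[i]] <- list(level = i, label = paste0("L", i),
                      universe = Ui, concept = Xi,
                      granulation = "similarity covering",
                      xi = xi[i],
                      alpha = thr[["alpha"]], beta = thr[["beta"]],
                      membership = memb,
                      pos = regions$pos, bnd = regions$bnd, neg = regions$neg)
    used <- i
    Ui <- regions$bnd
    Xi <- intersect(Xi, Ui)
    if (length(Ui) == 0L) { stop_reason <- "bnd_empty"; break }
  }
  fit <- new_seq3wd("gseq_dtrs", recs[seq_len(used)], universe, concept,
                    stop_reason, mode = mode, call = match.call())
  if (force_assign && length(fit$terminal_bnd)) {
    last <- fit$levels[[length(fit$levels)]]
    m <- last$membership[fit$terminal_bnd]
    fit$forced_pos <- fit$terminal_bnd[m >= 0.5]
    fit$forced_neg <- fit$terminal_bnd[m < 0.5]
    fit$accumulated_pos <- fit$universe[fit$universe %in%
                                          c(fit$accumulated_pos, fit$forced_pos)]
    fit$accumulated_neg <- fit$universe[fit$universe %in%
                                          c(fit$accumulated_neg, fit$forced_neg)]
    fit$terminal_bnd <- character(0)
  }
  class(fit) <- c("gseq_dtrs", class(fit))
  fit
}

#' Accumulated regions of a sequential run
#'
#' Unions of the per-level POS and NEG regions, plus the last level's
#' boundary.  By construction the three sets are disjoint and partition the
#' universe; this is re-validated here.
#'
#' @param x a `"seq3wd"` trace.
#' @return A list with `accumulated_pos`, `accumulated_neg`,
#'   `terminal_bnd` (character vectors in universe order).
#' @export
accumulate_regions <- function(x) {
  stopifnot(inherits(x, "seq3wd"))
  pos <- unique(unlist(lapply(x$levels, `[[`, "pos")))
  neg <- unique(unlist(lapply(x$levels, `[[`, "neg")))
  bnd <- if (length(x$levels)) x$levels[[length(x$levels)]]$bnd else x$universe
  out <- list(accumulated_pos = x$universe[x$universe %in% pos],
              accumulated_neg = x$universe[x$universe %in% neg],
              terminal_bnd = x$universe[x$universe %in% bnd])
  all_ids <- unlist(out)
  if (anyDuplicated(all_ids) || !setequal(all_ids, x$universe))
    stop("internal consistency error: accumulated regions do not partition ",
         "the universe", call. = FALSE)
  out
}

#' Per-level region counts of a sequential run
#'
#' The summary grid of a sequential classification: rows BND/POS/NEG,
#' one column per executed level.
#'
#' @param x a `"seq3wd"` trace.
#' @return An integer matrix, rows `BND`, `POS`, `NEG`.
#' @export
level_counts <- function(x) {
  stopifnot(inherits(x, "seq3wd"))
  counts <- vapply(x$levels, function(l) {
    c(BND = length(l$bnd), POS = length(l$pos), NEG = length(l$neg))
  }, integer(3))
  colnames(counts) <- vapply(x$levels, `[[`, character(1), "label")
  counts
}

#' @export
print.seq3wd <- function(x, ...) {
  cat(if (x$engine == "gseq_dtrs")
        "Generalized sequential three-way classification (similarity coverings)\n"
      else "Sequential three-way classification (equivalence granulations)\n")
  cat(sprintf("%d objects, concept |X| = %d, %d level(s), stopped: %s\n",
              length(x$universe), length(x$concept), length(x$levels),
              x$stop_reason))
  cat(sprintf("accumulated POS: %d, NEG: %d, terminal BND: %d\n",
              length(x$accumulated_pos), length(x$accumulated_neg),
              length(x$terminal_bnd)))
  invisible(x)
}

#' @export
summary.seq3wd <- function(object, ...) {
  lv <- object$levels
  cum_pos <- cumsum(vapply(lv, function(l) length(l$pos), integer(1)))
  cum_neg <- cumsum(vapply(lv, function(l) length(l$neg), integer(1)))
  df <- data.frame(
    level = vapply(lv, `[[`, integer(1), "level"),
    label = vapply(lv, `[[`, character(1), "label"),
    n_universe = vapply(lv, function(l) length(l$universe), integer(1)),
    xi = vapply(lv, `[[`, numeric(1), "xi"),
    alpha = vapply(lv, `[[`, numeric(1), "alpha"),
    beta = vapply(lv, `[[`, numeric(1), "beta"),
    n_pos = vapply(lv, function(l) length(l$pos), integer(1)),
    n_bnd = vapply(lv, function(l) length(l$bnd), integer(1)),
    n_neg = vapply(lv, function(l) length(l$neg), integer(1)),
    cum_pos = cum_pos, cum_neg = cum_neg)
  structure(list(engine = object$engine, table = df,
                 stop_reason = object$stop_reason,
                 n_universe = length(object$universe),
                 terminal_bnd = object$terminal_bnd),
            class = "summary.seq3wd")
}

#' @export
print.summary.seq3wd <- function(x, ...) {
  cat(sprintf("%s run over %d objects (stopped: %s)\n",
              x$engine, x$n_universe, x$stop_reason))
  print(x$table, row.names = FALSE, digits = 4)
  if (length(x$terminal_bnd))
    cat("unresolved boundary: ", paste(x$terminal_bnd, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.seq3wd <- function(x, ...) {
  do.call(rbind, lapply(x$levels, function(l) {
    tag <- rep("BND", length(l$universe))
    names(tag) <- l$universe
    tag[l$pos] <- "POS"
    tag[l$neg] <- "NEG"
    data.frame(level = l$level, label = l$label, object = l$universe,
               membership = unname(l$membership[l$universe]),
               region = unname(tag),
               xi = l$xi, alpha = l$alpha, beta = l$beta,
               row.names = NULL)
  }))
}

#' Plot per-level region counts of a sequential run
#'
#' Stacked bars of the POS/BND/NEG counts at each executed level, the usual
#' way sequential three-way runs are displayed.
#'
#' @param x a `"seq3wd"` trace.
#' @param ... passed to [graphics::barplot()].
#' @return The trace, invisibly.
#' @export
plot.seq3wd <- function(x, ...) {
  counts <- level_counts(x)
  graphics::barplot(counts[c("POS", "BND", "NEG"), , drop = FALSE],
                    col = c("#2c7fb8", "#bdbdbd", "#d95f0e"),
                    legend.text = c("POS", "BND", "NEG"),
                    xlab = "level", ylab = "objects", ...)
  invisible(x)
}
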