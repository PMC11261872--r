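#' Cumulative classification accuracy of a sequential run
#'
#' Accuracy is computed over the objects classified so far: at each level,
#' the accumulated POS and NEG regions up to and including that level are
#' compared with the true labels (an accumulated-POS object is correct iff
#' labelled positive, an accumulated-NEG object iff labelled negative).
#' Deferred objects do not enter the denominator; a level at which nothing
#' has been classified yet reports `NA`.  Note that this cumulative
#' definition is an interpretation — abstention-based classifiers admit
#' several accuracy notions — chosen because it is the one consistent with
#' tracking "accuracy at each new iteration" of a growing classified set.
#'
#' @param x a `"seq3wd"` trace.
#' @param labels true labels over the universe: a named logical vector
#'   (`TRUE` = positive) or a named character vector over
#'   `{"positive", "negative"}`.
#' @return A data frame of class `"accuracy_report"` with one row per
#'   level: `level`, `n_classified`, `n_correct`, `accuracy`.
#' @examples
#' fix <- example_fixture("fiveobj_gseq")
#' fit <- gseq_dtrs(fix$table, xi = fix$xi, thresholds = fix$thresholds)
#' classification_accuracy(fit, fix$table$decision)
#' @export
classification_accuracy <- function(x, labels) {
  stopifnot(inherits(x, "seq3wd"))
  if (is.character(labels)) labels <- labels == "positive"
  missing <- setdiff(x$universe, names(labels))
  if (length(missing))
    stop("missing label(s) for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  pos <- character(0)
  neg <- character(0)
  rows <- lapply(x$levels, function(l) {
    pos <<- union(pos, l$pos)
    neg <<- union(neg, l$neg)
    n_cls <- length(pos) + length(neg)
    n_ok <- sum(labels[pos]) + sum(!labels[neg])
    data.frame(level = l$level, n_classified = n_cls, n_correct = n_ok,
               accuracy = if (n_cls > 0) n_ok / n_cls else NA_real_)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("accuracy_report", class(out))
  out
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("Cumulative accuracy over classified objects\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Threshold-schedule sensitivity sweep
#'
#' Runs the generalized sequential engine once per schedule specification
#' and records how many iterations each needs and whether the boundary was
#' exhausted.  The gap alpha - beta and the step size dictate the number of
#' iterations, so sweeping them shows the cost/abstention trade-off of a
#' schedule on a fixed table.
#'
#' @param x an [information_table()].
#' @param grid either a data frame with columns among `xi`, `alpha0`,
#'   `beta0`, `step`, `max_levels` (missing columns take the [gseq_dtrs()]
#'   defaults), one row per run; or a list of argument lists passed to
#'   [gseq_dtrs()] directly (use the latter for per-level `xi` vectors or
#'   explicit threshold schedules).
#' @param mode membership aggregation passed to [gseq_dtrs()].
#' @return A data frame with one row per run: the swept parameters (or a
#'   `spec` index for list input) plus `iterations`, `bnd_emptied`,
#'   `n_pos`, `n_neg`, `n_bnd`.
#' @export
sensitivity_sweep <- function(x, grid, mode = "average") {
  measure <- function(fit) {
    data.frame(iterations = length(fit$levels),
               bnd_emptied = length(fit$terminal_bnd) == 0L,
               n_pos = length(fit$accumulated_pos),
               n_neg = length(fit$accumulated_neg),
               n_bnd = length(fit$terminal_bnd))
  }
  if (is.data.frame(grid)) {
    stopifnot(nrow(grid) > 0)
    defaults <- list(xi = 0.75, alpha0 = 1, beta0 = 0, step = 0.0225,
                     max_levels = 20L)
    res <- lapply(seq_len(nrow(grid)), function(i) {
      g <- utils::modifyList(defaults, as.list(grid[i, , drop = FALSE]))
      measure(gseq_dtrs(x, xi = g$xi, alpha0 = g$alpha0, beta0 = g$beta0,
                        step = g$step, max_levels = g$max_levels,
                        mode = mode))
    })
    cbind(grid, do.call(rbind, res))
  } else if (is.list(grid) && length(grid) > 0) {
    res <- lapply(grid, function(args) {
      measure(do.call(gseq_dtrs, c(list(x = x, mode = mode), args)))
    })
    cbind(data.frame(spec = seq_along(grid)), do.call(rbind, res))
  } else {
    stop("grid must be a nonempty data frame or list of argument lists",
         call. = FALSE)
  }
}
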