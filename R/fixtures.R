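#' Packaged worked-example fixtures
#'
#' Two small clinical decision problems, fully specified in code, that
#' exercise both sequential engines end to end:
#'
#' * `"covid_seq"` — twelve patients suspected of COVID with three symptom
#'   attributes (fever, cough, shortness of breath).  Three explicit
#'   equivalence granulations, processed from the finest attribute set
#'   downwards with thresholds (0.8, 0.2), (0.7, 0.3), (0.6, 0.4), drive
#'   the classical sequential engine.  The partitions are supplied
#'   explicitly: they are the fixture's givens, not derivable from a value
#'   table.
#' * `"fiveobj_gseq"` — five objects with three nonnegative attributes
#'   (and a binary decision), granulated by similarity classes at
#'   xi = (0.59, 0.6, 0.7) with thresholds (0.8, 0.2), (0.7, 0.3),
#'   (0.5, 0.4) for the generalized engine, which exhausts the boundary in
#'   three iterations.
#'
#' Each bundle records the inputs together with the expected per-level
#' regions, used by the test suite as frozen oracles.
#'
#' @param name `"covid_seq"` or `"fiveobj_gseq"`.
#' @return A list; for `covid_seq`: `universe`, `concept`, `levels` (ready
#'   for [seq_dtrs()]), `expected` (per-level and accumulated regions).
#'   For `fiveobj_gseq`: `table` (an [information_table()]), `xi`,
#'   `thresholds`, `expected` (normalized cells, similarity entries,
#'   level-1 memberships, per-level regions).
#' @examples
#' fix <- example_fixture("fiveobj_gseq")
#' fix$table$concept
#' @export
example_fixture <- function(name = c("covid_seq", "fiveobj_gseq")) {
  name <- match.arg(name)
  if (name == "covid_seq") {
    u <- paste0("c", 1:12)
    list(
      name = name,
      universe = u,
      concept = c("c1", "c2", "c3", "c5", "c7"),
      levels = list(
        list(label = "level-3", alpha = 0.8, beta = 0.2,
             partition = list(u)),
        list(label = "level-2", alpha = 0.7, beta = 0.3,
             partition = list(c("c1", "c2", "c3", "c4"),
                              c("c5", "c6", "c7", "c8", "c9", "c10"),
                              c("c11", "c12"))),
        list(label = "level-1", alpha = 0.6, beta = 0.4,
             partition = list(c("c1", "c2", "c3"), "c4",
                              c("c5", "c6", "c7"), c("c8", "c9", "c10"),
                              c("c11", "c12")))),
      expected = list(
        level1_cp = 5 / 12,
        counts = matrix(c(12L, 0L, 0L, 6L, 4L, 2L, 0L, 3L, 3L), 3,
                        dimnames = list(c("BND", "POS", "NEG"),
                                        c("level-3", "level-2", "level-1"))),
        pos_by_level = list(character(0), c("c1", "c2", "c3", "c4"),
                            c("c5", "c6", "c7")),
        neg_by_level = list(character(0), c("c11", "c12"),
                            c("c8", "c9", "c10")),
        accumulated_pos = c("c1", "c2", "c3", "c4", "c5", "c6", "c7"),
        accumulated_neg = c("c8", "c9", "c10", "c11", "c12")))
  } else {
    values <- matrix(c(8, 45, 80,
                       20, 3, 100,
                       40, 9, 18,
                       13, 17, 30,
                       50, 9, 15),
                     nrow = 5, byrow = TRUE,
                     dimnames = list(paste0("c", 1:5), c("a", "b", "c")))
    tab <- information_table(values,
                             decision = c(TRUE, FALSE, TRUE, FALSE, TRUE),
                             decision_attr = "d")
    list(
      name = name,
      table = tab,
      xi = c(0.59, 0.6, 0.7),
      thresholds = rbind(c(alpha = 0.8, beta = 0.2),
                         c(alpha = 0.7, beta = 0.3),
                         c(alpha = 0.5, beta = 0.4)),
      expected = list(
        normalized = matrix(c(8 / 50, 45 / 45, 80 / 100,
                              20 / 50, 3 / 45, 100 / 100,
                              40 / 50, 9 / 45, 18 / 100,
                              13 / 50, 17 / 45, 30 / 100,
                              50 / 50, 9 / 45, 15 / 100),
                            nrow = 5, byrow = TRUE,
                            dimnames = dimnames(values)),
        similarity = matrix(c(1, 0.59922179, 0.34394904, 0.57822086, 0.3081571,
                              0.59922179, 1, 0.48866499, 0.52125693, 0.43786982,
                              0.34394904, 0.48866499, 1, 0.60440714, 0.90909091,
                              0.57822086, 0.52125693, 0.60440714, 1, 0.53326858,
                              0.3081571, 0.43786982, 0.90909091, 0.53326858, 1),
                            nrow = 5, byrow = TRUE,
                            dimnames = list(paste0("c", 1:5), paste0("c", 1:5))),
        level1_classes = list(c1 = c("c1", "c2"), c2 = c("c1", "c2"),
                              c3 = c("c3", "c4", "c5"), c4 = c("c3", "c4"),
                              c5 = c("c3", "c5")),
        level3_classes = list(c1 = "c1", c2 = "c2", c3 = c("c3", "c5"),
                              c4 = "c4", c5 = c("c3", "c5")),
        level1_membership = c(c1 = 0.5, c2 = 0.5, c3 = 13 / 18,
                              c4 = 7 / 12, c5 = 5 / 6),
        pos_by_level = list("c5", "c1", "c3"),
        neg_by_level = list(character(0), "c2", "c4"),
        bnd_by_level = list(c("c1", "c2", "c3", "c4"), c("c3", "c4"),
                            character(0)),
        counts = matrix(c(4L, 1L, 0L, 2L, 1L, 1L, 0L, 1L, 1L), 3,
                        dimnames = list(c("BND", "POS", "NEG"),
                                        c("L1", "L2", "L3")))))
  }
}
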