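# Shared generators and independent oracles for the property suites.

# Random nonnegative table; discrete = small integer values so that
# equivalence classes are nontrivial.
random_table <- function(n, p, discrete = FALSE) {
  v <- if (discrete) matrix(sample(0:3, n * p, replace = TRUE), n, p)
       else matrix(round(runif(n * p, 0, 10), 3), n, p)
  colnames(v) <- paste0("a", seq_len(p))
  information_table(v, decision = runif(n) < 0.5,
                    object_ids = paste0("o", seq_len(n)))
}

# Random covering: every object owns a class that contains itself.
random_covering <- function(n, p_member = 0.4) {
  ids <- paste0("o", seq_len(n))
  class_of <- lapply(seq_len(n), function(i)
    ids[runif(n) < p_member | seq_len(n) == i])
  names(class_of) <- ids
  similarity_covering(class_of)
}

# Independent membership oracle: incidence-matrix enumeration over all
# owners, no shared code with generalized_membership().
oracle_membership <- function(X, covering, object) {
  ids <- names(covering$class_of)
  M <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  for (y in ids) M[y, covering$class_of[[y]]] <- 1L
  owners <- ids[M[, object] == 1L]
  ratios <- sapply(owners, function(y) {
    s <- ids[M[y, ] == 1L]
    length(intersect(s, X)) / length(s)
  })
  c(minimum = min(ratios), average = mean(ratios), maximum = max(ratios))
}

# Random loss matrix satisfying the rationality constraints and inducing
# alpha > beta (rejection sampling).
random_loss_matrix <- function() {
  repeat {
    lp <- sort(runif(3, 0, 10))   # PP <= BP < NP
    ln <- sort(runif(3, 0, 10))   # NN <= BN < PN
    loss <- try(loss_matrix(lp[1], lp[2], lp[3], ln[3], ln[2], ln[1]),
                silent = TRUE)
    if (inherits(loss, "try-error")) next
    thr <- try(thresholds_from_losses(loss), silent = TRUE)
    if (!inherits(thr, "try-error")) return(loss)
  }
}

# Straight-line re-implementation of one sequential level (partition case),
# used as the independent per-level oracle.
oracle_seq_level <- function(blocks, Ui, Xi, alpha, beta) {
  tag <- character(0)
  memb <- numeric(0)
  for (c in Ui) {
    b <- blocks[[which(vapply(blocks, function(s) c %in% s, logical(1)))[1]]]
    p <- length(intersect(b, Xi)) / length(b)
    memb[c] <- p
    tag[c] <- if (p >= alpha) "POS" else if (p <= beta) "NEG" else "BND"
  }
  list(pos = Ui[tag[Ui] == "POS"], bnd = Ui[tag[Ui] == "BND"],
       neg = Ui[tag[Ui] == "NEG"], membership = memb)
}

fiveobj <- example_fixture("fiveobj_gseq")
covid <- example_fixture("covid_seq")
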