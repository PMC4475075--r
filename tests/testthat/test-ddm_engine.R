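toy <- toy_example()
toy_R0 <- init_mode_matrix(order_rows(toy$kernel))

# mode columns of the initial matrix as plain lists
.mode_col <- function(R, j) {
  list(support = R$bin[, j], tail = R$tail[, j, drop = TRUE])
}

test_that("mode combination follows the weighted-subtraction formula", {
  m1 <- .mode_col(toy_R0, 1)  # tail (R2, R1) = (-1, -0.5), support {R3}
  m3 <- .mode_col(toy_R0, 3)  # tail (1, -0.5), support {R7rb}
  child <- combine_modes(m_pos = m3, m_neg = m1)
  expect_equal(names(which(child$support)), c("R3", "R7rb"))
  expect_equal(as.numeric(child$tail), c(0, -0.5))
  m2 <- .mode_col(toy_R0, 2)  # tail (-1, 0.5), support {R7rf}
  child2 <- combine_modes(m_pos = m3, m_neg = m2)
  expect_equal(names(which(child2$support)), c("R7rf", "R7rb"))
  expect_equal(as.numeric(child2$tail), c(0, 0))
  # the pivot entry of any child is exactly zero
  expect_true(child$tail$num[1] == 0 && child2$tail$num[1] == 0)
  expect_error(combine_modes(m_pos = m1, m_neg = m3), "positive and a negative")
})

test_that("the adjacency test matches an exhaustive subset-check oracle", {
  # equality with a third mode's support counts as superset
  keep <- matrix(c(TRUE, FALSE, FALSE, TRUE, TRUE, TRUE), nrow = 2)
  expect_false(adjacency_test(c(TRUE, TRUE), keep, parents = c(1, 2)))
  set.seed(5)
  for (k in 1:30) {
    nr <- 12; nm <- sample(3:8, 1)
    keep <- matrix(stats::runif(nr * nm) < 0.4, nr, nm)
    parents <- sample(nm, 2)
    cand <- keep[, parents[1]] | keep[, parents[2]]
    oracle <- TRUE
    for (j in setdiff(seq_len(nm), parents)) {
      if (all(!keep[, j] | cand)) oracle <- FALSE
    }
    expect_equal(adjacency_test(cand, keep, parents), oracle)
  }
})

test_that("the first iteration reproduces the worked example step", {
  step <- iterate_row(toy_R0)
  expect_equal(ncol(step$R$bin), 10)
  expect_equal(step$stats$adjacency_candidates, 6)
  expect_equal(step$stats$removed_infeasible, 0)
  expect_identical(step$R$pending, "R1")
  # tail values after the first step (multiset over the 10 modes)
  expect_equal(sort(as.numeric(step$R$tail)[1, ]),
               sort(c(-0.5, 0.5, 1.0, 0.5, 0.5, 0.5, 0.0, 0.0, 0.0, -0.5)))
  # with the compiled full-active patterns one child dies immediately
  pat <- compile_patterns(toy$rules_full, toy$ext)
  step_r <- iterate_row(toy_R0, pat)
  expect_equal(ncol(step_r$R$bin), 9)
  expect_equal(step_r$stats$removed_infeasible, 1)
  # the removed mode is the one carrying both R7rf and R9
  supp <- apply(step$R$bin, 2, function(b)
    paste(sort(rownames(step$R$bin)[b]), collapse = ","))
  supp_r <- apply(step_r$R$bin, 2, function(b)
    paste(sort(rownames(step_r$R$bin)[b]), collapse = ","))
  gone <- setdiff(supp, supp_r)
  expect_length(gone, 1)
  expect_match(gone, "R7rf")
  expect_match(gone, "R9")
})

test_that("a pivot row without negatives only binarizes", {
  R0 <- regefm:::mode_matrix(matrix(c(TRUE, FALSE), 1),
                             rat(matrix(c(0, 2), 1)),
                             binarized = "b", pending = "a")
  step <- iterate_row(R0)
  expect_equal(ncol(step$R$bin), 2)
  expect_equal(step$stats$adjacency_candidates, 0)
  expect_equal(unname(step$R$bin["a", ]), c(FALSE, TRUE))
})

test_that("the full iteration reproduces the worked example and stats", {
  run <- ddm_run(toy_R0)
  expect_equal(ncol(run$R$bin), 12)
  expect_length(run$R$pending, 0)
  expect_equal(run$stats$n_modes, c(10, 12))
  pat <- compile_patterns(toy$rules_full, toy$ext)
  run_r <- ddm_run(toy_R0, pat)
  expect_equal(ncol(run_r$R$bin), 8)
  expect_equal(run_r$stats$removed_infeasible, c(1, 3))
  expect_equal(run_r$initial_removed, 0)
  # no pending rows: identity run
  noop <- ddm_run(run$R)
  expect_identical(noop$R$bin, run$R$bin)
  expect_equal(nrow(noop$stats), 0)
})

test_that("pattern pruning equals post-hoc filtering of the full run", {
  pat <- compile_patterns(toy$rules_full, toy$ext)
  full <- ddm_run(toy_R0)
  pruned <- ddm_run(toy_R0, pat)
  filtered <- regefm:::.pattern_keep(full$R$bin, pat)
  expect_setequal(regefm:::mode_supports(pruned$R),
                  regefm:::mode_supports(full$R)[filtered])
  set.seed(21)
  for (s in 1:5) {
    net <- generate_network(3, 6, reversible_fraction = 0.3, seed = s)
    ext <- split_reversibles(net)
    rules <- generate_rules(net, 2, seed = s + 7)
    p <- compile_patterns(rules, ext)
    R0 <- init_mode_matrix(order_rows(compute_kernel(ext)))
    a <- ddm_run(R0, p)
    b <- ddm_run(R0)
    keep <- regefm:::.pattern_keep(b$R$bin, p)
    expect_setequal(regefm:::mode_supports(a$R),
                    regefm:::mode_supports(b$R)[keep])
  }
})

test_that("the final support set is invariant to the admissible row order", {
  ref <- sort(regefm:::mode_supports(ddm_run(toy_R0)$R))
  Ko <- order_rows(toy$kernel)
  nb <- Ko$n_binarizable
  n <- length(Ko$row_ids)
  set.seed(31)
  for (k in 1:5) {
    ord <- c(sample(nb), nb + sample(n - nb))
    Kp <- regefm:::kernel_matrix(Ko$K[ord, , drop = FALSE],
                                 Ko$row_ids[ord], n_binarizable = nb)
    out <- ddm_run(init_mode_matrix(Kp))
    expect_identical(sort(regefm:::mode_supports(out$R)), ref)
  }
})
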