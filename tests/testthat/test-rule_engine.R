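toy <- toy_example()

test_that("rule parsing handles activity prefixes, NOT/! and errors", {
  r <- parse_rules(net = toy$net, text = "R7r = NOT(fR9)")[[1]]
  expect_equal(r$output$reaction, "R7r")
  expect_equal(r$output$activity, "full_active")
  expect_equal(r$expr$op, "not")
  expect_equal(r$expr$x$reaction, "R9")
  expect_equal(r$expr$x$activity, "full_active")

  r2 <- parse_rules(net = toy$net, text = "R1 = (!fR5)")[[1]]
  expect_equal(r2$expr$op, "not")
  expect_equal(r2$expr$x$reaction, "R5")

  r3 <- parse_rules(net = toy$net,
                    text = "R1 = 0R2 AND (1R3 OR NOT R4)")[[1]]
  expect_equal(r3$expr$op, "and")
  expect_equal(r3$expr$lhs$activity, "zero_active")
  expect_equal(r3$expr$rhs$rhs$op, "not")

  expect_error(parse_rules(net = toy$net, text = "R7r = NOT(Rx)"),
               "line 1.*unknown reaction")
  expect_error(parse_rules(net = toy$net, text = "R7r NOT(R9)"), "OUTPUT")
  expect_error(parse_rules(net = toy$net, text = "R7r = NOT(R9"),
               "parenthesis")
  expect_warning(parse_rules(net = toy$net, text = "# only a comment"),
                 "no rules")
  # comments and numbering
  rs <- parse_rules(net = toy$net,
                    text = c("# header", "R7r = NOT(R9)", "R1 = fR2"))
  expect_equal(vapply(rs, `[[`, "", "id"), c("GR1", "GR2"))
})

test_that("three-valued evaluation matches an independent Kleene oracle", {
  a <- c(R9 = 0)
  one <- regefm:::rule_atom("R9", "one_active")
  expect_equal(eval_tribool(list(op = "not", x = one), a), "undefined")
  expect_equal(eval_tribool(list(op = "not", x = regefm:::rule_atom("R9")),
                            c(R9 = 1)), "false")
  # undefined AND false is false (strong Kleene)
  e <- list(op = "and", lhs = regefm:::rule_atom("Ra", "zero_active"),
            rhs = regefm:::rule_atom("Rb"))
  expect_equal(eval_tribool(e, c(Ra = 1, Rb = 0)), "false")

  set.seed(99)
  rxns <- c("Ra", "Rb", "Rc")
  for (k in 1:40) {
    expr <- random_expr(rxns)
    for (bits in 0:7) {
      assignment <- stats::setNames(bitwAnd(bits, c(1, 2, 4)) > 0, rxns)
      expect_equal(eval_tribool(expr, assignment),
                   kleene_oracle(expr, assignment))
    }
  }
})

test_that("violation requires both sides defined and unequal", {
  rule_f <- toy$rules_full[[1]]
  expect_true(rule_violated(rule_f, c(R7r = 1, R9 = 1)))
  expect_true(rule_violated(rule_f, c(R7r = 0, R9 = 0)))
  expect_false(rule_violated(rule_f, c(R7r = 1, R9 = 0)))
  expect_false(rule_violated(rule_f, c(R7r = 0, R9 = 1)))
  rule_1 <- toy$rules_one[[1]]
  expect_false(rule_violated(rule_1, c(R7r = 0, R9 = 0)))  # RHS undefined
  expect_true(rule_violated(rule_1, c(R7r = 1, R9 = 1)))
  # undefined output withholds the rule
  r0 <- parse_rules(net = toy$net, text = "0R7r = NOT(fR9)")[[1]]
  expect_false(rule_violated(r0, c(R7r = 1, R9 = 1)))
})

test_that("classification separates iteration-phase from post-only rules", {
  expect_equal(classify_rule(toy$rules_full[[1]]), "iteration_phase")
  expect_equal(classify_rule(toy$rules_one[[1]]), "iteration_phase")
  expect_equal(classify_rule(
    parse_rules(net = toy$net, text = "R1 = fR2")[[1]]), "post_only")
  expect_equal(classify_rule(
    parse_rules(net = toy$net, text = "0R1 = NOT(fR2)")[[1]]), "post_only")
  expect_equal(classify_rule(
    parse_rules(net = toy$net, text = "R1 = NOT(1R2)")[[1]]),
    "iteration_phase")
})

test_that("patterns expand over split reaction directions", {
  pat <- compile_patterns(toy$rules_full, toy$ext)
  expect_length(pat, 2)
  expect_setequal(vapply(pat, function(p) paste(sort(p$ext_ids),
                                                collapse = "+"), ""),
                  c("R7rf+R9", "R7rb+R9"))
  # irreversible-only rule: one pattern
  net_i <- metabolic_network(c("A", "B"), c("U", "V", "W"), rep(FALSE, 3),
                             matrix(c(1, 0, -1, 1, 0, -1), 2))
  pat_i <- compile_patterns(parse_rules(net = net_i, text = "U = NOT(fV)"),
                            split_reversibles(net_i))
  expect_length(pat_i, 1)
  expect_setequal(pat_i[[1]]$ext_ids, c("U", "V"))
  # reversible output and reversible input: 2 x 2 patterns
  net_r <- metabolic_network(c("A", "B"), c("U", "V", "W"),
                             c(TRUE, TRUE, FALSE),
                             matrix(c(1, 0, -1, 1, 0, -1), 2))
  pat_r <- compile_patterns(parse_rules(net = net_r, text = "U = NOT(fV)"),
                            split_reversibles(net_r))
  expect_length(pat_r, 4)
  expect_setequal(vapply(pat_r, function(p) paste(sort(p$ext_ids),
                                                  collapse = "+"), ""),
                  c("Uf+Vf", "Uf+Vb", "Ub+Vf", "Ub+Vb"))
  # post-only rules compile to no pattern
  expect_length(compile_patterns(
    parse_rules(net = net_i, text = "U = fV"), split_reversibles(net_i)), 0)
})

test_that("patterns never over-prune: every matched support violates the rule", {
  set.seed(17)
  for (s in 1:5) {
    net <- generate_network(3, 6, reversible_fraction = 0.4, seed = s)
    ext <- split_reversibles(net)
    rules <- generate_rules(net, 2, seed = s + 50)
    patterns <- compile_patterns(rules, ext)
    n <- length(ext$ext_ids)
    for (bits in seq_len(2^n) - 1) {
      supp_ext <- ext$ext_ids[bitwAnd(bits, 2^(seq_len(n) - 1)) > 0]
      matched <- any(vapply(patterns, function(p)
        all(p$ext_ids %in% supp_ext), TRUE))
      if (!matched) next
      merged <- vapply(net$reaction_ids, function(id)
        any(ext$col_map[[id]] %in% supp_ext), TRUE)
      expect_true(any(vapply(rules, rule_violated, TRUE,
                             assignment = merged)))
    }
  }
})
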