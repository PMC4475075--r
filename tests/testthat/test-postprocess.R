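toy <- toy_example()
toy_run <- ddm_run(init_mode_matrix(order_rows(toy$kernel)))

test_that("futile 2-cycles are removed exactly", {
  R <- remove_futile_cycles(toy_run$R, toy$ext)
  expect_equal(ncol(R$bin), 11)
  expect_false(any(regefm:::mode_supports(R) == "R7rb,R7rf"))
  # all-irreversible networks are untouched
  net <- metabolic_network(c("A", "B"), c("U", "V", "W"), rep(FALSE, 3),
                           matrix(c(1, 0, -1, 1, 0, -1), 2))
  ext <- split_reversibles(net)
  run <- ddm_run(init_mode_matrix(order_rows(compute_kernel(ext))))
  expect_equal(ncol(remove_futile_cycles(run$R, ext)$bin), ncol(run$R$bin))
  # every reversible reaction contributes exactly one futile cycle
  for (s in 1:4) {
    g <- generate_network(3, 6, reversible_fraction = 0.5, seed = s)
    eg <- split_reversibles(g)
    r <- ddm_run(init_mode_matrix(order_rows(compute_kernel(eg))))
    removed <- ncol(r$R$bin) - ncol(remove_futile_cycles(r$R, eg)$bin)
    expect_equal(removed, sum(g$reversible))
  }
})

test_that("merging reversibles ORs the split columns back together", {
  R <- remove_futile_cycles(toy_run$R, toy$ext)
  efms <- merge_reversibles(R, toy$ext)
  expect_equal(dim(efms), c(11, 11))
  keys <- support_keys(efms)
  expect_true("R2,R4,R7r,R8" %in% keys)        # backward-direction mode
  expect_true("R1,R4,R7r,R8" %in% keys)        # forward-direction mode
  expect_true("R11,R3,R4,R5,R9" %in% keys)     # irreversible-only mode
})

test_that("post-processing rules remove exactly the disobeying modes", {
  pat <- compile_patterns(toy$rules_full, toy$ext)
  run <- ddm_run(init_mode_matrix(order_rows(toy$kernel)), pat)
  efms <- merge_reversibles(remove_futile_cycles(run$R, toy$ext), toy$ext)
  expect_equal(ncol(efms), 7)
  kept_full <- apply_post_rules(efms, toy$rules_full)
  expect_equal(ncol(kept_full), 5)
  expect_equal(attr(kept_full, "removed"), 2)
  # the removed modes have neither R7r nor R9 active
  gone <- setdiff(support_keys(efms), support_keys(kept_full))
  expect_length(gone, 2)
  expect_false(any(grepl("R7r|R9", gone)))
  # 1-active variant: nothing to remove post hoc
  kept_one <- apply_post_rules(efms, toy$rules_one)
  expect_equal(ncol(kept_one), 7)
  # empty rule list is the identity
  expect_equal(ncol(apply_post_rules(efms, list())), 7)
})

test_that("numeric recovery reproduces the reference flux table exactly", {
  res <- enumerate_efms(toy$net, kernel = toy$kernel)
  expect_equal(ncol(res$efms), 11)
  got <- vapply(res$fluxes, function(f) flux_key(as.numeric(f)), "")
  want <- apply(expected_toy_fluxes(), 1, flux_key)
  expect_setequal(got, want)
  # the support {R1, R4, R7r, R8} mode is proportional to (1, 1, 1, 1)
  f <- res$fluxes[[which(vapply(seq_len(ncol(res$efms)), function(k)
    setequal(rownames(res$efms)[res$efms[, k]],
             c("R1", "R4", "R7r", "R8")), TRUE))]]
  expect_equal(unname(as.numeric(f)[as.numeric(f) != 0]), rep(1, 4))
})

test_that("kernel-based and stoichiometry-based recovery agree", {
  K <- toy$kernel
  res <- enumerate_efms(toy$net, kernel = K, numeric_fluxes = FALSE)
  Kord <- order_rows(K)
  for (k in seq_len(ncol(res$efms))) {
    a <- recover_numeric(res$efms[, k], Kord, toy$ext, method = "kernel")
    b <- recover_numeric(res$efms[, k], Kord, toy$ext,
                         method = "stoichiometry")
    na <- normalize_flux(a); nb <- normalize_flux(b)
    expect_identical(na$num, nb$num)
    expect_identical(na$den, nb$den)
    # steady state on the original network, exactly
    Sv <- regefm:::rat_mm(toy$net$S,
                          regefm:::new_rat(matrix(a$num, ncol = 1),
                                           matrix(a$den, ncol = 1)))
    expect_true(all(Sv$num == 0))
    # irreversible reactions never run backwards
    expect_true(all(a$num[!toy$net$reversible] >= 0))
  }
  expect_error(recover_numeric(c("R1", "R2"), Kord, toy$ext),
               "not elementary")
})

test_that("normalization scales to unit maximum and is idempotent", {
  v <- normalize_flux(rat(c(2, 4, -2, 0)))
  expect_equal(as.numeric(v), c(0.5, 1, -0.5, 0))
  v2 <- normalize_flux(v)
  expect_identical(v2$num, v$num)
  expect_equal(normalize_flux(c(3, -6)), c(0.5, -1))
  expect_error(normalize_flux(rat(c(0, 0))), "zero vector")
})

test_that("activity frequencies are percentages over the EFM set", {
  res <- enumerate_efms(toy$net, rules = toy$rules_full, kernel = toy$kernel,
                        numeric_fluxes = FALSE)
  af <- activity_frequencies(res$efms)
  expect_equal(unname(af["R4"]), 100)
  expect_equal(unname(af["R3"]), 20)
  expect_true(all(af >= 0 & af <= 100))
  expect_error(activity_frequencies(res$efms[, 0, drop = FALSE]), "no EFMs")
})

test_that("no final support is a proper subset of another", {
  res <- enumerate_efms(toy$net, kernel = toy$kernel, numeric_fluxes = FALSE)
  m <- res$efms
  for (i in seq_len(ncol(m))) {
    for (j in seq_len(ncol(m))) {
      if (i == j) next
      expect_false(all(m[, i] <= m[, j]) && any(m[, i] < m[, j]))
    }
  }
})
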