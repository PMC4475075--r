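# Built-in worked-example fixtures.
#
# The 12-metabolite / 11-reaction example (one reversible reaction, R7r,
# split into R7f/R7b) is anchored by a fixed reference kernel matrix: since a
# nullspace basis is not unique, starting from a fixed kernel is what makes
# the worked iteration reproducible entry by entry; the stoichiometric
# matrix is reconstructed from it.  The reordering example
# (12 reactions, 5 reversible) is a synthetic kernel built to exhibit a
# prescribed set of row sign patterns, which is all the ordering logic
# looks at.

# Kernel of the extended example network: 12 extended reactions x 6 basis
# vectors, exact rationals (printed as decimals with denominator 2).
.toy_kernel_rows <- function() {
  ids <- c("R1", "R2", "R3", "R4", "R5", "R6", "R7f", "R7b", "R8", "R9",
           "R10", "R11")
  num <- matrix(c(
    -1,  1, -1,  1,  2,  1,   # R1  (halves)
    -2, -2,  2,  2,  0,  2,   # R2
     2,  0,  0,  0,  0,  0,   # R3
     0,  0,  0,  2,  1,  1,   # R4
     0,  0,  0,  0,  0,  2,   # R5
     0,  0,  0,  0,  2,  0,   # R6
     0,  2,  0,  0,  0,  0,   # R7f
     0,  0,  2,  0,  0,  0,   # R7b
     0,  0,  0,  2,  0,  0,   # R8
     0,  0,  0,  0,  1,  1,   # R9
     0,  0,  0,  0,  2,  0,   # R10
     0,  0,  0,  0,  0,  2),  # R11
    nrow = 12, byrow = TRUE)
  list(ids = ids, K = rat(num, 2))
}

#' Built-in kernel of the worked example network
#'
#' The fixed 12 x 6 reference kernel of the extended (split) example
#' network,
#' held as exact rationals.  Using it as the initial mode matrix makes the
#' whole worked iteration reproducible entry by entry.
#'
#' @return a `kernel_matrix` (rows in extended network order).
#' @export
toy_kernel <- function() {
  k <- .toy_kernel_rows()
  kernel_matrix(k$K, k$ids)
}

#' Reconstructed stoichiometry of the worked example network
#'
#' The example's stoichiometric matrix is not part of the package's source
#' data; only its kernel is.  This builder reconstructs a *synthetic*
#' stand-in `S` whose extended nullspace is exactly the span of the stored
#' kernel: the left-annihilator of the kernel is computed exactly and
#' padded with sums of its basis rows to 12 metabolite rows.  Every
#' EFM-related quantity depends on `S` only through its nullspace, so the
#' stand-in reproduces the worked example's mode sets and fluxes exactly;
#' the individual metabolite rows are not the original ones.
#'
#' @return a [metabolic_network()] with 12 metabolites and 11 reactions
#'   (only `R7r` reversible).
#' @export
toy_network <- function() {
  k <- .toy_kernel_rows()
  # rows of S_ext = basis of the left annihilator {w : K^T w = 0}
  W <- rat_nullspace(rat_t(k$K))          # 12 x 6, columns are rows of S_ext
  base_rows <- rat_t(W)                   # 6 x 12
  nb <- nrow(base_rows$num)
  extra <- lapply(seq_len(nb), function(i) {
    base_rows[i, , drop = FALSE] + base_rows[(i %% nb) + 1, , drop = FALSE]
  })
  S_ext <- do.call(rat_rbind, c(list(base_rows), extra))
  stopifnot(nrow(S_ext$num) == 12,
            all(rowSums(S_ext$num != 0) > 0),
            all(rat_mm(S_ext, k$K)$num == 0),
            all(S_ext$num[, 8] == -S_ext$num[, 7]),   # R7b = -R7f
            all(S_ext$den[, 8] ==  S_ext$den[, 7]))
  S <- S_ext[, c(1:7, 9:12), drop = FALSE]            # drop R7b; R7f is R7r
  metabolic_network(paste0("X", 1:12),
                    c("R1", "R2", "R3", "R4", "R5", "R6", "R7r",
                      "R8", "R9", "R10", "R11"),
                    reversible = c(rep(FALSE, 6), TRUE, rep(FALSE, 4)),
                    S = S)
}

#' Worked example bundle
#'
#' The example network, its extended form, its reference kernel, and the
#' three regulatory variants used throughout the package's tests: no rule,
#' the 1-active rule `R7r = NOT(1R9)`, and the full-active rule
#' `R7r = NOT(fR9)`.  The split of the reconstructed network names the
#' extended columns `R7rf`/`R7rb`; the kernel's conventional row labels
#' `R7f`/`R7b` are remapped accordingly.
#'
#' @return a list with elements `net`, `ext`, `kernel`, `rules_none`,
#'   `rules_one`, `rules_full`.
#' @export
toy_example <- function() {
  net <- toy_network()
  ext <- split_reversibles(net)
  K <- toy_kernel()
  ids <- K$row_ids
  ids[ids == "R7f"] <- "R7rf"
  ids[ids == "R7b"] <- "R7rb"
  K <- kernel_matrix(K$K, ids)
  list(net = net,
       ext = ext,
       kernel = K,
       rules_none = structure(list(), class = "regulatory_rules"),
       rules_one = parse_rules(net = net, text = "R7r = NOT(1R9)"),
       rules_full = parse_rules(net = net, text = "R7r = NOT(fR9)"))
}

#' Synthetic reordering example
#'
#' A kernel fixture for the rule-aware row reordering: 17 extended
#' reactions (12 original, 5 reversible) whose rows reproduce the
#' prescribed sign-pattern counts -- a 12-row nonnegative block and a tail
#' with adjacency-candidate counts R11f:2, R5:4, R1:6, R2:6, R4f:12 --
#' together with the rule `R1 = NOT(fR5)`.  The kernel entries are
#' synthetic; only the sign patterns (which drive the ordering) are
#' meaningful, so the fixture is not tied to any stoichiometry.
#'
#' @return a list with `net`, `ext`, `kernel` (rows in initial extended
#'   order), and `rules`.
#' @export
reorder_example <- function() {
  rxn <- paste0("R", 1:12)
  reversible <- rxn %in% c("R4", "R6", "R7", "R11", "R12")
  net <- metabolic_network("X", rxn, reversible,
                           S = matrix(1, 1, 12))
  ext <- split_reversibles(net)
  # initial extended order: R1 R2 R3 R4f R4b R5 R6f R6b R7f R7b R8 R9 R10
  #                         R11f R11b R12f R12b
  sign_rows <- list(
    R1   = c(-1, -1,  1,  1,  1,  0,  0),   # 2 neg x 3 pos = 6
    R2   = c( 1, -1, -1,  1,  1,  0,  0),   # 6
    R3   = c( 1,  0,  0,  0,  0,  0,  0),
    R4f  = c(-1, -1, -1,  1,  1,  1,  1),   # 12
    R4b  = c( 1,  1,  0,  0,  0,  0,  0),
    R5   = c(-1, -1,  1,  1,  0,  0,  0),   # 4
    R6f  = c( 1,  0,  1,  0,  0,  0,  0),
    R6b  = c( 0,  1,  0,  0,  0,  0,  0),
    R7f  = c( 0,  0,  1,  1,  0,  0,  0),
    R7b  = c( 0,  0,  0,  1,  0,  0,  0),
    R8   = c( 1,  1,  0,  0,  0,  0,  0),
    R9   = c( 0,  1,  1,  0,  0,  0,  0),
    R10  = c( 0,  0,  0,  0,  1,  1,  0),
    R11f = c(-1,  1,  1,  0,  0,  0,  0),   # 1 neg x 2 pos = 2
    R11b = c( 1,  0,  0,  1,  0,  0,  0),
    R12f = c( 0,  0,  1,  1,  0,  0,  0),
    R12b = c( 0,  1,  1,  0,  0,  0,  0))
  stopifnot(identical(names(sign_rows), ext$ext_ids))
  K <- rat(do.call(rbind, sign_rows))
  K <- new_rat(matrix(K$num, nrow = 17), matrix(K$den, nrow = 17))
  list(net = net, ext = ext,
       kernel = kernel_matrix(K, ext$ext_ids),
       rules = parse_rules(net = net, text = "R1 = (!fR5)"))
}
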