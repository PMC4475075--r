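# Independent validation machinery: an exhaustive brute-force EFM
# enumerator (algorithmically unrelated to the double description engine)
# and seeded random generators for networks and rule sets, so every
# cross-check runs self-contained.

#' Brute-force EFM enumeration by exhaustive support search
#'
#' For every candidate support (subset of extended reaction columns) the
#' nullspace of the restricted stoichiometric matrix is computed exactly;
#' the support is an EFM iff that space is one-dimensional with a
#' representative that is nonzero on the whole support and sign-consistent
#' (scalable to all-nonnegative).  Futile 2-cycles are dropped and split
#' reactions merged, as in the main pipeline.  This is deliberately an
#' enumeration-plus-rank-test, not a second double description
#' implementation, so agreement with [ddm_run()] is a meaningful check.
#'
#' @param ext an extended network with at most `max_reactions` columns.
#' @param max_reactions refuse larger inputs (exhaustive search).
#' @return list of EFMs; each element has `support` (character vector of
#'   active original reaction ids) and `flux` (named `rat` vector over the
#'   original reactions, forward minus backward for reversibles).
#' @export
brute_force_efms <- function(ext, max_reactions = 16L) {
  stopifnot(inherits(ext, "extended_network"))
  n <- length(ext$ext_ids)
  if (n > max_reactions)
    stop("refusing exhaustive enumeration over ", n,
         " extended reactions (cap ", max_reactions, ")", call. = FALSE)
  found <- list()       # integer index vectors of extended supports
  fluxes <- list()      # rat extended flux vectors
  for (size in seq_len(n)) {
    combos <- utils::combn(n, size)
    for (ci in seq_len(ncol(combos))) {
      idx <- combos[, ci]
      is_super <- any(vapply(found, function(f) all(f %in% idx), TRUE))
      if (is_super) next
      ns <- rat_nullspace(ext$S_ext[, idx, drop = FALSE])
      if (ncol(ns$num) != 1) next
      v <- ns$num[, 1]
      if (any(v == 0)) next
      if (v[1] < 0) { ns <- -ns; v <- -v }
      if (any(v < 0)) next
      found[[length(found) + 1L]] <- idx
      fluxes[[length(fluxes) + 1L]] <- new_rat(ns$num[, 1], ns$den[, 1])
    }
  }
  # drop futile 2-cycles, merge split columns, deduplicate merged supports
  futile <- lapply(ext$base$reaction_ids[ext$base$reversible], function(id)
    sort(match(ext$col_map[[id]], ext$ext_ids)))
  out <- list()
  seen <- character(0)
  ids <- ext$base$reaction_ids
  for (k in seq_along(found)) {
    idx <- found[[k]]
    if (any(vapply(futile, function(f) identical(sort(idx), f), TRUE))) next
    flux <- rat(numeric(length(ids)))
    for (i in seq_along(ids)) {
      cols <- match(ext$col_map[[ids[i]]], ext$ext_ids)
      val <- rat(0)
      sgn <- c(1, -1)
      for (ck in seq_along(cols)) {
        pos <- match(cols[ck], idx)
        if (!is.na(pos)) val <- val + fluxes[[k]][pos] * rat(sgn[ck])
      }
      flux[i] <- val
    }
    names(flux$num) <- ids
    support <- ids[flux$num != 0]
    key <- paste(sort(support), collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- list(support = support, flux = flux)
  }
  out
}

# Canonical support keys of a brute-force result or binary_efms matrix.
efm_support_keys <- function(x) {
  if (is.matrix(x)) {
    keys <- apply(x != 0, 2, function(b)
      paste(sort(rownames(x)[b]), collapse = ","))
  } else {
    keys <- vapply(x, function(e) paste(sort(e$support), collapse = ","), "")
  }
  sort(unique(keys))
}

#' Filter brute-force EFMs by regulatory rules
#'
#' Post-hoc application of the full rule set to an unfiltered enumeration:
#' the reference behaviour the pattern-pruned iteration must reproduce.
#'
#' @param efms result of [brute_force_efms()].
#' @param rules a `regulatory_rules` list.
#' @param reaction_ids all original reaction ids (for the assignment).
#' @return the filtered list.
#' @export
filter_efms_by_rules <- function(efms, rules, reaction_ids) {
  if (length(rules) == 0) return(efms)
  Filter(function(e) {
    assignment <- stats::setNames(reaction_ids %in% e$support, reaction_ids)
    !any(vapply(rules, rule_violated, TRUE, assignment = assignment))
  }, efms)
}

#' Generate a random metabolic network
#'
#' Builds a connected toy network: an uptake reaction, a linear conversion
#' backbone covering every metabolite, a secretion reaction, and random
#' extra conversions with coefficients from `coef_pool`.  The backbone
#' guarantees no all-zero row or column and (since the rank is at most the
#' metabolite count) a nontrivial nullspace.  A fixed seed gives a
#' bit-reproducible network.
#'
#' @param n_metabolites,n_reactions network size; `n_reactions` must exceed
#'   `n_metabolites`.
#' @param reversible_fraction fraction of reactions flagged reversible
#'   (count = `round(fraction * n_reactions)`).
#' @param coef_pool positive integers to draw stoichiometric coefficients
#'   from.
#' @param seed RNG seed.
#' @return a [metabolic_network()].
#' @export
generate_network <- function(n_metabolites, n_reactions,
                             reversible_fraction = 0.2,
                             coef_pool = c(1, 2), seed = 1) {
  if (n_metabolites < 1 || n_reactions <= n_metabolites)
    stop("infeasible config: need n_reactions > n_metabolites >= 1",
         call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  m <- n_metabolites
  S <- matrix(0, m, n_reactions)
  # uptake -> backbone -> secretion
  S[1, 1] <- 1
  j <- 1L
  for (i in seq_len(m - 1)) {
    j <- j + 1L
    if (j > n_reactions - 1) break
    S[i, j] <- -sample(coef_pool, 1)
    S[i + 1, j] <- sample(coef_pool, 1)
  }
  S[m, j + 1] <- -1
  extra <- seq.int(j + 2, length.out = n_reactions - j - 1)
  for (e in extra) {
    repeat {
      a <- sample(m, 1)
      b <- sample(m, 1)
      if (a != b) break
    }
    S[a, e] <- -sample(coef_pool, 1)
    S[b, e] <- sample(coef_pool, 1)
  }
  n_rev <- round(reversible_fraction * n_reactions)
  reversible <- rep(FALSE, n_reactions)
  if (n_rev > 0) reversible[sample(n_reactions, n_rev)] <- TRUE
  metabolic_network(paste0("M", seq_len(m)), paste0("R", seq_len(n_reactions)),
                    reversible, S)
}

#' Generate a random rule set
#'
#' Rules of the form `X = NOT(aY)` with random activity `a` in `{1, f}` and
#' distinct reactions `X`, `Y`; every generated rule classifies as an
#' iteration-phase rule.
#'
#' @param net a [metabolic_network()].
#' @param n_rules number of rules.
#' @param seed RNG seed.
#' @return a `regulatory_rules` list (empty for `n_rules = 0`).
#' @export
generate_rules <- function(net, n_rules, seed = 1) {
  if (n_rules == 0)
    return(structure(list(), class = "regulatory_rules"))
  if (length(net$reaction_ids) < 2)
    stop("need at least two reactions to form a rule", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  lines <- character(n_rules)
  for (k in seq_len(n_rules)) {
    pair <- sample(net$reaction_ids, 2)
    act <- sample(c("1", "f"), 1)
    lines[k] <- paste0(pair[1], " = NOT(", act, pair[2], ")")
  }
  parse_rules(net = net, text = lines)
}
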