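# End-to-end enumeration: split, kernel, order, iterate with rule pruning,
# post-process, recover numeric fluxes; plus the rule-subset sweep.

#' Enumerate the regulation-constrained EFMs of a network
#'
#' Runs the complete pipeline in memory: split reversibles, compute (or
#' take) the kernel, order its rows, iterate the binary double description
#' method with compiled iteration-phase rule patterns, remove futile
#' 2-cycles, merge split reactions, apply all rules in post-processing,
#' and optionally recover the exact numeric flux vectors.
#'
#' @param net a [metabolic_network()].
#' @param rules a `regulatory_rules` list (default: none).
#' @param kernel optional pre-computed `kernel_matrix` (rows in any order);
#'   by default the kernel is computed from the network.
#' @param rule_sort move rule-involved kernel rows forward ([order_rows()]).
#' @param numeric_fluxes recover exact flux vectors for the final EFMs?
#' @param normalize scale each recovered flux to unit maximum magnitude?
#' @return a list of class `"efm_result"`:
#'   `efms` (binary matrix, original reactions x EFMs, columns in
#'   lexicographic support order), `fluxes` (list of `rat` vectors or
#'   `NULL`), `stats` (per-iteration data frame), and `counts` (named
#'   vector: `initial_modes`, `removed_iteration`, `modes_after_iteration`,
#'   `futile_removed`, `post_removed`, `final_efms`).
#' @export
enumerate_efms <- function(net, rules = NULL, kernel = NULL,
                           rule_sort = FALSE, numeric_fluxes = TRUE,
                           normalize = TRUE) {
  stopifnot(inherits(net, "metabolic_network"))
  if (is.null(rules)) rules <- structure(list(), class = "regulatory_rules")
  ext <- split_reversibles(net)
  K <- if (is.null(kernel)) compute_kernel(ext) else kernel
  if (!setequal(K$row_ids, ext$ext_ids))
    stop("kernel rows do not match the extended reactions", call. = FALSE)
  K <- order_rows(K, rules = rules, rule_sort = rule_sort, ext = ext)
  R0 <- init_mode_matrix(K)
  patterns <- compile_patterns(rules, ext)
  run <- ddm_run(R0, patterns)
  n_after_iter <- n_modes(run$R)
  R_nf <- remove_futile_cycles(run$R, ext)
  futile_removed <- n_after_iter - n_modes(R_nf)
  efms <- merge_reversibles(R_nf, ext)
  efms <- apply_post_rules(efms, rules)
  post_removed <- attr(efms, "removed")
  ord <- order(apply(efms, 2, function(b) paste(as.integer(b), collapse = "")))
  efms <- efms[, ord, drop = FALSE]
  class(efms) <- c("binary_efms", "matrix")
  fluxes <- NULL
  if (numeric_fluxes && ncol(efms) > 0) {
    fluxes <- lapply(seq_len(ncol(efms)), function(k) {
      f <- recover_numeric(efms[, k], K, ext)
      if (normalize) normalize_flux(f) else f
    })
  }
  counts <- c(initial_modes = ncol(K$K$num),
              removed_iteration = run$initial_removed +
                sum(run$stats$removed_infeasible),
              modes_after_iteration = n_after_iter,
              futile_removed = futile_removed,
              post_removed = post_removed,
              final_efms = ncol(efms))
  structure(list(efms = efms, fluxes = fluxes, stats = run$stats,
                 counts = counts, rules = rules, ext = ext, kernel = K),
            class = "efm_result")
}

#' @export
print.efm_result <- function(x, ...) {
  cat("EFM enumeration:", x$counts[["final_efms"]], "feasible EFMs\n")
  cat("  initial modes:          ", x$counts[["initial_modes"]], "\n")
  cat("  removed by rules (iter):", x$counts[["removed_iteration"]], "\n")
  cat("  modes after iteration:  ", x$counts[["modes_after_iteration"]], "\n")
  cat("  futile 2-cycles removed:", x$counts[["futile_removed"]], "\n")
  cat("  removed by rules (post):", x$counts[["post_removed"]], "\n")
  invisible(x)
}

#' Run the pipeline against files and write all artifacts
#'
#' File-level front end of [enumerate_efms()]: reads the network (and
#' optionally a kernel and a rule file), enumerates, and writes the binary
#' EFM tsv, the numeric EFM tsv, the per-iteration statistics tsv, the
#' activity-frequency tsv, and a JSON run manifest into `out_dir`.  On any
#' error, partial outputs are removed and the error is propagated.
#'
#' @param network path to the network file.
#' @param format network format passed to [read_network()].
#' @param kernel optional kernel tsv path ([load_kernel()]).
#' @param generule optional regulatory rule file path.
#' @param rulesort rule-aware row reordering flag.
#' @param out_dir output directory (created if missing).
#' @param numeric_fluxes,normalize as in [enumerate_efms()].
#' @param digits decimal places in the numeric output.
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(network, format = "auto", kernel = NULL,
                         generule = NULL, rulesort = FALSE,
                         out_dir = ".", numeric_fluxes = TRUE,
                         normalize = TRUE, digits = 4) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- file.path(out_dir, c("efms_binary.tsv", "efms_numeric.tsv",
                                  "iteration_stats.tsv",
                                  "activity_frequencies.tsv",
                                  "manifest.json"))
  ok <- FALSE
  on.exit(if (!ok) unlink(outputs))
  net <- read_network(network, format)
  ext <- split_reversibles(net)
  K <- if (!is.null(kernel)) load_kernel(kernel, ext) else NULL
  rules <- if (!is.null(generule)) parse_rules(generule, net) else NULL
  res <- enumerate_efms(net, rules = rules, kernel = K,
                        rule_sort = rulesort,
                        numeric_fluxes = numeric_fluxes,
                        normalize = normalize)
  write_binary_efms(res$efms, outputs[1])
  if (!is.null(res$fluxes))
    write_numeric_efms(res$fluxes, outputs[2], digits = digits)
  utils::write.table(res$stats, outputs[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (ncol(res$efms) > 0) {
    af <- activity_frequencies(res$efms)
    utils::write.table(data.frame(reaction = names(af),
                                  activity_pct = sprintf("%.2f", af)),
                       outputs[4], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  rule_class <- if (is.null(rules)) character(0) else
    vapply(rules, classify_rule, "")
  manifest <- list(
    inputs = list(network = network, kernel = kernel, generule = generule,
                  rulesort = rulesort),
    rules = if (is.null(rules)) list() else
      stats::setNames(as.list(rule_class), vapply(rules, `[[`, "", "id")),
    counts = as.list(res$counts))
  jsonlite::write_json(manifest, outputs[5], auto_unbox = TRUE, pretty = TRUE)
  ok <- TRUE
  invisible(manifest)
}

#' Sweep all subsets of a rule set
#'
#' Re-runs the enumeration for every subset of the supplied rules and
#' tabulates the final EFM count, the total number of rule-removed modes,
#' and the iteration count, plus per-cardinality averages.  EFM counts are
#' non-increasing as rule subsets grow.
#'
#' @param net a [metabolic_network()].
#' @param rules a `regulatory_rules` list, at most `max_rules` long.
#' @param kernel optional `kernel_matrix`.
#' @param max_rules refuse sweeps beyond `2^max_rules` runs.
#' @return a list with `runs` (one row per subset: `subset`, `n_rules`,
#'   `final_efms`, `total_removed`, `iterations`) and `by_cardinality`
#'   (mean final EFM count per subset size).
#' @export
rule_subset_sweep <- function(net, rules, kernel = NULL, max_rules = 12L) {
  n <- length(rules)
  if (n > max_rules)
    stop("refusing sweep over 2^", n, " rule subsets", call. = FALSE)
  rows <- list()
  for (mask in 0:(2^n - 1)) {
    take <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    sub <- structure(rules[take], class = "regulatory_rules")
    res <- enumerate_efms(net, rules = sub, kernel = kernel,
                          numeric_fluxes = FALSE)
    rows[[mask + 1]] <- data.frame(
      subset = paste(vapply(sub, `[[`, "", "id"), collapse = "+"),
      n_rules = length(take),
      final_efms = unname(res$counts["final_efms"]),
      total_removed = unname(res$counts["removed_iteration"] +
                               res$counts["post_removed"]),
      iterations = nrow(res$stats))
  }
  runs <- do.call(rbind, rows)
  by_card <- stats::aggregate(final_efms ~ n_rules, runs, mean)
  names(by_card)[2] <- "mean_final_efms"
  list(runs = runs, by_cardinality = by_card)
}
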