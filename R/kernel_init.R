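# Initial mode matrix: exact kernel of the extended stoichiometric matrix,
# row ordering for the iteration phase (including the rule-aware resort),
# and binarization of the rows that are already sign-definite.

kernel_matrix <- function(K, row_ids, n_binarizable = NA_integer_) {
  stopifnot(inherits(K, "rat"), nrow(K$num) == length(row_ids))
  structure(list(K = K, row_ids = as.character(row_ids),
                 n_binarizable = n_binarizable),
            class = "kernel_matrix")
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat("Kernel matrix:", nrow(x$K$num), "extended reactions x",
      ncol(x$K$num), "basis vectors")
  if (!is.na(x$n_binarizable))
    cat(";", x$n_binarizable, "leading rows binarizable")
  cat("\n")
  invisible(x)
}

#' Compute the kernel of the extended stoichiometric matrix
#'
#' Exact rational basis of the right nullspace of `S_ext`, computed by
#' Gauss-Jordan elimination with a fixed first-nonzero pivot rule, so the
#' basis is deterministic for a given input.  The columns of the kernel are
#' the initial intermediate modes of the double description iteration.
#'
#' @param ext an [split_reversibles()] extended network.
#' @return a `kernel_matrix` (rows = extended reactions in network order).
#'   A zero-dimensional nullspace yields a kernel with zero columns and a
#'   warning: no steady-state flux is possible.
#' @export
compute_kernel <- function(ext) {
  stopifnot(inherits(ext, "extended_network"))
  K <- rat_nullspace(ext$S_ext)
  if (ncol(K$num) == 0)
    warning("nullspace has dimension 0: no steady-state flux possible")
  kernel_matrix(K, ext$ext_ids)
}

#' Load a pre-computed kernel matrix from tsv
#'
#' A nullspace basis is not unique, so reproducing a published worked
#' example bit-exactly requires starting from the published kernel.  The
#' file layout is one row per extended reaction: the reaction id followed
#' by the rational basis entries.
#'
#' @param path kernel tsv path.
#' @param ext the matching extended network, or `NULL` to accept the kernel
#'   unvalidated (with a warning).
#' @return a `kernel_matrix` with rows in file order.
#' @export
load_kernel <- function(path, ext = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  rows <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(rows, `[`, "", 1)
  widths <- lengths(rows) - 1L
  if (length(unique(widths)) != 1)
    stop("ragged kernel file: unequal column counts", call. = FALSE)
  v <- rat_parse(unlist(lapply(rows, `[`, -1)))
  K <- new_rat(matrix(v$num, nrow = length(ids), byrow = TRUE),
               matrix(v$den, nrow = length(ids), byrow = TRUE))
  if (is.null(ext)) {
    warning("no extended network supplied; kernel accepted unvalidated")
  } else {
    if (!setequal(ids, ext$ext_ids) || anyDuplicated(ids))
      stop("kernel row labels do not match the extended reactions",
           call. = FALSE)
    Kord <- K[match(ext$ext_ids, ids), , drop = FALSE]
    prod <- rat_mm(ext$S_ext, Kord)
    if (any(prod$num != 0))
      stop("kernel validation failed: S_ext K != 0", call. = FALSE)
  }
  kernel_matrix(K, ids)
}

#' Write a kernel matrix as tsv
#' @param K a `kernel_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_kernel <- function(K, path) {
  fm <- format(K$K)
  writeLines(vapply(seq_along(K$row_ids), function(i)
    paste(c(K$row_ids[i], fm[i, ]), collapse = "\t"), ""), path)
  invisible(path)
}

#' Potential adjacency candidates of a kernel row
#'
#' The number of negative entries times the number of positive entries:
#' the count of mode pairs that would have to be tested for adjacency if
#' this row were the next to be converted to binary form.  Used to order
#' the numeric rows of the initial mode matrix.
#'
#' @param row a `rat` vector or numeric vector.
#' @return a single count.
#' @export
count_adjacency_candidates <- function(row) {
  v <- if (inherits(row, "rat")) rat_sign(row) else sign(row)
  sum(v < 0) * sum(v > 0)
}

#' Order the kernel rows for the iteration phase
#'
#' Rows without negative entries come first (they can be binarized before
#' the iteration starts); the remaining rows are sorted by increasing
#' adjacency-candidate count, ties broken by the incoming row position
#' (stable).  With `rule_sort = TRUE`, rows belonging to reactions that
#' appear in any regulatory rule are moved directly behind the nonnegative
#' block, keeping their candidate-sorted relative order, so that
#' iteration-phase rules start pruning as early as possible.  Rows already
#' inside the nonnegative block are never moved.
#'
#' @param K a `kernel_matrix`.
#' @param rules a list of parsed rules (see [parse_rules()]), or `NULL`.
#' @param rule_sort move rule-involved rows forward?
#' @param ext the extended network; required when `rule_sort = TRUE` to map
#'   original reaction ids in rules to extended columns.
#' @return the reordered `kernel_matrix` with `n_binarizable` set.
#' @export
order_rows <- function(K, rules = NULL, rule_sort = FALSE, ext = NULL) {
  stopifnot(inherits(K, "kernel_matrix"))
  n <- nrow(K$K$num)
  nonneg <- vapply(seq_len(n), function(i) all(K$K$num[i, ] >= 0), TRUE)
  head_idx <- which(nonneg)
  tail_idx <- which(!nonneg)
  cand <- vapply(tail_idx, function(i)
    count_adjacency_candidates(K$K[i, , drop = FALSE]), 0)
  tail_idx <- tail_idx[order(cand)]   # stable: ties keep row position
  if (rule_sort && length(rules) > 0) {
    if (is.null(ext))
      stop("rule_sort requires the extended network", call. = FALSE)
    involved <- unique(unlist(lapply(rules, rule_reactions)))
    involved_ext <- unlist(ext$col_map[involved], use.names = FALSE)
    is_rule_row <- K$row_ids[tail_idx] %in% involved_ext
    tail_idx <- c(tail_idx[is_rule_row], tail_idx[!is_rule_row])
  }
  ord <- c(head_idx, tail_idx)
  kernel_matrix(K$K[ord, , drop = FALSE], K$row_ids[ord],
                n_binarizable = length(head_idx))
}

#' Initial mode matrix
#'
#' Converts the ordered kernel into the hybrid mode representation: the
#' leading sign-definite rows become the binary support prefix (bit set iff
#' the entry is nonzero), the remaining rows stay as an exact numeric tail
#' to be converted one per iteration step.
#'
#' @param K an [order_rows()]-ordered `kernel_matrix`.
#' @return an object of class `"mode_matrix"` with elements `bin` (logical
#'   matrix, binarized rows x modes), `tail` (`rat` matrix, pending rows x
#'   modes), `binarized` and `pending` (extended reaction ids).
#' @export
init_mode_matrix <- function(K) {
  stopifnot(inherits(K, "kernel_matrix"))
  if (is.na(K$n_binarizable))
    stop("kernel rows are not ordered; call order_rows() first", call. = FALSE)
  nb <- K$n_binarizable
  n <- nrow(K$K$num)
  m <- ncol(K$K$num)
  bin <- matrix(K$K$num[seq_len(nb), , drop = FALSE] != 0, nrow = nb,
                ncol = m, dimnames = list(K$row_ids[seq_len(nb)], NULL))
  tail_rows <- if (nb < n) seq.int(nb + 1L, n) else integer(0)
  mode_matrix(bin,
              K$K[tail_rows, , drop = FALSE],
              binarized = K$row_ids[seq_len(nb)],
              pending = K$row_ids[tail_rows])
}
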