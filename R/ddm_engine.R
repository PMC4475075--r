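# The binary double description iteration.
#
# Intermediate modes are columns of a hybrid matrix: a logical support
# prefix over the already-binarized extended reactions plus an exact
# rational tail over the rows still to be converted.  Each iteration
# converts the first pending row: nonnegative modes survive, negative x
# positive pairs passing the adjacency test spawn children (support =
# bitwise OR), and modes whose support contains an iteration-phase rule
# pattern are eliminated on the spot.

mode_matrix <- function(bin, tail, binarized, pending) {
  stopifnot(is.logical(bin), inherits(tail, "rat"))
  if (ncol(bin) != ncol(tail$num))
    stop("binary part and numeric tail disagree on mode count", call. = FALSE)
  rownames(bin) <- binarized
  structure(list(bin = bin, tail = tail,
                 binarized = as.character(binarized),
                 pending = as.character(pending)),
            class = "mode_matrix")
}

#' @export
print.mode_matrix <- function(x, ...) {
  cat("Mode matrix:", ncol(x$bin), "modes;", length(x$binarized),
      "binarized +", length(x$pending), "pending rows\n")
  invisible(x)
}

n_modes <- function(R) ncol(R$bin)

# Supports of fully binary modes as a character vector of sorted
# comma-joined extended reaction ids (canonical, order-independent).
mode_supports <- function(R) {
  if (length(R$pending) > 0)
    stop("mode matrix still has numeric rows", call. = FALSE)
  apply(R$bin, 2, function(b) paste(sort(R$binarized[b]), collapse = ","))
}

#' Combine two adjacent modes
#'
#' The child of a positive and a negative parent at the current pivot row:
#' its support is the bitwise OR of the parents' supports, and each tail
#' entry is the weighted subtraction
#' `(v1+ vr- - v1- vr+) / (v1+ - v1-)`,
#' where `v1+`/`v1-` are the parents' pivot entries.  By construction the
#' child's pivot entry is exactly zero.
#'
#' @param m_pos,m_neg modes as lists with elements `support` (logical) and
#'   `tail` (`rat` vector, pivot first).
#' @param pivot index of the pivot row within the tail (default 1, the row
#'   being converted).
#' @return a mode list with the combined support and the full-length child
#'   tail (pivot entry zero).
#' @export
combine_modes <- function(m_pos, m_neg, pivot = 1L) {
  v_pos <- m_pos$tail[pivot]
  v_neg <- m_neg$tail[pivot]
  if (!(v_pos$num > 0) || !(v_neg$num < 0))
    stop("combine requires a positive and a negative pivot entry",
         call. = FALSE)
  child_tail <- (m_neg$tail * v_pos - m_pos$tail * v_neg) / (v_pos - v_neg)
  list(support = m_pos$support | m_neg$support, tail = child_tail)
}

#' Adjacency test
#'
#' Two parent modes are adjacent (their child is an extreme ray and may be
#' kept) iff the child's support is not a superset of any existing mode's
#' support other than the two parents'.  Superset includes equality.
#'
#' @param candidate_support logical vector: the OR of the parents' supports.
#' @param keep logical matrix of existing supports (rows = binarized
#'   reactions, columns = modes).
#' @param parents column indices of the two parents within `keep`.
#' @return `TRUE` iff the candidate passes.
#' @export
adjacency_test <- function(candidate_support, keep, parents = integer(0)) {
  others <- setdiff(seq_len(ncol(keep)), parents)
  for (k in others) {
    if (!any(keep[, k] & !candidate_support)) return(FALSE)
  }
  TRUE
}

# Which modes survive the compiled rule patterns?  A pattern applies only
# once all its reactions are binarized; a mode dies if every pattern bit is
# set in its support.
.pattern_keep <- function(bin, patterns) {
  keep <- rep(TRUE, ncol(bin))
  if (length(patterns) == 0 || ncol(bin) == 0) return(keep)
  rows <- rownames(bin)
  for (p in patterns) {
    idx <- match(p$ext_ids, rows)
    if (anyNA(idx)) next  # involves a not-yet-binarized reaction
    keep <- keep & colSums(!bin[idx, , drop = FALSE]) > 0
  }
  keep
}

#' One iteration step of the binary double description method
#'
#' Converts the first pending row to binary form: zero and positive modes
#' are kept (support bit 0 / 1), every negative x positive pair passing the
#' adjacency test appends a child (support bit 0), negative modes are
#' discarded.  Compiled rule patterns are then applied to all surviving
#' modes (children included) and matching modes are removed.
#'
#' @param R a `mode_matrix` with at least one pending row.
#' @param patterns compiled patterns from [compile_patterns()].
#' @param iteration_no iteration counter stored in the stats row.
#' @return list with elements `R` (the new `mode_matrix`) and `stats`
#'   (one-row data frame: `iteration`, `removed_infeasible`, `n_modes`,
#'   `adjacency_candidates`).
#' @export
iterate_row <- function(R, patterns = list(), iteration_no = 1L) {
  if (length(R$pending) == 0)
    stop("no pending rows left to convert", call. = FALSE)
  pivot_id <- R$pending[1]
  sgn <- sign(R$tail$num[1, ])
  keep_idx <- which(sgn >= 0)
  neg_idx <- which(sgn < 0)
  pos_idx <- which(sgn > 0)
  n_tail <- length(R$pending)

  new_bin_cols <- list(rbind(R$bin[, keep_idx, drop = FALSE],
                             matrix(sgn[keep_idx] > 0, nrow = 1)))
  new_tail_cols <- list(R$tail[-1, keep_idx, drop = FALSE])
  # children in deterministic (negative-index, positive-index) order
  for (i in neg_idx) {
    for (j in pos_idx) {
      cand <- R$bin[, i] | R$bin[, j]
      if (!adjacency_test(cand, R$bin, parents = c(i, j))) next
      v_neg <- R$tail[1, i]
      v_pos <- R$tail[1, j]
      child_tail <- if (n_tail > 1) {
        (R$tail[-1, i, drop = FALSE] * v_pos -
           R$tail[-1, j, drop = FALSE] * v_neg) / (v_pos - v_neg)
      } else {
        rat_matrix(0, 0, 1)
      }
      new_bin_cols[[length(new_bin_cols) + 1L]] <-
        matrix(c(cand, FALSE), ncol = 1)
      new_tail_cols[[length(new_tail_cols) + 1L]] <- child_tail
    }
  }
  bin <- do.call(cbind, new_bin_cols)
  tail <- do.call(rat_cbind, new_tail_cols)
  binarized <- c(R$binarized, pivot_id)
  rownames(bin) <- binarized
  pre_rule <- ncol(bin)
  keep <- .pattern_keep(bin, patterns)
  bin <- bin[, keep, drop = FALSE]
  tail <- tail[, which(keep), drop = FALSE]
  out <- mode_matrix(bin, tail, binarized, R$pending[-1])
  stats <- data.frame(iteration = iteration_no,
                      removed_infeasible = pre_rule - ncol(bin),
                      n_modes = ncol(bin),
                      adjacency_candidates = length(neg_idx) * length(pos_idx))
  list(R = out, stats = stats)
}

#' Run the binary double description iteration to completion
#'
#' Applies the compiled rule patterns once to the initial matrix, then
#' iterates [iterate_row()] until every mode is fully binary.
#'
#' @param R0 initial `mode_matrix` from [init_mode_matrix()].
#' @param patterns compiled patterns from [compile_patterns()].
#' @return list with `R` (final, fully binary `mode_matrix`), `stats`
#'   (data frame, one row per iteration), and `initial_removed` (modes of
#'   the initial matrix eliminated by patterns before iteration 1).
#' @export
ddm_run <- function(R0, patterns = list()) {
  keep <- .pattern_keep(R0$bin, patterns)
  initial_removed <- sum(!keep)
  R <- mode_matrix(R0$bin[, keep, drop = FALSE],
                   R0$tail[, which(keep), drop = FALSE],
                   R0$binarized, R0$pending)
  stats <- list()
  it <- 0L
  while (length(R$pending) > 0) {
    it <- it + 1L
    step <- iterate_row(R, patterns, iteration_no = it)
    R <- step$R
    stats[[it]] <- step$stats
  }
  stats <- if (length(stats)) do.call(rbind, stats) else
    data.frame(iteration = integer(0), removed_infeasible = integer(0),
               n_modes = integer(0), adjacency_candidates = integer(0))
  list(R = R, stats = stats, initial_removed = initial_removed)
}
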