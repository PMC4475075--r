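# From the final binary mode matrix to the feasible EFM set: futile-cycle
# removal, merging of split reversibles, post-processing rule filtering,
# exact numeric flux recovery, and summary statistics.

#' Remove futile 2-cycles
#'
#' Splitting a reversible reaction creates one artifact mode whose support
#' is exactly the forward+backward pair; it carries a net flux of zero and
#' is removed before merging.
#'
#' @param R a fully binary `mode_matrix`.
#' @param ext the extended network.
#' @return the filtered `mode_matrix`.
#' @export
remove_futile_cycles <- function(R, ext) {
  if (length(R$pending) > 0)
    stop("modes are not fully binary", call. = FALSE)
  futile <- vapply(ext$base$reaction_ids[ext$base$reversible], function(id)
    paste(sort(ext$col_map[[id]]), collapse = ","), "")
  keep <- !(mode_supports(R) %in% futile)
  mode_matrix(R$bin[, keep, drop = FALSE], R$tail[, which(keep), drop = FALSE],
              R$binarized, R$pending)
}

#' Merge split reversible reactions
#'
#' Collapses the extended binary modes back onto the original reactions:
#' a reversible reaction carries flux iff its forward or backward column
#' does (bitwise OR).
#'
#' @param R a fully binary `mode_matrix` (futile cycles removed).
#' @param ext the extended network.
#' @return a logical matrix, original reactions x EFMs (class
#'   `"binary_efms"`).
#' @export
merge_reversibles <- function(R, ext) {
  if (length(R$pending) > 0)
    stop("modes are not fully binary", call. = FALSE)
  ids <- ext$base$reaction_ids
  out <- matrix(FALSE, nrow = length(ids), ncol = ncol(R$bin),
                dimnames = list(ids, NULL))
  for (id in ids) {
    idx <- match(ext$col_map[[id]], R$binarized)
    out[id, ] <- colSums(R$bin[idx, , drop = FALSE]) > 0
  }
  structure(out, class = c("binary_efms", "matrix"))
}

#' Apply post-processing rules
#'
#' Removes every EFM whose (merged) flux assignment violates any rule under
#' three-valued evaluation.  This is where rule branches that involve
#' inactive reactions take effect: they can only be checked once a mode is
#' final, because an inactive reaction may still become active in a child.
#'
#' @param efms a `binary_efms` matrix.
#' @param rules a `regulatory_rules` list (may be empty).
#' @return the filtered matrix; the number of removed EFMs is available as
#'   `attr(, "removed")`.
#' @export
apply_post_rules <- function(efms, rules = list()) {
  if (length(rules) == 0) {
    attr(efms, "removed") <- 0L
    return(efms)
  }
  ids <- rownames(efms)
  keep <- vapply(seq_len(ncol(efms)), function(k) {
    assignment <- stats::setNames(efms[, k], ids)
    !any(vapply(rules, rule_violated, TRUE, assignment = assignment))
  }, TRUE)
  out <- efms[, keep, drop = FALSE]
  class(out) <- c("binary_efms", "matrix")
  attr(out, "removed") <- sum(!keep)
  out
}

#' Recover the numeric flux vector of a binary EFM
#'
#' The rows of the kernel belonging to the reactions *inactive* in the mode
#' span the constraints the numeric mode must annihilate: solving that
#' homogeneous system yields a one-dimensional coefficient space, and the
#' kernel times the solution is the flux vector.  For an active reversible
#' reaction the flux direction is not stored in the merged support, so the
#' directions are tried (forward first) until the one-dimensional,
#' sign-consistent solution appears.  Alternatively (`method =
#' "stoichiometry"`) the nullspace of `S_ext` restricted to the active
#' columns is used; both routes give the same ray.
#'
#' @param support logical vector over original reactions (a `binary_efms`
#'   column), or a character vector of active reaction ids.
#' @param K a `kernel_matrix` of the extended network.
#' @param ext the extended network.
#' @param method `"kernel"` (default) or `"stoichiometry"`.
#' @return exact rational flux vector over the original reactions (named);
#'   reversible entries are forward minus backward.
#' @export
recover_numeric <- function(support, K, ext, method = c("kernel", "stoichiometry")) {
  method <- match.arg(method)
  ids <- ext$base$reaction_ids
  if (is.character(support)) support <- ids %in% support
  stopifnot(length(support) == length(ids))
  active <- ids[support]
  active_rev <- active[ext$base$reversible[match(active, ids)]]
  # direction alternatives for active reversibles, forward tried first
  alt <- lapply(active_rev, function(id) ext$col_map[[id]])
  grids <- if (length(alt)) expand.grid(alt, stringsAsFactors = FALSE) else
    data.frame(row.names = 1)
  fixed_ext <- unlist(ext$col_map[setdiff(active, active_rev)], use.names = FALSE)
  for (g in seq_len(nrow(grids))) {
    active_ext <- c(fixed_ext, unname(unlist(grids[g, ])))
    sol <- .recover_for_support(active_ext, K, ext, method)
    if (!is.null(sol)) {
      flux <- rat(numeric(length(ids)))
      for (i in seq_along(ids)) {
        cols <- ext$col_map[[ids[i]]]
        if (length(cols) == 2) {
          flux[i] <- sol[match(cols[1], ext$ext_ids)] -
            sol[match(cols[2], ext$ext_ids)]
        } else {
          flux[i] <- sol[match(cols, ext$ext_ids)]
        }
      }
      names(flux$num) <- ids
      return(flux)
    }
  }
  stop("support is not elementary: no 1-dimensional sign-consistent ",
       "solution exists", call. = FALSE)
}

# Solve for the extended flux vector of one direction assignment; NULL if
# the solution space is not 1-dimensional or not sign-consistent.
.recover_for_support <- function(active_ext, K, ext, method) {
  all_ext <- ext$ext_ids
  inactive <- setdiff(all_ext, active_ext)
  if (method == "kernel") {
    Z <- K$K[match(inactive, K$row_ids), , drop = FALSE]
    cs <- rat_nullspace(Z)
    if (ncol(cs$num) != 1) return(NULL)
    sol_rows <- rat_mm(K$K, cs)
    sol <- sol_rows[match(all_ext, K$row_ids), 1, drop = FALSE]
  } else {
    idx <- match(active_ext, all_ext)
    ns <- rat_nullspace(ext$S_ext[, idx, drop = FALSE])
    if (ncol(ns$num) != 1) return(NULL)
    sol <- rat(numeric(length(all_ext)))
    sol <- new_rat(matrix(sol$num, ncol = 1), matrix(sol$den, ncol = 1))
    for (k in seq_along(idx)) sol[idx[k], 1] <- ns[k, 1]
  }
  v <- sol$num[, 1]
  nz <- which(v != 0)
  if (length(nz) == 0) return(NULL)
  if (v[nz[1]] < 0) { sol <- -sol; v <- -v }
  if (any(v < 0)) return(NULL)
  if (!setequal(all_ext[v != 0], active_ext)) return(NULL)
  sol <- new_rat(sol$num[, 1], sol$den[, 1])
  sol
}

#' Normalize a flux vector to unit maximum
#'
#' Divides by the maximum absolute entry so the largest flux magnitude is
#' exactly 1 (the conventional printed scale for worked examples).
#'
#' @param flux a `rat` or numeric vector, not all zero.
#' @return the scaled vector, same type.
#' @export
normalize_flux <- function(flux) {
  if (inherits(flux, "rat")) {
    a <- abs(flux$num / flux$den)
    if (all(a == 0)) stop("cannot normalize the zero vector", call. = FALSE)
    m <- which.max(a)
    flux / rat_abs(flux[m])
  } else {
    if (all(flux == 0)) stop("cannot normalize the zero vector", call. = FALSE)
    flux / max(abs(flux))
  }
}

#' Reaction activity frequencies
#'
#' For each reaction, the percentage of EFMs in which it carries flux.
#' Comparing the frequencies with and without regulatory rules shows how
#' regulation propagates through the network structure.
#'
#' @param efms a `binary_efms` matrix (original reactions x EFMs).
#' @return named numeric vector of percentages in `[0, 100]`.
#' @export
activity_frequencies <- function(efms) {
  if (ncol(efms) == 0) stop("no EFMs: frequencies undefined", call. = FALSE)
  100 * rowMeans(efms != 0)
}

#' Write binary EFMs as tsv
#' @param efms a `binary_efms` matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_binary_efms <- function(efms, path) {
  m <- matrix(as.integer(efms), nrow = nrow(efms))
  cols <- sprintf("EFM%02d", seq_len(ncol(efms)))
  lines <- c(paste(c("#", cols), collapse = "\t"),
             vapply(seq_len(nrow(efms)), function(i)
               paste(c(rownames(efms)[i], m[i, ]), collapse = "\t"), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Write numeric EFMs as tsv
#' @param fluxes list of `rat` flux vectors (one per EFM, all named by the
#'   same reaction ids).
#' @param path output path.
#' @param digits decimal places for printing.
#' @return `path`, invisibly.
#' @export
write_numeric_efms <- function(fluxes, path, digits = 4) {
  if (length(fluxes) == 0) {
    writeLines("#", path)
    return(invisible(path))
  }
  ids <- names(fluxes[[1]]$num)
  cols <- sprintf("EFM%02d", seq_along(fluxes))
  vals <- vapply(fluxes, as.numeric, numeric(length(ids)))
  vals <- matrix(vals, nrow = length(ids))
  lines <- c(paste(c("#", cols), collapse = "\t"),
             vapply(seq_along(ids), function(i)
               paste(c(ids[i], formatC(vals[i, ], digits = digits,
                                       format = "f")), collapse = "\t"), ""))
  writeLines(lines, path)
  invisible(path)
}
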