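# Boolean transcriptional-regulatory rules over reaction flux states.
#
# A rule line reads `OUTPUT = EXPR` with EXPR ::= atom | NOT(EXPR) | !EXPR |
# (EXPR) | EXPR AND EXPR | EXPR OR EXPR.  Atoms are reaction ids optionally
# prefixed with an activity tag: `0X` (defined only when X carries no flux),
# `1X` (defined only when X carries flux), `fX` (always defined; the default
# for unprefixed atoms).  Rules are evaluated in strong three-valued
# (Kleene) logic with states true / false / undefined; a rule whose output
# or expression evaluates to undefined is simply not consulted.

ACT_ZERO <- "zero_active"
ACT_ONE  <- "one_active"
ACT_FULL <- "full_active"

rule_atom <- function(reaction, activity = ACT_FULL)
  list(op = "atom", reaction = reaction, activity = activity)

# All original reaction ids a rule touches (expression inputs + output).
rule_reactions <- function(rule) {
  unique(c(expr_reactions(rule$expr), rule$output$reaction))
}

expr_reactions <- function(expr) {
  switch(expr$op,
         atom = expr$reaction,
         not  = expr_reactions(expr$x),
         unique(c(expr_reactions(expr$lhs), expr_reactions(expr$rhs))))
}

.rule_tokenize <- function(text) {
  pat <- "[A-Za-z0-9_]+|\\(|\\)|!|="
  m <- gregexpr(pat, text)[[1]]
  if (m[1] == -1) return(character(0))
  toks <- regmatches(text, gregexpr(pat, text))[[1]]
  # anything not matched must be whitespace
  residue <- gsub(pat, "", text)
  if (grepl("[^[:space:]]", residue))
    stop("unexpected character(s): '",
         gsub("[[:space:]]", "", residue), "'", call. = FALSE)
  toks
}

.resolve_atom <- function(token, reaction_ids) {
  if (token %in% reaction_ids) return(rule_atom(token, ACT_FULL))
  first <- substr(token, 1, 1)
  rest <- substr(token, 2, nchar(token))
  if (first %in% c("0", "1", "f") && rest %in% reaction_ids) {
    act <- c("0" = ACT_ZERO, "1" = ACT_ONE, "f" = ACT_FULL)[[first]]
    return(rule_atom(rest, act))
  }
  stop("unknown reaction id '", token, "'", call. = FALSE)
}

# Recursive descent parser; precedence OR < AND < NOT.
.parse_expr <- function(toks, pos, reaction_ids) {
  parse_or <- function(pos) {
    r <- parse_and(pos)
    while (r$pos <= length(toks) && toupper(toks[r$pos]) == "OR") {
      rhs <- parse_and(r$pos + 1L)
      r <- list(expr = list(op = "or", lhs = r$expr, rhs = rhs$expr),
                pos = rhs$pos)
    }
    r
  }
  parse_and <- function(pos) {
    r <- parse_unary(pos)
    while (r$pos <= length(toks) && toupper(toks[r$pos]) == "AND") {
      rhs <- parse_unary(r$pos + 1L)
      r <- list(expr = list(op = "and", lhs = r$expr, rhs = rhs$expr),
                pos = rhs$pos)
    }
    r
  }
  parse_unary <- function(pos) {
    if (pos > length(toks)) stop("unexpected end of rule", call. = FALSE)
    tok <- toks[pos]
    if (tok == "!" || toupper(tok) == "NOT") {
      r <- parse_unary(pos + 1L)
      return(list(expr = list(op = "not", x = r$expr), pos = r$pos))
    }
    if (tok == "(") {
      r <- parse_or(pos + 1L)
      if (r$pos > length(toks) || toks[r$pos] != ")")
        stop("missing closing parenthesis", call. = FALSE)
      return(list(expr = r$expr, pos = r$pos + 1L))
    }
    if (tok %in% c(")", "=", "AND", "OR"))
      stop("unexpected token '", tok, "'", call. = FALSE)
    list(expr = .resolve_atom(tok, reaction_ids), pos = pos + 1L)
  }
  parse_or(pos)
}

parse_rule_line <- function(line, reaction_ids, rule_id = "GR1") {
  toks <- .rule_tokenize(line)
  eq <- which(toks == "=")
  if (length(eq) != 1 || eq[1] != 2)
    stop("rule must have the form 'OUTPUT = EXPR'", call. = FALSE)
  output <- .resolve_atom(toks[1], reaction_ids)
  r <- .parse_expr(toks, 3L, reaction_ids)
  if (r$pos <= length(toks))
    stop("trailing tokens after expression: '",
         paste(toks[r$pos:length(toks)], collapse = " "), "'", call. = FALSE)
  structure(list(id = rule_id, output = output, expr = r$expr,
                 source_text = line),
            class = "regulatory_rule")
}

#' Parse a regulatory rule file
#'
#' One rule per non-comment line (`#` starts a comment); rules are named
#' `GR1`, `GR2`, ... in file order.  Multiple rules combine conjunctively:
#' a mode must obey every rule.
#'
#' @param path rule file path, or a character vector of rule lines via
#'   `text`.
#' @param net the [metabolic_network()] whose reaction ids the atoms must
#'   resolve against.
#' @param text optional character vector of rule lines (overrides `path`).
#' @return a list of `regulatory_rule` objects (class `"regulatory_rules"`).
#' @export
parse_rules <- function(path = NULL, net, text = NULL) {
  stopifnot(inherits(net, "metabolic_network"))
  if (is.null(text)) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    text <- readLines(path, encoding = "UTF-8")
  }
  keep <- nzchar(trimws(text)) & !startsWith(trimws(text), "#")
  lines <- trimws(text[keep])
  lineno <- which(keep)
  rules <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    rules[[k]] <- tryCatch(
      parse_rule_line(lines[k], net$reaction_ids, rule_id = paste0("GR", k)),
      error = function(e) stop("rule error at line ", lineno[k], ": ",
                               conditionMessage(e), call. = FALSE))
  }
  if (length(rules) == 0) warning("rule file contains no rules")
  structure(rules, class = "regulatory_rules")
}

#' @export
print.regulatory_rules <- function(x, ...) {
  cat(length(x), "regulatory rule(s)\n")
  for (r in x) {
    cat(" ", r$id, ": ", r$source_text, "  [", classify_rule(r), "]\n",
        sep = "")
  }
  invisible(x)
}

.TRI_TRUE <- "true"; .TRI_FALSE <- "false"; .TRI_UNDEF <- "undefined"

atom_tribool <- function(atom, assignment) {
  bit <- assignment[[atom$reaction]]
  if (is.na(bit)) stop("no flux state for reaction ", atom$reaction,
                       call. = FALSE)
  bit <- as.logical(bit)
  defined <- switch(atom$activity,
                    zero_active = !bit,
                    one_active  = bit,
                    full_active = TRUE)
  if (!defined) .TRI_UNDEF else if (bit) .TRI_TRUE else .TRI_FALSE
}

#' Evaluate a rule expression in three-valued logic
#'
#' Atoms take the flux bit of their reaction when their activity tag makes
#' them defined, and `undefined` otherwise.  Connectives follow strong
#' Kleene semantics: `NOT undefined = undefined`, `undefined AND false =
#' false`, `undefined AND true = undefined`, `undefined OR true = true`,
#' `undefined OR false = undefined`.
#'
#' @param expr an expression tree (from a parsed rule's `$expr`).
#' @param assignment named logical/0-1 vector: original reaction id ->
#'   flux bit.  After merging, a reversible reaction carries flux iff its
#'   forward or backward split column does.
#' @return `"true"`, `"false"`, or `"undefined"`.
#' @export
eval_tribool <- function(expr, assignment) {
  switch(expr$op,
    atom = atom_tribool(expr, assignment),
    not = {
      v <- eval_tribool(expr$x, assignment)
      if (v == .TRI_UNDEF) v else if (v == .TRI_TRUE) .TRI_FALSE else .TRI_TRUE
    },
    and = {
      a <- eval_tribool(expr$lhs, assignment)
      b <- eval_tribool(expr$rhs, assignment)
      if (a == .TRI_FALSE || b == .TRI_FALSE) .TRI_FALSE
      else if (a == .TRI_UNDEF || b == .TRI_UNDEF) .TRI_UNDEF
      else .TRI_TRUE
    },
    or = {
      a <- eval_tribool(expr$lhs, assignment)
      b <- eval_tribool(expr$rhs, assignment)
      if (a == .TRI_TRUE || b == .TRI_TRUE) .TRI_TRUE
      else if (a == .TRI_UNDEF || b == .TRI_UNDEF) .TRI_UNDEF
      else .TRI_FALSE
    },
    stop("unknown expression node: ", expr$op))
}

#' Is a rule violated by a flux assignment?
#'
#' A rule `Ro = B(R1, ..., Rn)` is violated iff the output atom and the
#' expression both evaluate to defined states that disagree.  If either
#' side is undefined the rule is not consulted and nothing is removed.
#'
#' @param rule a parsed `regulatory_rule`.
#' @param assignment as in [eval_tribool()].
#' @return `TRUE` or `FALSE`.
#' @export
rule_violated <- function(rule, assignment) {
  lhs <- atom_tribool(rule$output, assignment)
  if (lhs == .TRI_UNDEF) return(FALSE)
  rhs <- eval_tribool(rule$expr, assignment)
  if (rhs == .TRI_UNDEF) return(FALSE)
  lhs != rhs
}

#' Classify a rule as iteration-phase or post-processing-only
#'
#' A rule qualifies for the iteration phase iff its output must be inactive
#' whenever all its input reactions are active: with every input flux bit
#' set to 1 the expression evaluates to a defined `false`, and the output
#' atom is defined at flux bit 1.  Such a violation is permanent under the
#' bitwise-OR mode combination, so matching intermediate modes can be
#' discarded at any iteration without losing feasible modes.  Every rule,
#' iteration-phase or not, is additionally checked in post-processing.
#'
#' @param rule a parsed `regulatory_rule`.
#' @return `"iteration_phase"` or `"post_only"`.
#' @export
classify_rule <- function(rule) {
  inputs <- expr_reactions(rule$expr)
  assignment <- stats::setNames(rep(TRUE, length(inputs) + 1),
                                c(inputs, rule$output$reaction))
  expr_at_one <- eval_tribool(rule$expr, assignment)
  out_defined <- rule$output$activity %in% c(ACT_ONE, ACT_FULL)
  if (expr_at_one == .TRI_FALSE && out_defined) "iteration_phase" else "post_only"
}

#' Compile iteration-phase rules to bit patterns
#'
#' Each iteration-phase rule becomes one pattern per element of the
#' cartesian product over its involved reactions' extended columns
#' (irreversible reaction: its single column; reversible: forward or
#' backward, since either direction makes the original reaction flux
#' carrying).  A mode whose binary support has every pattern bit set is
#' infeasible and is eliminated.
#'
#' @param rules a `regulatory_rules` list (mixed classes allowed; only
#'   iteration-phase rules are compiled).
#' @param ext the extended network.
#' @return a list of patterns: each has `ext_ids` (extended column ids,
#'   at least two) and `rule_id`.
#' @export
compile_patterns <- function(rules, ext) {
  stopifnot(inherits(ext, "extended_network"))
  patterns <- list()
  for (rule in rules) {
    if (classify_rule(rule) != "iteration_phase") next
    involved <- rule_reactions(rule)
    alts <- lapply(involved, function(id) {
      cols <- ext$col_map[[id]]
      if (is.null(cols)) stop("rule ", rule$id, " names unknown reaction ",
                              id, call. = FALSE)
      cols
    })
    grid <- expand.grid(alts, stringsAsFactors = FALSE)
    for (g in seq_len(nrow(grid))) {
      patterns[[length(patterns) + 1L]] <-
        list(ext_ids = unname(unlist(grid[g, ])), rule_id = rule$id)
    }
  }
  patterns
}
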