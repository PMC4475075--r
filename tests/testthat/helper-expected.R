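# Shared fixtures and frozen expected values for the worked example.

# Reference numeric EFMs of the unregulated worked example, max-abs
# normalized, columns R1..R11 (reversible R7r signed forward minus
# backward).  Row order here is arbitrary; comparisons are set-based.
expected_toy_fluxes <- function() {
  m <- matrix(c(
    0.0, 1, 0, 0.50, 0.0, 0.0, -0.5, 0.5, 0.00, 0.0, 0.0,
    0.0, 1, 0, 0.25, 0.5, 0.0, -0.5, 0.0, 0.25, 0.0, 0.5,
    0.0, 1, 0, 0.25, 0.0, 0.5, -1.0, 0.0, 0.25, 0.5, 0.0,
    0.0, 0, 1, 0.50, 0.0, 1.0, -1.0, 0.0, 0.50, 1.0, 0.0,
    0.5, 1, 0, 1.00, 0.0, 0.0,  0.0, 1.0, 0.00, 0.0, 0.0,
    0.5, 1, 0, 0.50, 1.0, 0.0,  0.0, 0.0, 0.50, 0.0, 1.0,
    1.0, 0, 0, 0.50, 0.0, 1.0,  0.0, 0.0, 0.50, 1.0, 0.0,
    1.0, 0, 0, 0.50, 1.0, 0.0,  1.0, 0.0, 0.50, 0.0, 1.0,
    1.0, 0, 0, 1.00, 0.0, 0.0,  1.0, 1.0, 0.00, 0.0, 0.0,
    0.0, 0, 1, 0.50, 1.0, 0.0,  0.0, 0.0, 0.50, 0.0, 1.0,
    0.0, 0, 1, 1.00, 0.0, 0.0,  0.0, 1.0, 0.00, 0.0, 0.0),
    nrow = 11, byrow = TRUE,
    dimnames = list(NULL, c("R1", "R2", "R3", "R4", "R5", "R6", "R7r",
                            "R8", "R9", "R10", "R11")))
  m
}

# Which rows of expected_toy_fluxes() survive the full-active rule
# R7r = NOT(fR9): exactly those where R7r and R9 are not both active and
# not both inactive.
expected_toy_regulated_rows <- function() {
  m <- expected_toy_fluxes()
  which(xor(m[, "R7r"] != 0, m[, "R9"] != 0))
}

flux_key <- function(v) paste(sprintf("%.6f", round(v, 6) + 0), collapse = ",")

# Canonical sorted support-key sets for comparing enumerations.
support_keys <- function(x) regefm:::efm_support_keys(x)

# An independent strong-Kleene evaluator: encode false/undefined/true as
# 0 / 0.5 / 1; NOT = 1 - x, AND = min, OR = max.
kleene_oracle <- function(expr, assignment) {
  ev <- function(e) {
    switch(e$op,
      atom = {
        bit <- as.logical(assignment[[e$reaction]])
        defined <- switch(e$activity,
                          zero_active = !bit, one_active = bit,
                          full_active = TRUE)
        if (!defined) 0.5 else as.numeric(bit)
      },
      not = 1 - ev(e$x),
      and = min(ev(e$lhs), ev(e$rhs)),
      or  = max(ev(e$lhs), ev(e$rhs)))
  }
  c("0" = "false", "0.5" = "undefined", "1" = "true")[[as.character(ev(expr))]]
}

# Random expression tree over the given reactions (for parser-independent
# logic checks).
random_expr <- function(reactions, depth = 3) {
  acts <- c("zero_active", "one_active", "full_active")
  if (depth == 0 || stats::runif(1) < 0.3) {
    return(regefm:::rule_atom(sample(reactions, 1), sample(acts, 1)))
  }
  op <- sample(c("not", "and", "or"), 1)
  if (op == "not") list(op = "not", x = random_expr(reactions, depth - 1))
  else list(op = op, lhs = random_expr(reactions, depth - 1),
            rhs = random_expr(reactions, depth - 1))
}
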