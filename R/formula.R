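# Hill-notation elemental formulas.
#
# Grammar: a formula is a sequence of element tokens; an element symbol is a
# capital letter plus optional lowercase letter(s), followed by an optional
# non-negative integer count (default 1). Generic residue symbols "R" and "X"
# mark a metabolite as chemically generic: reactions containing it cannot be
# audited for mass balance.

# atomic masses (g/mol), IUPAC 2021 conventional values, for biomass bookkeeping
.ATOMIC_MASS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974, S = 32.06,
  K = 39.098, Na = 22.990, Mg = 24.305, Ca = 40.078, Fe = 55.845, Zn = 65.38,
  Cl = 35.45, Mn = 54.938, Cu = 63.546, Co = 58.933, Mo = 95.95, Se = 78.971
)

#' Parse an elemental formula
#'
#' @param formula Character scalar in Hill notation (e.g. `"C6H12O6"`).
#'   An empty string or `NA` returns an empty named vector (no formula).
#' @return Named numeric vector, element symbol -> count.
#' @examples
#' parse_formula("C6H12O6")
#' @export
parse_formula <- function(formula) {
  if (is.null(formula) || length(formula) == 0L || is.na(formula) || !nzchar(formula)) {
    return(stats::setNames(numeric(0), character(0)))
  }
  m <- gregexpr("([A-Z][a-z]*)([0-9]*)", formula, perl = TRUE)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  if (!length(toks) || sum(attr(m, "match.length")) != nchar(formula)) {
    stop("malformed formula: '", formula, "'", call. = FALSE)
  }
  el <- sub("[0-9]*$", "", toks)
  ct <- suppressWarnings(as.numeric(sub("^[A-Za-z]+", "", toks)))
  ct[is.na(ct)] <- 1
  out <- tapply(ct, el, sum)
  stats::setNames(as.numeric(out), names(out))
}

# TRUE when a formula contains a generic residue (R or X group)
formula_is_generic <- function(formula) {
  counts <- parse_formula(formula)
  any(names(counts) %in% c("R", "X"))
}

#' Molecular weight of a formula
#' @param formula Character scalar in Hill notation.
#' @return Weight in g/mol (`NA` for empty or generic formulas).
#' @export
formula_weight <- function(formula) {
  counts <- parse_formula(formula)
  if (!length(counts)) return(NA_real_)
  if (any(!names(counts) %in% names(.ATOMIC_MASS))) return(NA_real_)
  sum(counts * .ATOMIC_MASS[names(counts)])
}
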