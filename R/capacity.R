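#' Map a gene expression level to an edge capacity
#'
#' Capacities of regulatory interactions are derived from the abundance of
#' the reactant gene's transcript as `log2(e_g) / kappa`, where `e_g` is the
#' expression level and `kappa` a capacity constant (default 2). The log
#' transform follows the microarray convention of compressing highly skewed
#' expression values. Since capacities must be positive integers, the raw
#' value is integerized (`floor` by default, the most conservative choice)
#' and clamped below at 1.
#'
#' @param e_g positive expression value(s).
#' @param kappa positive capacity constant; larger values give tighter
#'   capacities.
#' @param rounding integerization rule: `"floor"` (default), `"round"` or
#'   `"ceiling"`.
#' @return integer capacity vector, every entry at least 1.
#' @examples
#' expression_to_capacity(256)   # log2 = 8, kappa = 2 -> 4
#' expression_to_capacity(2)     # raw 0.5 -> clamped to 1
#' @export
expression_to_capacity <- function(e_g, kappa = 2,
                                   rounding = c("floor", "round", "ceiling")) {
  rounding <- match.arg(rounding)
  if (any(!is.finite(e_g) | e_g <= 0)) {
    bad <- which(!is.finite(e_g) | e_g <= 0)
    nm <- names(e_g)[bad]
    stop("non-positive expression value",
         if (length(nm) && any(nzchar(nm))) paste0(" for gene(s) ",
                                                   paste(nm, collapse = ", "))
         else paste0(" at position(s) ", paste(bad, collapse = ", ")))
  }
  stopifnot(kappa > 0)
  raw <- log2(e_g) / kappa
  val <- switch(rounding, floor = floor(raw), round = round(raw),
                ceiling = ceiling(raw))
  as.integer(pmax(1, val))
}

#' Assign expression-derived capacities to network edges
#'
#' Each edge's capacity is set from the expression of its reactant gene,
#' interpreted by default as the edge's source node (the regulator of a
#' regulatory interaction); `rule = "target"` uses the regulated gene
#' instead. Genes missing from the profile fall back to `default_capacity`
#' with a warning.
#'
#' @param network a [pomoc_network()].
#' @param profile named numeric vector of expression values (names are gene
#'   labels), e.g. from [read_expression()].
#' @param rule which edge endpoint is the reactant: `"source"` (default) or
#'   `"target"`.
#' @param kappa,rounding passed to [expression_to_capacity()].
#' @param default_capacity capacity used for genes absent from the profile.
#' @return the network with its capacity vector replaced.
#' @export
assign_edge_capacities <- function(network, profile, rule = c("source", "target"),
                                   kappa = 2, rounding = "floor",
                                   default_capacity = 1) {
  rule <- match.arg(rule)
  genes <- network$edges[[rule]]
  known <- genes %in% names(profile)
  if (any(!known)) {
    warning("no expression value for gene(s) ",
            paste(unique(genes[!known]), collapse = ", "),
            "; using default capacity ", default_capacity)
  }
  cap <- rep(as.numeric(default_capacity), length(genes))
  if (any(known)) {
    cap[known] <- expression_to_capacity(profile[genes[known]], kappa = kappa,
                                         rounding = rounding)
  }
  network$capacity <- cap
  bad <- validate_network(network)
  if (length(bad)) stop("capacity assignment produced an invalid network: ",
                        paste(bad, collapse = "; "))
  network
}

#' Classify the variation between two values as significant or not
#'
#' A variation is significant (digit 1) when the relative difference
#' `|a - b| / max(a, b)` exceeds the threshold fraction (default 10%). The
#' maximum of the two values is used as the base so the measure is symmetric
#' and scale invariant; two zeros are defined as non-significant.
#'
#' @param value_a,value_b non-negative values (e.g. a gene's mean capacity
#'   or motif count under two conditions).
#' @param threshold significance threshold as a fraction (default 0.10).
#' @return integer 0 or 1.
#' @export
classify_variation <- function(value_a, value_b, threshold = 0.10) {
  stopifnot(value_a >= 0, value_b >= 0, threshold >= 0)
  base <- pmax(value_a, value_b)
  ifelse(base == 0, 0L, as.integer(abs(value_a - value_b) / base > threshold))
}

#' Two-digit capacity/count variation code
#'
#' Codes a gene's behaviour between two conditions as two binary digits: the
#' first digit flags a significant variation of its edge capacity, the
#' second a significant variation of its motif participation count, both via
#' [classify_variation()].
#'
#' @param capacity_a,capacity_b the gene's (mean) edge capacity in the two
#'   conditions.
#' @param count_a,count_b the gene's motif count in the two conditions.
#' @param threshold significance threshold fraction.
#' @return two-character string such as `"10"`.
#' @examples
#' variation_code(4, 4, 100, 89)  # "01"
#' @export
variation_code <- function(capacity_a, capacity_b, count_a, count_b,
                           threshold = 0.10) {
  paste0(classify_variation(capacity_a, capacity_b, threshold),
         classify_variation(count_a, count_b, threshold))
}
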