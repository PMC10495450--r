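## Electrical-analog composition algebra for lumped vascular elements.
## Resistances combine like resistors; compliances combine like capacitors,
## which is the dual rule: series compliance is harmonic, parallel compliance
## is additive.

as_element_list <- function(elements) {
  if (is_lumped_element(elements)) elements <- list(elements)
  if (!is.list(elements) || length(elements) == 0L)
    stop("`elements` must be a non-empty list of lumped elements", call. = FALSE)
  if (!all(vapply(elements, is_lumped_element, logical(1))))
    stop("every entry of `elements` must be a lumped_element", call. = FALSE)
  elements
}

#' Combine lumped elements in series
#'
#' Series composition along a flow path: resistances add, compliances
#' combine harmonically (capacitors in series),
#' \deqn{R = \sum_i R_i, \qquad C = \left(\sum_i C_i^{-1}\right)^{-1}.}
#'
#' @param elements Non-empty list of [lumped_element()] objects.
#' @return A single [lumped_element()].
#' @export
combine_series <- function(elements) {
  elements <- as_element_list(elements)
  r <- vapply(elements, `[[`, numeric(1), "resistance")
  c_ <- vapply(elements, `[[`, numeric(1), "compliance")
  if (any(c_ == 0))
    stop("series combination is undefined for zero compliance (harmonic mean)",
         call. = FALSE)
  lumped_element(sum(r), 1 / sum(1 / c_))
}

#' Combine lumped elements in parallel
#'
#' Parallel composition of daughter branches: conductances add, compliances
#' add (capacitors in parallel),
#' \deqn{R^{-1} = \sum_i n_i / R_i, \qquad C = \sum_i n_i C_i,}
#' where \eqn{n_i} is the multiplicity of the i-th element.  Fractional
#' multiplicities are permitted (mean anatomical branch counts such as 7.6).
#'
#' @param elements Non-empty list of [lumped_element()] objects.
#' @param factors Positive multiplicities, one per element.
#' @return A single [lumped_element()].
#' @export
combine_parallel <- function(elements, factors = rep(1, length(elements))) {
  elements <- as_element_list(elements)
  if (length(factors) != length(elements))
    stop("`factors` must have one multiplicity per element", call. = FALSE)
  if (!is.numeric(factors) || any(!is.finite(factors)) || any(factors <= 0))
    stop_field("factors", "must be > 0")
  r <- vapply(elements, `[[`, numeric(1), "resistance")
  c_ <- vapply(elements, `[[`, numeric(1), "compliance")
  if (any(r == 0))
    stop("parallel combination is undefined for zero resistance", call. = FALSE)
  lumped_element(1 / sum(factors / r), sum(factors * c_))
}

#' Named series/parallel reduction recipe
#'
#' One step of a reduction table: a named combination of base branch labels
#' and/or earlier recipe names, each with a parallel multiplicity.
#'
#' @param name Recipe name (e.g. `"R7"`).
#' @param mode `"series"` or `"parallel"`.
#' @param refs Character vector of references (branch labels or earlier
#'   recipe names).
#' @param factors Multiplicity per reference (default all 1).  Only
#'   meaningful for parallel nodes; series nodes require unit factors.
#' @param stated_factors Optional: the multiplicities as stated by the
#'   source table when they differ from the effective `factors` (used by the
#'   discrepancy report).
#' @return An object of class `reduction_recipe`.
#' @export
reduction_recipe <- function(name, mode = c("series", "parallel"), refs,
                             factors = rep(1, length(refs)),
                             stated_factors = NULL) {
  mode <- match.arg(mode)
  if (!is.character(refs) || length(refs) == 0L)
    stop("`refs` must be a non-empty character vector", call. = FALSE)
  if (length(factors) != length(refs))
    stop("`factors` must match `refs` in length", call. = FALSE)
  if (any(!is.finite(factors)) || any(factors <= 0))
    stop_field("factors", "must be > 0")
  if (mode == "series" && any(factors != 1))
    stop("series recipes take unit factors; repeat the reference instead",
         call. = FALSE)
  structure(list(name = name, mode = mode, refs = refs, factors = factors,
                 stated_factors = stated_factors),
            class = "reduction_recipe")
}

#' Build a recipe table
#'
#' An ordered collection of [reduction_recipe()] steps.  References must
#' resolve to a base label or to an earlier recipe, so the table is acyclic
#' by construction; [evaluate_recipes()] enforces this.
#'
#' @param ... `reduction_recipe` objects, or a single list of them.
#' @return An object of class `recipe_table` (a named list).
#' @export
recipe_table <- function(...) {
  recipes <- list(...)
  if (length(recipes) == 1L && is.list(recipes[[1]]) &&
      !inherits(recipes[[1]], "reduction_recipe"))
    recipes <- recipes[[1]]
  if (!all(vapply(recipes, inherits, logical(1), "reduction_recipe")))
    stop("all entries must be reduction_recipe objects", call. = FALSE)
  nm <- vapply(recipes, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop("duplicate recipe name: ", nm[duplicated(nm)][1], call. = FALSE)
  structure(stats::setNames(recipes, nm), class = "recipe_table")
}

#' Evaluate a reduction recipe table
#'
#' Evaluates every recipe in definition order against a base mapping of
#' branch labels to lumped elements.  Intermediates are kept at full
#' floating-point precision; rounded published intermediates are never fed
#' back into later steps.
#'
#' @param recipes A [recipe_table()].
#' @param base Named list of [lumped_element()] objects keyed by branch
#'   label.
#' @return Named list of [lumped_element()] objects, one per recipe, in
#'   definition order.
#' @export
evaluate_recipes <- function(recipes, base) {
  if (!inherits(recipes, "recipe_table"))
    stop("`recipes` must be a recipe_table", call. = FALSE)
  if (!is.list(base) || is.null(names(base)))
    stop("`base` must be a named list of lumped elements", call. = FALSE)
  env <- base
  out <- vector("list", length(recipes))
  names(out) <- names(recipes)
  for (i in seq_along(recipes)) {
    rec <- recipes[[i]]
    known <- c(names(base), names(recipes)[seq_len(i - 1L)])
    missing <- setdiff(rec$refs, known)
    if (length(missing))
      stop(sprintf("recipe `%s` references unknown or later name `%s`",
                   rec$name, missing[1]), call. = FALSE)
    els <- env[rec$refs]
    out[[i]] <- if (rec$mode == "series") combine_series(els)
                else combine_parallel(els, rec$factors)
    env[[rec$name]] <- out[[i]]
  }
  out
}

#' Compare computed values against published ones
#'
#' Per-name relative error of a computed mapping against a published
#' (printed) mapping, with a pass/fail verdict at a relative tolerance.
#' Names present on only one side are reported with `NA` errors rather than
#' raising an error.  The report is deterministic and sorted by name.
#'
#' @param computed Named numeric vector of computed values.
#' @param printed Named numeric vector of published values.
#' @param rel_tol Relative tolerance for a pass (default 0.01, absorbing the
#'   3-significant-figure rounding of published tables).
#' @return A data frame with columns `name`, `computed`, `printed`,
#'   `rel_err`, `pass`.
#' @export
compare_to_printed <- function(computed, printed, rel_tol = 0.01) {
  stopifnot(is.numeric(computed), is.numeric(printed))
  nm <- sort(union(names(computed), names(printed)))
  comp <- computed[nm]
  prnt <- printed[nm]
  rel <- ifelse(is.na(comp) | is.na(prnt), NA_real_,
                abs(comp - prnt) / abs(prnt))
  data.frame(name = nm,
             computed = unname(comp),
             printed = unname(prnt),
             rel_err = unname(rel),
             pass = unname(!is.na(rel) & rel <= rel_tol),
             row.names = NULL, stringsAsFactors = FALSE)
}
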