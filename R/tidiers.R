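#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a weighted CCA ordination
#'
#' @param x A `wcca` object.
#' @param type `"genes"` (default), `"conditions"` or `"arrows"`.
#' @param ... Unused.
#' @return A tibble of scores for the requested component.
#' @export
tidy.wcca <- function(x, type = c("genes", "conditions", "arrows"), ...) {
  type <- match.arg(type)
  switch(type,
         genes = x$gene_scores,
         conditions = x$condition_scores,
         arrows = x$arrows)
}

#' One-row summary of a weighted CCA
#'
#' @param x A `wcca` object.
#' @param ... Unused.
#' @return Tibble with inertia decomposition, axis count and the leading
#'   eigenvalue share of constrained inertia.
#' @export
glance.wcca <- function(x, ...) {
  tibble(
    inertia_total = unname(x$inertia["total"]),
    inertia_constrained = unname(x$inertia["constrained"]),
    inertia_unconstrained = unname(x$inertia["unconstrained"]),
    n_axes = length(x$eigenvalues),
    prop_constrained = unname(x$inertia["constrained"] / x$inertia["total"]),
    prop_axis1 = x$eigenvalues[1] / sum(x$eigenvalues)
  )
}

#' Tidy a weighted MDS embedding
#'
#' @param x A `wmds` object.
#' @param ... Unused.
#' @return Tibble of point coordinates with weights.
#' @export
tidy.wmds <- function(x, ...) {
  x$points |> mutate(weight = x$weights)
}

#' One-row summary of a weighted MDS fit
#'
#' @param x A `wmds` object.
#' @param ... Unused.
#' @return Tibble with final stress, iteration count and convergence flag.
#' @export
glance.wmds <- function(x, ...) {
  tibble(stress = x$stress, n_iter = length(x$stress_history) - 1,
         converged = x$converged)
}

#' @export
print.wcca <- function(x, ...) {
  cat("<wcca>", length(x$eigenvalues), "constrained axes\n")
  cat("  eigenvalues:", paste(signif(x$eigenvalues, 4), collapse = ", "),
      "\n")
  cat("  constrained inertia:",
      signif(x$inertia["constrained"] / x$inertia["total"] * 100, 3),
      "% of total\n")
  invisible(x)
}

#' @export
print.wmds <- function(x, ...) {
  cat("<wmds>", nrow(x$points), "points, stress",
      signif(x$stress, 4), if (x$converged) "(converged)" else "", "\n")
  invisible(x)
}
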