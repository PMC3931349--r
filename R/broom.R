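# Tidiers and plot methods for the pipeline's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a provenance table
#'
#' @param x a `dron_provenance` table.
#' @param ... unused.
#' @return One row per retired identifier: `old_rxcui`, `new_rxcui`, `status`.
#' @method tidy dron_provenance
#' @export
tidy.dron_provenance <- function(x, ...) {
  x$entries
}

#' One-row summary of a provenance table
#'
#' @param x a `dron_provenance` table.
#' @param ... unused.
#' @return A tibble with the count of current identifiers and of retired
#'   identifiers per status.
#' @method glance dron_provenance
#' @export
glance.dron_provenance <- function(x, ...) {
  tibble(
    n_current = length(x$observed_current),
    n_retired = nrow(x$entries),
    n_merged = sum(x$entries$status == STATUS_MERGED),
    n_error = sum(x$entries$status == STATUS_ERROR),
    n_split = sum(x$entries$status == STATUS_SPLIT),
    n_orphaned = sum(x$entries$status == STATUS_ORPHANED),
    compacted = x$compacted
  )
}

#' Tidy an NDC registry
#'
#' @param x a `dron_ndc_registry`.
#' @param ... unused.
#' @return One row per (ndc, original identifier) pair ever observed.
#' @method tidy dron_ndc_registry
#' @export
tidy.dron_ndc_registry <- function(x, ...) {
  x$entries
}

#' One-row summary of an NDC registry
#'
#' @param x a finalized `dron_ndc_registry`.
#' @param ... unused.
#' @return A tibble with pair counts per status class.
#' @method glance dron_ndc_registry
#' @export
glance.dron_ndc_registry <- function(x, ...) {
  n <- function(s) if (x$finalized) sum(x$entries$status == s) else NA_integer_
  tibble(
    n_pairs = nrow(x$entries),
    n_ndcs = dplyr::n_distinct(x$entries$ndc),
    n_releases = nrow(x$versions),
    n_included = n(NDC_INCLUDED),
    n_excluded_error = n(NDC_EXCLUDED_ERROR),
    n_excluded_split = n(NDC_EXCLUDED_SPLIT),
    n_orphaned = n(NDC_ORPHANED)
  )
}

#' One-row summary of an emitted module set
#'
#' @param x a `dron_modules` set.
#' @param ... unused.
#' @return A tibble with one class-count column per module and the total.
#' @method glance dron_modules
#' @export
glance.dron_modules <- function(x, ...) {
  counts <- module_class_counts(x)
  out <- as_tibble(as.list(setNames(counts, gsub("-", "_", names(counts)))))
  out$total <- sum(counts)
  out
}

#' Plot the status partition of a finalized NDC registry
#'
#' Bar chart of (ndc, identifier) pairs per status class: included, excluded
#' as entered-in-error, excluded as split, orphaned.
#'
#' @param object a finalized `dron_ndc_registry`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot dron_ndc_registry
#' @export
autoplot.dron_ndc_registry <- function(object, ...) {
  if (!object$finalized) {
    dron_abort("finalize the registry before plotting", class = "dronr_unfinalized")
  }
  dat <- dplyr::count(object$entries, .data$status)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$status, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "(NDC, RXCUI) pairs",
                  title = "Historical NDC registry by status") +
    ggplot2::theme_minimal()
}

#' Plot class counts per emitted ontology module
#'
#' @param object a `dron_modules` set.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot dron_modules
#' @export
autoplot.dron_modules <- function(object, ...) {
  counts <- module_class_counts(object)
  dat <- tibble(module = names(counts), classes = as.integer(counts))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$module, y = .data$classes)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "classes", title = "Classes per ontology module") +
    ggplot2::theme_minimal()
}
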