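#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a signature-calling result
#'
#' The result is already tibble-shaped; `tidy()` returns it (optionally
#' restricted to called genes) and `glance()` a one-row summary.
#'
#' @param x A `signature_result`.
#' @param called_only Keep only called genes (default `FALSE`).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.signature_result <- function(x, called_only = FALSE, ...) {
  out <- as_tibble(x)
  if (called_only) out <- filter(out, .data$called)
  out
}

#' @rdname tidy.signature_result
#' @export
glance.signature_result <- function(x, ...) {
  p <- attr(x, "params")
  tibble(
    n_genes = nrow(x),
    n_called = sum(x$called),
    n_up_in_a = sum(x$direction == "up_in_a"),
    n_up_in_b = sum(x$direction == "up_in_b"),
    min_fraction = p$min_fraction,
    min_log2fc = p$min_log2fc
  )
}

#' Tidy a module set
#'
#' `tidy()` returns the gene-to-module assignment, `glance()` one row per
#' module (plus grey) with sizes and the network parameters used.
#'
#' @param x A `module_set` from [detect_modules()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.module_set <- function(x, ...) as_tibble(x$genes)

#' @rdname tidy.module_set
#' @export
glance.module_set <- function(x, ...) {
  tibble(
    module = names(x$sizes),
    size = as.integer(x$sizes),
    soft_power = x$soft_power,
    fit_r2 = x$fit_r2
  )
}

#' Tidy a pseudotime screen
#'
#' @param x A `pt_screen` from [screen_pseudotime_genes()].
#' @param ... Unused.
#' @return `tidy()`: the per-gene table; `glance()`: one-row summary with
#'   the numbers of positively and negatively associated genes.
#' @export
tidy.pt_screen <- function(x, ...) as_tibble(x)

#' @rdname tidy.pt_screen
#' @export
glance.pt_screen <- function(x, ...) {
  p <- attr(x, "params")
  tibble(
    n_tested = nrow(x),
    n_pos = sum(x$association == "pos"),
    n_neg = sum(x$association == "neg"),
    min_abs_rho = p$min_abs_rho,
    max_q = p$max_q,
    n_cells = p$n_cells
  )
}

#' Tidy a differential interaction network
#'
#' @param x An `lr_diff` from [differential_network()].
#' @param ... Unused.
#' @return `tidy()`: the labelled edge table; `glance()`: gained/lost/
#'   shared totals.
#' @export
tidy.lr_diff <- function(x, ...) as_tibble(x$edges)

#' @rdname tidy.lr_diff
#' @export
glance.lr_diff <- function(x, ...) {
  tibble(
    condition_a = unname(x$conditions["a"]),
    condition_b = unname(x$conditions["b"]),
    gained = sum(x$edges$status == "gained"),
    lost = sum(x$edges$status == "lost"),
    shared = sum(x$edges$status == "shared")
  )
}
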