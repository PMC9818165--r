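#' @import ggplot2
NULL

#' Plot cluster composition per condition
#'
#' Side-by-side proportion bars per cluster, one fill per condition —
#' the standard "cell number per cluster" comparison.
#'
#' @param tab A `composition_table` from [composition_shift()].
#' @return A ggplot.
#' @export
plot_composition <- function(tab) {
  conds <- attr(tab, "conditions")
  long <- tab |>
    select("cluster", dplyr::starts_with("prop_")) |>
    tidyr::pivot_longer(-"cluster", names_to = "condition", values_to = "proportion",
                        names_prefix = "prop_")
  ggplot(long, aes(x = .data$cluster, y = .data$proportion, fill = .data$condition)) +
    geom_col(position = "dodge") +
    labs(x = NULL, y = "proportion of cells", fill = NULL) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Volcano-style plot of a signature result
#'
#' Detection fraction (max of the two groups) against log2 fold change,
#' called genes highlighted.
#'
#' @param object A `signature_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.signature_result <- function(object, ...) {
  df <- mutate(as_tibble(object),
               max_fraction = pmax(.data$fraction_a, .data$fraction_b))
  ggplot(df, aes(x = .data$log2fc, y = .data$max_fraction, colour = .data$called)) +
    geom_point(alpha = 0.6, size = 0.8) +
    scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    labs(x = "log2 fold change", y = "max detection fraction", colour = "called") +
    theme_minimal()
}

#' Pseudotime-association plot
#'
#' Rank correlation with pseudotime per gene against BH q-value, screen
#' calls coloured.
#'
#' @param object A `pt_screen`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pt_screen <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$rho, y = -log10(pmax(.data$q_value, 1e-300)),
             colour = .data$association)) +
    geom_point(alpha = 0.6, size = 0.8) +
    scale_colour_manual(values = c(pos = "firebrick", neg = "steelblue", none = "grey60")) +
    labs(x = "Spearman rho vs pseudotime", y = "-log10 q", colour = NULL) +
    theme_minimal()
}

#' Module-trait correlation heat tile plot
#'
#' @param mt Output of [module_trait_correlation()].
#' @return A ggplot.
#' @export
plot_module_trait <- function(mt) {
  ggplot(mt, aes(x = .data$trait, y = .data$module, fill = .data$correlation)) +
    geom_tile() +
    geom_text(aes(label = sprintf("%.2f", .data$correlation)), size = 3) +
    scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick",
                         limits = c(-1, 1)) +
    labs(x = NULL, y = NULL, fill = "r") +
    theme_minimal()
}

#' Differential interaction network summary plot
#'
#' Gained and lost edge counts per sender-receiver cluster pair.
#'
#' @param object An `lr_diff`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lr_diff <- function(object, ...) {
  long <- object$summary |>
    tidyr::pivot_longer(c("gained", "lost"), names_to = "status", values_to = "n") |>
    filter(.data$n > 0)
  ggplot(long, aes(x = .data$receiver, y = .data$sender, size = .data$n,
                   colour = .data$status)) +
    geom_point(position = position_dodge(width = 0.4)) +
    scale_colour_manual(values = c(gained = "firebrick", lost = "steelblue")) +
    labs(x = "receiver", y = "sender", size = "edges", colour = NULL) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}
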