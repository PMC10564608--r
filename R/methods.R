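#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an ICC result
#'
#' @param x An `icc_result`.
#' @param ... Unused.
#' @return One-row tibble with `icc`, `ci_low`, `ci_high`, `band`.
#' @method tidy icc_result
#' @export
tidy.icc_result <- function(x, ...) {
  tibble(icc = x$icc, ci_low = x$ci_low, ci_high = x$ci_high, band = x$band)
}

#' @rdname tidy.icc_result
#' @method glance icc_result
#' @export
glance.icc_result <- function(x, ...) {
  tibble(icc = x$icc, ci_low = x$ci_low, ci_high = x$ci_high, band = x$band,
         n = x$n, k = x$k, form = x$form, conf_level = x$conf_level,
         ms_rows = unname(x$ms["msr"]), ms_cols = unname(x$ms["msc"]),
         ms_error = unname(x$ms["mse"]))
}

#' Tidy a quintile cross-classification
#'
#' @param x A `quintile_agreement`.
#' @param ... Unused.
#' @return `tidy()`: long tibble of the 5 x 5 cross-table; `glance()`: one
#'   row of summary statistics.
#' @method tidy quintile_agreement
#' @export
tidy.quintile_agreement <- function(x, ...) {
  as_tibble(as.data.frame(as.table(x$cross_table))) %>%
    stats::setNames(c("quintile_a", "quintile_b", "n")) %>%
    dplyr::mutate(dplyr::across(dplyr::starts_with("quintile"),
                                ~ as.integer(as.character(.x))))
}

#' @rdname tidy.quintile_agreement
#' @method glance quintile_agreement
#' @export
glance.quintile_agreement <- function(x, ...) {
  tibble(p_same = x$p_same, p_same_or_adjacent = x$p_same_or_adjacent,
         pabak = x$pabak, band = x$band, n = x$n, mode = x$mode)
}

#' Tidy an agreement report
#'
#' @param x A `nova_agreement_report`.
#' @param ... Unused.
#' @return A tibble with one row per Nova group combining the paired mean
#'   comparison, the ICC (with CI and band) and the quintile agreement
#'   summary. `glance()` returns the analysis settings.
#' @method tidy nova_agreement_report
#' @export
tidy.nova_agreement_report <- function(x, ...) {
  icc <- purrr::map_dfr(x$per_group, function(pg) tidy(pg$icc))
  qt <- purrr::map_dfr(x$per_group, function(pg) glance(pg$quintiles))
  dplyr::bind_cols(
    x$means,
    stats::setNames(icc, c("icc", "icc_ci_low", "icc_ci_high", "icc_band")),
    stats::setNames(qt[, c("p_same", "p_same_or_adjacent", "pabak", "band")],
                    c("p_same", "p_same_or_adjacent", "pabak", "pabak_band"))
  )
}

#' @rdname tidy.nova_agreement_report
#' @method glance nova_agreement_report
#' @export
glance.nova_agreement_report <- function(x, ...) {
  tibble(tool_a = x$tools[1], tool_b = x$tools[2],
         n = x$means$n[1], icc_form = x$settings$icc_form,
         quintile_mode = x$settings$quintile_mode,
         method = x$settings$method, alpha = x$settings$alpha)
}

nova_group_labels <- c(
  "1" = "Nova 1: unprocessed/minimally processed",
  "2" = "Nova 2: processed culinary ingredients",
  "3" = "Nova 3: processed foods",
  "4" = "Nova 4: ultra-processed foods"
)

#' Plot Nova energy shares
#'
#' Stacked per-participant bars of the relative energy contribution of the
#' four Nova groups.
#'
#' @param object A `nova_shares` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nova_shares
#' @export
autoplot.nova_shares <- function(object, ...) {
  d <- object[!object$zero_energy, ]
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$participant_id, y = .data$share_pct,
    fill = factor(.data$nova_group, levels = 4:1)
  )) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "RdYlGn", name = NULL,
                               labels = nova_group_labels[as.character(4:1)]) +
    ggplot2::labs(x = NULL, y = "% of total energy intake") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Plot a between-tool agreement report
#'
#' Scatter of tool-A against tool-B energy shares, faceted by Nova group,
#' with the identity line and each group's ICC in the panel label.
#'
#' @param object A `nova_agreement_report`.
#' @param paired The long paired-shares tibble the report was computed from.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nova_agreement_report
#' @export
autoplot.nova_agreement_report <- function(object, paired, ...) {
  w <- paired %>%
    tidyr::pivot_wider(names_from = "tool", values_from = "share_pct")
  names(w)[match(object$tools, names(w))] <- c("tool_a", "tool_b")
  icc <- vapply(object$per_group, function(pg) pg$icc$icc, double(1))
  w$panel <- sprintf("%s (ICC %.2f)",
                     nova_group_labels[as.character(w$nova_group)],
                     icc[paste0("nova", w$nova_group)])
  ggplot2::ggplot(w, ggplot2::aes(x = .data$tool_a, y = .data$tool_b)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = paste(object$tools[1], "(% energy)"),
                  y = paste(object$tools[2], "(% energy)")) +
    ggplot2::theme_minimal()
}

#' Plot a quintile cross-classification
#'
#' Heatmap of the 5 x 5 joint quintile membership table.
#'
#' @param object A `quintile_agreement`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot quintile_agreement
#' @export
autoplot.quintile_agreement <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$quintile_a, y = .data$quintile_b,
                                  fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_fill_viridis_c(guide = "none") +
    ggplot2::labs(x = "Quintile, tool A", y = "Quintile, tool B",
                  subtitle = sprintf("PABAK %.2f (%s)", object$pabak,
                                     gsub("_", " ", object$band))) +
    ggplot2::theme_minimal()
}
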