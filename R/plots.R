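#' Plot the PCR family-size distribution
#'
#' @param stats A `family_size_stats` from [family_size_stats()].
#' @param by `"families"` or `"reads"` on the y axis.
#' @return A ggplot.
#' @export
plot_family_sizes <- function(stats, by = c("reads", "families")) {
  by <- match.arg(by)
  df <- stats$histogram
  df$y <- if (by == "reads") df$n_reads else df$n_families
  ggplot2::ggplot(df, ggplot2::aes(x = .data$size, y = .data$y)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "PCR family size (reads)",
      y = if (by == "reads") "Total reads" else "Families",
      title = sprintf("Peak family size: %s", stats$peak_family_size)
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-position annealing-mispairing frequencies
#'
#' Ligation-proximal (duplex-key) positions are highlighted; mispairing
#' frequency is expected to fall towards the ligation site.
#'
#' @param profile A `mispair_profile` from [mispairing_profile()].
#' @return A ggplot.
#' @export
plot_mispairing_profile <- function(profile) {
  ggplot2::ggplot(profile$per_position,
                  ggplot2::aes(x = .data$position, y = .data$frequency,
                               fill = .data$terminal)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(
      values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
      labels = c("distal", "ligation-proximal"), name = NULL
    ) +
    ggplot2::labs(x = "Combined canonical barcode position",
                  y = "Mispairing frequency") +
    ggplot2::theme_minimal()
}

#' Plot a background error profile by substitution class
#'
#' @param profile An `error_profile` from [background_error_profile()], or
#'   a list of them (one bar facet per consensus level).
#' @return A ggplot.
#' @export
plot_error_profile <- function(profile) {
  if (inherits(profile, "error_profile")) profile <- list(profile)
  df <- dplyr::bind_rows(lapply(profile, function(p) {
    dplyr::mutate(p$by_class, level = p$level)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$rate)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::facet_wrap(~level, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Substitution class (reference strand)",
                  y = "Non-reference call rate") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Autoplot a finished run
#'
#' Side-by-side single-strand and duplex VAF per targeted site.
#'
#' @param object A `dbc_run`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dbc_run <- function(object, ...) {
  df <- object$calls |>
    tidyr::pivot_longer(c("vaf_sscs", "vaf_duplex"),
                        names_to = "level", values_to = "vaf",
                        names_prefix = "vaf_")
  df$site <- paste0(df$locus, ":", df$position + 1)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$site, y = .data$vaf,
                                   fill = .data$level)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Targeted site", y = "Variant allele fraction",
                  fill = "Consensus level") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
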