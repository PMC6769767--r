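# Static plotting conveniences: a stream-style clone prevalence chart and
# a Kaplan-Meier step plot.

#' Stream plot of clone prevalences across samples
#'
#' A static stacked-area ("fishplot-lite") view of clone prevalences over
#' the architecture's samples, in sample order. Clones covered by a
#' regimen can be highlighted by passing the proposal.
#'
#' @param arch A `clonal_architecture` with >= 1 sample.
#' @param regimen Optional `regimen_proposal`; covered clones are drawn
#'   opaque, uncovered ones hatched down to a lower alpha.
#' @return A ggplot object.
#' @export
plot_clone_prevalence <- function(arch, regimen = NULL) {
  stopifnot(inherits(arch, "clonal_architecture"))
  ct_assert(length(arch$samples) >= 1, "architecture has no samples")
  df <- dplyr::bind_rows(lapply(names(arch$samples), function(sid) {
    p <- arch$samples[[sid]]
    tibble::tibble(sample = sid, clone = names(p), prevalence = unname(p))
  }))
  df$sample <- factor(df$sample, levels = names(arch$samples))
  if (!is.null(regimen)) {
    covered <- unique(unlist(regimen$covered_clones))
    df$covered <- ifelse(df$clone %in% covered, "covered", "uncovered")
  } else df$covered <- "covered"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$prevalence,
                                   fill = .data$clone,
                                   alpha = .data$covered,
                                   group = .data$clone)) +
    ggplot2::geom_col(position = "stack", width = 0.7) +
    ggplot2::scale_alpha_manual(values = c(covered = 1, uncovered = 0.35),
                                guide = "none") +
    ggplot2::labs(x = "sample", y = "clone prevalence", fill = "clone") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier step plot for a stratified OS report
#'
#' @param os An `os_report` from [stratified_os_analysis()].
#' @return A ggplot object with one right-continuous step curve per
#'   stratum and the log-rank p-value in the subtitle.
#' @export
plot_km <- function(os) {
  stopifnot(inherits(os, "os_report"))
  df <- dplyr::bind_rows(lapply(names(os$fits), function(g) {
    s <- os$fits[[g]]$steps
    tibble::tibble(group = g,
                   time = c(0, s$time),
                   surv = c(1, s$surv))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv,
                                   colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (days)", y = "overall survival",
                  colour = NULL,
                  subtitle = sprintf("log-rank p = %.3g", os$p_value)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
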