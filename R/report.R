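#' Build summary figures and tidy tables from a pipeline run
#'
#' Assembles the standard figure set from a [run_pipeline()] result bundle:
#' per-category abundance-vs-time panels, the proteome volcano plot with its
#' significance boundary, maturation and thermostability time courses, FP
#' traces with fitted curves, and the enhancement-factor dot plot. Every
#' figure is backed by a tidy data frame so downstream checks can assert on
#' numbers rather than images; with `out_dir` set, those tables are written
#' as CSV and the figures as PDF. Stages absent from the bundle are skipped
#' with a notice.
#'
#' @param res result bundle from [run_pipeline()].
#' @param out_dir optional directory for `report_*.csv` / `report_*.pdf`.
#' @return (invisibly) list of `ggplot` objects (`timecourse`, `volcano`,
#'   `maturation`, `thermostability`, `fp_association`, `fp_dissociation`,
#'   `enhancement`) and their backing tibbles under `$data`.
#' @export
make_report <- function(res, out_dir = NULL) {
  plots <- list()
  data <- list()

  if (!is.null(res$mrm)) {
    tc <- res$mrm$profiles |>
      dplyr::filter(!is.na(.data$timepoint_h)) |>
      dplyr::left_join(dplyr::select(res$mrm$calls, "peptide", "category"),
                       by = "peptide")
    data$timecourse <- dplyr::select(tc, "peptide", "category", "timepoint_h",
                                     "mean_norm_abundance", "sd_norm_abundance")
    plots$timecourse <- ggplot2::ggplot(
      tc, ggplot2::aes(x = .data$timepoint_h, y = .data$mean_norm_abundance,
                       group = .data$peptide)) +
      ggplot2::geom_line(alpha = 0.4) +
      ggplot2::facet_wrap(~category) +
      ggplot2::labs(x = "drug exposure (h)", y = "normalised abundance",
                    title = "Peptide abundance time courses by impact category") +
      ggplot2::theme_minimal()
  } else {
    message("report: MRM stage absent; time-course panel skipped")
  }

  if (!is.null(res$proteome)) {
    pr <- dplyr::mutate(res$proteome$results,
                        neg_log_p = -log10(pmax(.data$p, 1e-300)))
    data$volcano <- dplyr::select(pr, "protein_id", "difference", "p",
                                  "neg_log_p", "d", "significant")
    plots$volcano <- ggplot2::ggplot(
      pr, ggplot2::aes(x = .data$difference, y = .data$neg_log_p,
                       colour = .data$significant)) +
      ggplot2::geom_point(size = 0.6, alpha = 0.6) +
      ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "red")) +
      ggplot2::labs(x = "difference (log2 fold change)", y = "-log10 p",
                    title = sprintf("Proteome comparison (|d| cut = %.3g)",
                                    attr(res$proteome$results, "d_cut"))) +
      ggplot2::theme_minimal()
  } else {
    message("report: proteome stage absent; volcano skipped")
  }

  if (!is.null(res$pulsechase)) {
    data$maturation <- res$pulsechase$maturation_summary
    plots$maturation <- ggplot2::ggplot(
      res$pulsechase$maturation_summary,
      ggplot2::aes(x = .data$chase_min, y = .data$mean)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd), width = 2) +
      ggplot2::labs(x = "chase (min)", y = "% EndoH resistant",
                    title = "MHC I maturation") +
      ggplot2::theme_minimal()

    data$thermostability <- res$pulsechase$thermostability_summary
    plots$thermostability <- ggplot2::ggplot(
      res$pulsechase$thermostability_summary,
      ggplot2::aes(x = .data$chase_min, y = .data$mean,
                   colour = factor(.data$temperature_C))) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd), width = 2) +
      ggplot2::labs(x = "chase (min)", y = "% recovered vs 4 C",
                    colour = "challenge (C)", title = "MHC I thermostability") +
      ggplot2::theme_minimal()
  } else {
    message("report: pulse-chase stage absent; maturation/thermostability skipped")
  }

  if (!is.null(res$fp)) {
    for (mode in c("association", "dissociation")) {
      key <- if (mode == "association") "assoc" else "dissoc"
      fits <- res$fp[[paste0(key, "_fits")]]
      curves <- dplyr::bind_rows(lapply(seq_len(nrow(fits)), function(i) {
        cv <- fits$fitted[[i]]
        if (is.null(cv)) return(NULL)
        dplyr::mutate(cv, condition = fits$condition[i])
      }))
      data[[paste0("fp_", mode)]] <- curves
      plots[[paste0("fp_", mode)]] <- ggplot2::ggplot(
        res$fp[[key]]$traces,
        ggplot2::aes(x = .data$time_h, y = .data$mP, colour = .data$condition)) +
        ggplot2::geom_point(size = 0.5, alpha = 0.5) +
        { if (nrow(curves)) ggplot2::geom_line(
            data = curves, ggplot2::aes(y = .data$mP_fit)) } +
        ggplot2::labs(x = "time (h)", y = "polarisation (mP)",
                      title = sprintf("Peptide %s kinetics", mode)) +
        ggplot2::theme_minimal()
    }
    if (!is.null(res$fp$enhancement)) {
      data$enhancement <- res$fp$enhancement
      plots$enhancement <- ggplot2::ggplot(
        res$fp$enhancement,
        ggplot2::aes(x = .data$condition, y = .data$factor_pct)) +
        ggplot2::geom_point(position = ggplot2::position_jitter(width = 0.05, seed = 1)) +
        ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4) +
        ggplot2::labs(x = NULL, y = "enhancement factor (%)",
                      title = "Binding enhancement over intrinsic") +
        ggplot2::theme_minimal()
    }
  } else {
    message("report: FP stage absent; kinetics panels skipped")
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(data)) {
      readr::write_csv(data[[nm]], file.path(out_dir, sprintf("report_%s.csv", nm)))
    }
    for (nm in names(plots)) {
      ggplot2::ggsave(file.path(out_dir, sprintf("report_%s.pdf", nm)),
                      plots[[nm]], width = 7, height = 5)
    }
  }
  invisible(c(plots, list(data = data)))
}
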