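#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("%s fit: logLik = %.4f, k = %d, AIC = %.4f\n",
              x$model, x$loglik, x$k, x$aic))
  p <- x$params
  if (!is.null(p)) {
    cat(sprintf("  sigma2 = %.6g", p$sigma2))
    if (x$model == "OU") cat(sprintf(", alpha = %.6g, theta = %.6g",
                                     p$alpha, p$theta))
    if (x$model == "EB") cat(sprintf(", r = %.6g, z0 = %.6g", p$r, p$z0))
    if (x$model == "BM") cat(sprintf(", z0 = %.6g", p$z0))
    cat("\n")
  }
  if (!is.null(x$boundary))
    cat("  boundary:", paste(x$boundary, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.adequacy_result <- function(x, ...) {
  cat(sprintf("Model adequacy (%s fit, %d bootstrap replicates):\n",
              x$unit_tree$fit$model, x$n_sim))
  df <- data.frame(observed = round(x$observed, 4),
                   p_value = round(x$p_values, 4),
                   flag = x$flags)
  print(df)
  invisible(x)
}

#' @export
print.dataset_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Dataset report: %d gene/tissue combinations (%d ok, %d skipped, %d failed)\n",
              s$n_total, s$n_ok, s$n_skipped, s$n_fit_failed))
  cat("Best-fit proportions:",
      paste(sprintf("%s %.3f", names(s$prop_best), s$prop_best),
            collapse = ", "), "\n")
  if (s$n_ok > 0) {
    cat("Per-statistic failure proportions:",
        paste(sprintf("%s %.3f", names(s$prop_fail_by_stat),
                      s$prop_fail_by_stat), collapse = ", "), "\n")
    cat(sprintf("Adequate on all five statistics: %.3f; best-fit OU and adequate: %.3f\n",
                s$prop_adequate_all, s$prop_ou_and_adequate))
  }
  invisible(x)
}
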