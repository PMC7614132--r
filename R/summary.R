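# Treatment-level aggregation and the two-sample comparisons named in the
# figure legends (unpaired two-tailed t-test; paired t-test). Percentages
# are relative to the total organoid count in the treatment and include an
# explicit unclassified bucket; rejected records never enter any summary.

#' Summarise organoid records per treatment
#'
#' @param records record data frame; rejected rows are dropped here (and
#'   must stay dropped downstream).
#' @param counts optional named per-organoid tuft counts keyed like
#'   `paste(image_id, organoid_id)` or a plain named vector by organoid_id
#'   for single-image record sets.
#' @return data frame, one row per treatment (sorted by name): n_organoids,
#'   percent_spheroid, percent_budding, percent_unclassified, metric means
#'   and SDs; the per-treatment value vectors are attached as the
#'   `distributions` attribute.
#' @export
summarize_treatment <- function(records, counts = NULL) {
  records <- records[records$review_status != "rejected", , drop = FALSE]
  if (nrow(records) == 0) stop("no records in treatment after exclusions")
  if (any(is.na(records$treatment) | records$treatment == ""))
    stop("record with missing treatment label")
  groups <- sort(unique(records$treatment))
  dist <- list()
  rows <- lapply(groups, function(tr) {
    r <- records[records$treatment == tr, ]
    n <- nrow(r)
    tc <- if (!is.null(counts)) {
      key <- paste(r$image_id, r$organoid_id)
      if (!is.null(names(counts)) && all(key %in% names(counts))) as.numeric(counts[key])
      else as.numeric(counts[as.character(r$organoid_id)])
    } else rep(NA_real_, n)
    dist[[tr]] <<- list(area_um2 = r$area_um2, mean_gray = r$mean_gray,
                        tuft_counts = tc)
    data.frame(treatment = tr, n_organoids = n,
               percent_spheroid = 100 * sum(r$class_label == "spheroid") / n,
               percent_budding = 100 * sum(r$class_label == "budding") / n,
               percent_unclassified = 100 * sum(r$class_label == "unclassified") / n,
               mean_area_um2 = mean(r$area_um2), sd_area_um2 = stats::sd(r$area_um2),
               mean_gray = mean(r$mean_gray), sd_gray = stats::sd(r$mean_gray),
               mean_tuft_count = mean(tc), sd_tuft_count = stats::sd(tc),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "distributions") <- dist
  out
}

#' Two-sample comparison between groups
#'
#' Two-tailed by default. `welch_t` (unequal variances) is the unpaired
#' default; `student_t` pools variances; `paired_t` requires equal n with
#' declared pairing by position. When both groups have zero variance and
#' equal means the statistic is 0 and p = 1 (no evidence of difference)
#' rather than an error.
#'
#' @param values_a,values_b numeric vectors, each n >= 2, finite.
#' @param test "welch_t", "student_t" or "paired_t".
#' @param two_tailed logical (default TRUE).
#' @param metric label carried into the result.
#' @param unit_of_replication what one value represents (e.g. "organoid",
#'   "mouse"); required declaration, recorded in the result.
#' @return list of class `group_comparison`: test, statistic, df, p_value,
#'   n per group, means, metric, unit_of_replication.
#' @export
compare_groups <- function(values_a, values_b,
                           test = c("welch_t", "student_t", "paired_t"),
                           two_tailed = TRUE, metric = "",
                           unit_of_replication = "organoid") {
  test <- match.arg(test)
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("each group needs at least 2 values")
  if (any(!is.finite(c(values_a, values_b)))) stop("values must be finite")
  if (test == "paired_t" && length(values_a) != length(values_b))
    stop("paired test requires equal group sizes")

  degenerate <- stats::var(values_a) == 0 && stats::var(values_b) == 0
  if (degenerate && mean(values_a) == mean(values_b)) {
    stat <- 0; df <- length(values_a) + length(values_b) - 2; p <- 1
  } else if (degenerate) {
    stat <- ifelse(mean(values_a) > mean(values_b), Inf, -Inf); df <- NA; p <- 0
  } else {
    ht <- stats::t.test(values_a, values_b,
                        var.equal = (test == "student_t"),
                        paired = (test == "paired_t"),
                        alternative = if (two_tailed) "two.sided" else "greater")
    stat <- unname(ht$statistic); df <- unname(ht$parameter); p <- ht$p.value
  }
  structure(list(metric = metric, test = test, statistic = stat, df = df,
                 p_value = p, two_tailed = two_tailed,
                 n = c(length(values_a), length(values_b)),
                 means = c(mean(values_a), mean(values_b)),
                 unit_of_replication = unit_of_replication),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: %s t = %.4f, df = %.4g, p = %.4g (n = %d vs %d, per %s)\n",
              x$metric, x$test, x$statistic, x$df, x$p_value,
              x$n[1], x$n[2], x$unit_of_replication))
  invisible(x)
}

#' Standard figures from a treatment summary
#'
#' Presentation only — no computation beyond binning. Kinds:
#' `scatter_gray_vs_area` (per-organoid gray value vs area, the standard
#' morphology overview), `count_histogram` (tuft-count histogram per
#' treatment), `group_dots` (per-treatment metric dots).
#'
#' @param records record data frame (rejected rows are dropped).
#' @param kind figure kind.
#' @param path output file (png or pdf).
#' @param counts optional per-organoid tuft counts for `count_histogram`.
#' @return `path`, invisibly; empty treatments are skipped with a warning.
#' @export
plot_distributions <- function(records, kind = c("scatter_gray_vs_area",
                                                 "count_histogram", "group_dots"),
                               path, counts = NULL) {
  kind <- match.arg(kind)
  records <- records[records$review_status != "rejected", , drop = FALSE]
  if (nrow(records) == 0) {
    warning("no records to plot; skipped")
    return(invisible(NULL))
  }
  if (kind == "scatter_gray_vs_area") {
    p <- ggplot2::ggplot(records,
           ggplot2::aes(x = .data$area_um2, y = .data$mean_gray,
                        colour = .data$class_label)) +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::scale_x_log10() +
      ggplot2::facet_wrap(~treatment) +
      ggplot2::labs(x = "area (µm²)", y = "mean gray value (higher = whiter)",
                    colour = "class") +
      ggplot2::theme_bw()
  } else if (kind == "count_histogram") {
    if (is.null(counts)) stop("count_histogram needs tuft counts")
    df <- data.frame(count = as.integer(counts),
                     treatment = records$treatment[
                       match(as.integer(names(counts)), records$organoid_id)])
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$count)) +
      ggplot2::geom_histogram(binwidth = 1, boundary = -0.5) +
      ggplot2::facet_wrap(~treatment) +
      ggplot2::labs(x = "tuft cells per organoid", y = "organoids") +
      ggplot2::theme_bw()
  } else {
    p <- ggplot2::ggplot(records,
           ggplot2::aes(x = .data$treatment, y = .data$mean_gray)) +
      ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.7) +
      ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4) +
      ggplot2::labs(x = NULL, y = "mean gray value") +
      ggplot2::theme_bw()
  }
  ggplot2::ggsave(path, p, width = 7, height = 5, dpi = 150)
  invisible(path)
}
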