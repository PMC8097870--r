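#' Significance stars for adjusted p values
#'
#' Mapping: p < 0.05 `*`, < 0.01 `**`, < 0.001 `***`, < 0.0001 `****`,
#' otherwise `ns`.
#'
#' @param p Numeric p values in `[0, 1]`.
#' @return Character vector of star codes.
#' @export
significance_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE) |>
    as.character()
}

check_group_data <- function(data, min_groups = 2L) {
  if (!all(c("group", "value") %in% names(data))) {
    abort("`data` must have columns `group` and `value`")
  }
  data <- data[is.finite(data$value), , drop = FALSE]
  data$group <- factor(data$group)
  sizes <- table(data$group)
  if (length(sizes) < min_groups) {
    abort(sprintf("need >= %d groups, got %d", min_groups, length(sizes)))
  }
  if (any(sizes < 2L)) abort("each group needs >= 2 values")
  data
}

#' One-way analysis of variance across groups
#'
#' Classical equal-variance one-way ANOVA (between/within mean-square ratio,
#' p from the F distribution). Degenerate data with zero within- and
#' between-group variance give `F = 0`, `p = 1`.
#'
#' @param data Tidy data frame with columns `group`, `value`.
#' @return One-row tibble: `statistic` (F), `p.value`, `df_between`,
#'   `df_within`.
#' @export
one_way_anova <- function(data) {
  data <- check_group_data(data)
  if (stats::var(data$value) == 0) {  # all observations identical
    return(tibble(statistic = 0, p.value = 1,
                  df_between = nlevels(data$group) - 1L,
                  df_within = nrow(data) - nlevels(data$group)))
  }
  fit <- aov(value ~ group, data = data)
  tab <- summary(fit)[[1L]]
  fstat <- tab[["F value"]][1L]
  p <- tab[["Pr(>F)"]][1L]
  if (!is.finite(fstat)) {  # zero within-group variance
    ms_between <- tab[["Mean Sq"]][1L]
    if (ms_between <= .Machine$double.eps) {
      fstat <- 0; p <- 1
    } else {
      fstat <- Inf; p <- 0
    }
  }
  tibble(statistic = fstat, p.value = p,
         df_between = tab[["Df"]][1L], df_within = tab[["Df"]][2L])
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range-based adjusted p values for all group pairs after
#' one-way ANOVA; unbalanced designs use the Tukey-Kramer form (as provided
#' by [stats::TukeyHSD()]).
#'
#' @param data Tidy data frame with columns `group`, `value`.
#' @return Tibble: `group1`, `group2`, `mean_diff`, `conf.low`, `conf.high`,
#'   `adj.p.value`, `stars`.
#' @export
tukey_hsd <- function(data) {
  data <- check_group_data(data)
  fit <- aov(value ~ group, data = data)
  tab <- TukeyHSD(fit)$group
  pairs <- strsplit(rownames(tab), "-", fixed = TRUE)
  out <- tibble(
    group1 = vapply(pairs, `[`, character(1L), 1L),
    group2 = vapply(pairs, `[`, character(1L), 2L),
    mean_diff = unname(tab[, "diff"]),
    conf.low = unname(tab[, "lwr"]),
    conf.high = unname(tab[, "upr"]),
    adj.p.value = unname(tab[, "p adj"]))
  out$stars <- significance_stars(out$adj.p.value)
  out
}

#' Compare normalised rates across groups
#'
#' One-way ANOVA with post hoc Tukey HSD, the standard comparison of
#' cell-line or treatment groups of normalised OCR/ECAR values.
#'
#' @param data Tidy data frame with columns `group`, `value`.
#' @return A `group_comparison`: list with `anova` (from [one_way_anova()]),
#'   `pairwise` (from [tukey_hsd()]) and the input data.
#' @export
compare_groups <- function(data) {
  data <- check_group_data(data)
  structure(list(anova = one_way_anova(data), pairwise = tukey_hsd(data),
                 data = as_tibble(data)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  a <- x$anova
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              a$df_between, a$df_within, a$statistic, a$p.value))
  cat("Pairwise (Tukey HSD):\n")
  print(as.data.frame(x$pairwise), row.names = FALSE)
  invisible(x)
}

#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) x$pairwise

#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) x$anova

#' Write a comparison report
#'
#' A comparison CSV (`group1,group2,mean_diff,adj_p,stars`) and, optionally,
#' a short text report with the ANOVA line and starred pairs.
#'
#' @param cmp A `group_comparison`.
#' @param csv_path Output CSV path.
#' @param txt_path Optional text report path.
#' @export
write_comparison <- function(cmp, csv_path, txt_path = NULL) {
  df <- as.data.frame(cmp$pairwise[, c("group1", "group2", "mean_diff",
                                       "adj.p.value", "stars")])
  names(df) <- c("group1", "group2", "mean_diff", "adj_p", "stars")
  utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(txt_path)) {
    a <- cmp$anova
    lines <- c(sprintf("One-way ANOVA: F(%d, %d) = %.6g, p = %.6g",
                       a$df_between, a$df_within, a$statistic, a$p.value),
               sprintf("%s vs %s: diff = %.6g, adj p = %.6g %s",
                       df$group1, df$group2, df$mean_diff, df$adj_p, df$stars))
    writeLines(lines, txt_path)
  }
  invisible(csv_path)
}

#' Dot plot of group values with mean lines
#'
#' The standard presentation of normalised OCR/ECAR comparisons: one dot per
#' replicate, a horizontal bar at each group mean.
#'
#' @param object A `group_comparison`.
#' @param ... Unused.
#' @method autoplot group_comparison
#' @export
autoplot.group_comparison <- function(object, ...) {
  means <- dplyr::summarise(dplyr::group_by(object$data, .data$group),
                            value = mean(.data$value))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.12, height = 0, size = 2, alpha = 0.8) +
    ggplot2::geom_crossbar(data = means,
                           ggplot2::aes(ymin = .data$value, ymax = .data$value),
                           width = 0.4, linewidth = 0.5) +
    ggplot2::labs(x = NULL, y = "normalised rate") +
    ggplot2::theme_classic()
}
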