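#' Two-way fixed-effects ANOVA on a coefficient table slice
#'
#' Fits `value ~ cytotype * photoperiod` on one coefficient's per-plant
#' values and returns the ANOVA table with Type II sums of squares —
#' appropriate for the unbalanced cell sizes (3-11 plants) these designs
#' have, while still reporting both main effects and the interaction — plus
#' the pooled-residual context (cell means, cell sizes, residual mean
#' square and degrees of freedom) that the post-hoc tests need.
#'
#' @param table a [coefficient_table()] (or data frame with columns
#'   `cytotype`, `photoperiod_h`, `value`, and optionally `coefficient`).
#' @param coefficient coefficient name to slice out; may be omitted when
#'   `table` already holds a single coefficient.
#' @param ss_type `"II"` (default) or `"III"` sums of squares.
#' @return A list of class `pam_anova`: `table` (tibble: term, sum_sq, df,
#'   mean_sq, statistic, p_value), `cells` (tibble: cell, cytotype,
#'   photoperiod_h, n, mean), `mse`, `df_resid`, `coefficient`.
#' @export
two_way_anova <- function(table, coefficient = NULL, ss_type = c("II", "III")) {
  ss_type <- match.arg(ss_type)
  df <- as.data.frame(table)
  if (!is.null(coefficient)) {
    if (!"coefficient" %in% names(df)) {
      pk_stop("table has no `coefficient` column to slice",
              "pamkit_validation_error")
    }
    avail <- unique(df$coefficient)
    if (!coefficient %in% avail) {
      pk_stop(sprintf("coefficient '%s' not present; available: %s",
                      coefficient, paste(sort(avail), collapse = ", ")),
              "pamkit_validation_error")
    }
    df <- df[df$coefficient == coefficient, , drop = FALSE]
  } else if ("coefficient" %in% names(df) &&
             length(unique(df$coefficient)) > 1) {
    pk_stop("table holds several coefficients; name one via `coefficient`",
            "pamkit_validation_error")
  }
  df <- df[complete.cases(df[, c("cytotype", "photoperiod_h", "value")]), ]
  df$cytotype <- factor(df$cytotype)
  df$photoperiod <- factor(df$photoperiod_h)
  if (nlevels(df$cytotype) < 2 || nlevels(df$photoperiod) < 2) {
    pk_stop("need >= 2 levels of both cytotype and photoperiod",
            "pamkit_validation_error")
  }
  tab <- table(df$cytotype, df$photoperiod)
  if (any(tab == 0)) {
    idx <- which(tab == 0, arr.ind = TRUE)[1, ]
    pk_stop(sprintf("empty design cell (%s, %s h)",
                    rownames(tab)[idx[1]], colnames(tab)[idx[2]]),
            "pamkit_validation_error")
  }
  k <- nlevels(df$cytotype) * nlevels(df$photoperiod)
  if (nrow(df) - k < 1) {
    pk_stop("zero residual degrees of freedom: need replicates within cells",
            "pamkit_validation_error")
  }
  fit <- lm(value ~ cytotype * photoperiod, data = df)
  rss <- sum(residuals(fit)^2)
  if (rss <= .Machine$double.eps * sum(df$value^2)) {
    pk_stop("degenerate data: zero residual variance (all replicates identical)",
            "pamkit_degenerate_data_error")
  }
  a <- car::Anova(fit, type = ss_type)
  an <- as.data.frame(a)
  term_map <- c("cytotype" = "cytotype", "photoperiod" = "photoperiod",
                "cytotype:photoperiod" = "cytotype:photoperiod",
                "Residuals" = "residual")
  out <- tibble(
    term = unname(term_map[rownames(an)]),
    sum_sq = an[["Sum Sq"]],
    df = an[["Df"]],
    mean_sq = an[["Sum Sq"]] / an[["Df"]],
    statistic = an[["F value"]],
    p_value = an[["Pr(>F)"]]
  )
  res <- out[out$term == "residual", ]
  agg <- aggregate(value ~ cytotype + photoperiod, df, mean)
  nn <- aggregate(value ~ cytotype + photoperiod, df, length)
  cells <- tibble(
    cell = paste(as.character(agg$cytotype), as.character(agg$photoperiod),
                 sep = ":"),
    cytotype = as.character(agg$cytotype),
    photoperiod_h = as.numeric(as.character(agg$photoperiod)),
    n = nn$value,
    mean = agg$value
  )
  structure(
    list(table = out, cells = cells, mse = res$mean_sq, df_resid = res$df,
         coefficient = coefficient, ss_type = ss_type, data = df),
    class = "pam_anova"
  )
}

#' @export
print.pam_anova <- function(x, ...) {
  cat(sprintf("<pam_anova%s> Type %s SS, residual df = %d, MSE = %.4g\n",
              if (!is.null(x$coefficient)) paste0(" ", x$coefficient) else "",
              x$ss_type, x$df_resid, x$mse))
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}
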