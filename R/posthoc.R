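# Post-hoc machinery behind the significance letters: Tukey HSD (Tukey-
# Kramer for unbalanced cells), Duncan's multiple range test with the
# classical step-down protection levels, and the insert-and-absorb compact
# letter display.

posthoc_groups <- function(anova, factors) {
  cells <- anova$cells
  switch(factors,
    cell = tibble(group = cells$cell, n = cells$n, mean = cells$mean),
    cytotype = {
      agg <- aggregate(value ~ cytotype, anova$data, mean)
      nn <- aggregate(value ~ cytotype, anova$data, length)
      tibble(group = as.character(agg$cytotype), n = nn$value,
             mean = agg$value)
    },
    photoperiod = {
      agg <- aggregate(value ~ photoperiod, anova$data, mean)
      nn <- aggregate(value ~ photoperiod, anova$data, length)
      tibble(group = as.character(agg$photoperiod), n = nn$value,
             mean = agg$value)
    }
  )
}

new_posthoc <- function(method, alpha, comparisons, groups, letters_map) {
  structure(
    list(method = method, alpha = alpha, comparisons = comparisons,
         groups = groups, letters = letters_map),
    class = "posthoc_result"
  )
}

#' Tukey HSD on the cytotype x photoperiod cells
#'
#' Tukey-Kramer test of all pairwise differences between the (by default)
#' eight design-cell means, using the pooled residual mean square of the
#' two-way ANOVA: pair (i, j) is significant at level `alpha` when
#' |m_i - m_j| > q(1 - alpha; k, df) sqrt(MSE/2 (1/n_i + 1/n_j)).
#'
#' @param anova a `pam_anova` from [two_way_anova()].
#' @param alpha familywise error rate, default 0.05 (the "95 %" letters).
#' @param factors compare the 8 cells (default) or the marginal means of
#'   one factor.
#' @return A `posthoc_result`: `comparisons` (tibble with columns group_a,
#'   group_b, diff, se, critical, p_value, significant), `groups` (means),
#'   and `letters` — the compact letter display, where groups sharing a
#'   letter are not significantly different.
#' @export
tukey_hsd <- function(anova, alpha = 0.05,
                      factors = c("cell", "cytotype", "photoperiod")) {
  stopifnot(inherits(anova, "pam_anova"))
  factors <- match.arg(factors)
  check_number(alpha, "alpha", lower = 1e-6, upper = 0.5)
  g <- posthoc_groups(anova, factors)
  k <- nrow(g)
  qcrit <- studentized_range_quantile(1 - alpha, k, anova$df_resid)
  pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  comp <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    se <- sqrt(anova$mse / 2 * (1 / g$n[i] + 1 / g$n[j]))
    d <- g$mean[i] - g$mean[j]
    tibble(group_a = g$group[i], group_b = g$group[j], diff = d, se = se,
           critical = qcrit * se,
           p_value = 1 - studentized_range_cdf(abs(d) / se, k,
                                               anova$df_resid),
           significant = abs(d) > qcrit * se)
  }))
  sig <- significance_matrix(g$group, comp)
  new_posthoc("tukey", alpha, comp, g, compact_letter_display(sig))
}

#' Duncan's multiple range test on the design cells
#'
#' Classical step-down multiple range test: means are ordered, and the
#' difference between two means that are `p` ordered positions apart is
#' referred to the studentized range quantile at the protection level
#' alpha_p = 1 - (1 - alpha)^(p - 1), i.e. q(1 - alpha_p; p, df). Testing
#' proceeds from the widest span downwards with the usual blocking rule: a
#' pair lying inside a span already declared non-significant is never
#' declared significant. For two groups alpha_2 = alpha and the test
#' coincides with Tukey's; because its critical values never exceed
#' Tukey's, Duncan rejects at least as often. Standard errors use the
#' Kramer form for unequal cell sizes. Duncan's procedure yields
#' decisions, not exact p-values: `p_value` is reported as NA and the
#' per-span protection level is given in `alpha_span`.
#'
#' @inheritParams tukey_hsd
#' @return A `posthoc_result` (see [tukey_hsd()]); comparisons carry
#'   `span` and `alpha_span` instead of an exact p-value.
#' @export
duncan_mrt <- function(anova, alpha = 0.05,
                       factors = c("cell", "cytotype", "photoperiod")) {
  stopifnot(inherits(anova, "pam_anova"))
  factors <- match.arg(factors)
  check_number(alpha, "alpha", lower = 1e-6, upper = 0.5)
  g <- posthoc_groups(anova, factors)
  ord <- order(g$mean, decreasing = TRUE)
  g <- g[ord, ]
  k <- nrow(g)
  sig <- matrix(FALSE, k, k, dimnames = list(g$group, g$group))
  blocked <- matrix(FALSE, k, k)
  rows <- list()
  for (span in seq(k, 2)) {
    alpha_span <- 1 - (1 - alpha)^(span - 1)
    qcrit <- studentized_range_quantile(1 - alpha_span, span, anova$df_resid)
    for (i in seq_len(k - span + 1)) {
      j <- i + span - 1
      se <- sqrt(anova$mse / 2 * (1 / g$n[i] + 1 / g$n[j]))
      d <- g$mean[i] - g$mean[j]
      is_sig <- !blocked[i, j] && abs(d) > qcrit * se
      if (!is_sig) {
        # blocking rule: protect every pair inside this span
        for (a in i:(j - 1)) for (b in (a + 1):j) blocked[a, b] <- TRUE
      } else {
        sig[i, j] <- sig[j, i] <- TRUE
      }
      rows[[length(rows) + 1L]] <- tibble(
        group_a = g$group[i], group_b = g$group[j], diff = d, se = se,
        span = span, alpha_span = alpha_span, critical = qcrit * se,
        p_value = NA_real_, significant = is_sig)
    }
  }
  comp <- do.call(rbind, rows)
  new_posthoc("duncan", alpha, comp, g, compact_letter_display(sig))
}

# pairwise tibble -> symmetric logical matrix
significance_matrix <- function(groups, comparisons) {
  k <- length(groups)
  m <- matrix(FALSE, k, k, dimnames = list(groups, groups))
  for (r in seq_len(nrow(comparisons))) {
    a <- comparisons$group_a[r]; b <- comparisons$group_b[r]
    m[a, b] <- m[b, a] <- comparisons$significant[r]
  }
  m
}

#' Compact letter display from a pairwise significance matrix
#'
#' Insert-and-absorb algorithm: start with all groups in one letter class;
#' for every significantly different pair, split each class containing
#' both into two (one without each member); absorb classes that are
#' subsets of others. The result satisfies the display contract exactly —
#' two groups share at least one letter if and only if they are not
#' significantly different. Minimality of the letter count is attempted
#' via absorption but not guaranteed.
#'
#' @param sig_matrix symmetric logical matrix (TRUE = significantly
#'   different) with group names as dimnames.
#' @return Named character vector: letter string per group.
#' @export
compact_letter_display <- function(sig_matrix) {
  if (!is.matrix(sig_matrix) || nrow(sig_matrix) != ncol(sig_matrix) ||
      !identical(sig_matrix, t(sig_matrix))) {
    pk_stop("significance matrix must be symmetric", "pamkit_validation_error")
  }
  groups <- rownames(sig_matrix)
  if (is.null(groups)) groups <- as.character(seq_len(nrow(sig_matrix)))
  k <- length(groups)
  classes <- list(seq_len(k))
  pairs <- which(upper.tri(sig_matrix) & sig_matrix, arr.ind = TRUE)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    nxt <- list()
    for (cl in classes) {
      if (i %in% cl && j %in% cl) {
        nxt[[length(nxt) + 1L]] <- setdiff(cl, i)
        nxt[[length(nxt) + 1L]] <- setdiff(cl, j)
      } else {
        nxt[[length(nxt) + 1L]] <- cl
      }
    }
    nxt <- unique(lapply(Filter(length, nxt), sort))
    # absorb classes strictly contained in another
    keep <- vapply(seq_along(nxt), function(a) {
      !any(vapply(seq_along(nxt), function(b) {
        b != a && length(nxt[[a]]) < length(nxt[[b]]) &&
          all(nxt[[a]] %in% nxt[[b]])
      }, logical(1)))
    }, logical(1))
    classes <- nxt[keep]
  }
  classes <- classes[order(vapply(classes, min, numeric(1)))]
  alphabet <- c(letters, as.vector(outer(letters, letters, paste0)))
  out <- setNames(rep("", k), groups)
  for (ci in seq_along(classes)) {
    for (g in classes[[ci]]) out[g] <- paste0(out[g], alphabet[ci])
  }
  out
}

#' @export
print.posthoc_result <- function(x, ...) {
  cat(sprintf("<posthoc_result %s, alpha = %g>\n", x$method, x$alpha))
  df <- as.data.frame(x$groups)
  df$letters <- x$letters[df$group]
  print(df, digits = 4)
  nsig <- sum(x$comparisons$significant)
  cat(sprintf("%d of %d pairwise comparisons significant\n",
              nsig, nrow(x$comparisons)))
  invisible(x)
}

#' One-stop group comparison of a coefficient
#'
#' Slices one coefficient out of a tidy [coefficient_table()], runs the
#' two-way ANOVA, the chosen post-hoc test on the eight design cells and
#' the compact letter display. The per-intensity light-curve entries
#' (`rETR@10` ... `rETR@500`) are ordinary coefficient names, so the
#' per-PPFD panels are produced by calling this once per entry.
#'
#' @param table a [coefficient_table()].
#' @param coefficient one coefficient name present in `table`.
#' @param method `"tukey"` or `"duncan"`.
#' @param alpha significance level, default 0.05.
#' @param factors see [tukey_hsd()].
#' @param ss_type ANOVA sums-of-squares type, see [two_way_anova()].
#' @return A list of class `coefficient_analysis`: `coefficient`, `anova`
#'   (`pam_anova`), `posthoc` (`posthoc_result`), `letters`.
#' @export
analyze_coefficient <- function(table, coefficient,
                                method = c("tukey", "duncan"),
                                alpha = 0.05, factors = "cell",
                                ss_type = "II") {
  method <- match.arg(method)
  anova <- two_way_anova(table, coefficient, ss_type = ss_type)
  ph <- switch(method,
               tukey = tukey_hsd(anova, alpha, factors),
               duncan = duncan_mrt(anova, alpha, factors))
  structure(
    list(coefficient = coefficient, anova = anova, posthoc = ph,
         letters = ph$letters),
    class = "coefficient_analysis"
  )
}

#' @export
print.coefficient_analysis <- function(x, ...) {
  cat(sprintf("== %s ==\n", x$coefficient))
  print(x$anova)
  print(x$posthoc)
  invisible(x)
}
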