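# Group comparisons of per-well endpoints: one-way fixed-effects ANOVA,
# Tukey HSD post-hoc tests, and compact letter displays. Homogeneity of
# variance is assumed (the analysis convention for these assays); a
# Brown-Forsythe/Levene diagnostic is reported but never gates.

as_group_list <- function(x, group = NULL) {
  if (is.list(x) && !is.data.frame(x)) return(x)
  if (is.data.frame(x)) return(split(x$value, x$treatment_id))
  split(x, group)
}

check_groups <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  sizes <- lengths(groups)
  if (any(sizes < 2))
    stop("every group needs at least 2 values (offending group: ",
         names(groups)[which(sizes < 2)[1]], ")", call. = FALSE)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  groups
}

groups_to_frame <- function(groups) {
  data.frame(value = unlist(groups, use.names = FALSE),
             group = factor(rep(names(groups), lengths(groups)),
                            levels = names(groups)))
}

#' One-way fixed-effects ANOVA
#'
#' Classical one-way ANOVA over per-well endpoint values; all wells enter,
#' including values a box-plot convention would mark as outliers.
#'
#' @param x a named list of numeric vectors (one per treatment group), a
#'   data frame with \code{treatment_id}/\code{value} columns (e.g. from
#'   [endpoint_values()]), or a numeric vector with \code{group}.
#' @param group grouping vector when \code{x} is numeric.
#' @return list with \code{f_statistic}, \code{p_value}, \code{df_between},
#'   \code{df_within}.
#' @export
one_way_anova <- function(x, group = NULL) {
  groups <- check_groups(as_group_list(x, group))
  dat <- groups_to_frame(groups)
  fit <- stats::aov(value ~ group, data = dat)
  tab <- summary(fit)[[1]]
  list(f_statistic = tab[["F value"]][1], p_value = tab[["Pr(>F)"]][1],
       df_between = tab[["Df"]][1], df_within = tab[["Df"]][2])
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range pairwise comparisons after a one-way ANOVA, with the
#' standard harmonic-mean-style adjustment for unbalanced group sizes.
#'
#' @inheritParams one_way_anova
#' @return symmetric matrix of Tukey-adjusted p-values (diagonal \code{NA}),
#'   with the long-form comparison table in the \code{"comparisons"}
#'   attribute.
#' @export
tukey_hsd <- function(x, group = NULL) {
  groups <- check_groups(as_group_list(x, group))
  dat <- groups_to_frame(groups)
  fit <- stats::aov(value ~ group, data = dat)
  tab <- stats::TukeyHSD(fit)$group
  k <- length(groups)
  p <- matrix(NA_real_, k, k, dimnames = list(names(groups), names(groups)))
  # TukeyHSD rows follow combn(levels, 2) order as "second-first"; group
  # labels may themselves contain hyphens, so rely on order, not parsing.
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  stopifnot(nrow(tab) == length(pairs),
            identical(rownames(tab),
                      vapply(pairs, function(pr) paste(pr[2], pr[1], sep = "-"),
                             character(1))))
  for (i in seq_along(pairs)) {
    a <- pairs[[i]][1]; b <- pairs[[i]][2]
    p[a, b] <- p[b, a] <- tab[i, "p adj"]
  }
  attr(p, "comparisons") <- as.data.frame(tab)
  p
}

letter_symbols <- function(n) {
  if (n <= 26) return(letters[seq_len(n)])
  c(letters, as.vector(t(outer(letters, letters, paste0))))[seq_len(n)]
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Insert-and-absorb letter assignment: groups sharing any letter are
#' pairwise non-significant at \code{alpha}; groups sharing no letter differ
#' significantly. Non-transitive significance patterns are representable
#' (letter sets may overlap); they are never an error.
#'
#' @param p_matrix symmetric matrix of pairwise adjusted p-values with group
#'   names as dimnames, e.g. from [tukey_hsd()].
#' @param alpha significance level; p <= alpha is significant.
#' @param means optional named vector of group means; letters are assigned
#'   in order of decreasing mean so the best-performing group reads "a".
#' @return named character vector of letter sets, one per group.
#' @export
compact_letter_display <- function(p_matrix, alpha = 0.05, means = NULL) {
  g <- rownames(p_matrix)
  k <- length(g)
  stopifnot(k >= 1, identical(rownames(p_matrix), colnames(p_matrix)))
  cols <- list(seq_len(k))
  sig <- which(p_matrix <= alpha & upper.tri(p_matrix), arr.ind = TRUE)
  for (r in seq_len(nrow(sig))) {
    i <- sig[r, 1]; j <- sig[r, 2]
    nxt <- list()
    for (s in cols) {
      if (i %in% s && j %in% s)
        nxt <- c(nxt, list(setdiff(s, i)), list(setdiff(s, j)))
      else nxt <- c(nxt, list(s))
    }
    nxt <- nxt[lengths(nxt) > 0]
    # absorb: drop any set contained in another (ties keep the first)
    keep <- rep(TRUE, length(nxt))
    for (a in seq_along(nxt)) for (b in seq_along(nxt)) {
      if (a == b || !keep[a]) next
      if (all(nxt[[a]] %in% nxt[[b]]) &&
          (length(nxt[[a]]) < length(nxt[[b]]) || a > b)) keep[a] <- FALSE
    }
    cols <- nxt[keep]
  }
  ord <- if (!is.null(means)) {
    vapply(cols, function(s) -max(means[g[s]]), numeric(1))
  } else {
    vapply(cols, min, numeric(1))
  }
  cols <- cols[order(ord)]
  sym <- letter_symbols(length(cols))
  membership <- vapply(cols, function(s) seq_len(k) %in% s, logical(k))
  membership <- matrix(membership, nrow = k,
                       dimnames = list(g, sym))
  out <- apply(membership, 1, function(m) paste(sym[m], collapse = ""))
  names(out) <- g
  attr(out, "membership") <- membership
  out
}

# Brown-Forsythe variant of Levene's test (ANOVA on deviations from group
# medians); reported as a diagnostic only.
levene_p <- function(groups) {
  dev <- lapply(groups, function(v) abs(v - stats::median(v)))
  if (all(vapply(dev, stats::var, numeric(1)) == 0)) return(NA_real_)
  one_way_anova(dev)$p_value
}

#' Compare treatment groups on one endpoint
#'
#' Full group-comparison workflow for a per-well endpoint: one-way ANOVA,
#' Tukey HSD pairwise p-values, and a compact letter display. Undefined
#' fecundity indices (progeny recovered but no live adults) are excluded
#' listwise.
#'
#' @param wells validated well table (single species).
#' @param endpoint endpoint name, see [endpoint_values()].
#' @param alpha significance level for the letter display.
#' @param zero_recovery passed to [fecundity_index()].
#' @return an object of class \code{group_comparison}: list with
#'   \code{endpoint}, \code{groups}, \code{group_means},
#'   \code{f_statistic}, \code{p_value}, \code{pairwise} (matrix),
#'   \code{letters}, \code{alpha} and \code{levene_p} (diagnostic).
#' @export
compare_groups <- function(wells, endpoint = "p0_recovery", alpha = 0.05,
                           zero_recovery = c("zero", "exclude")) {
  vals <- endpoint_values(wells, endpoint, zero_recovery)
  groups <- check_groups(split(vals$value, vals$treatment_id))
  aov_res <- one_way_anova(groups)
  p <- tukey_hsd(groups)
  means <- vapply(groups, mean, numeric(1))
  letters_out <- compact_letter_display(p, alpha = alpha, means = means)
  structure(list(endpoint = endpoint, groups = names(groups),
                 group_means = means, f_statistic = aov_res$f_statistic,
                 p_value = aov_res$p_value, pairwise = p,
                 letters = letters_out, alpha = alpha,
                 levene_p = levene_p(groups)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison of %s across %d treatments\n",
              x$endpoint, length(x$groups)))
  cat(sprintf("  one-way ANOVA: F = %.4g, p = %.4g\n",
              x$f_statistic, x$p_value))
  if (!is.na(x$levene_p))
    cat(sprintf("  variance-homogeneity diagnostic (Brown-Forsythe) p = %.3g\n",
                x$levene_p))
  tab <- data.frame(mean = round(x$group_means, 3), letters = x$letters)
  print(tab)
  invisible(x)
}
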