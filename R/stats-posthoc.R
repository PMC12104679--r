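#' Pairwise t tests with Bonferroni correction
#'
#' All pairwise comparisons between groups, with the family size `m`
#' equal to the number of pairs and adjusted p values `min(1, m * p)`.
#' Comparisons across days within a treatment are typically paired on the
#' subject id (same seedlings re-measured); comparisons across treatments
#' at a day are unpaired.
#'
#' @param values Numeric response.
#' @param group Grouping vector (coerced to factor).
#' @param subject Subject ids, required when `paired = TRUE` (pairs are
#'   matched on subject within each group pair).
#' @param paired Paired t tests (default `FALSE`).
#' @param alpha Significance level for the letter display (default 0.05).
#' @return List of class `group_comparison`: `test`, `table` (one row per
#'   pair with statistic, df, `p_raw`, `p_adj`, `significant`), `letters`
#'   (compact letter display), `m`.
#' @export
pairwise_t_bonferroni <- function(values, group, subject = NULL,
                                  paired = FALSE, alpha = 0.05) {
  group <- factor(group)
  lev <- levels(group)
  sizes <- table(group)
  usable <- names(sizes)[sizes >= 2]
  if (length(usable) < length(lev)) {
    warning("groups with n < 2 excluded: ",
            paste(setdiff(lev, usable), collapse = ", "))
  }
  if (length(usable) < 2) stop("need >= 2 groups with n >= 2", call. = FALSE)
  if (paired && is.null(subject)) {
    stop("paired tests need subject ids", call. = FALSE)
  }
  pairs <- utils::combn(usable, 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    x <- values[group == g1]; y <- values[group == g2]
    if (paired) {
      s1 <- subject[group == g1]; s2 <- subject[group == g2]
      common <- intersect(s1, s2)
      x <- x[match(common, s1)]; y <- y[match(common, s2)]
    }
    degenerate <- if (paired) stats::sd(x - y) == 0 else
      stats::sd(x) == 0 && stats::sd(y) == 0
    if (degenerate) {
      ## constant data: identical groups are trivially non-significant,
      ## a constant nonzero shift trivially significant
      delta <- mean(x) - mean(y)
      data.frame(group1 = g1, group2 = g2,
                 statistic = ifelse(delta == 0, 0, sign(delta) * Inf),
                 df = NA_real_, p_raw = as.numeric(delta == 0),
                 stringsAsFactors = FALSE)
    } else {
      tt <- if (paired) stats::t.test(x, y, paired = TRUE) else
        stats::t.test(x, y, var.equal = TRUE)
      data.frame(group1 = g1, group2 = g2,
                 statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_raw = tt$p.value, stringsAsFactors = FALSE)
    }
  })
  tab <- do.call(rbind, rows)
  tab$p_adj <- pmin(1, m * tab$p_raw)
  tab$significant <- tab$p_adj < alpha
  sig <- matrix(FALSE, length(usable), length(usable),
                dimnames = list(usable, usable))
  for (i in seq_len(m)) {
    sig[tab$group1[i], tab$group2[i]] <- tab$significant[i]
    sig[tab$group2[i], tab$group1[i]] <- tab$significant[i]
  }
  out <- list(test = if (paired) "paired t (Bonferroni)" else
                "t (Bonferroni)",
              table = tab, letters = compact_letter_display(sig), m = m)
  class(out) <- "group_comparison"
  out
}

#' Compact letter display from a significance matrix
#'
#' Insert-absorb letter assignment with a completion pass: the result is
#' not guaranteed to use a minimal number of letters, but it is guaranteed
#' correct -- two groups share at least one letter if and only if their
#' comparison is non-significant.
#'
#' @param sig Symmetric logical matrix (`TRUE` = significantly different)
#'   with group names as dimnames.
#' @return Named character vector of letter strings per group.
#' @export
compact_letter_display <- function(sig) {
  stopifnot(is.matrix(sig), nrow(sig) == ncol(sig))
  if (!isSymmetric(unname(sig))) {
    stop("significance matrix must be symmetric", call. = FALSE)
  }
  k <- nrow(sig)
  groups <- rownames(sig) %||% as.character(seq_len(k))
  sets <- list(seq_len(k))
  absorb <- function(sets) {
    sets <- unique(lapply(sets, sort))
    keep <- rep(TRUE, length(sets))
    for (i in seq_along(sets)) {
      for (j in seq_along(sets)) {
        if (i != j && keep[j] && length(sets[[i]]) < length(sets[[j]]) &&
            all(sets[[i]] %in% sets[[j]])) {
          keep[i] <- FALSE
          break
        }
      }
    }
    sets[keep]
  }
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (!sig[i, j]) next
      hit <- vapply(sets, function(s) all(c(i, j) %in% s), logical(1))
      if (!any(hit)) next
      for (s in sets[hit]) {
        sets[[length(sets) + 1L]] <- setdiff(s, i)
        sets[[length(sets) + 1L]] <- setdiff(s, j)
      }
      sets <- sets[!hit]
      sets <- sets[lengths(sets) > 0]
      sets <- absorb(sets)
    }
  }
  ## completion: every non-significant pair must share a letter
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (sig[i, j]) next
      hit <- any(vapply(sets, function(s) all(c(i, j) %in% s), logical(1)))
      if (!hit) sets[[length(sets) + 1L]] <- c(i, j)
    }
  }
  ## isolated groups still need a letter
  for (i in seq_len(k)) {
    if (!any(vapply(sets, function(s) i %in% s, logical(1)))) {
      sets[[length(sets) + 1L]] <- i
    }
  }
  sets <- sets[order(vapply(sets, min, numeric(1)))]
  letter_pool <- c(letters, paste0(rep(letters, each = 26), letters))
  out <- vapply(seq_len(k), function(i) {
    paste0(letter_pool[which(vapply(sets, function(s) i %in% s, logical(1)))],
           collapse = "")
  }, character(1))
  stats::setNames(out, groups)
}

#' Kruskal-Wallis test followed by pairwise Mann-Whitney tests
#'
#' The nonparametric battery for small-sample (n <= 10) seedling-level
#' parameters: a tie-corrected Kruskal-Wallis test across all groups and,
#' when it is significant at `alpha`, all pairwise Mann-Whitney (Wilcoxon
#' rank-sum) tests with Bonferroni correction. The exact Mann-Whitney null
#' distribution is used whenever the data are tie-free (combined n up to
#' 100); the tie-corrected normal approximation otherwise.
#'
#' @inheritParams pairwise_t_bonferroni
#' @return List of class `group_comparison` with `kw` (list: `h`, `df`,
#'   `p`), `table` (pairwise results, `NULL` when the omnibus test is not
#'   significant), `letters`, `m`.
#' @export
kw_mw_battery <- function(values, group, alpha = 0.05) {
  group <- factor(group)
  lev <- levels(group)
  if (length(lev) < 2) stop("need >= 2 groups", call. = FALSE)
  if (length(unique(values)) == 1) {
    kw <- list(h = 0, df = length(lev) - 1, p = 1)
  } else {
    k <- stats::kruskal.test(values, group)
    kw <- list(h = unname(k$statistic), df = unname(k$parameter),
               p = k$p.value)
  }
  out <- list(test = "Kruskal-Wallis + Mann-Whitney (Bonferroni)", kw = kw,
              table = NULL,
              letters = stats::setNames(rep("a", length(lev)), lev),
              m = 0L)
  class(out) <- "group_comparison"
  if (kw$p >= alpha) return(out)

  pairs <- utils::combn(lev, 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(i) {
    x <- values[group == pairs[1, i]]
    y <- values[group == pairs[2, i]]
    ties <- anyDuplicated(c(x, y)) > 0
    exact <- !ties && (length(x) + length(y)) <= 100
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                              correct = !exact))
    data.frame(group1 = pairs[1, i], group2 = pairs[2, i],
               u = unname(wt$statistic), exact = exact, p_raw = wt$p.value,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$p_adj <- pmin(1, m * tab$p_raw)
  tab$significant <- tab$p_adj < alpha
  sig <- matrix(FALSE, length(lev), length(lev),
                dimnames = list(lev, lev))
  for (i in seq_len(m)) {
    sig[tab$group1[i], tab$group2[i]] <- tab$significant[i]
    sig[tab$group2[i], tab$group1[i]] <- tab$significant[i]
  }
  out$table <- tab
  out$letters <- compact_letter_display(sig)
  out$m <- m
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>", x$test, "\n")
  if (!is.null(x$kw)) {
    cat(sprintf("  Kruskal-Wallis H = %.3f, df = %d, p = %.4g\n",
                x$kw$h, x$kw$df, x$kw$p))
  }
  if (!is.null(x$table)) {
    print(x$table, row.names = FALSE)
  }
  cat("  letters:", paste(names(x$letters), x$letters, sep = "=",
                          collapse = " "), "\n")
  invisible(x)
}
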