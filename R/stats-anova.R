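#' Mixed repeated-measures ANOVA
#'
#' Univariate within-between decomposition for a balanced complete design:
#' one between-subject factor (treatment) crossed with one or two
#' within-subject factors (day, or day and time of day), subjects nested
#' in treatment. Between effects are tested against subjects-within-groups;
#' each within effect and its interactions with treatment are tested
#' against the corresponding subject-by-factor stratum. No sphericity
#' correction is applied by default; `gg_correction = TRUE` applies the
#' Greenhouse-Geisser epsilon to within-effect p values.
#'
#' @param data Long-format data frame.
#' @param response Name of the numeric response column.
#' @param between Name of the between-subject factor column.
#' @param within Character vector (length 1 or 2) of within-subject factor
#'   columns.
#' @param subject Name of the subject identifier column.
#' @param gg_correction Apply Greenhouse-Geisser correction (default
#'   `FALSE`).
#' @return Data frame of class `rm_anova_table`: one row per effect with
#'   `effect`, `stratum`, `df`, `ss`, `ms`, `f`, `p` (error rows included).
#' @export
rm_anova <- function(data, response, between, within, subject,
                     gg_correction = FALSE) {
  stopifnot(length(within) %in% 1:2)
  cols <- c(response, between, within, subject)
  miss <- setdiff(cols, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  d <- data.frame(
    y = as.numeric(data[[response]]),
    B = factor(data[[between]]),
    S = factor(data[[subject]])
  )
  for (i in seq_along(within)) d[[paste0("W", i)]] <- factor(data[[within[i]]])
  if (anyNA(d$y)) stop("response contains NA; filter excluded seedlings first",
                       call. = FALSE)

  ## balance check: every subject must have exactly one row per within cell
  wcell <- interaction(d[paste0("W", seq_along(within))], drop = FALSE)
  tab <- table(d$S, wcell)
  if (any(tab != 1)) {
    bad <- which(tab != 1, arr.ind = TRUE)
    cells <- apply(bad, 1, function(ij) {
      paste0(rownames(tab)[ij[1]], " x ", colnames(tab)[ij[2]],
             " (n=", tab[ij[1], ij[2]], ")")
    })
    stop("unbalanced design; offending cells: ",
         paste(utils::head(cells, 10), collapse = "; "),
         if (length(cells) > 10) " ...", call. = FALSE)
  }
  ## subjects nested in exactly one between level
  if (any(rowSums(table(d$S, d$B) > 0) != 1)) {
    stop("each subject must belong to exactly one between-subject group",
         call. = FALSE)
  }

  wterms <- paste0("W", seq_along(within))
  rhs <- paste(c("B", wterms), collapse = " * ")
  err <- paste0("Error(S/(", paste(wterms, collapse = " * "), "))")
  form <- stats::as.formula(paste("y ~", rhs, "+", err))
  fit <- stats::aov(form, data = d)
  sm <- summary(fit)

  rows <- list()
  for (stratum_name in names(sm)) {
    t1 <- sm[[stratum_name]][[1]]
    terms <- trimws(rownames(t1))
    for (i in seq_along(terms)) {
      rows[[length(rows) + 1L]] <- data.frame(
        effect = terms[i], stratum = sub("^Error: ", "", stratum_name),
        df = t1[i, "Df"], ss = t1[i, "Sum Sq"], ms = t1[i, "Mean Sq"],
        f = if ("F value" %in% colnames(t1)) t1[i, "F value"] else NA_real_,
        p = if ("Pr(>F)" %in% colnames(t1)) t1[i, "Pr(>F)"] else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  ## translate factor aliases back to user-facing names
  alias <- c(B = between, stats::setNames(within, wterms), S = subject)
  relabel <- function(x) {
    parts <- strsplit(x, ":", fixed = TRUE)
    vapply(parts, function(p) {
      paste(ifelse(p %in% names(alias), alias[p], p), collapse = ":")
    }, character(1))
  }
  out$effect <- relabel(out$effect)
  out$stratum <- relabel(out$stratum)

  if (gg_correction) {
    for (i in which(!is.na(out$f) & out$stratum != subject)) {
      wname <- setdiff(strsplit(out$stratum[i], ":")[[1]], subject)
      eps <- gg_epsilon(d, within_cols = paste0("W", match(wname, within)))
      if (!is.na(eps) && out$df[i] > 0) {
        err_row <- which(out$stratum == out$stratum[i] &
                           out$effect == "Residuals")
        out$p[i] <- stats::pf(out$f[i], eps * out$df[i],
                              eps * out$df[err_row], lower.tail = FALSE)
      }
    }
  }
  class(out) <- c("rm_anova_table", "data.frame")
  out
}

## Greenhouse-Geisser epsilon from the subject x cell covariance of the
## (possibly collapsed) within-factor combination
gg_epsilon <- function(d, within_cols) {
  cell <- interaction(d[within_cols], drop = TRUE)
  wide <- tapply(d$y, list(d$S, cell), mean)
  if (any(is.na(wide)) || ncol(wide) < 2) return(NA_real_)
  S <- stats::cov(wide)
  k <- ncol(S)
  C <- diag(k) - 1 / k
  M <- C %*% S %*% C
  sum(diag(M))^2 / ((k - 1) * sum(M * M))
}
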