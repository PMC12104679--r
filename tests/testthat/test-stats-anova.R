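## hand-computed cell-means decomposition for a balanced 2 (between) x 2
## (within) design with subjects nested in the between factor; written
## directly from the classical SS formulas, independent of aov()
hand_rm_ss <- function(d) {
  ## d: y, B, W, S (factors); n subjects per group, all cells present
  gm <- mean(d$y)
  nB <- tapply(d$y, d$B, length)
  ss_b <- sum(tapply(d$y, d$B, function(v) length(v) * 0) +
                tapply(d$y, d$B, mean)^2 * nB) - sum(nB) * gm^2
  subj_means <- tapply(d$y, d$S, mean)
  subj_n <- tapply(d$y, d$S, length)
  ss_subj_tot <- sum(subj_n * subj_means^2) - sum(subj_n) * gm^2
  ss_subj_within <- ss_subj_tot - ss_b
  nW <- tapply(d$y, d$W, length)
  ss_w <- sum(nW * tapply(d$y, d$W, mean)^2) - sum(nW) * gm^2
  cell_bw <- tapply(d$y, list(d$B, d$W), mean)
  n_bw <- tapply(d$y, list(d$B, d$W), length)
  ss_cells_bw <- sum(n_bw * cell_bw^2) - sum(n_bw) * gm^2
  ss_bw <- ss_cells_bw - ss_b - ss_w
  ss_tot <- sum((d$y - gm)^2)
  ss_err_w <- ss_tot - ss_b - ss_subj_within - ss_w - ss_bw
  list(treatment = ss_b, subj_within = ss_subj_within, day = ss_w,
       day_treatment = ss_bw, err_within = ss_err_w)
}

test_that("rm_anova matches the hand-worked decomposition on a toy table", {
  ## 2 treatments x 2 days x 3 subjects each: 12 rows
  d <- data.frame(
    subject = rep(c("s1", "s2", "s3", "s4", "s5", "s6"), each = 2),
    treatment = rep(c("ctl", "dr"), each = 6),
    day = rep(c("d1", "d2"), 6),
    y = c(5, 6, 4, 5, 6, 8,    9, 13, 8, 11, 10, 15)
  )
  tab <- rm_anova(d, "y", between = "treatment", within = "day",
                  subject = "subject")
  hand <- hand_rm_ss(data.frame(y = d$y, B = factor(d$treatment),
                                W = factor(d$day), S = factor(d$subject)))
  get <- function(effect, stratum) {
    tab$ss[tab$effect == effect & grepl(stratum, tab$stratum)]
  }
  expect_equal(get("treatment", "subject"), hand$treatment, tolerance = 1e-10)
  expect_equal(get("Residuals", "^subject$"), hand$subj_within,
               tolerance = 1e-10)
  expect_equal(get("day", "subject:day"), hand$day, tolerance = 1e-10)
  expect_equal(get("treatment:day", "subject:day"), hand$day_treatment,
               tolerance = 1e-10)
  expect_equal(get("Residuals", "subject:day"), hand$err_within,
               tolerance = 1e-10)
  ## dfs: between stratum n_subj - 1 total; F ratios consistent with MS
  expect_equal(tab$df[tab$effect == "treatment"], 1)
  expect_equal(tab$df[tab$effect == "Residuals" & tab$stratum == "subject"], 4)
  fx <- tab[tab$effect == "day", ]
  err <- tab[tab$effect == "Residuals" & tab$stratum == "subject:day", ]
  expect_equal(fx$f, fx$ms / err$ms, tolerance = 1e-10)
  ## SS additivity over the whole table
  expect_equal(sum(tab$ss), sum((d$y - mean(d$y))^2), tolerance = 1e-10)
})

test_that("rm_anova supports two within factors with the right strata", {
  set.seed(1)
  d <- expand.grid(subject = sprintf("s%02d", 1:8),
                   day = c("d1", "d2", "d3"), time = c("M", "E"),
                   stringsAsFactors = FALSE)
  d$treatment <- ifelse(d$subject %in% sprintf("s%02d", 1:4), "ctl", "dr")
  d$y <- rnorm(nrow(d))
  tab <- rm_anova(d, "y", between = "treatment",
                  within = c("day", "time"), subject = "subject")
  expect_setequal(
    unique(tab$stratum),
    c("subject", "subject:day", "subject:time", "subject:day:time"))
  ## three-way interaction lives in the triple stratum
  expect_true("treatment:day:time" %in%
                tab$effect[tab$stratum == "subject:day:time"])
})

test_that("rm_anova rejects unbalanced designs, naming offending cells", {
  d <- data.frame(subject = c("s1", "s1", "s2"),
                  treatment = c("a", "a", "b"),
                  day = c("d1", "d2", "d1"), y = 1:3)
  expect_error(rm_anova(d, "y", "treatment", "day", "subject"),
               "unbalanced.*s2", ignore.case = TRUE)
  d2 <- data.frame(subject = rep(c("s1", "s2"), each = 2),
                   treatment = c("a", "b", "a", "a"),
                   day = rep(c("d1", "d2"), 2), y = 1:4)
  expect_error(rm_anova(d2, "y", "treatment", "day", "subject"),
               "exactly one")
  d3 <- data.frame(subject = rep(c("s1", "s2"), each = 2),
                   treatment = "a", day = rep(c("d1", "d2"), 2),
                   y = c(1, NA, 2, 3))
  expect_error(rm_anova(d3, "y", "treatment", "day", "subject"), "NA")
})

test_that("identical responses give zero effect SS", {
  d <- expand.grid(subject = sprintf("s%d", 1:6), day = c("d1", "d2"),
                   stringsAsFactors = FALSE)
  d$treatment <- ifelse(d$subject %in% c("s1", "s2", "s3"), "a", "b")
  d$y <- 7
  tab <- rm_anova(d, "y", "treatment", "day", "subject")
  expect_true(all(tab$ss < 1e-20))
})

test_that("type-I error calibration under the null (reduced runs)", {
  ## scaled-down calibration: 200 replicates (the acceptance suite runs
  ## the full 1,000); band widened accordingly
  set.seed(99)
  n_rep <- 200
  rej <- logical(n_rep)
  grid <- expand.grid(subject = sprintf("s%02d", 1:20),
                      day = c("d1", "d2", "d3"), stringsAsFactors = FALSE)
  grid$treatment <- ifelse(grid$subject %in% sprintf("s%02d", 1:10),
                           "ctl", "dr")
  for (i in seq_len(n_rep)) {
    grid$y <- rnorm(nrow(grid))
    tab <- rm_anova(grid, "y", "treatment", "day", "subject")
    rej[i] <- tab$p[tab$effect == "treatment"] < 0.05
  }
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})
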