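# Statistical workflow on a long-format cohort table:
# assumption checks (Shapiro-Wilk, Levene), preliminary side comparison,
# within-group repeated-measures ANOVA across sessions with
# Greenhouse-Geisser correction and Holm-corrected paired post hocs,
# 2 x 2 mixed-design session x group ANOVA, control-group paired PRE-POST
# tests, Cohen's d with effect-size bands, and the per-repetition fatigue
# analysis.

.sessions_all <- c("PRE", "ACUTE", "POST")

#' Cohen's d effect-size band
#'
#' Bands (left-closed): `|d| < 0.20` small, `0.20 <= |d| < 0.50` moderate,
#' `0.50 <= |d| < 0.80` large, `|d| >= 0.80` very large.
#'
#' @param d Cohen's d.
#' @return character band.
#' @export
effect_band <- function(d) {
  ad <- abs(d)
  ifelse(ad < 0.20, "small",
         ifelse(ad < 0.50, "moderate",
                ifelse(ad < 0.80, "large", "very large")))
}

#' Cohen's d
#'
#' Paired mode: `mean(x - y) / sd(x - y)`. Pooled mode for two independent
#' samples: `(mean(y) - mean(x)) / sqrt((sd(x)^2 + sd(y)^2) / 2)` (average
#' of the two variances).
#'
#' @param x,y numeric samples (paired samples must be equal length).
#' @param mode `"paired"` or `"pooled"`.
#' @return list with `d` and `band`.
#' @export
cohens_d <- function(x, y, mode = c("paired", "pooled")) {
  mode <- match.arg(mode)
  if (length(x) < 2 || length(y) < 2) stop("need n >= 2 per sample")
  if (mode == "paired") {
    if (length(x) != length(y)) stop("paired mode needs equal lengths")
    dv <- x - y
    s <- stats::sd(dv)
    if (s == 0 && mean(dv) != 0) stop("undefined effect: zero variance")
    d <- if (s == 0) 0 else mean(dv) / s
  } else {
    s <- sqrt((stats::sd(x)^2 + stats::sd(y)^2) / 2)
    if (s == 0) {
      if (mean(y) != mean(x)) stop("undefined effect: zero variance")
      d <- 0
    } else d <- (mean(y) - mean(x)) / s
  }
  list(d = d, band = effect_band(d))
}

#' Cohen's d (pooled) from summary statistics
#'
#' `(m2 - m1) / sqrt((s1^2 + s2^2) / 2)`.
#'
#' @param m1,s1 mean and SD of the first sample.
#' @param m2,s2 mean and SD of the second sample.
#' @return list with `d` and `band`.
#' @export
cohens_d_summary <- function(m1, s1, m2, s2) {
  s <- sqrt((s1^2 + s2^2) / 2)
  if (s == 0) stop("undefined effect: zero variance")
  d <- (m2 - m1) / s
  list(d = d, band = effect_band(d))
}

.test_result <- function(test, statistic, df, p_value, adjusted_p = NA_real_,
                         d = NA_real_, extra = list()) {
  structure(
    c(list(test = test, statistic = statistic, df = df, p_value = p_value,
           adjusted_p = adjusted_p, d = d,
           band = if (is.na(d)) NA_character_ else effect_band(d)),
      extra),
    class = "rom_test")
}

#' @export
print.rom_test <- function(x, ...) {
  dfs <- paste(signif(unlist(x$df), 4), collapse = ", ")
  cat(sprintf("<rom_test> %s: statistic %.4g, df (%s), p = %.4g", x$test,
              x$statistic, dfs, x$p_value))
  if (!is.na(x$adjusted_p)) cat(sprintf(", p_holm = %.4g", x$adjusted_p))
  if (!is.na(x$d)) cat(sprintf(", d = %.3f (%s)", x$d, x$band))
  cat("\n")
  invisible(x)
}

#' Normality and variance-homogeneity checks
#'
#' Shapiro-Wilk per group x session x parameter cell (cells with fewer
#' than 3 values or zero variance are skipped with a log entry) and
#' Levene's test across groups per session x parameter.
#'
#' @param table cohort data frame with columns `participant`, `group`,
#'   `session`, `task`, `parameter`, `value`.
#' @return data frame: one row per performed test with `test`, `task`,
#'   `parameter`, `group`, `session`, `statistic`, `p_value`, `note`.
#' @export
check_assumptions <- function(table) {
  rows <- list()
  cells <- unique(table[, c("task", "parameter", "group", "session")])
  for (i in seq_len(nrow(cells))) {
    c_ <- cells[i, ]
    v <- table$value[table$task == c_$task & table$parameter == c_$parameter &
                       table$group == c_$group & table$session == c_$session]
    v <- v[!is.na(v)]
    if (length(v) < 3 || stats::sd(v) == 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        test = "shapiro_wilk", task = c_$task, parameter = c_$parameter,
        group = c_$group, session = c_$session, statistic = NA_real_,
        p_value = NA_real_, note = "skipped: degenerate cell")
      next
    }
    sw <- stats::shapiro.test(v)
    rows[[length(rows) + 1L]] <- data.frame(
      test = "shapiro_wilk", task = c_$task, parameter = c_$parameter,
      group = c_$group, session = c_$session,
      statistic = unname(sw$statistic), p_value = sw$p.value, note = "")
  }
  lev_cells <- unique(table[, c("task", "parameter", "session")])
  for (i in seq_len(nrow(lev_cells))) {
    c_ <- lev_cells[i, ]
    sub <- table[table$task == c_$task & table$parameter == c_$parameter &
                   table$session == c_$session & !is.na(table$value), ]
    if (length(unique(sub$group)) < 2 || nrow(sub) < 4) next
    lv <- car::leveneTest(value ~ factor(group), data = sub)
    rows[[length(rows) + 1L]] <- data.frame(
      test = "levene", task = c_$task, parameter = c_$parameter,
      group = "WG|CG", session = c_$session,
      statistic = lv[1, "F value"], p_value = lv[1, "Pr(>F)"], note = "")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Preliminary left-right side comparison
#'
#' Paired t-test on participants' left vs right values of one
#' task x parameter; its outcome justifies pooling the two sides.
#'
#' @param table data frame with columns `participant`, `side`, `value`
#'   (already restricted to one task x parameter x session).
#' @param alpha significance level for the pooling decision.
#' @return `rom_test` with extra field `justified` (`TRUE` when the sides
#'   do not differ at `alpha`).
#' @export
side_comparison <- function(table, alpha = 0.05) {
  wide <- merge(table[table$side == "left", c("participant", "value")],
                table[table$side == "right", c("participant", "value")],
                by = "participant", suffixes = c("_left", "_right"))
  wide <- wide[stats::complete.cases(wide), ]
  if (nrow(wide) < 2) stop("side comparison needs >= 2 paired participants")
  dv <- wide$value_left - wide$value_right
  if (stats::sd(dv) == 0) {
    tt <- list(statistic = 0, parameter = nrow(wide) - 1, p.value = 1)
  } else {
    tt <- stats::t.test(wide$value_left, wide$value_right, paired = TRUE)
  }
  d <- if (stats::sd(dv) == 0) 0 else mean(dv) / stats::sd(dv)
  .test_result("side_paired_t", unname(tt$statistic),
               list(df = unname(tt$parameter)), tt$p.value, d = d,
               extra = list(justified = tt$p.value > alpha,
                            n = nrow(wide)))
}

# participants x sessions wide matrix for one parameter, complete cases
.session_matrix <- function(table, sessions) {
  ids <- unique(table$participant)
  m <- matrix(NA_real_, nrow = length(ids), ncol = length(sessions),
              dimnames = list(ids, sessions))
  for (k in seq_along(sessions)) {
    sub <- table[table$session == sessions[k], ]
    m[match(sub$participant, ids), k] <- sub$value
  }
  keep <- stats::complete.cases(m)
  dropped <- sum(!keep)
  if (dropped) message(dropped, " participant(s) dropped (incomplete sessions)")
  m[keep, , drop = FALSE]
}

# Greenhouse-Geisser epsilon from the session covariance matrix
.gg_epsilon <- function(m) {
  k <- ncol(m)
  S <- stats::cov(m)
  C <- stats::contr.helmert(k)
  C <- qr.Q(qr(C)) # orthonormal contrasts
  M <- t(C) %*% S %*% C
  (sum(diag(M)))^2 / ((k - 1) * sum(M^2))
}

#' One-way repeated-measures ANOVA across sessions
#'
#' Within-subject F-test of the session effect on one parameter;
#' participants with incomplete session data are dropped (listwise,
#' logged). The Greenhouse-Geisser-corrected p-value is reported alongside
#' the uncorrected one.
#'
#' @param table cohort rows of one group (long format, columns
#'   `participant`, `session`, `value`), already restricted to one
#'   task x parameter.
#' @param sessions sessions to include (default all three).
#' @return `rom_test` with fields `statistic` (F), `df`, `p_value`,
#'   extras `gg_epsilon`, `p_gg`, `n`.
#' @export
rm_anova_within <- function(table, sessions = .sessions_all) {
  sessions <- intersect(sessions, unique(table$session))
  if (length(sessions) < 2) stop("need >= 2 sessions")
  m <- .session_matrix(table, sessions)
  n <- nrow(m); k <- ncol(m)
  if (n < 2) stop("need >= 2 complete participants")
  # degenerate case: no within-participant variation at all
  if (max(abs(m - rowMeans(m))) < 1e-10 * max(1, max(abs(m))))
    return(.test_result("rm_anova_session", 0,
                        list(df1 = k - 1, df2 = (n - 1) * (k - 1)), 1,
                        extra = list(gg_epsilon = 1, p_gg = 1, n = n,
                                     sessions = sessions)))
  d <- data.frame(
    value = as.vector(m),
    session = factor(rep(colnames(m), each = n), levels = sessions),
    participant = factor(rep(rownames(m), k)))
  fit <- stats::aov(value ~ session + Error(participant), data = d)
  tab <- summary(fit)[["Error: Within"]][[1]]
  rn <- trimws(rownames(tab))
  i <- match("session", rn); j <- match("Residuals", rn)
  df1 <- tab$Df[i]; df2 <- tab$Df[j]
  f <- tab[i, "F value"]
  if (!is.finite(f)) f <- 0 # zero residual variance
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  eps <- if (k > 2) .gg_epsilon(m) else 1
  p_gg <- stats::pf(f, df1 * eps, df2 * eps, lower.tail = FALSE)
  .test_result("rm_anova_session", f, list(df1 = df1, df2 = df2), p,
               extra = list(gg_epsilon = eps, p_gg = p_gg, n = n,
                            sessions = sessions))
}

#' Holm-corrected paired post hoc comparisons
#'
#' Paired t-tests for each named session pair with Holm step-down
#' adjustment (monotone, `adjusted_p >= p`); paired Cohen's d per
#' comparison.
#'
#' @param table long-format rows (`participant`, `session`, `value`) of
#'   one group x task x parameter.
#' @param pairs list of length-2 character vectors of session names;
#'   default all pairs among the sessions present.
#' @return data frame: one row per comparison with `comparison`, `t`,
#'   `df`, `p_value`, `adjusted_p`, `d`, `band`.
#' @export
holm_posthoc <- function(table, pairs = NULL) {
  sess <- intersect(.sessions_all, unique(table$session))
  if (is.null(pairs))
    pairs <- utils::combn(sess, 2, simplify = FALSE)
  res <- lapply(pairs, function(pr) {
    m <- .session_matrix(table[table$session %in% pr, ], pr)
    dv <- m[, 1] - m[, 2]
    if (stats::sd(dv) == 0) {
      t <- 0; df <- nrow(m) - 1; p <- 1; d <- 0
    } else {
      tt <- stats::t.test(m[, 1], m[, 2], paired = TRUE)
      t <- unname(tt$statistic); df <- unname(tt$parameter); p <- tt$p.value
      d <- mean(dv) / stats::sd(dv)
    }
    data.frame(comparison = paste(pr, collapse = "-"), t = t, df = df,
               p_value = p, d = d)
  })
  out <- do.call(rbind, res)
  out$adjusted_p <- stats::p.adjust(out$p_value, method = "holm")
  out$band <- effect_band(out$d)
  out[, c("comparison", "t", "df", "p_value", "adjusted_p", "d", "band")]
}

#' Mixed-design session x group repeated-measures ANOVA
#'
#' 2 x 2 mixed ANOVA on PRE and POST values with group as the
#' between-subject factor; the session x group interaction p-value is the
#' headline output (a significant interaction means the time effect
#' differed between groups).
#'
#' @param table long-format rows (`participant`, `group`, `session`,
#'   `value`) of one task x parameter, PRE and POST sessions.
#' @param sessions the two sessions entering the within factor.
#' @return list of `rom_test` objects: `session`, `group`, `interaction`.
#' @export
mixed_rm_anova <- function(table, sessions = c("PRE", "POST")) {
  sub <- table[table$session %in% sessions & !is.na(table$value), ]
  groups <- unique(sub$group)
  if (length(groups) < 2) stop("mixed ANOVA needs both groups")
  for (g in groups)
    if (length(unique(sub$session[sub$group == g])) < 2)
      stop("group ", g, " lacks a session: mixed ANOVA undefined")
  mats <- lapply(groups, function(g)
    .session_matrix(sub[sub$group == g, ], sessions))
  names(mats) <- groups
  ns <- vapply(mats, nrow, integer(1))
  if (any(ns < 2)) stop("need >= 2 complete participants per group")
  k <- length(sessions)
  all_m <- do.call(rbind, mats)
  d <- data.frame(
    value = as.vector(all_m),
    session = factor(rep(colnames(all_m), each = nrow(all_m)),
                     levels = sessions),
    group = factor(rep(rep(groups, ns), k)),
    participant = factor(rep(paste0(rep(groups, ns), "_",
                                    unlist(lapply(mats, rownames))), k)))
  fit <- stats::aov(value ~ group * session + Error(participant), data = d)
  s <- summary(fit)
  btab <- s[["Error: participant"]][[1]]
  wtab <- s[["Error: Within"]][[1]]
  pick <- function(tab, term) {
    rn <- trimws(rownames(tab))
    i <- match(term, rn); j <- match("Residuals", rn)
    f <- tab[i, "F value"]
    if (!is.finite(f)) f <- 0
    list(f = f, df1 = tab$Df[i], df2 = tab$Df[j],
         p = stats::pf(f, tab$Df[i], tab$Df[j], lower.tail = FALSE))
  }
  g_ <- pick(btab, "group")
  s_ <- pick(wtab, "session")
  i_ <- pick(wtab, "group:session")
  list(
    session = .test_result("mixed_session", s_$f,
                           list(df1 = s_$df1, df2 = s_$df2), s_$p),
    group = .test_result("mixed_group", g_$f,
                         list(df1 = g_$df1, df2 = g_$df2), g_$p),
    interaction = .test_result("mixed_interaction", i_$f,
                               list(df1 = i_$df1, df2 = i_$df2), i_$p)
  )
}

#' Paired PRE-POST test for the control group
#'
#' @param table long-format rows (`participant`, `session`, `value`)
#'   of one group x task x parameter with PRE and POST sessions.
#' @return `rom_test` with paired t statistic, p-value and paired d.
#' @export
paired_prepost <- function(table) {
  m <- .session_matrix(table, c("PRE", "POST"))
  if (nrow(m) < 2) stop("paired PRE-POST test needs >= 2 participants")
  dv <- m[, "POST"] - m[, "PRE"]
  if (stats::sd(dv) == 0) {
    .test_result("paired_prepost_t", 0, list(df = nrow(m) - 1), 1, d = 0,
                 extra = list(n = nrow(m)))
  } else {
    tt <- stats::t.test(m[, "POST"], m[, "PRE"], paired = TRUE)
    .test_result("paired_prepost_t", unname(tt$statistic),
                 list(df = unname(tt$parameter)), tt$p.value,
                 d = mean(dv) / stats::sd(dv), extra = list(n = nrow(m)))
  }
}

#' Fatigue analysis across repetitions
#'
#' Repeated-measures ANOVA of per-repetition ROM across the ordered
#' repetitions of one session, a first-vs-last paired post hoc, and the
#' percent change between first and last repetition. Percent change is
#' computed per participant as `100 * (last - first) / first` and
#' averaged (default); the ratio-of-group-means variant
#' `100 * (mean(last) - mean(first)) / mean(first)` is also reported.
#'
#' @param table data frame with columns `participant`, `repetition`
#'   (integer), `value` (per-repetition ROM, deg) for one session.
#' @return list: `anova` (`rom_test` across repetitions),
#'   `first_vs_last` (`rom_test`), `percent_change` (mean of per-subject
#'   changes), `percent_change_of_means`.
#' @export
fatigue_analysis <- function(table) {
  reps <- sort(unique(table$repetition))
  if (length(reps) < 2) stop("fatigue analysis needs >= 2 repetitions")
  tab <- table
  tab$session <- paste0("R", tab$repetition) # reuse session machinery
  sess <- paste0("R", reps)
  m <- .session_matrix(tab, sess)
  anova <- rm_anova_within(tab, sessions = sess)
  first <- m[, 1]; last <- m[, ncol(m)]
  dv <- last - first
  if (stats::sd(dv) == 0) {
    fl <- .test_result("first_vs_last_t", 0, list(df = nrow(m) - 1),
                       if (mean(dv) == 0) 1 else NA_real_, d = 0)
  } else {
    tt <- stats::t.test(last, first, paired = TRUE)
    fl <- .test_result("first_vs_last_t", unname(tt$statistic),
                       list(df = unname(tt$parameter)), tt$p.value,
                       d = mean(dv) / stats::sd(dv))
  }
  list(anova = anova, first_vs_last = fl,
       percent_change = mean(100 * (last - first) / first),
       percent_change_of_means = 100 * (mean(last) - mean(first)) / mean(first))
}
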