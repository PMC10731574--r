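# Cohort aggregation, the two-group comparison, and the stacked
# contribution figure.

#' Build a cohort table from trials
#'
#' Runs the full decomposition pipeline on each trial and assembles one row
#' per subject per task, carrying the total, each component displacement
#' (mm) and each percent contribution. Columns for components that do not
#' belong to a row's task are `NA`.
#'
#' @param trials List of [trial_recording()] objects.
#' @param subjects Optional `data.frame` of [subject_record()] rows; used to
#'   attach the `group` column by `subject_id`.
#' @param group Fallback group label when `subjects` is not given.
#' @param ... Passed to [analyze_trial()] (e.g. `cutoff`,
#'   `denominator_mode`).
#' @return A `data.frame` of class `cohort_table`.
#' @export
cohort_table <- function(trials, subjects = NULL, group = NA_character_, ...) {
  rows <- lapply(trials, function(tr) {
    tryCatch(as.data.frame(analyze_trial(tr, ...)),
             reachcomp_degenerate_error = function(e) {
               warning(sprintf("dropping degenerate trial (subject %s, %s): %s",
                               tr$subject_id, tr$task, conditionMessage(e)))
               NULL
             })
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    stop_reachcomp("no analyzable trials", "reachcomp_data_error")
  }
  all_cols <- c("subject_id", "task", "total_mm", "denominator_mode",
                unlist(lapply(c(FORWARD_COMPONENTS, HTM_COMPONENTS),
                              function(x) paste0(x, c("_mm", "_pct")))))
  rows <- lapply(rows, function(r) {
    for (cc in setdiff(all_cols, names(r))) r[[cc]] <- NA_real_
    r[all_cols]
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$group <- if (!is.null(subjects)) {
    subjects$group[match(out$subject_id, subjects$subject_id)]
  } else group
  out <- out[c("subject_id", "group", setdiff(names(out), c("subject_id", "group")))]
  class(out) <- c("cohort_table", class(out))
  out
}

#' @noRd
task_components <- function(task) {
  if (task == "forward_reach") FORWARD_COMPONENTS else HTM_COMPONENTS
}

#' Summarize a cohort table
#'
#' Per-group, per-component sample mean and SD (n-1 denominator) of the
#' percent contributions for one task.
#'
#' @param table A [cohort_table()] `data.frame`.
#' @param task Task to summarize.
#' @return `data.frame` with columns `group`, `component`, `n`, `mean_pct`,
#'   `sd_pct` (and `mean_mm`). A single-subject group gets `sd = NaN` with a
#'   warning.
#' @export
summarize_cohort <- function(table, task = c("forward_reach", "hand_to_mouth")) {
  task <- match.arg(task)
  tab <- table[table$task == task, , drop = FALSE]
  if (!nrow(tab)) stop_reachcomp("no rows for task", "reachcomp_data_error")
  comps <- task_components(task)
  out <- NULL
  for (g in unique(tab$group)) {
    sub <- tab[tab$group == g, , drop = FALSE]
    if (!nrow(sub)) stop_reachcomp(sprintf("empty group %s", g), "reachcomp_data_error")
    for (cmp in comps) {
      pct <- sub[[paste0(cmp, "_pct")]]
      mm <- sub[[paste0(cmp, "_mm")]]
      sdv <- if (length(pct) < 2L) {
        warning(sprintf("group %s has a single subject; SD undefined", g))
        NaN
      } else stats::sd(pct)
      out <- rbind(out, data.frame(
        group = g, component = cmp, n = length(pct),
        mean_pct = mean(pct), sd_pct = sdv, mean_mm = mean(mm),
        stringsAsFactors = FALSE))
    }
  }
  out
}

#' Two-sample t test (pooled-variance Student form)
#'
#' The classical two-sided Student t test with pooled variance,
#' `df = n_a + n_b - 2`, implemented from the textbook formula (the test
#' suite cross-checks it against an independent implementation). A Welch
#' variant (recommended with unequal group sizes/variances) is available via
#' `welch = TRUE`.
#'
#' Degenerate inputs: identical constant groups give `t = 0, p = 1` by
#' convention; zero pooled variance with unequal means is flagged
#' (`degenerate = TRUE`, `p = NA`).
#'
#' @param a,b Numeric vectors (each length >= 2).
#' @param alpha Significance level for the `significant` flag.
#' @param welch Use the Welch (unpooled) variant.
#' @return One-row `data.frame`: `mean_a`, `sd_a`, `mean_b`, `sd_b`, `t`,
#'   `df`, `p`, `significant`, `degenerate`.
#' @export
student_t_compare <- function(a, b, alpha = 0.05, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L) {
    stop_reachcomp("each group needs at least 2 values", "reachcomp_data_error")
  }
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  dm <- mean(a) - mean(b)
  degenerate <- FALSE
  if (welch) {
    se2 <- va / na + vb / nb
    if (se2 == 0) {
      if (dm == 0) { tt <- 0; df <- na + nb - 2; p <- 1 }
      else { tt <- NA_real_; df <- NA_real_; p <- NA_real_; degenerate <- TRUE }
    } else {
      tt <- dm / sqrt(se2)
      df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
      p <- 2 * stats::pt(-abs(tt), df)
    }
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    df <- na + nb - 2
    if (sp2 == 0) {
      if (dm == 0) { tt <- 0; p <- 1 }
      else { tt <- NA_real_; p <- NA_real_; degenerate <- TRUE }
    } else {
      tt <- dm / sqrt(sp2 * (1 / na + 1 / nb))
      p <- 2 * stats::pt(-abs(tt), df)
    }
  }
  data.frame(mean_a = mean(a), sd_a = stats::sd(a),
             mean_b = mean(b), sd_b = stats::sd(b),
             t = tt, df = df, p = p,
             significant = !is.na(p) && p < alpha,
             degenerate = degenerate)
}

#' Compare all components between groups
#'
#' Applies [student_t_compare()] to each component's percent contribution,
#' healthy vs stroke. No multiplicity correction by default (each component
#' is tested at `alpha`, matching common practice in small kinematic
#' studies); Holm adjustment available via `holm = TRUE`.
#'
#' @param table A [cohort_table()].
#' @param task Task to compare.
#' @param alpha Significance level.
#' @param welch,holm Options (see [student_t_compare()]).
#' @return `data.frame`, one row per component: group means/SDs, `t`, `df`,
#'   `p`, `significant`.
#' @export
compare_components_table <- function(table, task = c("forward_reach", "hand_to_mouth"),
                                     alpha = 0.05, welch = FALSE, holm = FALSE) {
  task <- match.arg(task)
  tab <- table[table$task == task, , drop = FALSE]
  groups <- unique(tab$group)
  if (!all(c("healthy", "stroke") %in% groups)) {
    stop_reachcomp("need both healthy and stroke rows", "reachcomp_data_error")
  }
  comps <- task_components(task)
  out <- NULL
  for (cmp in comps) {
    h <- tab[[paste0(cmp, "_pct")]][tab$group == "healthy"]
    s <- tab[[paste0(cmp, "_pct")]][tab$group == "stroke"]
    r <- student_t_compare(s, h, alpha = alpha, welch = welch)
    out <- rbind(out, data.frame(
      component = cmp,
      healthy_mean = r$mean_b, healthy_sd = r$sd_b,
      stroke_mean = r$mean_a, stroke_sd = r$sd_a,
      t = r$t, df = r$df, p = r$p, stringsAsFactors = FALSE))
  }
  if (holm) out$p_adj <- stats::p.adjust(out$p, "holm")
  pcol <- if (holm) out$p_adj else out$p
  out$significant <- !is.na(pcol) & pcol < alpha
  out
}

#' Stacked contribution plot
#'
#' Renders the cohort's movement strategy as per-group stacked bars of mean
#' component displacements (mm), with a companion percent-stacked panel.
#' Negative components are drawn below the baseline. Components whose group
#' difference is significant (when both groups are present) are marked with
#' asterisks.
#'
#' @param table A [cohort_table()].
#' @param task Task to plot.
#' @param output PNG output path.
#' @param alpha Significance level for the markers.
#' @param width,height,res PNG device parameters.
#' @return `output`, invisibly.
#' @export
plot_stacked_contributions <- function(table, task = c("forward_reach", "hand_to_mouth"),
                                       output, alpha = 0.05,
                                       width = 900, height = 500, res = 96) {
  task <- match.arg(task)
  summ <- summarize_cohort(table, task)
  groups <- unique(summ$group)
  comps <- task_components(task)
  sig <- rep(FALSE, length(comps))
  if (all(c("healthy", "stroke") %in% groups)) {
    cmp_tab <- compare_components_table(table, task, alpha = alpha)
    sig <- cmp_tab$significant[match(comps, cmp_tab$component)]
  }
  cols <- c("#E69F00", "#F0E442", "#009E73", "#56B4E9")[seq_along(comps)]

  ok <- tryCatch({
    grDevices::png(output, width = width, height = height, res = res)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) {
    stop_reachcomp(sprintf("cannot open '%s' for writing", output),
                   "reachcomp_io_error")
  }
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 2), mar = c(7, 4, 3, 1))
  for (mode in c("mm", "pct")) {
    vals <- vapply(groups, function(g) {
      v <- vapply(comps, function(cmp) {
        col <- if (mode == "mm") "mean_mm" else "mean_pct"
        summ[[col]][summ$group == g & summ$component == cmp]
      }, numeric(1))
      v
    }, numeric(length(comps)))
    vals <- matrix(vals, nrow = length(comps),
                   dimnames = list(comps, groups))
    # stack positive and negative segments separately around the baseline
    pos <- pmax(vals, 0); neg <- pmin(vals, 0)
    ylim <- c(min(colSums(neg)) * 1.1 - 1, max(colSums(pos)) * 1.15)
    bp <- graphics::barplot(pos, col = cols, ylim = ylim,
                            ylab = if (mode == "mm") "displacement (mm)" else "contribution (%)",
                            main = sprintf("%s (%s)", gsub("_", " ", task), mode))
    graphics::barplot(neg, col = cols, add = TRUE, axes = FALSE,
                      names.arg = rep("", ncol(neg)))
    graphics::abline(h = 0)
    for (j in seq_along(groups)) {
      graphics::text(bp[j], sum(pos[, j]) + 0.04 * diff(ylim),
                     paste0(ifelse(sig, "*", ""), collapse = ""))
    }
    graphics::legend("topright", legend = gsub("_", " ", comps), fill = cols,
                     cex = 0.7, bty = "n")
  }
  invisible(output)
}
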