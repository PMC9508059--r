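#' Trial-exclusion configuration
#'
#' Parameters of the standard exclusion cascade for speeded categorization
#' data.  The cascade is applied in a fixed order: subject exclusion (by
#' session-wide accuracy), run exclusion (by run accuracy), fast-RT trim,
#' slow-RT trim (mean + k SD), warm-up removal, first-presentation removal.
#' Thresholds are strict: a subject or run is excluded iff its accuracy is
#' strictly below the minimum, so a run at exactly 80% is retained.
#'
#' @param sd_multiplier Trials with RT above mean + `sd_multiplier` * SD are
#'   removed (3 for the 6-cycle designs; 2 is appropriate when a warm-up
#'   phase has already absorbed the early-run RT drop).
#' @param min_rt_s Trials faster than this are removed (anticipatory
#'   responses), in seconds.
#' @param run_accuracy_min Runs with accuracy strictly below this are
#'   dropped entirely.
#' @param subject_accuracy_min Subjects with session accuracy strictly
#'   below this are dropped entirely.
#' @param drop_first_presentations Remove each chunk's first structured
#'   presentation (no learning effect is possible there).
#' @param drop_first_k_trials Number of initial trials per run ignored by
#'   plotting utilities; never applied to statistics.
#' @param drop_warmup Remove warm-up (random phase) trials after the
#'   accuracy-based exclusions.
#' @param trim_group Grouping within which the slow-RT trimming mean and SD
#'   are computed (over correct structured trials): `"subject"` (default),
#'   `"subject_run"` or `"subject_condition"`.
#' @return An object of class `sl_filter`.
#' @export
filter_config <- function(sd_multiplier = 3, min_rt_s = 0.200,
                          run_accuracy_min = 0.80,
                          subject_accuracy_min = 0.60,
                          drop_first_presentations = TRUE,
                          drop_first_k_trials = 3L,
                          drop_warmup = TRUE,
                          trim_group = c("subject", "subject_run",
                                         "subject_condition")) {
  trim_group <- match.arg(trim_group)
  stopifnot(sd_multiplier > 0, min_rt_s >= 0,
            run_accuracy_min > 0, run_accuracy_min <= 1,
            subject_accuracy_min > 0, subject_accuracy_min <= 1)
  structure(list(sd_multiplier = sd_multiplier, min_rt_s = min_rt_s,
                 run_accuracy_min = run_accuracy_min,
                 subject_accuracy_min = subject_accuracy_min,
                 drop_first_presentations = drop_first_presentations,
                 drop_first_k_trials = as.integer(drop_first_k_trials),
                 drop_warmup = drop_warmup, trim_group = trim_group),
            class = "sl_filter")
}

#' @export
print.sl_filter <- function(x, ...) {
  cat("<sl_filter>\n")
  cat(sprintf("  RT: keep %.0f ms <= rt <= mean + %g SD (per %s)\n",
              x$min_rt_s * 1000, x$sd_multiplier, x$trim_group))
  cat(sprintf("  accuracy: run >= %.0f%%, subject >= %.0f%%\n",
              100 * x$run_accuracy_min, 100 * x$subject_accuracy_min))
  cat(sprintf("  drop warm-up: %s; drop first presentations: %s\n",
              x$drop_warmup, x$drop_first_presentations))
  invisible(x)
}

check_response_table <- function(table, need = c("subject_id", "correct")) {
  missing <- setdiff(need, names(table))
  if (length(missing)) {
    stop("response table lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  invisible(table)
}

#' Sequential-correctness (NVAR) coding
#'
#' Scores every trial by the correctness of the current and previous
#' responses: 1 = both correct, 2 = current correct only, 3 = previous
#' correct only, 4 = both incorrect.  The first trial of each run has no
#' predecessor and receives `NA`.  Coding must happen on the full presented
#' sequence, before any trial-level removal, so the cascade applies it
#' first.
#'
#' @param table A response table ordered by subject, run, trial.
#' @return The table with an integer `nvar` column.
#' @export
code_nvar <- function(table) {
  check_response_table(table, c("subject_id", "run", "trial", "correct"))
  n <- nrow(table)
  if (n == 0L) {
    table$nvar <- integer(0)
    return(table)
  }
  key <- paste(table$subject_id, table$session_id, table$run)
  if (is.unsorted(order(key, table$trial)) ||
      any(diff(table$trial)[key[-n] == key[-1L]] < 0)) {
    stop("code_nvar() requires rows ordered by subject, run, trial")
  }
  first <- c(TRUE, key[-1L] != key[-n])
  prev <- c(NA, table$correct[-n])
  prev[first] <- NA
  table$nvar <- ifelse(is.na(prev), NA_integer_,
                       1L + (!table$correct) * 2L + (!prev) * 1L)
  table
}

subject_key <- function(table) paste(table$subject_id, table$session_id)
run_key <- function(table) {
  paste(table$subject_id, table$session_id, table$run)
}

#' Exclusion-cascade steps
#'
#' Each step removes rows and reports how many.  [exclude_subjects()] drops
#' all rows of subjects whose session-wide accuracy is strictly below the
#' threshold; [exclude_runs()] drops whole subject-runs below the run
#' threshold; [trim_rts()] removes anticipatory responses (fast rule) and
#' outlying slow responses (mean + k SD, computed per `trim_group` over
#' correct structured trials); [drop_first_presentations()] removes every
#' chunk's first structured presentation.  Accuracy is always computed
#' before RT trimming.
#'
#' @param table A response table.
#' @param config An [filter_config()] object.
#' @return A list with elements `data` (the filtered table) and `removed`
#'   (rows removed), plus step-specific detail.
#' @export
exclude_subjects <- function(table, config = filter_config()) {
  check_response_table(table)
  if (nrow(table) == 0L) stop("empty response table")
  key <- subject_key(table)
  acc <- tapply(table$correct, key, mean)
  bad <- names(acc)[acc < config$subject_accuracy_min]
  keep <- !(key %in% bad)
  list(data = table[keep, , drop = FALSE], removed = sum(!keep),
       excluded_subjects = bad)
}

#' @rdname exclude_subjects
#' @export
exclude_runs <- function(table, config = filter_config()) {
  check_response_table(table)
  key <- run_key(table)
  acc <- tapply(table$correct, key, mean)
  bad <- names(acc)[acc < config$run_accuracy_min]
  keep <- !(key %in% bad)
  list(data = table[keep, , drop = FALSE], removed = sum(!keep),
       excluded_runs = bad)
}

#' @rdname exclude_subjects
#' @export
trim_rts <- function(table, config = filter_config()) {
  check_response_table(table, c("subject_id", "correct", "rt_s"))
  fast <- table$rt_s < config$min_rt_s
  n_fast <- sum(fast)
  table <- table[!fast, , drop = FALSE]

  grp <- switch(config$trim_group,
    subject = subject_key(table),
    subject_run = run_key(table),
    subject_condition = paste(subject_key(table), table$condition))
  ref <- table$correct & table$phase == "structured"
  mu <- tapply(table$rt_s[ref], grp[ref], mean)
  sdv <- tapply(table$rt_s[ref], grp[ref], stats::sd)
  lim <- mu + config$sd_multiplier * ifelse(is.na(sdv), 0, sdv)
  slow <- table$rt_s > lim[grp]
  slow[is.na(slow)] <- FALSE      # groups with no reference trials
  list(data = table[!slow, , drop = FALSE],
       removed = n_fast + sum(slow), removed_fast = n_fast,
       removed_slow = sum(slow))
}

#' @rdname exclude_subjects
#' @export
drop_first_presentations <- function(table) {
  drop <- table$phase == "structured" & !is.na(table$repetition) &
    table$repetition == 1L
  list(data = table[!drop, , drop = FALSE], removed = sum(drop))
}

#' Remove category-repeating trials
#'
#' Drops every trial whose response category equals that of the immediately
#' preceding presented trial (within subject x run).  In a design whose
#' pairs all alternate categories, the removed trials can only be first
#' pair members or singles, so this reanalysis isolates stimulus-pair
#' learning from motor (response-alternation) priming.  A trial whose
#' predecessor has already been removed from the table is retained, since
#' its transition type cannot be assessed.
#'
#' @param table A response table.
#' @return A list with `data`, `removed` and `fraction_removed`.
#' @export
drop_category_repeating_trials <- function(table) {
  check_response_table(table, c("subject_id", "run", "trial", "category"))
  n <- nrow(table)
  if (n == 0L) return(list(data = table, removed = 0L, fraction_removed = 0))
  key <- run_key(table)
  o <- order(key, table$trial)
  tab <- table[o, , drop = FALSE]
  key <- key[o]
  adjacent <- c(FALSE, key[-1L] == key[-n] &
                  tab$trial[-1L] == tab$trial[-n] + 1L)
  prev_cat <- c(NA_character_, tab$category[-n])
  drop <- adjacent & tab$category == prev_cat
  drop[is.na(drop)] <- FALSE
  list(data = tab[!drop, , drop = FALSE], removed = sum(drop),
       fraction_removed = mean(drop))
}

#' Apply the full exclusion cascade
#'
#' Runs NVAR coding followed by the exclusion steps in their fixed order
#' (subjects, runs, fast RTs, slow RTs, warm-up, first presentations) and
#' assembles an auditable exclusion report with per-rule counts and
#' percentages of the input trial total.
#'
#' @inheritParams exclude_subjects
#' @return A list with `data` (the analysis table, including an `nvar`
#'   column) and `report` (class `sl_exclusion_report`).
#' @export
preprocess <- function(table, config = filter_config()) {
  check_response_table(table, c("subject_id", "run", "trial", "phase",
                                "condition", "repetition", "correct",
                                "rt_s"))
  if (nrow(table) == 0L) stop("empty response table")
  key <- run_key(table)
  table <- table[order(key, table$trial), , drop = FALSE]
  table <- code_nvar(table)
  n0 <- nrow(table)

  s1 <- exclude_subjects(table, config)
  s2 <- exclude_runs(s1$data, config)
  s3 <- trim_rts(s2$data, config)
  n_warm <- 0L
  d <- s3$data
  if (config$drop_warmup) {
    w <- d$phase == "warmup"
    n_warm <- sum(w)
    d <- d[!w, , drop = FALSE]
  }
  s5 <- if (config$drop_first_presentations) {
    drop_first_presentations(d)
  } else {
    list(data = d, removed = 0L)
  }

  counts <- c(low_accuracy_subject = s1$removed,
              low_accuracy_run = s2$removed,
              fast_rt = s3$removed_fast, slow_rt = s3$removed_slow,
              warmup = n_warm, first_presentation = s5$removed)
  per_subject <- table(table$subject_id[!(rownames(table) %in%
                                            rownames(s5$data))])
  report <- structure(list(
    n_input = n0, n_retained = nrow(s5$data),
    counts = as.list(counts),
    percentages = as.list(100 * counts / n0),
    overall_percentage = 100 * (n0 - nrow(s5$data)) / n0,
    excluded_subjects = s1$excluded_subjects,
    excluded_runs = s2$excluded_runs,
    per_subject_removed = as.list(per_subject)),
    class = "sl_exclusion_report")
  list(data = s5$data, report = report)
}

#' @export
print.sl_exclusion_report <- function(x, ...) {
  cat("<sl_exclusion_report>\n")
  cat(sprintf("  input %d trials, retained %d (%.1f%% excluded)\n",
              x$n_input, x$n_retained, x$overall_percentage))
  for (rule in names(x$counts)) {
    cat(sprintf("  %-22s %6d  (%.2f%%)\n", rule, x$counts[[rule]],
                x$percentages[[rule]]))
  }
  if (length(x$excluded_subjects)) {
    cat("  excluded subjects:", paste(x$excluded_subjects, collapse = ", "),
        "\n")
  }
  invisible(x)
}
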