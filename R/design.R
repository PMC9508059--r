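#' Experiment design specification
#'
#' Construct the full parameterization of one SRT sequence design: the chunk
#' inventory template (associated stimulus pairs and unpaired single stimuli
#' over two abstract response categories), the cycle structure, and the
#' ordering constraints.  Three named presets cover the designs used in
#' practice:
#'
#' * `"exp1a"` -- 4 category-alternating pairs (2 x A->B, 2 x B->A) plus
#'   2 single stimuli per category; 6 cycles of 12 trials per run, 8 runs,
#'   fixed 500 ms ITI, cycle-juncture gap of 3 distinct stimuli.
#' * `"exp1b"` -- as `"exp1a"` but with balanced category transitions:
#'   2 category-alternating pairs (A->B, B->A) and 2 category-repeating
#'   pairs (A->A, B->B).
#' * `"exp2"` -- the exp1b pair template with 4 singles per category
#'   (16 stimuli, 12 chunks), a 10-cycle fully random warm-up phase,
#'   15 structured cycles (400 trials: 160 warm-up + 240 structured),
#'   2 runs, jittered 500--1200 ms ITI, and the constraint that every
#'   pair is followed by at least one single stimulus.
#'
#' Category labels are abstract (`"A"`/`"B"`); the mapping onto concrete
#' response categories (Large/Small, Object/Animal) is metadata only.
#'
#' @param preset One of `"exp1a"`, `"exp1b"`, `"exp2"`, or `"custom"`.
#' @param ... For `preset = "custom"` (or to override a preset field):
#'   any of `pair_templates` (list of length-2 character vectors of
#'   category labels), `n_singles_per_category`, `n_cycles`,
#'   `warmup_cycles`, `juncture_min_gap`, `pair_followed_by_single`,
#'   `n_runs`, `iti_model` (see [iti_fixed()] / [iti_uniform()]),
#'   `stimulus_duration_ms`.
#' @return An object of class `sl_design`.
#' @examples
#' design_spec("exp1a")
#' design_spec("exp2", n_runs = 1)
#' @export
design_spec <- function(preset = c("exp1a", "exp1b", "exp2", "custom"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    exp1a = list(
      pair_templates = list(c("A", "B"), c("A", "B"), c("B", "A"), c("B", "A")),
      n_singles_per_category = 2L, n_cycles = 6L, warmup_cycles = 0L,
      juncture_min_gap = 3L, pair_followed_by_single = FALSE,
      n_runs = 8L, iti_model = iti_fixed(500)),
    exp1b = list(
      pair_templates = list(c("A", "B"), c("B", "A"), c("A", "A"), c("B", "B")),
      n_singles_per_category = 2L, n_cycles = 6L, warmup_cycles = 0L,
      juncture_min_gap = 3L, pair_followed_by_single = FALSE,
      n_runs = 8L, iti_model = iti_fixed(500)),
    exp2 = list(
      pair_templates = list(c("A", "B"), c("B", "A"), c("A", "A"), c("B", "B")),
      n_singles_per_category = 4L, n_cycles = 15L, warmup_cycles = 10L,
      juncture_min_gap = 0L, pair_followed_by_single = TRUE,
      n_runs = 2L, iti_model = iti_uniform(500, 1200)),
    custom = list(
      pair_templates = list(c("A", "B"), c("B", "A")),
      n_singles_per_category = 2L, n_cycles = 6L, warmup_cycles = 0L,
      juncture_min_gap = 0L, pair_followed_by_single = FALSE,
      n_runs = 1L, iti_model = iti_fixed(500))
  )
  override <- list(...)
  bad <- setdiff(names(override), c(names(base), "stimulus_duration_ms"))
  if (length(bad)) {
    stop("unknown design field(s): ", paste(bad, collapse = ", "))
  }
  base[names(override)] <- override
  spec <- c(list(name = preset, n_categories = 2L,
                 stimulus_duration_ms = 300L), base)
  if (!is.null(override$stimulus_duration_ms)) {
    spec$stimulus_duration_ms <- as.integer(override$stimulus_duration_ms)
  }
  spec$n_pairs <- length(spec$pair_templates)
  spec$n_singles <- 2L * as.integer(spec$n_singles_per_category)
  spec$n_chunks <- spec$n_pairs + spec$n_singles
  spec$n_stimuli <- 2L * spec$n_pairs + spec$n_singles
  class(spec) <- "sl_design"
  validate_design(spec)
  spec
}

#' @rdname design_spec
#' @param ms,min_ms,max_ms Intertrial interval in milliseconds.
#' @export
iti_fixed <- function(ms = 500) list(type = "fixed", ms = as.numeric(ms))

#' @rdname design_spec
#' @export
iti_uniform <- function(min_ms = 500, max_ms = 1200) {
  stopifnot(max_ms >= min_ms)
  list(type = "uniform", min_ms = as.numeric(min_ms), max_ms = as.numeric(max_ms))
}

validate_design <- function(spec) {
  if (!all(unlist(spec$pair_templates) %in% c("A", "B"))) {
    stop("pair templates must use the abstract category labels 'A'/'B'")
  }
  if (any(lengths(spec$pair_templates) != 2L)) {
    stop("every pair template must name exactly two categories")
  }
  # equal numbers of each category across the run's stimulus inventory
  cats <- c(unlist(spec$pair_templates),
            rep(c("A", "B"), each = spec$n_singles_per_category))
  if (sum(cats == "A") != sum(cats == "B")) {
    stop("category imbalance: the stimulus inventory must contain equal ",
         "numbers of category-A and category-B stimuli")
  }
  if (spec$n_cycles < 1L || spec$n_runs < 1L) {
    stop("n_cycles and n_runs must be positive")
  }
  if (spec$juncture_min_gap < 0L || spec$warmup_cycles < 0L) {
    stop("juncture_min_gap and warmup_cycles must be non-negative")
  }
  invisible(spec)
}

#' @export
print.sl_design <- function(x, ...) {
  cat("<sl_design>", x$name, "\n")
  cat("  chunks: ", x$n_pairs, " pairs + ", x$n_singles, " singles (",
      x$n_stimuli, " stimuli)\n", sep = "")
  cat("  pairs:  ", paste(vapply(x$pair_templates, paste, "", collapse = "->"),
                          collapse = ", "), "\n", sep = "")
  cat("  cycles: ", x$warmup_cycles, " warm-up + ", x$n_cycles,
      " structured, ", x$n_runs, " run(s)\n", sep = "")
  cat("  constraints: juncture gap ", x$juncture_min_gap,
      if (x$pair_followed_by_single) ", pair followed by single" else "",
      "\n", sep = "")
  invisible(x)
}

#' Build a chunk inventory for one run
#'
#' Randomly assigns fresh stimulus ids to the roles defined by the design's
#' pair templates and single slots.  A pair's first stimulus always carries
#' condition `P1` and its second `P2`; singles carry `S`.  Stimulus ids are
#' drawn from a per-category pool so the run inventory is category balanced.
#'
#' @param spec An [design_spec()] object.
#' @param stim_offset Integer id offset, so successive runs of one session
#'   receive disjoint stimulus ids.
#' @return A data frame with one row per chunk slot and columns
#'   `chunk_id`, `kind`, `slot`, `stimulus_id`, `category`, `condition`.
#' @export
make_chunks <- function(spec, stim_offset = 0L) {
  ct <- chunk_tables(spec, stim_offset)
  data.frame(
    chunk_id = rep.int(ct$ids, ct$len),
    kind = rep.int(ifelse(ct$is_pair, "pair", "single"), ct$len),
    slot = unlist(lapply(ct$len, seq_len), use.names = FALSE),
    stimulus_id = unlist(ct$stim, use.names = FALSE),
    category = unlist(ct$cat, use.names = FALSE),
    condition = unlist(ct$cond, use.names = FALSE),
    stringsAsFactors = FALSE)
}

# Compact chunk inventory used by the sequence sampler: fresh stimulus ids
# randomly assigned to template roles, category balanced.
chunk_tables <- function(spec, stim_offset = 0L) {
  validate_design(spec)
  n_a <- spec$n_stimuli %/% 2L
  ids_a <- sample(stim_offset + seq_len(n_a))
  ids_b <- sample(stim_offset + n_a + seq_len(n_a))
  np <- spec$n_pairs
  cat_slots <- c(unlist(spec$pair_templates),
                 rep(c("A", "B"), each = spec$n_singles_per_category))
  slot_ids <- integer(length(cat_slots))
  slot_ids[cat_slots == "A"] <- ids_a[seq_len(sum(cat_slots == "A"))]
  slot_ids[cat_slots == "B"] <- ids_b[seq_len(sum(cat_slots == "B"))]
  stim <- c(split(slot_ids[seq_len(2L * np)], rep(seq_len(np), each = 2L)),
            as.list(slot_ids[-seq_len(2L * np)]))
  cat <- c(spec$pair_templates, as.list(cat_slots[-seq_len(2L * np)]))
  k <- np + spec$n_singles
  is_pair <- c(rep(TRUE, np), rep(FALSE, spec$n_singles))
  cond <- c(rep(list(c("P1", "P2")), np), rep(list("S"), spec$n_singles))
  ids <- c(sprintf("pair%d", seq_len(np)),
           sprintf("single%d", seq_len(spec$n_singles)))
  names(stim) <- NULL
  list(ids = ids, stim = stim, cond = cond, cat = cat, is_pair = is_pair,
       len = lengths(stim))
}

# Rebuild the sampler's compact representation from a make_chunks() frame.
ct_from_frame <- function(chunks) {
  ids <- unique(chunks$chunk_id)
  idx <- split(seq_len(nrow(chunks)), factor(chunks$chunk_id, levels = ids))
  idx <- lapply(idx, function(i) i[order(chunks$slot[i])])
  list(ids = ids,
       stim = lapply(idx, function(i) chunks$stimulus_id[i]),
       cond = lapply(idx, function(i) chunks$condition[i]),
       cat = lapply(idx, function(i) chunks$category[i]),
       is_pair = vapply(idx, function(i) chunks$kind[i][1] == "pair", TRUE),
       len = lengths(idx))
}

# Juncture check across one cycle boundary.  Within a cycle every stimulus
# appears at most once, so a violation can only pair the tail of the previous
# cycle with the head of the new one; with gap g only the last g positions of
# the previous cycle and the first g of the new one can participate.
juncture_ok <- function(prev_stims, new_stims, gap) {
  if (gap <= 0L || is.null(prev_stims)) return(TRUE)
  np <- length(prev_stims)
  lo <- max(1L, np - gap + 1L)
  for (j in lo:np) {
    s <- prev_stims[j]
    t <- match(s, new_stims)
    if (!is.na(t) && t <= gap) {
      between <- c(if (j < np) prev_stims[(j + 1L):np],
                   if (t > 1L) new_stims[seq_len(t - 1L)])
      if (length(unique(between)) < gap) return(FALSE)
    }
  }
  TRUE
}

# Draw one valid cycle order by rejection resampling.
draw_cycle <- function(ct, spec, prev_stims, prev_was_pair,
                       budget = 10000L) {
  k <- length(ct$ids)
  gap <- spec$juncture_min_gap
  pfs <- spec$pair_followed_by_single
  for (try in seq_len(budget)) {
    ord <- sample.int(k)
    if (pfs) {
      ip <- ct$is_pair[ord]
      if (prev_was_pair && ip[1L]) next
      if (any(ip[-k] & ip[-1L])) next
    }
    if (gap > 0L) {
      new_stims <- unlist(ct$stim[ord], use.names = FALSE)
      if (!juncture_ok(prev_stims, new_stims, gap)) next
    }
    return(ord)
  }
  stop("sequence generation failed: no cycle order satisfying the ",
       if (pfs) "pair-followed-by-single" else "juncture",
       " constraint was found within ", budget, " redraws")
}

draw_itis <- function(n, iti_model) {
  if (iti_model$type == "fixed") {
    rep(iti_model$ms, n)
  } else {
    round(stats::runif(n, iti_model$min_ms, iti_model$max_ms), 1)
  }
}

# Fast internal path: generate one run as a list of parallel vectors.
# Stimulus ids are integers here; callers format them for output.
gen_run_vectors <- function(spec, ct, budget = 10000L) {
  k <- length(ct$ids)
  n_stim <- spec$n_stimuli
  all_stims <- unlist(ct$stim, use.names = FALSE)
  stim_cat <- character(max(all_stims) - min(all_stims) + 1L)
  # per-stimulus category lookup (offset-corrected)
  off <- min(all_stims) - 1L
  stim_cat[unlist(ct$stim) - off] <- unlist(ct$cat)

  # warm-up: independent uniform permutations, no immediate repeat across
  # warm-up cycle boundaries
  warm_stim <- integer(0)
  if (spec$warmup_cycles > 0L) {
    warm <- vector("list", spec$warmup_cycles)
    last <- NA_integer_
    for (w in seq_len(spec$warmup_cycles)) {
      for (try in seq_len(budget)) {
        perm <- all_stims[sample.int(n_stim)]
        if (is.na(last) || perm[1L] != last) break
        if (try == budget) stop("warm-up generation failed")
      }
      warm[[w]] <- perm
      last <- perm[n_stim]
    }
    warm_stim <- unlist(warm, use.names = FALSE)
  }

  # structured cycles
  cyc_chunks <- vector("list", spec$n_cycles)
  prev_stims <- NULL
  prev_was_pair <- FALSE
  for (cy in seq_len(spec$n_cycles)) {
    ord <- draw_cycle(ct, spec, prev_stims, prev_was_pair, budget)
    cyc_chunks[[cy]] <- ord
    prev_stims <- unlist(ct$stim[ord], use.names = FALSE)
    prev_was_pair <- ct$is_pair[ord[k]]
  }
  ord_all <- unlist(cyc_chunks, use.names = FALSE)          # chunk index per slot
  len <- ct$len[ord_all]
  chunk_seq <- rep.int(ord_all, len)                        # chunk index per trial
  rep_seq <- rep.int(rep(seq_len(spec$n_cycles), each = k), len)
  struct_stim <- unlist(ct$stim[ord_all], use.names = FALSE)
  struct_cond <- unlist(ct$cond[ord_all], use.names = FALSE)

  n_warm <- length(warm_stim)
  n_struct <- length(struct_stim)
  n <- n_warm + n_struct
  list(
    trial = seq_len(n),
    phase = rep(c("warmup", "structured"), c(n_warm, n_struct)),
    stimulus_id = c(warm_stim, struct_stim),
    category = stim_cat[c(warm_stim, struct_stim) - off],
    condition = c(rep("RANDOM", n_warm), struct_cond),
    chunk_id = c(rep(NA_character_, n_warm), ct$ids[chunk_seq]),
    repetition = c(rep(NA_integer_, n_warm), rep_seq),
    iti_ms = draw_itis(n, spec$iti_model)
  )
}

format_stim <- function(ids) {
  ifelse(is.na(ids), NA_character_, sprintf("s%03d", ids))
}

#' Generate one constrained pseudo-random run
#'
#' Produces the ordered trial list for a single run: an optional warm-up
#' phase in which every stimulus appears exactly once per warm-up cycle in
#' fully random order, followed by the structured phase in which every chunk
#' appears exactly once per cycle in a randomized order subject to the
#' design's constraints (cycle-juncture stimulus gap; pair followed by
#' single).  Constraint satisfaction is by rejection resampling of cycle
#' orders; exhausting the redraw budget is an explicit error.
#'
#' @param spec An [design_spec()] object.
#' @param chunks A chunk inventory from [make_chunks()]; generated fresh
#'   if `NULL`.
#' @param seed Optional integer seed.
#' @param session_id,subject_id,run_index Book-keeping labels.
#' @return A trial data frame with columns `session_id`, `subject_id`,
#'   `run`, `trial`, `phase`, `stimulus_id`, `category`, `condition`,
#'   `chunk_id`, `repetition`, `iti_ms`.  `repetition` is the 1-based count
#'   of how often the trial's chunk has appeared in the structured phase
#'   (`NA` for warm-up trials).
#' @export
generate_run <- function(spec, chunks = NULL, seed = NULL,
                         session_id = "sess1", subject_id = "subj1",
                         run_index = 1L) {
  if (!is.null(seed)) set.seed(seed)
  ct <- if (is.null(chunks)) chunk_tables(spec) else ct_from_frame(chunks)
  v <- gen_run_vectors(spec, ct)
  n <- length(v$trial)
  data.frame(
    session_id = rep(session_id, n), subject_id = rep(subject_id, n),
    run = rep(as.integer(run_index), n), trial = v$trial, phase = v$phase,
    stimulus_id = format_stim(v$stimulus_id), category = v$category,
    condition = v$condition, chunk_id = v$chunk_id,
    repetition = v$repetition, iti_ms = v$iti_ms,
    stringsAsFactors = FALSE)
}

#' Generate a full multi-run session
#'
#' Runs use disjoint stimulus-id sets (fresh stimuli each run, same chunk
#' template), so an 8-run session of a 12-stimulus design consumes 96
#' distinct ids.
#'
#' @inheritParams generate_run
#' @return A trial data frame (all runs stacked); see [generate_run()].
#' @export
generate_session <- function(spec, subject_id = "subj1", seed = NULL,
                             session_id = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(session_id)) session_id <- paste0("sess_", subject_id)
  runs <- vector("list", spec$n_runs)
  for (r in seq_len(spec$n_runs)) {
    ct <- chunk_tables(spec, stim_offset = (r - 1L) * spec$n_stimuli)
    v <- gen_run_vectors(spec, ct)
    v$run <- rep(r, length(v$trial))
    runs[[r]] <- v
  }
  n_per <- vapply(runs, function(v) length(v$trial), 1L)
  n <- sum(n_per)
  data.frame(
    session_id = rep(session_id, n), subject_id = rep(subject_id, n),
    run = as.integer(unlist(lapply(runs, `[[`, "run"))),
    trial = unlist(lapply(runs, `[[`, "trial")),
    phase = unlist(lapply(runs, `[[`, "phase")),
    stimulus_id = format_stim(unlist(lapply(runs, `[[`, "stimulus_id"))),
    category = unlist(lapply(runs, `[[`, "category")),
    condition = unlist(lapply(runs, `[[`, "condition")),
    chunk_id = unlist(lapply(runs, `[[`, "chunk_id")),
    repetition = unlist(lapply(runs, `[[`, "repetition")),
    iti_ms = unlist(lapply(runs, `[[`, "iti_ms")),
    stringsAsFactors = FALSE)
}

#' Empirical transition statistics of generated sequences
#'
#' Summarizes the realized transition-probability structure of structured
#' trial sequences, for checking generated designs against their nominal
#' transition probabilities (1.0 within pairs; low and near-uniform
#' elsewhere).
#'
#' Chunk-to-chunk statistics treat each chunk-final trial (a pair's P2 or a
#' single) as the conditioning event and ask which chunk starts at the next
#' trial.  "Specific successor" probabilities are means over the eligible
#' successor chunks of their empirical conditional frequencies (e.g. with 8
#' chunks and self-succession excluded by the juncture constraint, the
#' design value is 1/7 = 14.3%).
#'
#' @param trials A trial data frame (one or more runs; warm-up trials are
#'   ignored).  Transitions are only counted within a subject x run
#'   sequence.
#' @return A list with elements:
#'   \describe{
#'     \item{within_pair}{P(next trial is the pair's P2 | current is P1).}
#'     \item{specific_successor_chunk}{mean empirical probability of one
#'       particular eligible (non-self) successor chunk after a chunk-final
#'       trial.}
#'     \item{p2_to_specific_single}{mean empirical probability that one
#'       particular single chunk follows a P2 trial.}
#'     \item{single_to_specific_successor}{mean empirical probability that
#'       one particular other eligible chunk's first stimulus follows a
#'       single-stimulus trial (with 12 chunks: design value 1/11).}
#'     \item{category_repetition_rate}{fraction of consecutive structured
#'       trial pairs with identical category.}
#'     \item{n_transitions}{number of structured transitions scanned.}
#'   }
#' @export
empirical_transition_stats <- function(trials) {
  tr <- trials[trials$phase == "structured", , drop = FALSE]
  if (nrow(tr) == 0L) stop("no structured trials in input")
  key <- paste(tr$subject_id, tr$session_id, tr$run)
  o <- order(key, tr$trial)
  tr <- tr[o, , drop = FALSE]
  key <- key[o]
  n <- nrow(tr)
  same_run <- key[-n] == key[-1L]

  cur_cond <- tr$condition[-n]
  nxt_cond <- tr$condition[-1L]
  cur_chunk <- tr$chunk_id[-n]
  nxt_chunk <- tr$chunk_id[-1L]
  cur_stim <- tr$stimulus_id[-n]
  nxt_stim <- tr$stimulus_id[-1L]
  cur_cat <- tr$category[-n]
  nxt_cat <- tr$category[-1L]

  # within-pair: P1 -> same chunk's P2
  p1 <- same_run & cur_cond == "P1"
  within_pair <- if (any(p1)) {
    mean(nxt_chunk[p1] == cur_chunk[p1] & nxt_cond[p1] == "P2")
  } else NA_real_

  # chunk-final transitions: current trial ends its chunk
  fin <- same_run & cur_cond %in% c("P2", "S")
  n_chunks <- length(unique(tr$chunk_id))
  spec_succ <- if (any(fin)) {
    mean(nxt_chunk[fin] != cur_chunk[fin]) / (n_chunks - 1L)
  } else NA_real_

  singles <- unique(tr$chunk_id[tr$condition == "S"])
  n_singles <- length(singles)
  p2f <- fin & cur_cond == "P2"
  p2_single <- if (any(p2f) && n_singles > 0L) {
    mean(nxt_chunk[p2f] %in% singles) / n_singles
  } else NA_real_
  sf <- fin & cur_cond == "S"
  s_successor <- if (any(sf) && n_chunks > 1L) {
    mean(nxt_chunk[sf] != cur_chunk[sf]) / (n_chunks - 1L)
  } else NA_real_

  cat_rep <- mean(cur_cat[same_run] == nxt_cat[same_run])

  list(within_pair = within_pair,
       specific_successor_chunk = spec_succ,
       p2_to_specific_single = p2_single,
       single_to_specific_successor = s_successor,
       category_repetition_rate = cat_rep,
       n_transitions = sum(same_run))
}

#' Scan a trial sequence for juncture-constraint violations
#'
#' Returns the number of positions at which a stimulus reappears with fewer
#' than `gap` distinct other stimuli since its previous presentation
#' (structured phase, within subject x run).
#'
#' @inheritParams empirical_transition_stats
#' @param gap Minimum number of distinct intervening stimuli.
#' @export
count_juncture_violations <- function(trials, gap) {
  tr <- trials[trials$phase == "structured", , drop = FALSE]
  key <- paste(tr$subject_id, tr$session_id, tr$run)
  total <- 0L
  for (k in unique(key)) {
    s <- tr$stimulus_id[key == k][order(tr$trial[key == k])]
    n <- length(s)
    for (t in seq_len(n)[-1L]) {
      prev <- which(s[seq_len(t - 1L)] == s[t])
      if (length(prev)) {
        j <- max(prev)
        between <- if (t - j > 1L) unique(s[(j + 1L):(t - 1L)]) else character(0)
        if (length(between) < gap) total <- total + 1L
      }
    }
  }
  total
}
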