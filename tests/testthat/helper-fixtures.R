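# Small deterministic fixtures built in code.

# A hand-specified response table: one subject, one run, explicit RTs and
# correctness.  Conditions/categories follow a minimal alternating layout.
toy_response_table <- function(rt, correct = rep(TRUE, length(rt)),
                               category = rep(c("A", "B"),
                                              length.out = length(rt)),
                               condition = rep("S", length(rt)),
                               repetition = rep(2L, length(rt)),
                               subject_id = "s1", run = 1L) {
  n <- length(rt)
  data.frame(
    session_id = "sess", subject_id = subject_id, run = run,
    trial = seq_len(n), phase = "structured",
    stimulus_id = sprintf("s%03d", seq_len(n)), category = category,
    condition = condition, chunk_id = paste0("c", seq_len(n)),
    repetition = repetition, iti_ms = 500, rt_s = rt, correct = correct,
    stringsAsFactors = FALSE)
}

# A subject x condition summary table from an explicit matrix.
toy_summaries <- function(m, acc = NULL) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("s%d", seq_len(nrow(m)))
  colnames(m) <- c("P1", "P2", "S")
  if (is.null(acc)) acc <- matrix(0.9, nrow(m), 3, dimnames = dimnames(m))
  data.frame(
    subject_id = rep(rownames(m), 3),
    condition = rep(colnames(m), each = nrow(m)),
    mean_rt_s = as.vector(m), accuracy = as.vector(acc),
    n_trials = 10L, n_correct = 9L, stringsAsFactors = FALSE)
}

# A small simulated exp2-style cohort for trajectory tests (1 run, no
# warm-up, to keep fits fast).
small_exp2_cohort <- function(n_subjects = 8, seed = 99, ...) {
  spec <- design_spec("exp2", n_runs = 1, warmup_cycles = 0)
  make_cohort(spec, n_subjects, observer_params(...), seed = seed)
}
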