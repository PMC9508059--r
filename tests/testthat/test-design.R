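test_that("chunk inventories match their design templates", {
  set.seed(1)
  for (case in list(list(preset = "exp1a", pairs = 4, singles = 4,
                         stimuli = 12, repeating = 0),
                    list(preset = "exp1b", pairs = 4, singles = 4,
                         stimuli = 12, repeating = 2),
                    list(preset = "exp2", pairs = 4, singles = 8,
                         stimuli = 16, repeating = 2))) {
    spec <- design_spec(case$preset)
    ch <- make_chunks(spec)
    expect_equal(sum(ch$kind == "pair") / 2, case$pairs)
    expect_equal(sum(ch$kind == "single"), case$singles)
    expect_equal(length(unique(ch$stimulus_id)), case$stimuli)
    # category balance across the run inventory
    expect_equal(sum(ch$category == "A"), sum(ch$category == "B"))
    # pair structure: first slot P1, second P2, singles S
    expect_true(all(ch$condition[ch$kind == "pair" & ch$slot == 1] == "P1"))
    expect_true(all(ch$condition[ch$kind == "pair" & ch$slot == 2] == "P2"))
    expect_true(all(ch$condition[ch$kind == "single"] == "S"))
    # category-repeating pair count
    pair_ids <- unique(ch$chunk_id[ch$kind == "pair"])
    n_rep <- sum(vapply(pair_ids, function(id) {
      cats <- ch$category[ch$chunk_id == id][order(ch$slot[ch$chunk_id == id])]
      cats[1] == cats[2]
    }, TRUE))
    expect_equal(n_rep, case$repeating)
  }
})

test_that("category-imbalanced custom designs are rejected", {
  expect_error(design_spec("custom",
                           pair_templates = list(c("A", "A"), c("A", "B"))),
               "imbalance")
})

test_that("generated runs have the documented trial structure", {
  r1 <- generate_run(design_spec("exp1a"), seed = 11)
  expect_equal(nrow(r1), 72)
  expect_true(all(r1$phase == "structured"))
  expect_equal(range(r1$repetition), c(1, 6))

  r2 <- generate_run(design_spec("exp2"), seed = 12)
  expect_equal(nrow(r2), 400)
  expect_equal(sum(r2$phase == "warmup"), 160)
  expect_equal(sum(r2$phase == "structured"), 240)
  expect_true(all(r2$condition[r2$phase == "warmup"] == "RANDOM"))
  expect_true(all(is.na(r2$repetition[r2$phase == "warmup"])))
  # each warm-up cycle presents every stimulus exactly once
  warm <- r2[r2$phase == "warmup", ]
  cyc <- rep(1:10, each = 16)
  expect_true(all(tapply(warm$stimulus_id, cyc,
                         function(s) length(unique(s))) == 16))
  # each chunk appears exactly 15 times structured
  counts <- table(r2$chunk_id[r2$phase == "structured"],
                  r2$repetition[r2$phase == "structured"])
  expect_true(all(rowSums(counts > 0) == 15))
})

test_that("every structured cycle contains each chunk exactly once and pairs are contiguous", {
  for (preset in c("exp1a", "exp1b", "exp2")) {
    run <- generate_run(design_spec(preset), seed = 21)
    st <- run[run$phase == "structured", ]
    by_cycle <- split(st$chunk_id, st$repetition)
    for (cyc in by_cycle) {
      expect_setequal(unique(cyc), unique(st$chunk_id))
    }
    # pairs contiguous and in order: P1 immediately followed by its P2
    p1 <- which(st$condition == "P1")
    expect_true(all(st$condition[p1 + 1] == "P2"))
    expect_true(all(st$chunk_id[p1 + 1] == st$chunk_id[p1]))
  }
})

test_that("single-cycle run with no warm-up is one shuffled inventory", {
  spec <- design_spec("custom", n_cycles = 1)
  run <- generate_run(spec, seed = 5)
  expect_equal(nrow(run), 8)  # 2 pairs (4 trials) + 4 singles
  expect_equal(length(unique(run$chunk_id)), 6)
  expect_true(all(run$repetition == 1))
  # every pair contiguous and in order even in the single-cycle case
  p1 <- which(run$condition == "P1")
  expect_equal(run$chunk_id[p1 + 1], run$chunk_id[p1])
})

test_that("sessions use disjoint stimulus sets across runs", {
  sess <- generate_session(design_spec("exp1a"), seed = 31)
  expect_equal(length(unique(sess$stimulus_id)), 96)
  by_run <- tapply(sess$stimulus_id, sess$run, unique)
  expect_equal(length(Reduce(intersect, by_run)), 0)

  sess2 <- generate_session(design_spec("exp2"), seed = 32)
  expect_equal(length(unique(sess2$stimulus_id)), 32)

  spec1 <- design_spec("exp1a", n_runs = 1)
  one <- generate_session(spec1, seed = 33)
  expect_equal(nrow(one), 72)
})

test_that("juncture constraint holds at every cycle boundary", {
  for (preset in c("exp1a", "exp1b")) {
    sess <- generate_session(design_spec(preset), seed = 41)
    expect_equal(count_juncture_violations(sess, 3), 0)
  }
})

test_that("pair-followed-by-single constraint holds throughout exp2 runs", {
  for (s in 1:5) {
    run <- generate_run(design_spec("exp2"), seed = 50 + s)
    st <- run[run$phase == "structured", ]
    after_p2 <- st$condition[which(st$condition == "P2") + 1]
    expect_true(all(after_p2 == "S", na.rm = TRUE))
  }
})

test_that("identical seed and spec give identical trial tables", {
  for (preset in c("exp1b", "exp2")) {
    spec <- design_spec(preset)
    a <- generate_session(spec, seed = 77)
    b <- generate_session(spec, seed = 77)
    expect_identical(a, b)
    f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
    write_trials(a, f1); write_trials(b, f2)
    expect_identical(readLines(f1), readLines(f2))
    unlink(c(f1, f2))
  }
})

test_that("unsatisfiable constraints raise a generation error", {
  spec <- design_spec("custom",
                      pair_templates = list(c("A", "B"), c("B", "A")),
                      n_singles_per_category = 0, n_cycles = 3,
                      pair_followed_by_single = TRUE)
  set.seed(1)
  expect_error(generate_run(spec), "pair-followed-by-single")
})

test_that("transition statistics recover the design probabilities", {
  # moderate run counts here; the full-scale convergence check lives in
  # the acceptance suite
  set.seed(60)
  runs_1b <- do.call(rbind, lapply(1:150, function(i) {
    r <- generate_run(design_spec("exp1b"), subject_id = sprintf("v%d", i))
    r
  }))
  st_1b <- empirical_transition_stats(runs_1b)
  expect_equal(st_1b$within_pair, 1.0)
  expect_equal(st_1b$specific_successor_chunk, 1 / 7, tolerance = 0.02)
  expect_equal(st_1b$category_repetition_rate, 0.476, tolerance = 0.03)

  set.seed(61)
  runs_2 <- do.call(rbind, lapply(1:60, function(i) {
    generate_run(design_spec("exp2"), subject_id = sprintf("v%d", i))
  }))
  st_2 <- empirical_transition_stats(runs_2)
  expect_equal(st_2$within_pair, 1.0)
  expect_equal(st_2$p2_to_specific_single, 0.125, tolerance = 0.02)
  expect_equal(st_2$single_to_specific_successor, 1 / 11, tolerance = 0.05)

  # exp1a repeats categories strictly less often than exp1b (all its
  # pairs alternate) -- the structural source of the motor confound
  set.seed(62)
  runs_1a <- do.call(rbind, lapply(1:60, function(i) {
    generate_run(design_spec("exp1a"), subject_id = sprintf("v%d", i))
  }))
  expect_lt(empirical_transition_stats(runs_1a)$category_repetition_rate,
            st_1b$category_repetition_rate - 0.05)

  expect_error(empirical_transition_stats(runs_1a[0, ]), "no structured")
})
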