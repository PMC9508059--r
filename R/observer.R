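#' Generative parameters of the synthetic observer
#'
#' The synthetic observer produces reaction times and correctness with the
#' variance structure the downstream mixed-model analysis assumes:
#'
#' \deqn{RT = \beta_0 + b_{subj} + (\beta_{rep} + b_{slope})\,f(rep) + b_{pic}
#'   + \beta_{ITI}\,ITI - A_{prime} f(rep)\,[P2] + A_{ant} f(rep)\,[P1]
#'   - A_{motor} \ln(1+t)\,[alt] + \delta_{NVAR} + \varepsilon}
#'
#' where `f(rep)` is the learning-curve shape (`ln(rep)` by default, or
#' `rep - 1` for the linear variant), `t` the number of trials seen so far
#' within the session (the accrual of procedural motor priming), `[alt]`
#' indicates that the trial's response category differs from the previous
#' trial's, and \eqn{\delta_{NVAR}} is an additive offset for the
#' current/previous-correctness class (post-error slowing).  Warm-up trials
#' receive no repetition or condition terms.  Correctness is Bernoulli with
#' a condition-specific lapse probability.
#'
#' Defaults are on the scale of typical speeded 2AFC categorization data:
#' a grand mean RT of 0.6 s, trial-to-trial residual SD of 0.12 s, a
#' between-subject intercept SD of 0.08 s, a priming amplitude of 0.005 s
#' per ln-unit of repetition (so the second pair member's RT trend is about
#' -0.004 s per ln-unit against a +0.001 s/ln-unit task-general drift), and
#' a 6% lapse rate.  The motor-confound amplitude defaults to 0 and is
#' switched on explicitly to emulate unbalanced category-transition designs.
#'
#' @param beta0 Grand mean RT (s).
#' @param beta_rep Task-general mean slope of RT on `f(rep)` (s per unit).
#' @param sd_subject_int SD of per-subject intercepts (s).
#' @param sd_subject_slope SD of per-subject slopes on `f(rep)`.
#' @param sd_picture SD of per-picture intercepts (s).
#' @param beta_iti RT change per ms of intertrial interval (s/ms).
#' @param prime_amp P2 RT reduction amplitude (s) scaling with `f(rep)`.
#' @param anticip_amp P1 RT change amplitude (s) scaling with `f(rep)`.
#' @param motor_amp RT reduction (s) for category-alternating responses,
#'   accruing with `ln(1 + trials seen within session)`.
#' @param sigma_resid Residual RT SD (s).
#' @param lapse_rate Baseline probability of an incorrect response.
#' @param lapse_delta Named additive offsets to the lapse probability for
#'   conditions `P1`, `P2`, `S` (condition-dependent accuracy effects).
#' @param nvar_effects Additive RT offsets (s) for NVAR classes 2--4
#'   relative to class 1.
#' @param learning_shape `"log"` (`f(rep) = ln(rep)`) or `"linear"`
#'   (`f(rep) = rep - 1`).
#' @param rt_floor Lower truncation bound for simulated RTs (s).
#' @return An object of class `sl_observer`.
#' @export
observer_params <- function(beta0 = 0.6, beta_rep = 0.001,
                            sd_subject_int = 0.08, sd_subject_slope = 0.003,
                            sd_picture = 0.02, beta_iti = 5e-5,
                            prime_amp = 0.005, anticip_amp = 0,
                            motor_amp = 0, sigma_resid = 0.12,
                            lapse_rate = 0.06,
                            lapse_delta = c(P1 = 0, P2 = 0, S = 0),
                            nvar_effects = c(nvar2 = 0.03, nvar3 = 0.02,
                                             nvar4 = 0.04),
                            learning_shape = c("log", "linear"),
                            rt_floor = 0.05) {
  learning_shape <- match.arg(learning_shape)
  p <- list(beta0 = beta0, beta_rep = beta_rep,
            sd_subject_int = sd_subject_int,
            sd_subject_slope = sd_subject_slope, sd_picture = sd_picture,
            beta_iti = beta_iti, prime_amp = prime_amp,
            anticip_amp = anticip_amp, motor_amp = motor_amp,
            sigma_resid = sigma_resid, lapse_rate = lapse_rate,
            lapse_delta = lapse_delta, nvar_effects = nvar_effects,
            learning_shape = learning_shape, rt_floor = rt_floor)
  validate_observer(p)
  class(p) <- "sl_observer"
  p
}

validate_observer <- function(p) {
  sds <- c(p$sd_subject_int, p$sd_subject_slope, p$sd_picture, p$sigma_resid)
  if (any(sds < 0)) stop("all observer SDs must be >= 0")
  lapse <- p$lapse_rate + c(0, p$lapse_delta)
  if (any(lapse < 0) || any(lapse >= 1)) {
    stop("lapse probabilities must lie in [0, 1)")
  }
  if (!all(c("P1", "P2", "S") %in% names(p$lapse_delta))) {
    stop("lapse_delta must be named with conditions P1, P2, S")
  }
  if (length(p$nvar_effects) != 3L) {
    stop("nvar_effects must give offsets for NVAR classes 2-4")
  }
  if (p$rt_floor <= 0) stop("rt_floor must be positive")
  invisible(p)
}

#' @export
print.sl_observer <- function(x, ...) {
  cat("<sl_observer>\n")
  cat(sprintf("  beta0 %.3f s, resid SD %.3f s, shape %s\n",
              x$beta0, x$sigma_resid, x$learning_shape))
  cat(sprintf("  priming %.4f s/unit, anticipation %.4f, motor %.4f\n",
              x$prime_amp, x$anticip_amp, x$motor_amp))
  cat(sprintf("  RE SDs: subject %.3f, slope %.4f, picture %.3f\n",
              x$sd_subject_int, x$sd_subject_slope, x$sd_picture))
  cat(sprintf("  lapse %.3f\n", x$lapse_rate))
  invisible(x)
}

learn_fun <- function(rep, shape) {
  if (shape == "log") log(rep) else rep - 1
}

#' Simulate observer responses for a trial table
#'
#' Adds reaction times (`rt_s`) and correctness (`correct`) to a generated
#' trial table according to the generative model of [observer_params()].
#' Rows are processed in `subject, session, run, trial` order and returned
#' in that order.
#'
#' @param trials A trial data frame from [generate_run()] or
#'   [generate_session()] (possibly several subjects stacked).
#' @param params An [observer_params()] object.
#' @param seed Optional integer seed.
#' @return The input with columns `rt_s` and `correct` appended.
#' @export
simulate_responses <- function(trials, params = observer_params(),
                               seed = NULL) {
  validate_observer(params)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(trials)
  if (n == 0L) {
    trials$rt_s <- numeric(0)
    trials$correct <- logical(0)
    return(trials)
  }
  key_subj <- paste(trials$subject_id, trials$session_id)
  o <- order(key_subj, trials$run, trials$trial)
  tr <- trials[o, , drop = FALSE]
  key_subj <- key_subj[o]

  subjects <- unique(key_subj)
  b_int <- stats::rnorm(length(subjects), 0, params$sd_subject_int)
  b_slope <- stats::rnorm(length(subjects), 0, params$sd_subject_slope)
  si <- match(key_subj, subjects)
  pics <- unique(tr$stimulus_id)
  b_pic <- stats::rnorm(length(pics), 0, params$sd_picture)
  pi_ <- match(tr$stimulus_id, pics)

  L <- ifelse(tr$phase == "structured" & !is.na(tr$repetition),
              learn_fun(tr$repetition, params$learning_shape), 0)
  is_p1 <- tr$condition == "P1"
  is_p2 <- tr$condition == "P2"

  # previous-trial category within subject x run
  key_run <- paste(key_subj, tr$run)
  first_of_run <- c(TRUE, key_run[-1L] != key_run[-n])
  prev_cat <- c(NA_character_, tr$category[-n])
  prev_cat[first_of_run] <- NA_character_
  alt <- !is.na(prev_cat) & tr$category != prev_cat

  # exposure: trials seen so far within the session (0-based)
  expo <- stats::ave(rep(1, n), key_subj, FUN = seq_along) - 1

  # correctness and NVAR class
  lapse <- rep(params$lapse_rate, n)
  for (cond in c("P1", "P2", "S")) {
    lapse[tr$condition == cond] <- params$lapse_rate +
      params$lapse_delta[[cond]]
  }
  correct <- stats::runif(n) >= lapse
  prev_correct <- c(NA, correct[-n])
  prev_correct[first_of_run] <- NA
  nvar <- ifelse(is.na(prev_correct), NA_integer_,
                 1L + (!correct) * 2L + (!prev_correct) * 1L)
  nvar_off <- c(0, params$nvar_effects)[ifelse(is.na(nvar), 1L, nvar)]
  nvar_off[is.na(nvar)] <- 0

  rt <- params$beta0 + b_int[si] +
    (params$beta_rep + b_slope[si]) * L +
    b_pic[pi_] +
    params$beta_iti * tr$iti_ms -
    params$prime_amp * L * is_p2 +
    params$anticip_amp * L * is_p1 -
    params$motor_amp * log1p(expo) * alt +
    nvar_off +
    stats::rnorm(n, 0, params$sigma_resid)
  tr$rt_s <- pmax(rt, params$rt_floor)
  tr$correct <- correct
  rownames(tr) <- NULL
  tr
}

#' Simulate a cohort of subjects
#'
#' Generates an independent session and response stream for each subject.
#' Seeding is counter-based per `(stage, subject)`, so extending the cohort
#' does not perturb the streams of already-simulated subjects.
#'
#' @param spec An [design_spec()] object.
#' @param n_subjects Number of subjects.
#' @param params An [observer_params()] object.
#' @param seed Master seed for the cohort.
#' @return A response table: one row per trial with the full trial schema
#'   plus `rt_s` and `correct`.
#' @export
make_cohort <- function(spec, n_subjects, params = observer_params(),
                        seed = 1L) {
  stopifnot(n_subjects >= 0L)
  out <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    sid <- sprintf("subj%03d", i)
    trials <- generate_session(spec, subject_id = sid,
                               seed = substream_seed(seed, "design", i))
    out[[i]] <- simulate_responses(trials, params,
                                   seed = substream_seed(seed, "observer", i))
  }
  if (n_subjects == 0L) {
    tr <- generate_run(spec, seed = 1L)[0, , drop = FALSE]
    tr$rt_s <- numeric(0)
    tr$correct <- logical(0)
    return(tr)
  }
  do.call(rbind, out)
}
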