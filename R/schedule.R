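#' Curriculum configuration
#'
#' Houses the parameters of the unpaired-probability curve
#' \deqn{P(t) = B - \frac{A}{1 + e^{-k (t - \mathrm{shift})}}}
#' where `t` is the current step divided by the total number of training
#' steps. `B` is the curve's upper bound, `A` its height (so the curve
#' decays from near `B` toward near `B - A`), `k` the slope of the sigmoid
#' decay, and `shift` its midpoint as a fraction of training. When `shift`
#' is `NULL` it is calibrated with [solve_shift()] so that the discrete
#' mean of `P(t)` over all steps equals `target_unpaired_fraction` — the
#' total fraction of training examples drawn from the unpaired pool.
#'
#' A probability range "`a` to `b`" (e.g. the optimized 0.7 to 0.3)
#' corresponds to `B = a`, `A = a - b`; the range describes the sigmoid's
#' asymptotic bounds, so values at `t = 0, 1` are near but not exactly the
#' endpoints for moderate `k`.
#'
#' @param B Upper bound of the curve, in \[0, 1\].
#' @param A Height of the curve, in \[0, B\].
#' @param k Slope parameter, > 0.
#' @param total_steps Total training steps.
#' @param target_unpaired_fraction Total unpaired data fraction the
#'   calibrated curve must average to; must lie in \[B - A, B\].
#' @param shift Sigmoid midpoint; calibrated when `NULL`.
#' @return An object of class `curriculum_config`.
#' @export
curriculum_config <- function(B = 0.7, A = 0.4, k = 15,
                              total_steps = 100000L,
                              target_unpaired_fraction = 0.625,
                              shift = NULL) {
  check_proportion(B, "B")
  if (!is.numeric(A) || A < 0 || A > B) stop_config("`A` must lie in [0, B]")
  if (!is.numeric(k) || k <= 0) stop_config("`k` must be > 0")
  stopifnot(is_count(total_steps), total_steps > 0)
  check_proportion(target_unpaired_fraction, "target_unpaired_fraction")
  if (is.null(shift)) {
    shift <- solve_shift(B, A, k, total_steps, target_unpaired_fraction)
  }
  structure(list(B = B, A = A, k = k, shift = shift,
                 total_steps = as.integer(total_steps),
                 target_unpaired_fraction = target_unpaired_fraction),
            class = "curriculum_config")
}

#' @export
print.curriculum_config <- function(x, ...) {
  cat(sprintf("<curriculum_config> P(t) = %.3g - %.3g / (1 + exp(-%.3g (t - %.6g)))\n",
              x$B, x$A, x$k, x$shift))
  cat(sprintf("  %d steps, target unpaired fraction %.4g (mean P = %.6g)\n",
              x$total_steps, x$target_unpaired_fraction,
              schedule_mean(x$B, x$A, x$k, x$shift, x$total_steps)))
  invisible(x)
}

#' Unpaired sampling probability at a training fraction
#'
#' Evaluates the sigmoid-decay curve `P(t) = B - A / (1 + exp(-k (t -
#' shift)))`. `P` decreases strictly in `t` for `A, k > 0`: training starts
#' with mostly unpaired single chains and shifts toward natively paired
#' sequences.
#'
#' @param cfg A [curriculum_config()].
#' @param t Fraction(s) of training completed, each in \[0, 1\].
#' @return The unpaired probability, strictly inside `(B - A, B)`.
#' @export
unpaired_probability <- function(cfg, t) {
  stopifnot(inherits(cfg, "curriculum_config"))
  if (any(t < 0 | t > 1)) stop_config("`t` must lie in [0, 1]")
  sigmoid_curve(cfg$B, cfg$A, cfg$k, cfg$shift, t)
}

sigmoid_curve <- function(B, A, k, shift, t) {
  B - A / (1 + exp(-k * (t - shift)))
}

# Discrete mean of the curve over steps s = 0..total_steps-1, t = s/total.
schedule_mean <- function(B, A, k, shift, total_steps) {
  t <- (seq_len(total_steps) - 1) / total_steps
  mean(sigmoid_curve(B, A, k, shift, t))
}

#' Calibrate the sigmoid midpoint against a data budget
#'
#' Finds `shift` such that the discrete mean of the unpaired-probability
#' curve over steps `0 .. total_steps - 1` equals
#' `target_unpaired_fraction`. The mean is strictly increasing in `shift`
#' (delaying the decay keeps the probability near `B` for longer), so a
#' bisection on `shift` in \[-1, 2\] converges; the widened interval admits
#' curves saturated at either end for extreme `k`.
#'
#' @param B,A,k Curve parameters (see [curriculum_config()]).
#' @param total_steps Total training steps.
#' @param target_unpaired_fraction Required mean, within the attainable
#'   interval \[B - A, B\].
#' @param tol Bisection tolerance on the mean.
#' @return The calibrated `shift`.
#' @export
solve_shift <- function(B, A, k, total_steps, target_unpaired_fraction,
                        tol = 1e-9) {
  check_proportion(B, "B")
  target <- target_unpaired_fraction
  if (target < B - A - 1e-12 || target > B + 1e-12) {
    stop_config(sprintf(
      "target unpaired fraction %.4g is unattainable: the curve's mean lies in [%.4g, %.4g]",
      target, B - A, B))
  }
  if (A == 0) return(0.5)  # constant curve: any shift reproduces the mean
  lo <- -1; hi <- 2
  mean_at <- function(s) schedule_mean(B, A, k, s, total_steps)
  m_lo <- mean_at(lo); m_hi <- mean_at(hi)
  if (target < m_lo - tol || target > m_hi + tol) {
    stop_config(sprintf(
      "target %.6g outside the range [%.6g, %.6g] reachable at this k; attainable asymptotically in [%.4g, %.4g]",
      target, m_lo, m_hi, B - A, B))
  }
  for (i in seq_len(200L)) {
    mid <- (lo + hi) / 2
    m <- mean_at(mid)
    if (abs(m - target) <= tol) return(mid)
    if (m < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Build a sampling-schedule plan
#'
#' Produces the per-step unpaired-probability function for the five
#' training strategies compared in the framework, all matched on the same
#' total amount of unpaired and paired data:
#' \describe{
#'   \item{`curriculum`}{calibrated sigmoid decay ([curriculum_config()]);}
#'   \item{`constant`}{a fixed mixing ratio, `P(s) = target` at every step;}
#'   \item{`finetuned`}{unpaired-only pre-training then paired-only
#'     finetuning: `P = 1` for the first `round(target * total_steps)`
#'     steps, 0 after;}
#'   \item{`unpaired_only`}{`P = 1` throughout;}
#'   \item{`paired_only`}{`P = 0` throughout.}
#' }
#' For every mixed kind the discrete mean of the probability equals
#' `target_unpaired_fraction` to within `1 / (2 total_steps)`.
#'
#' @param kind Schedule kind, one of the five above.
#' @param target_unpaired_fraction Total unpaired data fraction (ignored by
#'   the single-datatype kinds).
#' @param total_steps Total training steps.
#' @param B,A,k Curve parameters for `kind = "curriculum"`.
#' @return An object of class `schedule_plan` with fields `kind`,
#'   `probability_fn` (a vectorized function of the 0-based step),
#'   `total_steps`, `target_unpaired_fraction`.
#' @export
make_schedule <- function(kind = c("curriculum", "constant", "finetuned",
                                   "unpaired_only", "paired_only"),
                          target_unpaired_fraction = 0.625,
                          total_steps = 100000L,
                          B = 0.7, A = 0.4, k = 15) {
  kind <- match.arg(kind)
  stopifnot(is_count(total_steps), total_steps > 0)
  check_proportion(target_unpaired_fraction, "target_unpaired_fraction")
  total_steps <- as.integer(total_steps)
  fn <- switch(kind,
    curriculum = {
      cfg <- curriculum_config(B, A, k, total_steps, target_unpaired_fraction)
      function(step) unpaired_probability(cfg, step / total_steps)
    },
    constant = function(step) rep(target_unpaired_fraction, length(step)),
    finetuned = {
      switch_step <- round(target_unpaired_fraction * total_steps)
      function(step) as.numeric(step < switch_step)
    },
    unpaired_only = function(step) rep(1, length(step)),
    paired_only = function(step) rep(0, length(step))
  )
  structure(list(kind = kind, probability_fn = fn,
                 total_steps = total_steps,
                 target_unpaired_fraction = target_unpaired_fraction),
            class = "schedule_plan")
}

#' @export
print.schedule_plan <- function(x, ...) {
  steps <- 0:(x$total_steps - 1L)
  cat(sprintf("<schedule_plan> %s over %d steps, mean unpaired probability %.6g\n",
              x$kind, x$total_steps, mean(x$probability_fn(steps))))
  invisible(x)
}

#' Learning-rate schedule configuration
#'
#' @param kind `"linear"` (warmup then linear decay to 0), `"wsd"`
#'   (warmup-stable-decay: warmup, constant at peak, linear decay over the
#'   final `wsd_decay_fraction` of steps) or `"sgdr"` (warmup then cosine
#'   annealing with warm restarts over `sgdr_cycles` equal cycles).
#' @param peak_lr Peak learning rate (the pilot pre-training runs use 4e-4).
#' @param warmup_steps Linear warmup length in steps.
#' @param total_steps Total steps.
#' @param wsd_decay_fraction Fraction of steps in the final decay phase.
#' @param sgdr_cycles Number of cosine cycles after warmup.
#' @return An object of class `lr_schedule_config`.
#' @export
lr_schedule_config <- function(kind = c("linear", "wsd", "sgdr"),
                               peak_lr = 4e-4, warmup_steps = 6000L,
                               total_steps = 100000L,
                               wsd_decay_fraction = 0.2, sgdr_cycles = 3L) {
  kind <- match.arg(kind)
  if (peak_lr <= 0) stop_config("peak_lr must be > 0")
  stopifnot(is_count(warmup_steps), is_count(total_steps))
  if (warmup_steps >= total_steps) stop_config("warmup_steps must be < total_steps")
  structure(list(kind = kind, peak_lr = peak_lr,
                 warmup_steps = as.integer(warmup_steps),
                 total_steps = as.integer(total_steps),
                 wsd_decay_fraction = wsd_decay_fraction,
                 sgdr_cycles = as.integer(sgdr_cycles)),
            class = "lr_schedule_config")
}

#' Learning rate at a step
#'
#' @param cfg An [lr_schedule_config()].
#' @param step 0-based step(s) in `[0, total_steps)`.
#' @return Learning rate(s).
#' @export
lr_at <- function(cfg, step) {
  stopifnot(inherits(cfg, "lr_schedule_config"))
  if (any(step < 0 | step >= cfg$total_steps)) {
    stop_config("step must lie in [0, total_steps)")
  }
  w <- cfg$warmup_steps; total <- cfg$total_steps; peak <- cfg$peak_lr
  warm <- pmin(1, if (w > 0) step / w else 1)
  after <- switch(cfg$kind,
    linear = (total - step) / (total - w),
    wsd = {
      decay_start <- total - round(cfg$wsd_decay_fraction * total)
      ifelse(step < decay_start, 1, (total - step) / (total - decay_start))
    },
    sgdr = {
      span <- total - w
      cycle_len <- span / cfg$sgdr_cycles
      pos <- pmax(0, step - w)
      frac <- (pos %% cycle_len) / cycle_len
      0.5 * (1 + cos(pi * frac))
    })
  peak * ifelse(step < w, warm, after)
}
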