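# Analytic forward recursion over pair-status states, used as an
# independent oracle for the stochastic copying engine. Works directly
# from the model parameters: the per-incorporation match probability is
# the template-distribution-weighted correct-incorporation probability,
# plain or with the post-mismatch boost applied to mismatch weights; the
# chain over positions is Markov in the status of the terminal pair.
oracle_position_probs <- function(model, L) {
  sys <- model$system
  alpha <- sys$alphabet
  comp_idx <- match(unname(sys$complement[alpha]), alpha)
  W <- model$propensity
  dist <- model$template_dist

  match_prob <- function(boost) {
    p <- 0
    for (t in seq_along(alpha)) {
      w <- W[t, ]
      mis <- setdiff(seq_along(alpha), comp_idx[t])
      w[mis] <- w[mis] * boost
      p <- p + dist[t] * w[comp_idx[t]] / sum(w)
    }
    unname(p)
  }
  pm <- match_prob(1)
  pm_b <- match_prob(model$post_mismatch_error_boost)

  p_comp <- p_mis <- numeric(L)
  c_prev <- model$p_ext_initial * pm
  m_prev <- model$p_ext_initial * (1 - pm)
  p_comp[1] <- c_prev
  p_mis[1] <- m_prev
  for (i in seq_len(L)[-1]) {
    inc_c <- c_prev * model$p_ext_after_match
    inc_m <- m_prev * model$p_ext_after_mismatch
    c_prev <- inc_c * pm + inc_m * pm_b
    m_prev <- inc_c * (1 - pm) + inc_m * (1 - pm_b)
    p_comp[i] <- c_prev
    p_mis[i] <- m_prev
  }
  tibble::tibble(
    position = seq_len(L),
    p_comp = p_comp,
    p_mismatch = p_mis,
    p_unextended = 1 - p_comp - p_mis
  )
}

# 3-binomial-SE band check of an observed frequency against an analytic
# probability
within_3se <- function(observed, p, n) {
  se <- sqrt(p * (1 - p) / n)
  abs(observed - p) <= 3 * pmax(se, .Machine$double.eps)
}
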