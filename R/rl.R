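# Tabular Q-learning attack loop: discrete (add, remove) actions, the
# probability-dilution reward, epsilon-greedy action selection over a
# discretized state, and the episode loop that runs until misclassification
# or the step limit.

#' Enumerate legal (add, remove) actions
#'
#' All pairs with `1 <= add <= P_max`, `0 <= remove < add`, and
#' `remove <= n_distorted_patches`, in deterministic order (add ascending,
#' remove ascending). With no constraint from the distorted count the action
#' space has `P_max * (P_max + 1) / 2` elements.
#'
#' @param p_max maximum number of patches distorted per step, `>= 1`.
#' @param n_distorted number of currently distorted patches (bounds
#'   `remove`); default unbounded.
#' @return data frame with integer columns `add` and `remove`.
#' @export
enumerate_actions <- function(p_max, n_distorted = Inf) {
  if (p_max < 1L) config_stop("p_max must be >= 1")
  add <- rep(seq_len(p_max), times = seq_len(p_max))
  remove <- unlist(lapply(seq_len(p_max), function(a) 0:(a - 1L)))
  keep <- remove <= n_distorted
  data.frame(add = as.integer(add[keep]), remove = as.integer(remove[keep]))
}

#' Probability dilution
#'
#' The signed margin `max_{c != gt} p_c - p_gt`: how far probability mass
#' has shifted from the ground-truth class toward the best alternative. It
#' is zero exactly at the decision boundary and positive exactly when the
#' image is misclassified, matching the episode termination rule. The
#' complement convention `1 - p_gt` is available for comparison.
#'
#' @param probs probability vector on the simplex (length `>= 2`).
#' @param gt_label 0-based ground-truth class index.
#' @param convention `"margin"` (default) or `"complement"`.
#' @return scalar in `[-1, 1]`.
#' @export
probability_dilution <- function(probs, gt_label,
                                 convention = c("margin", "complement")) {
  convention <- match.arg(convention)
  if (length(probs) < 2L) {
    data_stop("probability dilution needs at least 2 classes")
  }
  gt1 <- as.integer(gt_label) + 1L
  if (convention == "margin") {
    max(probs[-gt1]) - probs[gt1]
  } else {
    1 - probs[gt1]
  }
}

#' Reward configuration
#'
#' Two reward modes are available. `pd_ratio` is the per-step default: the
#' change in probability dilution divided by the change in L2 distance,
#' guarded against a vanishing denominator. `sensitivity_linear` is the
#' linear combination `alpha * sensitivity - beta * FPR` computed over a
#' held-out evaluation batch.
#'
#' @param mode `"pd_ratio"` or `"sensitivity_linear"`.
#' @param alpha,beta non-negative weights (sensitivity_linear only).
#' @param l2_floor denominator guard `epsilon > 0` for pd_ratio.
#' @param r_max cap on the reward magnitude for pd_ratio.
#' @return a `reward_config` list.
#' @export
reward_config <- function(mode = c("pd_ratio", "sensitivity_linear"),
                          alpha = 1, beta = 1, l2_floor = 1e-8, r_max = 1e6) {
  mode <- match.arg(mode)
  if (alpha < 0 || beta < 0) config_stop("alpha and beta must be >= 0")
  if (l2_floor <= 0) config_stop("l2_floor must be > 0")
  structure(list(mode = mode, alpha = alpha, beta = beta,
                 l2_floor = l2_floor, r_max = r_max),
            class = "reward_config")
}

#' Per-step probability-dilution reward
#'
#' `R = dPD / max(|dL2|, epsilon)`, with `|R|` capped at `r_max`. The
#' absolute value in the denominator handles the rare net-removal step where
#' the L2 distance decreases.
#'
#' @param pd_before,pd_after probability dilution before/after the action.
#' @param d_before,d_after L2 distance before/after the action.
#' @param config a [reward_config()] with `mode = "pd_ratio"`.
#' @return scalar reward.
#' @export
step_reward <- function(pd_before, pd_after, d_before, d_after,
                        config = reward_config()) {
  if (config$mode != "pd_ratio") {
    config_stop("step_reward requires reward mode 'pd_ratio'")
  }
  r <- (pd_after - pd_before) / max(abs(d_after - d_before), config$l2_floor)
  sign(r) * min(abs(r), config$r_max)
}

#' Linear sensitivity/false-positive-rate reward
#'
#' `R = alpha * sensitivity - beta * FPR`, where both rates are evaluated on
#' a held-out batch (see [eval_batch_rates()]).
#'
#' @param sensitivity recall of the positive class on the evaluation batch,
#'   in `[0,1]`.
#' @param false_positive_rate `FP / (FP + TN)` on the evaluation batch, in
#'   `[0,1]`.
#' @param alpha,beta non-negative weights.
#' @return scalar reward.
#' @export
linear_reward <- function(sensitivity, false_positive_rate,
                          alpha = 1, beta = 1) {
  if (is.na(sensitivity) || is.na(false_positive_rate) ||
      sensitivity < 0 || sensitivity > 1 ||
      false_positive_rate < 0 || false_positive_rate > 1) {
    data_stop("sensitivity and false_positive_rate must lie in [0, 1]")
  }
  alpha * sensitivity - beta * false_positive_rate
}

#' Sensitivity and false positive rate of a classifier on a batch
#'
#' @param bb a [as_blackbox()] classifier.
#' @param samples non-empty list of [image_sample()] objects.
#' @param positive_class 0-based label treated as positive.
#' @return list with `sensitivity` and `fpr` (either may be `NA` when the
#'   batch lacks positives/negatives).
#' @export
eval_batch_rates <- function(bb, samples, positive_class = 1L) {
  if (length(samples) == 0) data_stop("empty evaluation batch")
  probs <- query_probs(bb, lapply(samples, function(s) s$pixels))
  pred <- max.col(probs) - 1L
  truth <- vapply(samples, function(s) s$label, integer(1))
  cc <- confusion_from_predictions(truth, pred, positive_class)
  list(sensitivity = if (cc$TP + cc$FN > 0) cc$TP / (cc$TP + cc$FN) else NA_real_,
       fpr = if (cc$FP + cc$TN > 0) cc$FP / (cc$FP + cc$TN) else NA_real_)
}

#' Q-learning configuration
#'
#' @param gamma discount factor in `[0,1]`.
#' @param q_learning_rate tabular update step in `(0,1]`.
#' @param eps_start,eps_end,eps_decay epsilon-greedy schedule: episode `k`
#'   (0-based) explores with probability
#'   `max(eps_end, eps_start * eps_decay^k)`.
#' @param max_steps episode step limit `T >= 0`.
#' @param p_max maximum patches distorted per step (8 matches the reference
#'   configuration for 224x224 images with 2x2 patches).
#' @param bins integer vector of bin counts for the four state features:
#'   P_GT, L2 distance, step fraction t/T, and top patch sensitivity.
#' @param d_scale reference L2 scale: distances are binned over
#'   `[0, d_scale]`.
#' @param sens_scale reference scale for the top `p_add` feature.
#' @param seed RNG seed for action exploration.
#' @return a `qlearning_config` list.
#' @export
qlearning_config <- function(gamma = 0.9, q_learning_rate = 0.1,
                             eps_start = 1.0, eps_end = 0.05,
                             eps_decay = 0.9, max_steps = 50L, p_max = 8L,
                             bins = c(4L, 4L, 4L, 4L), d_scale = 2.0,
                             sens_scale = 0.2, seed = 1L) {
  if (gamma < 0 || gamma > 1) config_stop("gamma must lie in [0, 1]")
  if (q_learning_rate <= 0 || q_learning_rate > 1) {
    config_stop("q_learning_rate must lie in (0, 1]")
  }
  if (max_steps < 0L) config_stop("max_steps must be >= 0")
  if (any(bins < 1L)) config_stop("all bin counts must be >= 1")
  structure(list(gamma = gamma, q_learning_rate = q_learning_rate,
                 eps_start = eps_start, eps_end = eps_end,
                 eps_decay = eps_decay, max_steps = as.integer(max_steps),
                 p_max = as.integer(p_max), bins = as.integer(bins),
                 d_scale = d_scale, sens_scale = sens_scale,
                 seed = as.integer(seed)),
            class = "qlearning_config")
}

#' A tabular action-value function
#'
#' Maps discretized state keys to a value per action; unseen (state, action)
#' pairs default to 0. Visit counts are tracked alongside.
#'
#' @param n_actions number of actions per state.
#' @return object of class `qtable`.
#' @export
qtable_new <- function(n_actions) {
  e <- new.env(parent = emptyenv())
  e$values <- new.env(parent = emptyenv())
  e$visits <- new.env(parent = emptyenv())
  e$n_actions <- as.integer(n_actions)
  class(e) <- "qtable"
  e
}

#' Action values for a state
#'
#' @param Q a [qtable_new()] table.
#' @param s state key (character).
#' @return numeric vector of length `n_actions` (zeros if unseen).
#' @export
q_values <- function(Q, s) {
  v <- Q$values[[s]]
  if (is.null(v)) numeric(Q$n_actions) else v
}

#' One tabular Q-learning update
#'
#' `Q(s,a) <- Q(s,a) + lr * (r + gamma * max_a' Q(s',a') - Q(s,a))`; a
#' terminal next state contributes zero future value.
#'
#' @param Q a [qtable_new()] table (updated in place).
#' @param s state key.
#' @param a 1-based action index.
#' @param r reward.
#' @param s_next next-state key (ignored when `terminal`).
#' @param config a [qlearning_config()] supplying `gamma` and the learning
#'   rate.
#' @param terminal logical; `TRUE` for episode-ending transitions.
#' @return `Q`, invisibly.
#' @export
q_update <- function(Q, s, a, r, s_next = NULL, config = qlearning_config(),
                     terminal = FALSE) {
  v <- q_values(Q, s)
  future <- if (terminal || is.null(s_next)) 0 else max(q_values(Q, s_next))
  v[a] <- v[a] + config$q_learning_rate * (r + config$gamma * future - v[a])
  Q$values[[s]] <- v
  nv <- Q$visits[[s]]
  if (is.null(nv)) nv <- integer(Q$n_actions)
  nv[a] <- nv[a] + 1L
  Q$visits[[s]] <- nv
  invisible(Q)
}

bin_index <- function(x, n_bins) {
  # equal-width bins on [0, 1]; values at 1 fall in the top bin
  min(max(floor(x * n_bins), 0), n_bins - 1L)
}

#' Discretize a perturbation state for the Q-table
#'
#' Four binned features: the ground-truth probability `P_GT`, the L2
#' distance relative to `d_scale`, the step fraction `t / T`, and the
#' magnitude of the largest per-patch add-sensitivity relative to
#' `sens_scale`. Deterministic: states equal in all binned quantities share
#' a key.
#'
#' @param state a [perturbation_state()].
#' @param smap the current [compute_sensitivity()] map.
#' @param config a [qlearning_config()].
#' @return character state key.
#' @export
discretize_state <- function(state, smap, config = qlearning_config()) {
  b <- config$bins
  top_add <- if (length(smap$p_add) > 0) max(smap$p_add, 0) else 0
  tfrac <- if (config$max_steps > 0) state$t / config$max_steps else 0
  paste(
    bin_index(smap$p_gt, b[1]),
    bin_index(min(state_distance(state) / config$d_scale, 1), b[2]),
    bin_index(min(tfrac, 1), b[3]),
    bin_index(min(top_add / config$sens_scale, 1), b[4]),
    sep = "_")
}

# Greedy (or random, for the ablation arm) patch target selection.
select_patches <- function(smap, state, action, selector) {
  np <- state$grid$n_patches
  dist <- distorted_patches(state)
  if (selector == "random") {
    adds <- sample.int(np, action$add, replace = FALSE) - 1L
    rems <- if (action$remove > 0) {
      avail <- setdiff(dist, adds)
      if (length(avail) >= action$remove) {
        avail[sample.int(length(avail), action$remove)]
      } else integer(0)
    } else integer(0)
  } else {
    # stable tie-break: order() is stable, lower patch index wins ties
    adds <- (order(-smap$p_add)[seq_len(action$add)]) - 1L
    rems <- integer(0)
    if (action$remove > 0) {
      cand <- setdiff(dist, adds)  # never undo a patch being re-distorted now
      if (length(cand) > 0) {
        pr <- smap$p_remove[cand + 1L]
        rems <- cand[order(-pr)][seq_len(min(action$remove, length(cand)))]
      }
    }
  }
  list(add = adds, remove = rems)
}

#' Run one attack episode
#'
#' The episode loop: at each step, compute the sensitivity map, pick an
#' (add, remove) action epsilon-greedily from the Q-table, distort the
#' `add` patches with the largest add-sensitivity and undo the `remove`
#' distorted patches with the largest remove-sensitivity, observe the reward
#' and update the Q-table. The episode stops when the image is misclassified
#' (probability dilution becomes positive) or after `max_steps` steps. An
#' image misclassified before any perturbation returns success immediately
#' with an empty trajectory.
#'
#' @param bb a [as_blackbox()] classifier.
#' @param sample the [image_sample()] under attack.
#' @param Q a shared [qtable_new()] table (updated in place when `learn`).
#' @param filter the [distortion_filter()] used for every application.
#' @param qcfg a [qlearning_config()].
#' @param rcfg a [reward_config()].
#' @param epsilon exploration probability for this episode.
#' @param learn update the Q-table from observed transitions.
#' @param selector `"sensitivity"` (greedy by sensitivity ranking) or
#'   `"random"` (uniform patch choice ablation).
#' @param patch_size patch side length `n` for the grid.
#' @param eval_samples held-out evaluation batch, required for the
#'   `sensitivity_linear` reward mode.
#' @return an `episode_result`: `success`, the final `state`, the
#'   `adversarial` image, the per-step `trajectory` (action, reward, PD, D),
#'   and `queries` issued during the episode.
#' @export
run_episode <- function(bb, sample, Q, filter,
                        qcfg = qlearning_config(),
                        rcfg = reward_config(),
                        epsilon = qcfg$eps_end, learn = TRUE,
                        selector = c("sensitivity", "random"),
                        patch_size = 2L, eval_samples = NULL) {
  selector <- match.arg(selector)
  if (rcfg$mode == "sensitivity_linear" &&
      (is.null(eval_samples) || length(eval_samples) == 0)) {
    data_stop("sensitivity_linear reward requires a non-empty eval_samples batch")
  }
  grid <- segment_patches(sample, patch_size)
  q0 <- query_count(bb)
  probs0 <- query_probs(bb, sample$pixels)[1, ]
  gt <- sample$label
  state <- perturbation_state(sample, grid, filter)
  actions <- enumerate_actions(qcfg$p_max)
  traj <- list()

  pd <- probability_dilution(probs0, gt)
  if (pd > 0) {
    return(episode_result(TRUE, state, traj, query_count(bb) - q0,
                          p_gt = probs0[gt + 1L]))
  }
  if (qcfg$max_steps == 0L) {
    return(episode_result(FALSE, state, traj, query_count(bb) - q0,
                          p_gt = probs0[gt + 1L]))
  }

  p_gt <- probs0[gt + 1L]
  pending <- NULL
  success <- FALSE
  for (t in seq_len(qcfg$max_steps)) {
    # the random-ablation arm ignores sensitivities entirely, so the
    # per-patch probes are skipped (a zero map keeps the state key defined)
    smap <- if (selector == "random") {
      structure(list(p_add = numeric(grid$n_patches),
                     p_remove = rep(NA_real_, grid$n_patches),
                     p_gt = p_gt),
                class = "sensitivity_map")
    } else {
      compute_sensitivity(bb, state, gt, p_gt_current = p_gt)
    }
    skey <- discretize_state(state, smap, qcfg)
    if (!is.null(pending)) {
      q_update(Q, pending$s, pending$a, pending$r, skey, qcfg)
    }
    n_dist <- length(distorted_patches(state))
    legal <- which(actions$remove <= n_dist)
    a_idx <- if (stats::runif(1) < epsilon) {
      legal[sample.int(length(legal), 1L)]
    } else {
      qv <- q_values(Q, skey)[legal]
      # random tie-break among maximal actions: under a flat (e.g. fresh)
      # Q-table greedy selection would otherwise collapse onto the first
      # action and starve the attack of large add counts
      best <- which(qv >= max(qv) - 1e-12)
      legal[best[sample.int(length(best), 1L)]]
    }
    action <- actions[a_idx, ]
    sel <- select_patches(smap, state, action, selector)
    d_before <- state_distance(state)
    for (k in sel$remove) state <- remove_distortion(state, k)
    for (k in sel$add) state <- apply_distortion(state, k, filter)
    state$t <- t
    probs_t <- query_probs(bb, state$current)[1, ]
    pd_new <- probability_dilution(probs_t, gt)
    reward <- if (rcfg$mode == "pd_ratio") {
      step_reward(pd, pd_new, d_before, state_distance(state), rcfg)
    } else {
      rates <- eval_batch_rates(bb, eval_samples, positive_class = 1L)
      linear_reward(rates$sensitivity, rates$fpr, rcfg$alpha, rcfg$beta)
    }
    traj[[t]] <- data.frame(
      t = t, add = action$add, remove = action$remove,
      n_added = length(sel$add), n_removed = length(sel$remove),
      reward = reward, pd = pd_new, d = state_distance(state))
    success <- pd_new > 0
    if (learn) {
      if (success || t == qcfg$max_steps) {
        q_update(Q, skey, a_idx, reward, NULL, qcfg, terminal = TRUE)
        pending <- NULL
      } else {
        pending <- list(s = skey, a = a_idx, r = reward)
      }
    }
    pd <- pd_new
    p_gt <- probs_t[gt + 1L]
    if (success) break
  }
  episode_result(success, state, traj, query_count(bb) - q0, p_gt = p_gt)
}

episode_result <- function(success, state, traj, queries, p_gt) {
  structure(
    list(success = success, state = state, adversarial = state$current,
         trajectory = if (length(traj) > 0) do.call(rbind, traj)
                      else data.frame(),
         queries = queries, steps = length(traj), p_gt_final = p_gt),
    class = "episode_result")
}

#' @export
print.episode_result <- function(x, ...) {
  cat(sprintf(
    "<episode_result> %s after %d step(s), D = %.4f, %d queries\n",
    if (x$success) "misclassified" else "not misclassified",
    x$steps, state_distance(x$state), x$queries))
  invisible(x)
}

#' Attack a set of images with a shared Q-table
#'
#' Runs one episode per image, sharing the Q-table across episodes so the
#' agent learns across the set; epsilon decays per episode according to the
#' configured schedule.
#'
#' @param bb a [as_blackbox()] classifier.
#' @param samples list of [image_sample()] objects.
#' @param filter the [distortion_filter()] to use.
#' @param qcfg a [qlearning_config()].
#' @param rcfg a [reward_config()].
#' @param Q optionally a pre-existing [qtable_new()] table to continue.
#' @param learn update the Q-table.
#' @param selector passed to [run_episode()].
#' @param patch_size patch side length `n`.
#' @param eval_samples passed to [run_episode()] for the
#'   `sensitivity_linear` reward mode.
#' @return list with `episodes` (one `episode_result` per sample) and `Q`.
#' @export
run_attack <- function(bb, samples, filter, qcfg = qlearning_config(),
                       rcfg = reward_config(), Q = NULL, learn = TRUE,
                       selector = "sensitivity", patch_size = 2L,
                       eval_samples = NULL) {
  if (is.null(Q)) {
    Q <- qtable_new(nrow(enumerate_actions(qcfg$p_max)))
  }
  episodes <- vector("list", length(samples))
  with_seed(qcfg$seed, {
    for (i in seq_along(samples)) {
      eps <- max(qcfg$eps_end, qcfg$eps_start * qcfg$eps_decay^(i - 1L))
      episodes[[i]] <- run_episode(bb, samples[[i]], Q, filter, qcfg, rcfg,
                                   epsilon = eps, learn = learn,
                                   selector = selector,
                                   patch_size = patch_size,
                                   eval_samples = eval_samples)
    }
  })
  list(episodes = episodes, Q = Q)
}
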