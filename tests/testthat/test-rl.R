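test_that("the action space enumerates (add, remove) pairs exactly", {
  expect_equal(enumerate_actions(1), data.frame(add = 1L, remove = 0L))
  expect_equal(enumerate_actions(2),
               data.frame(add = c(1L, 2L, 2L), remove = c(0L, 0L, 1L)))
  a8 <- enumerate_actions(8)
  expect_equal(nrow(a8), 36L)   # P_max (P_max + 1) / 2
  expect_true(all(a8$remove < a8$add))
  expect_true(all(a8$add <= 8))
  # the distorted-patch count caps the removals
  a_cap <- enumerate_actions(8, n_distorted = 0)
  expect_true(all(a_cap$remove == 0))
  expect_equal(nrow(a_cap), 8L)
  expect_error(enumerate_actions(0), "p_max")
})

test_that("probability dilution is the signed margin", {
  expect_equal(probability_dilution(c(1, 0), 0), -1)
  expect_equal(probability_dilution(c(0.5, 0.5), 0), 0)
  expect_equal(probability_dilution(c(0.2, 0.8), 0), 0.6)
  expect_equal(probability_dilution(c(0.2, 0.5, 0.3), 1), -0.2)
  expect_equal(probability_dilution(c(0.2, 0.8), 0, "complement"), 0.8)
  expect_error(probability_dilution(c(1), 0), "2 classes")
  # sign characterizes misclassification
  set.seed(15)
  for (i in 1:20) {
    p <- stats::runif(3); p <- p / sum(p)
    gt <- sample(0:2, 1)
    expect_equal(probability_dilution(p, gt) > 0,
                 which.max(p) - 1L != gt)
  }
})

test_that("the ratio reward divides dPD by guarded |dL2|", {
  cfg <- reward_config()
  expect_equal(step_reward(-0.5, -0.5, 0, 1, cfg), 0)
  expect_equal(step_reward(-0.5, -0.2, 0, 0.15, cfg), 2.0)
  # vanishing denominator: floor at epsilon, cap at r_max
  expect_equal(step_reward(-0.5, -0.4, 1, 1, cfg), 1e6)
  expect_equal(step_reward(-0.4, -0.5, 1, 1, cfg), -1e6)
  # net removal (negative dL2) uses the magnitude
  expect_equal(step_reward(-0.5, -0.3, 1, 0.9, cfg), 0.2 / 0.1,
               tolerance = 1e-9)
  expect_error(step_reward(0, 0, 0, 0, reward_config("sensitivity_linear")),
               "pd_ratio")
})

test_that("the linear reward combines sensitivity and FPR", {
  expect_equal(linear_reward(0, 0), 0)
  expect_equal(linear_reward(0.9, 0.1, alpha = 1, beta = 1), 0.8)
  expect_equal(linear_reward(0.5, 0.9, alpha = 2, beta = 0), 1.0)
  expect_error(linear_reward(1.2, 0), "\\[0, 1\\]")
  expect_error(eval_batch_rates(as_blackbox(function(i) c(1, 0)), list()),
               "empty")
  # rates on a tiny labeled batch recomputed against known predictions
  bb <- as_blackbox(function(img) if (mean(img) > 0.5) c(0, 1) else c(1, 0))
  batch <- list(flat_sample(0.8, label = 1L), flat_sample(0.2, label = 1L),
                flat_sample(0.7, label = 0L), flat_sample(0.1, label = 0L))
  r <- eval_batch_rates(bb, batch, positive_class = 1L)
  expect_equal(r$sensitivity, 0.5)  # one of two positives found
  expect_equal(r$fpr, 0.5)          # one of two negatives flagged
})

test_that("Q updates follow the Bellman arithmetic", {
  cfg1 <- qlearning_config(gamma = 0.9, q_learning_rate = 1)
  Q <- qtable_new(2)
  q_update(Q, "s", 1, r = 1, terminal = TRUE, config = cfg1)
  expect_equal(q_values(Q, "s")[1], 1)

  cfg2 <- qlearning_config(gamma = 0, q_learning_rate = 1)
  Q2 <- qtable_new(2)
  q_update(Q2, "s", 2, r = 0.37, s_next = "t", config = cfg2)
  expect_equal(q_values(Q2, "s")[2], 0.37)

  cfg3 <- qlearning_config(gamma = 0.9, q_learning_rate = 0.5)
  Q3 <- qtable_new(2)
  Q3$values[["s"]] <- c(0.2, 0)
  Q3$values[["t"]] <- c(0.1, 0.4)
  q_update(Q3, "s", 1, r = 1, s_next = "t", config = cfg3)
  expect_equal(q_values(Q3, "s")[1], 0.2 + 0.5 * (1 + 0.9 * 0.4 - 0.2),
               tolerance = 1e-12)
  expect_equal(q_values(Q3, "s")[1], 0.78, tolerance = 1e-12)
  # unseen states read as zeros
  expect_equal(q_values(Q3, "unseen"), c(0, 0))
})

test_that("tabular Q-learning converges to value iteration on a fixed MDP", {
  # deterministic 5-state chain: action 1 moves right (reward 1 on reaching
  # the terminal state s5), action 2 stays (reward 0.05)
  gamma <- 0.9
  n_states <- 5L
  step_mdp <- function(s, a) {
    if (a == 1L) {
      if (s == 4L) list(s2 = 5L, r = 1, terminal = TRUE)
      else list(s2 = s + 1L, r = 0, terminal = FALSE)
    } else {
      list(s2 = s, r = 0.05, terminal = FALSE)
    }
  }
  # independent oracle: value iteration on the same MDP
  Qstar <- matrix(0, n_states - 1L, 2)
  for (it in 1:500) {
    Qn <- Qstar
    for (s in 1:4) for (a in 1:2) {
      tr <- step_mdp(s, a)
      v2 <- if (tr$terminal) 0 else max(Qstar[tr$s2, ])
      Qn[s, a] <- tr$r + gamma * v2
    }
    Qstar <- Qn
  }
  cfg <- qlearning_config(gamma = gamma, q_learning_rate = 1.0)
  Q <- qtable_new(2)
  set.seed(16)
  for (ep in 1:200) {
    s <- 1L
    for (t in 1:30) {
      a <- sample(1:2, 1)                 # pure exploration
      tr <- step_mdp(s, a)
      q_update(Q, as.character(s), a, tr$r,
               s_next = as.character(tr$s2), config = cfg,
               terminal = tr$terminal)
      if (tr$terminal) break
      s <- tr$s2
    }
  }
  for (s in 1:4) {
    expect_equal(q_values(Q, as.character(s)), Qstar[s, ], tolerance = 1e-6)
  }
})

test_that("state discretization bins the four features deterministically", {
  s <- flat_sample(0.5)
  grid <- segment_patches(s, 2)
  f <- distortion_filter("gaussian_noise", noise_sd = 0.1, seed = 6)
  st <- perturbation_state(s, grid, f)
  cfg <- qlearning_config(bins = c(4L, 4L, 4L, 4L), max_steps = 50L)
  zero_map <- structure(list(p_add = numeric(16),
                             p_remove = rep(NA_real_, 16), p_gt = 0.9),
                        class = "sensitivity_map")
  k1 <- discretize_state(st, zero_map, cfg)
  expect_match(k1, "^3_0_0_0$")          # fresh episode: D and t bins are 0
  expect_identical(discretize_state(st, zero_map, cfg), k1)

  # sweeping P_GT over [0,1] yields exactly 4 bins split at 0.25/0.5/0.75
  keys <- vapply(seq(0, 1, by = 0.01), function(p) {
    m <- zero_map; m$p_gt <- p
    strsplit(discretize_state(st, m, cfg), "_")[[1]][1]
  }, character(1))
  expect_equal(unique(keys), c("0", "1", "2", "3"))
  expect_equal(keys[c(25, 26, 51, 76)], c("0", "1", "2", "3"))
})

test_that("episodes respect termination, legality and query budgets", {
  # toy threshold model: one decisive central patch
  bb <- as_blackbox(central_patch_classifier(8, 8, thr = 0.5))
  s <- image_sample(array(0.6, dim = c(8, 8, 1)), label = 1L)
  f <- distortion_filter("brightness", brightness = -0.2, seed = 7)
  Q <- qtable_new(1)

  # T = 0 on a correctly classified input: no steps, no success
  cfg0 <- qlearning_config(max_steps = 0L, p_max = 1L)
  ep0 <- run_episode(bb, s, Q, f, cfg0, epsilon = 0)
  expect_false(ep0$success)
  expect_equal(ep0$steps, 0L)
  expect_equal(state_distance(ep0$state), 0)

  # the brightness filter drops the central 2x2 mean from 0.6 to 0.4:
  # hand simulation says the flip happens after exactly one step on the
  # central patch
  cfg1 <- qlearning_config(max_steps = 10L, p_max = 1L, seed = 17)
  set.seed(17)
  ep1 <- run_episode(bb, s, Q, f, cfg1, epsilon = 0)
  expect_true(ep1$success)
  expect_equal(ep1$steps, 1L)
  central <- which(vapply(seq_len(16) - 1L, function(k) {
    px <- patch_pixels(segment_patches(s, 2), k)
    all(px$rows %in% 5:6) && all(px$cols %in% 5:6)
  }, logical(1))) - 1L
  expect_equal(distorted_patches(ep1$state), central)

  # an already-misclassified input returns success with no trajectory
  s_wrong <- image_sample(array(0.4, dim = c(8, 8, 1)), label = 1L)
  ep2 <- run_episode(bb, s_wrong, Q, f, cfg1, epsilon = 0)
  expect_true(ep2$success)
  expect_equal(ep2$steps, 0L)
})

test_that("episode trajectories keep the RL invariants on the study model", {
  run <- study_attack()
  actions <- enumerate_actions(run$qcfg$p_max)
  for (ep in run$episodes[1:10]) {
    if (ep$steps == 0) next
    tr <- ep$trajectory
    # action legality
    expect_true(all(tr$remove < tr$add))
    expect_true(all(tr$add <= run$qcfg$p_max))
    # net outstanding distortions grow by (add - remove) >= 1 per step
    expect_true(all(tr$n_added - tr$n_removed >= 1))
    expect_equal(distortion_total(ep$state), sum(tr$n_added - tr$n_removed))
    # PD sign at termination characterizes success
    expect_equal(ep$success, tr$pd[nrow(tr)] > 0)
    # success replays: the returned adversarial image is misclassified
    if (ep$success) {
      probs <- query_probs(run$bb, ep$adversarial)[1, ]
      expect_true(which.max(probs) - 1L != ep$state$label)
    }
    # query budget
    np <- segment_patches(c(16L, 16L), 2)$n_patches
    expect_lte(ep$queries,
               ep$steps * (np + run$qcfg$p_max * ep$steps + 1) + 2)
  }
})
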