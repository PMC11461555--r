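test_that("belief updates follow Bayes rule and reject impossible observations", {
  # 3-state toy: posterior computed by direct arithmetic
  P <- matrix(c(0.7, 0.2, 0.1,
                0.0, 0.6, 0.4,
                0.0, 0.0, 1.0), 3, 3, byrow = TRUE)
  O <- list(screen = diag(3),
            wait = matrix(c(1, 0, 1, 0, 0, 1), 3, 2, byrow = TRUE))
  prior <- c(0.5, 0.3, 0.2)
  pb <- as.numeric(prior %*% P)            # c(0.35, 0.28, 0.37)
  expected <- c(pb[1], pb[2], 0) / (pb[1] + pb[2])
  post <- belief_update(prior, "Wait", 1, P, O)
  expect_equal(post, expected, tolerance = 1e-12)
  expect_equal(sum(post), 1, tolerance = 1e-12)

  # perfect screen collapses any prior to a unit vector
  for (k in 1:2) {
    post <- belief_update(prior, "Screen", k, P, O)
    expect_equal(post, as.numeric(1:3 == k))
  }
  # observing "Alive" from a surely-dead prior is impossible
  expect_error(belief_update(c(0, 0, 1), "Wait", 1, P, O),
               "zero-probability")
})

test_that("reachable-belief enumeration is complete, deduplicated and conserves probability", {
  sol <- get_short_solution()
  g <- enumerate_reachable_beliefs(sol$pomdp)
  ep <- g$epochs
  expect_equal(ep[[1]]$m, 1L)
  expect_equal(as.numeric(ep[[1]]$B), sol$pomdp$initial_belief)
  for (t in c(1, 5, 20, g$horizon - 1)) {
    e <- ep[[t]]
    # beliefs on the simplex
    expect_true(all(abs(rowSums(e$B) - 1) < 1e-9))
    expect_true(all(e$B >= -1e-15))
    # per (node, action): observation probabilities sum to one, so child
    # reach plus termination mass is conserved
    expect_true(all(abs(rowSums(e$wait_p) - 1) < 1e-10))
    expect_true(all(abs(rowSums(e$screen_p) - 1) < 1e-10))
    # no duplicate beliefs within an epoch
    keys <- apply(round(e$B, 9), 1, paste, collapse = "|")
    expect_false(anyDuplicated(keys) > 0)
  }
  # perfect-observation structure: gap-0 nodes are unit vectors at their
  # anchor, so (last observed state, epochs since screen) indexes the graph
  nodes2 <- ep[[4]]
  g0 <- which(nodes2$gap == 0L)
  for (i in g0)
    expect_equal(as.numeric(nodes2$B[i, ]),
                 as.numeric(1:10 == nodes2$anchor[i]))
  # a two-epoch process holds only the root and its immediate children
  p2 <- sol$pomdp
  p2$horizon <- 2L
  p2$transitions <- p2$transitions[, , 1, drop = FALSE]
  p2$terminal_rewards <- p2$terminal_rewards[1:2, ]
  g2 <- enumerate_reachable_beliefs(p2)
  expect_equal(length(g2$epochs), 2L)
  expect_lte(g2$epochs[[2]]$m, 4L)  # wait-alive child + observed 1..3
})

test_that("backward induction satisfies the boundary condition and Bellman recursion", {
  sol <- get_short_solution()
  g <- enumerate_reachable_beliefs(sol$pomdp)
  tree <- backward_induction(sol$pomdp, g)
  T <- g$horizon
  # boundary: horizon value is the expected terminal reward (zero here)
  vT <- tree$nodes$value[tree$nodes$epoch == T]
  expect_equal(vT, as.numeric(g$epochs[[T]]$B %*%
                                sol$pomdp$terminal_rewards[T, ]))
  # root value is reproduced by one manual Bellman step over the stored graph
  e1 <- g$epochs[[1]]
  v2 <- tree$nodes$value[tree$nodes$epoch == 2]
  child_val <- function(p, ch, tv) {
    cv <- tv
    cv[!is.na(ch)] <- v2[ch[!is.na(ch)]]
    rowSums(p * cv)
  }
  qW <- as.numeric(e1$B %*% sol$pomdp$stage_rewards[, "Wait"]) +
    sol$pomdp$gamma * child_val(e1$wait_p, e1$wait_child, e1$wait_term_val)
  qS <- as.numeric(e1$B %*% sol$pomdp$stage_rewards[, "Screen"]) +
    sol$pomdp$gamma * child_val(e1$screen_p, e1$screen_child,
                                e1$screen_term_val)
  expect_equal(tree$value_root, max(qW, qS), tolerance = 1e-9)
  # reach probabilities: root 1, conserved or lost to termination after
  reach2 <- tree$nodes$reach[tree$nodes$epoch == 2]
  expect_lte(sum(reach2), 1 + 1e-12)
  expect_equal(tree$nodes$reach[1], 1)
})

test_that("solver equals independent oracles on random small processes", {
  for (i in 1:20) {
    Tn <- c(2L, 3L, 3L, 4L)[(i %% 4) + 1]
    pom <- make_toy_pomdp(S = 2 + (i %% 3), T = Tn, Kw = 2, Ks = 2 + (i %% 2),
                          seed = 1000 + i)
    v <- solve_pomdp(pom)$value_root
    v_hist <- oracle_history_recursion(pom)
    expect_equal(v, v_hist, tolerance = 1e-9)
    if (Tn <= 3) {
      v_enum <- oracle_policy_enumeration(pom)
      expect_equal(v, v_enum, tolerance = 1e-9)
      expect_equal(v_hist, v_enum, tolerance = 1e-9)
    }
  }
})

test_that("raising rewards never lowers the optimal value", {
  for (i in 1:10) {
    pom <- make_toy_pomdp(S = 3, T = 3, seed = 2000 + i)
    v0 <- solve_pomdp(pom)$value_root
    up <- pom
    up$terminal_rewards[up$horizon, 2] <- up$terminal_rewards[up$horizon, 2] + 0.5
    expect_gte(solve_pomdp(up)$value_root, v0 - 1e-12)
    up2 <- pom
    up2$stage_rewards[1, "Wait"] <- up2$stage_rewards[1, "Wait"] + 0.3
    expect_gte(solve_pomdp(up2)$value_root, v0 - 1e-12)
    # a uniform terminal bump of c raises the value by at most gamma^(T-1) c
    up3 <- pom
    up3$terminal_rewards[up3$horizon, ] <- up3$terminal_rewards[up3$horizon, ] + 1
    dv <- solve_pomdp(up3)$value_root - v0
    expect_lte(dv, pom$gamma^(pom$horizon - 1) + 1e-9)
    expect_gte(dv, -1e-12)
  }
})

test_that("optimal actions resolve by observable history with explicit stopping", {
  sol <- get_short_solution()
  tree <- sol$tree
  # a screen that just revealed CKD stage 3+ ends the process
  expect_identical(optimal_action(tree, 10, anchor = 5, gap = 0), "Stop")
  expect_identical(optimal_action(tree, tree$horizon, anchor = 1, gap = 2),
                   "Stop")
  # reachable histories give a decision
  expect_true(optimal_action(tree, 1, anchor = 0, gap = 0) %in%
                c("Screen", "Wait"))
  expect_true(optimal_action(tree, 5, anchor = 0, gap = 4) %in%
                c("Screen", "Wait"))
  expect_error(optimal_action(tree, 2, anchor = 1, gap = 37), "reachable")
  # ties break toward Wait: when both actions carry identical rewards and
  # identical observation structure, their values tie exactly at every node
  pom <- make_toy_pomdp(S = 3, T = 4, Kw = 2, Ks = 2, seed = 77)
  pom$observations$screen <- pom$observations$wait
  pom$stage_rewards[, "Screen"] <- pom$stage_rewards[, "Wait"]
  tied <- backward_induction(pom)
  acts <- tied$nodes$action[tied$nodes$epoch < tied$horizon]
  expect_true(all(acts == "Wait"))
})
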