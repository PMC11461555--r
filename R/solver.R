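`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bayesian belief update
#'
#' Posterior over health states after taking an action and receiving an
#' observation: \eqn{\pi'(j) \propto \sum_i \pi(i) p_{ij} q^a_{jk}},
#' normalized over \eqn{j}. With a perfect screen (identity observation
#' matrix) the posterior collapses to a unit vector at the observed state.
#'
#' @param belief Probability vector over states.
#' @param action "Screen" or "Wait".
#' @param observation Observation index: a reported state for "Screen", or
#'   1 = Alive, 2 = Dead for "Wait".
#' @param P One-step transition matrix (states x states).
#' @param O A \code{ckd_obsmodel} (or list with \code{screen}/\code{wait}
#'   matrices).
#' @return The posterior belief vector (sums to 1). An observation with zero
#'   predicted probability under (belief, action) is an error, never a
#'   silent renormalization.
#' @export
belief_update <- function(belief, action = c("Screen", "Wait"), observation,
                          P, O) {
  action <- match.arg(action)
  Q <- if (action == "Screen") O$screen else O$wait
  if (observation < 1 || observation > ncol(Q))
    stop("observation index out of range")
  pb <- as.numeric(belief %*% P)
  num <- pb * Q[, observation]
  denom <- sum(num)
  if (denom <= 0)
    stop("zero-probability observation: posterior undefined")
  num / denom
}

belief_key <- function(b) paste(round(b, 9), collapse = "|")

#' Enumerate the reachable belief graph
#'
#' Starting from the single initial belief, expands every action
#' (Screen/Wait) and every positive-probability observation breadth-first
#' over the horizon. Beliefs at the same epoch matching an existing node
#' within \code{dedup_tol} (max-norm) are merged. Under the screening
#' semantics, a screen observation of CKD stage 3 or above starts treatment
#' and terminates that branch with the lump-sum terminal reward, and a Dead
#' observation terminates with value 0; such branches are folded into the
#' parent's expectation rather than stored as nodes. Because the perfect
#' screen collapses beliefs to unit vectors, every node is characterized by
#' (last observed state, epochs since that observation), recorded as the
#' node's \code{anchor} and \code{gap}.
#'
#' @param pomdp A \code{ckd_pomdp} (set \code{pomdp$ckd_semantics = FALSE}
#'   for a generic two-action POMDP with no terminating observations).
#' @param dedup_tol Merge tolerance on beliefs, default 1e-9; with perfect
#'   observation it only guards floating-point noise.
#' @return A \code{ckd_belief_graph}: per-epoch node tables (belief matrix,
#'   anchor, gap) plus, for each node and action, the observation
#'   probabilities, child-node indices and terminal values needed by
#'   \code{\link{backward_induction}}.
#' @export
enumerate_reachable_beliefs <- function(pomdp, dedup_tol = 1e-9) {
  stopifnot(inherits(pomdp, "ckd_pomdp"))
  T <- as.integer(pomdp$horizon)
  S <- length(pomdp$initial_belief)
  P <- pomdp$transitions
  Qs <- pomdp$observations$screen
  Qw <- pomdp$observations$wait
  Ks <- ncol(Qs)
  Kw <- ncol(Qw)
  R <- pomdp$terminal_rewards
  ckd <- !isFALSE(pomdp$ckd_semantics)
  # observations that terminate the process (value folded into the parent)
  screen_term <- if (ckd) c(TREAT_STATES, DEAD_STATE) else integer(0)
  wait_term <- if (ckd) 2L else integer(0)   # the Dead column

  digits <- max(0L, ceiling(-log10(dedup_tol)))
  key_of <- function(M) apply(round(M, digits), 1, paste, collapse = "|")

  ep <- vector("list", T)
  ep[[1]] <- list(B = matrix(pomdp$initial_belief, 1, S),
                  anchor = 0L, gap = 0L, m = 1L)

  for (t in seq_len(T - 1L)) {
    node <- ep[[t]]
    m <- node$m
    if (m == 0L) {
      ep[[t + 1L]] <- list(B = matrix(numeric(0), 0, S),
                           anchor = integer(0), gap = integer(0), m = 0L)
      next
    }
    PB <- node$B %*% P[, , t]

    # observation probabilities, non-terminal posteriors, and terminal
    # values (expected terminal reward under the posterior) per action
    expand <- function(Q, K, term_obs) {
      p <- matrix(0, m, K)
      tv <- matrix(0, m, K)
      cand <- vector("list", K)
      for (k in seq_len(K)) {
        num <- PB * matrix(Q[, k], m, S, byrow = TRUE)
        pk <- rowSums(num)
        p[, k] <- pk
        pos <- which(pk > 0)
        if (!length(pos)) next
        post <- num[pos, , drop = FALSE] / pk[pos]
        if (k %in% term_obs) {
          tv[pos, k] <- as.numeric(post %*% R[t + 1L, ])
        } else {
          cand[[k]] <- list(obs = k, parent = pos, post = post)
        }
      }
      list(p = p, tv = tv, cand = cand)
    }

    wait <- expand(Qw, Kw, wait_term)
    screen <- expand(Qs, Ks, screen_term)

    # pool candidate children of epoch t+1 and deduplicate by belief key
    post_all <- NULL
    meta <- NULL
    for (src in list(list(act = 1L, x = wait), list(act = 2L, x = screen))) {
      for (cd in src$x$cand) {
        if (is.null(cd)) next
        post_all <- rbind(post_all, cd$post)
        meta <- rbind(meta, cbind(act = src$act, obs = cd$obs,
                                  parent = cd$parent))
      }
    }

    wait_child <- matrix(NA_integer_, m, Kw)
    screen_child <- matrix(NA_integer_, m, Ks)
    if (is.null(post_all)) {
      B_next <- matrix(numeric(0), 0, S)
      anchor_next <- gap_next <- integer(0)
    } else {
      keys <- key_of(post_all)
      first <- !duplicated(keys)
      idx <- match(keys, keys[first])
      B_next <- post_all[first, , drop = FALSE]

      # history labels (anchor = last observed state, gap = epochs since)
      fi <- which(first)
      anchor_next <- integer(length(fi))
      gap_next <- integer(length(fi))
      for (j in seq_along(fi)) {
        r <- fi[j]
        if (meta[r, "act"] == 1L) {           # Wait
          pa <- meta[r, "parent"]
          anchor_next[j] <- node$anchor[pa]
          gap_next[j] <- node$gap[pa] + 1L
        } else {                              # Screen, non-terminal result
          anchor_next[j] <- as.integer(meta[r, "obs"])
          gap_next[j] <- 0L
        }
      }

      for (r in seq_along(idx)) {
        if (meta[r, "act"] == 1L)
          wait_child[meta[r, "parent"], meta[r, "obs"]] <- idx[r]
        else
          screen_child[meta[r, "parent"], meta[r, "obs"]] <- idx[r]
      }
    }

    ep[[t]]$wait_p <- wait$p
    ep[[t]]$screen_p <- screen$p
    ep[[t]]$wait_child <- wait_child
    ep[[t]]$screen_child <- screen_child
    ep[[t]]$wait_term_val <- wait$tv
    ep[[t]]$screen_term_val <- screen$tv
    ep[[t]]$wait_term_obs <- wait_term
    ep[[t]]$screen_term_obs <- screen_term

    ep[[t + 1L]] <- list(B = B_next, anchor = anchor_next, gap = gap_next,
                         m = nrow(B_next))
  }

  structure(list(epochs = ep, horizon = T, n_states = S,
                 dedup_tol = dedup_tol, ckd_semantics = ckd),
            class = "ckd_belief_graph")
}

#' @export
print.ckd_belief_graph <- function(x, ...) {
  cat("<reachable belief graph> horizon", x$horizon, "| nodes:",
      sum(vapply(x$epochs, function(e) e$m, integer(1))), "\n")
  invisible(x)
}

#' Solve the screening POMDP by backward induction
#'
#' Computes the optimal value and action for every node of the reachable
#' belief graph by the finite-horizon Bellman recursion: at the horizon the
#' value of a belief is its expected terminal reward; earlier, the value of
#' (belief, action) is the expected stage reward plus the discounted
#' expectation of the next epoch's optimal values over observations, with
#' screen results of CKD stage 3+ contributing their lump-sum treatment
#' value and Dead contributing zero. Ties within \code{tie_tol} are broken
#' in favour of Wait (minimizing intervention burden at equal value).
#'
#' @param pomdp A \code{ckd_pomdp}.
#' @param graph The matching \code{\link{enumerate_reachable_beliefs}}
#'   output (recomputed if omitted).
#' @param tie_tol Value tolerance for the Wait tie-break, default 1e-9.
#' @return A \code{ckd_policy_tree}: per-node tables of epoch, anchor, gap,
#'   optimal action, value and reach probability under the optimal policy,
#'   plus \code{value_root}, the optimal expected discounted NMB at the
#'   initial belief.
#' @export
backward_induction <- function(pomdp, graph = NULL, tie_tol = 1e-9) {
  stopifnot(inherits(pomdp, "ckd_pomdp"))
  if (is.null(graph)) graph <- enumerate_reachable_beliefs(pomdp)
  stopifnot(inherits(graph, "ckd_belief_graph"))
  T <- graph$horizon
  ep <- graph$epochs
  gamma <- pomdp$gamma
  R <- pomdp$terminal_rewards
  stage <- pomdp$stage_rewards

  vals <- vector("list", T)
  acts <- vector("list", T)
  vals[[T]] <- as.numeric(ep[[T]]$B %*% R[T, ])
  acts[[T]] <- rep("Stop", ep[[T]]$m)

  child_values <- function(p, child, term_val, v_next) {
    cv <- term_val
    has <- !is.na(child)
    cv[has] <- v_next[child[has]]
    rowSums(p * cv)
  }

  for (t in seq.int(T - 1L, 1L)) {
    node <- ep[[t]]
    v_next <- vals[[t + 1L]]
    rW <- as.numeric(node$B %*% stage[, "Wait"])
    rS <- as.numeric(node$B %*% stage[, "Screen"])
    qW <- rW + gamma * child_values(node$wait_p, node$wait_child,
                                    node$wait_term_val, v_next)
    qS <- rS + gamma * child_values(node$screen_p, node$screen_child,
                                    node$screen_term_val, v_next)
    screen_wins <- (qS - qW) > tie_tol
    acts[[t]] <- ifelse(screen_wins, "Screen", "Wait")
    vals[[t]] <- ifelse(screen_wins, qS, qW)
  }

  # forward pass: reach probabilities under the optimal policy
  reach <- lapply(ep, function(e) numeric(e$m))
  if (ep[[1]]$m > 0) reach[[1]][1] <- 1
  for (t in seq_len(T - 1L)) {
    node <- ep[[t]]
    if (node$m == 0L) next
    r <- reach[[t]]
    for (branch in list(list(a = "Wait", p = node$wait_p,
                             ch = node$wait_child),
                        list(a = "Screen", p = node$screen_p,
                             ch = node$screen_child))) {
      sel <- which(acts[[t]] == branch$a & r > 0)
      if (!length(sel)) next
      for (k in seq_len(ncol(branch$p))) {
        ch <- branch$ch[sel, k]
        pk <- branch$p[sel, k]
        ok <- !is.na(ch) & pk > 0
        if (!any(ok)) next
        add <- tapply(r[sel][ok] * pk[ok], ch[ok], sum)
        ci <- as.integer(names(add))
        reach[[t + 1L]][ci] <- reach[[t + 1L]][ci] + as.numeric(add)
      }
    }
  }

  nodes <- do.call(rbind, lapply(seq_len(T), function(t) {
    e <- ep[[t]]
    data.frame(epoch = t, node = seq_len(e$m),
               anchor = e$anchor, gap = e$gap,
               action = acts[[t]], value = vals[[t]], reach = reach[[t]],
               stringsAsFactors = FALSE)
  }))

  lookup <- new.env(parent = emptyenv(), hash = TRUE)
  keys <- sprintf("%d|%d|%d", nodes$epoch, nodes$anchor, nodes$gap)
  for (i in seq_len(nrow(nodes)))
    if (is.null(lookup[[keys[i]]])) lookup[[keys[i]]] <- nodes$action[i]

  structure(list(nodes = nodes, lookup = lookup,
                 value_root = vals[[1]][1], horizon = T,
                 start_age = pomdp$start_age %||% NA_real_,
                 tie_tol = tie_tol),
            class = "ckd_policy_tree")
}

#' @rdname backward_induction
#' @export
solve_pomdp <- function(pomdp, dedup_tol = 1e-9, tie_tol = 1e-9) {
  graph <- enumerate_reachable_beliefs(pomdp, dedup_tol)
  backward_induction(pomdp, graph, tie_tol)
}

#' @export
print.ckd_policy_tree <- function(x, ...) {
  cat("<policy tree> horizon", x$horizon, "|", nrow(x$nodes), "nodes",
      sprintf("| value at initial belief $%s\n",
              format(round(x$value_root), big.mark = ",")))
  invisible(x)
}

#' @export
as.data.frame.ckd_policy_tree <- function(x, ...) x$nodes

# vectorized action lookup by (epoch, last observed state, epochs since
# observation); NA where the history is not in the graph
tree_action_lookup <- function(tree, t, anchor, gap) {
  n <- max(length(anchor), length(gap))
  keys <- sprintf("%d|%d|%d", rep_len(t, n), rep_len(anchor, n),
                  rep_len(gap, n))
  vapply(keys, function(k) {
    v <- tree$lookup[[k]]
    if (is.null(v)) NA_character_ else v
  }, character(1), USE.NAMES = FALSE)
}

#' Optimal action for an observable history
#'
#' Looks up the solved policy's action at epoch \code{t} for a patient whose
#' last exactly-observed state is \code{anchor} (0 before any screen) seen
#' \code{gap} epochs ago. Histories where a screen has just revealed CKD
#' stage 3+ (anchor 4..9) and the final epoch return \code{"Stop"}: the
#' decision process has ended.
#'
#' @param tree A \code{ckd_policy_tree}.
#' @param t Epoch.
#' @param anchor Last observed state (0, or 1..9).
#' @param gap Epochs since that observation.
#' @return "Screen", "Wait" or "Stop".
#' @export
optimal_action <- function(tree, t, anchor, gap = 0L) {
  stopifnot(inherits(tree, "ckd_policy_tree"))
  if (anchor %in% TREAT_STATES) return("Stop")
  if (t >= tree$horizon) return("Stop")
  act <- tree_action_lookup(tree, t, anchor, gap)
  if (is.na(act)) stop("history (", t, ", ", anchor, ", ", gap,
                       ") is not reachable in the policy tree")
  act
}

#' Recommended screening cadence for an example individual
#'
#' Follows the solved policy from the initial belief assuming every screen
#' returns "Normal" (the example individual stays healthy), and records the
#' gap, in epochs, preceding each recommended screen. This is the Wait-run
#' profile used to summarize the policy as "screens at least every X years
#' from age Y".
#'
#' @param tree A \code{ckd_policy_tree}.
#' @param start_age First decision age, default 30.
#' @return Data frame with \code{epoch}, \code{age} and \code{gap_epochs}
#'   (epochs since the previous screen, or since the process start for the
#'   first screen).
#' @export
policy_gap_profile <- function(tree, start_age = 30) {
  stopifnot(inherits(tree, "ckd_policy_tree"))
  t <- 1L
  anchor <- 0L
  gap <- 0L
  last_screen <- 0L
  out <- list()
  while (t < tree$horizon) {
    act <- tree_action_lookup(tree, t, anchor, gap)
    if (is.na(act)) break
    if (act == "Screen") {
      out[[length(out) + 1L]] <- data.frame(
        epoch = t, age = start_age + 0.25 * (t - 1),
        gap_epochs = t - last_screen)
      last_screen <- t
      anchor <- 1L
      gap <- 0L
    } else {
      gap <- gap + 1L
    }
    t <- t + 1L
  }
  if (!length(out))
    return(data.frame(epoch = integer(0), age = numeric(0),
                      gap_epochs = integer(0)))
  do.call(rbind, out)
}
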