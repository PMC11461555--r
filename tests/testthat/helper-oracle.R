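# independent oracles for the finite-horizon solver, used to validate
# backward induction on small random decision processes

rand_simplex <- function(k) {
  x <- stats::runif(k) + 0.05
  x / sum(x)
}

rand_stochastic <- function(nr, nc) {
  m <- matrix(stats::runif(nr * nc) + 0.05, nr, nc)
  m / rowSums(m)
}

# a generic two-action partially observable process with no terminating
# observations (every branch runs to the horizon)
make_toy_pomdp <- function(S = 3, T = 3, Kw = 2, Ks = 3, seed = 1) {
  set.seed(seed)
  P <- array(0, c(S, S, T - 1))
  for (t in seq_len(T - 1)) P[, , t] <- rand_stochastic(S, S)
  stage <- cbind(Wait = stats::runif(S, -1, 1),
                 Screen = stats::runif(S, -1, 1))
  Rterm <- matrix(0, T, S)
  Rterm[T, ] <- stats::runif(S, -1, 1)
  structure(list(
    horizon = as.integer(T), start_age = NA_real_, transitions = P,
    observations = list(screen = rand_stochastic(S, Ks),
                        wait = rand_stochastic(S, Kw)),
    stage_rewards = stage, terminal_rewards = Rterm,
    gamma = stats::runif(1, 0.8, 1), initial_belief = rand_simplex(S),
    ckd_semantics = FALSE
  ), class = "ckd_pomdp")
}

# oracle for T = 2 or 3: literal enumeration of every history-dependent
# policy, each evaluated by explicit summation over state/observation paths
oracle_policy_enumeration <- function(pom) {
  T <- pom$horizon
  stopifnot(T %in% c(2L, 3L))
  S <- length(pom$initial_belief)
  b <- pom$initial_belief
  g <- pom$gamma
  r <- pom$stage_rewards
  RT <- pom$terminal_rewards[T, ]
  Q <- list(pom$observations$wait, pom$observations$screen)  # 1=Wait,2=Screen
  rcol <- c("Wait", "Screen")
  P1 <- pom$transitions[, , 1]

  if (T == 2L) {
    vals <- vapply(1:2, function(a1) {
      sum(b * r[, rcol[a1]]) + g * sum((b %*% P1) * RT)
    }, numeric(1))
    return(max(vals))
  }

  P2 <- pom$transitions[, , 2]
  best <- -Inf
  for (a1 in 1:2) {
    K <- ncol(Q[[a1]])
    # joint weight of (s2, o1): P(s2, o1) under a1
    w <- matrix(0, S, K)
    for (s2 in 1:S)
      w[s2, ] <- sum(b * P1[, s2]) * Q[[a1]][s2, ]
    # terminal expectation given s2: E[R(s3) | s2]
    tailR <- as.numeric(P2 %*% RT)
    stage1 <- sum(b * r[, rcol[a1]])
    # enumerate every assignment of a2 to each observation o1
    for (code in 0:(2^K - 1)) {
      a2 <- as.integer(intToBits(code))[1:K] + 1L  # 1=Wait, 2=Screen
      v <- stage1
      for (o1 in 1:K) {
        v <- v + g * sum(w[, o1] * r[, rcol[a2[o1]]]) +
          g^2 * sum(w[, o1] * tailR)
      }
      if (v > best) best <- v
    }
  }
  best
}

# oracle for any small T: history recursion over unnormalized state weights
# computed by direct path summation (no beliefs, no normalization, no graph)
oracle_history_recursion <- function(pom) {
  T <- pom$horizon
  S <- length(pom$initial_belief)
  g <- pom$gamma
  r <- pom$stage_rewards
  Q <- list(pom$observations$wait, pom$observations$screen)
  rcol <- c("Wait", "Screen")
  rec <- function(t, w) {
    if (t == T) return(sum(w * pom$terminal_rewards[T, ]))
    P <- pom$transitions[, , t]
    vals <- vapply(1:2, function(a) {
      v <- sum(w * r[, rcol[a]])
      wp <- as.numeric(w %*% P)
      for (k in seq_len(ncol(Q[[a]]))) {
        wk <- wp * Q[[a]][, k]
        if (sum(wk) > 0) v <- v + g * rec(t + 1L, wk)
      }
      v
    }, numeric(1))
    max(vals)
  }
  rec(1L, pom$initial_belief)
}
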