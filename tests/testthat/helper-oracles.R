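# Independent reference implementations used as test oracles. These are
# deliberately naive (explicit loops, repeated recomputation) and share no
# code with the package internals they check.

# Literal window-enumeration peak caller on a filtered profile. Walks every
# window position explicitly, recomputes max/min/neighbourhood maxima from
# scratch each time, and applies the documented rules: adaptive threshold
# acceptance, summit candidates only, steric exclusion, boundary clipping,
# plateau-middle tie-break, resume right of the called core.
oracle_scan <- function(pos, v, w, thr, window_bp) {
  n <- length(v)
  h <- (w - 1) %/% 2
  is_summit <- function(j) {
    if (is.na(v[j])) return(FALSE)
    nb <- max(1, j - h):min(n, j + h)
    all(v[j] >= v[nb], na.rm = TRUE)
  }
  covered_lo <- max(0, pos[1] - window_bp / 2)
  covered_hi <- pos[n] + window_bp / 2
  centers <- numeric(0)
  scores <- numeric(0)
  prev_end <- covered_lo
  i <- 1
  while (i <= n - w + 1) {
    win <- v[i:(i + w - 1)]
    moved <- FALSE
    if (!all(is.na(win))) {
      p_i <- max(win, na.rm = TRUE) - min(win, na.rm = TRUE)
      if (p_i >= thr && p_i > 0) {
        wmax <- max(win, na.rm = TRUE)
        cand <- c()
        for (j in i:(i + w - 1)) {
          if (!is.na(v[j]) && v[j] == wmax && is_summit(j) &&
              pos[j] - 73 >= prev_end && pos[j] + 74 <= covered_hi) {
            cand <- c(cand, j)
          }
        }
        if (length(cand) > 0) {
          run <- cand[1]
          for (t in cand[-1]) {
            if (t == run[length(run)] + 1) run <- c(run, t) else break
          }
          pc <- pos[run[floor((length(run) + 1) / 2)]]
          centers <- c(centers, pc)
          scores <- c(scores, p_i)
          prev_end <- pc + 74
          i2 <- which(pos >= prev_end)
          i <- if (length(i2) == 0) n + 1 else i2[1]
          moved <- TRUE
        }
      }
    }
    if (!moved) i <- i + 1
  }
  data.frame(center = centers, score = scores)
}

# Valley-based caller: the argmin mirror of the peak rules, applied to the
# ORIGINAL (un-negated) profile of a negative-class feature.
oracle_valley_scan <- function(pos, v, w, thr, window_bp) {
  res <- oracle_scan(pos, -v, w, thr, window_bp)
  res
}

# Brute-force Viterbi: enumerate every legal state path and maximize the
# joint log probability directly.
oracle_viterbi <- function(model, x) {
  states <- c("L0", paste0("N", 1:15))
  succ <- list(L0 = c("L0", "N1"), N15 = if (isTRUE(model$allow_wrap)) {
    c("L0", "N1")
  } else "L0")
  for (k in 1:14) succ[[paste0("N", k)]] <- paste0("N", k + 1)
  n <- nrow(x)
  emis <- function(s, t) {
    tot <- 0
    for (j in seq_len(ncol(x))) {
      if (!is.na(x[t, j])) {
        tot <- tot + dnorm(x[t, j], model$mean[s, j],
                           sqrt(model$var[s, j]), log = TRUE)
      }
    }
    tot
  }
  best <- list(lp = -Inf, path = NULL)
  recurse <- function(path, lp) {
    t <- length(path)
    if (t == n) {
      if (lp > best$lp) best <<- list(lp = lp, path = path)
      return(invisible())
    }
    s <- path[t]
    for (nxt in succ[[s]]) {
      recurse(c(path, nxt),
              lp + log(model$transition[s, nxt]) + emis(nxt, t + 1))
    }
  }
  for (s0 in states) {
    recurse(s0, log(model$init[[s0]]) + emis(s0, 1))
  }
  best
}

# Brute-force greedy one-to-one matcher: repeatedly pick the globally
# closest unmatched (prediction, reference) pair within the cutoff.
oracle_match_count <- function(pred, ref, cutoff) {
  tp <- 0
  pred_used <- rep(FALSE, length(pred))
  ref_used <- rep(FALSE, length(ref))
  repeat {
    bestd <- Inf; bi <- 0; bj <- 0
    for (i in seq_along(pred)) {
      if (pred_used[i]) next
      for (j in seq_along(ref)) {
        if (ref_used[j]) next
        d <- abs(pred[i] - ref[j])
        if (d < bestd) { bestd <- d; bi <- i; bj <- j }
      }
    }
    if (!is.finite(bestd) || bestd > cutoff) break
    pred_used[bi] <- TRUE; ref_used[bj] <- TRUE
    tp <- tp + 1
  }
  tp
}

# Brute-force count of full smoothing windows in a raw vector of length m.
oracle_n_windows <- function(m, window, step) {
  count <- 0
  start <- 0
  while (start + window <= m) {
    count <- count + 1
    start <- start + step
  }
  count
}

# Random legal HMM for Viterbi tests: random allowed-transition rows,
# random Gaussian emissions over n_feat channels.
random_hmm <- function(n_feat = 2, allow_wrap = TRUE) {
  states <- c("L0", paste0("N", 1:15))
  trans <- matrix(0, 16, 16, dimnames = list(states, states))
  rnd <- function(k) { p <- runif(k) + 0.05; p / sum(p) }
  trans["L0", c("L0", "N1")] <- rnd(2)
  for (k in 1:14) trans[paste0("N", k), paste0("N", k + 1)] <- 1
  if (allow_wrap) {
    trans["N15", c("L0", "N1")] <- rnd(2)
  } else {
    trans["N15", "L0"] <- 1
  }
  init <- rnd(16)
  mu <- matrix(rnorm(16 * n_feat, 0, 2), 16, n_feat,
               dimnames = list(states, NULL))
  v <- matrix(runif(16 * n_feat, 0.2, 2), 16, n_feat,
              dimnames = list(states, NULL))
  colnames(mu) <- colnames(v) <- paste0("f", seq_len(n_feat))
  structure(list(transition = trans, init = setNames(init, states),
                 mean = mu, var = v, features = colnames(mu),
                 allow_wrap = allow_wrap, trained_on = "synthetic",
                 n_bins = 0L),
            class = "nuc_hmm")
}
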