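# Independent reference implementations used as oracles. These deliberately
# use naive enumeration / plain loops, not the package's code paths.

# O(n^2) pairwise AUC with ties counted one half
auc_bruteforce <- function(scores, labels) {
  labels <- as.logical(labels)
  sp <- scores[labels]; sn <- scores[!labels]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(sp) * length(sn))
}

# exhaustive threshold search under the sensitivity > 50% constraint
threshold_bruteforce <- function(scores, labels) {
  labels <- as.logical(labels)
  u <- sort(unique(scores))
  cand <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else u
  best <- NULL
  for (thr in cand) {
    pos <- scores >= thr
    sens <- sum(pos & labels) / sum(labels)
    spec <- sum(!pos & !labels) / sum(!labels)
    if (sens <= 0.5) next
    if (is.null(best) ||
        sens + spec > best$sens + best$spec + 1e-12 ||
        (abs(sens + spec - (best$sens + best$spec)) <= 1e-12 &&
         (spec > best$spec + 1e-12 ||
          (abs(spec - best$spec) <= 1e-12 && thr < best$thr))))
      best <- list(thr = thr, sens = sens, spec = spec)
  }
  best
}

# two-sided Fisher exact p by hypergeometric enumeration
fisher_enumeration <- function(tab) {
  m <- tab[1, 1] + tab[1, 2]   # row 1 total
  n2 <- tab[2, 1] + tab[2, 2]
  k <- tab[1, 1] + tab[2, 1]   # column 1 total
  support <- max(0, k - n2):min(m, k)
  probs <- dhyper(support, m, n2, k)
  p_obs <- dhyper(tab[1, 1], m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Clopper-Pearson bounds by bisection on the binomial tail sums
cp_bisection <- function(s, n, level = 0.95) {
  a <- (1 - level) / 2
  lo <- if (s == 0) 0 else
    uniroot(function(p) 1 - pbinom(s - 1, n, p) - a, c(1e-12, 1 - 1e-12),
            tol = 1e-12)$root
  hi <- if (s == n) 1 else
    uniroot(function(p) pbinom(s, n, p) - a, c(1e-12, 1 - 1e-12),
            tol = 1e-12)$root
  c(lo, hi)
}

# duration-dependent Viterbi reference: plain-R dynamic programme with the
# same truncated-boundary conventions as the decoder under test
viterbi_reference <- function(L, dur) {
  T_ <- nrow(L)
  tails <- lapply(dur, function(v) rev(cummax(rev(v))))
  cum <- rbind(0, apply(L, 2, cumsum))
  NEG <- -1e18
  delta <- matrix(NEG, T_ + 1, 4)
  for (t in 1:T_) {
    for (s in 1:4) {
      prev <- ((s - 2) %% 4) + 1
      best <- NEG
      for (d in 1:t) {
        em <- cum[t + 1, s] - cum[t - d + 1, s]
        if (d == t) {
          sc <- em + tails[[s]][min(d, length(tails[[s]]))]
        } else {
          if (d > length(dur[[s]])) next
          if (delta[t - d + 1, prev] <= NEG / 2) next
          sc <- delta[t - d + 1, prev] + dur[[s]][d] + em
        }
        if (sc > best) best <- sc
      }
      delta[t + 1, s] <- best
    }
  }
  best <- NEG
  for (s in 1:4) {
    prev <- ((s - 2) %% 4) + 1
    for (d in 1:T_) {
      em <- cum[T_ + 1, s] - cum[T_ - d + 1, s]
      pr <- tails[[s]][min(d, length(tails[[s]]))]
      sc <- if (d == T_) em + pr else {
        if (delta[T_ - d + 1, prev] <= NEG / 2) next
        delta[T_ - d + 1, prev] + pr + em
      }
      if (sc > best) best <- sc
    }
  }
  best
}

# plain-R forward pass of the murmur network (independent of the C++ path)
lstm_forward_reference <- function(params, X, y) {
  U <- nrow(params$W1h) / 4
  sig <- function(z) 1 / (1 + exp(-z))
  N <- dim(X)[3]; T_ <- dim(X)[2]
  yhat <- numeric(N)
  for (s in seq_len(N)) {
    h1 <- numeric(U); c1 <- numeric(U); h2 <- numeric(U); c2 <- numeric(U)
    for (t in seq_len(T_)) {
      a <- params$W1x %*% X[, t, s] + params$W1h %*% h1 + params$b1
      i <- sig(a[1:U]); f <- sig(a[(U + 1):(2 * U)])
      g <- tanh(a[(2 * U + 1):(3 * U)]); o <- sig(a[(3 * U + 1):(4 * U)])
      c1 <- f * c1 + i * g; h1 <- o * tanh(c1)
      a2 <- params$W2x %*% h1 + params$W2h %*% h2 + params$b2
      i <- sig(a2[1:U]); f <- sig(a2[(U + 1):(2 * U)])
      g <- tanh(a2[(2 * U + 1):(3 * U)]); o <- sig(a2[(3 * U + 1):(4 * U)])
      c2 <- f * c2 + i * g; h2 <- o * tanh(c2)
    }
    fc <- pmax(0, params$Wf %*% h2 + params$bf)
    yhat[s] <- params$Wo %*% fc + params$bo
  }
  list(yhat = yhat, loss = mean((yhat - y)^2))
}

# reference iterative spike removal (independent plain-loop implementation)
spike_removal_reference <- function(x, fs, window_s = 0.5) {
  wlen <- max(1, round(window_s * fs))
  starts <- seq(1, length(x), by = wlen)
  ends <- pmin(starts + wlen - 1, length(x))
  nw <- length(starts)
  for (iter in 1:(nw * 10)) {
    maa <- sapply(seq_len(nw), function(w) max(abs(x[starts[w]:ends[w]])))
    if (max(maa) <= 3 * median(maa)) break
    w <- which.max(maa)
    a <- starts[w]; b <- ends[w]
    k <- a + which.max(abs(x[a:b])) - 1
    lo <- k
    while (lo > a && !(x[lo - 1] == 0 || sign(x[lo - 1]) != sign(x[lo]))) lo <- lo - 1
    hi <- k
    while (hi < b && !(x[hi + 1] == 0 || sign(x[hi + 1]) != sign(x[hi]))) hi <- hi + 1
    x[lo:hi] <- 0
  }
  x
}
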