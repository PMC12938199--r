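# Independent brute-force oracles: every formula is evaluated term by
# term with scalar loops, sharing no code with the package implementation.

oracle_minmax <- function(x) (x - min(x)) / (max(x) - min(x))

oracle_apaac <- function(seq, scale, omega, lambda) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  phi <- list(scale[, 1], scale[, 2])
  tau <- numeric(2 * lambda)
  for (d in seq_len(lambda)) {
    s1 <- 0; s2 <- 0
    for (i in seq_len(L - d)) {
      s1 <- s1 + phi[[1]][chars[i]] * phi[[1]][chars[i + d]]
      s2 <- s2 + phi[[2]][chars[i]] * phi[[2]][chars[i + d]]
    }
    tau[2 * d - 1] <- s1 / (L - d)
    tau[2 * d] <- s2 / (L - d)
  }
  f <- numeric(20)
  for (m in seq_along(AA_ALPHABET)) f[m] <- sum(chars == AA_ALPHABET[m]) / L
  denom <- 1 + omega * sum(tau)
  c(f / denom, omega * tau / denom)
}

oracle_interval_stats <- function(segment) {
  chars <- strsplit(segment, "")[[1]]
  s <- length(chars)
  out <- numeric(0)
  for (m in AA_ALPHABET) {
    alpha <- which(chars == m)
    q <- length(alpha)
    if (q == 0) {
      stats <- c(0, 0, 0, 0)
    } else if (q == 1) {
      g <- s - alpha[1]
      stats <- c(g, g, g, 1 / s)
    } else {
      g <- numeric(q - 1)
      for (tt in seq_len(q - 1)) g[tt] <- alpha[tt + 1] - alpha[tt]
      stats <- c(sum(g) / (q - 1), min(g), max(g), (length(g) + 1) / s)
    }
    out <- c(out, stats)
  }
  out
}

oracle_evolution <- function(pssm_alpha_order, thetas = 1:3) {
  a <- 1 / (1 + exp(-pssm_alpha_order))
  L <- nrow(a)
  abar <- numeric(20)
  for (w in 1:20) abar[w] <- sum(a[, w]) / L
  zs <- c()
  for (th in thetas) {
    for (w in 1:20) {
      acc <- 0
      for (i in seq_len(L - th)) {
        acc <- acc + (a[i, w] - abar[w]) * (a[i + th, w] - abar[w])
      }
      zs <- c(zs, acc / (L - th))
    }
  }
  c(zs, abar)
}

oracle_metrics <- function(tp, tn, fp, fn) {
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  c(sensitivity = sens,
    specificity = if (tn + fp > 0) tn / (tn + fp) else 0,
    precision = prec,
    f1 = if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0,
    mcc = {
      den <- sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tp + fp) * sqrt(tn + fn)
      if (den == 0) 0 else (tp * tn - fp * fn) / den
    },
    accuracy = (tp + tn) / (tp + tn + fp + fn))
}

# AUC by exhaustive pairwise comparison with half credit for ties.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  acc <- 0
  for (p in pos) for (n in neg) {
    acc <- acc + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  acc / (length(pos) * length(neg))
}

oracle_aupr <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  prev_r <- 0; area <- 0
  for (t in thr) {
    called <- scores >= t
    prec <- sum(labels[called] == 1) / sum(called)
    rec <- sum(labels[called] == 1) / sum(labels == 1)
    area <- area + (rec - prev_r) * prec
    prev_r <- rec
  }
  area
}

oracle_top_u <- function(scores, labels, u) {
  df <- data.frame(s = scores, l = labels, i = seq_along(scores))
  df <- df[order(-df$s, df$i), ]
  sum(df$l[1:u] == 1) / u
}

# Spatial sizes from layer-by-layer arithmetic.
oracle_layer_dims <- function(H = 36, W = 32, conv = 6, pool = 3) {
  dims <- list()
  shrink <- function(hw, d) hw - d + 1
  hw <- c(H, W)
  for (op in c(conv, conv, pool, conv, pool)) {
    hw <- shrink(hw, op)
    dims[[length(dims) + 1]] <- hw
  }
  dims
}
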