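# Literal, loop-based transcriptions of the model's defining formulas and
# brute-force metric implementations. These stay deliberately naive and
# independent of the vectorized package code they check.

# sim(x, y) by explicit position counting
brute_fused <- function(x, y, lambda) {
  n <- length(x)
  c_shared <- 0
  d_diff <- 0
  for (p in seq_len(n)) {
    if (x[p] == 1 && y[p] == 1) c_shared <- c_shared + 1
    if (x[p] != y[p]) d_diff <- d_diff + 1
  }
  (lambda * sqrt(c_shared) + (1 - lambda) * sqrt(d_diff)) / sqrt(n)
}

brute_similarity <- function(P, lambda) {
  n <- nrow(P)
  s <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s[i, j] <- brute_fused(P[i, ], P[j, ], lambda)
  }
  s
}

# top-k neighbor ids of row i, descending similarity, ties by ascending id
loop_neighbors <- function(sim, k, include_self = FALSE) {
  n <- nrow(sim)
  idx <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    cand <- seq_len(n)
    if (!include_self) cand <- cand[cand != i]
    # selection sort: repeatedly take the largest remaining, smallest id first
    chosen <- integer(0)
    for (t in seq_len(k)) {
      best <- cand[1L]
      for (cc in cand) if (sim[i, cc] > sim[i, best]) best <- cc
      chosen <- c(chosen, best)
      cand <- cand[cand != best]
    }
    idx[i, ] <- chosen
  }
  idx
}

# one row-filling pass, cell by cell
loop_fill_rows <- function(m, idx, sim, w, literal_ones = FALSE) {
  out <- m
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    if (m[i, j] == 0) {
      acc <- 0
      for (t in seq_len(ncol(idx))) {
        acc <- acc + m[idx[i, t], j] * sim[i, idx[i, t]] * w[t]
      }
      out[i, j] <- acc
    } else if (literal_ones) {
      out[i, j] <- 1
    }
  }
  out
}

loop_fill_cols <- function(m, idx, sim, w, literal_ones = FALSE) {
  t(loop_fill_rows(t(m), idx, sim, w, literal_ones))
}

# full multilayer prediction, loops all the way down
loop_predict <- function(y, sl, sd, k, layers, eta1 = 0.5, eta2 = 0.5,
                         include_self = FALSE) {
  kl <- loop_neighbors(sl, k, include_self)
  kd <- loop_neighbors(sd, k, include_self)
  w <- sapply(seq_len(k) - 1, function(t) 2 * (k - t) / (k * (k + 1)))
  cur <- y
  for (l in seq_len(layers)) {
    if (all(cur != 0)) break
    a <- loop_fill_rows(cur, kl, sl, w)
    b <- loop_fill_cols(cur, kd, sd, w)
    cur <- eta1 * a + eta2 * b
  }
  cur
}

# AUC as the concordant-pair fraction (ties count 1/2)
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# AUPR by walking distinct thresholds with naive recounting at each
brute_aupr <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  np <- sum(labels == 1)
  area <- 0
  prev_rec <- 0
  for (t in th) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    prec <- tp / sum(sel)
    rec <- tp / np
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

# random completion instance: binary target + valid similarity matrices
random_instance <- function(nr, nc, density = 0.3) {
  y <- matrix(rbinom(nr * nc, 1, density), nr, nc)
  rand_sim <- function(n) {
    s <- matrix(runif(n * n), n, n)
    s <- (s + t(s)) / 2
    diag(s) <- 1
    s
  }
  list(y = y, sl = rand_sim(nr), sd = rand_sim(nc))
}

# tiny coupled network fixture used across files
tiny_networks <- function(seed = 42) {
  generate_networks(synthetic_config(
    n_lnc = 40, n_mir = 15, n_dis = 20,
    latent_dim = 2, density_ld = 0.08, density_lm = 0.15, density_md = 0.15,
    seed = seed))
}

adjacency <- function(values, row_kind = "lncRNA", col_kind = "disease") {
  dmwnn:::new_adjacency(values, row_kind, col_kind)
}
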