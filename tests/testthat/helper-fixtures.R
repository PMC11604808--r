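# Fixture builders shared across the suite; everything is generated in
# code at test time.

# a minute of deterministic or random signal
make_minute <- function(start_minute = 0, n_channels = 2, sample_rate = 10,
                        fill = NULL, mask = NULL, seed = NULL) {
  nsamp <- round(60 * sample_rate)
  if (!is.null(seed)) set.seed(seed)
  data <- if (is.null(fill))
    matrix(rnorm(n_channels * nsamp), n_channels, nsamp)
  else matrix(fill, n_channels, nsamp)
  minute_record(start_minute, data, sample_rate, mask)
}

# per-gate parameter list for lstm_cell_step from concatenated matrices
split_gate_params <- function(Wx, Wh, b) {
  u <- nrow(Wh)
  blk <- function(m, k) m[, ((k - 1) * u + 1):(k * u), drop = FALSE]
  list(U = list(i = blk(Wx, 1), f = blk(Wx, 2), o = blk(Wx, 3),
                g = blk(Wx, 4)),
       W = list(i = blk(Wh, 1), f = blk(Wh, 2), o = blk(Wh, 3),
                g = blk(Wh, 4)),
       b = list(i = b[1:u], f = b[u + 1:u], o = b[2 * u + 1:u],
                g = b[3 * u + 1:u]))
}

# independent R recurrence over a sequence batch, built on
# lstm_cell_step (the oracle for the compiled path)
r_layer_forward <- function(Wx, Wh, b, x, activation = "tanh") {
  u <- nrow(Wh)
  params <- split_gate_params(Wx, Wh, b)
  B <- dim(x)[1]; T <- dim(x)[3]
  H <- array(0, c(B, u, T))
  for (bi in seq_len(B)) {
    h <- rep(0, u); cc <- rep(0, u)
    for (t in seq_len(T)) {
      st <- lstm_cell_step(x[bi, , t], h, cc, params, activation)
      h <- st$h; cc <- st$c
      H[bi, , t] <- h
    }
  }
  H
}

# brute-force AUC by concordant-pair counting with tie midpoints
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}
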