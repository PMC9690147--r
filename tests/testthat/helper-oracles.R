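# brute-force Shapley oracle: textbook permutation-average definition,
# recomputing coalition values directly from hybrid predictions; shared by
# the interpretability unit tests and the end-to-end suite
oracle_shapley <- function(model, table, background) {
  feats <- model$feature_names
  d <- length(feats)
  n <- nrow(table)
  nb <- nrow(background)
  K <- length(model$class_levels)
  value <- function(S, z_row) {
    hybrid <- background[, feats, drop = FALSE]
    for (f in feats[S]) hybrid[[f]] <- rep(table[[f]][z_row], nb)
    colMeans(predict(model, hybrid, type = "prob"))
  }
  phi <- array(0, dim = c(n, d, K))
  perms <- combinat_perms(d)
  for (z in seq_len(n)) {
    for (p in seq_len(nrow(perms))) {
      ord <- perms[p, ]
      S <- logical(d)
      v_prev <- value(S, z)
      for (j in ord) {
        S[j] <- TRUE
        v_new <- value(S, z)
        phi[z, j, ] <- phi[z, j, ] + (v_new - v_prev) / nrow(perms)
        v_prev <- v_new
      }
    }
  }
  phi
}

combinat_perms <- function(d) {
  if (d == 1) return(matrix(1))
  sub <- combinat_perms(d - 1)
  do.call(rbind, lapply(seq_len(d), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}
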