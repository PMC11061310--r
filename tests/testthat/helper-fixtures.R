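# shared small fixtures, built in code at load time

# small planted tensor used by several decomposition/screen tests
small_sim <- function(seed = 42, ...) {
  simulate_tensor(tensor_sim_params(
    n_individuals = 120, n_genes = 600, n_components = 3,
    sparsity = 0.05, seed = seed, ...))
}

# expression tensor wrapping a raw normalized-scale array (bypasses prep)
tensor_from_array <- function(z) {
  structure(z,
            individual_ids = dimnames(z)[[1]], gene_ids = dimnames(z)[[2]],
            tissue_labels = dimnames(z)[[3]],
            class = c("expression_tensor", "array"))
}

# raw tissue matrix fixture with hand-set properties
toy_tissue <- function(values, label = "CN") {
  g <- nrow(values); s <- ncol(values)
  rownames(values) <- sprintf("g%d", seq_len(g))
  colnames(values) <- sprintf("s%d", seq_len(s))
  tissue_matrix(values, label)
}

# brute-force hypergeometric upper tail by enumeration over overlap counts
enum_hyper_tail <- function(k_obs, n_target, n_universe, n_query) {
  ks <- 0:min(n_target, n_query)
  probs <- choose(n_target, ks) * choose(n_universe - n_target,
                                         n_query - ks) /
    choose(n_universe, n_query)
  sum(probs[ks >= k_obs])
}

# step-through reimplementation of the greedy unique pairing rule
greedy_oracle <- function(S) {
  dn <- rownames(S); rn <- colnames(S)
  avail <- rep(TRUE, ncol(S)); left <- seq_len(nrow(S))
  out <- NULL
  while (length(left) && any(avail)) {
    best_val <- -Inf; best_i <- NA
    for (i in left) {
      v <- max(S[i, avail])
      if (v > best_val) { best_val <- v; best_i <- i }
    }
    js <- which(avail)
    j <- js[which.max(S[best_i, js])]
    out <- rbind(out, data.frame(discovery = dn[best_i],
                                 replication = rn[j],
                                 similarity = S[best_i, j]))
    avail[j] <- FALSE
    left <- setdiff(left, best_i)
  }
  out
}
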