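# Brute-force oracles and small fixture builders shared by the tests.

# exhaustive minimum-image search over the 3^3 neighbour images
brute_min_image <- function(ri, rj, h) {
  best <- Inf
  for (a in -1:1) for (b in -1:1) for (cc in -1:1) {
    d <- ri - rj + as.numeric(h %*% c(a, b, cc))
    best <- min(best, sqrt(sum(d^2)))
  }
  best
}

# sliding-window lifetime filter: bonded at frame t iff within cutoff at
# every one of frames t-L+1 .. t
brute_lifetime_filter <- function(within_matrix, L) {
  nf <- nrow(within_matrix)
  out <- matrix(FALSE, nf, ncol(within_matrix))
  for (t in seq_len(nf)) {
    if (t < L) next
    out[t, ] <- colSums(within_matrix[(t - L + 1):t, , drop = FALSE]) == L
  }
  out
}

# standard LJ fixture: nearest-neighbour-only iron-like fcc crystal
lj_pot <- function(eps = 0.1, sigma = 2.2, cutoff = 3.2) {
  potential_model("lj", list("Fe-Fe" = c(eps = eps, sigma = sigma,
                                         cutoff = cutoff)))
}

harmonic_dimer <- function(d, k = 30, r0 = 1.0, box = 12) {
  list(frame = md_frame(c("H", "H"), rbind(c(5, 5, 5), c(5 + d, 5, 5)),
                        c(box, box, box)),
       pot = potential_model("lj", list(),
                             bonds = data.frame(i = 1, j = 2, k = k,
                                                r0 = r0)))
}

# random connected-ish bond graph over a random composition
random_bond_graph <- function(seed) {
  set.seed(seed)
  n <- sample(5:40, 1)
  el <- sample(c("H", "N", "O", "Fe"), n, replace = TRUE)
  n_edges <- sample(0:(2 * n), 1)
  edges <- if (n_edges > 0 && n >= 2) {
    cbind(sample.int(n, n_edges, replace = TRUE),
          sample.int(n, n_edges, replace = TRUE))
  } else matrix(integer(), 0, 2)
  edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  list(n = n, elements = el, edges = edges)
}
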