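# Independent numerical oracles, coded directly from the underlying physics
# definitions (kept deliberately separate from the package's implementation
# paths: plain Riemann sums and label propagation instead of cached splines
# and graph components).

oracle_constants <- list(
  K = 0.307075, me = 0.51099895,
  ions = list(proton = c(Z = 1, A = 1, m = 938.2721),
              helium = c(Z = 2, A = 4, m = 3727.379 / 4)),
  mats = list(water   = c(rho = 1.0,      I = 75,   za = 0.55509),
              pmma    = c(rho = 1.19,     I = 74,   za = 0.53937),
              air     = c(rho = 1.205e-3, I = 85.7, za = 0.49919),
              silicon = c(rho = 2.33,     I = 173,  za = 0.49848))
)

oracle_stopping <- function(ion, e_mev_u, mat) {
  k <- oracle_constants
  io <- k$ions[[ion]]; ma <- k$mats[[mat]]
  g <- 1 + e_mev_u / io[["m"]]
  b2 <- 1 - 1 / g^2
  k$K * io[["Z"]]^2 * ma[["za"]] / b2 *
    (log(2 * k$me * b2 * g^2 / (ma[["I"]] * 1e-6)) - b2)
}

# CSDA range by plain fine-step Riemann midpoint sum from the 0.5 MeV/u cutoff
oracle_range <- function(ion, e_mev_u, mat, n_steps = 20000) {
  k <- oracle_constants
  io <- k$ions[[ion]]; ma <- k$mats[[mat]]
  e <- seq(0.5, e_mev_u, length.out = n_steps + 1)
  mid <- (head(e, -1) + tail(e, -1)) / 2
  de <- diff(e)
  sum(io[["A"]] * de / (oracle_stopping(ion, mid, mat) * ma[["rho"]]))
}

# brute-force connected components of one frame's hit list by iterative
# minimum-label propagation over the full pairwise adjacency
oracle_components <- function(col, row, connectivity = 8) {
  n <- length(col)
  if (n == 0) return(integer(0))
  dx <- abs(outer(col, col, "-"))
  dy <- abs(outer(row, row, "-"))
  adj <- if (connectivity == 8) pmax(dx, dy) <= 1 else dx + dy <= 1
  lab <- seq_len(n)
  repeat {
    new <- vapply(seq_len(n), function(i) min(lab[adj[i, ]]), 1L)
    if (all(new == lab)) break
    lab <- new
  }
  lab
}

# canonical partition signature: each pixel tagged with the smallest
# (col,row) key of its component, sorted
partition_signature <- function(col, row, membership) {
  key <- col * 256 + row
  rep_key <- stats::ave(key, membership, FUN = min)
  sort(paste(key, rep_key))
}

bhattacharyya_overlap <- function(a, b, n_breaks = 60) {
  br <- seq(min(a, b) - 1e-9, max(a, b) + 1e-9, length.out = n_breaks)
  pa <- hist(a, breaks = br, plot = FALSE)$counts / length(a)
  pb <- hist(b, breaks = br, plot = FALSE)$counts / length(b)
  sum(sqrt(pa * pb))
}
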