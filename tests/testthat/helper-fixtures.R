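# Shared fixtures, built once per test run.

toy_tree <- make_toy_taxonomy()
toy_panel <- make_reference_panel(toy_tree, seq_len = 1000, seed = 101)

# quick lookup: name -> taxid
tax_of <- setNames(toy_tree$nodes$taxid, toy_tree$nodes$name)

# Brute-force LCA oracle: intersect explicit root paths, take maximal depth.
lca_oracle <- function(tree, taxids) {
  paths <- lapply(taxids, function(t) root_path(tree, t))
  common <- Reduce(intersect, paths)
  depths <- vapply(common, function(t) length(root_path(tree, t)), integer(1))
  common[which.max(depths)]
}

# Full (unbanded) quadratic DP oracle for semi-global edit distance:
# best alignment of `read` against any window of `ref`, one strand.
semiglobal_oracle <- function(read, ref) {
  r <- strsplit(read, "")[[1]]
  f <- strsplit(ref, "")[[1]]
  m <- length(r); n <- length(f)
  prev <- 0:m
  best <- m
  for (j in seq_len(n)) {
    cur <- numeric(m + 1)
    cur[1] <- 0
    for (i in seq_len(m)) {
      cur[i + 1] <- min(prev[i] + (r[i] != f[j]),
                        cur[i] + 1, prev[i + 1] + 1)
    }
    best <- min(best, cur[m + 1])
    prev <- cur
  }
  best
}

# a small simulated library most tests can share
shared_sim <- local({
  cfg <- sim_config(
    seed = 202, n_reads = 1500,
    mixture = c("30" = 0.5, "31" = 0.3, "39" = 0.2),
    damage_d1 = 0.1, dup_frac = 0.1, lowcomplex_frac = 0.02
  )
  simulate_library(cfg, toy_panel)
})
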