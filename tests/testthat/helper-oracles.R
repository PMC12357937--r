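# Independent oracles and small builders used across the suite.

## Brute-force Dollo oracle: minimal loss count over all internal-state
## assignments with exactly one origin (either the root is 1 with no 0->1
## edge, or exactly one 0->1 edge exists).  Exponential in internal nodes;
## used only on trees with <= 8 leaves.
dollo_oracle_losses <- function(tr, tip_states) {
  ntip <- ape::Ntip(tr)
  nint <- tr$Nnode
  leaf <- as.integer(tip_states[tr$tip.label])
  best <- Inf
  for (mask in 0:(2^nint - 1)) {
    st <- c(leaf, as.integer(intToBits(mask))[seq_len(nint)])
    gains_edges <- sum(st[tr$edge[, 1]] == 0 & st[tr$edge[, 2]] == 1)
    origins <- gains_edges + (st[ntip + 1] == 1)
    if (origins != 1) next
    losses <- sum(st[tr$edge[, 1]] == 1 & st[tr$edge[, 2]] == 0)
    best <- min(best, losses)
  }
  best
}

## Brute-force tandem period oracle: for every k, exhaustively score all
## segments of the shifted-match indicator with length >= k by
## (matches - thr * length); report the k with the best positive score,
## ties to the smallest k.  Quadratic; for short sequences only.
tandem_oracle_unit <- function(seq, min_unit = 5, max_unit = 100,
                               thr = 0.8) {
  ch <- strsplit(tolower(seq), "")[[1]]
  n <- length(ch)
  best_k <- NULL
  best_excess <- 0
  for (k in seq(min_unit, min(max_unit, n %/% 2))) {
    m <- as.integer(ch[seq_len(n - k)] == ch[(k + 1):n])
    nm <- length(m)
    for (i in seq_len(nm)) {
      run <- 0
      for (j in i:nm) {
        run <- run + m[j]
        len <- j - i + 1
        if (len < k) next
        excess <- run - thr * len
        if (excess > best_excess + 1e-9) {
          best_excess <- excess
          best_k <- k
        }
      }
    }
  }
  best_k
}

rc <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))[1]

random_seq <- function(n, alphabet = c("a", "c", "g", "t"))
  paste(sample(alphabet, n, replace = TRUE), collapse = "")

## a random rooted binary tree with unit-free branch lengths
random_tree <- function(n) ape::rtree(n)

## replay a truth log along the path from the root to a leaf; returns the
## character ids present at that leaf
replay_truth_to_leaf <- function(sim, leaf) {
  tr <- sim$tree
  ntip <- ape::Ntip(tr)
  path <- character(0)
  node <- match(leaf, tr$tip.label)
  repeat {
    lbl <- c(tr$tip.label, tr$node.label)[node]
    path <- c(lbl, path)
    parent <- tr$edge[tr$edge[, 2] == node, 1]
    if (!length(parent)) break
    node <- parent
  }
  present <- character(0)
  for (lbl in path) {
    g <- sim$truth$characters[sim$truth$characters$child == lbl, "character"]
    present <- union(present, g)
    l <- sim$truth$losses[sim$truth$losses$child == lbl, "character"]
    present <- setdiff(present, l)
  }
  present
}
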