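## shared fixtures and independent oracles, built in code at test time

## small named interactome from an edge string like "A-B B-C"
toy_net <- function(edge_str, extra_nodes = character(0)) {
  pairs <- strsplit(strsplit(edge_str, "[ ]+")[[1]], "-")
  em <- do.call(rbind, pairs)
  new_interactome(sort(unique(c(em, extra_nodes))), em)
}

## two k-cliques joined by a single bridge edge
two_clique_net <- function(k = 5) {
  e <- c()
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    e <- c(e, sprintf("a%d-a%d", i, j), sprintf("b%d-b%d", i, j))
  }
  toy_net(paste(c(e, "a1-b1"), collapse = " "))
}

complete_net <- function(n, prefix = "n") {
  e <- c()
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
    e <- c(e, sprintf("%s%d-%s%d", prefix, i, prefix, j))
  toy_net(paste(e, collapse = " "))
}

star_net <- function(leaves = 5) {
  toy_net(paste(sprintf("hub-L%d", seq_len(leaves)), collapse = " "))
}

## independent BFS influence oracle (neighbour-list expansion, no igraph)
influence_oracle <- function(net, lambda = 0.5, depth = 3) {
  nodes <- net$nodes
  adj <- lapply(nodes, function(v) {
    e <- net$edges
    unique(c(e[e[, 1] == v, 2], e[e[, 2] == v, 1]))
  })
  names(adj) <- nodes
  sapply(nodes, function(v) {
    dist <- setNames(rep(Inf, length(nodes)), nodes)
    dist[v] <- 0
    frontier <- v
    d <- 0
    while (length(frontier) && d < depth) {
      d <- d + 1
      nxt <- setdiff(unique(unlist(adj[frontier])), names(dist)[dist < Inf])
      dist[nxt] <- d
      frontier <- nxt
    }
    sum(lambda^dist[is.finite(dist)])
  })
}

## exhaustive permutation enumerator (iterative heap-style, independent of
## the package's recursive generator)
perm_enumerate <- function(n) {
  out <- matrix(1L, 1, 1)
  for (k in 2:n) {
    blocks <- lapply(seq_len(k), function(pos) {
      cbind(out[, seq_len(pos - 1L), drop = FALSE], k,
            if (pos <= k - 1) out[, pos:(k - 1L), drop = FALSE])
    })
    out <- do.call(rbind, blocks)
  }
  out
}

## exact two-sided Spearman permutation p-value oracle
spearman_perm_oracle <- function(x, y) {
  n <- length(x)
  perms <- perm_enumerate(n)
  rx <- rank(x); ry <- rank(y)
  obs <- cor(rx, ry)
  rho <- apply(perms, 1, function(p) cor(rx, ry[p]))
  mean(abs(rho) >= abs(obs) - 1e-12)
}

## brute-force Kruskal-Wallis H with midrank tie correction
kw_oracle <- function(y, g) {
  g <- factor(g)
  n <- length(y)
  r <- rank(y)
  h <- 12 / (n * (n + 1)) * sum(tapply(r, g, sum)^2 / table(g)) - 3 * (n + 1)
  ties <- table(y)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

## hypergeometric upper-tail by exhaustive enumeration of draws
hyper_oracle <- function(nA, nB, k, N) {
  draws <- combn(N, nB)
  mean(colSums(draws <= nA) >= k)
}

## a small deterministic cohort for classification tests
toy_cohort <- function(seed = 1, n_genes = 300) {
  n_genes <- max(n_genes, 80)
  gi <- generate_interactome(60, rep(10, 3), 0.55, 0.001, seed = seed)
  truth <- synthetic_truth(names(gi$membership)[gi$membership > 0],
                           bio_r2 = 0.3, seed = seed)
  co <- generate_cohort(truth, gi$interactome,
                        n_per_condition = c(GHD = 40, TS = 24),
                        n_genes_expressed = n_genes, seed = seed)
  list(gi = gi, truth = truth, expression = co$expression,
       phenotype = co$phenotype)
}

tiny_config <- function(...) {
  netsig_config(
    n_genes_interactome = 200, module_sizes = rep(10, 3),
    n_per_condition = c(GHD = 30, TS = 20), n_genes_expressed = 600,
    n_markers = 60, n_ld_blocks = 40, n_methyl_genes = 300,
    n_methyl_associated = 80, rf_trees = 100, boruta_perms = 20, ...)
}
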